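#' Read an expression matrix from TSV or GCT
#'
#' TSV format: header row of sample ids, first column of row ids, numeric
#' body. GCT 1.2: the standard `#1.2` / dimensions / `Name  Description`
#' layout; the `Description` column is kept as the probe-to-gene mapping.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return an [expression_matrix()]; row and column order are preserved.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || !startsWith(lines[[1]], "#1.2"))
      stop2("not a GCT 1.2 file: ", path)
    body <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(body[[1]])
    desc <- as.character(body[[2]])
    vals <- body[, -(1:2), drop = FALSE]
    map <- stats::setNames(desc, ids)
  } else {
    body <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
    ids <- as.character(body[[1]])
    vals <- body[, -1, drop = FALSE]
    map <- NULL
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop2("duplicate row id: '", dup[[1]], "' in ", path)
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop2("non-numeric value '", col[bad[[1]]], "' at row '",
              ids[bad[[1]]], "', column '", names(vals)[j], "' in ", path)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, probe_to_gene = map)
}

#' Write an expression matrix
#'
#' @param x an [expression_matrix()] (or plain named matrix).
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  x <- as_expression_matrix(x)
  if (format == "gct") {
    map <- attr(x, "probe_to_gene")
    desc <- if (is.null(map)) rownames(x) else
      ifelse(rownames(x) %in% names(map), map[rownames(x)], rownames(x))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    df <- data.frame(Name = rownames(x), Description = desc,
                     as.data.frame(unclass(x)), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a network to SIF, weighted edge TSV, or GraphML
#'
#' SIF lines are `A <tab> pp <tab> B`, one per undirected edge with the
#' lexicographically smaller node first; the edge TSV adds a `score`
#' column; GraphML (via igraph) embeds the node attributes. A companion
#' node-attribute TSV (`<path>.nodes.tsv`: node, degree, direction, style
#' color) is always written.
#'
#' @param net a [gene_network()].
#' @param path output path.
#' @param format one of `"sif"`, `"edge_tsv"`, `"graphml"`.
#' @return invisibly, the main output path.
#' @export
write_network <- function(net, path, format = c("sif", "edge_tsv", "graphml")) {
  if (length(format) == 1 && !format %in% c("sif", "edge_tsv", "graphml"))
    stop2("unknown network format '", format, "'")
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$from, "pp", e$to, sep = "\t")
               else character(), path)
  } else if (format == "edge_tsv") {
    utils::write.table(e[, c("from", "to", "score")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  attrs <- net$node_attrs
  attrs$style <- de_style_color(attrs$direction)
  utils::write.table(attrs, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# node fill colors following the convention for case-control overlays:
# suppressed genes olive-green, elevated white, unchanged pink
de_style_color <- function(direction) {
  c(down = "olive-green", up = "white", unchanged = "pink",
    unknown = "grey")[direction]
}

#' Read a weighted edge TSV back into a network
#' @param path file written by [write_network()] with format `edge_tsv`.
#' @param threshold,mode recorded on the resulting network.
#' @return a [gene_network()].
#' @export
read_network_edges <- function(path, threshold = NA_real_, mode = "file") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "score") %in% names(df)))
  gene_network(df, threshold = threshold, mode = mode)
}

#' Read gene sets in GMT format
#'
#' GMT dialect: one set per line, tab-separated: name, description, then
#' members.
#'
#' @param path GMT file.
#' @return a list of class `gene_set_collection`: named list of character
#'   vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop2("empty gene set '", parts[[1]], "' rejected")
    name <- parts[[1]]
    if (name %in% names(sets)) stop2("duplicate set name: '", name, "'")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop2("empty gene set '", name, "' rejected")
    if (anyDuplicated(members))
      stop2("duplicate member '", members[duplicated(members)][[1]],
            "' in set '", name, "'")
    sets[[name]] <- members
    descs[[name]] <- parts[[2]]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (or a `gene_set_collection`).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- cytogenetic band parsing --------------------------------------------

# A band label like "33.1" is a point; "33" without a sub-band spans all of
# major band 33 (33.0 up to but not including 34). Numeric encoding:
# lo = value, hi = value for explicit sub-bands; [major, major + .999...]
# for bare major bands.
BAND_MAJOR_SPAN <- 0.9999

parse_band_token <- function(tok, context = tok) {
  tok <- trimws(tok)
  m <- regmatches(tok, regexec("^(?:([0-9XY]+)?([pq]))?([0-9]+(?:\\.[0-9]+)?)$",
                               tok))[[1]]
  if (!length(m)) stop2("unparseable band token '", tok, "' in '", context, "'")
  chrom <- m[[2]]
  arm <- m[[3]]
  num <- as.numeric(m[[4]])
  has_minor <- grepl(".", m[[4]], fixed = TRUE)
  list(chrom = if (nzchar(chrom)) chrom else NA_character_,
       arm = if (nzchar(arm)) arm else NA_character_,
       lo = num, hi = if (has_minor) num else num + BAND_MAJOR_SPAN)
}

#' Parse a cytogenetic band or band-range label
#'
#' Accepts labels like `"2q33.1"`, `"2p13"`, and ranges `"2q36-37"`,
#' `"2q32.3-q33"`, `"2q33.3-2q37.2"` with en-dash or hyphen. A bare major
#' band (no sub-band digit) spans all of its sub-bands, so `"2q33-34"`
#' contains `2q33.3`.
#'
#' @param label band or range string.
#' @return list with `chrom`, `arm`, `lo`, `hi` (numeric band interval).
#' @export
parse_band <- function(label) {
  raw <- label
  lab <- gsub("–|—", "-", trimws(label))
  parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
  if (!length(parts) || length(parts) > 2)
    stop2("unparseable band label '", raw, "'")
  a <- parse_band_token(parts[[1]], raw)
  if (is.na(a$chrom) || is.na(a$arm))
    stop2("band label '", raw, "' lacks a chromosome/arm prefix")
  if (length(parts) == 2) {
    b <- parse_band_token(parts[[2]], raw)
    if (!is.na(b$chrom) && b$chrom != a$chrom)
      stop2("band range '", raw, "' crosses chromosomes")
    if (!is.na(b$arm) && b$arm != a$arm)
      stop2("band range '", raw, "' crosses arms")
    if (b$lo < a$lo)
      stop2("band range '", raw, "' is not ordered (start > end)")
    hi <- b$hi
  } else {
    hi <- a$hi
  }
  list(chrom = a$chrom, arm = a$arm, lo = a$lo, hi = hi)
}

#' Build a cytoband map from gene location strings
#' @param genes character vector of gene symbols.
#' @param locations character vector of band labels (see [parse_band()]).
#' @return data.frame of class `cytoband_map`: gene, chrom, arm, lo, hi.
#' @export
cytoband_map <- function(genes, locations) {
  stopifnot(length(genes) == length(locations))
  parsed <- lapply(locations, parse_band)
  out <- data.frame(
    gene = as.character(genes),
    chrom = vapply(parsed, `[[`, character(1), "chrom"),
    arm = vapply(parsed, `[[`, character(1), "arm"),
    lo = vapply(parsed, `[[`, numeric(1), "lo"),
    hi = vapply(parsed, `[[`, numeric(1), "hi"),
    label = as.character(locations),
    stringsAsFactors = FALSE)
  dup <- out$gene[duplicated(out$gene)]
  if (length(dup)) stop2("duplicate gene in cytoband map: '", dup[[1]], "'")
  class(out) <- c("cytoband_map", class(out))
  out
}

#' Read a gene cytoband table
#'
#' Four-column TSV with header: gene, chromosome, band_start, band_end.
#' Band columns may carry arm-prefixed (`q33.1`) or full (`2q33.1`)
#' labels; band_end may be empty or equal to band_start for point bands.
#'
#' @param path TSV path.
#' @return a [cytoband_map()].
#' @export
read_cytobands <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 4) stop2("cytoband table needs 4 columns in ", path)
  labels <- ifelse(!nzchar(df[[4]]) | df[[4]] == df[[3]],
                   paste0(df[[2]], df[[3]]),
                   paste0(df[[2]], df[[3]], "-", df[[4]]))
  # tolerate band columns already carrying the chromosome prefix
  labels <- ifelse(grepl("^[0-9XY]+[pq]", df[[3]]),
                   ifelse(!nzchar(df[[4]]) | df[[4]] == df[[3]],
                          df[[3]], paste0(df[[3]], "-", df[[4]])),
                   labels)
  cytoband_map(df[[1]], labels)
}

#' Read a UCSC cytoBand.txt band dictionary
#'
#' Five columns, no header: chrom, start, end, band name (e.g. `q33.1`),
#' Giemsa stain. Returned as a plain data.frame usable as a band
#' dictionary; gene placement still comes from [read_cytobands()].
#'
#' @param path cytoBand.txt path (uncompressed).
#' @return data.frame: chrom, start, end, band, stain.
#' @export
read_ucsc_cytoband <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop2("not a UCSC cytoBand file: ", path)
  names(df) <- c("chrom", "start", "end", "band", "stain")
  df
}

#' Read a protein-to-domain annotation table
#' @param path two-column TSV with header: protein, domain.
#' @return named list mapping protein to its (unique) domain vector.
#' @export
read_domains <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop2("domain table needs 2 columns in ", path)
  split(df[[2]], df[[1]]) |> lapply(unique)
}

#' Read an observed protein-interaction table
#' @param path three-column TSV with header: proteinA, proteinB,
#'   observed (0/1).
#' @return data.frame: a, b, observed.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop2("interaction table needs 3 columns in ", path)
  out <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                    observed = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(!out$observed %in% c(0L, 1L)))
    stop2("observed column must be 0/1 in ", path)
  out
}

#' Write an observed protein-interaction table
#' @param interactions data.frame as returned by [read_interactions()].
#' @param path output path.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a protein-to-domain table
#' @param domains named list protein -> domain vector.
#' @param path output path.
#' @export
write_domains <- function(domains, path) {
  df <- data.frame(protein = rep(names(domains), lengths(domains)),
                   domain = unlist(domains, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
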