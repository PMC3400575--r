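# Results-side integration: consensus between networks, hub ranking,
# differential-expression overlay, neighbor queries, gene-set
# sub-networking, and susceptibility-locus overlap.

#' Consensus direct neighbors between two networks
#'
#' For each queried gene, the direct neighbor sets in each network, their
#' intersection, and the "k/n" proportions (shared over per-network
#' neighbor count).
#'
#' @param netA,netB [gene_network()] objects.
#' @param genes character vector of genes to report.
#' @return data.frame of class `consensus_report`: gene, n_A, n_B,
#'   n_shared, prop_A ("k/nA"), prop_B, shared (comma-separated sorted
#'   list). Genes absent from both networks are reported with zero counts
#'   and a warning.
#' @export
consensus_neighbors <- function(netA, netB, genes) {
  rows <- lapply(genes, function(g) {
    inA <- g %in% netA$nodes
    inB <- g %in% netB$nodes
    if (!inA && !inB)
      warn2("gene '", g, "' absent from both networks")
    na_ <- if (inA) network_neighbors(netA, g) else character()
    nb_ <- if (inB) network_neighbors(netB, g) else character()
    shared <- sort(intersect(na_, nb_))
    data.frame(gene = g, n_A = length(na_), n_B = length(nb_),
               n_shared = length(shared),
               prop_A = sprintf("%d/%d", length(shared), length(na_)),
               prop_B = sprintf("%d/%d", length(shared), length(nb_)),
               shared = paste(shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("consensus_report", class(out))
  out
}

#' Rank genes by connectedness (degree)
#'
#' Degree is the hub measure; ties are broken lexicographically.
#'
#' @param net a [gene_network()].
#' @param top_k how many genes to return (default all).
#' @return data.frame: gene, degree, sorted by degree descending.
#' @export
hub_rank <- function(net, top_k = Inf) {
  if (!length(net$nodes)) stop2("empty network")
  a <- net$node_attrs
  a <- a[order(-a$degree, a$node), , drop = FALSE]
  out <- data.frame(gene = a$node, degree = a$degree,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, n = min(top_k, nrow(out)))
}

#' Overlay differential-expression directions onto network nodes
#'
#' Every node is annotated `up`, `down`, `unchanged`, or `unknown` (not in
#' the DE result). The conventional fill colors (suppressed olive-green,
#' elevated white, unchanged pink) are written as a style column whenever
#' the network is exported. Applying the overlay twice is idempotent.
#'
#' @param net a [gene_network()].
#' @param de a `de_result` (possibly probe-collapsed).
#' @return the network with updated `node_attrs$direction`.
#' @export
overlay_de <- function(net, de) {
  dir <- stats::setNames(de$direction, de$id)
  hit <- net$node_attrs$node %in% names(dir)
  net$node_attrs$direction <- ifelse(hit, dir[net$node_attrs$node],
                                     "unknown")
  net
}

#' Genes reachable with at most k intervening nodes
#'
#' Returns all genes connected to `gene` by a path with at most
#' `max_intervening` interior nodes (0 = direct neighbors, 1 or 2 = one or
#' two intervening nodes), each with one shortest witnessing path.
#'
#' @param net a [gene_network()].
#' @param gene query node (must be present).
#' @param max_intervening 0, 1 or 2 (larger values allowed).
#' @return data.frame: gene, distance, path (witness as
#'   "a -> b -> c" string).
#' @export
neighbors_within <- function(net, gene, max_intervening = 1) {
  if (!gene %in% net$nodes) stop2("gene '", gene, "' not in network")
  g <- as_igraph(net)
  d <- igraph::distances(g, v = gene)[1, ]
  reach <- names(d)[d >= 1 & d <= max_intervening + 1]
  if (!length(reach))
    return(data.frame(gene = character(), distance = integer(),
                      path = character(), stringsAsFactors = FALSE))
  paths <- igraph::shortest_paths(g, from = gene, to = reach)$vpath
  out <- data.frame(
    gene = reach,
    distance = as.integer(d[reach]),
    path = vapply(paths, function(p) paste(names(p), collapse = " -> "),
                  character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict an expression matrix to the union of named gene sets
#'
#' @param X an [expression_matrix()].
#' @param sets a `gene_set_collection` from [read_gene_sets()] or a named
#'   list of character vectors.
#' @param names which sets to use.
#' @return the row-restricted [expression_matrix()]; attribute
#'   `set_hits` records per-set hit counts. Errors if no member of any
#'   named set is present.
#' @export
subnetwork_by_sets <- function(X, sets, names) {
  X <- as_expression_matrix(X)
  missing <- setdiff(names, base::names(sets))
  if (length(missing)) stop2("unknown gene set '", missing[[1]], "'")
  members <- unique(unlist(sets[names], use.names = FALSE))
  present <- intersect(rownames(X), members)
  if (!length(present)) stop2("no gene of the named sets is in the matrix")
  hits <- vapply(names, function(nm) {
    sum(sets[[nm]] %in% rownames(X))
  }, integer(1))
  out <- expression_matrix(unclass(X)[rownames(X) %in% members, ,
                                      drop = FALSE],
                           probe_to_gene = attr(X, "probe_to_gene"))
  attr(out, "set_hits") <- stats::setNames(hits, names)
  out
}

#' Classify hub-neighbor genes against a susceptibility locus
#'
#' A gene is `inside` if its band interval intersects the locus interval;
#' `bordering` if it intersects the locus expanded to whole major bands at
#' each end (for locus 2q33.3-2q37.2 the border zone is all of 2q33
#' through all of 2q37) but not the locus itself; otherwise `outside`.
#' Genes on other chromosomes or arms are `outside`; genes missing from
#' the band map are `unknown` (with a warning).
#'
#' @param rows data.frame with columns `hub` and `gene`.
#' @param bands a [cytoband_map()].
#' @param locus locus band-range string, e.g. `"2q33.3-2q37.2"`.
#' @return data.frame of class `locus_overlap`: hub, gene, location,
#'   classification; attribute `locus`.
#' @export
locus_overlap <- function(rows, bands, locus) {
  loc <- parse_band(locus)
  border_lo <- floor(loc$lo)
  border_hi <- floor(loc$hi) + BAND_MAJOR_SPAN
  idx <- match(rows$gene, bands$gene)
  classification <- character(nrow(rows))
  location <- character(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    i <- idx[r]
    if (is.na(i)) {
      warn2("gene '", rows$gene[r], "' missing from band map")
      classification[r] <- "unknown"
      location[r] <- NA_character_
      next
    }
    b <- bands[i, ]
    location[r] <- b$label
    if (b$chrom != loc$chrom || b$arm != loc$arm) {
      classification[r] <- "outside"
    } else if (b$lo <= loc$hi && b$hi >= loc$lo) {
      classification[r] <- "inside"
    } else if (b$lo <= border_hi && b$hi >= border_lo) {
      classification[r] <- "bordering"
    } else {
      classification[r] <- "outside"
    }
  }
  out <- data.frame(hub = rows$hub, gene = rows$gene, location = location,
                    classification = classification,
                    stringsAsFactors = FALSE)
  attr(out, "locus") <- locus
  class(out) <- c("locus_overlap", class(out))
  out
}
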