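#' Construct a validated expression matrix
#'
#' The common currency of the pipeline: a real-valued genes-by-samples
#' matrix with unique row (probe set or gene) and column (sample)
#' identifiers, plus an optional probe-to-gene mapping used by
#' [collapse_probes()].
#'
#' @param values numeric matrix; rows are probe sets or genes, columns are
#'   samples. Must have unique, non-empty dimnames and only finite values.
#' @param probe_to_gene optional named character vector mapping row ids to
#'   gene symbols.
#' @return a numeric matrix of class `expr_matrix` carrying the mapping as
#'   an attribute.
#' @export
expression_matrix <- function(values, probe_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  rid <- rownames(values)
  cid <- colnames(values)
  if (is.null(rid) || is.null(cid) || any(!nzchar(rid)) || any(!nzchar(cid)))
    stop2("expression matrix needs non-empty row and column ids")
  dup <- rid[duplicated(rid)]
  if (length(dup)) stop2("duplicate row id: '", dup[[1]], "'")
  dup <- cid[duplicated(cid)]
  if (length(dup)) stop2("duplicate column id: '", dup[[1]], "'")
  if (any(!is.finite(values)))
    stop2("expression values must all be finite")
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop2("`probe_to_gene` must be a named character vector")
    probe_to_gene <- probe_to_gene[names(probe_to_gene) %in% rid]
  }
  structure(values, probe_to_gene = probe_to_gene,
            class = c("expr_matrix", class(values)))
}

as_expression_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) x else expression_matrix(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d rows x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a scored gene network
#'
#' An undirected network over gene symbols with a real score per edge
#' (mutual information, CLR likelihood, ...), the threshold that produced
#' the edge set, and per-node attributes (degree, differential-expression
#' direction).
#'
#' @param edges data.frame with columns `from`, `to`, `score`. Self-edges
#'   are rejected; each undirected pair is stored once with the
#'   lexicographically smaller node first.
#' @param nodes optional character vector of node ids (defaults to the ids
#'   appearing in `edges`). Isolated nodes are allowed.
#' @param threshold the score threshold the edge set was produced at.
#' @param mode free-text label of how the threshold was chosen.
#' @return an object of class `gene_network` with elements `nodes`,
#'   `edges`, `node_attrs`, `threshold`, `mode`.
#' @export
gene_network <- function(edges, nodes = NULL, threshold = NA_real_,
                         mode = "manual") {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to))
    stop2("self-edges are not allowed in a thresholded network")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  node_attrs <- data.frame(node = nodes,
                           degree = as.integer(deg),
                           direction = rep("unknown", length(nodes)),
                           stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, node_attrs = node_attrs,
                 threshold = threshold, mode = mode),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges (threshold %s, mode %s)\n",
              length(x$nodes), nrow(x$edges),
              format(x$threshold), x$mode))
  invisible(x)
}

#' Neighbors of a gene in a network
#' @param net a [gene_network()].
#' @param gene node id.
#' @return character vector of direct neighbors (sorted).
#' @export
network_neighbors <- function(net, gene) {
  e <- net$edges
  sort(unique(c(e$to[e$from == gene], e$from[e$to == gene])))
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "score")],
    directed = FALSE,
    vertices = net$node_attrs[, c("node", "degree", "direction")])
  g
}

#' Union of two scored gene networks
#'
#' Edge union; where both networks carry the same edge the maximum score is
#' kept and the edge is flagged in the `merged_max_score` column.
#'
#' @param netA,netB [gene_network()] objects.
#' @return a `gene_network`; its `edges` carry a logical
#'   `merged_max_score` column marking score conflicts resolved by max.
#' @export
union_networks <- function(netA, netB) {
  ea <- netA$edges
  eb <- netB$edges
  key_a <- paste(ea$from, ea$to, sep = "\r")
  key_b <- paste(eb$from, eb$to, sep = "\r")
  both <- intersect(key_a, key_b)
  all_edges <- rbind(ea[, c("from", "to", "score")],
                     eb[!(key_b %in% key_a), c("from", "to", "score")])
  key <- paste(all_edges$from, all_edges$to, sep = "\r")
  conflict <- key %in% both
  if (length(both)) {
    sb <- stats::setNames(eb$score, key_b)
    idx <- which(conflict)
    all_edges$score[idx] <- pmax(all_edges$score[idx], sb[key[idx]],
                                 na.rm = TRUE)
  }
  net <- gene_network(all_edges,
                      nodes = union(netA$nodes, netB$nodes),
                      threshold = min(netA$threshold, netB$threshold),
                      mode = "union")
  key2 <- paste(net$edges$from, net$edges$to, sep = "\r")
  net$edges$merged_max_score <- key2 %in% both
  net
}
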