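# Two-group differential expression with Benjamini-Hochberg control and
# median probe-set collapsing.

#' Two-group differential expression (Welch test, BH step-up)
#'
#' Per-row Welch unequal-variance t-test between the case and control
#' groups, Benjamini-Hochberg adjustment across rows, and a direction call:
#' a row is `up`/`down` only if p <= `p_cut` AND q <= `fdr_cut` (the
#' reference thresholds are 0.01 and 0.01), with the sign taken from
#' (case mean - control mean); otherwise `unchanged`.
#'
#' @param X an [expression_matrix()] (assumed on a log-like scale).
#' @param groups vector over columns with exactly two levels.
#' @param case which level is the case group (default: the level that is
#'   not the first sorted level is chosen via `setdiff`; pass explicitly
#'   for clarity).
#' @param p_cut,fdr_cut significance thresholds.
#' @return data.frame of class `de_result`: id, mean_expr, lfc, t, df, p,
#'   q, direction; attribute `thresholds`.
#' @export
two_group_de <- function(X, groups, case = NULL, p_cut = 0.01,
                         fdr_cut = 0.01) {
  X <- as_expression_matrix(X)
  groups <- as.character(groups)
  if (length(groups) != ncol(X))
    stop2("`groups` must label every column")
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop2("need exactly two groups")
  if (is.null(case)) case <- if ("case" %in% lev) "case" else lev[2]
  if (!case %in% lev) stop2("unknown case level '", case, "'")
  ctrl <- setdiff(lev, case)
  i1 <- groups == case
  i2 <- groups == ctrl
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 3 || n2 < 3) stop2("both groups need >= 3 samples")
  M <- unclass(X)
  m1 <- rowMeans(M[, i1, drop = FALSE])
  m2 <- rowMeans(M[, i2, drop = FALSE])
  v1 <- rowSums((M[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((M[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1  # zero-variance identical rows
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(p <= p_cut & q <= fdr_cut,
                      ifelse(m1 > m2, "up", "down"), "unchanged")
  out <- data.frame(id = rownames(M), mean_expr = rowMeans(M),
                    lfc = m1 - m2, t = tstat, df = df, p = p, q = q,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(p = p_cut, fdr = fdr_cut)
  class(out) <- c("de_result", class(out))
  out
}

# index of the median-rank element; even counts take the lower middle
median_rank_index <- function(k) ceiling(k / 2)

#' Collapse probe sets to genes by the median-expression probe
#'
#' For each gene the probe sets are ranked by mean expression across
#' samples and the probe of median rank is selected (lower of the two
#' middles for even counts); that probe's statistics (or expression row)
#' represent the gene. Genes with zero probes are absent from the output;
#' collapsing an already gene-level result (identity mapping) is the
#' identity.
#'
#' @param x a `de_result` from [two_group_de()] or an
#'   [expression_matrix()].
#' @param probe_to_gene named character vector probe id -> gene symbol;
#'   defaults to the matrix's own mapping for expression input.
#' @return same class as the input, with one row per gene (ids replaced by
#'   gene symbols; a `probe` column records the selected probe for DE
#'   results).
#' @export
collapse_probes <- function(x, probe_to_gene = NULL) {
  if (inherits(x, "de_result")) {
    if (is.null(probe_to_gene)) stop2("need `probe_to_gene` for a DE result")
    keep <- x$id %in% names(probe_to_gene)
    df <- x[keep, , drop = FALSE]
    gene <- probe_to_gene[df$id]
    sel <- unlist(lapply(split(seq_len(nrow(df)), gene), function(rows) {
      ord <- rows[order(df$mean_expr[rows], df$id[rows])]
      ord[median_rank_index(length(ord))]
    }))
    out <- df[sel, , drop = FALSE]
    out$probe <- out$id
    out$id <- probe_to_gene[out$probe]
    out <- out[order(out$id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "thresholds") <- attr(x, "thresholds")
    class(out) <- class(x)
    return(out)
  }
  X <- as_expression_matrix(x)
  probe_to_gene <- probe_to_gene %||% attr(X, "probe_to_gene")
  if (is.null(probe_to_gene)) stop2("no probe-to-gene mapping available")
  keep <- rownames(X) %in% names(probe_to_gene)
  M <- unclass(X)[keep, , drop = FALSE]
  gene <- probe_to_gene[rownames(M)]
  means <- rowMeans(M)
  sel <- unlist(lapply(split(seq_len(nrow(M)), gene), function(rows) {
    ord <- rows[order(means[rows], rownames(M)[rows])]
    ord[median_rank_index(length(ord))]
  }))
  out <- M[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out)
}
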