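# Context-likelihood (CLR) scoring and data-processing-inequality (DPI)
# pruning of mutual-information matrices.

#' CLR background-corrected scores
#'
#' For each gene the background is its empirical row of MI values
#' (excluding self). The pair score combines the two positive-part
#' z-scores: f(X_z, Y_z) = sqrt(max(0, X_z)^2 + max(0, Y_z)^2). A gene
#' whose background has zero variance contributes z = 0 and is flagged.
#'
#' @param mi an [mi_matrix()] (full or regulator-restricted).
#' @return object of class `clr_scores`: list with `scores` (symmetric
#'   matrix, `NA` where MI was not computed), `bg_mean`, `bg_sd`,
#'   `flagged` (zero-variance genes), and the MI estimator attributes.
#' @export
clr_scores <- function(mi) {
  stopifnot(is.matrix(mi))
  G <- nrow(mi)
  if (G < 3) stop2("need at least 3 genes")
  genes <- rownames(mi)
  M <- unclass(mi)
  diag(M) <- NA_real_  # self-information is not part of the background
  bg_mean <- apply(M, 1, mean, na.rm = TRUE)
  bg_sd <- apply(M, 1, stats::sd, na.rm = TRUE)
  flagged <- genes[is.na(bg_sd) | bg_sd == 0]
  sd_safe <- ifelse(is.na(bg_sd) | bg_sd == 0, Inf, bg_sd)
  Z <- (M - bg_mean) / sd_safe       # z within each row's distribution
  Zp <- pmax(Z, 0)
  S <- sqrt(Zp^2 + t(Zp)^2)
  S[is.na(M)] <- NA_real_
  diag(S) <- NA_real_
  dimnames(S) <- dimnames(mi)
  structure(list(scores = S, bg_mean = bg_mean, bg_sd = bg_sd,
                 flagged = flagged,
                 estimator = attr(mi, "estimator"),
                 regulators = attr(mi, "regulators")),
            class = "clr_scores")
}

clr_edges_at <- function(S, cutoff) {
  idx <- which(upper.tri(S) & !is.na(S) & S >= cutoff, arr.ind = TRUE)
  data.frame(from = rownames(S)[idx[, 1]], to = colnames(S)[idx[, 2]],
             score = S[idx], stringsAsFactors = FALSE)
}

#' Threshold CLR scores into a network
#'
#' `cutoff` mode keeps every pair whose joint likelihood score meets the
#' cutoff (default 2.5, the value used for the all-probe-set run).
#' `fdr` mode calibrates the cutoff against scores recomputed from
#' column-permuted expression data: the smallest cutoff at which
#' (mean permuted edge count) / (observed edge count) <= `fdr`.
#'
#' @param scores a [clr_scores()] object.
#' @param mode `"cutoff"` or `"fdr"`.
#' @param cutoff likelihood-score cutoff (cutoff mode).
#' @param fdr target false discovery rate in (0,1) (fdr mode).
#' @param X expression matrix the MI was computed from (required for fdr
#'   mode).
#' @param n_perm permutations for fdr calibration.
#' @param seed integer seed.
#' @return a [gene_network()] recording the mode and active threshold.
#' @export
clr_network <- function(scores, mode = c("cutoff", "fdr"), cutoff = 2.5,
                        fdr = 0.05, X = NULL, n_perm = 3, seed = 1) {
  mode <- match.arg(mode)
  S <- scores$scores
  if (mode == "cutoff") {
    edges <- clr_edges_at(S, cutoff)
    return(gene_network(edges, nodes = rownames(S), threshold = cutoff,
                        mode = sprintf("clr_cutoff_%g", cutoff)))
  }
  if (fdr <= 0 || fdr >= 1) stop2("fdr level must be in (0,1)")
  if (is.null(X)) stop2("fdr mode needs the expression matrix `X`")
  est <- scores$estimator %||% list(method = "bspline", bins = 10, order = 3)
  null_scores <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      Xp <- t(apply(unclass(X), 1, sample))
      dimnames(Xp) <- dimnames(X)
      mip <- mi_matrix(expression_matrix(Xp), method = est$method,
                       bins = est$bins, order = est$order,
                       regulators = scores$regulators)
      sp <- clr_scores(mip)$scores
      sp[upper.tri(sp) & !is.na(sp)]
    }))
  })
  obs <- sort(S[upper.tri(S) & !is.na(S)], decreasing = TRUE)
  cand <- unique(obs)
  fdr_hat <- vapply(cand, function(t) {
    (sum(null_scores >= t) / n_perm) / sum(obs >= t)
  }, numeric(1))
  ok <- fdr_hat <= fdr
  thr <- if (any(ok)) min(cand[ok]) else Inf
  edges <- if (is.finite(thr)) clr_edges_at(S, thr) else
    data.frame(from = character(), to = character(), score = numeric())
  gene_network(edges, nodes = rownames(S), threshold = thr,
               mode = sprintf("clr_fdr_%g", fdr))
}

#' ARACNE-style network: MI significance filter plus DPI pruning
#'
#' Pairs failing the MI significance threshold are dropped first; then for
#' every triangle among the surviving edges the strictly smallest MI edge
#' is removed unless its MI is at least (1 - tolerance) times the smaller
#' of the other two. All removal decisions are taken against the original
#' (pre-pruning) edge set, so a removed edge still witnesses other
#' triangles; ties keep all edges.
#'
#' @param mi an [mi_matrix()].
#' @param p_threshold MI significance level (the reference run used 1e-7);
#'   converted to an MI cutoff via the permutation null, with exponential
#'   tail extrapolation below the permutation resolution.
#' @param dpi_tolerance DPI tolerance in `[0, 0.2]` (the reference run used
#'   0.15); values above 0.2 provoke a warning, not an error, because they
#'   are known to admit many false edges.
#' @param X expression matrix for building the permutation null (used when
#'   neither `null_mi` nor `mi_threshold` is given).
#' @param null_mi optional pre-computed null MI sample.
#' @param mi_threshold optional explicit MI cutoff (skips the null).
#' @param n_null null sample size when drawing from `X`.
#' @param seed integer seed.
#' @return list with `network` (a [gene_network()]) and `dpi` (class
#'   `dpi_result`: `retained`, `removed` with witnessing triangles,
#'   `tolerance`).
#' @export
aracne_network <- function(mi, p_threshold = 1e-7, dpi_tolerance = 0.15,
                           X = NULL, null_mi = NULL, mi_threshold = NULL,
                           n_null = 2000, seed = 1) {
  if (dpi_tolerance < 0) stop2("dpi_tolerance must be >= 0")
  if (dpi_tolerance > 0.2)
    warn2("DPI tolerance above 0.2 is known to admit many false edges")
  if (is.null(mi_threshold)) {
    if (is.null(null_mi)) {
      if (is.null(X))
        stop2("need one of `mi_threshold`, `null_mi`, or `X`")
      est <- attr(mi, "estimator") %||% list(method = "equal_width",
                                             bins = 10, order = 3)
      null_mi <- mi_null_sample(X, n_null = n_null, seed = seed,
                                method = est$method, bins = est$bins,
                                order = est$order)
    }
    mi_threshold <- as.numeric(mi_significance_threshold(null_mi, p_threshold))
  }
  M <- unclass(mi)
  diag(M) <- NA_real_
  idx <- which(upper.tri(M) & !is.na(M) & M >= mi_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(M)[idx[, 1]],
                      to = colnames(M)[idx[, 2]],
                      score = M[idx], stringsAsFactors = FALSE)
  dpi <- dpi_prune(M, edges, dpi_tolerance)
  net <- gene_network(dpi$retained, nodes = rownames(M),
                      threshold = mi_threshold,
                      mode = sprintf("aracne_p_%g_dpi_%g",
                                     p_threshold, dpi_tolerance))
  list(network = net, dpi = dpi)
}

#' Data-processing-inequality pruning
#'
#' @param M symmetric MI matrix (named).
#' @param edges data.frame(from, to, score): the significant edge set.
#' @param tolerance DPI tolerance.
#' @return `dpi_result`: `retained` and `removed` edge frames (the latter
#'   with the witnessing third node and the triangle's MI values) plus the
#'   tolerance used.
#' @export
dpi_prune <- function(M, edges, tolerance = 0.15) {
  genes <- rownames(M)
  G <- length(genes)
  adj <- matrix(FALSE, G, G, dimnames = dimnames(M))
  ei <- match(edges$from, genes)
  ej <- match(edges$to, genes)
  adj[cbind(ei, ej)] <- TRUE
  adj[cbind(ej, ei)] <- TRUE
  keep <- rep(TRUE, nrow(edges))
  witness <- rep(NA_character_, nrow(edges))
  wit_vals <- matrix(NA_real_, nrow(edges), 2)
  for (e in seq_len(nrow(edges))) {
    i <- ei[e]; j <- ej[e]
    common <- which(adj[i, ] & adj[j, ])
    if (!length(common)) next
    a <- edges$score[e]
    b <- M[i, common]
    c <- M[j, common]
    lo <- pmin(b, c)
    bad <- a < b & a < c & a < (1 - tolerance) * lo
    if (any(bad)) {
      k <- common[which(bad)[1]]
      keep[e] <- FALSE
      witness[e] <- genes[k]
      wit_vals[e, ] <- c(M[i, k], M[j, k])
    }
  }
  removed <- edges[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$witness <- witness[!keep]
    removed$witness_mi_from <- wit_vals[!keep, 1]
    removed$witness_mi_to <- wit_vals[!keep, 2]
  } else {
    removed$witness <- character()
    removed$witness_mi_from <- numeric()
    removed$witness_mi_to <- numeric()
  }
  rownames(removed) <- NULL
  retained <- edges[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, removed = removed,
                 tolerance = tolerance),
            class = "dpi_result")
}
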