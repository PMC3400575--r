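# Mutual-information estimation over discretized expression profiles.
#
# The estimator assigns each observation a weight vector over bins; hard
# binning gives 0/1 indicators, B-spline soft binning (order k over M bins)
# spreads each observation over up to k adjacent bins, which reduces the
# variance of the plug-in entropy estimate at small sample sizes. All
# entropies are in nats.

# Per-observation bin weight matrix (n x bins); rows sum to 1.
bin_weights <- function(x, method = c("bspline", "equal_width", "equal_freq"),
                        bins = 10, order = 3) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3) stop2("need at least 3 observations")
  if (bins < 2) stop2("need at least 2 bins")
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    if (method == "equal_freq")
      warn2("constant vector: single occupied bin, entropy 0")
    W <- matrix(0, n, bins)
    W[, 1] <- 1
    return(W)
  }
  if (method == "bspline") {
    k <- as.integer(order)
    if (k < 1 || k > bins) stop2("spline order must be in [1, bins]")
    top <- bins - k + 1
    # soft assignment on the empirical-CDF (copula) scale: robust to
    # outliers and monotone transforms, and keeps the soft estimate close
    # to the hard-binned one at matched bin counts
    u <- (rank(x, ties.method = "average") - 0.5) / n
    z <- pmin(pmax(u * top, 0), top)
    knots <- c(rep(0, k - 1), 0:top, rep(top, k - 1))
    W <- splines::splineDesign(knots, z, ord = k, outer.ok = TRUE)
    # at the right boundary splineDesign can drop the final basis mass
    s <- rowSums(W)
    W <- W / s
    return(W)
  }
  if (method == "equal_width") {
    breaks <- seq(r[1], r[2], length.out = bins + 1)
  } else {
    breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                     names = FALSE, type = 7))
    if (length(breaks) < 2) {
      warn2("degenerate quantile bins; entropy 0")
      W <- matrix(0, n, bins)
      W[, 1] <- 1
      return(W)
    }
  }
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  W <- matrix(0, n, bins)
  W[cbind(seq_len(n), idx)] <- 1
  W
}

entropy_from_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon entropy of a real vector under discretization
#'
#' H = -sum p_i log p_i (nats), where p_i are bin weights normalized to 1.
#' B-spline soft assignment gives fractional weights; `equal_width` and
#' `equal_freq` give hard counts.
#'
#' @param x numeric vector, length >= 3.
#' @param method discretization: `"bspline"` (default, order-3 B-splines
#'   over 10 bins), `"equal_width"` or `"equal_freq"`.
#' @param bins number of bins (>= 2).
#' @param order B-spline order (ignored for hard binning).
#' @return entropy in nats (>= 0).
#' @export
entropy <- function(x, method = "bspline", bins = 10, order = 3) {
  W <- bin_weights(x, method, bins, order)
  entropy_from_p(colSums(W) / nrow(W))
}

mi_from_weights <- function(Wx, Wy) {
  n <- nrow(Wx)
  px <- colSums(Wx) / n
  py <- colSums(Wy) / n
  pj <- crossprod(Wx, Wy) / n
  mi <- entropy_from_p(px) + entropy_from_p(py) - entropy_from_p(as.vector(pj))
  max(mi, 0)
}

#' Mutual information between two real vectors
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y) under one shared discretization, clipped
#' at 0 (the finite-sample three-entropy subtraction can go fractionally
#' negative). Symmetric in its arguments.
#'
#' @inheritParams entropy
#' @param y numeric vector, same length as `x`.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, method = "bspline", bins = 10, order = 3) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  Wx <- bin_weights(x, method, bins, order)
  Wy <- bin_weights(y, method, bins, order)
  mi_from_weights(Wx, Wy)
}

#' Pairwise mutual-information matrix over the rows of an expression matrix
#'
#' The diagonal holds each gene's entropy under the same discretization.
#' With `regulators` set, only regulator-vs-gene pairs are computed (the
#' designated-transcription-regulator execution mode); other entries are
#' `NA`.
#'
#' @param X an [expression_matrix()] (genes x samples), >= 3 samples.
#' @param regulators optional character vector of row ids restricting the
#'   computed pairs to regulator x all.
#' @inheritParams entropy
#' @return symmetric matrix of class `mi_matrix` with attributes
#'   `estimator` (method/bins/order) and `regulators`.
#' @export
mi_matrix <- function(X, method = "bspline", bins = 10, order = 3,
                      regulators = NULL) {
  X <- as_expression_matrix(X)
  if (ncol(X) < 3) stop2("need at least 3 samples")
  genes <- rownames(X)
  G <- length(genes)
  if (!is.null(regulators)) {
    if (!length(regulators)) stop2("empty regulator list in restricted mode")
    missing <- setdiff(regulators, genes)
    if (length(missing))
      stop2("regulator not in matrix: '", missing[[1]], "'")
  }
  W <- lapply(seq_len(G), function(i) bin_weights(X[i, ], method, bins, order))
  H <- vapply(W, function(w) entropy_from_p(colSums(w) / nrow(w)), numeric(1))
  M <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  diag(M) <- H
  if (is.null(regulators)) {
    for (i in seq_len(G - 1L)) {
      Wi <- W[[i]]
      for (j in (i + 1L):G) {
        M[i, j] <- M[j, i] <- mi_from_weights(Wi, W[[j]])
      }
    }
  } else {
    ridx <- match(regulators, genes)
    for (i in ridx) {
      Wi <- W[[i]]
      for (j in seq_len(G)) {
        if (j == i || !is.na(M[i, j])) next
        M[i, j] <- M[j, i] <- mi_from_weights(Wi, W[[j]])
      }
    }
  }
  structure(M,
            estimator = list(method = method, bins = bins, order = order),
            regulators = regulators,
            class = c("mi_matrix", "matrix", "array"))
}

#' Permutation p-value for the mutual information of a pair
#'
#' Add-one estimator p = (1 + #permuted MI >= observed) / (n_perm + 1).
#' Because counting cannot resolve p-values below 1/(n_perm + 1), an
#' exponential (peaks-over-threshold) tail fit to the permutation
#' distribution is also returned (`p_tail`, flagged by `tail_extrapolated`)
#' for use against thresholds such as 1e-7.
#'
#' @inheritParams mutual_information
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `p_value` (counting), `p_tail`, `tail_extrapolated`
#'   (TRUE when no permutation reached the observed MI), `observed_mi`.
#' @export
mi_permutation_pvalue <- function(x, y, n_perm = 1000, seed = 1,
                                  method = "bspline", bins = 10, order = 3) {
  if (n_perm < 100) stop2("n_perm must be >= 100")
  Wx <- bin_weights(x, method, bins, order)
  Wy <- bin_weights(y, method, bins, order)
  obs <- mi_from_weights(Wx, Wy)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mi_from_weights(Wx, Wy[sample.int(nrow(Wy)), , drop = FALSE])
    }, numeric(1))
  })
  k <- sum(null >= obs)
  p_count <- (1 + k) / (n_perm + 1)
  tail_flag <- k == 0
  p_tail <- exponential_tail_p(null, obs)
  list(p_value = p_count, p_tail = p_tail,
       tail_extrapolated = tail_flag, observed_mi = obs)
}

# peaks-over-threshold exponential tail: p(x) = frac * exp(-rate (x - u))
exponential_tail_p <- function(null, obs, frac = 0.1) {
  u <- stats::quantile(null, 1 - frac, names = FALSE)
  exc <- null[null > u] - u
  if (length(exc) < 5 || mean(exc) <= 0)
    return(mean(null >= obs))
  rate <- 1 / mean(exc)
  if (obs <= u) return(mean(null >= obs))
  min(1, frac * exp(-rate * (obs - u)))
}

#' Null mutual-information sample from permuted expression data
#'
#' Draws random gene pairs, permutes one profile, and records the MI:
#' an empirical null for the no-dependence hypothesis, used to convert
#' a significance level into an MI threshold.
#'
#' @param X an [expression_matrix()].
#' @param n_null number of null MI draws.
#' @param seed integer seed.
#' @inheritParams entropy
#' @return numeric vector of null MI values.
#' @export
mi_null_sample <- function(X, n_null = 2000, seed = 1,
                           method = "bspline", bins = 10, order = 3) {
  X <- as_expression_matrix(X)
  G <- nrow(X)
  n <- ncol(X)
  with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      ij <- sample.int(G, 2)
      Wx <- bin_weights(X[ij[1], ], method, bins, order)
      Wy <- bin_weights(X[ij[2], ][sample.int(n)], method, bins, order)
      mi_from_weights(Wx, Wy)
    }, numeric(1))
  })
}

#' MI threshold at a given significance level
#'
#' For levels resolvable by counting, the empirical (1 - p) quantile of the
#' null sample; for smaller levels (e.g. 1e-7) the exponential tail fit is
#' inverted, which extrapolates beyond the permutation resolution.
#'
#' @param null_mi numeric vector from [mi_null_sample()].
#' @param p significance level.
#' @return MI threshold; attribute `tail_extrapolated` marks extrapolation.
#' @export
mi_significance_threshold <- function(null_mi, p) {
  stopifnot(p > 0, p < 1)
  n <- length(null_mi)
  if (p >= 1 / (n + 1)) {
    thr <- stats::quantile(null_mi, 1 - p, names = FALSE)
    return(structure(thr, tail_extrapolated = FALSE))
  }
  frac <- 0.1
  u <- stats::quantile(null_mi, 1 - frac, names = FALSE)
  exc <- null_mi[null_mi > u] - u
  rate <- 1 / mean(exc)
  structure(u + log(frac / p) / rate, tail_extrapolated = TRUE)
}
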