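# Sparse factor-analysis biclustering: X = sum_i lambda_i z_i^T + noise
# with l1-sparse loadings and factors. A bicluster is the joint support of
# one loading/factor pair.

soft_threshold <- function(x, a) sign(x) * pmax(abs(x) - a, 0)

#' Fit a sparse factor model
#'
#' Fits X = sum_i lambda_i z_i^T + noise by block-coordinate penalized
#' least squares: the objective 0.5 ||X - L Z^T||_F^2 +
#' sparseness (|L|_1 + |Z|_1) is minimized by cycling over factors,
#' solving each loading/factor block exactly (soft-thresholded projection),
#' so the penalized objective is monotone non-increasing. Initialization is
#' the truncated SVD plus a small seeded jitter; an optional final
#' unpenalized refit on the selected support removes the l1 shrinkage bias.
#'
#' Rows of X are mean-centered before fitting (the row means are stored).
#'
#' @param X an [expression_matrix()] or matrix (genes x samples).
#' @param p number of factors/biclusters (1 <= p <= min(dim)/2). The
#'   reference protocol ran p in {5, 10, 20}.
#' @param n_iter maximum sweeps (reference protocol: 500).
#' @param sparseness l1 penalty weight (reference protocol: 0.1).
#' @param seed integer seed (init jitter).
#' @param refit if `TRUE` (default), unpenalized alternating refit on the
#'   nonzero support after convergence.
#' @param tol relative objective-change stopping tolerance.
#' @return object of class `factor_model`: `L` (genes x p), `Z`
#'   (samples x p), `row_means`, `objective` (per-sweep trace),
#'   `n_iter_run`, `sparseness`, `seed`.
#' @export
fit_factor_model <- function(X, p, n_iter = 500, sparseness = 0.1, seed = 1,
                             refit = TRUE, tol = 1e-9) {
  X <- as_expression_matrix(X)
  G <- nrow(X); N <- ncol(X)
  if (p < 1) stop2("p must be >= 1")
  if (p > min(G, N) / 2) stop2("p too large for the matrix dimensions")
  mu <- rowMeans(X)
  Xc <- unclass(X) - mu
  a <- sparseness
  with_seed(seed, {
    sv <- svd(Xc, nu = p, nv = p)
    d <- sqrt(pmax(sv$d[seq_len(p)], .Machine$double.eps))
    L <- sv$u %*% diag(d, p)
    Z <- sv$v %*% diag(d, p)
    L <- L + matrix(stats::rnorm(G * p, sd = 1e-3), G, p)
    Z <- Z + matrix(stats::rnorm(N * p, sd = 1e-3), N, p)
    R <- Xc - tcrossprod(L, Z)
    objective <- function() 0.5 * sum(R^2) + a * (sum(abs(L)) + sum(abs(Z)))
    obj <- numeric(n_iter)
    prev <- objective()
    n_run <- 0
    for (it in seq_len(n_iter)) {
      for (i in seq_len(p)) {
        Ri <- R + tcrossprod(L[, i], Z[, i])
        li <- L[, i]
        ss_l <- sum(li^2)
        zi <- if (ss_l > 0)
          soft_threshold(crossprod(Ri, li)[, 1], a) / ss_l else Z[, i] * 0
        ss_z <- sum(zi^2)
        li <- if (ss_z > 0)
          soft_threshold((Ri %*% zi)[, 1], a) / ss_z else li * 0
        L[, i] <- li
        Z[, i] <- zi
        R <- Ri - tcrossprod(li, zi)
      }
      cur <- objective()
      obj[it] <- cur
      n_run <- it
      if (prev - cur < tol * max(1, abs(prev))) break
      prev <- cur
    }
    if (refit) {
      SL <- L != 0
      SZ <- Z != 0
      for (it2 in seq_len(25)) {
        for (i in seq_len(p)) {
          Ri <- R + tcrossprod(L[, i], Z[, i])
          li <- L[, i]
          ss_l <- sum(li^2)
          zi <- if (ss_l > 0) (crossprod(Ri, li)[, 1] / ss_l) * SZ[, i]
                else Z[, i] * 0
          ss_z <- sum(zi^2)
          li <- if (ss_z > 0) ((Ri %*% zi)[, 1] / ss_z) * SL[, i] else li * 0
          L[, i] <- li
          Z[, i] <- zi
          R <- Ri - tcrossprod(li, zi)
        }
      }
    }
    dimnames(L) <- list(rownames(X), paste0("F", seq_len(p)))
    dimnames(Z) <- list(colnames(X), paste0("F", seq_len(p)))
    structure(list(L = L, Z = Z, row_means = mu,
                   objective = obj[seq_len(n_run)], n_iter_run = n_run,
                   sparseness = sparseness, seed = seed),
              class = "factor_model")
  })
}

#' Reconstruct the model fit
#' @param model a `factor_model`.
#' @param center if `TRUE` return the centered reconstruction L Z^T,
#'   otherwise add the row means back.
#' @return numeric matrix.
#' @export
reconstruct <- function(model, center = FALSE) {
  M <- tcrossprod(model$L, model$Z)
  if (!center) M <- M + model$row_means
  M
}

#' Extract biclusters from a fitted factor model
#'
#' Gene i belongs to bicluster k iff |L[i,k]| exceeds `gene_thresh` scale
#' units of the k-th loading vector; samples analogously from Z. The scale
#' unit is the standard deviation of the vector (`units = "sd"`, default)
#' or its median absolute deviation (`units = "mad"`). Empty biclusters
#' are dropped with a notice.
#'
#' @param model a `factor_model`.
#' @param gene_thresh,sample_thresh thresholds in scale units.
#' @param units `"sd"` or `"mad"`.
#' @return object of class `bicluster_set`: list of biclusters (each with
#'   `id`, `genes`, `samples`, `gene_scores`, `sample_scores`) plus
#'   provenance (`p`, `seed`, thresholds).
#' @export
extract_biclusters <- function(model, gene_thresh = 0.5, sample_thresh = 0.5,
                               units = c("sd", "mad")) {
  units <- match.arg(units)
  scale_fn <- if (units == "sd") stats::sd else
    function(v) stats::mad(v, center = 0)
  p <- ncol(model$L)
  bics <- list()
  for (k in seq_len(p)) {
    sl <- scale_fn(model$L[, k])
    sz <- scale_fn(model$Z[, k])
    genes <- if (is.finite(sl) && sl > 0)
      rownames(model$L)[abs(model$L[, k]) > gene_thresh * sl] else character()
    samples <- if (is.finite(sz) && sz > 0)
      rownames(model$Z)[abs(model$Z[, k]) > sample_thresh * sz] else character()
    if (!length(genes) || !length(samples)) {
      message("bicluster ", k, " is empty at the given thresholds; dropped")
      next
    }
    bics[[length(bics) + 1]] <- list(
      id = k, genes = genes, samples = samples,
      gene_scores = stats::setNames(model$L[genes, k], genes),
      sample_scores = stats::setNames(model$Z[samples, k], samples))
  }
  if (!length(bics)) warn2("all biclusters empty at the given thresholds")
  structure(list(biclusters = bics, p = p, seed = model$seed,
                 gene_thresh = gene_thresh, sample_thresh = sample_thresh,
                 units = units),
            class = "bicluster_set")
}

#' Jaccard index of two sets
#' @param a,b character vectors.
#' @return |intersection| / |union|.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Best-match Jaccard of planted biclusters against an extraction
#' @param truth_genes list of planted gene sets.
#' @param bicset a `bicluster_set`.
#' @return numeric vector: for each planted set, the best Jaccard over
#'   extracted biclusters (0 when nothing was extracted).
#' @export
best_match_jaccard <- function(truth_genes, bicset) {
  vapply(truth_genes, function(tg) {
    if (!length(bicset$biclusters)) return(0)
    max(vapply(bicset$biclusters, function(b) jaccard(tg, b$genes),
               numeric(1)))
  }, numeric(1))
}

#' CLR network within one bicluster's genes
#'
#' Restricts the expression matrix to the bicluster's member genes (all
#' samples by default; optionally only the bicluster's samples) and runs
#' the CLR scoring and thresholding. Too-small biclusters (fewer than 5
#' genes or 4 samples) are skipped with a notice (returns `NULL`).
#'
#' @param X an [expression_matrix()].
#' @param bicluster one element of a `bicluster_set`'s `biclusters` list.
#' @param cutoff CLR likelihood cutoff.
#' @param samples `"all"` or `"bicluster"`.
#' @param method,bins,order MI estimator settings.
#' @return a [gene_network()] tagged with the bicluster id, or `NULL`.
#' @export
within_bicluster_network <- function(X, bicluster, cutoff = 2.5,
                                     samples = c("all", "bicluster"),
                                     method = "bspline", bins = 10,
                                     order = 3) {
  samples <- match.arg(samples)
  X <- as_expression_matrix(X)
  genes <- intersect(bicluster$genes, rownames(X))
  cols <- if (samples == "bicluster")
    intersect(bicluster$samples, colnames(X)) else colnames(X)
  if (length(genes) < 5 || length(cols) < 4) {
    message("bicluster ", bicluster$id %||% "?",
            " too small for network inference; skipped")
    return(NULL)
  }
  sub <- expression_matrix(unclass(X)[genes, cols, drop = FALSE])
  mi <- mi_matrix(sub, method = method, bins = bins, order = order)
  net <- clr_network(clr_scores(mi), mode = "cutoff", cutoff = cutoff)
  attr(net, "bicluster_id") <- bicluster$id
  net
}
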