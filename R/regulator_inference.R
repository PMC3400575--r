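# Selection of a minimal signed regulator set per bicluster: l1-regularized
# regression of the bicluster's condensed expression profile on candidate
# regulator profiles (equilibrium mode, no temporal terms), with optional
# AND-gate pair terms.

#' Condensed per-sample response profile of a bicluster
#'
#' The per-sample mean of the standardized member-gene expression rows.
#' Member genes whose loading sign is negative are flipped first so that
#' anti-correlated members reinforce rather than cancel.
#'
#' @param X an [expression_matrix()].
#' @param bicluster element of a `bicluster_set` (needs `genes`, and
#'   optionally `gene_scores` for the sign flip), or a character vector of
#'   gene ids.
#' @return named numeric vector over samples.
#' @export
bicluster_response <- function(X, bicluster) {
  X <- as_expression_matrix(X)
  if (is.character(bicluster)) bicluster <- list(genes = bicluster)
  genes <- intersect(bicluster$genes, rownames(X))
  if (!length(genes)) stop2("bicluster has no genes in the matrix")
  M <- unclass(X)[genes, , drop = FALSE]
  Ms <- t(scale(t(M)))
  Ms[!is.finite(Ms)] <- 0  # constant rows standardize to 0
  signs <- rep(1, length(genes))
  if (!is.null(bicluster$gene_scores)) {
    s <- sign(bicluster$gene_scores[genes])
    signs <- ifelse(is.na(s) | s == 0, 1, s)
  }
  stats::setNames(colMeans(Ms * signs), colnames(X))
}

#' Build a regulator design matrix
#'
#' Standardized single-regulator columns; with `interactions = TRUE`,
#' pairwise AND-gate columns labeled `"A_with_B"` — the elementwise
#' minimum of the two standardized profiles (a product encoding is
#' available behind `pair_encoding`). When the number of pairs exceeds
#' `pair_budget`, pairs are ranked by the mutual information of their
#' column with `response` and the budget kept.
#'
#' @param X an [expression_matrix()].
#' @param regulators character vector of regulator row ids (nonempty, all
#'   present in `X`).
#' @param interactions include pair terms?
#' @param pair_encoding `"min"` (AND-gate, default) or `"product"`.
#' @param pair_budget maximum number of pair columns kept.
#' @param response optional response vector used to rank pairs when the
#'   budget binds.
#' @return numeric matrix samples x terms, column names are regulator ids
#'   and `"A_with_B"` labels.
#' @export
design_matrix <- function(X, regulators, interactions = TRUE,
                          pair_encoding = c("min", "product"),
                          pair_budget = 200, response = NULL) {
  pair_encoding <- match.arg(pair_encoding)
  X <- as_expression_matrix(X)
  if (!length(regulators)) stop2("empty regulator list")
  missing <- setdiff(regulators, rownames(X))
  if (length(missing)) stop2("regulator not in matrix: '", missing[[1]], "'")
  R <- t(unclass(X)[regulators, , drop = FALSE])
  R <- scale(R)
  R[!is.finite(R)] <- 0
  colnames(R) <- regulators
  if (!interactions || length(regulators) < 2) return(R)
  pairs <- utils::combn(regulators, 2)
  P <- apply(pairs, 2, function(pr) {
    if (pair_encoding == "min") pmin(R[, pr[1]], R[, pr[2]])
    else R[, pr[1]] * R[, pr[2]]
  })
  colnames(P) <- paste(pairs[1, ], pairs[2, ], sep = "_with_")
  if (ncol(P) > pair_budget) {
    if (!is.null(response)) {
      rank_score <- apply(P, 2, function(col)
        mutual_information(col, response))
    } else {
      rank_score <- apply(P, 2, stats::var)
    }
    P <- P[, order(rank_score, decreasing = TRUE)[seq_len(pair_budget)],
           drop = FALSE]
  }
  cbind(R, P)
}

#' Select a minimal signed regulator set (l1 path + cross-validation)
#'
#' Lasso fit of the response on the design; the penalty is chosen by
#' 10-fold cross-validation at the most-regularized model within one
#' standard error of the best ("minimal set" surrogate). Nonzero
#' coefficients become calls, signed by their coefficient. Constant
#' design columns are dropped with a warning. No temporal terms are used
#' (equilibrium observations).
#'
#' @param response numeric vector over samples (>= 10).
#' @param design matrix from [design_matrix()].
#' @param seed integer seed (controls the CV fold assignment).
#' @param nfolds CV folds.
#' @param s penalty rule: `"lambda.1se"` (default) or `"lambda.min"`.
#' @return data.frame of class `regulator_calls`: term, sign
#'   (`positive`/`negative`), coefficient, score (|coefficient|), ordered
#'   by score.
#' @export
select_regulators <- function(response, design, seed = 1, nfolds = 10,
                              s = c("lambda.1se", "lambda.min")) {
  s <- match.arg(s)
  if (length(response) < 10) stop2("need >= 10 samples")
  stopifnot(nrow(design) == length(response))
  const <- apply(design, 2, function(col) stats::var(col) == 0)
  if (any(const)) {
    warn2("dropping constant design column(s): ",
          paste(colnames(design)[const], collapse = ", "))
    design <- design[, !const, drop = FALSE]
  }
  if (ncol(design) < 2)
    stop2("need at least 2 non-constant design columns")
  fit <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), length(response)))
    glmnet::cv.glmnet(design, response, alpha = 1, foldid = foldid,
                      standardize = TRUE)
  })
  co <- as.matrix(stats::coef(fit, s = s))[-1, 1]  # drop intercept
  nz <- co[co != 0]
  out <- data.frame(term = names(nz),
                    sign = ifelse(nz > 0, "positive", "negative"),
                    coefficient = unname(nz), score = abs(unname(nz)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- fit[[s]]
  class(out) <- c("regulator_calls", class(out))
  out
}

#' Regulator calls for every bicluster in a set
#'
#' @param X an [expression_matrix()].
#' @param bicset a `bicluster_set`.
#' @param regulators candidate regulator ids.
#' @param interactions,pair_budget passed to [design_matrix()].
#' @param seed integer seed.
#' @return data.frame: bicluster, term, sign, coefficient, score.
#' @export
infer_bicluster_regulators <- function(X, bicset, regulators,
                                       interactions = TRUE,
                                       pair_budget = 200, seed = 1) {
  rows <- lapply(bicset$biclusters, function(b) {
    y <- bicluster_response(X, b)
    # member genes cannot regulate their own condensed profile trivially;
    # regulators that are bicluster members stay eligible, as in the
    # reference protocol, but the design excludes none a priori
    D <- design_matrix(X, regulators, interactions = interactions,
                       pair_budget = pair_budget, response = y)
    calls <- select_regulators(y, D, seed = seed + b$id)
    if (!nrow(calls)) return(NULL)
    cbind(bicluster = b$id, calls)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bicluster = integer(), term = character(),
                      sign = character(), coefficient = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
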