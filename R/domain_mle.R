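# Maximum-likelihood estimation of domain-domain interaction
# probabilities from an observed interactome, and composition into
# protein-pair interaction probabilities.
#
# Model: proteins interact via their component domains. A protein pair
# (i, j) truly interacts with probability
#   P_ij = 1 - prod over distinct domain pairs (m in i, n in j) (1 - lambda_mn),
# and the observation flips the truth with false-positive rate fp and
# false-negative rate fn. lambda is estimated by EM: the E-step computes,
# per protein pair and contributing domain pair, the posterior that the
# domain pair interacts given the observation; the M-step averages these
# posteriors over the protein pairs carrying the domain pair.

#' Compose a protein-pair interaction probability from domain pairs
#'
#' P = 1 - prod over all distinct unordered domain pairs (m in A, n in B)
#' of (1 - lambda_mn); symmetric in A and B, monotone in every lambda.
#' Domain pairs absent from the model are treated as lambda = 0 with a
#' warning.
#'
#' @param model a `domain_model` from [fit_domain_mle()], or a named
#'   numeric vector of lambdas keyed `"m|n"` (sorted domain names).
#' @param domainsA,domainsB nonempty character vectors of domains.
#' @return probability in `[0, 1]`.
#' @export
protein_pair_probability <- function(model, domainsA, domainsB) {
  if (!length(domainsA) || !length(domainsB))
    stop2("domain lists must be nonempty")
  lambda <- if (is.list(model)) model$lambda else model
  keys <- unique(domain_pair_keys(domainsA, domainsB))
  known <- keys %in% names(lambda)
  if (any(!known))
    warn2("unknown domain pair(s) treated as lambda = 0: ",
          paste(utils::head(keys[!known], 3), collapse = ", "),
          if (sum(!known) > 3) ", ..." else "")
  lam <- ifelse(known, lambda[keys], 0)
  1 - prod(1 - lam)
}

#' Fit domain-pair interaction probabilities by EM
#'
#' @param domains named list protein -> character vector of domains; every
#'   protein appearing in `interactions` must be covered.
#' @param interactions data.frame with columns `a`, `b`, `observed` (0/1):
#'   the training interactome.
#' @param fp,fn observation false-positive and false-negative rates
#'   (user-supplied constants, each in `[0, 0.5)`; they are not estimated).
#' @param n_iter maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than `tol`.
#' @param seed integer seed (jitters the frequency-based initialization).
#' @return object of class `domain_model`: `lambda` (named per unordered
#'   domain pair), `fp`, `fn`, `loglik` (trace, non-decreasing),
#'   `converged`, `n_iter_run`. Non-convergence at `n_iter` sets
#'   `converged = FALSE` with a warning.
#' @export
fit_domain_mle <- function(domains, interactions, fp = 0.05, fn = 0.10,
                           n_iter = 200, tol = 1e-6, seed = 1) {
  if (fp < 0 || fp >= 0.5 || fn < 0 || fn >= 0.5)
    stop2("fp and fn must be in [0, 0.5)")
  missing <- setdiff(unique(c(interactions$a, interactions$b)),
                     names(domains))
  if (length(missing))
    stop2("protein without domain annotation: '", missing[[1]], "'")
  # long table: one row per (protein pair, contributing domain pair)
  long <- pair_domain_long(domains, interactions$a, interactions$b)
  pair_idx <- long$pair_idx
  dp_fac <- factor(long$key)
  dp_levels <- levels(dp_fac)
  dp_i <- as.integer(dp_fac)
  n_dp <- length(dp_levels)
  obs <- interactions$observed
  # init: observed interaction frequency among carriers, seeded jitter
  freq <- tapply(obs[pair_idx], dp_i, mean)
  lambda <- with_seed(seed, {
    pmin(pmax(as.numeric(freq) + stats::runif(n_dp, -0.02, 0.02),
              1e-4), 1 - 1e-4)
  })
  carriers <- tabulate(dp_i, n_dp)
  loglik <- numeric(n_iter)
  converged <- FALSE
  n_run <- 0
  ll_prev <- -Inf
  for (it in seq_len(n_iter)) {
    log1m <- log1p(-lambda)
    s <- as.numeric(rowsum(log1m[dp_i], pair_idx, reorder = TRUE))
    P <- -expm1(s)                       # P(true interaction)
    Po1 <- (1 - fn) * P + fp * (1 - P)   # P(observed = 1)
    Po0 <- 1 - Po1
    denom <- ifelse(obs[pair_idx] == 1, Po1[pair_idx], Po0[pair_idx])
    num <- ifelse(obs[pair_idx] == 1, 1 - fn, fn)
    e <- lambda[dp_i] * num / pmax(denom, 1e-300)
    lambda <- as.numeric(rowsum(e, dp_i)) / carriers
    lambda <- pmin(pmax(lambda, 0), 1 - 1e-12)
    ll <- sum(ifelse(obs == 1, log(pmax(Po1, 1e-300)),
                     log(pmax(Po0, 1e-300))))
    loglik[it] <- ll
    n_run <- it
    if (it > 1 && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged)
    warn2("domain-pair EM did not converge in ", n_iter, " iterations")
  structure(list(lambda = stats::setNames(lambda, dp_levels),
                 fp = fp, fn = fn, loglik = loglik[seq_len(n_run)],
                 converged = converged, n_iter_run = n_run),
            class = "domain_model")
}

#' Score network edges with composed interaction probabilities
#'
#' For every edge of the network whose endpoints map to domain-annotated
#' proteins, the composed protein-pair probability; unmapped nodes are
#' skipped with a notice.
#'
#' @param model a `domain_model`.
#' @param net a [gene_network()].
#' @param domains named list protein -> domains.
#' @return data.frame: from, to, probability, sorted descending. Errors
#'   if no edge is mappable.
#' @export
score_network_pairs <- function(model, net, domains) {
  e <- net$edges
  ok <- e$from %in% names(domains) & e$to %in% names(domains)
  if (!any(ok)) stop2("no network edge maps to domain-annotated proteins")
  if (any(!ok))
    message(sum(!ok), " edge(s) skipped: endpoints without domain annotation")
  e <- e[ok, , drop = FALSE]
  probs <- vapply(seq_len(nrow(e)), function(r) {
    keys <- unique(domain_pair_keys(domains[[e$from[r]]],
                                    domains[[e$to[r]]]))
    lam <- ifelse(keys %in% names(model$lambda), model$lambda[keys], 0)
    1 - prod(1 - lam)
  }, numeric(1))
  out <- data.frame(from = e$from, to = e$to, probability = probs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
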