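# Generators with planted structure: regulator-driven co-expression,
# additive-noise biclusters, two-group differential expression, and
# domain-mediated interactomes. Every generator is a pure function of its
# parameters and an integer seed, and returns the ground truth alongside
# the data so recovery can be scored.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Simulate regulator-driven expression
#'
#' Regulator profiles are standard normal draws; each target is
#' coefficient * f(regulator) + Gaussian noise, where f is linear or a
#' fixed sigmoid (exercising detection of monotone-nonlinear dependence);
#' background genes are i.i.d. noise.
#'
#' @param n_regulators,targets_per_regulator,n_background,n_samples counts
#'   (all >= 1; `n_samples` >= 10).
#' @param noise_sd target/background noise standard deviation (> 0).
#' @param coef_range absolute regulatory coefficients are drawn uniformly
#'   from this range, with random sign.
#' @param p_nonlinear probability a target uses the sigmoid link.
#' @param seed integer seed.
#' @return list: `expr` (an [expression_matrix()]; regulators `R1..`,
#'   targets `T1..`, background `B1..`) and `truth` (regulons with per-edge
#'   link/coefficient, regulator ids, and all planted edges as a
#'   data.frame).
#' @export
simulate_grn_expression <- function(n_regulators = 20,
                                    targets_per_regulator = 10,
                                    n_background = 300,
                                    n_samples = 100,
                                    noise_sd = 0.5,
                                    coef_range = c(0.8, 1.2),
                                    p_nonlinear = 0.25,
                                    seed = 1) {
  stopifnot(n_regulators >= 1, targets_per_regulator >= 1, n_background >= 0)
  if (n_samples < 10) stop2("n_samples must be >= 10")
  if (noise_sd <= 0) stop2("noise_sd must be > 0")
  with_seed(seed, {
    regs <- paste0("R", seq_len(n_regulators))
    R <- matrix(stats::rnorm(n_regulators * n_samples), n_regulators,
                dimnames = list(regs, NULL))
    edges <- list()
    Tm <- matrix(0, n_regulators * targets_per_regulator, n_samples)
    tids <- paste0("T", seq_len(nrow(Tm)))
    k <- 0
    for (r in seq_len(n_regulators)) {
      for (tt in seq_len(targets_per_regulator)) {
        k <- k + 1
        link <- if (stats::runif(1) < p_nonlinear) "sigmoid" else "linear"
        coef <- sample(c(-1, 1), 1) *
          stats::runif(1, coef_range[1], coef_range[2])
        f <- if (link == "sigmoid") 4 * (sigmoid(2 * R[r, ]) - 0.5) else R[r, ]
        Tm[k, ] <- coef * f + stats::rnorm(n_samples, sd = noise_sd)
        edges[[k]] <- data.frame(regulator = regs[r], target = tids[k],
                                 link = link, coefficient = coef,
                                 stringsAsFactors = FALSE)
      }
    }
    rownames(Tm) <- tids
    B <- matrix(stats::rnorm(n_background * n_samples), n_background,
                dimnames = list(if (n_background) paste0("B", seq_len(n_background)), NULL))
    X <- rbind(R, Tm, B)
    colnames(X) <- paste0("S", seq_len(n_samples))
    truth <- list(kind = "grn", regulators = regs,
                  edges = do.call(rbind, edges),
                  noise_sd = noise_sd, seed = seed)
    list(expr = expression_matrix(X), truth = truth)
  })
}

#' Simulate additive-noise biclusters
#'
#' The data follow the sparse factor model X = sum_i lambda_i z_i^T + noise
#' exactly: each planted bicluster is a rank-1 block, its loading vector
#' supported on the member genes and its factor vector on the member
#' samples, with i.i.d. Gaussian noise added everywhere.
#'
#' Member loadings have magnitude in `loading_range` (random sign per
#' gene), factors magnitude in `factor_range`, so planted block cells
#' carry signal of magnitude >= 2 by default against `noise_sd` noise.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param p_planted number of planted biclusters (>= 1).
#' @param genes_per_bicluster,samples_per_bicluster ranges (min, max) the
#'   per-bicluster member counts are drawn from.
#' @param overlap if `FALSE` (default) planted gene and sample sets are
#'   disjoint across biclusters.
#' @param noise_sd Gaussian noise sd (0 allowed: noise-free model check).
#' @param loading_range,factor_range magnitude ranges for nonzero loading
#'   and factor entries.
#' @param seed integer seed.
#' @return list: `expr` and `truth` (per bicluster: `genes`, `samples`,
#'   `lambda`, `z`).
#' @export
simulate_biclusters <- function(n_genes = 200, n_samples = 50, p_planted = 3,
                                genes_per_bicluster = c(15, 25),
                                samples_per_bicluster = c(10, 15),
                                overlap = FALSE, noise_sd = 0.5,
                                loading_range = c(1.5, 2.5),
                                factor_range = c(1, 2),
                                seed = 1) {
  stopifnot(p_planted >= 1)
  if (!overlap &&
      (p_planted * genes_per_bicluster[2] > n_genes ||
       p_planted * samples_per_bicluster[2] > n_samples))
    stop2("planted blocks exceed matrix dimensions")
  with_seed(seed, {
    X <- matrix(0, n_genes, n_samples,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("S", seq_len(n_samples))))
    free_g <- seq_len(n_genes)
    free_s <- seq_len(n_samples)
    bics <- vector("list", p_planted)
    for (b in seq_len(p_planted)) {
      ng <- sample(seq(genes_per_bicluster[1], genes_per_bicluster[2]), 1)
      ns <- sample(seq(samples_per_bicluster[1], samples_per_bicluster[2]), 1)
      gsel <- sample(if (overlap) seq_len(n_genes) else free_g, ng)
      ssel <- sample(if (overlap) seq_len(n_samples) else free_s, ns)
      if (!overlap) {
        free_g <- setdiff(free_g, gsel)
        free_s <- setdiff(free_s, ssel)
      }
      lam <- stats::runif(ng, loading_range[1], loading_range[2]) *
        sample(c(-1, 1), ng, replace = TRUE)
      z <- stats::runif(ns, factor_range[1], factor_range[2]) *
        sample(c(-1, 1), ns, replace = TRUE)
      X[gsel, ssel] <- X[gsel, ssel] + outer(lam, z)
      bics[[b]] <- list(genes = rownames(X)[gsel],
                        samples = colnames(X)[ssel],
                        lambda = stats::setNames(lam, rownames(X)[gsel]),
                        z = stats::setNames(z, colnames(X)[ssel]))
    }
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                      n_genes, n_samples)
    truth <- list(kind = "biclusters", biclusters = bics,
                  noise_sd = noise_sd, seed = seed)
    list(expr = expression_matrix(X), truth = truth)
  })
}

#' Plant two-group differential expression onto a base matrix
#'
#' Columns are split into a control and a case group (default sizes 18 and
#' 15, matching a case-control lung study design); `n_up` rows are shifted
#' up and `n_down` rows down by `lfc` in the case group.
#'
#' @param base an [expression_matrix()] or plain matrix; if `NULL`, an
#'   i.i.d. normal matrix of `n_rows` x `sum(group_sizes)` is generated.
#' @param n_up,n_down numbers of up-/down-shifted rows.
#' @param lfc shift magnitude (must be nonzero when rows are planted).
#' @param group_sizes c(control, case) sample counts, both >= 3.
#' @param n_rows rows when `base` is `NULL`.
#' @param seed integer seed.
#' @return list: `expr`, `groups` (character vector "control"/"case"),
#'   `truth` (direction per row: up/down/null and planted lfc).
#' @export
simulate_two_group_de <- function(base = NULL, n_up = 50, n_down = 50,
                                  lfc = 2, group_sizes = c(18, 15),
                                  n_rows = 1000, seed = 1) {
  if (any(group_sizes < 3)) stop2("both groups need >= 3 samples")
  if (lfc == 0 && (n_up + n_down) > 0)
    stop2("lfc must be nonzero when differential rows are planted")
  with_seed(seed, {
    n <- sum(group_sizes)
    if (is.null(base)) {
      base <- matrix(stats::rnorm(n_rows * n), n_rows, n,
                     dimnames = list(paste0("G", seq_len(n_rows)),
                                     paste0("S", seq_len(n))))
    }
    base <- as_expression_matrix(base)
    if (ncol(base) != n) stop2("base must have sum(group_sizes) columns")
    if (n_up + n_down > nrow(base)) stop2("more DE rows than matrix rows")
    groups <- rep(c("control", "case"), group_sizes)
    sel <- sample(nrow(base), n_up + n_down)
    up <- sel[seq_len(n_up)]
    down <- sel[n_up + seq_len(n_down)]
    X <- unclass(base)
    case <- groups == "case"
    if (n_up) X[up, case] <- X[up, case] + lfc
    if (n_down) X[down, case] <- X[down, case] - lfc
    direction <- rep("null", nrow(X))
    direction[up] <- "up"
    direction[down] <- "down"
    truth <- list(kind = "two_group_de",
                  direction = stats::setNames(direction, rownames(X)),
                  lfc = lfc, group_sizes = group_sizes, seed = seed)
    list(expr = expression_matrix(X), groups = groups, truth = truth)
  })
}

#' Simulate a domain-mediated interactome
#'
#' Each protein carries `domains_per_protein` domains drawn from a pool of
#' `n_domains`. A set of active unordered domain pairs is planted with the
#' interaction probabilities in `lambda_active`; all other domain pairs
#' have probability 0. A protein pair truly interacts with probability
#' 1 - prod over its distinct domain pairs of (1 - lambda); the observation
#' flips the truth with false-positive rate `fp` (0 -> 1) and
#' false-negative rate `fn` (1 -> 0).
#'
#' @param n_proteins,n_domains,domains_per_protein pool sizes.
#' @param lambda_active numeric vector in (0,1]: one planted probability
#'   per active domain pair.
#' @param fp,fn observation error rates, each in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list: `domains` (named list protein -> domains), `interactions`
#'   (data.frame a, b, observed over all unordered protein pairs), `truth`
#'   (active domain pairs with lambdas, true interaction labels, rates).
#' @export
simulate_domain_interactome <- function(n_proteins = 300, n_domains = 30,
                                        domains_per_protein = 2,
                                        lambda_active = c(0.8, 0.3),
                                        fp = 0.05, fn = 0.05, seed = 1) {
  if (any(lambda_active <= 0) || any(lambda_active > 1))
    stop2("lambda_active values must be in (0, 1]")
  if (fp < 0 || fp >= 0.5 || fn < 0 || fn >= 0.5)
    stop2("fp and fn must be in [0, 0.5)")
  with_seed(seed, {
    prots <- paste0("P", seq_len(n_proteins))
    doms <- paste0("D", seq_len(n_domains))
    domains <- stats::setNames(lapply(seq_len(n_proteins), function(i) {
      sort(sample(doms, domains_per_protein))
    }), prots)
    all_dp <- t(utils::combn(doms, 2))
    dp_keys <- paste(pmin(all_dp[, 1], all_dp[, 2]),
                     pmax(all_dp[, 1], all_dp[, 2]), sep = "|")
    dp_keys <- c(dp_keys, paste(doms, doms, sep = "|"))  # same-domain pairs
    active <- sample(dp_keys, length(lambda_active))
    lambda <- stats::setNames(rep(0, length(dp_keys)), dp_keys)
    lambda[active] <- lambda_active
    pairs <- t(utils::combn(prots, 2))
    long <- pair_domain_long(domains, pairs[, 1], pairs[, 2])
    s <- as.numeric(rowsum(log1p(-lambda[long$key]), long$pair_idx))
    p_true <- -expm1(s)
    true_int <- stats::rbinom(nrow(pairs), 1, p_true)
    observed <- ifelse(true_int == 1,
                       stats::rbinom(nrow(pairs), 1, 1 - fn),
                       stats::rbinom(nrow(pairs), 1, fp))
    interactions <- data.frame(a = pairs[, 1], b = pairs[, 2],
                               observed = observed, stringsAsFactors = FALSE)
    truth <- list(kind = "domain_interactome",
                  lambda = lambda[lambda > 0],
                  true_interaction = true_int, p_true = p_true,
                  fp = fp, fn = fn, seed = seed)
    list(domains = domains, interactions = interactions, truth = truth)
  })
}

# unordered domain-pair keys for the cross product of two domain lists;
# duplicate copies of a domain count once per unordered pair
domain_pair_keys <- function(da, db) {
  da <- unique(da)
  db <- unique(db)
  a <- rep(da, each = length(db))
  b <- rep(db, length(da))
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# vectorized long table of (protein pair index, distinct domain-pair key)
# for a list of protein pairs; one row per distinct key per pair
pair_domain_long <- function(domains, a, b) {
  da <- domains[a]
  db <- domains[b]
  la <- lengths(da)
  lb <- lengths(db)
  n <- length(a)
  avec <- unlist(da, use.names = FALSE)
  # repeat every domain of protein a once per domain of protein b
  aa <- rep(avec, times = lb[rep(seq_len(n), la)])
  bb <- unlist(db[rep(seq_len(n), la)], use.names = FALSE)
  pair_idx <- rep(seq_len(n), la * lb)
  key <- paste(pmin(aa, bb), pmax(aa, bb), sep = "|")
  keep <- !duplicated(paste0(pair_idx, "\r", key))
  list(pair_idx = pair_idx[keep], key = key[keep])
}

#' Serialize a synthetic truth object to JSON
#' @param truth a `truth` list from any simulate_* generator.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
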