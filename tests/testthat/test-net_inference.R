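mi_from_pairs <- function(genes, vals) {
  # build a symmetric MI matrix from an upper-triangle value list
  G <- length(genes)
  M <- matrix(0, G, G, dimnames = list(genes, genes))
  k <- 0
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    k <- k + 1
    M[i, j] <- M[j, i] <- vals[k]
  }
  diag(M) <- 1
  structure(M, estimator = list(method = "equal_width", bins = 10,
                                order = 3),
            class = c("mi_matrix", "matrix", "array"))
}

test_that("CLR scores match a hand-computed oracle on a 5-gene toy", {
  withr::with_seed(50, {
    genes <- paste0("g", 1:5)
    vals <- runif(10, 0.1, 1)
    mi <- mi_from_pairs(genes, vals)
    cs <- clr_scores(mi)
    M <- unclass(mi)
    diag(M) <- NA
    for (i in 1:4) for (j in (i + 1):5) {
      zi <- (M[i, j] - mean(M[i, ], na.rm = TRUE)) / sd(M[i, ], na.rm = TRUE)
      zj <- (M[i, j] - mean(M[j, ], na.rm = TRUE)) / sd(M[j, ], na.rm = TRUE)
      expect_equal(cs$scores[i, j],
                   sqrt(max(0, zi)^2 + max(0, zj)^2), tolerance = 1e-12)
    }
  })
})

test_that("CLR degenerate backgrounds: equal MI rows give zero scores", {
  genes <- paste0("g", 1:4)
  mi <- mi_from_pairs(genes, rep(0.4, 6))
  cs <- clr_scores(mi)
  expect_true(all(cs$scores[upper.tri(cs$scores)] == 0))
  expect_setequal(cs$flagged, genes)
})

test_that("CLR networks threshold exactly, and +Inf empties the edge set", {
  withr::with_seed(51, {
    genes <- paste0("g", 1:6)
    mi <- mi_from_pairs(genes, runif(15, 0, 1))
    cs <- clr_scores(mi)
    net <- clr_network(cs, "cutoff", cutoff = 2.5)
    S <- cs$scores
    expected <- sum(S[upper.tri(S)] >= 2.5)
    expect_equal(nrow(net$edges), expected)
    expect_true(all(net$edges$score >= 2.5))
    expect_equal(nrow(clr_network(cs, "cutoff", cutoff = Inf)$edges), 0)
    expect_error(clr_network(cs, "fdr", fdr = 1.5, X = NULL), "fdr level")
  })
})

test_that("FDR-calibrated CLR keeps the false-edge fraction controlled", {
  false_edges <- 0
  total_edges <- 0
  for (s in 1:8) {
    sim <- simulate_grn_expression(n_regulators = 5,
                                   targets_per_regulator = 5,
                                   n_background = 30, n_samples = 60,
                                   seed = s)
    X <- sim$expr
    mi <- mi_matrix(X, regulators = sim$truth$regulators)
    net <- clr_network(clr_scores(mi), "fdr", fdr = 0.05, X = X,
                       n_perm = 3, seed = s)
    if (!nrow(net$edges)) next
    truekey <- paste(pmin(sim$truth$edges$regulator,
                          sim$truth$edges$target),
                     pmax(sim$truth$edges$regulator,
                          sim$truth$edges$target))
    ekey <- paste(net$edges$from, net$edges$to)
    false_edges <- false_edges + sum(!(ekey %in% truekey))
    total_edges <- total_edges + length(ekey)
  }
  expect_gt(total_edges, 0)
  expect_lte(false_edges / total_edges, 0.10)
})

test_that("DPI triangle arithmetic: strict minimum, ties, tolerance margin", {
  genes <- c("a", "b", "c")
  # (0.9, 0.8, 0.3), tolerance 0 -> the 0.3 edge is removed
  mi <- mi_from_pairs(genes, c(0.9, 0.8, 0.3))
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                      score = c(0.9, 0.8, 0.3), stringsAsFactors = FALSE)
  r0 <- dpi_prune(unclass(mi), edges, tolerance = 0)
  expect_equal(nrow(r0$removed), 1)
  expect_identical(r0$removed$from, "b")
  expect_identical(r0$removed$to, "c")
  expect_identical(r0$removed$witness, "a")

  # tie (0.5, 0.5, 0.5): no strict minimum, nothing removed
  mi_tie <- mi_from_pairs(genes, c(0.5, 0.5, 0.5))
  edges_tie <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                          score = c(0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  expect_equal(nrow(dpi_prune(unclass(mi_tie), edges_tie, 0)$removed), 0)

  # (0.9, 0.8, 0.72) at tolerance 0.15: 0.72 >= 0.85 * 0.8, retained
  mi_tol <- mi_from_pairs(genes, c(0.9, 0.8, 0.72))
  edges_tol <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                          score = c(0.9, 0.8, 0.72), stringsAsFactors = FALSE)
  r15 <- dpi_prune(unclass(mi_tol), edges_tol, tolerance = 0.15)
  expect_equal(nrow(r15$removed), 0)
  # and at tolerance 0 it is removed
  expect_equal(nrow(dpi_prune(unclass(mi_tol), edges_tol, 0)$removed), 1)
})

test_that("DPI equals exhaustive triangle enumeration on random graphs", {
  withr::with_seed(52, {
    for (trial in 1:30) {
      g <- random_weighted_graph(sample(5:20, 1))
      for (tol in c(0, 0.15)) {
        res <- dpi_prune(g$M, g$edges, tol)
        got <- if (nrow(res$removed))
          edge_keys(res$removed$from, res$removed$to) else character()
        want <- brute_force_dpi_removed(g$M, g$edges, tol)
        expect_setequal(got, want)
        # retained + removed partition the input
        expect_equal(nrow(res$retained) + nrow(res$removed), nrow(g$edges))
      }
    }
  })
})

test_that("aracne_network filters by significance then prunes, warning above 0.2", {
  sim <- simulate_grn_expression(n_regulators = 4, targets_per_regulator = 4,
                                 n_background = 20, n_samples = 50, seed = 6)
  mi <- mi_matrix(sim$expr)
  res <- aracne_network(mi, p_threshold = 1e-7, dpi_tolerance = 0.15,
                        X = sim$expr, seed = 6)
  expect_true(all(res$network$edges$score >= res$network$threshold))
  truekey <- paste(pmin(sim$truth$edges$regulator, sim$truth$edges$target),
                   pmax(sim$truth$edges$regulator, sim$truth$edges$target))
  ekey <- paste(res$network$edges$from, res$network$edges$to)
  # nearly all planted direct edges survive the filter + DPI; the residual
  # extra edges are indirect target-target dependencies DPI spares at
  # tolerance 0.15
  expect_gte(mean(truekey %in% ekey), 0.85)
  expect_gt(mean(ekey %in% truekey), 0.5)
  expect_warning(aracne_network(mi, dpi_tolerance = 0.25, mi_threshold = 0.5),
                 "0.2")
})

test_that("CLR at matched stringency is the more conservative algorithm", {
  conservative <- logical(0)
  for (s in 1:5) {
    sim <- simulate_grn_expression(n_regulators = 5,
                                   targets_per_regulator = 5,
                                   n_background = 30, n_samples = 60,
                                   seed = s)
    mi <- mi_matrix(sim$expr)
    cs <- clr_scores(mi)
    nclr <- clr_network(cs, "fdr", fdr = 0.05, X = sim$expr, n_perm = 3,
                        seed = s)
    ar <- aracne_network(mi, p_threshold = 0.01, dpi_tolerance = 0.15,
                         X = sim$expr, seed = s)
    pre_dpi <- nrow(ar$dpi$retained) + nrow(ar$dpi$removed)
    conservative <- c(conservative, nrow(nclr$edges) <= pre_dpi)
  }
  expect_true(all(conservative))
})
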