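make_reg_matrix <- function(n_reg = 10, n = 40, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n_reg * n), n_reg,
                dimnames = list(paste0("R", seq_len(n_reg)),
                                paste0("s", seq_len(n))))
    expression_matrix(M)
  })
}

test_that("bicluster responses condense member profiles", {
  X <- make_reg_matrix(6, 30, seed = 90)
  # single gene: its standardized profile
  r1 <- bicluster_response(X, list(genes = "R1"))
  expect_equal(unname(r1), as.numeric(scale(unclass(X)["R1", ])),
               tolerance = 1e-12)
  # two perfectly correlated genes: same profile as either
  M <- unclass(X)
  M <- rbind(M, dup = 3 * M["R1", ] + 5)
  X2 <- expression_matrix(M)
  r2 <- bicluster_response(X2, list(genes = c("R1", "dup")))
  expect_equal(unname(r2), unname(r1), tolerance = 1e-12)

  # planted block: response tracks the planted factor
  sim <- simulate_biclusters(n_genes = 100, n_samples = 40, p_planted = 1,
                             noise_sd = 0.5, seed = 91)
  b <- sim$truth$biclusters[[1]]
  resp <- bicluster_response(sim$expr,
                             list(genes = b$genes,
                                  gene_scores = b$lambda))
  z_full <- setNames(rep(0, ncol(sim$expr)), colnames(sim$expr))
  z_full[names(b$z)] <- b$z
  expect_gt(abs(cor(resp, z_full)), 0.9)
})

test_that("design matrices standardize, pair, and budget correctly", {
  X <- make_reg_matrix(3, 30, seed = 92)
  D <- design_matrix(X, c("R1", "R2", "R3"), interactions = TRUE)
  expect_equal(ncol(D), 3 + 3)
  expect_true(all(abs(colMeans(D[, 1:3])) < 1e-12))
  # "A_with_B" is the elementwise min of the standardized profiles
  expect_equal(unname(D[, "R1_with_R2"]),
               unname(pmin(D[, "R1"], D[, "R2"])), tolerance = 1e-12)
  # min(a, a) = a
  expect_equal(pmin(D[, "R1"], D[, "R1"]), D[, "R1"])
  # product encoding behind the flag
  Dp <- design_matrix(X, c("R1", "R2"), pair_encoding = "product")
  expect_equal(unname(Dp[, "R1_with_R2"]),
               unname(D[, "R1"] * D[, "R2"]), tolerance = 1e-12)
  # pair budget caps the interaction columns
  X8 <- make_reg_matrix(8, 30, seed = 93)
  y <- unclass(X8)["R1", ]
  Db <- design_matrix(X8, rownames(X8), pair_budget = 5, response = y)
  expect_equal(ncol(Db), 8 + 5)
  expect_error(design_matrix(X, character()), "empty")
  expect_error(design_matrix(X, "nope"), "nope")
})

test_that("an obvious single driver is called alone with positive sign", {
  hits <- 0
  for (s in 1:10) {
    X <- make_reg_matrix(10, 40, seed = 100 + s)
    y <- unclass(X)["R3", ] + withr::with_seed(200 + s, rnorm(40, sd = 0.1))
    D <- design_matrix(X, rownames(X), interactions = FALSE)
    calls <- select_regulators(y, D, seed = s)
    expect_true("R3" %in% calls$term)
    expect_identical(calls$sign[calls$term == "R3"], "positive")
    if (nrow(calls) == 1) hits <- hits + 1
  }
  expect_gte(hits, 8)  # the 1-SE rule occasionally keeps a spurious term
})

test_that("signed two-regulator recovery and null calibration", {
  ok <- 0
  for (s in 1:10) {
    X <- make_reg_matrix(20, 60, seed = 300 + s)
    y <- 2 * unclass(X)["R1", ] - unclass(X)["R2", ] +
      withr::with_seed(400 + s, rnorm(60, sd = 0.3))
    calls <- select_regulators(y, design_matrix(X, rownames(X),
                                                interactions = FALSE),
                               seed = s)
    s1 <- calls$sign[calls$term == "R1"]
    s2 <- calls$sign[calls$term == "R2"]
    if (length(s1) && s1 == "positive" && length(s2) && s2 == "negative")
      ok <- ok + 1
  }
  expect_gte(ok, 9)

  empty <- 0
  for (s in 1:10) {
    X <- make_reg_matrix(10, 40, seed = 500 + s)
    y <- withr::with_seed(600 + s, rnorm(40))
    if (nrow(select_regulators(y, design_matrix(X, rownames(X),
                                                interactions = FALSE),
                               seed = s)) == 0)
      empty <- empty + 1
  }
  expect_gte(empty, 8)
})

test_that("penalty path endpoints: OLS limit and the empty model", {
  withr::with_seed(94, {
    X <- make_reg_matrix(5, 50, seed = 95)
    y <- unclass(X)["R1", ] - 0.5 * unclass(X)["R4", ] + rnorm(50, sd = 0.2)
    D <- design_matrix(X, rownames(X), interactions = FALSE)
    fit <- glmnet::glmnet(D, y, alpha = 1)
    ols <- coef(lm(y ~ D))[-1]
    near_zero <- as.numeric(coef(fit, s = 1e-6))[-1]
    expect_lt(max(abs(near_zero - ols)), 0.02)
    all_pen <- as.numeric(coef(fit, s = 1e3))[-1]
    expect_true(all(all_pen == 0))
  })
})

test_that("calls are invariant to regulator column order", {
  X <- make_reg_matrix(8, 50, seed = 96)
  y <- 1.5 * unclass(X)["R2", ] - unclass(X)["R7", ] +
    withr::with_seed(97, rnorm(50, sd = 0.3))
  D <- design_matrix(X, rownames(X), interactions = FALSE)
  c1 <- select_regulators(y, D, seed = 5)
  c2 <- select_regulators(y, D[, rev(colnames(D))], seed = 5)
  expect_setequal(paste(c1$term, c1$sign), paste(c2$term, c2$sign))
})

test_that("constant design columns are dropped with a warning", {
  X <- make_reg_matrix(5, 40, seed = 98)
  D <- design_matrix(X, rownames(X), interactions = FALSE)
  D <- cbind(D, FLAT = rep(0, nrow(D)))
  y <- unclass(X)["R1", ] + withr::with_seed(99, rnorm(40, sd = 0.2))
  expect_warning(calls <- select_regulators(y, D, seed = 1), "FLAT")
  expect_false("FLAT" %in% calls$term)
})

test_that("AND-gate responses prefer the pair term over singles", {
  wins <- 0
  for (s in 1:10) {
    X <- make_reg_matrix(6, 60, seed = 700 + s)
    D <- design_matrix(X, rownames(X), interactions = TRUE)
    y <- D[, "R1_with_R2"] + withr::with_seed(800 + s, rnorm(60, sd = 0.25))
    calls <- select_regulators(y, D, seed = s)
    if (nrow(calls) && calls$term[1] == "R1_with_R2") wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("per-bicluster inference recovers a planted driver with its sign", {
  withr::with_seed(110, {
    n <- 50
    reg <- rnorm(n)
    members <- t(sapply(1:10, function(i) -1.2 * reg + rnorm(n, sd = 0.4)))
    decoys <- matrix(rnorm(8 * n), 8)
    X <- rbind(REG = reg, members, decoys,
               matrix(rnorm(20 * n), 20))
    rownames(X) <- c("REG", paste0("M", 1:10), paste0("D", 1:8),
                     paste0("B", 1:20))
    colnames(X) <- paste0("s", 1:n)
    X <- expression_matrix(X)
    bicset <- list(biclusters = list(list(
      id = 1, genes = paste0("M", 1:10),
      gene_scores = setNames(rep(1, 10), paste0("M", 1:10)))))
    calls <- infer_bicluster_regulators(X, bicset,
                                        c("REG", paste0("D", 1:8)),
                                        interactions = FALSE, seed = 1)
    expect_true("REG" %in% calls$term)
    expect_identical(calls$sign[calls$term == "REG"], "negative")
  })
})
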