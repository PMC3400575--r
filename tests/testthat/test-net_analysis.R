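test_that("consensus neighbors: identical, disjoint, and partial overlap", {
  A <- toy_network(rbind(c("T", "a"), c("T", "b"), c("T", "c")))
  expect_warning(r0 <- consensus_neighbors(A, A, c("T", "zz")), "zz")
  expect_equal(r0$n_shared[1], 3)
  expect_identical(r0$prop_A[1], "3/3")
  expect_equal(r0$n_A[2], 0)

  B <- toy_network(rbind(c("T", "b"), c("T", "c"), c("T", "d")))
  r <- consensus_neighbors(A, B, "T")
  expect_identical(r$shared, "b,c")
  expect_identical(r$prop_A, "2/3")
  expect_identical(r$prop_B, "2/3")

  C <- toy_network(rbind(c("T", "x"), c("T", "y")))
  expect_equal(consensus_neighbors(A, C, "T")$n_shared, 0)
})

test_that("consensus equals set-algebra brute force on random graph pairs", {
  withr::with_seed(70, {
    for (trial in 1:10) {
      gA <- random_weighted_graph(sample(10:40, 1), p_edge = 0.15)
      gB <- random_weighted_graph(sample(10:40, 1), p_edge = 0.15)
      nA <- gene_network(gA$edges)
      nB <- gene_network(gB$edges)
      probe <- sample(nA$nodes, 3)
      rep <- suppressWarnings(consensus_neighbors(nA, nB, probe))
      for (k in seq_along(probe)) {
        g <- probe[k]
        # independent oracle from the adjacency matrices
        na_ <- if (g %in% rownames(gA$M)) names(which(gA$M[g, ] > 0))
               else character()
        nb_ <- if (g %in% rownames(gB$M)) names(which(gB$M[g, ] > 0))
               else character()
        expect_equal(rep$n_A[k], length(na_))
        expect_equal(rep$n_shared[k], length(intersect(na_, nb_)))
      }
    }
  })
})

test_that("hub ranking: star center first, complete graph lexicographic", {
  star <- toy_network(cbind("hub", paste0("leaf", 1:5)))
  h <- hub_rank(star)
  expect_identical(h$gene[1], "hub")
  expect_equal(h$degree[1], 5)

  k4 <- toy_network(t(combn(c("d", "b", "a", "c"), 2)))
  h4 <- hub_rank(k4)
  expect_identical(h4$gene, c("a", "b", "c", "d"))
  expect_true(all(h4$degree == 3))
  expect_error(hub_rank(gene_network(NULL)), "empty")
})

test_that("regulators out-rank background genes in a planted-regulon CLR network", {
  sim <- simulate_grn_expression(n_regulators = 5, targets_per_regulator = 6,
                                 n_background = 30, n_samples = 80, seed = 71)
  mi <- mi_matrix(sim$expr, regulators = sim$truth$regulators)
  net <- clr_network(clr_scores(mi), "cutoff", cutoff = 2.5)
  deg <- setNames(net$node_attrs$degree, net$node_attrs$node)
  regs <- sim$truth$regulators
  bg <- grep("^B", net$node_attrs$node, value = TRUE)
  expect_gt(median(deg[regs]), median(deg[bg]))
})

test_that("DE overlay annotates directions idempotently with style colors", {
  net <- toy_network(rbind(c("g1", "g2"), c("g2", "g3")))
  de <- data.frame(id = c("g1", "g2"), direction = c("down", "up"),
                   stringsAsFactors = FALSE)
  class(de) <- c("de_result", class(de))
  ov <- overlay_de(net, de)
  dirs <- setNames(ov$node_attrs$direction, ov$node_attrs$node)
  expect_identical(unname(dirs[c("g1", "g2", "g3")]),
                   c("down", "up", "unknown"))
  # suppressed genes are drawn olive-green, elevated white
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(ov, path, "sif")
  attrs <- read.delim(paste0(path, ".nodes.tsv"))
  expect_identical(attrs$style[attrs$node == "g1"], "olive-green")
  expect_identical(attrs$style[attrs$node == "g2"], "white")
  expect_identical(overlay_de(ov, de), ov)

  empty_de <- de[0, ]
  all_unknown <- overlay_de(net, empty_de)
  expect_true(all(all_unknown$node_attrs$direction == "unknown"))
})

test_that("neighbors_within walks 0/1/2 intervening nodes with witnesses", {
  net <- path_network(c("a", "b", "c", "d"))
  r1 <- neighbors_within(net, "a", 1)
  expect_setequal(r1$gene, c("b", "c"))
  r2 <- neighbors_within(net, "a", 2)
  expect_setequal(r2$gene, c("b", "c", "d"))
  expect_identical(r2$path[r2$gene == "d"], "a -> b -> c -> d")
  r0 <- neighbors_within(net, "a", 0)
  expect_identical(r0$gene, "b")
  # monotone in the allowed number of intervening nodes
  expect_true(all(r1$gene %in% r2$gene))
  expect_error(neighbors_within(net, "zz", 1), "zz")
})

test_that("gene-set restriction: identity, union counting, deduplication", {
  withr::with_seed(72, {
    X <- expression_matrix(matrix(rnorm(30 * 8), 30,
                                  dimnames = list(paste0("g", 1:30),
                                                  paste0("s", 1:8))))
    all_set <- list(everything = rownames(X))
    expect_equal(unclass(subnetwork_by_sets(X, all_set, "everything")),
                 unclass(X), ignore_attr = TRUE)

    # sets of sizes 10 and 15 with 5 members absent -> 20 rows retained
    sets <- list(s1 = paste0("g", 1:10),
                 s2 = c(paste0("g", 16:25), paste0("zz", 1:5)))
    sub <- subnetwork_by_sets(X, sets, c("s1", "s2"))
    expect_equal(nrow(sub), 20)
    expect_equal(unname(attr(sub, "set_hits")), c(10L, 10L))

    # union semantics: a shared gene appears once
    sets2 <- list(a = c("g1", "g2"), b = c("g2", "g3"))
    expect_equal(nrow(subnetwork_by_sets(X, sets2, c("a", "b"))), 3)

    expect_error(subnetwork_by_sets(X, list(a = "nope"), "a"), "no gene")
    expect_error(subnetwork_by_sets(X, sets2, "missing_set"), "unknown")
  })
})

test_that("locus overlap reproduces the chromosome-2 fixture classification", {
  fx <- table_bands_fixture()
  rep <- locus_overlap(fx$rows, fx$bands, "2q33.3-2q37.2")
  in_or_border <- unique(rep$gene[rep$classification %in%
                                    c("inside", "bordering")])
  expect_setequal(in_or_border, fx$bold)
  outside <- unique(rep$gene[rep$classification == "outside"])
  expect_setequal(outside, setdiff(unique(fx$rows$gene), fx$bold))
  # spot classifications: in-locus span, edge band, other arm
  cls <- function(g) unique(rep$classification[rep$gene == g])
  expect_identical(cls("COL4A3"), "inside")
  expect_identical(cls("PDCD1"), "bordering")
  expect_identical(cls("HSPD1"), "bordering")
  expect_identical(cls("ANXA4"), "outside")
  expect_identical(cls("IL1A"), "outside")
  # missing gene -> unknown with a warning
  rows2 <- data.frame(hub = "H", gene = "MYSTERY", stringsAsFactors = FALSE)
  expect_warning(u <- locus_overlap(rows2, fx$bands, "2q33.3-2q37.2"),
                 "MYSTERY")
  expect_identical(u$classification, "unknown")
})

test_that("network union keeps the maximum score on conflicting edges", {
  A <- toy_network(rbind(c("a", "b"), c("b", "c")), scores = c(1, 5))
  B <- toy_network(rbind(c("a", "b"), c("c", "d")), scores = c(3, 2))
  U <- union_networks(A, B)
  expect_equal(nrow(U$edges), 3)
  ab <- U$edges[U$edges$from == "a" & U$edges$to == "b", ]
  expect_equal(ab$score, 3)
  expect_true(ab$merged_max_score)
  expect_false(U$edges$merged_max_score[U$edges$from == "b"])
})
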