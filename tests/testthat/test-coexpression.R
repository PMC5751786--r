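test_that("signed adjacency maps correlation through ((1+r)/2)^beta", {
  s <- seq_len(10)
  x <- rbind(a = s, b = 2 * s + 3,      # r = 1
             c = -s,                    # r = -1 with a
             d = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  a <- signed_adjacency(x, beta = 12)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 0)
  expect_equal(diag(a), rep(0, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(a))
  # r = 0 at beta 12 gives 0.5^12
  x0 <- rbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  a0 <- signed_adjacency(x0, beta = 12)
  expect_equal(a0["a", "b"], 0.5^12)
  expect_equal(a0["a", "b"], 2.44140625e-4)
  expect_error(signed_adjacency(x, beta = 0), "beta")
  expect_warning(signed_adjacency(rbind(x, e = rep(1, 10))), "constant")
})

test_that("TOM matches its defining formula on hand-checkable cases", {
  # 3-node clique with unit adjacency has perfect overlap
  a3 <- matrix(1, 3, 3); diag(a3) <- 0
  expect_equal(topological_overlap(a3),
               matrix(1, 3, 3), ignore_attr = TRUE)
  # two nodes only: TOM equals the adjacency
  a2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.5)
  # empty adjacency gives zero off-diagonal
  a0 <- matrix(0, 4, 4)
  expect_equal(topological_overlap(a0), diag(4), ignore_attr = TRUE)
})

test_that("vectorized TOM equals the triple-loop oracle and stays in [0,1]", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- topological_overlap(a)
    expect_equal(tom, tom_loop(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  # 2-node limit holds for random adjacencies
  for (v in runif(5)) {
    a <- matrix(c(0, v, v, 0), 2, 2)
    expect_equal(topological_overlap(a)[1, 2], v)
  }
})

test_that("module detection applies the size rule deterministically", {
  # two tight blocks with dimnames, below min size -> all unassigned
  set.seed(5)
  tom <- diag(10) * 0 + 0.05
  tom[1:5, 1:5] <- 0.9; tom[6:10, 6:10] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
  expect_warning(p <- detect_modules(tom, min_module_size = 30), "unassigned")
  expect_true(all(p == "unassigned"))
  p2 <- detect_modules(tom, min_module_size = 3)
  expect_equal(length(attr(p2, "modules")), 2L)
  expect_setequal(attr(p2, "modules")$M1, sprintf("g%02d", 1:5))  # tie -> smallest id
  # duplicated rows (zero distance) co-cluster
  expect_equal(unname(p2["g01"]), unname(p2["g02"]))
})

test_that("planted modules are recovered from expression end to end", {
  cfg <- synthetic_config(seed = 12, within_module_cor = 0.9, n_samples = 100)
  g <- generate_genomes(cfg)
  em <- generate_expression(cfg, g$truth, "A")
  ma <- g$truth$module_assignment
  feats <- c(ma$id, sample(setdiff(rownames(em$values), ma$id), 30))
  adj <- signed_adjacency(em$values[feats, ], beta = 12, log_transform = TRUE)
  part <- detect_modules(topological_overlap(adj))
  truth <- stats::setNames(ma$module, ma$id)
  ari <- mclust::adjustedRandIndex(part[ma$id], truth[ma$id])
  expect_gte(ari, 0.9)
  expect_equal(length(attr(part, "modules")), cfg$n_modules)
})

test_that("connectivity is degree over module total degree", {
  ids <- c("x", "y", "z")
  # all pairwise TOM 0.3 -> triangle, equal connectivity
  tom <- matrix(0.3, 3, 3, dimnames = list(ids, ids)); diag(tom) <- 1
  part <- structure(stats::setNames(rep("M1", 3), ids),
                    class = "module_partition",
                    modules = list(M1 = ids))
  ct <- module_connectivity(tom, part, tom_edge_cutoff = 0.2)
  expect_equal(ct$degree, c(2, 2, 2))
  expect_equal(ct$connectivity, rep(1 / 3, 3))
  # path topology x-y-z
  tomp <- matrix(0, 3, 3, dimnames = list(ids, ids))
  tomp["x", "y"] <- tomp["y", "x"] <- 0.5
  tomp["y", "z"] <- tomp["z", "y"] <- 0.5
  diag(tomp) <- 1
  ctp <- module_connectivity(tomp, part, tom_edge_cutoff = 0.2)
  expect_equal(ctp$degree, c(1, 2, 1))
  expect_equal(ctp$connectivity, c(0.25, 0.5, 0.25))
  expect_equal(sum(ctp$connectivity), 1)
  # isolated node in a module scores zero
  tomi <- tomp; tomi["x", c("y", "z")] <- tomi[c("y", "z"), "x"] <- 0.1
  cti <- module_connectivity(tomi, part, tom_edge_cutoff = 0.2)
  expect_equal(cti$connectivity[1], 0)
})

test_that("connectivity comparison is a one-sided rank-sum test", {
  ct <- data.frame(node_id = sprintf("n%d", 1:40),
                   module = "M1", degree = 1,
                   connectivity = c(rep(0.9, 20), rep(0.1, 20)),
                   node_type = rep(c("lncRNA", "PCG"), each = 20))
  r <- compare_connectivity(ct)
  expect_lt(r$p_value, 1e-6)
  expect_equal(unname(r$medians), c(0.9, 0.1))
  # identical distributions: no evidence either way
  ct$connectivity <- rep(c(0.2, 0.4), 20)
  expect_gt(compare_connectivity(ct)$p_value, 0.2)
  expect_error(compare_connectivity(ct[ct$node_type == "PCG", ]), ">= 3")
})

test_that("soft-threshold picker falls back to the signed convention", {
  set.seed(3)
  x <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(sprintf("g%d", 1:40), NULL))
  ps <- pick_soft_threshold(x, powers = c(1, 2))
  expect_true(ps$beta %in% c(1, 2, 12))
  expect_equal(nrow(ps$fits), 2L)
})
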