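# hand-rolled per-pair Hamming oracle
hamming_oracle <- function(calls) {
  n <- nrow(calls)
  D <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(calls[i, ] != calls[j, ])
    }
  }
  D
}

random_matrix <- function(seed, n = 5, m = 30) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 1, 0.4), n, m,
    dimnames = list(paste0("S", seq_len(n)), paste0("v", seq_len(m)))
  )
  calls["S1", ] <- 0L
  calls
}

test_that("Manhattan distance on binary calls equals the Hamming oracle", {
  expect_equal(
    unname(manhattan_distance(rbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1)))["a", "b"]), 2
  )
  expect_equal(
    unname(manhattan_distance(rbind(a = c(1, 1), b = c(1, 1)))["a", "b"]), 0
  )
  for (seed in 1:5) {
    calls <- random_matrix(seed)
    D <- manhattan_distance(calls)
    expect_equal(unname(D), unname(hamming_oracle(calls)), ignore_attr = TRUE)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
  }
  expect_error(manhattan_distance(rbind(a = c(0, 2), b = c(0, 1))), "non-binary")
})

test_that("topology enumeration has the right counts", {
  expect_equal(length(tertdup:::enumerate_topologies(3)), 1)
  expect_equal(length(tertdup:::enumerate_topologies(4)), 3)
  expect_equal(length(tertdup:::enumerate_topologies(5)), 15)
  expect_equal(length(tertdup:::enumerate_topologies(6)), 105)
})

test_that("OLS minimum evolution recovers additive trees exactly (n = 4..8)", {
  for (n in c(4, 5, 6, 8)) {
    set.seed(n * 13)
    true <- ape::rtree(n, tip.label = paste0("S", seq_len(n)))
    true$edge.length <- round(true$edge.length * 10) + 1
    D <- ape::cophenetic.phylo(true)
    fit <- ols_me_tree(D, root_label = "S1")
    expect_lt(fit$residual, 1e-18)
    # recovered tree metric equals the input distances exactly
    rec <- ape::cophenetic.phylo(fit$tree)[rownames(D), colnames(D)]
    expect_equal(unname(rec), unname(D), tolerance = 1e-10)
  }
})

test_that("exhaustive search agrees with the independent fastme.ols implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    set.seed(seed)
    true <- ape::rtree(5, tip.label = paste0("S", 1:5))
    true$edge.length <- round(true$edge.length * 20) + 2
    D <- ape::cophenetic.phylo(true)
    fit <- ols_me_tree(D, root_label = "S1")
    reference <- ape::fastme.ols(as.dist(D), nni = TRUE)
    expect_equal(
      phangorn::RF.dist(ape::unroot(fit$tree), ape::unroot(reference)), 0
    )
  }
})

test_that("sizes beyond the exhaustive limit need the explicit heuristic flag", {
  calls <- random_matrix(1, n = 10, m = 60)
  D <- manhattan_distance(calls)
  expect_error(ols_me_tree(D, root_label = "S1"), "exhaustive_max")
  fit <- ols_me_tree(D, root_label = "S1", allow_heuristic = TRUE)
  expect_equal(sort(fit$tree$tip.label), sort(rownames(calls)))
})

test_that("a planted multiregion tumor is reconstructed with the normal on the root edge", {
  sim <- gen_multiregion(sim_config(seed = 23))
  D <- manhattan_distance(sim$matrix)
  fit <- ols_me_tree(D, root_label = "N")
  expect_lt(fit$residual, 1e-16)
  # recovered tumor topology matches the planted tree
  skip_if_not_installed("phangorn")
  rec_tumor <- ape::unroot(ape::drop.tip(fit$tree, "N"))
  expect_equal(phangorn::RF.dist(rec_tumor, ape::unroot(sim$tree)), 0)
})

test_that("mutations map to edges by presence pattern, truncal on the trunk", {
  sim <- gen_multiregion(sim_config(seed = 31))
  fit <- ols_me_tree(manhattan_distance(sim$matrix), root_label = "N")
  asg <- assign_mutations(sim$matrix, fit)
  expect_equal(sum(asg$clusters$n), ncol(sim$matrix$calls))
  truncal <- asg$clusters[asg$clusters$truncal, ]
  expect_equal(nrow(truncal), 1)
  expect_equal(truncal$n, 17)
  expect_false(any(asg$clusters$homoplasy))
  # every planted cluster recovered with its exact size
  planted <- sort(sim$clusters$size)
  expect_equal(sort(asg$clusters$n), planted)
  # single-sample pattern maps to that terminal edge
  single <- asg$clusters[grepl("^10+$", asg$clusters$pattern), ]
  if (nrow(single)) expect_equal(single$edge, asg$tumor_order[1])
})

test_that("an incompatible pattern is homoplasy-flagged on its minimal covering edge", {
  # caterpillar tree over 5 tumors + normal, plus one planted 10101 variant
  calls <- matrix(0L, 6, 16, dimnames = list(
    c("N", paste0("T", 1:5)), paste0("v", 1:16)
  ))
  calls[paste0("T", 1:5), 1:5] <- 1L # truncal block
  calls[paste0("T", 1:2), 6:8] <- 1L
  calls["T1", 9:11] <- 1L
  calls["T2", 12] <- 1L
  calls[paste0("T", 4:5), 13:14] <- 1L
  calls["T5", 15] <- 1L
  calls["T1", 16] <- 1L
  calls["T3", 16] <- 1L
  calls["T5", 16] <- 1L # pattern 10101: no clade matches
  M <- mutation_matrix(calls, normal = "N")
  fit <- ols_me_tree(manhattan_distance(M), root_label = "N")
  asg <- assign_mutations(M, fit)
  bad <- asg$assignments[asg$assignments$variant == "v16", ]
  expect_true(bad$homoplasy)
  expect_match(bad$edge, "clade")
  expect_equal(sum(asg$clusters$n), 16)
})

test_that("newick output re-parses to an isomorphic tree", {
  sim <- gen_multiregion(sim_config(seed = 41))
  fit <- ols_me_tree(manhattan_distance(sim$matrix), root_label = "N")
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(fit, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, fit$tree$tip.label)
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(back), ape::unroot(fit$tree)), 0)
  expect_true(all(back$edge.length >= 0))
})
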