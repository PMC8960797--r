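test_that("preference setting uses the quantile of off-diagonal values", {
  S <- matrix(0.3, 4, 4)
  expect_equal(unique(diag(set_preference(S, 0.5))), 0.3)
  expect_equal(unique(diag(set_preference(S, 0.9))), 0.3)
  S2 <- matrix(c(0, 0, 1, 0), 2, 2)        # off-diagonal values {0, 1}
  expect_equal(unique(diag(set_preference(S2, 0.5))), 0.5)
  S3 <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  expect_equal(unique(diag(set_preference(S3, 0))), 0)        # minimum
  expect_equal(unique(diag(set_preference(S3, 1))), 1)        # maximum
  off <- S3[row(S3) != col(S3)]
  expect_equal(unique(diag(set_preference(S3, 0.5))),
               unname(quantile(off, 0.5)))
  expect_error(set_preference(matrix(numeric(), 0, 0)), "empty")
})

test_that("a single item clusters as its own exemplar", {
  S <- matrix(0.4, 1, 1, dimnames = list("a", "a"))
  res <- affinity_propagation(S)
  expect_equal(unname(res$cluster), 1L)
  expect_equal(unname(res$exemplars), "a")
  expect_true(res$converged)
})

test_that("two tight pairs with weak cross-similarity split into two clusters", {
  S <- matrix(0.1, 4, 4)
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.9
  diag(S) <- 0.5
  rownames(S) <- colnames(S) <- letters[1:4]
  res <- suppressWarnings(affinity_propagation(S, seed = 3))
  expect_equal(length(res$exemplars), 2L)
  expect_equal(res$cluster[["a"]], res$cluster[["b"]])
  expect_equal(res$cluster[["c"]], res$cluster[["d"]])
  expect_false(res$cluster[["a"]] == res$cluster[["c"]])
  # exhaustive search agrees this is optimal
  bf <- brute_force_exemplars(S)
  expect_equal(res$net_similarity, bf$net_similarity, tolerance = 1e-9)
})

test_that("brute force prefers one cluster when joint similarity beats preferences", {
  S <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  bf <- brute_force_exemplars(S)
  expect_equal(length(bf$exemplars), 1L)
  expect_equal(bf$net_similarity, 1.0)   # 0.9 member + 0.1 preference
  expect_error(brute_force_exemplars(matrix(0, 12, 12)), "n <= 10")
})

test_that("AP reaches >= 95% of the exact optimum on random nonnegative instances", {
  ok <- 0L
  n_inst <- 100L
  for (s in seq_len(n_inst)) {
    set.seed(s)
    n <- sample(3:8, 1)
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    S <- set_preference(S, 0.5)
    ap <- suppressWarnings(affinity_propagation(S, seed = s))
    bf <- brute_force_exemplars(S)
    expect_lte(ap$net_similarity, bf$net_similarity + 1e-9)   # oracle is an upper bound
    if (ap$net_similarity >= 0.95 * bf$net_similarity) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})

test_that("planted five-block structure is recovered at high ARI with q = 0.5", {
  fx <- planted_similarity(200, 5, within = 0.8, between = 0.1,
                           noise = 0.05, seed = 42)
  S <- set_preference(fx$S, 0.5)
  res <- suppressWarnings(affinity_propagation(S, seed = 1))
  expect_gte(ari(res$cluster, fx$blocks), 0.9)
})

test_that("permuting item order permutes labels only", {
  fx <- planted_similarity(30, 3, seed = 5)
  S <- set_preference(fx$S, 0.5)
  res1 <- suppressWarnings(affinity_propagation(S, jitter = 0, seed = 1))
  perm <- sample(nrow(S))
  Sp <- S[perm, perm]
  res2 <- suppressWarnings(affinity_propagation(Sp, jitter = 0, seed = 1))
  ids <- rownames(S)
  expect_equal(ari(res1$cluster[ids], res2$cluster[ids]), 1)
})

test_that("cluster count trends upward in the preference quantile", {
  counts <- sapply(c(0.1, 0.9), function(q) {
    med <- sapply(1:10, function(s) {
      fx <- planted_similarity(40, 4, within = 0.6, between = 0.2,
                               noise = 0.1, seed = s)
      S <- set_preference(fx$S, q)
      length(suppressWarnings(affinity_propagation(S, seed = s))$exemplars)
    })
    median(med)
  })
  expect_lte(counts[1], counts[2])
})

test_that("agglomeration merges the most similar clusters first and is identity at current k", {
  fx <- planted_similarity(24, 3, within = 0.9, between = 0.1,
                           noise = 0.02, seed = 9)
  S <- set_preference(fx$S, 0.5)
  res <- suppressWarnings(affinity_propagation(S, seed = 1))
  k <- length(res$exemplars)
  same <- agglomerate_exemplars(S, res, k)
  expect_equal(ari(same$cluster, res$cluster), 1)
  expect_equal(nrow(same$merges), 0L)
  merged <- agglomerate_exemplars(S, res, k - 1L)
  expect_equal(length(unique(merged$cluster)), k - 1L)
  # first merge matches exhaustive evaluation of the joint-exemplar score
  groups <- split(names(res$cluster), res$cluster)
  best <- -Inf; best_pair <- NULL
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      u <- c(groups[[i]], groups[[j]])
      sc <- max(sapply(u, function(e) mean(S[setdiff(u, e), e])))
      if (sc > best) { best <- sc; best_pair <- sort(c(names(groups)[i], names(groups)[j])) }
    }
  }
  expect_equal(sort(c(merged$merges$cluster_a[1], merged$merges$cluster_b[1])),
               best_pair)
  expect_error(agglomerate_exemplars(S, res, k + 1L), "exceeds")
})
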