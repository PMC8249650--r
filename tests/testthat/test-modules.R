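test_that("wilcoxon exact p matches enumeration on canonical cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)
  expect_equal(res$p.value, 0.1)                 # 2/20 assignments
  # identical groups give p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 2, 5), c(2, 5, 2))$p.value, 1)
  # symmetry under group swap
  x <- c(0.3, 1.2, 7); y <- c(0.1, 0.4, 2.2, 9)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               wilcoxon_rank_sum(y, x)$p.value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("wilcoxon exact p equals the enumeration oracle for n <= 10", {
  set.seed(42)
  for (rep in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    # integer draws so ties occur often
    x <- sample(1:4, na, replace = TRUE)
    y <- sample(1:4, nb, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, oracle_wilcoxon_p(x, y),
                 info = paste("x:", paste(x, collapse = ","),
                              "y:", paste(y, collapse = ",")))
  }
  # tie-free case cross-checked against the standard exact test
  x <- c(1.1, 3.2, 5.5, 7.1); y <- c(2.2, 4.1, 9.9)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("differential screen honours its two thresholds", {
  sim <- simulate_expression_matrix(30, 12, integer(0), seed = 8)
  mat <- abs(sim$matrix) + 1
  groups <- rep(c("a", "b"), each = 6)
  # planted 4-fold feature is recovered
  mat[1, groups == "a"] <- mat[1, groups == "a"] * 8
  hits <- differential_features(mat, groups)
  expect_true("gene_00001" %in% hits$feature)
  # a feature identical across groups is excluded
  mat[2, ] <- 3
  expect_false("gene_00002" %in%
                 differential_features(mat, groups)$feature)
  # no-op thresholds return everything
  all <- differential_features(mat, groups, p_threshold = 1,
                               lfc_threshold = 0)
  expect_equal(nrow(all), nrow(mat))
})

test_that("module detection recovers planted modules", {
  # zero noise: perfect recovery
  sim0 <- simulate_expression_matrix(110, 10, c(40, 40), noise_sd = 0,
                                     seed = 12)
  det0 <- detect_modules(sim0$matrix)
  expect_equal(adjusted_rand_index(sim0$labels[sim0$labels > 0],
                                   det0$labels[sim0$labels > 0]), 1)
  # empty module spec: everything unassigned
  simn <- simulate_expression_matrix(120, 12, integer(0), seed = 13)
  detn <- detect_modules(simn$matrix)
  expect_gte(mean(detn$labels == "unassigned"), 0.9)
})

test_that("module detection is invariant under gene permutation", {
  sim <- simulate_expression_matrix(140, 12, c(45, 45), noise_sd = 0.4,
                                    seed = 14)
  det <- detect_modules(sim$matrix)
  set.seed(1); p <- sample(nrow(sim$matrix))
  detp <- detect_modules(sim$matrix[p, ])
  expect_equal(adjusted_rand_index(det$labels[rownames(sim$matrix)[p]],
                                   detp$labels), 1)
})

test_that("constant gene rows are dropped with a warning", {
  sim <- simulate_expression_matrix(80, 8, c(40), noise_sd = 0.3, seed = 15)
  m <- sim$matrix; m[5, ] <- 2
  expect_warning(det <- detect_modules(m), "constant")
  expect_equal(length(det$labels), 79L)
})

test_that("module eigengene has unit norm, orientation and variance 1 in
           the rank-one case", {
  profile <- c(1, 3, 2, 5, 4, 6)
  mat <- matrix(rep(profile, each = 4), 4, 6, byrow = FALSE)
  mat <- mat * c(1, 2, 3, 4)                  # scaled copies of one profile
  colnames(mat) <- paste0("s", 1:6)
  me <- module_eigengene(mat)
  expect_equal(sum(me$eigengene^2), 1, tolerance = 1e-12)
  expect_equal(me$variance_explained, 1, tolerance = 1e-12)
  expect_gt(stats::cor(me$eigengene, profile), 0.999)
  # flipping all gene rows flips nothing after orientation
  me2 <- module_eigengene(-mat)
  expect_gt(stats::cor(me2$eigengene, colMeans(-mat)), 0.999)
  expect_error(module_eigengene(matrix(1, 3, 4)), "constant|degenerate")
})

test_that("eigengenes track planted module profiles under noise", {
  sim <- simulate_expression_matrix(160, 12, c(50, 50), noise_sd = 0.5,
                                    seed = 16)
  det <- detect_modules(sim$matrix)
  for (m in colnames(det$eigengenes)) {
    best <- max(vapply(sim$effects, function(p)
      abs(stats::cor(det$eigengenes[, m], p)), numeric(1)))
    expect_gte(best, 0.95)
  }
})

test_that("hypergeometric p equals enumeration for all small cases", {
  # spot value: N=10, K=5, n=5, k=5 -> 1/252
  res <- hypergeometric_enrichment(
    paste0("g", 1:5), list(pw = paste0("g", 1:5)), paste0("g", 1:10))
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # exhaustive agreement with the draw-counting oracle at N = 8
  N <- 8
  bg <- paste0("g", 1:N)
  for (K in c(2, 4, 6)) for (n in c(1, 3, 5)) {
    pw <- list(pw = bg[seq_len(K)])
    for (k_target in 0:min(K, n)) {
      if (n - k_target > N - K) next  # infeasible draw
      module <- c(bg[seq_len(k_target)],
                  bg[setdiff(seq_len(N), seq_len(K))][
                    seq_len(n - k_target)])
      res <- hypergeometric_enrichment(module, pw, bg)
      expect_equal(res$p_value, oracle_hypergeom_p(N, K, n, res$k),
                   tolerance = 1e-9,
                   info = sprintf("K=%d n=%d k=%d", K, n, res$k))
    }
  }
})

test_that("enrichment handles the boundary cases and adjusts p-values", {
  bg <- paste0("g", 1:12)
  sets <- list(a = bg[1:4], b = bg[5:12])
  # k = 0 forces p = 1 (upper tail includes X >= 0)
  res <- hypergeometric_enrichment(bg[5:6], sets["a"], bg)
  expect_equal(res$p_value, 1)
  # module = background forces k = K and p = 1
  res2 <- hypergeometric_enrichment(bg, sets, bg)
  expect_equal(res2$p_value, c(1, 1))
  # BH adjustment is applied across pathways
  res3 <- hypergeometric_enrichment(bg[1:4], sets, bg)
  expect_equal(res3$adjusted_p,
               stats::p.adjust(res3$p_value, "BH"))
  expect_error(hypergeometric_enrichment("zz", sets, bg), "background")
})

test_that("pathway false-positive rate is controlled on pure noise", {
  set.seed(99)
  n_sig <- 0; n_tests <- 0
  bg <- paste0("g", 1:200)
  for (i in 1:100) {
    module <- sample(bg, 30)
    sets <- list(p1 = sample(bg, 25), p2 = sample(bg, 40))
    res <- hypergeometric_enrichment(module, sets, bg)
    n_sig <- n_sig + sum(res$adjusted_p < 0.05)
    n_tests <- n_tests + nrow(res)
  }
  expect_lte(n_sig / n_tests, 0.05)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(c("x", "y", "z"), 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(letters[1:5], 2)),
               mclust::adjustedRandIndex(1:10, rep(letters[1:5], 2)))
})
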