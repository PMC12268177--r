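nb_counts <- function(n_genes = 400L, n_samples = 4L, seed = 1L,
                      mu = 100) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 10),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

test_that("identical libraries get unit TMM factors", {
  m <- nb_counts(n_samples = 1L)
  m <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  expect_equal(unname(tmm_factors(m)), rep(1, 3))
})

test_that("a doubled library gives factors (1/sqrt(2), sqrt(2))", {
  a <- nb_counts(n_samples = 1L)[, 1] + 1L   # strictly positive counts
  m <- cbind(A = a, B = 2L * a)
  f <- tmm_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM factors are invariant to gene order", {
  m <- nb_counts(n_samples = 4L, seed = 3L)
  set.seed(5)
  perm <- sample(nrow(m))
  expect_equal(unname(tmm_factors(m)), unname(tmm_factors(m[perm, ])))
})

test_that("all-zero samples are rejected", {
  m <- nb_counts(n_samples = 2L)
  m[, 2] <- 0L
  expect_error(tmm_factors(m), "all-zero")
})

test_that("TMM agrees with edgeR's calcNormFactors on equal-depth data", {
  skip_if_not_installed("edgeR")
  m <- nb_counts(n_genes = 2000L, n_samples = 4L, seed = 11L)
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  # conventions differ (raw-count vs depth-normalised M); on equal-depth
  # data both estimate the same composition factors
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("expression values follow the stated arithmetic", {
  # count 100, library 1e6, factor 1, length 2000 bp -> 50
  m <- matrix(c(100L, 999900L), ncol = 1,
              dimnames = list(c("g1", "g2"), "s1"))
  v <- expression_values(m, factors = c(s1 = 1), lengths = c(2000, 1000))
  expect_equal(v["g1", "s1"], 50)
  m0 <- m; m0["g1", 1] <- 0L
  v0 <- expression_values(m0, factors = c(s1 = 1), lengths = c(2000, 1000))
  expect_equal(v0["g1", "s1"], 0)
})

test_that("scaling one library's counts leaves expression values unchanged", {
  m <- nb_counts(n_genes = 500L, n_samples = 4L, seed = 7L) + 1L
  len <- stats::setNames(sample(500:5000, nrow(m)), rownames(m))
  v1 <- expression_values(m, lengths = len)
  m2 <- m; m2[, 2] <- 3L * m2[, 2]
  v2 <- expression_values(m2, lengths = len)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("the display transform adds the pseudocount monotonically", {
  expect_equal(log_display(0), 1)
  x <- c(0, 0.5, 2, 100)
  expect_true(all(diff(log_display(x)) > 0))
  expect_identical(log_display(x, offset = 0), x)
})

test_that("noiseless flat and cubic genes are classified exactly", {
  times <- rep(c(12, 13, 14, 16), each = 2)
  flat <- rep(5, 8)
  cubic <- exp(0.01 * (times - 12)^3 + 0.1 * times) - 1
  set.seed(1)
  noisy <- exp(stats::rnorm(8)) - 1
  expr <- rbind(flat = flat, cubic = cubic, noisy = noisy)
  res <- timecourse_deg(expr, times)
  expect_equal(res$p[res$gene_id == "flat"], 1)
  expect_lt(res$p[res$gene_id == "cubic"], 1e-12)
  expect_true(res$is_deg[res$gene_id == "cubic"])
  expect_false(res$is_deg[res$gene_id == "flat"])
})

test_that("degree is capped by the number of distinct times", {
  times <- rep(c(0, 1), each = 3)
  set.seed(2)
  expr <- matrix(exp(stats::rnorm(12)), 2, 6,
                 dimnames = list(c("a", "b"), NULL))
  res <- timecourse_deg(expr, times, max_degree = 3)
  expect_true(all(is.finite(res$p)))   # degree 1 fit, 4 residual df
})

test_that("planted orthogonal profiles cluster into their own groups", {
  stages <- rep(c("E12", "E13", "E14", "E16"), each = 2)
  shapes <- rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 0, 1), c(0, 1, 1, 0),
    c(1, 0, 1, 0))
  expr <- do.call(rbind, lapply(seq_len(nrow(shapes)), function(i) {
    profile <- exp(3 * shapes[i, ]) - 1
    m <- t(replicate(12, rep(profile, each = 2)))
    rownames(m) <- paste0("s", i, "_", seq_len(12))
    m
  }))
  cl <- cluster_profiles(expr, stages, k = 9, seed = 42)
  group <- rep(seq_len(9), each = 12)
  # within-group labels constant, across-group labels distinct
  per_group <- tapply(cl$cluster, group, function(x) length(unique(x)))
  expect_true(all(per_group == 1))
  expect_equal(length(unique(tapply(cl$cluster, group, unique))), 9L)

  # a duplicated gene lands in its twin's cluster; same seed, same labels
  expect_equal(cl$cluster[["s1_1"]], cl$cluster[["s1_2"]])
  cl2 <- cluster_profiles(expr, stages, k = 9, seed = 42)
  expect_identical(cl$cluster, cl2$cluster)

  expect_error(cluster_profiles(expr[1:5, ], stages, k = 9), "smaller k")
})

test_that("the twofold rule uses the display pseudocount", {
  a <- c(g1 = 0, g2 = 5, g3 = 10)
  b <- c(g1 = 3, g2 = 5, g3 = 2)
  fc <- fold_change_deg(a, b)
  expect_equal(fc$up, "g1")      # (3+1)/(0+1) = 4 > 2
  expect_equal(fc$down, "g3")    # (10+1)/(2+1) > 2
  eps <- fold_change_deg(a, b, threshold = 1 + 1e-9)
  expect_setequal(c(eps$up, eps$down), c("g1", "g3"))
})

test_that("the two-group t-test matches stats::t.test and finds big shifts", {
  a <- matrix(c(5.1, 4.9, 5.3), 1)
  b <- matrix(c(6.2, 6.0, 6.4), 1)
  res <- two_group_test(rbind(a, a), rbind(b, b))
  ref <- stats::t.test(a[1, ], b[1, ], var.equal = TRUE)
  expect_equal(res$t[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p[1], ref$p.value, tolerance = 1e-12)

  set.seed(8)
  null_a <- matrix(stats::rnorm(50 * 3, 10), 50)
  null_b <- matrix(stats::rnorm(50 * 3, 10), 50)
  shift_a <- matrix(stats::rnorm(5 * 3, 10, 0.1), 5)
  shift_b <- matrix(stats::rnorm(5 * 3, 11, 0.1), 5)  # 10 group SDs away
  res2 <- two_group_test(rbind(null_a, shift_a), rbind(null_b, shift_b))
  expect_true(all(res2$is_deg[51:55]))
  expect_lt(sum(res2$is_deg[1:50]), 5)

  same <- matrix(rep(1, 6), 2)
  res3 <- two_group_test(same, same)
  expect_equal(res3$p, c(1, 1))
})
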