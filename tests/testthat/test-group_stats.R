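mk_cm_list <- function(n_subj, n_node, f, metric = "sl") {
  lapply(seq_len(n_subj), function(s) {
    v <- f(s)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    connectivity_matrix(v, metric, sprintf("E%d", seq_len(n_node)))
  })
}

test_that("covariate residualization projects out the covariates", {
  set.seed(50)
  n <- 20
  cov_tab <- cbind(age = rnorm(n, 45, 6), iq = rnorm(n, 100, 10))
  # values proportional to a covariate vanish
  r <- residualize_covariates(2 * cov_tab[, "age"], cov_tab)
  expect_lt(max(abs(r)), 1e-8)
  # zero-variance covariates reduce to mean-centering
  v <- rnorm(n)
  expect_warning(rc <- residualize_covariates(v, matrix(5, n, 1)), "collinear")
  expect_equal(rc, v - mean(v), tolerance = 1e-10)
  # orthogonality on random data
  vals <- matrix(rnorm(n * 3), n)
  res <- residualize_covariates(vals, cov_tab)
  for (k in 1:2) {
    proj <- abs(colSums(res * cov_tab[, k])) /
      (sqrt(colSums(res^2)) * sqrt(sum(cov_tab[, k]^2)))
    expect_true(all(proj < 1e-8))
  }
})

test_that("the permutation test agrees with Welch's t and honours its contract", {
  set.seed(51)
  a <- rnorm(11); b <- rnorm(8, mean = 1)
  pr <- permutation_mean_diff(a, b, B = 1000, seed = 3)
  expect_equal(pr$observed_stat, unname(t.test(a, b)$statistic),
               tolerance = 1e-12)
  expect_length(pr$null_stats, 1000)
  expect_gt(pr$p_value, 0)
  # determinism
  pr2 <- permutation_mean_diff(a, b, B = 1000, seed = 3)
  expect_identical(pr$null_stats, pr2$null_stats)
  # identical multisets: observed t = 0, p = 1 > 0.5
  for (s in 1:5) {
    v <- rnorm(9)
    pid <- permutation_mean_diff(v, sample(v), B = 99, seed = s)
    expect_gt(pid$p_value, 0.5)
  }
  expect_error(permutation_mean_diff(rep(1, 5), rep(1, 5)),
               class = "nvf_validation_error")
})

test_that("a 3-SD planted shift is detected at the study's group sizes", {
  set.seed(52)
  hits <- vapply(1:20, function(s) {
    a <- rnorm(11)
    b <- rnorm(8) + 3
    permutation_mean_diff(a, b, B = 199, seed = s)$p_value <= 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("permutation p-values are uniform on the achievable grid", {
  set.seed(53)
  ps <- vapply(1:200, function(s) {
    permutation_mean_diff(rnorm(9), rnorm(9), B = 99, seed = s)$p_value
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_true(all(ps > 0))
})

test_that("edgewise Welch maps obey antisymmetry and flag planted edges", {
  set.seed(54)
  A <- mk_cm_list(8, 5, function(s) matrix(rnorm(25, 0.5, 0.05), 5))
  B <- mk_cm_list(8, 5, function(s) matrix(rnorm(25, 0.5, 0.05), 5))
  # plant a constant offset at edge (1,2) in group B
  B_off <- lapply(B, function(cm) {
    cm$values[1, 2] <- cm$values[2, 1] <- cm$values[1, 2] + 0.5
    cm
  })
  et <- edgewise_t(A, B_off)
  ut <- upper.tri(et$t)
  expect_equal(which.max(abs(et$t[ut])), which(ut, arr.ind = TRUE) |>
                 (\(ix) which(ix[, 1] == 1 & ix[, 2] == 2))())
  sw <- edgewise_t(B_off, A)
  expect_equal(sw$t, -et$t, tolerance = 1e-12)
  # zero-variance edges in both groups are masked
  A0 <- lapply(A, function(cm) { cm$values[4, 5] <- cm$values[5, 4] <- 0.2; cm })
  B0 <- lapply(B, function(cm) { cm$values[4, 5] <- cm$values[5, 4] <- 0.2; cm })
  expect_message(m <- edgewise_t(A0, B0), "masked")
  expect_true(is.na(m$t[4, 5]))
})

test_that("CBPT clusters by shared electrodes and is seed-deterministic", {
  set.seed(55)
  A <- mk_cm_list(8, 6, function(s) matrix(rnorm(36, 0.4, 0.05), 6))
  B <- mk_cm_list(8, 6, function(s) {
    v <- matrix(rnorm(36, 0.4, 0.05), 6)
    v[1, 2:4] <- v[1, 2:4] + 0.5       # star on electrode 1
    v
  })
  cr <- cbpt(A, B, B = 199, seed = 9)
  expect_gt(length(cr$clusters), 0)
  main <- cr$clusters[[1]]
  expect_true(all(apply(main, 1, function(e) 1 %in% e)))
  cr2 <- cbpt(A, B, B = 199, seed = 9)
  expect_identical(cr$null_max_mass, cr2$null_max_mass)
  expect_identical(cr$cluster_p, cr2$cluster_p)
  # an impossibly strict forming threshold on null data gives an empty
  # result, not an error
  B_null <- mk_cm_list(8, 6, function(s) matrix(rnorm(36, 0.4, 0.05), 6))
  cr3 <- cbpt(A, B_null, forming_alpha = 1e-9, B = 49, seed = 1)
  expect_length(cr3$clusters, 0)
})
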