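test_that("estimate_moments: sample moments, trace identity, unit diagonal", {
  set.seed(60)
  for (np in list(c(30, 3), c(100, 6))) {
    x <- matrix(rnorm(np[1] * np[2]), np[1])
    mom <- estimate_moments(x)
    expect_equal(mom$mu, colMeans(x))
    expect_equal(mom$S, cov(x))              # n-1 divisor
    expect_equal(mom$lambda, 0)
    # trace identity: mean squared distance of the sample from its own
    # moments is p(n-1)/n under the n-1 covariance divisor
    dm <- dm_mahalanobis(x, mom$mu, mom$S)
    expect_equal(mean(dm^2), np[2] * (np[1] - 1) / np[1], tolerance = 1e-10)
  }
})

test_that("estimate_moments applies minimal shrinkage, errors when singular", {
  set.seed(61)
  base <- matrix(rnorm(40 * 3), 40)
  x <- cbind(base, base[, 1] + 1e-8 * rnorm(40))  # near-collinear
  mom <- estimate_moments(x, cond_threshold = 1e6)
  expect_gt(mom$lambda, 0)
  expect_lte(mom$condition_number, 1e6 * (1 + 1e-6))
  ev <- eigen(mom$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # one profile repeated: zero-variance columns defeat any diagonal shrinkage
  dup <- matrix(rep(c(1, 2), 50), 50, 2, byrow = TRUE)
  expect_error(estimate_moments(dup), class = "dysregkit_conditioning_error")
  expect_error(estimate_moments(matrix(NA_real_, 10, 2)),
               class = "dysregkit_input_error")
})

test_that("dm_mahalanobis closed-form cases", {
  expect_equal(dm_mahalanobis(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(dm_mahalanobis(c(3, 4), c(0, 0), diag(2)), 5)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(dm_mahalanobis(c(1, 1), c(0, 0), S), sqrt(4 / 3),
               tolerance = 1e-12)
  expect_error(dm_mahalanobis(c(1, 2, 3), c(0, 0), diag(2)),
               class = "dysregkit_input_error")
})

test_that("dm is nonnegative and zero iff x equals mu", {
  set.seed(62)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  x <- matrix(rnorm(200 * 4), 200)
  dm <- dm_mahalanobis(x, rep(0, 4), S)
  expect_true(all(dm >= 0))
  expect_true(all(dm[rowSums(abs(x)) > 0] > 0))
})

test_that("score_cohort: reference self-scoring identity and dm_z contract", {
  co <- mvn_cohort(n = 50, p = 4, seed = 63)
  ref <- build_self_reference(co)
  sc <- score_cohort(co, ref)
  expect_equal(mean(sc$dm^2), 4 * 49 / 50, tolerance = 1e-8)
  expect_equal(mean(sc$dm_z), 0, tolerance = 1e-12)
  expect_equal(sd(sc$dm_z), 1, tolerance = 1e-12)
  expect_equal(unique(sc$reference_id), "self:A")
})

test_that("squared dm of MVN draws under the true moments is chi-squared", {
  set.seed(64)
  p <- 5
  Sigma <- 0.6 * diag(p) + 0.4
  x <- matrix(rnorm(4000 * p), 4000) %*% chol(Sigma)
  dm <- dm_mahalanobis(x, rep(0, p), Sigma)
  ks <- ks.test(dm^2, pchisq, df = p)
  expect_gt(ks$p.value, 0.01)
})

test_that("marker_score_correlations flags single-marker scores as non-emergent", {
  set.seed(65)
  z <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "m"))
  dm <- abs(z[, 1])      # 1-marker dm is |z|
  sc <- data.frame(dm = dm)
  rep1 <- marker_score_correlations(sc, z)
  # |r| between |z| and z is modest, but vs the |marker| axis it is 1
  rep2 <- marker_score_correlations(sc, abs(z))
  expect_equal(rep2$max_abs_r, 1, tolerance = 1e-12)
  expect_false(rep2$emergent)
  # multi-marker MVN scores are emergent
  co <- mvn_cohort(n = 200, p = 8, seed = 66)
  ref <- build_self_reference(co)
  sc2 <- score_cohort(co, ref, keep_z = TRUE)
  rep3 <- marker_score_correlations(sc2, attr(sc2, "marker_z"))
  expect_true(rep3$emergent)
  expect_lt(rep3$max_abs_r, 0.3)
  # constant marker reported as missing
  z4 <- cbind(attr(sc2, "marker_z"), const = 0)
  rep4 <- marker_score_correlations(sc2, z4)
  expect_true(is.na(rep4$per_marker$r[rep4$per_marker$marker == "const"]))
})

test_that("dm is invariant under joint affine maps of reference and scores", {
  set.seed(67)
  p <- 4
  ref <- matrix(rnorm(60 * p), 60)
  x <- matrix(rnorm(20 * p), 20)
  mom <- estimate_moments(ref)
  dm0 <- dm_mahalanobis(x, mom$mu, mom$S)
  for (i in 1:20) {
    A <- matrix(rnorm(p * p), p); while (abs(det(A)) < 1e-3)
      A <- matrix(rnorm(p * p), p)
    b <- rnorm(p)
    refA <- sweep(ref %*% A, 2, b, "+")
    xA <- sweep(x %*% A, 2, b, "+")
    momA <- estimate_moments(refA)
    expect_equal(dm_mahalanobis(xA, momA$mu, momA$S), dm0, tolerance = 1e-8)
  }
})
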