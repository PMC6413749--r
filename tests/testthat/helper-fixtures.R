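# In-code fixtures shared across test files.

# tiny two-marker, two-species cohort with known values
tiny_cohort <- function() {
  cohort_table(data.frame(
    species = rep(c("A", "B"), each = 4),
    individual_id = c("a1", "a1", "a2", "a2", "b1", "b1", "b2", "b2"),
    sex = c("female", "female", "male", "male",
            "female", "female", "male", "male"),
    age_at_obs = c(5.6, 7.0, 6.1, 9.1, 5.0, 6.0, 5.5, 8.0),
    death_age = c(NA, NA, 10, 10, NA, NA, NA, NA),
    body_mass = c(10, 9, 11, 10.5, 20, 19, 21, 20),
    g1 = c(5.1, 5.3, 4.9, 5.5, 6.1, 6.0, 6.3, 6.2),
    g2 = c(1.0, 1.2, 0.9, 1.4, 2.0, 2.1, 1.9, 2.2)
  ), markers = c("g1", "g2"))
}

# single-species multivariate-normal cohort with one visit per individual
mvn_cohort <- function(n = 80, p = 4, seed = 1, species = "A", mu = NULL,
                       Sigma = NULL) {
  set.seed(seed)
  mu <- mu %||% rep(10, p)
  Sigma <- Sigma %||% (diag(p) * 0.5 + 0.5)
  x <- matrix(rnorm(n * p), n) %*% chol(Sigma)
  x <- sweep(x, 2, mu, "+")
  colnames(x) <- sprintf("m%02d", 1:p)
  cohort_table(data.frame(
    species = species,
    individual_id = sprintf("%s_%03d", species, 1:n),
    sex = rep(c("female", "male"), length.out = n),
    age_at_obs = runif(n, 5, 30),
    x), markers = colnames(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# positive-definite correlation matrix for distributional fixtures
random_correlation_fixture <- function(p) {
  L <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(L) + diag(p))
}

expect_quiet_warning <- function(expr) suppressWarnings(expr)
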