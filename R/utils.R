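# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Sample skewness (g1, moment estimator). The 'moments' package is not a
# dependency; this is the only moment statistic the package needs.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dysreg <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dysregkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Wald-style coefficient table used by every model-reporting function.
wald_coef_table <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    ci_lower = unname(est - z * se),
    ci_upper = unname(est + z * se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
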