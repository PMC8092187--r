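# A-priori power analysis for the test of zero product-moment correlation
# under bivariate normality.
#
# The exact route uses the distributional identity
#   sqrt(n-2) R / sqrt(1-R^2)  =d  (rho' W + Z) / (V / sqrt(n-2)),
# with rho' = rho / sqrt(1-rho^2), W ~ chi_{n-1}, Z ~ N(0,1), V ~ chi_{n-2}
# all independent; conditioning on W makes the statistic noncentral t with
# n-2 df and noncentrality rho' * W, so exact power is a one-dimensional
# quadrature of a noncentral-t tail over the chi_{n-1} density. The common
# Fisher-z closed form is exposed for comparison (it is slightly
# conservative at moderate n).

# chi (not chi-squared) density with k df
.dchi <- function(w, k) {
  exp((k - 1) * log(w) - w^2 / 2 - (k / 2 - 1) * log(2) - lgamma(k / 2))
}

#' Power of the correlation test at a given sample size
#'
#' @param n Sample size (pairs); `n >= 4`.
#' @param rho True correlation under the alternative, in (0, 1).
#' @param alpha Test level.
#' @param sided `"one"` (H1: rho > 0) or `"two"`.
#' @param method `"exact"` (bivariate-normal sampling distribution, numerical
#'   integration) or `"fisher"` (Fisher z approximation).
#' @return Power in `[0, 1]`. For the two-sided exact method the (negligible)
#'   lower-tail rejection mass is included.
#' @export
correlation_power <- function(n, rho, alpha = 0.05,
                              sided = c("one", "two"),
                              method = c("exact", "fisher")) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  stopifnot(n >= 4, rho > 0, rho < 1, alpha > 0, alpha < 1)
  a <- if (sided == "one") alpha else alpha / 2
  if (method == "fisher") {
    se <- 1 / sqrt(n - 3)
    zc <- qnorm(1 - a)
    up <- pnorm((atanh(rho) - zc * se) / se)
    if (sided == "one") return(up)
    return(up + pnorm((-atanh(rho) - zc * se) / se))
  }
  tc <- qt(1 - a, df = n - 2)
  rp <- rho / sqrt(1 - rho^2)
  tail_above <- function(thr) {
    integrate(function(w)
      pt(thr, df = n - 2, ncp = rp * w, lower.tail = FALSE) *
        .dchi(w, n - 1),
      0, Inf, rel.tol = 1e-10)$value
  }
  pow <- tail_above(tc)
  if (sided == "two") {
    lower <- integrate(function(w)
      pt(-tc, df = n - 2, ncp = rp * w) * .dchi(w, n - 1),
      0, Inf, rel.tol = 1e-10)$value
    pow <- pow + lower
  }
  pow
}

#' Required sample size for a correlation test
#'
#' Smallest `n` at which the level-`alpha` test of zero correlation attains
#' the target power when the true bivariate-normal correlation is `rho`.
#'
#' @inheritParams correlation_power
#' @param power Target power, in (0, 1).
#' @param n_max Search ceiling; power unattainable below it is an error.
#' @return Integer sample size (per group when groups are analysed
#'   separately).
#' @examples
#' required_n_correlation(0.35, alpha = 0.05, power = 0.80, sided = "one")
#' # 49; the Fisher-z closed form gives 50:
#' required_n_correlation(0.35, sided = "one", method = "fisher")
#' @export
required_n_correlation <- function(rho, alpha = 0.05, power = 0.80,
                                   sided = c("one", "two"),
                                   method = c("exact", "fisher"),
                                   n_max = 100000L) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (method == "fisher") {
    a <- if (sided == "one") alpha else alpha / 2
    n <- ceiling(((qnorm(1 - a) + qnorm(power)) / atanh(rho))^2 + 3)
    return(max(4L, as.integer(n)))
  }
  # warm start from the Fisher approximation, then walk to the exact boundary
  n <- max(4L, required_n_correlation(rho, alpha, power, sided, "fisher") - 10L)
  while (n <= n_max && correlation_power(n, rho, alpha, sided) < power)
    n <- n + 1L
  if (n > n_max)
    stop("target power unattainable below n_max = ", n_max, call. = FALSE)
  while (n > 4L && correlation_power(n - 1L, rho, alpha, sided) >= power)
    n <- n - 1L
  n
}
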