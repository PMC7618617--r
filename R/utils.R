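#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median model.matrix pchisq pnorm quantile
#'   rbinom rlnorm rnorm runif sd setNames terms var complete.cases
#'   as.formula delete.response model.frame na.pass predict qnorm rbeta
#'   reformulate
#' @importFrom utils head modifyList
#' @import data.table
NULL

# round half away from zero (commercial rounding); base round() is
# round-half-even, which would turn e.g. 24.85 into 24.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

weighted_mean <- function(x, w) {
  ok <- !is.na(x) & !is.na(w)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

# weighted quantile by inverting the weighted ECDF (step function);
# adequate for medians of survey-weighted covariates
weighted_quantile <- function(x, w, probs = 0.5) {
  ok <- !is.na(x) & !is.na(w)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

weighted_skewness <- function(x, w) {
  ok <- !is.na(x) & !is.na(w)
  x <- x[ok]; w <- w[ok] / sum(w[ok])
  m <- sum(w * x)
  s2 <- sum(w * (x - m)^2)
  sum(w * (x - m)^3) / s2^1.5
}

weighted_mode <- function(x, w) {
  ok <- !is.na(x)
  tab <- tapply(w[ok], x[ok], sum)
  names(tab)[which.max(tab)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
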