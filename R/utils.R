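#' @keywords internal
"_PACKAGE"

DAYS_PER_YEAR <- 365.25

years_between <- function(from, to) as.numeric(to - from) / DAYS_PER_YEAR

add_years <- function(date, years) date + round(years * DAYS_PER_YEAR)

#' Clinical rating scale definitions
#'
#' Valid ranges for the scales handled by the generator and the extractor:
#' UPDRS total (0-199, higher = worse motor function), MMSE (0-30, lower =
#' worse cognition) and Hoehn & Yahr stage (1-5 in half stages).
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
scale_ranges <- function() {
  list(updrs_total = c(0, 199), mmse = c(0, 30), hy = c(1, 5))
}

known_scales <- function() names(scale_ranges())

assert_scale <- function(scale) {
  if (!is.character(scale) || length(scale) != 1L || !scale %in% known_scales())
    stop("unknown scale: ", paste(scale, collapse = ","), call. = FALSE)
  invisible(scale)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## H&Y is ordinal in half stages; floor-quantization means the quantized stage
## reaches 3 exactly when the latent trajectory does.
quantize_hy <- function(x) clamp(floor(2 * x) / 2, 1, 5)

## Truncated-normal sampler by rejection (bounds far in the tails for the ages
## used here, so rejection is cheap).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

## Location mu such that the [lo, hi]-truncated normal has the target mean.
trunc_norm_mu_for_mean <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  uniroot(function(m) trunc_norm_mean(m, sd, lo, hi) - target,
          c(lo, hi), extendInt = "yes")$root
}

## Exponential mean m such that E[min(X, cap)] = m (1 - exp(-cap/m)) equals
## `target`.
exp_mean_for_capped <- function(target, cap) {
  if (cap <= target) stop("followup cap must exceed the follow-up mean",
                          call. = FALSE)
  uniroot(function(m) m * (1 - exp(-cap / m)) - target,
          c(target, target * 50))$root
}

## Weibull scale such that the distribution median equals `median`.
weibull_scale_for_median <- function(median, shape) median / log(2)^(1 / shape)

## Deterministic per-stage seed derivation from a master seed. Stable across
## platforms: a small polynomial hash of the stage name folded into [0, 2^31).
derive_seed <- function(master_seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(master_seed)) * 1009 + h) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modal_value <- function(x) {
  tab <- table(x, useNA = "no")
  if (!length(tab)) return(list(value = NA_character_, count = 0L, tie = FALSE))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  list(value = winners[[1L]], count = as.integer(top), tie = length(winners) > 1L)
}
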