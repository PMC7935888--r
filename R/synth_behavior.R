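#' Simulate behavioral time series under LD or DD
#'
#' Group measurements (e.g. percent active larvae, grams of food consumed,
#' frass weight) with a sinusoidal daily mean and additive Gaussian noise:
#' \deqn{y(t) = B + A \cos(2\pi (t - \phi)/P) + \epsilon.}
#' Under LD the period is entrained to 24 h; under DD the free-running
#' period \eqn{\tau} applies, so the peak drifts by \eqn{24 - \tau} hours
#' per cycle relative to ZT.
#'
#' @param days number of 24 h observation days.
#' @param condition \code{"LD"} or \code{"DD"}.
#' @param acrophase_hours peak time (ZT under LD; initial phase under DD).
#' @param period_hours cycle length; forced to 24 under LD.
#' @param n_groups replicate groups measured at each timepoint.
#' @param noise_sd additive noise SD (measurement units).
#' @param baseline,amplitude mean level and half peak-to-trough range.
#' @param sampling_interval hours between measurements (default 3 h).
#' @param seed integer seed.
#' @return data.frame: condition, time_h, group, value.
#' @export
simulate_behavior <- function(days = 3, condition = c("LD", "DD"),
                              acrophase_hours = 18, period_hours = 24,
                              n_groups = 9, noise_sd = 0, baseline = 50,
                              amplitude = 30, sampling_interval = 3,
                              seed = 1L) {
  condition <- match.arg(condition)
  .assert(period_hours > 0, "period must be positive")
  .assert(days >= 1 && n_groups >= 1, "days and n_groups must be >= 1")
  if (condition == "LD") period_hours <- 24
  t <- seq(0, days * 24 - sampling_interval, by = sampling_interval)
  mu <- baseline + amplitude * cos(2 * pi * (t - acrophase_hours) / period_hours)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(n_groups), function(gp) {
    data.frame(condition = condition, time_h = t, group = gp,
               value = mu + rnorm(length(t), sd = noise_sd),
               stringsAsFactors = FALSE)
  }))
  out
}
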