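# Molecular-clock calibration and divergence/duplication dating from Ks.

#' Calibrate the synonymous substitution rate from anchor pairs
#'
#' Given Ks values for calibration pairs whose divergence time is known,
#' computes the clock rate `k = mean(ks_values) / (2 * t_cal)` (substitutions
#' per synonymous site per year). The mean is taken before dividing: dating a
#' pair with the mean calibration Ks then returns the calibration time exactly.
#'
#' @param ks_values Numeric vector of calibration Ks values (>= 0, non-empty).
#' @param t_cal Calibration divergence time in years (> 0). Use
#'   `t_cal_mya * 1e6` for times in million years.
#' @return Object of class `clock_calibration` with fields `ks_values`,
#'   `t_cal` and `k`.
#' @examples
#' calibrate_rate(c(0.089, 0.044, 0.059), t_cal = 10e6)  # k = 3.2e-9
#' @export
calibrate_rate <- function(ks_values, t_cal) {
  if (!is.numeric(ks_values) || length(ks_values) == 0L || anyNA(ks_values) ||
      any(ks_values < 0))
    stop("ks_values must be a non-empty vector of non-negative numbers",
         call. = FALSE)
  if (!is.numeric(t_cal) || length(t_cal) != 1L || is.na(t_cal) || t_cal <= 0)
    stop("t_cal must be a single positive time in years", call. = FALSE)
  k <- mean(ks_values) / (2 * t_cal)
  if (k == 0)
    warning("degenerate calibration: all calibration Ks are zero, k = 0",
            call. = FALSE)
  structure(list(ks_values = as.numeric(ks_values), t_cal = t_cal, k = k),
            class = "clock_calibration")
}

#' @export
print.clock_calibration <- function(x, ...) {
  cat(sprintf(
    "clock_calibration: k = %.4g subst/site/yr (mean Ks %.4g over %d pairs, t_cal %.4g MYA)\n",
    x$k, mean(x$ks_values), length(x$ks_values), x$t_cal / 1e6))
  invisible(x)
}

#' Convert a Ks value to a divergence time under the clock
#'
#' `T = Ks / (2k)`, reported both in years and million years (MYA).
#'
#' @param ks Synonymous distance (>= 0).
#' @param calib A [calibrate_rate] result, or a bare positive rate `k`.
#' @return List with `ks`, `t` (years) and `t_mya`.
#' @export
divergence_time <- function(ks, calib) {
  k <- if (inherits(calib, "clock_calibration")) calib$k else calib
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("clock rate k must be positive; calibration is degenerate",
         call. = FALSE)
  if (!is.numeric(ks) || length(ks) != 1L || is.na(ks) || ks < 0)
    stop("ks must be a single non-negative number", call. = FALSE)
  t <- ks / (2 * k)
  list(ks = ks, t = t, t_mya = t / 1e6)
}

#' Min-max divergence range over a set of cross-group Ks values
#'
#' Dates every Ks in `cross_group_ks` and returns the (min, max) range in MYA
#' (rounded to `digits`), alongside the individual estimates. This mirrors the
#' "about X-Y MYA" presentation of duplication ages as the spread over
#' cross-cluster pairwise estimates; no confidence interval is implied.
#'
#' @param cross_group_ks Non-empty numeric vector of Ks values.
#' @param calib A [calibrate_rate] result or bare rate.
#' @param digits Rounding for the reported MYA range (default 1).
#' @return List with `t_min_mya`, `t_max_mya` and `estimates` (data frame of
#'   per-Ks times).
#' @export
divergence_range <- function(cross_group_ks, calib, digits = 1) {
  if (!is.numeric(cross_group_ks) || length(cross_group_ks) == 0L)
    stop("cross_group_ks must be a non-empty numeric vector", call. = FALSE)
  est <- lapply(cross_group_ks, divergence_time, calib = calib)
  t_mya <- vapply(est, `[[`, numeric(1), "t_mya")
  list(t_min_mya = round(min(t_mya), digits),
       t_max_mya = round(max(t_mya), digits),
       estimates = data.frame(ks = cross_group_ks, t_mya = t_mya))
}
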