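#' Growth-curve container
#'
#' A time series of optical-density readings (600 nm) or cell densities.
#'
#' @param times Sampling times (hours), strictly increasing.
#' @param values Readings (OD, dimensionless, or cells/ml), non-negative.
#' @param kind `"od"` or `"density"`.
#' @return An object of class `growth_curve` (a data.frame `time_h, value`).
#' @export
growth_curve <- function(times, values, kind = c("od", "density")) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(values < 0)) stop("readings must be non-negative")
  structure(data.frame(time_h = times, value = values),
            kind = kind, class = c("growth_curve", "data.frame"))
}

#' Estimate the maximum growth rate by log-linear regression
#'
#' Ordinary least-squares slope of `ln(reading)` on time over a window of
#' (near-)exponential growth, with a standard 95% confidence interval from
#' the slope's standard error.  On OD data this estimates the realized
#' per-capita growth rate; with abundant resource it approaches the maximum
#' rate `v` (the Monod factor `r/(r+k)` is close to 1).
#'
#' @param curve A [growth_curve()].
#' @param window Time interval `c(t0, t1)` (hours, inclusive) to regress
#'   over; defaults to the whole curve.
#' @return List with `rate` (per hour), `ci_halfwidth` (95% CI half-width),
#'   `n` (points used) and `window`.
#' @examples
#' gc <- growth_curve(0:5 / 2, 0.01 * exp(1.37 * (0:5) / 2))
#' estimate_growth_rate(gc)$rate
#' @export
estimate_growth_rate <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(window)) window <- range(curve$time_h)
  sel <- curve$time_h >= window[1] & curve$time_h <= window[2]
  tt <- curve$time_h[sel]
  y <- curve$value[sel]
  if (length(tt) < 3L)
    stop("need at least 3 points in the regression window")
  if (any(y <= 0))
    stop("non-positive readings in the regression window; cannot take logs")
  fit <- stats::lm(log(y) ~ tt)
  slope <- unname(stats::coef(fit)[2L])
  # an exact exponential gives zero residual variance; the "essentially
  # perfect fit" warning is expected there and the SE handled below
  se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  if (!is.finite(se)) se <- 0   # exact fit: zero residual variance
  list(rate = slope,
       ci_halfwidth = stats::qt(0.975, df = length(tt) - 2L) * se,
       n = length(tt), window = window)
}

#' One-step growth experiment design
#'
#' Sampling grid and analysis windows for a one-step (single infection
#' cycle) growth experiment.  Windows are half-open, `[lo, hi)`: with a
#' latent period of ~24 min, samples taken at 25 min already contain the
#' first bursts, so the pre-burst window 15-25 min deliberately contains the
#' 15- and 20-min samples only.
#'
#' @param times Sampling times (hours); default every 5 min over the first
#'   hour.
#' @param pre_window Pre-burst window `c(lo, hi)` in hours
#'   (default 15-25 min).
#' @param post_window Post-burst window (default 40-60 min).
#' @param rise_threshold Fold-rise over the pre-burst mean that marks the end
#'   of the latent period (default 1.5).
#' @return An object of class `one_step_design`.
#' @export
one_step_design <- function(times = seq(0, 1, by = 1 / 12),
                            pre_window = c(15, 25) / 60,
                            post_window = c(40, 60) / 60,
                            rise_threshold = 1.5) {
  if (pre_window[1] >= pre_window[2] || post_window[1] >= post_window[2])
    stop("windows must have lo < hi")
  if (pre_window[2] > post_window[1])
    stop("pre-burst window must end before the post-burst window starts")
  if (rise_threshold <= 1) stop("'rise_threshold' must exceed 1")
  structure(list(times = times, pre_window = pre_window,
                 post_window = post_window, rise_threshold = rise_threshold),
            class = "one_step_design")
}

#' Latent period and burst size from a one-step growth curve
#'
#' The latent period is the earliest sampling time at which the
#' plaque-forming density exceeds `rise_threshold` times the mean over the
#' pre-burst window.  The burst size is the ratio of the post-burst to the
#' pre-burst window means: before the burst every plaque-forming unit is one
#' infected center (or an unadsorbed particle), afterwards each burst
#' contributes `beta - 1` free particles, so the ratio is calibrated in
#' particles per infected cell.
#'
#' @param times Sampling times (hours).
#' @param pfu Plaque-forming units per ml at each time.
#' @param design A [one_step_design()].
#' @return List with `latent_h` (hours), `burst` (phage per infected cell),
#'   `pre_mean`, `post_mean`.
#' @export
analyze_one_step <- function(times, pfu, design = one_step_design()) {
  stopifnot(inherits(design, "one_step_design"),
            length(times) == length(pfu))
  tol <- 1e-9   # guard against accumulated floating error in sampling grids
  pre <- times >= design$pre_window[1] - tol &
    times < design$pre_window[2] - tol
  post <- times >= design$post_window[1] - tol &
    times < design$post_window[2] - tol
  if (sum(pre) < 2L) stop("need at least two pre-burst samples")
  if (sum(post) < 1L) stop("pfu series does not cover the post-burst window")
  pre_mean <- mean(pfu[pre])
  post_mean <- mean(pfu[post])
  if (pre_mean <= 0) stop("zero pre-burst mean; burst size undefined")
  cross <- which(pfu > design$rise_threshold * pre_mean)
  if (length(cross) == 0L) stop("no burst detected")
  list(latent_h = times[cross[1L]],
       burst = post_mean / pre_mean,
       pre_mean = pre_mean, post_mean = post_mean)
}

#' Escape-mutant frequency from plaque counts on two lawns
#'
#' Ratio of the estimated phage density titred on a BIM lawn (only escape
#' mutants form plaques) to that on a wild-type lawn (all phage form
#' plaques): `(plaques_on_bim * dilution_bim) / (plaques_on_wt *
#' dilution_wt)`.
#'
#' @param plaques_on_bim,plaques_on_wt Plaque counts.
#' @param dilution_bim,dilution_wt Fold-dilutions at which the counts were
#'   made (>= 1).
#' @return List with `frequency` and `upper_bound` (the frequency that one
#'   plaque would have given; reported when a zero count makes the point
#'   estimate degenerate).  A zero wild-type count leaves the frequency
#'   undefined (`NA`) with the bound computed from one wild-type plaque.
#' @examples
#' cem_frequency(50, 10, 100, 1e6)$frequency  # 5e-6
#' @export
cem_frequency <- function(plaques_on_bim, dilution_bim,
                          plaques_on_wt, dilution_wt) {
  if (dilution_bim < 1 || dilution_wt < 1) stop("dilutions must be >= 1")
  if (plaques_on_bim < 0 || plaques_on_wt < 0) stop("counts must be >= 0")
  if (plaques_on_wt == 0) {
    warning("zero wild-type plaques: frequency undefined; ",
            "bound computed from one plaque")
    return(list(frequency = NA_real_,
                upper_bound = (max(plaques_on_bim, 1) * dilution_bim) /
                  (1 * dilution_wt)))
  }
  freq <- (plaques_on_bim * dilution_bim) / (plaques_on_wt * dilution_wt)
  list(frequency = freq,
       upper_bound = if (plaques_on_bim == 0)
         dilution_bim / (plaques_on_wt * dilution_wt) else freq)
}

#' Fit a cell-density to optical-density calibration curve
#'
#' Polynomial fit of OD (600 nm) on cell density, used to convert simulated
#' densities into the observable.  The fitted curve must be monotone
#' non-decreasing over the calibrated density range; if the requested degree
#' violates monotonicity the degree is reduced until it holds.  Conversion
#' never returns below the OD floor: below roughly 5e5 cells/ml, OD readings
#' level off around 0.005 and carry no density information.
#'
#' @param density Calibration cell densities (cells/ml).
#' @param od Matching OD readings.
#' @param degree Polynomial degree to attempt (default 3).
#' @param floor OD floor (default 0.005).
#' @return An object of class `od_calibration`.
#' @export
od_calibration <- function(density, od, degree = 3L, floor = 0.005) {
  if (length(density) != length(od)) stop("density/od length mismatch")
  if (length(density) < degree + 1L) stop("not enough calibration points")
  rng <- range(density)
  grid <- seq(rng[1], rng[2], length.out = 512L)
  for (d in rev(seq_len(degree))) {
    fit <- stats::lm(od ~ stats::poly(density, d, raw = TRUE))
    pred <- .poly_eval(stats::coef(fit), grid)
    if (all(diff(pred) >= -1e-12 * max(abs(pred)))) {
      return(structure(list(coef = stats::coef(fit), degree = d,
                            range = rng, floor = floor),
                       class = "od_calibration"))
    }
  }
  stop("no monotone polynomial fit found on the calibrated range")
}

.poly_eval <- function(coef, x) {
  y <- rep(coef[[1L]], length(x))
  xp <- x
  for (i in seq_len(length(coef) - 1L)) {
    y <- y + coef[[i + 1L]] * xp
    xp <- xp * x
  }
  y
}

#' Convert cell densities to predicted optical density
#'
#' Evaluates a fitted [od_calibration()] with clamping: densities outside
#' the calibrated range are clamped to the range endpoints (no
#' extrapolation) and the result never falls below the OD floor.
#'
#' @param cal An [od_calibration()].
#' @param densities Cell densities (cells/ml).
#' @return Predicted OD series.
#' @export
density_to_od <- function(cal, densities) {
  stopifnot(inherits(cal, "od_calibration"))
  x <- pmin(pmax(densities, cal$range[1]), cal$range[2])
  pmax(.poly_eval(cal$coef, x), cal$floor)
}
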