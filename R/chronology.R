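#' Read a radiocarbon calibration curve table
#'
#' Accepts the common `.14c`-style layout: a 3+ column whitespace- or
#' comma-separated table of (cal yr BP, 14C age yr BP, 1-sigma yr), with
#' `#` comment lines, in ascending or descending cal age (auto-sorted).
#'
#' @param path file path.
#' @return class `cal_curve`: data.frame `cal_bp`, `c14_bp`, `sigma`,
#'   sorted by ascending cal age.
#' @export
read_calcurve <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  sep <- if (any(grepl(",", first))) "," else ""
  x <- utils::read.table(path, header = FALSE, sep = sep,
                         comment.char = "#", fill = TRUE)
  # tolerate a header row of labels
  if (!is.numeric(x[[1]])) x <- utils::read.table(path, header = TRUE,
                                                  sep = sep,
                                                  comment.char = "#")
  cal_curve(x[[1]], x[[2]], x[[3]])
}

#' Construct a calibration curve
#'
#' @param cal_bp calendar ages (cal yr BP).
#' @param c14_bp conventional 14C ages at those calendar ages.
#' @param sigma 1-sigma curve uncertainty in 14C yr (must be positive, or
#'   zero for idealized test curves).
#' @return class `cal_curve` data.frame sorted by ascending `cal_bp`.
#' @export
cal_curve <- function(cal_bp, c14_bp, sigma) {
  df <- data.frame(cal_bp = as.numeric(cal_bp),
                   c14_bp = as.numeric(c14_bp),
                   sigma = as.numeric(sigma))
  df <- df[order(df$cal_bp), ]
  rownames(df) <- NULL
  if (anyDuplicated(df$cal_bp)) stop("calibration curve cal ages must be unique")
  if (any(df$sigma < 0)) stop("curve sigmas must be non-negative")
  structure(df, class = c("cal_curve", "data.frame"))
}

#' Calibrate a radiocarbon date against a marine calibration curve
#'
#' The reservoir offset is subtracted before the curve lookup, with its
#' uncertainty added in quadrature (standard marine practice): the
#' corrected age is `x = c14_age - deltaR` with `sigma'^2 = sigma^2 +
#' deltaR_sigma^2`. The posterior mass at calendar age t is proportional
#' to `exp(-(x - mu(t))^2 / (2 (sigma'^2 + sigma_curve(t)^2)))` evaluated
#' on a grid interpolated linearly between curve knots, weighted by grid
#' spacing and normalized. The summary reports the cumulative-mass median,
#' the central 95% quantile interval (a deterministic convention; the
#' symmetric "+/-" report is consistent with either central or HPD
#' intervals), and a rounded form in 0.1 cal ka.
#'
#' @param c14_age conventional 14C age (yr BP).
#' @param sigma 1-sigma measurement error (yr, > 0).
#' @param curve a [cal_curve()].
#' @param deltaR local marine reservoir offset Delta-R (yr), e.g. -49.
#' @param deltaR_sigma 1-sigma of Delta-R (yr), e.g. 59.
#' @param step optional grid step in cal yr; by default the curve's own
#'   knots are used (refine for coarse curves).
#' @return class `cal_density`: list with `grid` (cal yr BP), `mass`
#'   (sums to 1), `median`, `interval` (central 95%), `report` (median and
#'   interval half-width rounded to 0.1 cal ka BP), and the corrected age.
#' @export
calibrate <- function(c14_age, sigma, curve, deltaR = 0, deltaR_sigma = 0,
                      step = NULL) {
  stopifnot(inherits(curve, "cal_curve"), sigma > 0, deltaR_sigma >= 0)
  x <- c14_age - deltaR
  s2 <- sigma^2 + deltaR_sigma^2
  grid <- if (is.null(step)) curve$cal_bp else {
    seq(min(curve$cal_bp), max(curve$cal_bp), by = step)
  }
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, xout = grid)$y
  tau <- stats::approx(curve$cal_bp, curve$sigma, xout = grid)$y
  if (x + 5 * sqrt(s2) < min(mu) - 5 * max(tau) ||
      x - 5 * sqrt(s2) > max(mu) + 5 * max(tau)) {
    stop("date (", round(x), " 14C BP) does not overlap the calibration ",
         "curve range (out-of-range)")
  }
  dens <- stats::dnorm(x, mean = mu, sd = sqrt(s2 + tau^2))
  # trapezoidal grid weights (handles irregular knot spacing)
  w <- c(diff(grid) / 2, 0) + c(0, diff(grid) / 2)
  mass <- dens * w
  if (sum(mass) <= 0) {
    stop("calibration produced zero posterior mass (out-of-range)")
  }
  mass <- mass / sum(mass)
  cdf <- cumsum(mass)
  qfun <- function(p) {
    i <- which(cdf >= p)[1]
    if (i == 1L) return(grid[1])
    # linear interpolation inside the crossing cell
    p0 <- cdf[i - 1L]
    grid[i - 1L] + (grid[i] - grid[i - 1L]) * (p - p0) / (cdf[i] - p0)
  }
  med <- qfun(0.5)
  lo <- qfun(0.025); hi <- qfun(0.975)
  structure(list(
    grid = grid, mass = mass, median = med, interval = c(lo, hi),
    report = list(median_ka = round(med / 100) / 10,
                  halfwidth_ka = round((hi - lo) / 2 / 100) / 10),
    corrected_age = x, corrected_sigma = sqrt(s2)),
    class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat(sprintf("cal_density: %.1f +/- %.1f cal ka BP (median %.0f, 95%% [%.0f, %.0f])\n",
              x$report$median_ka, x$report$halfwidth_ka, x$median,
              x$interval[1], x$interval[2]))
  invisible(x)
}

# one draw per control point: cal_density sampled by mass; list(age, sd)
# sampled normally (sd = 0 pins the point exactly)
draw_control <- function(ctrl, n) {
  if (inherits(ctrl, "cal_density")) {
    sample(ctrl$grid, n, replace = TRUE, prob = ctrl$mass)
  } else if (is.list(ctrl) && all(c("age", "sd") %in% names(ctrl))) {
    if (ctrl$sd == 0) rep(ctrl$age, n) else stats::rnorm(n, ctrl$age, ctrl$sd)
  } else {
    stop("control points must be cal_density objects or list(age=, sd=)")
  }
}

#' Monte-Carlo age-depth model
#'
#' A simplified stochastic-interpolation age-depth model: each draw
#' samples one calendar age per control point from its calibrated density
#' (or Gaussian), rejects draws in which age does not increase
#' monotonically with depth, and linearly interpolates the accepted draws
#' between control depths. Per-depth quantiles over accepted draws give
#' median ages and 68%/95% intervals. Exact constraints (sd = 0), such as
#' a core-top pinned to the year of retrieval, are honored exactly.
#'
#' @param depths control-point depths (cm), strictly increasing.
#' @param controls list (same length) of `cal_density` objects or
#'   `list(age=, sd=)` entries.
#' @param out_depths depths at which ages are reported (defaults to 100
#'   evenly spaced depths spanning the controls, plus the control depths).
#' @param n_draws Monte-Carlo draws (>= 100, default 2000).
#' @param seed integer seed.
#' @return class `age_depth_model`: data.frame `depth`, `median`, `lo68`,
#'   `hi68`, `lo95`, `hi95`; attribute `acceptance_rate`. Errors if fewer
#'   than 1% of draws are monotone (age-model conflict — review outlying
#'   dates).
#' @export
build_age_depth <- function(depths, controls, out_depths = NULL,
                            n_draws = 2000, seed = NULL) {
  stopifnot(length(depths) == length(controls), length(depths) >= 2,
            n_draws >= 100)
  if (any(diff(depths) <= 0)) stop("control depths must strictly increase")
  set_seed_if(seed)
  draws <- vapply(controls, draw_control, numeric(n_draws), n = n_draws)
  ok <- apply(draws, 1L, function(a) all(diff(a) >= 0))
  acc <- mean(ok)
  if (acc < 0.01) {
    stop("age-depth acceptance rate below 1% (", round(100 * acc, 2),
         "%): control ages conflict with depth order; review outliers")
  }
  draws <- draws[ok, , drop = FALSE]
  if (is.null(out_depths)) {
    out_depths <- sort(unique(c(depths,
                                seq(min(depths), max(depths),
                                    length.out = 100))))
  }
  interp <- apply(draws, 1L, function(a) {
    stats::approx(depths, a, xout = out_depths, rule = 2)$y
  })
  interp <- matrix(interp, nrow = length(out_depths))
  qs <- apply(interp, 1L, stats::quantile,
              probs = c(0.5, 0.16, 0.84, 0.025, 0.975), names = FALSE)
  out <- data.frame(depth = out_depths, median = qs[1, ],
                    lo68 = qs[2, ], hi68 = qs[3, ],
                    lo95 = qs[4, ], hi95 = qs[5, ])
  structure(out, class = c("age_depth_model", "data.frame"),
            acceptance_rate = acc, n_accepted = nrow(draws))
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat(sprintf(
    "age_depth_model: %d depths, %.0f-%.0f cal yr BP (acceptance %.1f%%)\n",
    nrow(x), min(x$median), max(x$median),
    100 * attr(x, "acceptance_rate")))
  invisible(x)
}
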