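# Observed tilt-angle density (quadratic in theta, degrees) fitted to
# membrane-spanning helices of known structure. Values coincide with the
# fraction of helices per 5-degree bin.
OBSERVED_TILT_DENSITY <- c(c2 = -2.36e-4, c1 = 0.01095, c0 = 0.0202)

#' Validate a tilt-angle sample
#'
#' @param angles helix tilt angles in degrees
#' @return object of class `tilt_sample`
#' @export
tilt_sample <- function(angles) {
  angles <- as.numeric(angles)
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90))
    stop("tilt angles must lie in [0, 90] degrees", call. = FALSE)
  structure(list(angles = angles, n = length(angles)), class = "tilt_sample")
}

#' Fit a quadratic to an observed tilt-angle distribution
#'
#' Histograms the angles and least-squares fits a second-degree polynomial
#' in theta (degrees) to the per-bin statistic. Two normalisations are
#' offered:
#' \describe{
#'   \item{`"radians"`}{density per radian of tilt (unit area in radian
#'     measure). On this scale the random-sampling reference distribution
#'     is exactly sin(theta), so the fitted quadratic is directly
#'     comparable to it in [derive_penalty()]. Default.}
#'   \item{`"fraction"`}{probability mass per bin (fractions summing to 1).
#'     This is the convention of the shipped observed-density
#'     coefficients.}
#'   \item{`"degrees"`}{density per degree (unit area in degree measure).}
#' }
#' Only bins with at least one count and midpoint within `fit_range`
#' contribute to the fit: empty bins carry no density information and a
#' quadratic is only an adequate model in the low-tilt regime where
#' membrane spans are actually observed.
#'
#' @param sample a [tilt_sample()] or numeric vector of angles (degrees)
#' @param bin_width histogram bin width, degrees (default 5)
#' @param normalise `"radians"`, `"fraction"` or `"degrees"`
#' @param fit_range bin midpoints used in the fit (default `c(0, 60)`)
#' @param min_n minimum sample size (default 100)
#' @return object of class `tilt_density_fit` with elements `coefficients`
#'   (named c2, c1, c0), `bins` (data.frame mid/value/counts), `normalise`
#' @export
fit_tilt_density <- function(sample, bin_width = 5,
                             normalise = c("radians", "fraction", "degrees"),
                             fit_range = c(0, 60), min_n = 100L) {
  normalise <- match.arg(normalise)
  angles <- if (inherits(sample, "tilt_sample")) sample$angles else
    tilt_sample(sample)$angles
  n <- length(angles)
  if (n < min_n)
    stop("need at least ", min_n, " angles to fit a density", call. = FALSE)
  breaks <- seq(0, 90, by = bin_width)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  value <- switch(normalise,
    fraction = h$counts / n,
    degrees = h$counts / n / diff(breaks),
    radians = h$counts / n / (diff(breaks) * pi / 180)
  )
  use <- h$counts > 0 & h$mids >= fit_range[1] & h$mids <= fit_range[2]
  if (sum(use) < 4L)
    stop("too few occupied bins in fit_range for a quadratic fit",
         call. = FALSE)
  mid <- h$mids[use]
  fit <- stats::lm(value[use] ~ mid + I(mid^2))
  co <- stats::coef(fit)
  structure(
    list(coefficients = c(c2 = unname(co[3]), c1 = unname(co[2]),
                          c0 = unname(co[1])),
         bins = data.frame(mid = h$mids, value = value, counts = h$counts),
         normalise = normalise, bin_width = bin_width, n = n),
    class = "tilt_density_fit"
  )
}

eval_quadratic <- function(coefs, theta) {
  coefs[["c2"]] * theta^2 + coefs[["c1"]] * theta + coefs[["c0"]]
}

#' Tilt penalty from observed versus expected densities
#'
#' Converts the observed density f(theta) and the random-sampling reference
#' density sin(theta) to energies via a partition-function (Boltzmann)
#' inversion and subtracts: `-(ln f(theta) - ln sin(theta))`, theta in
#' degrees.
#'
#' @param observed_density named coefficients (c2, c1, c0) of the observed
#'   quadratic, a `tilt_density_fit`, or a function of theta
#' @param theta tilt angles in degrees (vectorised)
#' @param expected_density reference density as a function of theta in
#'   degrees (default sin(theta), the random-sampling expectation)
#' @return penalty values
#' @export
derive_penalty <- function(observed_density = OBSERVED_TILT_DENSITY, theta,
                           expected_density = function(t) sin(t * pi / 180)) {
  eval_density <- function(dens, t) {
    if (inherits(dens, "tilt_density_fit"))
      eval_quadratic(dens$coefficients, t)
    else if (is.function(dens)) dens(t)
    else eval_quadratic(dens, t)
  }
  if (any(theta <= 0))
    stop("theta must be positive (sin(theta) > 0 required)", call. = FALSE)
  f <- eval_density(observed_density, theta)
  s <- eval_density(expected_density, theta)
  if (any(f <= 0) || any(s <= 0))
    stop("density is non-positive inside the requested range",
         call. = FALSE)
  -(log(f) - log(s))
}

#' Cubic runtime approximation of the tilt penalty
#'
#' Samples [derive_penalty()] on a 1-degree grid over `fit_range` and
#' least-squares fits a third-degree polynomial, yielding a
#' [span_penalty_model()] free of the log-domain restriction of the exact
#' form.
#'
#' @param observed_density as in [derive_penalty()]
#' @param fit_range degrees, default `c(5, 45)`: the observed quadratic is
#'   positive and sin(theta) bounded away from 0 there
#' @return a [span_penalty_model()] with attributes `fit_range` and
#'   `max_residual`
#' @export
approximate_penalty <- function(observed_density = OBSERVED_TILT_DENSITY,
                                fit_range = c(5, 45)) {
  grid <- seq(fit_range[1], fit_range[2], by = 1)
  pen <- derive_penalty(observed_density, grid)
  fit <- stats::lm(pen ~ grid + I(grid^2) + I(grid^3))
  co <- stats::coef(fit)
  model <- span_penalty_model(a3 = unname(co[4]), a2 = unname(co[3]),
                              a1 = unname(co[2]), a0 = unname(co[1]))
  attr(model, "fit_range") <- fit_range
  attr(model, "max_residual") <- max(abs(stats::resid(fit)))
  model
}

#' Read tilt angles from a plain-text file
#'
#' @param path one angle (degrees) per line; blank lines and `#` comments
#'   ignored
#' @return a [tilt_sample()]
#' @export
read_tilt_angles <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tilt_sample(as.numeric(lines))
}
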