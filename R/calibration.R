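#' Poly-Ala mutation-scan grid
#'
#' Builds an ideal poly-Ala helix perpendicular to the membrane, centred on
#' the midplane, and returns the scan grid: one entry per helix position
#' with its membrane depth. The grid covers both membrane and aqueous
#' phases and is the reference state for profile calibration.
#'
#' @param helix_length number of residues (>= 20; default 40 spans roughly
#'   -30 to +30 A at the alpha-helical rise of ~1.5 A per residue)
#' @param frame a [membrane_frame()]
#' @return data.frame with columns `position` and `z`; the built helix is
#'   attached as attribute `"helix"`
#' @export
polyala_scan <- function(helix_length = 40L, frame = membrane_frame()) {
  helix_length <- as.integer(helix_length)
  if (helix_length < 20L)
    stop("scan helix must have at least 20 residues", call. = FALSE)
  helix <- build_helix(strrep("A", helix_length), tilt = 0, centre_depth = 0)
  res <- load_structure(helix, frame)
  out <- data.frame(position = seq_len(nrow(res)), z = res$z)
  attr(out, "helix") <- helix
  out
}

#' Iterative residual-encoding calibration
#'
#' Calibrates a per-(amino acid, depth) correction table so that a base
#' scorer plus the correction reproduces target insertion energies. Each
#' iteration scores every (aa, z) with the current correction and adds the
#' residual to the correction:
#' `correction <- correction + damping * (target - computed)`.
#' The loop stops when the maximum absolute residual drops below `tol` or
#' after `max_iter` updates (non-convergence is reported, not an error).
#' Ala is the reference residue; its correction is identically 0.
#'
#' @param base_scorer function(aa, z, correction) returning the computed
#'   energy for one (aa, z) given the current correction value; it may
#'   respond nonlinearly to the correction (emulating structural
#'   relaxation)
#' @param targets processed profile set (result of [process_profiles()]), a
#'   named list of `insertion_profile`s, or a matrix [aa x depth] with
#'   dimnames
#' @param max_iter maximum number of correction updates (default 10)
#' @param tol convergence tolerance on the max absolute residual, R.e.u.
#' @param damping residual step size in (0, 1] (default 1: encode the full
#'   difference)
#' @return object of class `calibration_result`: `correction` and
#'   `computed` matrices [aa x depth], `depths`, `iterations`, `converged`,
#'   `residual_history`, and `splines` (corrections encoded as
#'   [fit_spline()] splines)
#' @export
calibrate <- function(base_scorer, targets, max_iter = 10L, tol = 0.01,
                      damping = 1) {
  stopifnot(is.function(base_scorer), damping > 0, damping <= 1)
  tmat <- target_matrix(targets)
  depths <- as.numeric(colnames(tmat))
  aas <- rownames(tmat)

  corr <- matrix(0, nrow = nrow(tmat), ncol = ncol(tmat),
                 dimnames = dimnames(tmat))
  computed <- corr
  history <- numeric(0)
  iterations <- 0L
  converged <- FALSE
  repeat {
    for (i in seq_along(aas))
      for (j in seq_along(depths))
        computed[i, j] <- base_scorer(aas[i], depths[j], corr[i, j])
    if (any(!is.finite(computed)))
      stop("base scorer returned a non-finite energy", call. = FALSE)
    resid <- tmat - computed
    if ("A" %in% rownames(resid)) resid["A", ] <- 0
    history <- c(history, max(abs(resid)))
    if (max(abs(resid)) < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
    corr <- corr + damping * resid
    if ("A" %in% rownames(corr)) corr["A", ] <- 0
    iterations <- iterations + 1L
  }
  if (!converged)
    warning(sprintf("calibration did not converge in %d iterations (max residual %.4g)",
                    max_iter, history[length(history)]), call. = FALSE)

  splines <- lapply(aas, function(aa) {
    fit_spline(insertion_profile(aa, depths, corr[aa, ], units = "R.e.u.",
                                 processed = TRUE))
  })
  names(splines) <- aas
  structure(
    list(correction = corr, computed = computed, depths = depths,
         iterations = iterations, converged = converged,
         residual_history = history, splines = splines),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %d updates, %sconverged, final max residual %.4g>\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$residual_history[length(x$residual_history)]))
  invisible(x)
}

# Coerce targets to a matrix [aa x depth] with numeric-depth colnames.
target_matrix <- function(targets) {
  if (is.matrix(targets)) {
    stopifnot(!is.null(rownames(targets)), !is.null(colnames(targets)))
    return(targets)
  }
  profiles <- if (!is.null(targets$profiles)) targets$profiles else targets
  stopifnot(is.list(profiles), length(profiles) > 0)
  depths <- profiles[[1L]]$depths
  m <- t(vapply(profiles, function(p) {
    stopifnot(isTRUE(all.equal(p$depths, depths)))
    p$energies
  }, numeric(length(depths))))
  rownames(m) <- vapply(profiles, function(p) p$amino_acid, character(1))
  colnames(m) <- depths
  if (!"A" %in% rownames(m)) {
    m <- rbind(m, A = 0)
  }
  m
}

#' Trivial base scorer: no base energy
#'
#' Computed energy equals the current correction; calibration against any
#' target converges in a single update.
#' @return a base-scorer function
#' @export
base_scorer_zero <- function() {
  function(aa, z, correction) correction
}

#' Toy relaxing base scorer
#'
#' Emulates a scorer whose structural relaxation absorbs part of the
#' correction: computed = alpha * target + (1 - alpha) * correction.
#' Calibration converges geometrically: each residual-encoding update
#' shrinks the maximum residual by the factor alpha.
#'
#' @param targets target set (as in [calibrate()])
#' @param alpha fraction of the target captured directly, in (0, 1]
#' @return a base-scorer function
#' @export
base_scorer_linear <- function(targets, alpha = 0.5) {
  tmat <- target_matrix(targets)
  function(aa, z, correction) {
    j <- which.min(abs(as.numeric(colnames(tmat)) - z))
    alpha * tmat[aa, j] + (1 - alpha) * correction
  }
}

#' Noisy base scorer for robustness checks
#'
#' Adds bounded uniform noise on top of [base_scorer_linear()]; the final
#' calibration residual is bounded by the noise amplitude.
#'
#' @param targets target set
#' @param alpha as in [base_scorer_linear()]
#' @param eps noise half-width, R.e.u.
#' @return a base-scorer function (uses the current RNG stream)
#' @export
base_scorer_noisy <- function(targets, alpha = 0.5, eps = 0.05) {
  inner <- base_scorer_linear(targets, alpha)
  function(aa, z, correction) {
    inner(aa, z, correction) + stats::runif(1, -eps, eps)
  }
}

#' Serialise a calibration result to JSON
#'
#' @param result a `calibration_result`
#' @param path output path
#' @export
write_calibration_json <- function(result, path) {
  payload <- list(
    iterations = result$iterations,
    converged = result$converged,
    residual_history = result$residual_history,
    profiles = lapply(result$splines, function(s)
      list(amino_acid = s$amino_acid, knots = s$knots, values = s$values,
           units = s$units))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
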