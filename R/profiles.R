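#' Kcal/mol to Rosetta energy unit conversion factor
#'
#' Apparent insertion free energies in kcal/mol are mapped onto the Rosetta
#' energy scale by multiplying with 2.94.
#' @export
KCAL_TO_REU <- 2.94

# Cap (kcal/mol) applied to the His profile on the outer leaflet; the largest
# insertion penalty actually observed in the underlying experiment.
HIS_CAP_KCAL <- 2.3

#' Depth grid of a processed insertion profile
#'
#' Raw profiles are reported at 27 positions; these are mapped linearly onto
#' membrane depths -20 to +20 Angstrom (negative = inner leaflet).
#'
#' @param n number of positions (default 27)
#' @return numeric vector of depths in Angstrom
#' @export
profile_depth_grid <- function(n = 27L) {
  seq(-20, 20, length.out = n)
}

#' Construct an insertion profile
#'
#' An insertion profile holds the apparent transfer free energy
#' \eqn{\Delta\Delta G_{Ala \to aa}} of one amino acid as a function of
#' membrane depth, relative to alanine.
#'
#' @param amino_acid one-letter amino-acid code
#' @param depths strictly increasing membrane depths in Angstrom
#' @param energies energies, same length as `depths`
#' @param units `"kcal/mol"` or `"R.e.u."`
#' @param processed logical; `TRUE` once the profile has been through the
#'   smoothing/symmetrisation/special-case pipeline
#' @return object of class `insertion_profile`
#' @export
insertion_profile <- function(amino_acid, depths, energies,
                              units = c("kcal/mol", "R.e.u."),
                              processed = FALSE) {
  units <- match.arg(units)
  amino_acid <- as.character(amino_acid)
  stopifnot(length(amino_acid) == 1L, nchar(amino_acid) == 1L)
  depths <- as.numeric(depths)
  energies <- as.numeric(energies)
  if (length(depths) != length(energies))
    stop("depths and energies must have equal length", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(energies)))
    stop("energies must be finite", call. = FALSE)
  structure(
    list(amino_acid = amino_acid, depths = depths, energies = energies,
         units = units, processed = processed),
    class = "insertion_profile"
  )
}

#' @export
print.insertion_profile <- function(x, ...) {
  cat(sprintf("<insertion_profile %s: %d knots [%g, %g] A, %s%s>\n",
              x$amino_acid, length(x$depths), min(x$depths), max(x$depths),
              x$units, if (x$processed) ", processed" else ""))
  invisible(x)
}

#' Smooth an insertion profile with a centred moving average
#'
#' Endpoints use shrunken (one-sided) windows so the depth grid is unchanged.
#'
#' @param raw an [insertion_profile()]
#' @param window odd positive integer window width (knots)
#' @return smoothed `insertion_profile`
#' @export
smooth_profile <- function(raw, window = 3L) {
  stopifnot(inherits(raw, "insertion_profile"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  n <- length(raw$energies)
  if (n < window)
    stop("profile has fewer knots than the smoothing window", call. = FALSE)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(raw$energies[lo:hi])
  }, numeric(1))
  out <- raw
  out$energies <- sm
  out
}

#' Symmetrise a profile about the membrane midplane
#'
#' Replaces E(z) by (E(z) + E(-z)) / 2 at paired depth knots. The
#' positive-inside residues Arg, His and Lys are exempt and returned
#' unchanged: their leaflet asymmetry is the signal.
#'
#' @param p an [insertion_profile()] on a depth grid symmetric about 0
#' @return symmetrised `insertion_profile`
#' @export
symmetrise <- function(p) {
  stopifnot(inherits(p, "insertion_profile"))
  if (p$amino_acid %in% ASYMMETRIC_AA) return(p)
  d <- p$depths
  if (max(abs(sort(d) + rev(sort(d)))) > 1e-6)
    stop("depth grid is not symmetric about 0; cannot symmetrise",
         call. = FALSE)
  p$energies <- (p$energies + rev(p$energies)) / 2
  p
}

#' Apply the residue-specific processing rules to a profile set
#'
#' Three rules, all on the kcal/mol scale:
#' \itemize{
#'   \item His is capped at 2.3 kcal/mol between the midplane (0 A) and the
#'     outer membrane edge (+20 A).
#'   \item Cys inherits a copy of the (processed) Ser profile; the measured
#'     Cys profile is unusually asymmetric and Cys is rare in membranes.
#'   \item Asp, Glu, Gln and Asn, sparsely observed in the underlying
#'     experiment, are flattened: the mean energy over the membrane core
#'     (-10 to +10 A) is applied uniformly at every knot.
#' }
#'
#' @param profiles named list of [insertion_profile()]s (names = one-letter
#'   codes); must contain S, H, D, E, Q and N
#' @return named list of processed profiles
#' @export
apply_special_cases <- function(profiles) {
  need <- c("S", "H", "D", "E", "Q", "N")
  missing_aa <- setdiff(need, names(profiles))
  if (length(missing_aa))
    stop("profile set is missing required amino acids: ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  for (p in profiles)
    if (p$units != "kcal/mol")
      stop("special-case rules are defined on the kcal/mol scale",
           call. = FALSE)

  his <- profiles[["H"]]
  cap_idx <- his$depths >= 0 & his$depths <= 20
  his$energies[cap_idx] <- pmin(his$energies[cap_idx], HIS_CAP_KCAL)
  profiles[["H"]] <- his

  cys <- profiles[["S"]]
  cys$amino_acid <- "C"
  profiles[["C"]] <- cys

  for (aa in c("D", "E", "Q", "N")) {
    p <- profiles[[aa]]
    core <- p$depths >= -10 & p$depths <= 10
    p$energies[] <- mean(p$energies[core])
    profiles[[aa]] <- p
  }
  profiles
}

#' Convert a profile from kcal/mol to Rosetta energy units
#'
#' @param p an [insertion_profile()] in kcal/mol
#' @return the profile with energies multiplied by 2.94 and units flagged
#'   `"R.e.u."`
#' @export
to_rosetta_units <- function(p) {
  stopifnot(inherits(p, "insertion_profile"))
  if (p$units == "R.e.u.")
    stop("profile is already in R.e.u.; refusing to convert twice",
         call. = FALSE)
  p$energies <- p$energies * KCAL_TO_REU
  p$units <- "R.e.u."
  p
}

#' Fit a clamped cubic spline to a processed profile
#'
#' The spline interpolates every knot exactly; evaluation outside the knot
#' range returns the boundary knot value (the profile is only defined within
#' the membrane window; outside it base water solvation takes over). The
#' default is a natural cubic spline; `"monoH.FC"` (Fritsch-Carlson
#' monotone cubic Hermite) keeps the interpolant within the range of
#' neighbouring knots and is used for the capped His profile, where a
#' natural spline would overshoot the cap between knots.
#'
#' @param p an [insertion_profile()] with at least 4 knots
#' @param method `"natural"` (default) or `"monoH.FC"`
#' @return object of class `lipophilicity_spline`
#' @export
fit_spline <- function(p, method = c("natural", "monoH.FC")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "insertion_profile"))
  if (length(p$depths) < 4L)
    stop("need at least 4 knots to fit a cubic spline", call. = FALSE)
  fun <- stats::splinefun(p$depths, p$energies, method = method)
  structure(
    list(amino_acid = p$amino_acid, knots = p$depths, values = p$energies,
         units = p$units, method = method, fun = fun),
    class = "lipophilicity_spline"
  )
}

#' Evaluate a lipophilicity spline at membrane depths
#'
#' @param s a `lipophilicity_spline`
#' @param z membrane depths in Angstrom (vectorised); values outside the
#'   knot range are clamped to the boundary
#' @return energies in the spline's units
#' @export
eval_spline <- function(s, z) {
  stopifnot(inherits(s, "lipophilicity_spline"))
  z <- pmin(pmax(z, min(s$knots)), max(s$knots))
  s$fun(z)
}

#' @export
print.lipophilicity_spline <- function(x, ...) {
  cat(sprintf("<lipophilicity_spline %s: %d knots, %s>\n",
              x$amino_acid, length(x$knots), x$units))
  invisible(x)
}

#' Run the full profile-processing pipeline
#'
#' smooth -> symmetrise -> special cases -> (optionally) convert to R.e.u.
#' -> spline. Ala is forced to the all-zero reference profile; Pro, whose
#' apparent insertion signal reflects backbone perturbation rather than
#' sidechain lipophilicity, is assigned a zero profile and flagged.
#'
#' @param raw named list of raw [insertion_profile()]s in kcal/mol, or a
#'   data.frame with columns `aa`, `depth`, `energy_kcal`
#' @param window smoothing window (odd integer knots)
#' @param to_reu convert to Rosetta energy units (default TRUE)
#' @return named list with elements `profiles` (processed
#'   `insertion_profile`s) and `splines` (`lipophilicity_spline`s); carries
#'   attribute `pro_zeroed = TRUE` when a Pro profile was replaced
#' @export
process_profiles <- function(raw, window = 3L, to_reu = TRUE) {
  if (is.data.frame(raw)) raw <- profiles_from_table(raw)
  stopifnot(is.list(raw), length(raw) > 0)

  zero_profile <- function(aa, template) {
    insertion_profile(aa, template$depths, rep(0, length(template$depths)),
                      units = "kcal/mol")
  }
  template <- raw[[1L]]
  pro_zeroed <- FALSE
  if ("P" %in% names(raw)) {
    raw[["P"]] <- zero_profile("P", raw[["P"]])
    pro_zeroed <- TRUE
  }
  if ("A" %in% names(raw)) raw[["A"]] <- zero_profile("A", raw[["A"]])

  sm <- lapply(raw, smooth_profile, window = window)
  sy <- lapply(sm, symmetrise)
  sp <- apply_special_cases(sy)
  sp <- lapply(sp, function(p) { p$processed <- TRUE; p })
  if (to_reu) sp <- lapply(sp, to_rosetta_units)
  # His carries a hard cap; the monotone Hermite fit cannot overshoot it
  splines <- lapply(sp, function(p)
    fit_spline(p, method = if (p$amino_acid == "H") "monoH.FC" else
      "natural"))
  out <- list(profiles = sp, splines = splines)
  attr(out, "pro_zeroed") <- pro_zeroed
  out
}

#' Read raw insertion profiles from a CSV/TSV table
#'
#' @param path file with header `aa,depth,energy_kcal` (comma or tab
#'   separated), one row per (amino acid, depth)
#' @return named list of raw [insertion_profile()]s in kcal/mol
#' @export
read_raw_profiles <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  profiles_from_table(tab)
}

#' Build a profile list from a long-format table
#'
#' @param tab data.frame with columns `aa`, `depth`, `energy_kcal`
#' @return named list of [insertion_profile()]s
#' @export
profiles_from_table <- function(tab) {
  need <- c("aa", "depth", "energy_kcal")
  if (!all(need %in% names(tab)))
    stop("profile table must have columns aa, depth, energy_kcal",
         call. = FALSE)
  out <- lapply(split(tab, tab$aa), function(d) {
    d <- d[order(d$depth), ]
    insertion_profile(d$aa[1L], d$depth, d$energy_kcal, units = "kcal/mol")
  })
  out[order(names(out))]
}

#' Serialise processed profiles and splines to JSON
#'
#' A natural cubic spline is uniquely determined by its knots and knot
#' values, so those (plus units) are what gets stored.
#'
#' @param processed result of [process_profiles()]
#' @param path output JSON path
#' @export
write_profiles_json <- function(processed, path) {
  payload <- list(
    units = processed$profiles[[1L]]$units,
    pro_zeroed = isTRUE(attr(processed, "pro_zeroed")),
    profiles = lapply(processed$splines, function(s)
      list(amino_acid = s$amino_acid, knots = s$knots, values = s$values,
           units = s$units, method = s$method))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read splines back from a JSON profile file
#'
#' @param path JSON written by [write_profiles_json()]
#' @return named list of `lipophilicity_spline`s
#' @export
read_profiles_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  splines <- lapply(payload$profiles, function(p) {
    prof <- insertion_profile(p$amino_acid, unlist(p$knots),
                              unlist(p$values),
                              units = p$units, processed = TRUE)
    fit_spline(prof, method = p$method %||% "natural")
  })
  names(splines) <- vapply(splines, function(s) s$amino_acid, character(1))
  splines
}
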