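#' Helicality penalty parameters
#'
#' The paraboloid centre (phi, psi) = (-60, -45) degrees is the centre of
#' the alpha-helical region of the Ramachandran plot and carries zero
#' penalty; the curvature 25 keeps the penalty small throughout the helical
#' basin. The depth gate half-width of 10 A attenuates the penalty outside
#' the membrane core, following the trend of the hydrophobic-residue
#' insertion profiles.
#'
#' @param phi_center,psi_center paraboloid centre, degrees
#' @param curvature paraboloid curvature parameter, degrees
#' @param z_halfwidth depth-gate half-width, Angstrom
#' @return object of class `helicality_params`
#' @export
helicality_params <- function(phi_center = -60, psi_center = -45,
                              curvature = 25, z_halfwidth = 10) {
  stopifnot(curvature > 0, z_halfwidth > 0)
  structure(list(phi_center = phi_center, psi_center = psi_center,
                 curvature = curvature, z_halfwidth = z_halfwidth),
            class = "helicality_params")
}

#' Runtime helix-tilt penalty model (cubic in theta)
#'
#' @param a3,a2,a1,a0 cubic coefficients, theta in degrees
#' @return object of class `span_penalty_model`
#' @export
span_penalty_model <- function(a3, a2, a1, a0) {
  structure(list(a3 = a3, a2 = a2, a1 = a1, a0 = a0),
            class = "span_penalty_model")
}

#' Default helix-tilt penalty model
#'
#' The published cubic approximation to the log-ratio of expected (sin
#' theta) to observed tilt-angle densities:
#' penalty = 1.51e-4 theta^3 - 8.925e-3 theta^2 + 0.187 theta - 0.532.
#'
#' @return a [span_penalty_model()]
#' @export
default_span_penalty_model <- function() {
  span_penalty_model(a3 = 1.51e-4, a2 = -8.925e-3, a1 = 0.187, a0 = -0.532)
}

#' Lipophilicity energy of a residue
#'
#' Burial-weighted evaluation of the residue's lipophilicity spline at its
#' membrane depth: `weight * spline_aa(z)`. A fully buried residue (weight
#' 0) feels none of the membrane potential.
#'
#' @param aa one-letter amino-acid code
#' @param z membrane depth, Angstrom
#' @param weight burial weight in [0, 1]
#' @param splines named list of `lipophilicity_spline`s
#' @return energy in the splines' units
#' @export
lipophilicity_energy <- function(aa, z, weight, splines) {
  s <- splines[[aa]]
  if (is.null(s))
    stop("no lipophilicity spline for amino acid '", aa, "'", call. = FALSE)
  weight * eval_spline(s, z)
}

#' Mixed membrane/water solvation energy
#'
#' Linear mix of the lipophilicity spline and a base (water) solvation
#' value by the burial weight: `w * spline_aa(z) + (1 - w) * base`. Fully
#' exposed positions (w = 1) are scored purely by the membrane potential,
#' buried and water-embedded positions (w = 0) purely by the base solvation.
#'
#' @param aa,z,weight,splines as in [lipophilicity_energy()]
#' @param base_solvation base solvation energy for this residue (finite)
#' @return mixed energy
#' @export
solvation_mix <- function(aa, z, weight, splines, base_solvation = 0) {
  if (!is.finite(base_solvation))
    stop("base solvation energy must be finite", call. = FALSE)
  weight * eval_spline(splines[[aa]], z) + (1 - weight) * base_solvation
}

#' Helicality penalty of one backbone position
#'
#' Paraboloid penalty on deviation from ideal alpha-helical dihedrals,
#' gated by membrane depth and exposure:
#' \deqn{\frac{((\phi-\phi_c)^2 + (\psi-\psi_c)^2)^2}{25^4}
#'       \times \frac{1}{1 + (z/10)^4} \times w}
#' Maximal at the membrane midplane for lipid-exposed positions and
#' attenuated for buried or extra-membrane positions. Undefined dihedrals
#' (chain termini) give penalty 0 with attribute `undefined_dihedral`.
#'
#' @param phi,psi backbone dihedrals, degrees (NA at termini)
#' @param z membrane depth, Angstrom
#' @param weight burial/exposure weight in [0, 1]
#' @param params a [helicality_params()]
#' @return non-negative penalty (R.e.u.)
#' @export
helicality_penalty <- function(phi, psi, z, weight,
                               params = helicality_params()) {
  if (is.na(phi) || is.na(psi)) {
    out <- 0
    attr(out, "undefined_dihedral") <- TRUE
    return(out)
  }
  dev2 <- (phi - params$phi_center)^2 + (psi - params$psi_center)^2
  gate <- 1 / (1 + (z / params$z_halfwidth)^4)
  (dev2^2 / params$curvature^4) * gate * weight
}

#' Helix tilt-angle penalty
#'
#' Evaluates the runtime cubic penalty at a tilt angle theta in degrees.
#'
#' @param theta tilt angle(s), degrees, in [0, 90]
#' @param model a [span_penalty_model()]
#' @return penalty in R.e.u.
#' @export
span_angle_penalty <- function(theta, model = default_span_penalty_model()) {
  if (any(theta < 0 | theta > 90))
    stop("tilt angle must lie in [0, 90] degrees", call. = FALSE)
  model$a3 * theta^3 + model$a2 * theta^2 + model$a1 * theta + model$a0
}

#' Score a structure with the membrane energy terms
#'
#' Loads the structure, computes per-residue lipophilicity (as
#' [solvation_mix()]) and helicality, and a tilt penalty per span segment.
#' By default each chain with at least 6 residues is treated as one
#' membrane span; explicit spans may be declared instead.
#'
#' @param pdb_source PDB path or `bio3d` pdb object
#' @param splines named list of `lipophilicity_spline`s
#' @param frame a [membrane_frame()]
#' @param mode burial parameter set
#' @param base_solvation `NULL` (pure membrane-profile mode, base = 0) or a
#'   function(aa, z) returning a finite base solvation energy per residue
#' @param spans optional list of integer row-index vectors declaring span
#'   segments; default one span per chain
#' @param helical_params a [helicality_params()]
#' @param span_model a [span_penalty_model()]
#' @return list of class `mem_score`: `residues` (per-residue table with
#'   lipo and helicality columns), `spans` (per-span tilt and penalty),
#'   `totals` (named numeric)
#' @export
score_structure <- function(pdb_source, splines, frame = membrane_frame(),
                            mode = c("fullatom", "centroid"),
                            base_solvation = NULL, spans = NULL,
                            helical_params = helicality_params(),
                            span_model = default_span_penalty_model()) {
  mode <- match.arg(mode)
  res <- load_structure(pdb_source, frame, mode)
  if (nrow(res) == 0L) stop("empty residue selection", call. = FALSE)

  base_fun <- if (is.null(base_solvation)) function(aa, z) 0 else
    base_solvation
  res$lipo <- vapply(seq_len(nrow(res)), function(i) {
    b <- base_fun(res$aa[i], res$z[i])
    solvation_mix(res$aa[i], res$z[i], res$burial[i], splines, b)
  }, numeric(1))
  res$helicality <- vapply(seq_len(nrow(res)), function(i) {
    as.numeric(helicality_penalty(res$phi[i], res$psi[i], res$z[i],
                                  res$burial[i], helical_params))
  }, numeric(1))

  if (is.null(spans)) {
    spans <- split(seq_len(nrow(res)), res$chain)
    spans <- spans[vapply(spans, length, integer(1)) >= 6L]
  }
  span_df <- do.call(rbind, lapply(spans, function(rows) {
    seg <- helix_tilt(res, frame, rows)
    data.frame(chain = seg$chain, from = seg$resi_range[1],
               to = seg$resi_range[2], theta = seg$tilt_theta,
               span_penalty = span_angle_penalty(seg$tilt_theta, span_model),
               stringsAsFactors = FALSE)
  }))
  if (is.null(span_df))
    span_df <- data.frame(chain = character(), from = numeric(),
                          to = numeric(), theta = numeric(),
                          span_penalty = numeric())

  totals <- c(lipophilicity = sum(res$lipo),
              helicality = sum(res$helicality),
              span_penalty = sum(span_df$span_penalty),
              total = sum(res$lipo) + sum(res$helicality) +
                sum(span_df$span_penalty))
  structure(list(residues = res, spans = span_df, totals = totals),
            class = "mem_score")
}

#' @export
print.mem_score <- function(x, ...) {
  cat(sprintf("<mem_score: %d residues, %d spans>\n",
              nrow(x$residues), nrow(x$spans)))
  print(round(x$totals, 4))
  invisible(x)
}

#' Write a mem_score result to TSV
#'
#' Per-residue rows followed by `#total` and `#span` footer lines.
#'
#' @param score a `mem_score` from [score_structure()]
#' @param path output path
#' @export
write_score_tsv <- function(score, path) {
  con <- file(path, "w")
  on.exit(close(con))
  df <- as.data.frame(score$residues)
  cols <- c("chain", "resi", "aa", "z", "phi", "psi", "n6", "n12",
            "burial", "lipo", "helicality")
  utils::write.table(df[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(score$totals))
    writeLines(sprintf("#total\t%s\t%.6f", nm, score$totals[[nm]]), con)
  if (nrow(score$spans))
    for (i in seq_len(nrow(score$spans)))
      writeLines(sprintf("#span\t%s\t%d\t%d\ttheta=%.3f\tpenalty=%.6f",
                         score$spans$chain[i], score$spans$from[i],
                         score$spans$to[i], score$spans$theta[i],
                         score$spans$span_penalty[i]), con)
  invisible(path)
}
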