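# Ideal backbone geometry (Engh-Huber-like): bond lengths in Angstrom,
# angles in degrees.
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.1, omega = 180
)

rotation_matrix <- function(axis, angle_deg) {
  a <- unit3(axis); t <- angle_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + st * k + (1 - ct) * (k %*% k)
}

# CB by the tetrahedral bisector construction: equidistant in angle from
# the N-CA and C-CA bonds, on the L-chirality side. Deliberately a
# different construction from virtual_cb() so the two can check each other.
bisector_cb <- function(n, ca, c) {
  u1 <- unit3(n - ca); u2 <- unit3(c - ca)
  dot12 <- sum(u1 * u2)
  ct <- cos(110.5 * pi / 180)
  a <- ct / (1 + dot12)
  s <- u1 + u2
  p <- cross3(u1, u2)
  rem <- 1 - a^2 * sum(s^2)
  cc <- sqrt(max(0, rem)) / sqrt(sum(p^2))
  for (sgn in c(1, -1)) {
    dir <- a * s + sgn * cc * p
    cb <- ca + 1.53 * dir
    if (dihedral_angle(c, n, ca, cb) < 0) return(cb)  # L-amino acid
  }
  ca + 1.53 * (a * s + cc * p)
}

#' Build an ideal alpha-helix as a synthetic structure
#'
#' Grows a full backbone (N, CA, C, O, plus C-beta for non-Gly) residue by
#' residue from ideal bond geometry at the requested (phi, psi), then
#' places the helix in the default membrane frame: axis rotated `tilt`
#' degrees away from the membrane normal (about the x axis), C-alpha
#' centroid at depth `centre_depth`.
#'
#' @param sequence one-letter amino-acid string (length >= 4)
#' @param phi,psi backbone dihedrals, degrees (defaults -60, -45)
#' @param tilt angle between helix axis and membrane normal, degrees
#' @param centre_depth depth of the C-alpha centroid, Angstrom
#' @param chain chain identifier
#' @param resi_start first residue number
#' @return object of class `pdb` (bio3d-compatible atom table)
#' @export
build_helix <- function(sequence, phi = -60, psi = -45, tilt = 0,
                        centre_depth = 0, chain = "A", resi_start = 1L) {
  aa1 <- strsplit(toupper(sequence), "")[[1L]]
  if (length(aa1) < 4L)
    stop("helix needs at least 4 residues", call. = FALSE)
  if (!all(aa1 %in% names(AA_ONE_TO_THREE)))
    stop("nonstandard residue in sequence: ",
         paste(setdiff(aa1, names(AA_ONE_TO_THREE)), collapse = ","),
         call. = FALSE)
  g <- BB_GEOM
  nres <- length(aa1)
  N <- CA <- C <- vector("list", nres)
  # seed residue in a local frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres - 1L) + 1L) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$c_n, g$ang_ca_c_n, psi)
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, phi)
  }
  rows <- list()
  for (i in seq_len(nres)) {
    o <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o, psi + 180)
    atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = o)
    if (aa1[i] != "G")
      atoms$CB <- bisector_cb(N[[i]], CA[[i]], C[[i]])
    for (el in names(atoms))
      rows[[length(rows) + 1L]] <- data.frame(
        elety = el, resid = AA_ONE_TO_THREE[[aa1[i]]],
        chain = chain, resno = resi_start + i - 1L,
        x = atoms[[el]][1], y = atoms[[el]][2], z = atoms[[el]][3],
        stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  # orient: principal CA axis -> +z (N-to-C), then tip by `tilt` about x
  ca_mat <- do.call(rbind, CA)
  cen <- colMeans(ca_mat)
  ev <- eigen(crossprod(sweep(ca_mat, 2, cen)), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  if (sum(axis * (ca_mat[nres, ] - ca_mat[1L, ])) < 0) axis <- -axis
  v <- cross3(axis, c(0, 0, 1))
  if (sqrt(sum(v^2)) > 1e-9) {
    rot <- rotation_matrix(v, acos(pmax(-1, pmin(1, axis[3]))) * 180 / pi)
  } else {
    rot <- if (axis[3] > 0) diag(3) else rotation_matrix(c(1, 0, 0), 180)
  }
  rot <- rotation_matrix(c(1, 0, 0), tilt) %*% rot
  xyz <- sweep(xyz, 2, cen) %*% t(rot)
  ca_new <- sweep(ca_mat, 2, cen) %*% t(rot)
  shift <- c(-mean(ca_new[, 1]), -mean(ca_new[, 2]),
             centre_depth - mean(ca_new[, 3]))
  xyz <- sweep(xyz, 2, shift, `+`)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  as_pdb_object(at)
}

# Wrap an atom data.frame (elety, resid, chain, resno, x, y, z) as a
# minimal bio3d-compatible pdb object.
as_pdb_object <- function(at) {
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(nrow(at)), elety = at$elety,
    alt = NA_character_, resid = at$resid, chain = at$chain,
    resno = at$resno, insert = NA_character_,
    x = at$x, y = at$y, z = at$z, o = 1, b = 0,
    segid = NA_character_, elesy = substr(at$elety, 1L, 1L),
    charge = NA_character_, stringsAsFactors = FALSE
  )
  structure(list(atom = atom,
                 xyz = as.numeric(t(as.matrix(atom[, c("x", "y", "z")])))),
            class = "pdb")
}

#' Combine structures into a multi-chain complex
#'
#' @param ... `pdb` objects (e.g. from [build_helix()]) with distinct
#'   chain ids
#' @return a single `pdb` object
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  at <- do.call(rbind, lapply(parts, function(p) p$atom))
  at$eleno <- seq_len(nrow(at))
  structure(list(atom = at,
                 xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")])))),
            class = "pdb")
}

#' Apply a rigid-body transform to a structure
#'
#' @param pdb a `pdb` object
#' @param rotation 3 x 3 rotation matrix
#' @param translation 3-vector, Angstrom
#' @param chain optional chain id; transform only that chain
#' @return transformed `pdb` object
#' @export
transform_structure <- function(pdb, rotation = diag(3),
                                translation = c(0, 0, 0), chain = NULL) {
  at <- pdb$atom
  sel <- if (is.null(chain)) rep(TRUE, nrow(at)) else at$chain == chain
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  cen <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, cen) %*% t(rotation), 2, cen + translation, `+`)
  at$x[sel] <- xyz[, 1]; at$y[sel] <- xyz[, 2]; at$z[sel] <- xyz[, 3]
  as_pdb_object(at[, c("elety", "resid", "chain", "resno", "x", "y", "z")])
}

#' Write a structure as fixed-width PDB ATOM records
#'
#' Occupancy 1.00, B-factor 0.00, standard 80-column records.
#'
#' @param pdb a `pdb` object
#' @param path output path
#' @export
write_pdb <- function(pdb, path) {
  at <- pdb$atom
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$eleno, at$elety, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, substr(at$elety, 1L, 1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build an ideal parallel two-helix dimer
#'
#' Two identical helices (chains A and B) at the same tilt, separated
#' along x. A convenient base structure for decoy ensembles and
#' native-contact tests.
#'
#' @param sequence one-letter sequence of each monomer
#' @param separation inter-axis distance, Angstrom
#' @param tilt per-helix tilt, degrees (opposite signs, giving a crossing
#'   angle of `2 * tilt`)
#' @return a `pdb` object with chains A and B
#' @export
build_dimer <- function(sequence, separation = 8, tilt = 0) {
  a <- build_helix(sequence, tilt = tilt, chain = "A")
  b <- build_helix(sequence, tilt = -tilt, chain = "B")
  b <- transform_structure(b, translation = c(separation, 0, 0))
  combine_structures(a, b)
}

#' Generate a decoy ensemble around a base dimer
#'
#' Seeded rigid-body perturbations of the last chain of `base`. Each decoy
#' draws one perturbation mode (optionally with given probabilities), adds
#' the mode's translation plus Gaussian jitter, and rotates by a jittered
#' angle about a random axis. The true C-alpha RMSD of each decoy to the
#' base (optimal superposition) is returned as ground truth.
#'
#' @param base a multi-chain `pdb` object
#' @param n number of decoys
#' @param modes list of perturbation modes, each
#'   `list(translation = c(x, y, z), rotation = degrees)`; default a
#'   single null mode
#' @param jitter_sd Gaussian jitter on each translation component, Angstrom
#' @param rotation_sd Gaussian jitter on the rotation angle, degrees
#' @param seed integer RNG seed
#' @return list with `models` (named list of `pdb`), `truth` (data.frame
#'   id, mode, rmsd_to_base)
#' @export
build_decoy_ensemble <- function(base, n, modes = list(list(
                                   translation = c(0, 0, 0), rotation = 0)),
                                 jitter_sd = 0.3, rotation_sd = 1,
                                 seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  chains <- unique(base$atom$chain)
  target_chain <- chains[length(chains)]
  base_ca <- ca_coords(base)
  models <- list()
  truth <- data.frame(id = character(0), mode = integer(0),
                      rmsd_to_base = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- sample.int(length(modes), 1L)
    mode <- modes[[m]]
    tr <- mode$translation + stats::rnorm(3, 0, jitter_sd)
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- mode$rotation + stats::rnorm(1, 0, rotation_sd)
    dec <- transform_structure(base, rotation_matrix(axis, ang), tr,
                               chain = target_chain)
    id <- sprintf("decoy_%03d", i)
    models[[id]] <- dec
    truth <- rbind(truth, data.frame(
      id = id, mode = m, rmsd_to_base = kabsch_rmsd(ca_coords(dec), base_ca),
      stringsAsFactors = FALSE))
  }
  list(models = models, truth = truth)
}

#' C-alpha coordinate matrix of a structure
#'
#' @param pdb a `pdb` object
#' @return n x 3 matrix
#' @export
ca_coords <- function(pdb) {
  at <- pdb$atom[trimws(pdb$atom$elety) == "CA", , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Synthetic raw insertion-profile table
#'
#' Generates smooth, lightly noisy raw profiles (kcal/mol, 27 positions
#' mapped onto -20..+20 A) for all 20 amino acids, shaped to the hallmark
#' features of the measured insertion energetics: an approximately
#' 2 kcal/mol Gly penalty at the membrane midplane, approximately
#' -2 kcal/mol transfer energies for Leu/Ile/Phe at the core, a
#' 2 kcal/mol inner-leaflet preference for Arg and Lys, and a raw His
#' profile exceeding the 2.3 kcal/mol cap on the outer leaflet.
#'
#' @param seed integer RNG seed
#' @param noise_sd per-knot Gaussian noise, kcal/mol (default 0.05)
#' @return data.frame with columns `aa`, `depth`, `energy_kcal`
#' @export
synth_raw_profiles <- function(seed = 1L, noise_sd = 0.05) {
  set.seed(seed)
  d <- profile_depth_grid()
  bump <- function(z) exp(-(z / 12)^4)   # ~1 in the core, ~0 beyond +-20
  core_level <- c(A = 0, L = -2.0, I = -2.0, F = -2.0, V = -1.6, M = -1.3,
                  W = -0.9, Y = 0.6, C = 0.9, S = 0.8, T = 0.6, G = 2.0,
                  P = 1.5, N = 2.6, Q = 2.2, D = 3.4, E = 3.0)
  rows <- list()
  add <- function(aa, e) {
    noisy <- e + stats::rnorm(length(d), 0, noise_sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      aa = aa, depth = d, energy_kcal = noisy, stringsAsFactors = FALSE)
  }
  for (aa in names(core_level)) add(aa, core_level[[aa]] * bump(d))
  # His: symmetric base plus an outer-leaflet excursion past the cap
  add("H", 1.0 * bump(d) + 2.0 * exp(-((d - 10) / 6)^2))
  # positive-inside residues: core penalty plus a leaflet-asymmetric step
  # tuned so the inner-minus-outer interface mean is about -2 kcal/mol
  add("R", 2.5 * bump(d) + 1.03 * tanh(d / 6))
  add("K", 2.3 * bump(d) + 1.03 * tanh(d / 6))
  do.call(rbind, rows)
}

#' Sample helix tilt angles from a named density
#'
#' Seeded rejection sampling on the density's positive support.
#'
#' @param density `"sin"` (the random-sampling reference, support
#'   0..90 deg), `"eq2"` (the shipped observed quadratic, support up to
#'   its positive root, about 48 deg), or a function of theta (degrees);
#'   a custom function also needs `support`
#' @param n sample size
#' @param seed integer RNG seed
#' @param support numeric `c(lo, hi)` for custom densities
#' @return a [tilt_sample()]
#' @export
sample_tilt_angles <- function(density = c("sin", "eq2"), n, seed = 1L,
                               support = NULL) {
  set.seed(seed)
  if (is.function(density)) {
    f <- density
    if (is.null(support)) stop("custom density needs a support",
                               call. = FALSE)
  } else {
    density <- match.arg(density)
    if (density == "sin") {
      f <- function(t) sin(t * pi / 180)
      support <- c(0, 90)
    } else {
      f <- function(t) eval_quadratic(OBSERVED_TILT_DENSITY, t)
      hi <- stats::uniroot(f, c(30, 90))$root
      support <- c(0, hi)
    }
  }
  fmax <- max(f(seq(support[1], support[2], length.out = 2001)))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(1000L, 2L * (n - length(out)))
    x <- stats::runif(m, support[1], support[2])
    u <- stats::runif(m, 0, fmax * 1.001)
    out <- c(out, x[u < f(x)])
  }
  tilt_sample(out[seq_len(n)])
}
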