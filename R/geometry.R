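#' Define the membrane frame
#'
#' The membrane is a slab orthogonal to `normal` with its midplane at
#' `midplane_offset` Angstrom along the normal. Membrane depth of a point x
#' is `inner_leaflet_sign * (dot(x, normal) - midplane_offset)`; with the
#' default sign convention negative depths are the inner (cytoplasmic)
#' leaflet and positive depths the outer leaflet.
#'
#' @param normal membrane normal (3-vector, normalised internally)
#' @param midplane_offset midplane position along the normal, Angstrom
#' @param inner_leaflet_sign +1 (default) or -1; flip to swap leaflets
#' @return object of class `membrane_frame`
#' @export
membrane_frame <- function(normal = c(0, 0, 1), midplane_offset = 0,
                           inner_leaflet_sign = 1L) {
  normal <- as.numeric(normal)
  stopifnot(length(normal) == 3L)
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("membrane normal must be non-zero", call. = FALSE)
  if (!inner_leaflet_sign %in% c(-1L, 1L, -1, 1))
    stop("inner_leaflet_sign must be +1 or -1", call. = FALSE)
  structure(
    list(normal = normal / nrm, midplane_offset = midplane_offset,
         inner_leaflet_sign = as.integer(sign(inner_leaflet_sign))),
    class = "membrane_frame"
  )
}

#' Membrane depth of points
#'
#' @param xyz n x 3 matrix (or 3-vector) of coordinates
#' @param frame a [membrane_frame()]
#' @return signed depths in Angstrom
#' @export
membrane_depth <- function(xyz, frame) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  frame$inner_leaflet_sign *
    (as.numeric(xyz %*% frame$normal) - frame$midplane_offset)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise zero vector", call. = FALSE)
  v / n
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Places atom D such that |C-D| = `bond`, angle(B, C, D) = `angle` and
#' dihedral(A, B, C, D) = `dihedral`.
#'
#' @param a,b,c positions of the three reference atoms
#' @param bond bond length C-D, Angstrom
#' @param angle bond angle B-C-D, degrees
#' @param dihedral torsion A-B-C-D, degrees
#' @return 3-vector position of D
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- cross3(b - a, bc)
  if (sqrt(sum(n^2)) < 1e-10)
    stop("collinear reference atoms in internal-coordinate placement",
         call. = FALSE)
  n <- unit3(n)
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal (virtual) C-beta position from backbone atoms
#'
#' Constructs the C-beta an L-amino acid would have, from N, CA and C alone,
#' using ideal tetrahedral geometry (bond 1.53 A, angle N-CA-CB 110.1 deg,
#' torsion C-N-CA-CB -122.6 deg). Needed because neighbour counts are taken
#' around C-beta and Gly has none.
#'
#' @param n_xyz,ca_xyz,c_xyz backbone atom positions (3-vectors)
#' @return 3-vector C-beta position
#' @export
virtual_cb <- function(n_xyz, ca_xyz, c_xyz) {
  place_atom(c_xyz, n_xyz, ca_xyz,
             bond = 1.53, angle = 110.1, dihedral = -122.6)
}

#' Torsion angle of four points
#'
#' @param p1,p2,p3,p4 3-vectors
#' @return dihedral in degrees, in (-180, 180]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Extract a cleaned heavy-atom protein table from a bio3d pdb object:
# altloc '' or 'A', no hydrogens, no waters/het.
clean_atom_table <- function(pdb) {
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    toupper(at$resid) %in% names(AA_THREE_TO_ONE)
  at <- at[keep, , drop = FALSE]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("^[0-9 ]+", "", at$elety), 1L, 1L)
  at <- at[toupper(trimws(elesy)) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein atoms found", call. = FALSE)
  at
}

#' Load a structure and compute per-residue membrane geometry
#'
#' Parses a PDB file (or accepts a `bio3d` pdb object), establishes the
#' membrane frame, and returns one record per residue with membrane depth at
#' C-alpha, a real or virtual C-beta, backbone dihedrals, heavy-atom
#' neighbour counts within 6 and 12 A of C-beta (other residues only), and
#' the burial weight. Residues missing any of N, CA, C are skipped with a
#' warning. Only altloc ''/'A' heavy protein atoms are considered.
#'
#' @param pdb_source path to a PDB file or a `bio3d` pdb object
#' @param frame a [membrane_frame()]
#' @param mode burial parameter set, `"fullatom"` or `"centroid"`
#' @return data.frame with columns chain, resi, aa, ca_x/y/z, cb_x/y/z, phi,
#'   psi, z, n6, n12, burial; the cleaned atom table is attached as
#'   attribute `"atoms"`
#' @export
load_structure <- function(pdb_source, frame = membrane_frame(),
                           mode = c("fullatom", "centroid")) {
  mode <- match.arg(mode)
  pdb <- if (inherits(pdb_source, "pdb")) pdb_source else
    bio3d::read.pdb(pdb_source, verbose = FALSE)
  at <- clean_atom_table(pdb)

  key <- paste(at$chain, at$resno, at$insert %||% "", sep = "|")
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))

  res <- lapply(groups, function(idx) {
    sub <- at[idx, , drop = FALSE]
    get1 <- function(name) {
      i <- which(trimws(sub$elety) == name)[1L]
      if (is.na(i)) return(NULL)
      c(sub$x[i], sub$y[i], sub$z[i])
    }
    n <- get1("N"); ca <- get1("CA"); cc <- get1("C")
    if (is.null(n) || is.null(ca) || is.null(cc)) {
      warning(sprintf("skipping residue %s %s: missing backbone atoms",
                      sub$chain[1L], sub$resno[1L]), call. = FALSE)
      return(NULL)
    }
    cb <- get1("CB")
    if (is.null(cb)) cb <- virtual_cb(n, ca, cc)
    list(chain = sub$chain[1L], resi = sub$resno[1L],
         aa = unname(AA_THREE_TO_ONE[toupper(sub$resid[1L])]),
         n = n, ca = ca, c = cc, cb = cb, atom_idx = idx)
  })
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0L)
    stop("no residues with complete backbone", call. = FALSE)

  nres <- length(res)
  df <- data.frame(
    chain = vapply(res, `[[`, character(1), "chain"),
    resi = vapply(res, `[[`, numeric(1), "resi"),
    aa = vapply(res, `[[`, character(1), "aa"),
    stringsAsFactors = FALSE
  )
  ca_mat <- t(vapply(res, `[[`, numeric(3), "ca"))
  cb_mat <- t(vapply(res, `[[`, numeric(3), "cb"))
  df$ca_x <- ca_mat[, 1]; df$ca_y <- ca_mat[, 2]; df$ca_z <- ca_mat[, 3]
  df$cb_x <- cb_mat[, 1]; df$cb_y <- cb_mat[, 2]; df$cb_z <- cb_mat[, 3]
  df$z <- membrane_depth(ca_mat, frame)

  # backbone dihedrals; undefined at termini and across chain breaks
  df$phi <- NA_real_; df$psi <- NA_real_
  bonded <- function(i, j) {
    df$chain[i] == df$chain[j] &&
      sqrt(sum((res[[i]]$c - res[[j]]$n)^2)) < 2.0
  }
  for (i in seq_len(nres)) {
    if (i > 1L && bonded(i - 1L, i))
      df$phi[i] <- dihedral_angle(res[[i - 1L]]$c, res[[i]]$n,
                                  res[[i]]$ca, res[[i]]$c)
    if (i < nres && bonded(i, i + 1L))
      df$psi[i] <- dihedral_angle(res[[i]]$n, res[[i]]$ca,
                                  res[[i]]$c, res[[i + 1L]]$n)
  }

  # neighbour counts: heavy atoms of *other* residues around each CB
  axyz <- cbind(at$x, at$y, at$z)
  counts <- neighbour_counts_all(cb_mat, axyz, res)
  df$n6 <- counts$n6
  df$n12 <- counts$n12
  df$burial <- burial_weight(df$n6, df$n12, burial_params(mode))
  attr(df, "atoms") <- at
  attr(df, "frame") <- frame
  class(df) <- c("residue_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorised neighbour counting over all residues
neighbour_counts_all <- function(cb_mat, axyz, res) {
  n6 <- integer(nrow(cb_mat)); n12 <- integer(nrow(cb_mat))
  res_of_atom <- integer(nrow(axyz))
  for (i in seq_along(res)) res_of_atom[res[[i]]$atom_idx] <- i
  for (i in seq_len(nrow(cb_mat))) {
    d2 <- (axyz[, 1] - cb_mat[i, 1])^2 + (axyz[, 2] - cb_mat[i, 2])^2 +
      (axyz[, 3] - cb_mat[i, 3])^2
    other <- res_of_atom != i
    n6[i] <- sum(other & d2 < 36)
    n12[i] <- sum(other & d2 < 144)
  }
  list(n6 = n6, n12 = n12)
}

#' Heavy-atom neighbour counts around one residue's C-beta
#'
#' Counts heavy atoms belonging to other residues within 6 and 12 A of the
#' target residue's (possibly virtual) C-beta.
#'
#' @param residues a `residue_table` from [load_structure()]
#' @param target row index of the target residue
#' @return list with elements `n6` and `n12`
#' @export
neighbour_counts <- function(residues, target) {
  stopifnot(target >= 1L, target <= nrow(residues))
  list(n6 = residues$n6[target], n12 = residues$n12[target])
}

#' Helix axis and tilt angle of a residue segment
#'
#' The axis is the principal direction (largest-variance eigenvector) of the
#' segment's C-alpha coordinates, oriented N-to-C; the tilt is the angle
#' between the axis and the membrane normal, folded into [0, 90] degrees.
#'
#' @param residues a `residue_table` (or any data.frame with ca_x/ca_y/ca_z)
#' @param frame a [membrane_frame()]
#' @param rows optional row indices delimiting the segment (default: all)
#' @return object of class `helix_segment`: chain, residue range, axis,
#'   tilt_theta (degrees)
#' @export
helix_tilt <- function(residues, frame = membrane_frame(), rows = NULL) {
  if (!is.null(rows)) residues <- residues[rows, , drop = FALSE]
  if (nrow(residues) < 6L)
    stop("need at least 6 consecutive residues to define a helix axis",
         call. = FALSE)
  ca <- cbind(residues$ca_x, residues$ca_y, residues$ca_z)
  cen <- sweep(ca, 2L, colMeans(ca))
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  if (sum(axis * (ca[nrow(ca), ] - ca[1L, ])) < 0) axis <- -axis
  cosang <- abs(sum(axis * frame$normal))
  theta <- acos(pmin(1, cosang)) * 180 / pi
  structure(
    list(chain = residues$chain[1L],
         resi_range = range(residues$resi),
         axis = axis, tilt_theta = theta),
    class = "helix_segment"
  )
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("<helix_segment %s %d-%d: tilt %.1f deg>\n", x$chain,
              x$resi_range[1], x$resi_range[2], x$tilt_theta))
  invisible(x)
}

#' Write a per-residue geometry/energy table to TSV
#'
#' @param residues a `residue_table`
#' @param path output path
#' @export
write_residue_tsv <- function(residues, path) {
  cols <- intersect(c("chain", "resi", "aa", "z", "phi", "psi", "n6", "n12",
                      "burial", "lipo", "helicality"), names(residues))
  utils::write.table(as.data.frame(residues)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
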