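# Shared fixtures, built once per test run.

# processed synthetic profile sets (R.e.u. and kcal/mol) and their splines
fixture_processed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- synth_raw_profiles(seed = 42L)
      cache <<- list(
        raw = raw,
        reu = process_profiles(raw),
        kcal = process_profiles(raw, to_reu = FALSE)
      )
    }
    cache
  }
})

# a 25-residue ideal poly-Ala helix, perpendicular, centred
fixture_helix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_helix(strrep("A", 25))
    cache
  }
})

# flat synthetic profile used where the exact shape is irrelevant
flat_profile <- function(aa = "L", value = 1, n = 27L) {
  insertion_profile(aa, profile_depth_grid(n), rep(value, n))
}

# random point cloud scaled to unit root-mean-square radius, so that
# uniformly scaled copies have pairwise Kabsch RMSD |s1 - s2|
unit_rms_cloud <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  p <- matrix(stats::rnorm(3 * n), ncol = 3L)
  p <- sweep(p, 2L, colMeans(p))
  p / sqrt(mean(rowSums(p^2)))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis <- stats::rnorm(3)
  memlipo:::rotation_matrix(axis, stats::runif(1, 0, 360))
}

# toy residue table (the columns native_contact_fraction needs)
toy_residue_table <- function(chain, resi, xyz) {
  data.frame(chain = chain, resi = resi,
             cb_x = xyz[, 1], cb_y = xyz[, 2], cb_z = xyz[, 3],
             ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
             stringsAsFactors = FALSE)
}
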