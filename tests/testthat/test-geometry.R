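test_that("membrane depth follows the frame definition", {
  h <- fixture_helix()
  res <- load_structure(h)
  expect_equal(res$z, res$ca_z)   # identity frame: depth = CA z

  res5 <- load_structure(h, membrane_frame(midplane_offset = 5))
  expect_equal(res5$z, res$z - 5)

  flipped <- load_structure(h, membrane_frame(inner_leaflet_sign = -1))
  expect_equal(flipped$z, -res$z)
  expect_equal(flipped$n6, res$n6)      # only depth changes sign
  expect_equal(flipped$phi, res$phi)
})

test_that("frame validates its normal", {
  f <- membrane_frame(normal = c(0, 0, 10))
  expect_lt(abs(1 - sqrt(sum(f$normal^2))), 1e-9)
  expect_error(membrane_frame(normal = c(0, 0, 0)), "non-zero")
})

test_that("virtual C-beta matches real C-beta and is rigid-body equivariant", {
  h <- fixture_helix()
  at <- h$atom
  for (i in c(5L, 12L, 20L)) {
    g <- function(el) {
      j <- which(at$elety == el & at$resno == i)
      c(at$x[j], at$y[j], at$z[j])
    }
    vcb <- virtual_cb(g("N"), g("CA"), g("C"))
    expect_lt(sqrt(sum((vcb - g("CB"))^2)), 0.25)

    rot <- random_rotation(seed = i)
    shift <- c(3, -2, 7)
    vcb_t <- virtual_cb(rot %*% g("N") + shift, rot %*% g("CA") + shift,
                        rot %*% g("C") + shift)
    expect_equal(as.numeric(vcb_t), as.numeric(rot %*% vcb + shift),
                 tolerance = 1e-9)
  }
  expect_error(virtual_cb(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("Gly residues carry a virtual C-beta", {
  h <- build_helix("AAGAAGAA")
  expect_false("CB" %in% h$atom$elety[h$atom$resid == "GLY"])
  res <- load_structure(h)
  gly <- res[res$aa == "G", ]
  expect_true(all(is.finite(gly$cb_x)))
  # virtual CB sits ~1.5 A from CA, like a real one
  d <- sqrt((gly$cb_x - gly$ca_x)^2 + (gly$cb_y - gly$ca_y)^2 +
              (gly$cb_z - gly$ca_z)^2)
  expect_true(all(abs(d - 1.53) < 0.01))
})

test_that("neighbour counts exclude self, nest, and match hand geometry", {
  h <- fixture_helix()
  res <- load_structure(h)
  expect_true(all(res$n6 <= res$n12))

  # single isolated residue: no neighbours at all
  one <- build_helix("AAAA")   # then keep only residue 1's atoms
  at1 <- one$atom[one$atom$resno == 1, ]
  iso <- memlipo:::as_pdb_object(at1[, c("elety", "resid", "chain",
                                         "resno", "x", "y", "z")])
  r1 <- load_structure(iso)
  expect_equal(r1$n6, 0L)
  expect_equal(r1$n12, 0L)

  # two hand-placed backbone-only residues: counts must match an explicit
  # per-atom distance tally around each virtual C-beta
  bb <- data.frame(
    elety = rep(c("N", "CA", "C"), 2),
    resid = "GLY", chain = "A", resno = rep(c(1L, 2L), each = 3L),
    x = c(0, 1.46, 2.2, 0, 1.46, 2.2) + rep(c(0, 7), each = 3L),
    y = c(0, 0, 1.2, 0, 0, 1.2), z = 0,
    stringsAsFactors = FALSE)
  two <- memlipo:::as_pdb_object(bb)
  rr <- load_structure(two)
  for (i in 1:2) {
    other <- bb[bb$resno != i, c("x", "y", "z")]
    cb <- c(rr$cb_x[i], rr$cb_y[i], rr$cb_z[i])
    d <- sqrt((other$x - cb[1])^2 + (other$y - cb[2])^2 +
                (other$z - cb[3])^2)
    expect_equal(rr$n6[i], sum(d < 6))
    expect_equal(rr$n12[i], sum(d < 12))
  }
  expect_equal(unlist(neighbour_counts(rr, 1)),
               c(n6 = rr$n6[1], n12 = rr$n12[1]))
})

test_that("backbone dihedrals round-trip the builder and flip with chirality", {
  for (angles in list(c(-60, -45), c(-57, -47), c(-75, -35))) {
    h <- build_helix(strrep("A", 15), phi = angles[1], psi = angles[2])
    res <- load_structure(h)
    expect_lt(max(abs(res$phi[-1] - angles[1])), 0.5)
    expect_lt(max(abs(res$psi[-nrow(res)] - angles[2])), 0.5)
    expect_true(is.na(res$phi[1]))
    expect_true(is.na(res$psi[nrow(res)]))
  }
  # mirroring coordinates flips the dihedral sign
  set.seed(9)
  p <- matrix(stats::rnorm(12), 4, 3)
  mirrored <- p %*% diag(c(-1, 1, 1))
  expect_equal(dihedral_angle(mirrored[1, ], mirrored[2, ], mirrored[3, ],
                              mirrored[4, ]),
               -dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]))
})

test_that("dihedrals agree with an independent torsion implementation", {
  set.seed(21)
  for (i in 1:20) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    ref <- bio3d::torsion.xyz(as.numeric(t(p)))
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("helix tilt recovers construction angles and folds into [0, 90]", {
  frame <- membrane_frame()
  for (tilt in c(0, 15, 30, 45, 60)) {
    h <- build_helix(strrep("A", 25), tilt = tilt)
    seg <- helix_tilt(load_structure(h), frame)
    expect_lt(abs(seg$tilt_theta - tilt), 0.5)
  }
  h150 <- build_helix(strrep("A", 25), tilt = 150)
  expect_lt(abs(helix_tilt(load_structure(h150), frame)$tilt_theta - 30), 0.5)
  expect_error(helix_tilt(load_structure(build_helix("AAAAA"))), "6")
})

test_that("geometry is invariant under joint rigid-body motion of structure and frame", {
  h <- build_helix(strrep("A", 20), tilt = 25)
  res <- load_structure(h)
  rot <- random_rotation(seed = 31)
  moved <- transform_structure(h, rotation = rot, translation = c(5, -3, 9))
  # the same rotation applied to the frame normal; translation along the
  # new normal absorbed into the midplane offset
  cen <- colMeans(as.matrix(h$atom[, c("x", "y", "z")]))
  new_normal <- as.numeric(rot %*% c(0, 0, 1))
  offset <- sum((c(5, -3, 9) + cen - as.numeric(rot %*% cen)) * new_normal)
  res2 <- load_structure(moved, membrane_frame(new_normal, offset))
  expect_equal(res2$z, res$z, tolerance = 1e-6)
  expect_equal(res2$phi, res$phi, tolerance = 1e-6)
  expect_equal(res2$n6, res$n6)
  expect_equal(res2$burial, res$burial, tolerance = 1e-9)
  seg <- helix_tilt(res2, membrane_frame(new_normal, offset))
  expect_equal(seg$tilt_theta, helix_tilt(res)$tilt_theta, tolerance = 1e-6)
})

test_that("structures round-trip through PDB files", {
  h <- build_helix(strrep("A", 10), tilt = 20, centre_depth = 4)
  f <- tempfile(fileext = ".pdb")
  write_pdb(h, f)
  back <- load_structure(f)
  orig <- load_structure(h)
  expect_equal(back$ca_x, orig$ca_x, tolerance = 1e-3)
  expect_equal(back$z, orig$z, tolerance = 1e-3)
  expect_equal(back$aa, orig$aa)
})
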