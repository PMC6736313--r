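test_that("Kabsch RMSD is zero on identical and rigidly moved copies", {
  p <- unit_rms_cloud(12, seed = 1)
  expect_equal(kabsch_rmsd(p, p), 0, tolerance = 1e-9)
  moved <- p %*% t(random_rotation(seed = 2))
  moved <- sweep(moved, 2, c(4, -7, 2), `+`)
  expect_lt(kabsch_rmsd(p, moved), 1e-6)
  expect_equal(kabsch_rmsd(p, moved), kabsch_rmsd(moved, p))
  expect_error(kabsch_rmsd(p, p[1:5, ]), "matching")
  expect_error(kabsch_rmsd(p[1:2, ], p[1:2, ]), "3 matched")
})

test_that("Kabsch RMSD matches a brute-force rotation-grid oracle", {
  # exhaustive search over Euler angles on 4-point sets
  brute_force_rmsd <- function(a, b, step = 4) {
    a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
    grid <- seq(0, 360 - step, by = step) * pi / 180
    half <- seq(0, 180, by = step) * pi / 180
    best <- Inf
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    for (al in grid) for (be in half) for (ga in grid) {
      r <- rz(al) %*% ry(be) %*% rz(ga)
      best <- min(best, sqrt(mean(rowSums((a %*% t(r) - b)^2))))
    }
    best
  }
  set.seed(13)
  for (i in 1:2) {
    a <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    b <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    kb <- kabsch_rmsd(a, b)
    bf <- brute_force_rmsd(a, b)
    expect_gte(bf, kb - 1e-9)      # grid search cannot beat the optimum
    expect_lt(bf - kb, 1e-3 + bf * 0.01)
  }
})

test_that("Kabsch RMSD agrees with an independent superposition code", {
  set.seed(17)
  a <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  b <- a + matrix(stats::rnorm(30, sd = 0.4), 10, 3)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(a)), as.numeric(t(b))))
  ref_rmsd <- bio3d::rmsd(as.numeric(t(a)), fitted)
  expect_equal(kabsch_rmsd(a, b), ref_rmsd, tolerance = 1e-3)
})

test_that("Kabsch RMSD behaves as a pseudo-metric on random point sets", {
  set.seed(19)
  for (i in 1:20) {
    x <- matrix(stats::rnorm(15), 5, 3)
    y <- matrix(stats::rnorm(15), 5, 3)
    z <- matrix(stats::rnorm(15), 5, 3)
    dxy <- kabsch_rmsd(x, y); dyz <- kabsch_rmsd(y, z)
    dxz <- kabsch_rmsd(x, z)
    expect_equal(dxy, kabsch_rmsd(y, x), tolerance = 1e-9)
    expect_lte(dxz, dxy + dyz + 1e-9)
  }
})

test_that("filters keep and drop rows by threshold and flag bad config", {
  tab <- data.frame(model_id = paste0("m", 1:5),
                    energy = c(-10, -9, -8, -7, -6),
                    helicality = c(0.05, 0.2, 0.01, 0.5, 0.09),
                    helix_distance = c(5, 5, 12, 5, 5))
  out <- apply_filters(tab, list(helicality = list(max = 0.1),
                                 helix_distance = list(max = 9)))
  expect_equal(out$model_id, c("m1", "m5"))
  expect_equal(attr(out, "n_removed"), 3L)

  expect_identical(apply_filters(tab, list())$model_id, tab$model_id)
  empty <- tab[0, ]
  expect_equal(nrow(apply_filters(empty, list(helicality = list(max = 1)))), 0L)

  expect_error(apply_filters(tab, list(sasa = list(min = 500))), "sasa")
  ok <- apply_filters(tab, list(sasa = list(min = 500)),
                      skip_missing = "sasa")
  expect_equal(nrow(ok), 5L)
})

test_that("top fraction keeps the lowest-energy rows including boundary ties", {
  tab <- data.frame(model_id = 1:50, energy = c(-50:-2, -2))
  expect_equal(nrow(top_fraction(tab, 0.10)), 5L)
  expect_equal(nrow(top_fraction(tab, 1.0)), 50L)
  # tie at the cut: both -2 rows kept when the cut lands on them
  tied <- data.frame(model_id = 1:4, energy = c(-3, -2, -2, -1))
  kept <- top_fraction(tied, 0.5)
  expect_equal(sort(kept$energy), c(-3, -2, -2))
  # permutation invariance
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(sort(top_fraction(perm, 0.2)$energy),
               sort(top_fraction(tab, 0.2)$energy))
})

test_that("score-wise clustering follows the iterative rule on a hand example", {
  base <- unit_rms_cloud(10, seed = 23)
  # scaled copies: pairwise RMSD equals the scale difference
  coords <- list(A = 10 * base, B = 12 * base, C = 16 * base, D = 13 * base)
  energies <- c(A = -10, B = -9, C = -8, D = -7)
  rep <- scorewise_cluster(coords, energies, rmsd_cutoff = 4)
  expect_equal(length(rep$clusters), 2L)
  expect_equal(rep$clusters[[1]]$representative, "A")
  expect_setequal(rep$clusters[[1]]$members, c("A", "B", "D"))
  expect_setequal(rep$clusters[[2]]$members, "C")
  expect_lt(rep$clusters[[1]]$energy, rep$clusters[[2]]$energy)
})

test_that("clustering degenerate cases: identical models and zero cutoff", {
  base <- unit_rms_cloud(8, seed = 29)
  coords <- list(a = base, b = base, c = base)
  energies <- c(a = -3, b = -5, c = -4)
  rep <- scorewise_cluster(coords, energies, rmsd_cutoff = 4)
  expect_equal(length(rep$clusters), 1L)
  expect_setequal(rep$clusters[[1]]$members, c("a", "b", "c"))
  expect_equal(rep$clusters[[1]]$representative, "b")

  coords2 <- list(a = 1 * base, b = 2 * base, c = 3 * base)
  rep0 <- scorewise_cluster(coords2, energies, rmsd_cutoff = 0,
                            max_clusters = Inf)
  expect_equal(length(rep0$clusters), 3L)
  expect_equal(vapply(rep0$clusters, `[[`, character(1), "representative"),
               c("b", "c", "a"))   # ordered by energy
})

test_that("clustering matches an exhaustive simulation over random instances", {
  simulate_rule <- function(d, energies, cutoff, max_clusters) {
    pool <- names(sort(energies))
    clusters <- list()
    while (length(pool) > 0 && length(clusters) < max_clusters) {
      rep_id <- pool[1]
      members <- pool[d[rep_id, pool] < cutoff | pool == rep_id]
      clusters[[length(clusters) + 1]] <- list(rep = rep_id,
                                               members = sort(members))
      pool <- setdiff(pool, members)
    }
    clusters
  }
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:8, 1)
    base <- unit_rms_cloud(10, seed = seed + 1000)
    scales <- stats::runif(n, 0, 12)
    coords <- lapply(scales, function(s) s * base)
    names(coords) <- letters[seq_len(n)]
    energies <- stats::setNames(stats::rnorm(n), names(coords))
    cutoff <- stats::runif(1, 0.5, 6)
    d <- abs(outer(scales, scales, "-"))
    dimnames(d) <- list(names(coords), names(coords))
    want <- simulate_rule(d, energies, cutoff, 5)
    got <- scorewise_cluster(coords, energies, rmsd_cutoff = cutoff)
    expect_equal(length(got$clusters), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$clusters[[k]]$representative, want[[k]]$rep)
      expect_setequal(got$clusters[[k]]$members, want[[k]]$members)
    }
  }
})

test_that("native-contact fraction: identity, separation, and partial overlap", {
  ref <- load_structure(build_dimer(strrep("A", 15), separation = 7))
  expect_equal(native_contact_fraction(ref, ref), 1.0)
  far <- load_structure(
    transform_structure(build_dimer(strrep("A", 15), separation = 7),
                        translation = c(50, 0, 0), chain = "B"))
  expect_equal(native_contact_fraction(far, ref), 0.0)
  expect_warning(out <- native_contact_fraction(ref, far), "undefined")
  expect_true(is.na(out))

  # toy tables: reference has 4 contacts, model preserves exactly 3
  ref_tab <- rbind(
    toy_residue_table("A", 1:4, cbind(0, 0, c(0, 4, 8, 12))),
    toy_residue_table("B", 1:4, cbind(5, 0, c(0, 4, 8, 12))))
  mod_xyz_b <- cbind(c(5, 5, 5, 30), 0, c(0, 4, 8, 12))
  mod_tab <- rbind(
    toy_residue_table("A", 1:4, cbind(0, 0, c(0, 4, 8, 12))),
    toy_residue_table("B", 1:4, mod_xyz_b))
  ref_contacts <- memlipo:::interchain_contacts(ref_tab, 8)
  expect_equal(length(ref_contacts), 10L)  # |dz| <= 4 and dx 5 -> sqrt(41) < 8
  # moving B4 far away severs its two contacts (A3-B4 and A4-B4)
  frac <- native_contact_fraction(mod_tab, ref_tab)
  expect_equal(frac, 8 / 10)
})

test_that("native-contact fraction decreases monotonically under pulling", {
  dimer <- build_dimer(strrep("A", 15), separation = 7)
  ref <- load_structure(dimer)
  fracs <- vapply(c(0, 1, 2, 4, 8, 16), function(dx) {
    pulled <- transform_structure(dimer, translation = c(dx, 0, 0),
                                  chain = "B")
    native_contact_fraction(load_structure(pulled), ref)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_equal(fracs[1], 1.0)
})

test_that("ddG classification tallies a confusion matrix over mutations", {
  rep <- ddg_classify(list(m1 = c(1, 1, 1), m2 = c(-2, -2)),
                      c(m1 = "destabilising", m2 = "stabilising"))
  expect_equal(rep$accuracy, 1.0)
  expect_equal(unname(rep$confusion["TP"] + rep$confusion["TN"]), 2L)

  # tie rule: median exactly 0 is called stabilising (> threshold is
  # destabilising-exclusive)
  tie <- ddg_classify(list(m = c(-1, 0, 1)), c(m = "stabilising"))
  expect_equal(tie$table$call, "stabilising")

  # empty model set: flagged and excluded
  expect_warning(
    rep2 <- ddg_classify(list(m1 = c(2), m2 = numeric(0)),
                         c(m1 = "destabilising", m2 = "stabilising")),
    "m2")
  expect_equal(rep2$skipped, "m2")
  expect_equal(nrow(rep2$table), 1L)
})

test_that("ddG accuracy matches a hand tally on a 32-mutation synthetic set", {
  set.seed(41)
  n <- 32
  labels <- stats::setNames(sample(c("stabilising", "destabilising"), n,
                                   replace = TRUE),
                            sprintf("mut%02d", 1:n))
  true_ddg <- ifelse(labels == "destabilising", 2, -2)
  tables <- lapply(seq_len(n), function(i)
    true_ddg[i] + stats::rnorm(7, 0, 2.5))   # noisy medians, some flips
  names(tables) <- names(labels)
  rep <- ddg_classify(tables, labels)
  med <- vapply(tables, stats::median, numeric(1))
  call <- ifelse(med > 0, "destabilising", "stabilising")
  expect_equal(rep$accuracy, mean(call == labels))
  expect_equal(unname(rep$confusion["TP"]),
               sum(call == "destabilising" & labels == "destabilising"))
  expect_equal(unname(rep$confusion["FN"]),
               sum(call == "stabilising" & labels == "destabilising"))
  expect_equal(sum(rep$confusion), n)
})

test_that("inter-chain helix distance reports the closest CA approach", {
  dimer <- build_dimer(strrep("A", 15), separation = 9)
  res <- load_structure(dimer)
  d <- helix_distance(res)
  ca_a <- as.matrix(res[res$chain == "A", c("ca_x", "ca_y", "ca_z")])
  ca_b <- as.matrix(res[res$chain == "B", c("ca_x", "ca_y", "ca_z")])
  want <- min(sqrt(outer(rowSums(ca_a^2), rowSums(ca_b^2), "+") -
                     2 * ca_a %*% t(ca_b)))
  expect_equal(d, want, tolerance = 1e-9)
  expect_error(helix_distance(res[res$chain == "A", ]), "two chains")
})
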