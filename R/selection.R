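#' Minimal RMSD under rigid superposition (Kabsch)
#'
#' Optimal proper rotation via singular value decomposition of the
#' covariance of the centred coordinate sets.
#'
#' @param coords_a,coords_b n x 3 matrices of matched atoms (n >= 3)
#' @return RMSD in Angstrom
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)))
    stop("coordinate sets must have matching dimensions", call. = FALSE)
  if (nrow(coords_a) < 3L)
    stop("need at least 3 matched atoms", call. = FALSE)
  a <- sweep(coords_a, 2L, colMeans(coords_a))
  b <- sweep(coords_b, 2L, colMeans(coords_b))
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diffs <- b - a %*% t(rot)
  sqrt(mean(rowSums(diffs^2)))
}

#' Filter a model score table on metric thresholds
#'
#' Each threshold is `list(max = x)` or `list(min = x)` keyed by column
#' name; a row is kept only if it passes every supplied threshold (max:
#' value < x; min: value > x). A threshold naming an absent column is a
#' configuration error unless that name is listed in `skip_missing` —
#' metrics coming from external scorers may legitimately be absent, but
#' never silently.
#'
#' @param table data.frame of per-model metrics
#' @param thresholds named list of `list(max=)` / `list(min=)` entries
#' @param skip_missing character vector of threshold names that may be
#'   skipped when their column is absent
#' @return filtered data.frame (attribute `"n_removed"` records the count)
#' @export
apply_filters <- function(table, thresholds = list(), skip_missing = NULL) {
  stopifnot(is.data.frame(table))
  keep <- rep(TRUE, nrow(table))
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    if (!nm %in% names(table)) {
      if (nm %in% skip_missing) next
      stop("filter metric '", nm, "' is not a column of the score table ",
           "(add it or list it in skip_missing)", call. = FALSE)
    }
    v <- table[[nm]]
    if (!is.null(th$max)) keep <- keep & v < th$max
    if (!is.null(th$min)) keep <- keep & v > th$min
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Default structure/energy filter thresholds
#'
#' The benchmark filter set: solvent-accessible interface area > 500 A^2,
#' shape complementarity > 0.5, binding energy < -5 R.e.u., rotameric
#' binding strain < 4 R.e.u., total helicality < 0.1 R.e.u., and closest
#' inter-helix distance < 9 A. SASA, shape complementarity, binding energy
#' and strain come from external scorers and may be skipped when absent.
#'
#' @return named list of thresholds for [apply_filters()]
#' @export
default_filter_thresholds <- function() {
  list(sasa = list(min = 500),
       shape_complementarity = list(min = 0.5),
       ddg_binding = list(max = -5),
       binding_strain = list(max = 4),
       helicality = list(max = 0.1),
       helix_distance = list(max = 9))
}

#' Lowest-energy fraction of a score table
#'
#' Keeps the `ceiling(fraction * n)` lowest rows by `key`; rows tied with
#' the boundary value are all kept.
#'
#' @param table non-empty data.frame
#' @param fraction fraction in (0, 1]
#' @param key column to rank by (default `"energy"`)
#' @return subset of `table`
#' @export
top_fraction <- function(table, fraction = 0.10, key = "energy") {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            fraction > 0, fraction <= 1)
  if (!key %in% names(table))
    stop("ranking column '", key, "' not found", call. = FALSE)
  k <- ceiling(fraction * nrow(table))
  cutoff <- sort(table[[key]])[k]
  table[table[[key]] <= cutoff, , drop = FALSE]
}

#' Score-wise RMSD clustering
#'
#' Iterative clustering: each round seeds a new cluster with the
#' lowest-energy unclustered model and absorbs every unclustered model
#' within `rmsd_cutoff` of it (the representative included); rounds repeat
#' until `max_clusters` clusters exist or the pool is empty.
#'
#' @param coords named list of n x 3 coordinate matrices (matched atoms)
#' @param energies named numeric vector of model energies (same names)
#' @param rmsd_cutoff cluster radius, Angstrom (default 4)
#' @param max_clusters maximum clusters to emit (default 5; `Inf` to
#'   exhaust the pool)
#' @param reference optional n x 3 matrix; when given, each
#'   representative's RMSD to it is reported
#' @return object of class `cluster_report`: list of clusters (each with
#'   `representative`, `members`, `energy`, optional `rmsd_to_reference`),
#'   ordered by representative energy
#' @export
scorewise_cluster <- function(coords, energies, rmsd_cutoff = 4,
                              max_clusters = 5, reference = NULL) {
  stopifnot(length(coords) >= 1L, length(coords) == length(energies))
  ids <- names(coords)
  if (is.null(ids)) {
    ids <- as.character(seq_along(coords))
    names(coords) <- ids; names(energies) <- ids
  }
  pool <- ids[order(energies[ids])]
  clusters <- list()
  while (length(pool) > 0L && length(clusters) < max_clusters) {
    rep_id <- pool[1L]
    rms <- vapply(pool, function(id)
      kabsch_rmsd(coords[[rep_id]], coords[[id]]), numeric(1))
    members <- pool[rms < rmsd_cutoff | pool == rep_id]
    cl <- list(representative = rep_id, members = members,
               energy = unname(energies[rep_id]))
    if (!is.null(reference))
      cl$rmsd_to_reference <- kabsch_rmsd(coords[[rep_id]], reference)
    clusters[[length(clusters) + 1L]] <- cl
    pool <- setdiff(pool, members)
  }
  structure(list(clusters = clusters, unclustered = pool,
                 rmsd_cutoff = rmsd_cutoff),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report: %d clusters (cutoff %g A)>\n",
              length(x$clusters), x$rmsd_cutoff))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d. rep %s (E = %.3f), %d member(s)%s\n", i,
                cl$representative, cl$energy, length(cl$members),
                if (!is.null(cl$rmsd_to_reference))
                  sprintf(", RMSD to ref %.2f A", cl$rmsd_to_reference)
                else ""))
  }
  invisible(x)
}

# inter-chain residue contacts of a residue table: pairs (i, j) of rows in
# different chains with CB-CB distance < cutoff
interchain_contacts <- function(residues, cutoff = 8, atom = c("cb", "ca")) {
  atom <- match.arg(atom)
  xyz <- if (atom == "cb")
    cbind(residues$cb_x, residues$cb_y, residues$cb_z)
  else cbind(residues$ca_x, residues$ca_y, residues$ca_z)
  n <- nrow(residues)
  out <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (residues$chain[i] == residues$chain[j]) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
        key <- paste(residues$chain[i], residues$resi[i],
                     residues$chain[j], residues$resi[j], sep = "|")
        out <- c(out, key)
      }
    }
  }
  out
}

#' Fraction of native inter-chain contacts recovered by a model
#'
#' A contact is a pair of positions in different chains whose C-beta atoms
#' (virtual for Gly; optionally C-alpha) lie within `contact_cutoff` in the
#' reference. The fraction of reference contacts also present in the model
#' is returned. Model and reference must share chain ids and residue
#' numbering. A reference with no contacts has no defined fraction: `NA`
#' is returned with a warning, never a silent 0.
#'
#' @param model,reference `residue_table`s from [load_structure()]
#' @param contact_cutoff Angstrom (default 8)
#' @param atom `"cb"` (default) or `"ca"`
#' @return fraction in [0, 1], or `NA` for a contactless reference
#' @export
native_contact_fraction <- function(model, reference, contact_cutoff = 8,
                                    atom = c("cb", "ca")) {
  atom <- match.arg(atom)
  ref_contacts <- interchain_contacts(reference, contact_cutoff, atom)
  if (length(ref_contacts) == 0L) {
    warning("reference structure has no inter-chain contacts; ",
            "native-contact fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  mod_contacts <- interchain_contacts(model, contact_cutoff, atom)
  length(intersect(ref_contacts, mod_contacts)) / length(ref_contacts)
}

#' Median ddG classification of mutations
#'
#' For each mutation, takes the median binding energy change over its
#' surviving (filtered, top-scoring) models and classifies: median >
#' `threshold` is destabilising, median <= `threshold` stabilising.
#' Compared against experimental labels to give a 2 x 2 confusion table
#' and accuracy. Mutations with no surviving models are flagged and
#' excluded from the counts.
#'
#' @param ddg_tables named list (one entry per mutation) of numeric ddG
#'   vectors over surviving models, R.e.u.
#' @param labels named character vector of experimental calls,
#'   `"stabilising"` or `"destabilising"`, same names
#' @param threshold decision boundary on the median (default 0)
#' @return object of class `ddg_report`: per-mutation data.frame
#'   (mutation, n_models, median, call, label, correct), confusion counts
#'   (TP/TN/FP/FN, destabilising = positive), accuracy, and any skipped
#'   mutations
#' @export
ddg_classify <- function(ddg_tables, labels, threshold = 0) {
  stopifnot(is.list(ddg_tables), all(names(ddg_tables) %in% names(labels)))
  labels <- labels[names(ddg_tables)]
  if (!all(labels %in% c("stabilising", "destabilising")))
    stop("labels must be 'stabilising' or 'destabilising'", call. = FALSE)
  skipped <- names(ddg_tables)[vapply(ddg_tables, length, integer(1)) == 0L]
  used <- setdiff(names(ddg_tables), skipped)
  if (length(skipped))
    warning("no surviving models for: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  med <- vapply(ddg_tables[used], stats::median, numeric(1))
  call <- ifelse(med > threshold, "destabilising", "stabilising")
  correct <- call == labels[used]
  tab <- data.frame(mutation = used,
                    n_models = vapply(ddg_tables[used], length, integer(1)),
                    median = unname(med), call = unname(call),
                    label = unname(labels[used]),
                    correct = unname(correct),
                    stringsAsFactors = FALSE)
  confusion <- c(
    TP = sum(call == "destabilising" & labels[used] == "destabilising"),
    TN = sum(call == "stabilising" & labels[used] == "stabilising"),
    FP = sum(call == "destabilising" & labels[used] == "stabilising"),
    FN = sum(call == "stabilising" & labels[used] == "destabilising")
  )
  structure(
    list(table = tab, confusion = confusion,
         accuracy = if (length(used)) mean(correct) else NA_real_,
         skipped = skipped, threshold = threshold),
    class = "ddg_report"
  )
}

#' @export
print.ddg_report <- function(x, ...) {
  cat(sprintf("<ddg_report: %d mutations, accuracy %.3f>\n",
              nrow(x$table), x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Closest inter-chain C-alpha distance
#'
#' Helix-helix proximity metric used by the distance filter: the minimum
#' C-alpha to C-alpha distance between residues of different chains.
#'
#' @param residues a `residue_table` with at least two chains
#' @return distance in Angstrom
#' @export
helix_distance <- function(residues) {
  chains <- unique(residues$chain)
  if (length(chains) < 2L)
    stop("helix distance needs at least two chains", call. = FALSE)
  ca <- cbind(residues$ca_x, residues$ca_y, residues$ca_z)
  best <- Inf
  for (a in seq_along(chains)[-length(chains)]) {
    for (b in (a + 1L):length(chains)) {
      ia <- which(residues$chain == chains[a])
      ib <- which(residues$chain == chains[b])
      d2 <- outer(rowSums(ca[ia, , drop = FALSE]^2),
                  rowSums(ca[ib, , drop = FALSE]^2), "+") -
        2 * ca[ia, , drop = FALSE] %*% t(ca[ib, , drop = FALSE])
      best <- min(best, sqrt(max(0, min(d2))))
    }
  }
  best
}
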