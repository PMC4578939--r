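# Per-frame order parameters: native contacts (rho, Q), RMSD, SASA, RMSF.
#
# rho is the fraction of native side-chain contacts retained (minimum
# side-chain heavy-atom distance <= 0.55 nm); Q is the same ratio over
# all-heavy-atom residue contacts. Both exclude near-sequence pairs
# (|i - j| < min_sep, default 3), which are trivially always in contact.

#' Native residue-residue contact set
#'
#' A pair (i, j) is a native contact when the minimum distance between the
#' scoped atoms of residues i and j in the reference structure is at most
#' `cutoff`. Glycines contribute no atoms under the side-chain scope and are
#' silently excluded.
#'
#' @param structure reference `Structure`.
#' @param scope `"sidechain"` (heavy side-chain atoms) or `"heavy"` (all
#'   heavy atoms).
#' @param cutoff minimum-distance cutoff in nm (default 0.55).
#' @param min_sep minimum sequence separation |i - j| (default 3).
#' @return object of class `ContactSet`: data.frame with columns `i`, `j`
#'   (internal residue indices, i < j) and attributes `scope`, `cutoff`,
#'   `min_sep`, `atom_index` (list of scoped atom indices per residue).
#' @export
native_contacts <- function(structure, scope = c("sidechain", "heavy"),
                            cutoff = 0.55, min_sep = 3) {
  scope <- match.arg(scope)
  if (nrow(structure$residues) < min_sep + 1) {
    stop("structure has fewer than min_sep + 1 residues")
  }
  sel <- scoped_atoms(structure, scope)
  dmin <- residue_min_dist_matrix(as.matrix(structure$atoms[, c("x", "y", "z")]),
                                  structure$atoms$residue_index, sel,
                                  n_res = nrow(structure$residues))
  nres <- nrow(structure$residues)
  pairs <- which(upper.tri(dmin), arr.ind = TRUE)
  keep <- (pairs[, 2] - pairs[, 1]) >= min_sep &
    is.finite(dmin[pairs]) & dmin[pairs] <= cutoff
  out <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "scope") <- scope
  attr(out, "cutoff") <- cutoff
  attr(out, "min_sep") <- min_sep
  attr(out, "atom_index") <- split(sel, structure$atoms$residue_index[sel])
  class(out) <- c("ContactSet", "data.frame")
  out
}

#' @keywords internal
scoped_atoms <- function(structure, scope) {
  switch(scope,
         sidechain = select_sidechain(structure),
         heavy = select_heavy(structure),
         stop("unknown scope: ", scope))
}

# Minimum inter-residue distance matrix over a set of scoped atoms.
# Residues without scoped atoms get Inf rows/columns.
#' @keywords internal
residue_min_dist_matrix <- function(coords, atom_res, sel, n_res) {
  xyz <- coords[sel, , drop = FALSE]
  res <- atom_res[sel]
  d <- sqrt(dist2_cross(xyz, xyz))
  out <- matrix(Inf, n_res, n_res)
  grp <- split(seq_along(res), res)
  ids <- as.integer(names(grp))
  for (a in seq_along(grp)) {
    ra <- grp[[a]]
    for (b in seq_len(a - 1)) {
      m <- min(d[ra, grp[[b]], drop = FALSE])
      out[ids[a], ids[b]] <- out[ids[b], ids[a]] <- m
    }
  }
  out
}

#' Fraction of native contacts retained per frame
#'
#' `rho()` requires a side-chain-scope contact set, `q_fraction()` a
#' heavy-atom-scope one; both return, per frame, the number of native pairs
#' whose scoped minimum distance is within the native cutoff, divided by the
#' number of native pairs.
#'
#' @param x a `Trajectory`, or an n_atoms x 3 coordinate matrix (one frame).
#' @param native a `ContactSet` from [native_contacts()].
#' @return numeric vector, one value in \[0, 1\] per frame.
#' @export
rho <- function(x, native) {
  if (!identical(attr(native, "scope"), "sidechain")) {
    stop("rho requires a contact set built with sidechain scope")
  }
  contact_fraction(x, native)
}

#' @rdname rho
#' @export
q_fraction <- function(x, native) {
  if (!identical(attr(native, "scope"), "heavy")) {
    stop("q_fraction requires a contact set built with heavy scope")
  }
  contact_fraction(x, native)
}

#' @keywords internal
contact_fraction <- function(x, native) {
  if (nrow(native) == 0) stop("empty native contact set: fraction undefined")
  cutoff <- attr(native, "cutoff")
  atom_index <- attr(native, "atom_index")
  xyz <- if (inherits(x, "Trajectory")) x$xyz else
    matrix(c(t(as.matrix(x))), nrow = 1)
  nf <- nrow(xyz)
  intact <- matrix(FALSE, nf, nrow(native))
  for (p in seq_len(nrow(native))) {
    ai <- atom_index[[as.character(native$i[p])]]
    aj <- atom_index[[as.character(native$j[p])]]
    dmin2 <- rep(Inf, nf)
    for (a in ai) {
      ax <- xyz[, 3 * a - 2]; ay <- xyz[, 3 * a - 1]; az <- xyz[, 3 * a]
      for (b in aj) {
        d2 <- (ax - xyz[, 3 * b - 2])^2 + (ay - xyz[, 3 * b - 1])^2 +
          (az - xyz[, 3 * b])^2
        dmin2 <- pmin(dmin2, d2)
      }
    }
    intact[, p] <- dmin2 <= cutoff^2
  }
  rowMeans(intact)
}

#' Optimal-superposition RMSD of each frame to a reference
#'
#' Least-squares (Kabsch) superposition over the selection, then RMSD over
#' the same selection. Defaults to C-alpha atoms.
#'
#' @param x a `Trajectory` or an n_atoms x 3 coordinate matrix.
#' @param reference a `Structure` (its coordinates are the reference) or an
#'   n_atoms x 3 matrix.
#' @param selection integer atom indices; default C-alpha atoms of the
#'   trajectory topology / reference.
#' @return numeric vector of RMSD values (nm), one per frame.
#' @export
rmsd_series <- function(x, reference, selection = NULL) {
  if (inherits(x, "Trajectory")) {
    topo <- x$topology
    xyz <- x$xyz
  } else {
    topo <- NULL
    xyz <- matrix(c(t(as.matrix(x))), nrow = 1)
  }
  ref_xyz <- if (inherits(reference, "Structure")) {
    c(t(as.matrix(reference$atoms[, c("x", "y", "z")])))
  } else c(t(as.matrix(reference)))
  if (is.null(selection)) {
    selection <- if (inherits(reference, "Structure")) select_calpha(reference)
                 else if (!is.null(topo)) select_calpha(topo)
                 else seq_len(length(ref_xyz) / 3)
  }
  if (length(selection) < 3) stop("need at least 3 atoms for superposition")
  inds <- bio3d::atom2xyz(selection)
  as.numeric(bio3d::rmsd(a = ref_xyz, b = xyz, a.inds = inds, b.inds = inds,
                         fit = TRUE))
}

#' Solvent-accessible surface area by dot-surface quadrature
#'
#' Shrake-Rupley style: each atom's sphere of radius (r_vdw + probe) is
#' covered with a deterministic Fibonacci lattice of `dot_density` points;
#' a point is accessible when it lies outside every other atom's accessible
#' sphere. Each surviving point carries area 4 pi (r + probe)^2 / dot_density.
#'
#' @param x a `Structure`, or an n_atoms x 3 coordinate matrix paired with
#'   `structure` for radii.
#' @param probe probe radius in nm (default 0.14, water).
#' @param dot_density points per atom (default 960; < 32 is refused as
#'   unreliable quadrature).
#' @param structure topology providing radii when `x` is a bare matrix.
#' @param atom_subset optional indices: areas computed only for these atoms
#'   (all atoms still occlude).
#' @return list with `total` (nm^2) and `per_atom` (numeric vector, nm^2;
#'   zero for atoms outside `atom_subset`).
#' @export
sasa <- function(x, probe = 0.14, dot_density = 960, structure = NULL,
                 atom_subset = NULL) {
  if (dot_density < 32) stop("dot_density < 32: unreliable quadrature")
  if (probe < 0) stop("probe radius must be >= 0")
  if (inherits(x, "Structure")) {
    structure <- x
    coords <- as.matrix(x$atoms[, c("x", "y", "z")])
  } else {
    if (is.null(structure)) stop("a Structure is required for radii")
    coords <- as.matrix(x)
  }
  radii <- structure$atoms$radius
  if (is.null(radii) || anyNA(radii)) stop("all atoms need van der Waals radii")
  n <- nrow(coords)
  if (is.null(atom_subset)) atom_subset <- seq_len(n)
  # degenerate duplicate records (same position and radius) are one atom:
  # only the first contributes area or occludes
  dupkey <- paste(coords[, 1], coords[, 2], coords[, 3], radii)
  dup <- duplicated(dupkey)
  live <- which(!dup)
  atom_subset <- setdiff(atom_subset, which(dup))
  dots <- fibonacci_sphere(dot_density)
  racc <- radii + probe
  per_atom <- numeric(n)
  maxr <- max(racc)
  for (i in atom_subset) {
    ri <- racc[i]
    d2 <- colSums((t(coords[live, , drop = FALSE]) - coords[i, ])^2)
    nb <- live[d2 < (ri + maxr)^2 & live != i]
    nb <- nb[sqrt(colSums((t(coords[nb, , drop = FALSE]) - coords[i, ])^2)) <
               ri + racc[nb]]
    pts <- sweep(dots * ri, 2, coords[i, ], "+")
    if (length(nb)) {
      ok <- rep(TRUE, dot_density)
      for (j in nb) {
        dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
          (pts[, 3] - coords[j, 3])^2
        ok <- ok & dj2 > racc[j]^2
        if (!any(ok)) break
      }
      nsurv <- sum(ok)
    } else nsurv <- dot_density
    per_atom[i] <- 4 * pi * ri^2 * nsurv / dot_density
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the trajectory mean structure (two passes of
#' iterative superposition) over the selection; RMSF is the root mean square
#' displacement of each selected atom about its mean position, reported per
#' residue.
#'
#' @param trajectory a `Trajectory` with >= 2 frames.
#' @param selection atom indices (default C-alpha).
#' @return data.frame with `residue_index`, `resno`, `rmsf_nm`.
#' @export
rmsf_series <- function(trajectory, selection = NULL) {
  if (n_frames(trajectory) < 2) stop("RMSF needs at least 2 frames")
  topo <- trajectory$topology
  if (is.null(selection)) selection <- select_calpha(topo)
  inds <- bio3d::atom2xyz(selection)
  xyz <- trajectory$xyz
  ref <- xyz[1, ]
  for (pass in 1:2) {
    fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                             fixed.inds = inds, mobile.inds = inds)
    ref <- colMeans(fitted)
    xyz <- fitted
  }
  mu <- colMeans(xyz)
  rmsf_atom <- vapply(selection, function(a) {
    k <- 3 * a - 2
    sqrt(mean((xyz[, k] - mu[k])^2 + (xyz[, k + 1] - mu[k + 1])^2 +
                (xyz[, k + 2] - mu[k + 2])^2))
  }, numeric(1))
  data.frame(residue_index = topo$atoms$residue_index[selection],
             resno = topo$atoms$resno[selection],
             rmsf_nm = rmsf_atom)
}

#' Full order-parameter series for a trajectory
#'
#' Convenience wrapper computing RMSD, rho, Q and (optionally) SASA for
#' every frame against a native reference.
#'
#' @param trajectory a `Trajectory`.
#' @param native reference `Structure`.
#' @param with_sasa compute per-frame total SASA (slow for large systems).
#' @param cutoff,min_sep contact definition passed to [native_contacts()].
#' @param probe,dot_density passed to [sasa()].
#' @return data.frame with columns `frame`, `time_ps`, `rmsd_nm`, `rho`,
#'   `q`, and `sasa_nm2` when requested.
#' @export
order_parameter_series <- function(trajectory, native, with_sasa = FALSE,
                                   cutoff = 0.55, min_sep = 3,
                                   probe = 0.14, dot_density = 960) {
  nc_sc <- native_contacts(native, "sidechain", cutoff, min_sep)
  nc_hv <- native_contacts(native, "heavy", cutoff, min_sep)
  out <- data.frame(
    frame = seq_len(n_frames(trajectory)),
    time_ps = (seq_len(n_frames(trajectory)) - 1) * trajectory$frame_interval_ps,
    rmsd_nm = rmsd_series(trajectory, native),
    rho = rho(trajectory, nc_sc),
    q = q_fraction(trajectory, nc_hv))
  if (with_sasa) {
    out$sasa_nm2 <- vapply(seq_len(n_frames(trajectory)), function(f) {
      sasa(frame_coords(trajectory, f), probe, dot_density,
           structure = trajectory$topology)$total
    }, numeric(1))
  }
  out
}

#' Write an order-parameter series as TSV
#' @param series data.frame from [order_parameter_series()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_series_tsv <- function(series, file) {
  utils::write.table(series, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
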