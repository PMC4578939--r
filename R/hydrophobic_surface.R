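# Contiguous exposed hydrophobic surface patches on a dot surface.
#
# Dots are generated on nonpolar atoms at radius (r_vdw + probe); a dot
# survives when it lies outside every other atom's accessible sphere, with
# polar atoms' spheres additionally inflated by the polar expansion radius
# (default 0.14 nm) so that nonpolar surface adjacent to polar atoms is
# masked. Exposed nonpolar atoms are grouped into patches by
# accessible-sphere overlap; patches are ranked by area, the top five kept,
# and only patches of at least 300 A^2 considered significant.

#' Dot surface restricted to nonpolar atoms, with polar expansion
#'
#' @param structure a `Structure` with radii and polarity assigned.
#' @param probe probe radius (nm, default 0.14).
#' @param polar_expansion extra occlusion radius added to polar atoms (nm,
#'   default 0.14).
#' @param dot_density dots per atom (default 960).
#' @return list with `atom_index` (nonpolar atoms), `area_nm2` (surviving
#'   dot area per nonpolar atom), `n_dots_surviving`, and the parameters.
#' @export
hydrophobic_dot_surface <- function(structure, probe = 0.14,
                                    polar_expansion = 0.14,
                                    dot_density = 960) {
  if (dot_density < 32) stop("dot_density < 32: unreliable quadrature")
  at <- structure$atoms
  if (is.null(at$radius) || anyNA(at$radius)) {
    bad <- which(is.na(at$radius))[1]
    stop("atom ", if (length(bad)) bad else "?", " lacks a van der Waals radius")
  }
  if (is.null(at$polarity)) stop("polarity classes not assigned")
  coords <- as.matrix(at[, c("x", "y", "z")])
  racc <- at$radius + probe
  rocc <- racc + ifelse(at$polarity == "polar", polar_expansion, 0)
  dupkey <- paste(coords[, 1], coords[, 2], coords[, 3], at$radius)
  dup <- duplicated(dupkey)
  live <- which(!dup)
  nonpolar <- which(at$polarity == "nonpolar" & !at$is_solvent & !dup)
  dots <- fibonacci_sphere(dot_density)
  n <- nrow(coords)
  maxocc <- max(rocc)
  area <- nsurv <- numeric(length(nonpolar))
  for (k in seq_along(nonpolar)) {
    i <- nonpolar[k]
    ri <- racc[i]
    d2 <- colSums((t(coords[live, , drop = FALSE]) - coords[i, ])^2)
    nb <- live[d2 < (ri + maxocc)^2 & live != i]
    nb <- nb[sqrt(colSums((t(coords[nb, , drop = FALSE]) - coords[i, ])^2)) <
               ri + rocc[nb]]
    pts <- sweep(dots * ri, 2, coords[i, ], "+")
    ok <- rep(TRUE, dot_density)
    for (j in nb) {
      dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      ok <- ok & dj2 > rocc[j]^2
      if (!any(ok)) break
    }
    nsurv[k] <- sum(ok)
    area[k] <- 4 * pi * ri^2 * nsurv[k] / dot_density
  }
  list(atom_index = nonpolar, area_nm2 = area, n_dots_surviving = nsurv,
       probe = probe, polar_expansion = polar_expansion,
       dot_density = dot_density)
}

#' Find contiguous hydrophobic surface patches
#'
#' Nonpolar atoms with at least one surviving dot are graph nodes; two
#' atoms are adjacent when their accessible spheres overlap (center
#' distance < r_i + r_j + 2 probe). Patches are the connected components;
#' a patch's area is the sum of its members' surviving dot areas, reported
#' in A^2 with per-residue contributions.
#'
#' @param structure a `Structure`.
#' @param probe,polar_expansion,dot_density as [hydrophobic_dot_surface()].
#' @param surface optionally a precomputed [hydrophobic_dot_surface()]
#'   result.
#' @param significance_threshold area threshold in A^2 (default 300).
#' @param top_k patches kept before thresholding (default 5).
#' @return object of class `PatchSet`: list with `patches` (list of lists:
#'   `atoms`, `residues`, `area_A2`, `residue_area` named vector),
#'   `areas_A2` (descending), plus the parameters.
#' @export
find_patches <- function(structure, probe = 0.14, polar_expansion = 0.14,
                         dot_density = 960, surface = NULL,
                         significance_threshold = 300, top_k = 5) {
  if (is.null(surface)) {
    surface <- hydrophobic_dot_surface(structure, probe, polar_expansion,
                                       dot_density)
  }
  exposed <- surface$atom_index[surface$area_nm2 > 0]
  area_by_atom <- stats::setNames(surface$area_nm2[surface$area_nm2 > 0] * 100,
                                  exposed)   # A^2
  patches <- list()
  if (length(exposed)) {
    at <- structure$atoms
    coords <- as.matrix(at[exposed, c("x", "y", "z")])
    reach <- outer(at$radius[exposed], at$radius[exposed], "+") + 2 * surface$probe
    d <- sqrt(dist2_cross(coords, coords))
    adj <- d < reach
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cc in sort(unique(comp))) {
      members <- exposed[comp == cc]
      a <- area_by_atom[as.character(members)]
      res <- at$residue_index[members]
      ra <- tapply(a, res, sum)
      patches[[length(patches) + 1]] <- list(
        atoms = members,
        residues = sort(unique(res)),
        area_A2 = sum(a),
        residue_area = stats::setNames(as.numeric(ra), names(ra)))
    }
    patches <- patches[order(-vapply(patches, `[[`, numeric(1), "area_A2"))]
  }
  structure(list(patches = patches,
                 areas_A2 = vapply(patches, `[[`, numeric(1), "area_A2"),
                 significance_threshold = significance_threshold,
                 top_k = top_k, probe = surface$probe,
                 polar_expansion = surface$polar_expansion,
                 dot_density = surface$dot_density,
                 significant = FALSE),
            class = "PatchSet")
}

#' @export
print.PatchSet <- function(x, ...) {
  cat(sprintf("PatchSet: %d patch(es)%s\n", length(x$patches),
              if (x$significant) " (significant subset)" else ""))
  if (length(x$areas_A2)) {
    cat("  areas (A^2):", paste(sprintf("%.1f", x$areas_A2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Significant patches: top-k by area, then area threshold
#'
#' The top five patches are taken first and then filtered to those of at
#' least the significance threshold (300 A^2), in that order.
#'
#' @param patch_set a `PatchSet`.
#' @return a `PatchSet` containing only the significant patches.
#' @export
significant_patches <- function(patch_set) {
  keep <- utils::head(seq_along(patch_set$patches), patch_set$top_k)
  keep <- keep[patch_set$areas_A2[keep] >= patch_set$significance_threshold]
  patch_set$patches <- patch_set$patches[keep]
  patch_set$areas_A2 <- patch_set$areas_A2[keep]
  patch_set$significant <- TRUE
  patch_set
}

#' Total surface hydrophobicity: summed significant patch area
#'
#' @param patch_set a `PatchSet`; significance is applied first when it has
#'   not been already.
#' @return total area in A^2.
#' @export
total_surface_hydrophobicity <- function(patch_set) {
  if (!isTRUE(patch_set$significant)) patch_set <- significant_patches(patch_set)
  sum(patch_set$areas_A2)
}

#' Distinct Ile/Val/Leu residues exposed in significant patches
#'
#' @param patch_set a `PatchSet`.
#' @param structure the `Structure` the patches were computed on.
#' @return integer count of distinct IVL residues contributing positive
#'   area to any significant patch.
#' @export
exposed_ivl_count <- function(patch_set, structure) {
  if (!isTRUE(patch_set$significant)) patch_set <- significant_patches(patch_set)
  res <- unique(unlist(lapply(patch_set$patches, function(p) {
    as.integer(names(p$residue_area)[p$residue_area > 0])
  })))
  sum(structure$residues$resname[match(res, structure$residues$residue_index)]
      %in% c("ILE", "VAL", "LEU"))
}

#' Exposed Hydrophobic Surface Contribution (EHSC) per transition event
#'
#' Attributes every residue's area contribution to significant patches to
#' that residue's transition-event class and reports the class fractions.
#'
#' @param patch_set a `PatchSet`.
#' @param events a `TransitionEventTable` covering all contributing
#'   residues (column `residue` in internal indices).
#' @return object of class `PatchAttribution`: named numeric vector of
#'   fractions over the five event classes, summing to 1.
#' @export
ehsc <- function(patch_set, events) {
  if (!isTRUE(patch_set$significant)) patch_set <- significant_patches(patch_set)
  contrib <- stats::setNames(numeric(length(TRANSITION_EVENTS)), TRANSITION_EVENTS)
  total <- 0
  for (p in patch_set$patches) {
    for (r in names(p$residue_area)) {
      a <- p$residue_area[[r]]
      row <- match(as.integer(r), events$residue)
      if (is.na(row)) stop("event table does not cover residue ", r)
      cls <- as.character(events$event[row])
      contrib[cls] <- contrib[cls] + a
      total <- total + a
    }
  }
  if (total == 0) stop("zero total significant patch area")
  structure(contrib / total, class = "PatchAttribution")
}

#' Mean accessible area per residue over motif residue sets
#'
#' Total solvent-accessible surface area of all motif residues divided by
#' the total motif residue count, in A^2 per residue. Motif locations are
#' an explicit input, never inferred from sequence.
#'
#' @param structure a `Structure`.
#' @param motifs list of integer vectors (internal residue indices), or a
#'   data.frame with columns `motif_id` and `residue_index`.
#' @param probe,dot_density as [sasa()].
#' @return mean area per residue (A^2).
#' @export
motif_exposure <- function(structure, motifs, probe = 0.14, dot_density = 960) {
  if (is.data.frame(motifs)) motifs <- split(motifs$residue_index, motifs$motif_id)
  residues <- unlist(motifs)
  if (!length(residues)) stop("empty motif residue set")
  atoms <- which(structure$atoms$residue_index %in% residues &
                   !structure$atoms$is_solvent)
  s <- sasa(structure, probe = probe, dot_density = dot_density,
            atom_subset = atoms)
  sum(s$per_atom) * 100 / length(residues)
}

#' Write a patch report as TSV
#'
#' One row per patch (patch_id, area_A2, n_atoms, residues); a second file
#' with per-residue contributions when `residue_file` is given.
#'
#' @param patch_set a `PatchSet`.
#' @param structure the source `Structure` (for author residue numbers).
#' @param file output TSV path.
#' @param residue_file optional per-residue contribution TSV path.
#' @return `file`, invisibly.
#' @export
write_patch_report <- function(patch_set, structure, file, residue_file = NULL) {
  rows <- lapply(seq_along(patch_set$patches), function(k) {
    p <- patch_set$patches[[k]]
    resno <- structure$residues$resno[match(p$residues, structure$residues$residue_index)]
    data.frame(patch_id = k, area_A2 = p$area_A2, n_atoms = length(p$atoms),
               residues = paste(resno, collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(residue_file)) {
    rr <- lapply(seq_along(patch_set$patches), function(k) {
      p <- patch_set$patches[[k]]
      idx <- as.integer(names(p$residue_area))
      data.frame(patch_id = k,
                 resno = structure$residues$resno[match(idx, structure$residues$residue_index)],
                 area_A2 = as.numeric(p$residue_area))
    })
    utils::write.table(do.call(rbind, rr), residue_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
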