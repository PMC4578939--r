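# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (exhaustive enumeration, fine grids, closed forms) and share no
# code with the implementation paths they check.

# Minimal hand-built structure from a coordinate table.
mini_structure <- function(df) {
  defaults <- list(resname = "ALA", chain = "A")
  for (k in names(defaults)) if (is.null(df[[k]])) df[[k]] <- defaults[[k]]
  new_structure(df)
}

# A hand-written PDB file with two atoms in one residue.
write_two_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), path)
  path
}

# Brute-force residue contact oracle: all residue pairs, all scoped atom
# pairs, plain double loop.
brute_contacts <- function(structure, atom_names_keep, cutoff, min_sep) {
  at <- structure$atoms
  keep <- which(at$name %in% atom_names_keep)
  res <- sort(unique(at$residue_index))
  out <- NULL
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b - a < min_sep) next
      ia <- keep[at$residue_index[keep] == res[a]]
      ib <- keep[at$residue_index[keep] == res[b]]
      if (!length(ia) || !length(ib)) next
      dmin <- Inf
      for (i in ia) for (j in ib) {
        d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                    (at$z[i] - at$z[j])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff) out <- rbind(out, c(res[a], res[b]))
    }
  }
  out
}

# Coarse rotation-grid RMSD oracle: minimum RMSD over an Euler-angle grid
# (after centroid alignment). Approximate from above within the grid step.
grid_rmsd <- function(a, b, step_deg = 6) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  best <- Inf
  angs <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  betas <- seq(0, 180, by = step_deg) * pi / 180
  for (al in angs) for (be in betas) for (ga in angs) {
    Rz1 <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3)
    Rz2 <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3)
    rb <- b %*% (Rz1 %*% Ry %*% Rz2)
    best <- min(best, sqrt(mean(rowSums((a - rb)^2))))
  }
  best
}

# Exact accessible area of sphere i among two overlapping spheres with
# equal probe: closed-form spherical cap removal.
two_sphere_area <- function(r1, r2, d) {
  # accessible radii already include the probe
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  if (d + r1 <= r2) return(c(0, 4 * pi * r2^2))
  if (d + r2 <= r1) return(c(4 * pi * r1^2, 0))
  # cap height on sphere 1 buried inside sphere 2
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1, 4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Exhaustive minimax-barrier oracle: depth-first enumeration of all simple
# 8-connected paths through occupied cells.
brute_barrier <- function(delta_a, a, b) {
  nr <- nrow(delta_a); nc <- ncol(delta_a)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(cell, path_max) {
    if (path_max >= best) return()
    if (all(cell == b)) { best <<- min(best, path_max); return() }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- cell[1] + dr; cc <- cell[2] + dc
      if (r < 1 || r > nr || cc < 1 || cc > nc) next
      if (visited[r, cc] || !is.finite(delta_a[r, cc])) next
      visited[r, cc] <<- TRUE
      dfs(c(r, cc), max(path_max, delta_a[r, cc]))
      visited[r, cc] <<- FALSE
    }
  }
  visited[a[1], a[2]] <- TRUE
  dfs(a, delta_a[a[1], a[2]])
  best - delta_a[a[1], a[2]]
}

# Craft a FreeEnergyMap directly from a delta_a matrix (for barrier tests).
fake_map <- function(delta_a, temperature = 400) {
  counts <- matrix(0L, nrow(delta_a), ncol(delta_a))
  occ <- is.finite(delta_a)
  counts[occ] <- as.integer(round(1e6 * exp(-delta_a[occ] /
                                              (GAS_CONSTANT_KJ * temperature))))
  structure(list(counts = counts, probability = counts / sum(counts),
                 delta_a = delta_a,
                 axis_x = list(name = "x", breaks = seq(0, 1, length.out = nrow(delta_a) + 1)),
                 axis_y = list(name = "y", breaks = seq(0, 1, length.out = ncol(delta_a) + 1)),
                 temperature = temperature,
                 reference_cell = as.integer(which(delta_a == 0, arr.ind = TRUE)[1, ])),
            class = "FreeEnergyMap")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Short peptide surrounded by randomly placed water oxygens.
water_box_fixture <- function(n_waters = 50, seed = 42, n_res = 3) {
  pep <- make_extended_coil(n_res)$atoms
  set.seed(seed)
  span <- max(pep$x) - min(pep$x)
  wat <- data.frame(
    name = "OW", element = "O", resno = 100 + seq_len(n_waters),
    resname = "SOL", chain = "W",
    x = stats::runif(n_waters, min(pep$x) - 0.6, max(pep$x) + 0.6),
    y = stats::runif(n_waters, -0.8, 0.8),
    z = stats::runif(n_waters, -0.8, 0.8), stringsAsFactors = FALSE)
  cols <- c("name", "element", "resno", "resname", "chain", "x", "y", "z")
  new_structure(rbind(pep[, cols], wat[, cols]))
}

# Independent hydrogen-bond enumeration oracle: plain nested loop over
# protein N/O vs water O at the distance criterion (no hydrogens present).
brute_protein_solvent_hbonds <- function(structure, cutoff = 0.35,
                                         residues = NULL) {
  at <- structure$atoms
  prot <- which(!at$is_solvent & at$element %in% c("N", "O"))
  if (!is.null(residues)) prot <- prot[at$residue_index[prot] %in% residues]
  wat <- which(at$is_solvent & at$element %in% c("N", "O"))
  cnt <- 0L
  for (i in prot) for (j in wat) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# Rigid rotation + translation applied to a Structure.
rigid_move <- function(structure, angles = c(0.3, 1.1, -0.7), shift = c(1, -2, 3)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  al <- angles[1]; be <- angles[2]; ga <- angles[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(al), sin(al), 0, -sin(al), cos(al)), 3)
  Ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3)
  Rz <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3)
  xyz <- sweep(xyz %*% (Rx %*% Ry %*% Rz), 2, shift, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
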