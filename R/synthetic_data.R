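# Synthetic structures and ensembles with planted, analytically known
# properties. These generators stand in for MD trajectories so that every
# pipeline stage has a testable ground truth. All generators are pure
# functions of their arguments (fixed seed -> identical output), and the
# numerical oracles here share no code with the algorithms they validate.

# Backbone internal coordinates (Angstrom / degrees, Engh-Huber-like)
BB_N_CA <- 0.1458
BB_CA_C <- 0.1525
BB_C_N  <- 0.1329
BB_C_O  <- 0.1231
BB_CA_CB <- 0.1530
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

#' Build a poly-alanine backbone from phi/psi angles
#'
#' Natural-extension chain building with standard bond geometry; atoms
#' N, CA, C, O, CB per residue, omega fixed at 180 degrees.
#'
#' @param phi,psi numeric vectors of torsions in degrees (length n; phi\[1\]
#'   and psi\[n\] only orient terminal atoms).
#' @param chain chain identifier.
#' @param resno_start first author residue number.
#' @return data.frame of atoms (columns as required by [new_structure()]).
#' @keywords internal
build_backbone <- function(phi, psi, chain = "A", resno_start = 1) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_N_CA, 0, 0)
  th <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BB_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB_C_N, ANG_CA_C_N, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BB_N_CA, ANG_C_N_CA, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BB_CA_C,
                             ANG_N_CA_C, phi[i + 1])
  }
  for (i in seq_len(n)) {
    # carbonyl O anti to the next amide N (torsion psi + 180 about CA-C)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB_C_O, ANG_CA_C_O,
                         (if (i < n) psi[i] else psi[n]) + 180)
    CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ], BB_CA_CB, 110.1, 122.6)
  }
  res <- rep(seq_len(n) + resno_start - 1, each = 5)
  data.frame(
    name = rep(c("N", "CA", "C", "O", "CB"), n),
    element = rep(c("N", "C", "C", "O", "C"), n),
    resno = res, resname = "ALA", chain = chain,
    x = c(rbind(N[, 1], CA[, 1], C[, 1], O[, 1], CB[, 1])),
    y = c(rbind(N[, 2], CA[, 2], C[, 2], O[, 2], CB[, 2])),
    z = c(rbind(N[, 3], CA[, 3], C[, 3], O[, 3], CB[, 3])),
    stringsAsFactors = FALSE)
}

#' Ideal alpha helix
#'
#' Poly-alanine backbone at phi = -57, psi = -47 degrees.
#'
#' @param n_residues number of residues (>= 4).
#' @param chain chain id.
#' @return a `Structure`.
#' @export
make_ideal_helix <- function(n_residues, chain = "A") {
  stopifnot(n_residues >= 4)
  new_structure(build_backbone(rep(-57, n_residues), rep(-47, n_residues),
                               chain = chain))
}

#' Extended (coil) chain
#'
#' A single extended chain (phi = -120, psi = 130) has no hydrogen-bond
#' partner and is assigned coil throughout.
#'
#' @inheritParams make_ideal_helix
#' @return a `Structure`.
#' @export
make_extended_coil <- function(n_residues, chain = "A") {
  stopifnot(n_residues >= 2)
  new_structure(build_backbone(rep(-120, n_residues), rep(130, n_residues),
                               chain = chain))
}

# Rotate/translate a built strand into a canonical frame: strand axis on x,
# carbonyl (hydrogen-bonding) direction on y, centered on the CA centroid.
#' @keywords internal
canonical_strand <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- xyz[atoms$name == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  xyz <- sweep(xyz, 2, ctr)
  u <- ca[nrow(ca), ] - ca[1, ]
  u <- u / sqrt(sum(u^2))
  co <- xyz[atoms$name == "O", , drop = FALSE] - xyz[atoms$name == "C", , drop = FALSE]
  sgn <- rep_len(c(1, -1), nrow(co))            # carbonyls alternate sides
  v0 <- colSums(co * sgn)
  v0 <- v0 - sum(v0 * u) * u
  v <- v0 / sqrt(sum(v0^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  out <- xyz %*% cbind(u, v, w)
  atoms$x <- out[, 1]; atoms$y <- out[, 2]; atoms$z <- out[, 3]
  atoms
}

#' Ideal antiparallel two-strand beta template
#'
#' One chain whose first half runs as a beta strand and whose second half
#' runs antiparallel beside it, hydrogen-bonded in antiparallel register.
#' The two halves are not peptide-bonded (the connection is an explicit
#' chain break), so interior residues of both halves are assigned strand.
#' The partner strand is the first strand rotated 180 degrees about the
#' sheet normal; its register is fixed by a deterministic grid search that
#' places cross-strand amide N / carbonyl O pairs at hydrogen-bond distance
#' (0.29 nm), a purely geometric criterion.
#'
#' @param n_residues total residues (>= 8; split as evenly as possible).
#' @param chain chain id.
#' @return a `Structure`.
#' @export
make_sheet_pair <- function(n_residues, chain = "A") {
  stopifnot(n_residues >= 8)
  n1 <- ceiling(n_residues / 2)
  n2 <- n_residues - n1
  phi <- -139; psi <- 135
  s1 <- canonical_strand(build_backbone(rep(phi, n1), rep(psi, n1), chain = chain))
  s2 <- canonical_strand(build_backbone(rep(phi, n2), rep(psi, n2), chain = chain,
                                        resno_start = n1 + 1))
  # antiparallel partner: 2-fold rotation about the sheet normal (z)
  s2$x <- -s2$x
  s2$y <- -s2$y
  # amide H positions (bisector reconstruction) for directional scoring
  amide_h <- function(s) {
    nres <- max(s$resno) - min(s$resno) + 1
    N <- as.matrix(s[s$name == "N", c("x", "y", "z")])
    CA <- as.matrix(s[s$name == "CA", c("x", "y", "z")])
    C <- as.matrix(s[s$name == "C", c("x", "y", "z")])
    H <- matrix(NA_real_, nres, 3)
    for (k in 2:nres) {
      u1 <- N[k, ] - C[k - 1, ]; u2 <- N[k, ] - CA[k, ]
      u <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
      H[k, ] <- N[k, ] + 0.1 * u / sqrt(sum(u^2))
    }
    list(N = N, H = H, O = as.matrix(s[s$name == "O", c("x", "y", "z")]),
         all = as.matrix(s[, c("x", "y", "z")]))
  }
  g1 <- amide_h(s1)
  g2 <- amide_h(s2)
  hbond_score <- function(don, acc) {   # don: N/H donor strand; acc: O acceptor strand
    sc <- 0
    for (k in seq_len(nrow(don$H))) {
      if (is.na(don$H[k, 1])) next
      d <- sqrt(colSums((t(acc$O) - don$H[k, ])^2))
      j <- which.min(d)
      if (d[j] > 0.16 && d[j] < 0.24) {
        ang <- vertex_angle(don$N[k, ], don$H[k, ], acc$O[j, ])
        if (ang > 140) sc <- sc + 1 - abs(d[j] - 0.19)
      }
    }
    sc
  }
  best <- NULL
  for (dx in seq(-0.5, 0.5, by = 0.02)) {
    for (dy in seq(0.38, 0.60, by = 0.01)) {
      t2 <- c(dx, dy, 0)
      g2t <- list(N = sweep(g2$N, 2, t2, "+"), H = sweep(g2$H, 2, t2, "+"),
                  O = sweep(g2$O, 2, t2, "+"), all = sweep(g2$all, 2, t2, "+"))
      if (min(dist2_cross(g1$all, g2t$all)) < 0.055^2) next  # clash guard
      score <- hbond_score(g1, g2t) + hbond_score(g2t, g1)
      if (is.null(best) || score > best$score) best <- list(score = score, t = t2)
    }
  }
  s2$x <- s2$x + best$t[1]
  s2$y <- s2$y + best$t[2]
  new_structure(rbind(s1, s2))
}

#' Translate all atoms of a structure
#' @param structure a `Structure`.
#' @param offset numeric 3-vector (nm).
#' @return the shifted `Structure`.
#' @export
translate_structure <- function(structure, offset) {
  structure$atoms$x <- structure$atoms$x + offset[1]
  structure$atoms$y <- structure$atoms$y + offset[2]
  structure$atoms$z <- structure$atoms$z + offset[3]
  structure
}

#' Combine structures into one multi-chain structure
#' @param ... `Structure` objects (chains should be distinct).
#' @return a `Structure`.
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  cols <- c("name", "element", "resno", "resname", "chain", "x", "y", "z")
  new_structure(do.call(rbind, lapply(parts, function(s) s$atoms[, cols])))
}

#' Two-state conformational hopping trajectory
#'
#' Frames are drawn i.i.d. from two reference conformers with prescribed
#' state populations, plus isotropic Gaussian coordinate noise. The default
#' conditions are the landscape-recovery study conditions: populations
#' 0.8 / 0.2 at 400 K with 50,000 frames.
#'
#' @param conformer_a,conformer_b `Structure`s with identical atom counts;
#'   defaults: a compact 16-residue antiparallel strand pair (folded, with
#'   cross-strand side-chain contacts) and the same residues extended
#'   (unfolded).
#' @param populations numeric c(p_a, p_b), summing to 1.
#' @param n_frames number of frames.
#' @param noise_sigma Gaussian coordinate noise s.d. (nm) per coordinate.
#' @param temperature trajectory temperature (K).
#' @param seed integer RNG seed.
#' @return list with `trajectory` (a `Trajectory`), `states` (integer vector
#'   1/2 per frame), `conformer_a`, `conformer_b`.
#' @export
make_two_state_trajectory <- function(conformer_a = NULL, conformer_b = NULL,
                                      populations = c(0.8, 0.2),
                                      n_frames = 50000, noise_sigma = 0.02,
                                      temperature = 400, seed = 1) {
  stopifnot(abs(sum(populations) - 1) < 1e-9, all(populations > 0))
  if (is.null(conformer_a)) conformer_a <- make_sheet_pair(16)
  if (is.null(conformer_b)) conformer_b <- make_extended_coil(16)
  xa <- c(t(as.matrix(conformer_a$atoms[, c("x", "y", "z")])))
  xb <- c(t(as.matrix(conformer_b$atoms[, c("x", "y", "z")])))
  if (length(xa) != length(xb)) stop("conformers must have equal atom counts")
  set.seed(seed)
  states <- 1L + (stats::runif(n_frames) < populations[2])
  base <- rbind(xa, xb)[states, , drop = FALSE]
  xyz <- base + matrix(stats::rnorm(length(base), sd = noise_sigma),
                       nrow = n_frames)
  list(trajectory = new_trajectory(conformer_a, xyz, temperature = temperature,
                                   label = "two-state"),
       states = states, conformer_a = conformer_a, conformer_b = conformer_b)
}

#' Surface phantom with analytically planted hydrophobic patches
#'
#' Builds a structure from an explicit atom layout (positions, radii,
#' polarity, planted patch group) and computes, by an independent fine-grid
#' numerical occlusion oracle, the exposed hydrophobic area of every planted
#' group. The default layout is a planar grid of nonpolar atoms split into
#' two patches by a polar stripe.
#'
#' @param layout data.frame with columns `x`, `y`, `z` (nm), `radius` (nm),
#'   `polarity` ("polar"/"nonpolar"), `group` (planted patch id, NA for
#'   polar atoms). `NULL` for the default planar phantom.
#' @param probe probe radius (nm).
#' @param polar_expansion extra occlusion radius for polar atoms (nm).
#' @param oracle_grid angular subdivisions for the oracle quadrature.
#' @return list with `structure` (a `Structure`), `layout`, and `oracle`
#'   (data.frame: `group`, `area_A2` from the numerical oracle).
#' @export
make_patch_phantom <- function(layout = NULL, probe = 0.14,
                               polar_expansion = 0.14, oracle_grid = 180) {
  if (is.null(layout)) layout <- planar_phantom_layout()
  n <- nrow(layout)
  atoms <- data.frame(
    name = ifelse(layout$polarity == "nonpolar", "C1", "O1"),
    element = ifelse(layout$polarity == "nonpolar", "C", "O"),
    resno = seq_len(n), resname = "UNK", chain = "A",
    x = layout$x, y = layout$y, z = layout$z,
    radius = layout$radius, polarity = layout$polarity,
    stringsAsFactors = FALSE)
  st <- new_structure(atoms)
  st$atoms$radius <- layout$radius      # layout radii override the table
  groups <- sort(unique(stats::na.omit(layout$group)))
  oracle <- data.frame(group = groups, area_A2 = vapply(groups, function(g) {
    sum(vapply(which(!is.na(layout$group) & layout$group == g), function(i) {
      oracle_exposed_area(i, layout, probe, polar_expansion, oracle_grid)
    }, numeric(1)))
  }, numeric(1)))
  list(structure = st, layout = layout, oracle = oracle)
}

# Default planar phantom: nonpolar grid (0.32 nm spacing) split by a polar
# stripe; skip-one-column atoms are farther apart than the sphere-overlap
# adjacency reach, so the stripe partitions the surface into two patches.
#' @keywords internal
planar_phantom_layout <- function(n_cols = 7, n_rows = 4, spacing = 0.32,
                                  stripe_col = 4) {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  polar <- g$col == stripe_col
  data.frame(
    x = (g$col - 1) * spacing, y = (g$row - 1) * spacing, z = 0,
    radius = ifelse(polar, 0.152, 0.170),
    polarity = ifelse(polar, "polar", "nonpolar"),
    group = ifelse(polar, NA, ifelse(g$col < stripe_col, 1, 2)))
}

# Independent oracle: exposed accessible area of one nonpolar atom by
# latitude-longitude quadrature with occlusion (polar occluders inflated by
# the expansion radius). Deliberately distinct quadrature and code path
# from the package's Fibonacci dot surface.
#' @keywords internal
oracle_exposed_area <- function(i, layout, probe, polar_expansion, grid) {
  ri <- layout$radius[i] + probe
  ci <- c(layout$x[i], layout$y[i], layout$z[i])
  theta <- (seq_len(grid) - 0.5) * pi / grid
  phi <- (seq_len(2 * grid) - 0.5) * 2 * pi / (2 * grid)
  # quadrature weights: dA = r^2 sin(theta) dtheta dphi
  w <- ri^2 * sin(theta) * (pi / grid) * (2 * pi / (2 * grid))
  others <- setdiff(seq_len(nrow(layout)), i)
  rocc <- layout$radius[others] + probe +
    ifelse(layout$polarity[others] == "polar", polar_expansion, 0)
  occ_c <- cbind(layout$x[others], layout$y[others], layout$z[others])
  area <- 0
  for (t in seq_along(theta)) {
    st <- sin(theta[t]); ct <- cos(theta[t])
    pts <- cbind(ci[1] + ri * st * cos(phi),
                 ci[2] + ri * st * sin(phi),
                 ci[3] + ri * ct)
    free <- rep(TRUE, length(phi))
    for (k in seq_along(others)) {
      d2 <- (pts[, 1] - occ_c[k, 1])^2 + (pts[, 2] - occ_c[k, 2])^2 +
        (pts[, 3] - occ_c[k, 3])^2
      free <- free & d2 > rocc[k]^2
    }
    area <- area + sum(free) * w[t]
  }
  area * 100   # nm^2 -> A^2
}

#' Unfolding ensemble with planted secondary-structure transition events
#'
#' Each planted segment is generated as its own spatially isolated chain.
#' Its native conformation and its remodeled intermediate conformation are
#' chosen by the planted event class (helix / strand-pair / coil templates);
#' intermediate frames carry small Gaussian coordinate noise. Returns the
#' native structure, the intermediate-ensemble trajectory and the planted
#' truth table.
#'
#' @param events character vector of planted events, one per segment, from
#'   \{"alpha_to_coil", "beta_to_coil", "coil_to_beta", "alpha_to_beta",
#'   "unchanged"\}.
#' @param n_residues residues per segment (default 12; >= 8).
#' @param n_frames intermediate frames (default 20).
#' @param noise_sigma coordinate noise s.d. (nm) in intermediate frames.
#' @param seed integer RNG seed.
#' @return list with `native` (a `Structure`), `trajectory` (a `Trajectory`
#'   of the intermediate ensemble), `truth` (data.frame: `segment`, `chain`,
#'   `event`, `first_residue`, `last_residue` internal indices).
#' @export
make_unfolding_ensemble <- function(events, n_residues = 12, n_frames = 20,
                                    noise_sigma = 0.002, seed = 1) {
  stopifnot(all(events %in% TRANSITION_EVENTS), n_residues >= 8)
  template <- function(kind, chain) {
    switch(kind,
           H = make_ideal_helix(n_residues, chain),
           E = make_sheet_pair(n_residues, chain),
           C = make_extended_coil(n_residues, chain))
  }
  native_kind <- c(alpha_to_coil = "H", beta_to_coil = "E", coil_to_beta = "C",
                   alpha_to_beta = "H", unchanged = "H")
  inter_kind <- c(alpha_to_coil = "C", beta_to_coil = "C", coil_to_beta = "E",
                  alpha_to_beta = "E", unchanged = "H")
  chains <- LETTERS[seq_along(events)]
  sep <- 6   # nm between segment modules: far outside any interaction reach
  native_parts <- inter_parts <- vector("list", length(events))
  for (k in seq_along(events)) {
    off <- c(0, 0, (k - 1) * sep)
    native_parts[[k]] <- translate_structure(
      template(native_kind[[events[k]]], chains[k]), off)
    inter_parts[[k]] <- translate_structure(
      template(inter_kind[[events[k]]], chains[k]), off)
  }
  native <- do.call(combine_structures, native_parts)
  inter <- do.call(combine_structures, inter_parts)
  base <- c(t(as.matrix(inter$atoms[, c("x", "y", "z")])))
  set.seed(seed)
  xyz <- matrix(rep(base, each = n_frames), nrow = n_frames) +
    matrix(stats::rnorm(n_frames * length(base), sd = noise_sigma), nrow = n_frames)
  res <- native$residues
  truth <- data.frame(
    segment = seq_along(events), chain = chains,
    event = events,
    first_residue = vapply(chains, function(ch) min(res$residue_index[res$chain == ch]), numeric(1)),
    last_residue = vapply(chains, function(ch) max(res$residue_index[res$chain == ch]), numeric(1)),
    stringsAsFactors = FALSE)
  list(native = native,
       trajectory = new_trajectory(native, xyz, temperature = 400,
                                   label = "unfolding-ensemble"),
       truth = truth)
}

#' Aggregate per-residue transition events to per-segment calls
#'
#' A segment's call is the most frequent non-`unchanged` event among its
#' residues, provided that event covers at least `min_fraction` of the
#' segment; otherwise `unchanged`. Chain termini are natively coil, so a
#' remodeled segment always retains a few `unchanged` residues at its edges.
#'
#' @param event_table a `TransitionEventTable`.
#' @param truth segment table with `first_residue`, `last_residue`.
#' @param min_fraction minimum fraction of segment residues showing the
#'   event (default 0.25).
#' @return character vector, one event per segment.
#' @export
segment_event_summary <- function(event_table, truth, min_fraction = 0.25) {
  vapply(seq_len(nrow(truth)), function(k) {
    rows <- event_table$residue >= truth$first_residue[k] &
      event_table$residue <= truth$last_residue[k]
    ev <- as.character(event_table$event[rows])
    cnt <- table(ev[ev != "unchanged"])
    if (!length(cnt) || max(cnt) / sum(rows) < min_fraction) return("unchanged")
    names(cnt)[which.max(cnt)]
  }, character(1))
}

#' Two-residue trajectory with an exactly imposed distance distribution
#'
#' Generates a C-alpha pair whose inter-residue distance series has exactly
#' the requested mean and population variance (imposed by standardizing the
#' raw Gaussian series), for validating commute-time estimators.
#'
#' @param mean_A,variance_A2 target mean (Angstrom) and population variance
#'   (Angstrom^2) of the distance series.
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @return a `Trajectory` of two single-CA residues.
#' @export
make_distance_process <- function(mean_A = 10, variance_A2 = 1,
                                  n_frames = 500, seed = 1) {
  stopifnot(variance_A2 >= 0, n_frames >= 2, mean_A > 0)
  set.seed(seed)
  z <- stats::rnorm(n_frames)
  z <- z - mean(z)
  s <- sqrt(mean(z^2))
  d_A <- if (variance_A2 == 0 || s == 0) rep(mean_A, n_frames) else
    mean_A + z / s * sqrt(variance_A2)
  if (any(d_A <= 0)) stop("distance process crossed zero; increase mean_A")
  atoms <- data.frame(name = "CA", element = "C", resno = 1:2,
                      resname = "ALA", chain = c("A", "B"),
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  topo <- new_structure(atoms)
  xyz <- t(vapply(d_A / 10, function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  new_trajectory(topo, xyz, label = "distance-process")
}
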