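# Secondary-structure assignment (Kabsch-Sander hydrogen-bond patterns,
# reduced to helix / strand / coil), native-normalized propensities,
# transition-event classification and backbone dihedral series.
#
# The hydrogen-bond energy is the Kabsch-Sander electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
# (distances in Angstrom) with a bond when E < -0.5 kcal/mol. The amide
# hydrogen is reconstructed geometrically when the structure lacks it.

HB_ENERGY_CUTOFF <- -0.5   # kcal/mol
PEPTIDE_BREAK_NM <- 0.25   # C(i)-N(i+1) beyond this is a chain break

# Collect per-residue backbone atoms for protein residues.
# Returns list of n x 3 matrices (NA rows where missing) plus bookkeeping.
#' @keywords internal
backbone_table <- function(coords, topology) {
  at <- topology$atoms
  keep <- !at$is_solvent & !at$is_hetero
  res_ids <- unique(at$residue_index[keep])
  n <- length(res_ids)
  pick <- function(name) {
    m <- matrix(NA_real_, n, 3)
    idx <- which(keep & at$name %in% name)
    # first matching atom per residue
    idx <- idx[!duplicated(at$residue_index[idx])]
    m[match(at$residue_index[idx], res_ids), ] <- coords[idx, , drop = FALSE]
    m
  }
  list(res_ids = res_ids,
       N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
       H = pick(c("H", "HN")),
       resname = topology$residues$resname[match(res_ids, topology$residues$residue_index)],
       chain = topology$residues$chain[match(res_ids, topology$residues$residue_index)])
}

#' Assign secondary structure to one frame
#'
#' Kabsch-Sander style assignment from backbone hydrogen-bond patterns:
#' n-turns (i -> i+3/4/5) give helices (two consecutive turns required),
#' parallel/antiparallel bridge patterns give strands. The 8-state alphabet
#' is reduced to three: H (alpha/3-10/pi helix), E (strand or isolated
#' bridge), C (everything else). Residues with missing backbone atoms and
#' chains shorter than 3 residues are labeled C.
#'
#' @param x a `Structure`, or an n_atoms x 3 coordinate matrix (nm).
#' @param topology the `Structure` providing atom bookkeeping when `x` is a
#'   bare matrix.
#' @return character vector of labels in \{"H", "E", "C"\}, one per protein
#'   residue, named by author residue number.
#' @export
assign_secondary_structure <- function(x, topology = NULL) {
  if (inherits(x, "Structure")) {
    topology <- x
    coords <- as.matrix(x$atoms[, c("x", "y", "z")])
  } else {
    if (is.null(topology)) stop("topology Structure required")
    coords <- as.matrix(x)
  }
  bb <- backbone_table(coords, topology)
  n <- length(bb$res_ids)
  labels <- rep("C", n)
  if (n >= 3) {
    hb <- ks_hbond_matrix(bb)        # hb[i, j]: CO(i) bonded to NH(j)
    brk <- chain_breaks(bb)          # TRUE between residue k and k+1
    labels <- ks_labels(hb, brk, n)
  }
  resno <- topology$residues$resno[match(bb$res_ids, topology$residues$residue_index)]
  stats::setNames(labels, resno)
}

# TRUE at position k when residues k and k+1 are not peptide-bonded.
#' @keywords internal
chain_breaks <- function(bb) {
  n <- length(bb$res_ids)
  if (n < 2) return(logical(0))
  d <- sqrt(rowSums((bb$C[-n, , drop = FALSE] - bb$N[-1, , drop = FALSE])^2))
  brk <- is.na(d) | d > PEPTIDE_BREAK_NM
  brk | bb$chain[-n] != bb$chain[-1]
}

# Kabsch-Sander hydrogen-bond matrix: entry [i, j] TRUE when the carbonyl
# of residue i accepts from the amide of residue j.
#' @keywords internal
ks_hbond_matrix <- function(bb) {
  n <- length(bb$res_ids)
  H <- bb$H
  # reconstruct missing amide hydrogens: 0.1 nm from N along the bisector of
  # (N - C_prev) and (N - CA), i.e. opposite the preceding carbonyl direction
  brk <- c(TRUE, chain_breaks(bb))   # brk[k]: no predecessor peptide bond
  for (k in seq_len(n)) {
    if (!is.na(H[k, 1])) next
    if (bb$resname[k] == "PRO") next                # proline has no amide H
    if (brk[k]) next                                # chain start: no H built
    u1 <- bb$N[k, ] - bb$C[k - 1, ]
    u2 <- bb$N[k, ] - bb$CA[k, ]
    if (anyNA(u1) || anyNA(u2)) next
    u <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
    H[k, ] <- bb$N[k, ] + 0.1 * u / sqrt(sum(u^2))
  }
  donor_ok <- !is.na(H[, 1]) & !is.na(bb$N[, 1]) & bb$resname != "PRO"
  accept_ok <- !is.na(bb$O[, 1]) & !is.na(bb$C[, 1])
  hb <- matrix(FALSE, n, n)
  if (!any(donor_ok) || !any(accept_ok)) return(hb)
  ai <- which(accept_ok)
  dj <- which(donor_ok)
  # distances in Angstrom
  rON <- sqrt(dist2_cross(bb$O[ai, , drop = FALSE], bb$N[dj, , drop = FALSE])) * 10
  rCH <- sqrt(dist2_cross(bb$C[ai, , drop = FALSE], H[dj, , drop = FALSE])) * 10
  rOH <- sqrt(dist2_cross(bb$O[ai, , drop = FALSE], H[dj, , drop = FALSE])) * 10
  rCN <- sqrt(dist2_cross(bb$C[ai, , drop = FALSE], bb$N[dj, , drop = FALSE])) * 10
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  ok <- E < HB_ENERGY_CUTOFF
  # exclude self and sequence-adjacent pairs (covalently constrained)
  sep <- abs(outer(ai, dj, "-"))
  ok[sep < 2] <- FALSE
  hb[ai, dj] <- ok
  hb
}

# Helix and strand patterns from the hydrogen-bond matrix.
#' @keywords internal
ks_labels <- function(hb, brk, n) {
  labels <- rep("C", n)
  contiguous <- function(i, j) {        # no break between residues i..j
    i >= 1 && j <= n && (i == j || !any(brk[i:(j - 1)]))
  }
  turn <- function(len) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - len)) {
      if (hb[i, i + len] && contiguous(i, i + len)) t[i] <- TRUE
    }
    t
  }
  mark_helix <- function(t, len) {
    m <- rep(FALSE, n)
    for (i in which(t)) {
      if (i >= 2 && t[i - 1]) m[i:(i + len - 1)] <- TRUE
    }
    m
  }
  h4 <- mark_helix(turn(4), 4)
  h3 <- mark_helix(turn(3), 3)
  h5 <- mark_helix(turn(5), 5)
  # bridges (strands): parallel / antiparallel patterns, |i - j| >= 3
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (!contiguous(i - 1, i + 1)) next
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3 || !contiguous(j - 1, j + 1)) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[i] <- bridge[j] <- TRUE
    }
  }
  labels[h3 | h5] <- "H"
  labels[bridge] <- "E"
  labels[h4] <- "H"          # alpha helix takes precedence over bridges
  labels
}

#' Secondary-structure labels for every frame of a trajectory
#'
#' @param trajectory a `Trajectory`.
#' @return character matrix, frames x residues, entries in \{"H","E","C"\}.
#' @export
ss_matrix <- function(trajectory) {
  first <- assign_secondary_structure(frame_coords(trajectory, 1),
                                      trajectory$topology)
  nf <- n_frames(trajectory)
  out <- matrix(NA_character_, nf, length(first),
                dimnames = list(NULL, names(first)))
  out[1, ] <- first
  for (f in seq_len(nf)[-1]) {
    out[f, ] <- assign_secondary_structure(frame_coords(trajectory, f),
                                           trajectory$topology)
  }
  out
}

#' Per-residue secondary-structure propensities, native-normalized
#'
#' For each residue, the fraction of frames spent in each class and the
#' fraction spent in the residue's native class (the native-normalized
#' propensity).
#'
#' @param labels character matrix, frames x residues (from [ss_matrix()]).
#' @param native_labels character vector of native labels, one per residue.
#' @return data.frame of class `PropensityTable` with columns `residue`,
#'   `native`, `p_H`, `p_E`, `p_C`, `native_propensity`.
#' @export
propensity <- function(labels, native_labels) {
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1)
  if (ncol(labels) != length(native_labels)) {
    stop("native_labels length must match the number of residues")
  }
  pH <- colMeans(labels == "H")
  pE <- colMeans(labels == "E")
  pC <- colMeans(labels == "C")
  pnat <- vapply(seq_along(native_labels), function(r) {
    mean(labels[, r] == native_labels[r])
  }, numeric(1))
  out <- data.frame(residue = seq_along(native_labels),
                    native = as.character(native_labels),
                    p_H = pH, p_E = pE, p_C = pC,
                    native_propensity = pnat)
  class(out) <- c("PropensityTable", "data.frame")
  out
}

TRANSITION_EVENTS <- c("alpha_to_coil", "beta_to_coil", "coil_to_beta",
                       "alpha_to_beta", "unchanged")

#' Classify per-residue secondary-structure transition events
#'
#' Compares each residue's native label with its modal label over the
#' ensemble. The four transition classes are helix-to-coil, strand-to-coil,
#' coil-to-strand and helix-to-strand; everything else (including modal
#' ties, which are resolved conservatively) is `unchanged`.
#'
#' @param native_labels character vector of native labels.
#' @param ensemble_labels character matrix, frames x residues.
#' @return data.frame of class `TransitionEventTable` with columns
#'   `residue`, `native`, `modal`, `event`.
#' @export
classify_transition_events <- function(native_labels, ensemble_labels) {
  if (!is.matrix(ensemble_labels)) ensemble_labels <- matrix(ensemble_labels, nrow = 1)
  if (ncol(ensemble_labels) != length(native_labels)) {
    stop("label arrays are not aligned: ", length(native_labels),
         " native labels vs ", ncol(ensemble_labels), " residues")
  }
  n <- length(native_labels)
  modal <- character(n)
  for (r in seq_len(n)) {
    cnt <- table(factor(ensemble_labels[, r], levels = c("H", "E", "C")))
    top <- names(cnt)[cnt == max(cnt)]
    modal[r] <- if (length(top) == 1) top else as.character(native_labels[r])
  }
  event <- rep("unchanged", n)
  event[native_labels == "H" & modal == "C"] <- "alpha_to_coil"
  event[native_labels == "E" & modal == "C"] <- "beta_to_coil"
  event[native_labels == "C" & modal == "E"] <- "coil_to_beta"
  event[native_labels == "H" & modal == "E"] <- "alpha_to_beta"
  out <- data.frame(residue = seq_len(n), native = as.character(native_labels),
                    modal = modal, event = factor(event, levels = TRANSITION_EVENTS))
  class(out) <- c("TransitionEventTable", "data.frame")
  out
}

#' Backbone dihedral time series
#'
#' Signed torsion in (-180, 180\] degrees, IUPAC sign convention.
#' phi is C(i-1)-N(i)-CA(i)-C(i); psi is N(i)-CA(i)-C(i)-N(i+1).
#'
#' @param trajectory a `Trajectory`.
#' @param residue internal residue index.
#' @param angle `"phi"` or `"psi"`.
#' @return numeric vector of angles (degrees), one per frame.
#' @export
dihedral_series <- function(trajectory, residue, angle = c("phi", "psi")) {
  angle <- match.arg(angle)
  at <- trajectory$topology$atoms
  find_atom <- function(res, name) {
    idx <- which(at$residue_index == res & at$name == name)
    if (!length(idx)) {
      stop("residue ", res, " lacks atom ", name, " needed for ", angle)
    }
    idx[1]
  }
  quad <- if (angle == "phi") {
    c(find_atom(residue - 1, "C"), find_atom(residue, "N"),
      find_atom(residue, "CA"), find_atom(residue, "C"))
  } else {
    c(find_atom(residue, "N"), find_atom(residue, "CA"),
      find_atom(residue, "C"), find_atom(residue + 1, "N"))
  }
  vapply(seq_len(n_frames(trajectory)), function(f) {
    xyz <- frame_coords(trajectory, f)
    torsion_angle(xyz[quad[1], ], xyz[quad[2], ], xyz[quad[3], ], xyz[quad[4], ])
  }, numeric(1))
}

#' Cross-check an assignment against an external DSSP implementation
#'
#' Writes the structure to a temporary PDB and calls the mdtraj DSSP
#' implementation through the system `python`. Intended for validation
#' only; returns the per-residue agreement with [assign_secondary_structure()].
#'
#' @param structure a `Structure`.
#' @param python python executable (default `"python"`).
#' @return list with `agreement` (fraction), `ours`, `reference`.
#' @export
ss_crosscheck <- function(structure, python = "python") {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_structure(structure, pdb)
  script <- paste(
    "import sys, mdtraj",
    "t = mdtraj.load(sys.argv[1])",
    "print(''.join(mdtraj.compute_dssp(t, simplified=True)[0]))",
    sep = "; ")
  out <- suppressWarnings(system2(python, c("-c", shQuote(script), shQuote(pdb)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if ((!is.null(status) && status != 0) || !length(out)) {
    stop("reference DSSP call failed")
  }
  ref <- strsplit(out[length(out)], "")[[1]]
  ref[!ref %in% c("H", "E")] <- "C"
  ours <- unname(assign_secondary_structure(structure))
  m <- min(length(ref), length(ours))
  list(agreement = mean(ours[seq_len(m)] == ref[seq_len(m)]),
       ours = ours, reference = ref)
}
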