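# Protein-solvent and mainchain hydrogen-bond counting, segment
# normalization, and concordance with HDX-MS protection classes.
#
# Geometry criterion: donor-acceptor (N/O...N/O) distance <= 0.35 nm and,
# when hydrogens are present, an H-D-A angle <= 30 degrees. Structures
# without hydrogens fall back to the distance term alone.

#' Hydrogen-bond geometry criterion
#'
#' @param distance_cutoff donor-acceptor cutoff in nm (default 0.35).
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff in degrees
#'   (default 30); ignored when the structure carries no hydrogens.
#' @return list of class `HBondCriterion`.
#' @export
hbond_criterion <- function(distance_cutoff = 0.35, angle_cutoff = 30) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "HBondCriterion")
}

# Donor/acceptor atom indices. Donors and acceptors are N and O atoms;
# hydrogens are attached to the nearest heavy atom within the residue.
#' @keywords internal
hbond_sites <- function(structure, atom_subset = NULL) {
  at <- structure$atoms
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(at))
  idx <- atom_subset[toupper(at$element[atom_subset]) %in% c("N", "O")]
  h_for <- vector("list", nrow(at))
  h_all <- which(toupper(at$element) == "H")
  if (length(h_all)) {
    heavy <- which(toupper(at$element) != "H")
    for (h in h_all) {
      cand <- heavy[at$residue_index[heavy] == at$residue_index[h]]
      if (!length(cand)) next
      d2 <- (at$x[cand] - at$x[h])^2 + (at$y[cand] - at$y[h])^2 +
        (at$z[cand] - at$z[h])^2
      p <- cand[which.min(d2)]
      h_for[[p]] <- c(h_for[[p]], h)
    }
  }
  list(polar = idx, h_for = h_for, has_h = length(h_all) > 0)
}

# Count donor/acceptor pairs between two atom groups satisfying the
# criterion, for one coordinate frame. Pairs are counted once.
#' @keywords internal
count_hbond_pairs <- function(coords, structure, group_a, group_b, criterion,
                              min_res_sep = 0) {
  sa <- hbond_sites(structure, group_a)
  sb <- hbond_sites(structure, group_b)
  if (!length(sa$polar) || !length(sb$polar)) return(0L)
  xa <- coords[sa$polar, , drop = FALSE]
  xb <- coords[sb$polar, , drop = FALSE]
  d <- sqrt(dist2_cross(xa, xb))
  cand <- which(d <= criterion$distance_cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  res <- structure$atoms$residue_index
  cnt <- 0L
  seen <- character(0)
  for (r in seq_len(nrow(cand))) {
    i <- sa$polar[cand[r, 1]]
    j <- sb$polar[cand[r, 2]]
    if (i == j) next
    if (min_res_sep > 0 && abs(res[i] - res[j]) < min_res_sep) next
    # key pairs by their geometry so that duplicated records at identical
    # positions count once: counts depend on the geometry set, not on
    # record multiplicity
    ki <- paste(signif(coords[i, ], 10), collapse = ",")
    kj <- paste(signif(coords[j, ], 10), collapse = ",")
    if (ki == kj) next
    key <- paste(sort(c(ki, kj)), collapse = "|")
    if (key %in% seen) next
    if (sa$has_h || sb$has_h) {
      ok <- hbond_angle_ok(coords, i, j, sa$h_for, criterion) ||
        hbond_angle_ok(coords, j, i, sb$h_for, criterion)
      if (!ok) next
    }
    seen <- c(seen, key)
    cnt <- cnt + 1L
  }
  cnt
}

# TRUE when donor `i` has a hydrogen making an H-D-A angle within the
# cutoff toward acceptor `j` (or carries no hydrogens at all, in which case
# the heavy-atom fallback applies).
#' @keywords internal
hbond_angle_ok <- function(coords, i, j, h_for, criterion) {
  hs <- h_for[[i]]
  if (is.null(hs) || !length(hs)) return(TRUE)
  for (h in hs) {
    ang <- vertex_angle(coords[h, ], coords[i, ], coords[j, ])
    if (ang <= criterion$angle_cutoff) return(TRUE)
  }
  FALSE
}

#' Protein-solvent hydrogen bonds of a residue segment
#'
#' Counts, per frame, donor/acceptor pairs between the segment's atoms and
#' solvent satisfying the criterion; returns the mean and standard
#' deviation over frames. When several trajectories are given, the
#' per-trajectory means are averaged and the sd is taken across
#' trajectories (matching error bars across independent runs).
#'
#' @param trajectories a `Trajectory` or list of them; the topology must
#'   contain flagged solvent molecules.
#' @param segment_residues internal residue indices of the segment.
#' @param criterion an [hbond_criterion()].
#' @return list with `mean`, `sd`, `per_frame` (list of per-frame counts
#'   per trajectory).
#' @export
count_protein_solvent_hbonds <- function(trajectories, segment_residues,
                                         criterion = hbond_criterion()) {
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  per_traj <- lapply(trajectories, function(traj) {
    topo <- traj$topology
    solv <- which(topo$atoms$is_solvent)
    if (!length(solv)) stop("topology contains no solvent molecules")
    seg <- which(topo$atoms$residue_index %in% segment_residues &
                   !topo$atoms$is_solvent)
    vapply(seq_len(n_frames(traj)), function(f) {
      count_hbond_pairs(frame_coords(traj, f), topo, seg, solv, criterion)
    }, integer(1))
  })
  means <- vapply(per_traj, mean, numeric(1))
  if (length(per_traj) > 1) {
    list(mean = mean(means), sd = stats::sd(means), per_frame = per_traj)
  } else {
    list(mean = means[1], sd = stats::sd(per_traj[[1]]), per_frame = per_traj)
  }
}

#' Terminal-residue-normalized segment hydrogen bonds
#'
#' Restricts the protein-solvent count to seven terminal residues of the
#' segment (the first 4 and last 3 by default); segments shorter than 7
#' residues are excluded with an explicit marker rather than an error.
#'
#' @inheritParams count_protein_solvent_hbonds
#' @param head_n,tail_n how many residues from each end (defaults 4 and 3).
#' @return as [count_protein_solvent_hbonds()], plus `excluded` (logical)
#'   and `residues_used`.
#' @export
normalized_segment_hbonds <- function(trajectories, segment_residues,
                                      criterion = hbond_criterion(),
                                      head_n = 4, tail_n = 3) {
  segment_residues <- sort(segment_residues)
  if (length(segment_residues) < head_n + tail_n) {
    return(list(mean = NA_real_, sd = NA_real_, excluded = TRUE,
                residues_used = integer(0)))
  }
  used <- c(utils::head(segment_residues, head_n),
            utils::tail(segment_residues, tail_n))
  out <- count_protein_solvent_hbonds(trajectories, used, criterion)
  out$excluded <- FALSE
  out$residues_used <- used
  out
}

#' Intra-molecular mainchain hydrogen bonds of one frame
#'
#' Counts backbone N-H...O=C bonds satisfying the criterion, requiring a
#' residue separation of at least 2 (sequence-adjacent backbone polar atoms
#' are covalently constrained, not hydrogen-bonded). The amide hydrogen is
#' reconstructed geometrically when the structure lacks hydrogens, so the
#' angle term always applies to mainchain bonds; this keeps the count
#' directional (an ideal helix yields its i -> i+4 ladder, not every polar
#' pair within reach).
#'
#' @param x a `Structure` or coordinate matrix.
#' @param structure topology when `x` is a matrix.
#' @param criterion an [hbond_criterion()].
#' @return integer count.
#' @export
count_mainchain_hbonds <- function(x, structure = NULL,
                                   criterion = hbond_criterion()) {
  if (inherits(x, "Structure")) {
    structure <- x
    coords <- as.matrix(x$atoms[, c("x", "y", "z")])
  } else coords <- as.matrix(x)
  bb <- backbone_table(coords, structure)
  n <- length(bb$res_ids)
  if (n < 3) return(0L)
  H <- bb$H
  brk <- c(TRUE, chain_breaks(bb))
  for (k in seq_len(n)) {
    if (!is.na(H[k, 1]) || brk[k] || bb$resname[k] == "PRO") next
    u1 <- bb$N[k, ] - bb$C[k - 1, ]
    u2 <- bb$N[k, ] - bb$CA[k, ]
    if (anyNA(u1) || anyNA(u2)) next
    u <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
    H[k, ] <- bb$N[k, ] + 0.1 * u / sqrt(sum(u^2))
  }
  cnt <- 0L
  for (i in seq_len(n)) {          # donor amide of residue i
    if (is.na(H[i, 1]) || is.na(bb$N[i, 1])) next
    for (j in seq_len(n)) {        # acceptor carbonyl of residue j
      if (abs(i - j) < 2 || is.na(bb$O[j, 1])) next
      dno <- sqrt(sum((bb$N[i, ] - bb$O[j, ])^2))
      if (dno > criterion$distance_cutoff) next
      if (vertex_angle(H[i, ], bb$N[i, ], bb$O[j, ]) > criterion$angle_cutoff) next
      cnt <- cnt + 1L
    }
  }
  cnt
}

#' Read peptide segment definitions from a BED-like TSV
#'
#' Expected columns: `segment_id`, `start_residue`, `end_residue`,
#' `protection_class` (one of "more", "less", "unknown"); residue bounds in
#' author numbering, inclusive.
#'
#' @param file path to the TSV.
#' @return data.frame.
#' @export
read_segments <- function(file) {
  seg <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("segment_id", "start_residue", "end_residue", "protection_class")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("segment file missing columns: ", paste(miss, collapse = ", "))
  if (!all(seg$protection_class %in% c("more", "less", "unknown"))) {
    stop("protection_class must be 'more', 'less' or 'unknown'")
  }
  seg
}

#' Segment hydrogen-bond report across trajectories
#'
#' @param trajectories a `Trajectory` or list of them.
#' @param segments data.frame from [read_segments()] (residue bounds in
#'   author numbering).
#' @param criterion an [hbond_criterion()].
#' @param normalized also compute the terminal-residue-normalized mean.
#' @return data.frame of class `SegmentHBondReport`: one row per segment
#'   with `segment_id`, `protection_class`, `mean_hbonds`, `sd_hbonds`,
#'   `normalized_mean`, `excluded`.
#' @export
segment_hbond_report <- function(trajectories, segments,
                                 criterion = hbond_criterion(),
                                 normalized = TRUE) {
  topo <- if (inherits(trajectories, "Trajectory")) trajectories$topology
          else trajectories[[1]]$topology
  res <- topo$residues
  out <- lapply(seq_len(nrow(segments)), function(k) {
    ridx <- res$residue_index[res$resno >= segments$start_residue[k] &
                                res$resno <= segments$end_residue[k] &
                                !res$resname %in% SOLVENT_RESNAMES]
    full <- count_protein_solvent_hbonds(trajectories, ridx, criterion)
    norm <- if (normalized) normalized_segment_hbonds(trajectories, ridx, criterion)
            else list(mean = NA_real_, excluded = NA)
    data.frame(segment_id = segments$segment_id[k],
               protection_class = segments$protection_class[k],
               mean_hbonds = full$mean, sd_hbonds = full$sd,
               normalized_mean = norm$mean, excluded = isTRUE(norm$excluded))
  })
  out <- do.call(rbind, out)
  class(out) <- c("SegmentHBondReport", "data.frame")
  out
}

#' Concordance of segment hydrogen bonding with HDX protection classes
#'
#' More-protected amides are expected to show fewer protein-solvent
#' hydrogen bonds. Reports the class means and how many less-protected
#' segments lie strictly above the more-protected class mean.
#'
#' @param report a `SegmentHBondReport` (or compatible data.frame) with
#'   `protection_class` and `mean_hbonds`.
#' @return list with `mean_more`, `mean_less`, `n_less_above_more_mean`,
#'   `n_less_total`.
#' @export
protection_concordance <- function(report) {
  more <- report$mean_hbonds[report$protection_class == "more"]
  less <- report$mean_hbonds[report$protection_class == "less"]
  if (!length(more) || !length(less)) {
    stop("need at least one segment in each protection class")
  }
  list(mean_more = mean(more), mean_less = mean(less),
       n_less_above_more_mean = sum(less > mean(more)),
       n_less_total = length(less))
}
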