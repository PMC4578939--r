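# Residue contact maps: native vs non-native classification, persistence,
# and pair distance distributions. Default metric is C-alpha distance at a
# 7 A cutoff; a minimum heavy-atom mode is provided.

#' Residue-residue contact frequency map over an ensemble
#'
#' Contact frequency is the fraction of frames with pair distance at most
#' `cutoff_A`; pairs are classified against the native structure's contact
#' map at the same cutoff: `native` (contact in the native structure),
#' `non_native` (ensemble contact absent in the native), `absent`.
#'
#' @param trajectory a `Trajectory`.
#' @param native reference `Structure` (same residue count).
#' @param metric `"calpha"` or `"min_heavy"`.
#' @param cutoff_A distance cutoff in Angstrom (default 7).
#' @param min_sep minimum sequence separation (default 3).
#' @return object of class `ContactMap`: list with `frequency` (symmetric
#'   matrix), `class` (character matrix), `metric`, `cutoff_A`, `min_sep`.
#' @export
residue_contact_map <- function(trajectory, native,
                                metric = c("calpha", "min_heavy"),
                                cutoff_A = 7, min_sep = 3) {
  metric <- match.arg(metric)
  topo <- trajectory$topology
  nres <- nrow(topo$residues)
  cutoff <- cutoff_A / 10
  nat_d <- residue_distance_matrix(
    as.matrix(native$atoms[, c("x", "y", "z")]), native, metric)
  freq <- matrix(0, nres, nres)
  for (f in seq_len(n_frames(trajectory))) {
    d <- residue_distance_matrix(frame_coords(trajectory, f), topo, metric)
    freq <- freq + (d <= cutoff)
  }
  freq <- freq / n_frames(trajectory)
  excl <- abs(outer(seq_len(nres), seq_len(nres), "-")) < min_sep
  freq[excl] <- 0
  cls <- matrix("absent", nres, nres)
  nat <- nat_d <= cutoff & !excl
  cls[nat] <- "native"
  cls[!nat & freq > 0] <- "non_native"
  cls[excl] <- "absent"
  structure(list(frequency = freq, class = cls, metric = metric,
                 cutoff_A = cutoff_A, min_sep = min_sep),
            class = "ContactMap")
}

# Residue-level distance matrix for one frame: C-alpha distance or minimum
# heavy-atom distance. Residues lacking the scoped atoms get Inf.
#' @keywords internal
residue_distance_matrix <- function(coords, topology, metric) {
  at <- topology$atoms
  nres <- nrow(topology$residues)
  if (metric == "calpha") {
    ca <- which(at$name == "CA" & !at$is_solvent)
    out <- matrix(Inf, nres, nres)
    idx <- at$residue_index[ca]
    d <- sqrt(dist2_cross(coords[ca, , drop = FALSE], coords[ca, , drop = FALSE]))
    out[idx, idx] <- d
    out
  } else {
    heavy <- which(at$element != "H" & !at$is_solvent)
    residue_min_dist_matrix(coords, at$residue_index, heavy, nres)
  }
}

#' Persistent non-native pairs
#'
#' @param map a `ContactMap`.
#' @param persistence_min minimum contact frequency (default 0.5).
#' @return data.frame with `res_i`, `res_j`, `frequency`, sorted by
#'   frequency descending.
#' @export
nonnative_pairs <- function(map, persistence_min = 0.5) {
  hit <- which(upper.tri(map$frequency) & map$class == "non_native" &
                 map$frequency >= persistence_min, arr.ind = TRUE)
  out <- data.frame(res_i = hit[, 1], res_j = hit[, 2],
                    frequency = map$frequency[hit])
  out[order(-out$frequency, out$res_i, out$res_j), , drop = FALSE]
}

#' C-alpha distance distribution of a residue pair
#'
#' @param trajectory a `Trajectory`.
#' @param pair integer c(i, j), internal residue indices.
#' @param bin_width_A histogram bin width in Angstrom (default 0.5).
#' @return list with `breaks_A`, `density` (normalized so the histogram
#'   integrates to 1), `distances_A`.
#' @export
pair_distance_distribution <- function(trajectory, pair, bin_width_A = 0.5) {
  at <- trajectory$topology$atoms
  ca <- vapply(pair, function(r) {
    idx <- which(at$residue_index == r & at$name == "CA")
    if (!length(idx)) stop("residue ", r, " has no C-alpha atom")
    idx[1]
  }, integer(1))
  d_A <- vapply(seq_len(n_frames(trajectory)), function(f) {
    xyz <- frame_coords(trajectory, f)
    sqrt(sum((xyz[ca[1], ] - xyz[ca[2], ])^2)) * 10
  }, numeric(1))
  lo <- floor(min(d_A) / bin_width_A) * bin_width_A
  hi <- ceiling(max(d_A) / bin_width_A) * bin_width_A
  if (hi <= lo) hi <- lo + bin_width_A
  h <- graphics::hist(d_A, breaks = seq(lo, hi, by = bin_width_A), plot = FALSE)
  list(breaks_A = h$breaks, density = h$density, distances_A = d_A)
}

#' Write a contact map as TSV matrix with JSON metadata
#' @param map a `ContactMap`.
#' @param prefix output path prefix.
#' @return file paths, invisibly.
#' @export
write_contact_map <- function(map, prefix) {
  f1 <- paste0(prefix, "_frequency.tsv")
  f2 <- paste0(prefix, "_meta.json")
  utils::write.table(map$frequency, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(metric = map$metric, cutoff_A = map$cutoff_A,
                            min_sep = map$min_sep), f2, auto_unbox = TRUE)
  invisible(c(f1, f2))
}
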