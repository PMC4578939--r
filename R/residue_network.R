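# Commute-time residue communication networks.
#
# The commute time CT(i, j) is the time-variance of the C-alpha distance
# d(ij) over the trajectory: CT(i,j) = < (d(ij) - <d(ij)>)^2 >. Low values
# mark efficiently communicating residue pairs. Pathways are grown greedily
# on the interaction graph under a normalized CT threshold (default 0.1).

#' Neighbor matrix: time-averaged minimum inter-residue distance
#'
#' Entry (i, j) is TRUE when the time-averaged minimum heavy-atom distance
#' between residues i and j is below the threshold (default 3.6 A).
#'
#' @param trajectory a `Trajectory`.
#' @param threshold_A distance threshold in Angstrom.
#' @return logical symmetric matrix with FALSE diagonal.
#' @export
neighbor_matrix <- function(trajectory, threshold_A = 3.6) {
  topo <- trajectory$topology
  nres <- nrow(topo$residues)
  heavy <- which(topo$atoms$element != "H" & !topo$atoms$is_solvent)
  acc <- matrix(0, nres, nres)
  for (f in seq_len(n_frames(trajectory))) {
    acc <- acc + residue_min_dist_matrix(frame_coords(trajectory, f),
                                         topo$atoms$residue_index, heavy, nres)
  }
  avg <- acc / n_frames(trajectory)
  out <- avg < threshold_A / 10
  diag(out) <- FALSE
  out
}

#' Interaction matrix: persistent non-bonded contacts
#'
#' Entry (i, j) is TRUE when a non-bonded heavy-atom contact (minimum
#' distance <= `cutoff_A`, |i - j| >= `min_sep`) exists in at least
#' `frame_fraction` of the frames.
#'
#' @param trajectory a `Trajectory`.
#' @param frame_fraction persistence fraction (default 0.5).
#' @param cutoff_A heavy-atom contact cutoff in Angstrom (default 3.9).
#' @param min_sep minimum sequence separation (default 2).
#' @return logical symmetric matrix.
#' @export
interaction_matrix <- function(trajectory, frame_fraction = 0.5,
                               cutoff_A = 3.9, min_sep = 2) {
  topo <- trajectory$topology
  nres <- nrow(topo$residues)
  heavy <- which(topo$atoms$element != "H" & !topo$atoms$is_solvent)
  cnt <- matrix(0, nres, nres)
  for (f in seq_len(n_frames(trajectory))) {
    d <- residue_min_dist_matrix(frame_coords(trajectory, f),
                                 topo$atoms$residue_index, heavy, nres)
    cnt <- cnt + (d <= cutoff_A / 10)
  }
  out <- cnt / n_frames(trajectory) >= frame_fraction
  out[abs(outer(seq_len(nres), seq_len(nres), "-")) < min_sep] <- FALSE
  out
}

#' Commute-time matrix: variance of the C-alpha pair distance
#'
#' CT(i, j) is the population variance over frames of the C-alpha distance
#' between residues i and j, in A^2. Optional normalization divides by the
#' matrix maximum (the mode is recorded so thresholds are interpretable).
#'
#' @param trajectory a `Trajectory` with >= 2 frames.
#' @param normalize divide by the matrix maximum (default FALSE).
#' @return object of class `CommuteTimeMatrix`: the matrix with attributes
#'   `normalized` and `max_A2`.
#' @export
commute_time_matrix <- function(trajectory, normalize = FALSE) {
  if (n_frames(trajectory) < 2) stop("commute time needs >= 2 frames")
  topo <- trajectory$topology
  ca <- which(topo$atoms$name == "CA" & !topo$atoms$is_solvent)
  res_ids <- topo$atoms$residue_index[ca]
  nres <- nrow(topo$residues)
  nf <- n_frames(trajectory)
  m <- length(ca)
  # one-pass variance on distances shifted by the first frame's values;
  # the shift removes the catastrophic cancellation of raw sums of squares
  xyz1 <- frame_coords(trajectory, 1)[ca, , drop = FALSE]
  d0 <- sqrt(dist2_cross(xyz1, xyz1)) * 10    # Angstrom
  sum_d <- sum_d2 <- matrix(0, m, m)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(trajectory, f)[ca, , drop = FALSE]
    d <- sqrt(dist2_cross(xyz, xyz)) * 10 - d0
    sum_d <- sum_d + d
    sum_d2 <- sum_d2 + d^2
  }
  v <- sum_d2 / nf - (sum_d / nf)^2
  v[v < 0] <- 0
  diag(v) <- 0
  ct <- matrix(NA_real_, nres, nres)
  ct[res_ids, res_ids] <- v
  diag(ct) <- 0
  mx <- max(ct, na.rm = TRUE)
  if (normalize && mx > 0) ct <- ct / mx
  structure(ct, class = c("CommuteTimeMatrix", "matrix", "array"),
            normalized = normalize, max_A2 = mx)
}

#' Greedy communication-pathway growth
#'
#' Pathways are grown from the interacting pair of minimal CT: a residue is
#' appended when it (a) has an interaction edge to at least one current
#' member and (b) has CT at most `ct_threshold` to every current member.
#' When no candidate remains the members leave the pool and the next seed
#' starts; pathways shorter than 3 residues are discarded. Ties break
#' toward the lowest residue index, so growth is deterministic.
#'
#' @param ct a `CommuteTimeMatrix` (normalized when the threshold is the
#'   normalized default).
#' @param interactions logical interaction matrix.
#' @param ct_threshold CT threshold (default 0.1, normalized units).
#' @return list of integer vectors (ordered residue chains); empty when the
#'   interaction graph has no edges.
#' @export
grow_pathways <- function(ct, interactions, ct_threshold = 0.1) {
  nres <- nrow(ct)
  stopifnot(nrow(interactions) == nres)
  pool <- seq_len(nres)
  pathways <- list()
  repeat {
    # seed: interacting pair of minimal CT within the pool
    sub <- interactions[pool, pool, drop = FALSE]
    if (!any(sub)) break
    ctp <- ct[pool, pool, drop = FALSE]
    ctp[!sub] <- Inf
    k <- which(ctp == min(ctp), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    members <- sort(pool[c(k[1], k[2])])
    if (ct[members[1], members[2]] > ct_threshold) break
    repeat {
      cand <- setdiff(pool, members)
      ok <- cand[vapply(cand, function(r) {
        any(interactions[r, members]) && all(ct[r, members] <= ct_threshold)
      }, logical(1))]
      if (!length(ok)) break
      # deterministic choice: lowest CT sum to members, ties to lowest index
      sums <- vapply(ok, function(r) sum(ct[r, members]), numeric(1))
      members <- c(members, ok[order(sums, ok)][1])
    }
    pool <- setdiff(pool, members)
    if (length(members) >= 3) pathways[[length(pathways) + 1]] <- members
    if (length(pool) < 2) break
  }
  pathways
}

#' Build a residue communication network
#'
#' Combines the neighbor, interaction and commute-time analyses and grows
#' communication pathways. Node degree over the union of neighbor and
#' interaction edges is the communication efficiency.
#'
#' @param trajectory a `Trajectory`.
#' @param neighbor_threshold_A neighbor distance threshold (default 3.6).
#' @param frame_fraction interaction persistence (default 0.5).
#' @param interaction_cutoff_A contact cutoff (default 3.9).
#' @param ct_threshold normalized CT threshold (default 0.1).
#' @return object of class `CommunicationNetwork`: list with `neighbors`,
#'   `interactions`, `ct` (normalized), `pathways`, `thresholds`.
#' @export
build_network <- function(trajectory, neighbor_threshold_A = 3.6,
                          frame_fraction = 0.5, interaction_cutoff_A = 3.9,
                          ct_threshold = 0.1) {
  nb <- neighbor_matrix(trajectory, neighbor_threshold_A)
  im <- interaction_matrix(trajectory, frame_fraction, interaction_cutoff_A)
  ct <- commute_time_matrix(trajectory, normalize = TRUE)
  pw <- grow_pathways(ct, im, ct_threshold)
  structure(list(neighbors = nb, interactions = im, ct = ct, pathways = pw,
                 resno = trajectory$topology$residues$resno,
                 thresholds = list(neighbor_A = neighbor_threshold_A,
                                   frame_fraction = frame_fraction,
                                   interaction_A = interaction_cutoff_A,
                                   ct = ct_threshold,
                                   ct_normalized = TRUE)),
            class = "CommunicationNetwork")
}

#' Communication efficiency: node degree over neighbor and interaction edges
#'
#' @param network a `CommunicationNetwork`.
#' @return integer vector, one degree per residue.
#' @export
communication_efficiency <- function(network) {
  edges <- network$neighbors | network$interactions
  as.integer(rowSums(edges))
}

#' Export a communication network as GraphML
#'
#' Nodes carry the residue id, degree and pathway membership; edges carry
#' their type (neighbor / interaction / both) and pathway flag. Re-import
#' with [igraph::read_graph()] reproduces nodes, edges and attributes.
#'
#' @param network a `CommunicationNetwork`.
#' @param file output path.
#' @param format only `"graphml"` is supported; other strings error.
#' @return `file`, invisibly.
#' @export
export_graph <- function(network, file, format = "graphml") {
  if (!identical(tolower(format), "graphml")) {
    stop("unsupported graph format: ", format, " (supported: graphml)")
  }
  edges <- network$neighbors | network$interactions
  g <- igraph::graph_from_adjacency_matrix(edges, mode = "undirected")
  pathway_id <- rep(0L, nrow(edges))
  for (k in seq_along(network$pathways)) pathway_id[network$pathways[[k]]] <- k
  g <- igraph::set_vertex_attr(g, "resno", value = network$resno)
  g <- igraph::set_vertex_attr(g, "degree", value = communication_efficiency(network))
  g <- igraph::set_vertex_attr(g, "pathway", value = pathway_id)
  el <- igraph::as_edgelist(g)
  type <- character(nrow(el))
  for (r in seq_len(nrow(el))) {
    i <- as.integer(el[r, 1]); j <- as.integer(el[r, 2])
    nbr <- network$neighbors[i, j]; intx <- network$interactions[i, j]
    type[r] <- if (nbr && intx) "both" else if (nbr) "neighbor" else "interaction"
  }
  g <- igraph::set_edge_attr(g, "type", value = type)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Write pathways as TSV (pathway_id, ordered residues)
#' @param network a `CommunicationNetwork`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pathways <- function(network, file) {
  rows <- if (length(network$pathways)) {
    do.call(rbind, lapply(seq_along(network$pathways), function(k) {
      data.frame(pathway_id = k,
                 residues = paste(network$resno[network$pathways[[k]]],
                                  collapse = ","))
    }))
  } else data.frame(pathway_id = integer(0), residues = character(0))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
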