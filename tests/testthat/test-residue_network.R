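# Small rigid-body fixture: residues moving as two domains with noise.
two_domain_trajectory <- function(n_frames = 40, seed = 10) {
  s <- make_sheet_pair(12)           # halves 1-6 and 7-12 are the domains
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  set.seed(seed)
  dom2 <- s$atoms$residue_index >= 7
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    x <- base
    # domain 2 slides along x with a large random amplitude
    x[dom2, 1] <- x[dom2, 1] + rnorm(1, sd = 0.3)
    # small independent atomic jitter
    x <- x + matrix(rnorm(length(x), sd = 0.005), ncol = 3)
    c(t(x))
  }, numeric(3 * nrow(base))))
  new_trajectory(s, xyz)
}

test_that("neighbor matrix reflects time-averaged proximity", {
  s <- make_sheet_pair(10)
  tr <- new_trajectory(s, c(t(as.matrix(s$atoms[, c("x", "y", "z")]))))
  nb <- neighbor_matrix(tr)
  expect_true(nb[1, 2])      # covalently adjacent residues
  expect_false(nb[1, 1])
  # far-apart residues stay FALSE
  far <- translate_structure(make_extended_coil(2, chain = "B"), c(3, 0, 0))
  both <- combine_structures(make_extended_coil(2), far)
  tr2 <- new_trajectory(both, c(t(as.matrix(both$atoms[, c("x", "y", "z")]))))
  nb2 <- neighbor_matrix(tr2)
  expect_false(nb2[1, 3])
  # equals a direct averaging oracle on a 2-frame fixture
  base <- c(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  set.seed(3)
  alt <- base + rnorm(length(base), sd = 0.02)
  tr3 <- new_trajectory(s, rbind(base, alt))
  nb3 <- neighbor_matrix(tr3)
  heavy <- which(s$atoms$element != "H")
  d1 <- unfoldscape:::residue_min_dist_matrix(matrix(base, ncol = 3, byrow = TRUE),
                                              s$atoms$residue_index, heavy, 10)
  d2 <- unfoldscape:::residue_min_dist_matrix(matrix(alt, ncol = 3, byrow = TRUE),
                                              s$atoms$residue_index, heavy, 10)
  oracle <- (d1 + d2) / 2 < 0.36
  diag(oracle) <- FALSE
  expect_equal(nb3, oracle)
})

test_that("interaction matrix requires persistence across frames", {
  # three single-atom residues; the (1, 3) contact is toggled per frame
  s <- mini_structure(data.frame(name = "CA", element = "C", resno = 1:3,
                                 chain = "A", x = c(0, 10, 20), y = 0, z = 0))
  base <- c(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  near <- base
  near[7:9] <- c(0.3, 0, 0)    # residue 3 beside residue 1
  stack <- function(k) {
    rbind(do.call(rbind, replicate(k, near, simplify = FALSE)),
          do.call(rbind, replicate(10 - k, base, simplify = FALSE)))
  }
  im60 <- interaction_matrix(new_trajectory(s, stack(6)), frame_fraction = 0.5)
  expect_true(im60[1, 3])
  expect_true(im60[3, 1])
  # 40 % persistence at a 50 % threshold fails
  im40 <- interaction_matrix(new_trajectory(s, stack(4)), frame_fraction = 0.5)
  expect_false(im40[1, 3])
  # always-in-contact pair is TRUE; direct count agreement at the boundary
  im100 <- interaction_matrix(new_trajectory(s, stack(10)), frame_fraction = 0.5)
  expect_true(im100[1, 3])
  im50 <- interaction_matrix(new_trajectory(s, stack(5)), frame_fraction = 0.5)
  expect_true(im50[1, 3])      # exactly 50 % meets the >= threshold
  # sequence-adjacent pairs are excluded regardless of geometry
  expect_false(any(diag(im60[-1, ])))
})

test_that("commute time is the population variance of the C-alpha distance", {
  # rigid trajectory: all CT zero
  s <- make_sheet_pair(10)
  base <- c(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  rigid <- new_trajectory(s, rbind(base, base, base))
  ct0 <- commute_time_matrix(rigid)
  expect_true(all(ct0 == 0))
  # alternating 5 A / 7 A in equal halves: variance exactly 1 A^2
  xyz <- t(vapply(rep(c(0.5, 0.7), 10), function(d) c(0, 0, 0, d, 0, 0),
                  numeric(6)))
  pair <- make_distance_process(10, 0, n_frames = 2)$topology
  ct1 <- commute_time_matrix(new_trajectory(pair, xyz))
  expect_equal(ct1[1, 2], 1.0, tolerance = 1e-12)
  expect_equal(diag(ct1), c(0, 0))
  # random process: equals a direct variance computation
  tr <- make_distance_process(12, 4, n_frames = 200, seed = 5)
  ct <- commute_time_matrix(tr)
  d <- vapply(seq_len(n_frames(tr)), function(f) {
    xyz <- frame_coords(tr, f)
    sqrt(sum((xyz[1, ] - xyz[2, ])^2)) * 10
  }, numeric(1))
  expect_equal(ct[1, 2], mean((d - mean(d))^2), tolerance = 1e-12)
  expect_equal(ct[1, 2], ct[2, 1])
  expect_error(commute_time_matrix(new_trajectory(pair, xyz[1, , drop = FALSE])),
               "2 frames")
})

test_that("coordinate noise does not decrease commute times in expectation", {
  s <- make_sheet_pair(10)
  base <- c(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  set.seed(12)
  quiet <- new_trajectory(s, rbind(base, base + rnorm(length(base), sd = 1e-4)))
  noisy_xyz <- do.call(rbind, replicate(60, base, simplify = FALSE)) +
    matrix(rnorm(60 * length(base), sd = 0.02), nrow = 60)
  noisy <- new_trajectory(s, noisy_xyz)
  ct_q <- commute_time_matrix(quiet)
  ct_n <- commute_time_matrix(noisy)
  off <- upper.tri(ct_q)
  expect_gt(mean(ct_n[off]), mean(ct_q[off]))
})

test_that("pathway growth is greedy, thresholded and validated against its contract", {
  # 3 mutually interacting residues with CT 0 -> one pathway of 3
  im <- matrix(FALSE, 3, 3); im[1, 2] <- im[2, 1] <- im[2, 3] <- im[3, 2] <- im[1, 3] <- im[3, 1] <- TRUE
  ct <- matrix(0, 3, 3)
  class(ct) <- c("CommuteTimeMatrix", "matrix", "array")
  pw <- grow_pathways(ct, im)
  expect_equal(length(pw), 1)
  expect_setequal(pw[[1]], 1:3)
  # one residue with CT 0.5 to the others is excluded at threshold 0.1
  ct2 <- ct; ct2[3, 1:2] <- ct2[1:2, 3] <- 0.5
  pw2 <- grow_pathways(ct2, im)
  expect_equal(length(pw2), 0)      # remaining pair is shorter than 3
  # 5-node fixture: greedy result satisfies both growth conditions and
  # matches the exhaustive maximal feasible chain
  set.seed(30)
  n <- 5
  im5 <- matrix(FALSE, n, n)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 3))) {
    im5[p[1], p[2]] <- im5[p[2], p[1]] <- TRUE
  }
  ct5 <- matrix(1, n, n); diag(ct5) <- 0
  low <- c(1, 2, 3, 4)
  ct5[low, low] <- 0.05; diag(ct5) <- 0
  class(ct5) <- c("CommuteTimeMatrix", "matrix", "array")
  pw5 <- grow_pathways(ct5, im5)
  expect_equal(length(pw5), 1)
  expect_setequal(pw5[[1]], 1:4)
  # contract re-check: each member interacts with another member and all
  # pairwise CT within the pathway are below threshold
  for (p in pw5) {
    for (r in p) {
      expect_true(any(im5[r, setdiff(p, r)]))
      expect_true(all(ct5[r, setdiff(p, r)] <= 0.1))
    }
  }
  # exhaustive check: no feasible chain containing node 5 exists
  expect_false(any(vapply(pw5, function(p) 5 %in% p, logical(1))))
  # empty interaction graph -> empty result
  expect_equal(length(grow_pathways(ct5, matrix(FALSE, n, n))), 0)
})

test_that("communication efficiency is the degree over neighbor and interaction edges", {
  tr <- two_domain_trajectory()
  nw <- build_network(tr)
  deg <- communication_efficiency(nw)
  edges <- nw$neighbors | nw$interactions
  expect_equal(deg, as.integer(rowSums(edges)))
  expect_equal(sum(deg), 2 * sum(edges[upper.tri(edges)]))  # handshake lemma
})

test_that("intra-domain commute times are lower than inter-domain ones", {
  tr <- two_domain_trajectory()
  ct <- commute_time_matrix(tr)
  intra <- c(ct[1:6, 1:6][upper.tri(matrix(0, 6, 6))],
             ct[7:12, 7:12][upper.tri(matrix(0, 6, 6))])
  inter <- as.numeric(ct[1:6, 7:12])
  expect_lt(max(intra), min(inter))
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  tr <- two_domain_trajectory(n_frames = 10)
  nw <- build_network(tr)
  f <- tempfile(fileext = ".graphml")
  export_graph(nw, f)
  g <- igraph::read_graph(f, format = "graphml")
  edges <- nw$neighbors | nw$interactions
  expect_equal(igraph::vcount(g), nrow(edges))
  expect_equal(igraph::ecount(g), sum(edges[upper.tri(edges)]))
  expect_equal(igraph::vertex_attr(g, "degree"),
               as.numeric(communication_efficiency(nw)))
  expect_equal(igraph::vertex_attr(g, "resno"), as.numeric(nw$resno))
  expect_error(export_graph(nw, f, format = "dot"), "unsupported")
  # empty network still writes a valid zero-edge file
  empty <- nw
  empty$neighbors[] <- FALSE
  empty$interactions[] <- FALSE
  empty$pathways <- list()
  f2 <- tempfile(fileext = ".graphml")
  export_graph(empty, f2)
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), 0)
})
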