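# PatchSet built by hand for rule-order tests.
manual_patchset <- function(areas) {
  patches <- lapply(seq_along(areas), function(k) {
    list(atoms = k, residues = k, area_A2 = areas[k],
         residue_area = stats::setNames(areas[k], k))
  })
  ord <- order(-areas)
  structure(list(patches = patches[ord], areas_A2 = sort(areas, decreasing = TRUE),
                 significance_threshold = 300, top_k = 5, probe = 0.14,
                 polar_expansion = 0.14, dot_density = 960,
                 significant = FALSE), class = "PatchSet")
}

test_that("a single nonpolar atom yields the full accessible sphere", {
  ph <- make_patch_phantom(data.frame(x = 0, y = 0, z = 0, radius = 0.17,
                                      polarity = "nonpolar", group = 1))
  ps <- find_patches(ph$structure)
  expect_equal(length(ps$patches), 1)
  expect_equal(ps$areas_A2, 4 * pi * 0.31^2 * 100, tolerance = 0.02)
  expect_equal(ps$areas_A2, ph$oracle$area_A2, tolerance = 0.02)
})

test_that("an all-polar layout produces no patches", {
  ph <- make_patch_phantom(data.frame(x = c(0, 0.3), y = 0, z = 0,
                                      radius = 0.152, polarity = "polar",
                                      group = NA))
  ps <- find_patches(ph$structure)
  expect_equal(length(ps$patches), 0)
  expect_equal(total_surface_hydrophobicity(ps), 0)
})

test_that("polar expansion masks adjacent nonpolar surface monotonically", {
  layout <- data.frame(x = c(0, 0.35), y = 0, z = 0,
                       radius = c(0.17, 0.152),
                       polarity = c("nonpolar", "polar"), group = c(1, NA))
  st <- make_patch_phantom(layout)$structure
  areas <- vapply(c(0, 0.07, 0.14, 0.25), function(pe) {
    sum(hydrophobic_dot_surface(st, polar_expansion = pe)$area_nm2)
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-12))
  expect_lt(areas[3], areas[1])
})

test_that("distant exposed atoms form separate patches", {
  layout <- data.frame(x = c(0, 2), y = 0, z = 0, radius = 0.17,
                       polarity = "nonpolar", group = c(1, 2))
  ps <- find_patches(make_patch_phantom(layout)$structure)
  expect_equal(length(ps$patches), 2)
})

test_that("planar phantom decomposition matches the numerical occlusion oracle", {
  ph <- make_patch_phantom()
  ps <- find_patches(ph$structure)
  expect_equal(length(ps$patches), nrow(ph$oracle))
  expect_equal(sort(ps$areas_A2), sort(ph$oracle$area_A2), tolerance = 0.02)
})

test_that("patch decomposition is invariant under rigid motion and atom order", {
  ph <- make_patch_phantom()
  ps <- find_patches(ph$structure)
  moved <- rigid_move(ph$structure, c(0.9, -0.4, 2.2), c(3, 1, -7))
  ps2 <- find_patches(moved)
  # patch count and membership are exactly invariant; areas only to the
  # quadrature error of the rotated dot lattice
  expect_equal(length(ps2$patches), length(ps$patches))
  expect_equal(sort(ps2$areas_A2), sort(ps$areas_A2), tolerance = 0.01)
  perm <- ph$structure
  set.seed(1)
  ord <- sample(nrow(perm$atoms))
  at <- perm$atoms[ord, c("name", "element", "resno", "resname", "chain",
                          "x", "y", "z")]
  perm2 <- new_structure(at)
  perm2$atoms$radius <- perm$atoms$radius[ord]
  perm2$atoms$polarity <- perm$atoms$polarity[ord]
  ps3 <- find_patches(perm2)
  expect_equal(sort(ps3$areas_A2), sort(ps$areas_A2), tolerance = 1e-6)
})

test_that("total patch area never exceeds total nonpolar SASA", {
  s <- make_sheet_pair(12)
  ps <- find_patches(s)
  nonpolar <- which(s$atoms$polarity == "nonpolar")
  tot <- sasa(s, atom_subset = nonpolar)
  expect_lte(sum(ps$areas_A2), sum(tot$per_atom) * 100 + 1e-6)
})

test_that("significance takes the top five first, then the 300 A^2 threshold", {
  ps <- significant_patches(manual_patchset(c(770, 580, 490, 420, 350, 200)))
  expect_equal(ps$areas_A2, c(770, 580, 490, 420, 350))
  expect_equal(total_surface_hydrophobicity(ps), 2610)
  expect_equal(length(significant_patches(manual_patchset(c(100, 50, 299)))$patches), 0)
  # six patches above threshold: exactly five retained
  six <- significant_patches(manual_patchset(c(900, 800, 700, 600, 500, 400)))
  expect_equal(length(six$patches), 5)
  expect_false(400 %in% six$areas_A2)
})

test_that("exposed IVL residues are counted once across significant patches", {
  # three exposed leucines in one patch, one buried isoleucine
  layout <- data.frame(
    x = c(0, 0.32, 0.64, 5), y = 0, z = 0, radius = 0.17,
    polarity = "nonpolar", group = c(1, 1, 1, 2))
  ph <- make_patch_phantom(layout)
  st <- ph$structure
  st$atoms$resname <- c("LEU", "LEU", "LEU", "ILE")
  st$residues$resname <- c("LEU", "LEU", "LEU", "ILE")
  ps <- find_patches(st, significance_threshold = 100)
  # only the 3-atom patch is significant at 100 A^2? both are; drop the
  # isolated one by area threshold above a single sphere (~121 A^2)
  ps_sig <- significant_patches(find_patches(st, significance_threshold = 200))
  expect_equal(exposed_ivl_count(ps_sig, st), 3)
  none <- st
  none$residues$resname <- "ALA"
  expect_equal(exposed_ivl_count(ps_sig, none), 0)
})

test_that("EHSC attributes patch area to transition-event classes", {
  ps <- significant_patches(manual_patchset(c(400, 400)))
  ev1 <- data.frame(residue = 1:2, native = "H", modal = "C",
                    event = factor(rep("alpha_to_coil", 2),
                                   levels = unfoldscape:::TRANSITION_EVENTS))
  out <- ehsc(ps, ev1)
  expect_equal(unname(out["alpha_to_coil"]), 1)
  expect_equal(sum(out), 1)
  ev2 <- ev1
  ev2$event <- factor(c("alpha_to_beta", "unchanged"),
                      levels = unfoldscape:::TRANSITION_EVENTS)
  out2 <- ehsc(ps, ev2)
  expect_equal(unname(out2["alpha_to_beta"]), 0.5)
  expect_equal(unname(out2["unchanged"]), 0.5)
  # random areas: class fractions equal a direct per-class re-summation
  set.seed(6)
  areas <- round(runif(5, 310, 900))
  ps3 <- significant_patches(manual_patchset(areas))
  evs <- sample(unfoldscape:::TRANSITION_EVENTS, 5, replace = TRUE)
  ev3 <- data.frame(residue = 1:5, native = "H", modal = "C",
                    event = factor(evs, levels = unfoldscape:::TRANSITION_EVENTS))
  out3 <- ehsc(ps3, ev3)
  direct <- tapply(areas, factor(evs, levels = unfoldscape:::TRANSITION_EVENTS),
                   sum, default = 0) / sum(areas)
  expect_equal(as.numeric(out3), as.numeric(direct))
  expect_error(ehsc(ps3, ev3[1:3, ]), "cover")
})

test_that("motif exposure averages accessible area per residue", {
  iso <- make_patch_phantom(data.frame(x = 0, y = 0, z = 0, radius = 0.17,
                                       polarity = "nonpolar", group = 1))$structure
  standalone <- sasa(iso)$total * 100
  expect_equal(motif_exposure(iso, list(m1 = 1)), standalone, tolerance = 1e-9)
  expect_error(motif_exposure(iso, list()), "empty")
  # two-motif fixture equals a direct recomputation
  s <- make_sheet_pair(10)
  motifs <- list(m1 = c(2, 3), m2 = c(8, 9))
  got <- motif_exposure(s, motifs)
  atoms <- which(s$atoms$residue_index %in% c(2, 3, 8, 9))
  direct <- sum(sasa(s, atom_subset = atoms)$per_atom) * 100 / 4
  expect_equal(got, direct)
})

test_that("patch reports serialize with per-residue contributions", {
  ph <- make_patch_phantom()
  ps <- find_patches(ph$structure)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_patch_report(ps, ph$structure, f1, f2)
  tab <- read.delim(f1)
  expect_equal(nrow(tab), length(ps$patches))
  rr <- read.delim(f2)
  expect_equal(sum(rr$area_A2), sum(ps$areas_A2), tolerance = 1e-6)
})
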