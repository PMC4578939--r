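# Structure and Trajectory containers plus PDB / trajectory I/O.
#
# Internal units are nm throughout; PDB I/O converts from/to Angstrom.
# Residues are indexed 1..n_residues internally (sequential over chains);
# the author/PDB numbering is kept in `resno` and used in all reports.

SOLVENT_RESNAMES <- c("WAT", "HOH", "SOL", "TIP3", "TIP3P", "SPC", "T3P")

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", HSD = "H", HSE = "H", HSP = "H", HID = "H",
  HIE = "H", HIP = "H", CYX = "C", MSE = "M"
)

#' Construct a Structure object
#'
#' A `Structure` holds an atom table (coordinates in nm, van der Waals radii,
#' polarity class) and a residue table. Most users will obtain one from
#' [read_structure()] or from the synthetic generators; this constructor is
#' exposed for programmatic building.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`
#'   (author/PDB residue number), `resname`, `chain`, `x`, `y`, `z` (nm).
#'   Optional columns `radius` (nm), `polarity`, `is_solvent`, `is_hetero`
#'   are filled in when absent.
#' @param radii_file optional path to a radii table (see [load_radii()]);
#'   `NULL` uses the shipped set.
#' @return an object of class `Structure` with elements `atoms` (data.frame,
#'   one row per atom with `residue_index` added) and `residues` (data.frame
#'   with `residue_index`, `resno`, `resname`, `chain`, `aa1`).
#' @export
new_structure <- function(atoms, radii_file = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "resno", "resname", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$is_solvent)) atoms$is_solvent <- atoms$resname %in% SOLVENT_RESNAMES
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  # sequential residue index over (chain, resno) in file order
  key <- paste(atoms$chain, atoms$resno, atoms$resname, sep = "\r")
  atoms$residue_index <- match(key, unique(key))
  residues <- atoms[!duplicated(atoms$residue_index),
                    c("residue_index", "resno", "resname", "chain")]
  rownames(residues) <- NULL
  residues$aa1 <- unname(AA3_TO_1[residues$resname])
  residues$aa1[is.na(residues$aa1)] <- "X"
  s <- structure(list(atoms = atoms, residues = residues), class = "Structure")
  if (is.null(atoms$radius)) s <- assign_radii(s, radii_file)
  if (is.null(atoms$polarity)) s$atoms$polarity <- classify_atom_polarity(s)
  s
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain)),
              if (any(x$atoms$is_solvent)) sprintf(" (+%d solvent atoms)",
                                                   sum(x$atoms$is_solvent)) else ""))
  invisible(x)
}

#' Number of protein (non-solvent) residues in a Structure
#' @param structure a `Structure`.
#' @return integer count.
#' @export
n_residues <- function(structure) {
  sum(!structure$residues$resname %in% SOLVENT_RESNAMES)
}

#' One-letter sequence per chain
#' @param structure a `Structure`.
#' @return named character vector, one string per chain.
#' @export
chain_sequences <- function(structure) {
  res <- structure$residues
  res <- res[!res$resname %in% SOLVENT_RESNAMES, ]
  vapply(split(res$aa1, res$chain), paste0, character(1), collapse = "")
}

#' Load a van der Waals radii table
#'
#' Radii tables are two-column whitespace-separated text files
#' (`pattern` `radius_nm`), where `pattern` is an element symbol. Two sets
#' ship with the package: `"bondi"` (all-atom, Bondi 1964 values) and
#' `"united"` (heavy-atom/united-atom values for structures without
#' hydrogens).
#'
#' @param file path to a radii file, or one of `"bondi"`, `"united"`.
#' @return named numeric vector of radii (nm) keyed by element symbol.
#' @export
load_radii <- function(file = "bondi") {
  if (file %in% c("bondi", "united")) {
    file <- system.file("extdata", paste0("vdw_radii_", file, ".tsv"),
                        package = "unfoldscape", mustWork = TRUE)
  }
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(tab$radius_nm, toupper(tab$pattern))
}

#' Assign van der Waals radii to every atom of a Structure
#'
#' When the structure contains no hydrogens the united-atom set is used so
#' that heavy atoms implicitly absorb their hydrogens' volume; otherwise the
#' all-atom Bondi set. A custom table overrides both.
#'
#' @param structure a `Structure`.
#' @param radii_file optional custom radii table path.
#' @return the structure with `atoms$radius` filled (nm).
#' @export
assign_radii <- function(structure, radii_file = NULL) {
  has_h <- any(structure$atoms$element == "H")
  radii <- if (!is.null(radii_file)) load_radii(radii_file)
           else load_radii(if (has_h) "bondi" else "united")
  r <- radii[toupper(structure$atoms$element)]
  if (anyNA(r)) {
    bad <- unique(structure$atoms$element[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  structure$atoms$radius <- unname(r)
  structure
}

#' Classify atom polarity for hydrophobic-surface analysis
#'
#' Carbon and sulfur are nonpolar; nitrogen and oxygen polar. Hydrogens
#' inherit the class of their bonded heavy atom, with the bond inferred as
#' the nearest heavy atom within the same residue.
#'
#' @param structure a `Structure`.
#' @param atom_index optional indices; default all atoms.
#' @return character vector `"polar"`/`"nonpolar"`.
#' @export
classify_atom_polarity <- function(structure, atom_index = NULL) {
  at <- structure$atoms
  if (is.null(atom_index)) atom_index <- seq_len(nrow(at))
  el <- toupper(at$element)
  pol <- rep(NA_character_, nrow(at))
  pol[el %in% c("C", "S")] <- "nonpolar"
  pol[el %in% c("N", "O", "P")] <- "polar"
  h_idx <- which(el == "H")
  if (length(h_idx)) {
    heavy <- which(el != "H")
    hxyz <- as.matrix(at[h_idx, c("x", "y", "z")])
    for (k in seq_along(h_idx)) {
      i <- h_idx[k]
      cand <- heavy[at$residue_index[heavy] == at$residue_index[i]]
      if (!length(cand)) cand <- heavy
      d2 <- colSums((t(as.matrix(at[cand, c("x", "y", "z")])) - hxyz[k, ])^2)
      pol[i] <- pol[cand[which.min(d2)]]
    }
  }
  unknown <- unique(el[is.na(pol)])
  if (length(unknown)) {
    stop("cannot classify polarity of element(s): ", paste(unknown, collapse = ", "))
  }
  pol[atom_index]
}

#' Read a structure from a PDB file
#'
#' Coordinates are converted from Angstrom to nm. Waters and hetero groups
#' are flagged; alternate locations are resolved to the highest occupancy
#' (ties to altloc "A").
#'
#' @param file path to a PDB file.
#' @param keep_solvent keep water/solvent records (default TRUE; they are
#'   flagged, not dropped, so hydrogen-bond analyses can see them).
#' @param radii_file optional custom radii table.
#' @return a `Structure`.
#' @export
read_structure <- function(file, keep_solvent = TRUE, radii_file = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB '", file, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in '", file, "'")
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1]
    stop("non-numeric coordinate in record ", bad, " (atom ", at$eleno[bad], ")")
  }
  # resolve alternate locations: keep highest occupancy, tie -> altloc "A"
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
    ord <- order(key, -occ, alt)
    at2 <- at[ord, ]
    keep <- !duplicated(paste(at2$chain, at2$resno, at2$resid, at2$elety, sep = "\r"))
    at <- at2[keep, ][order(at2$eleno[keep]), ]
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) el <- rep(NA_character_, nrow(at))
  guess <- guess_element(at$elety)
  el <- ifelse(is.na(el) | el == "", guess, toupper(trimws(el)))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    name = trimws(at$elety), element = el, resno = at$resno,
    resname = toupper(trimws(at$resid)), chain = chain,
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$is_solvent <- atoms$resname %in% SOLVENT_RESNAMES
  if (!keep_solvent) atoms <- atoms[!atoms$is_solvent, ]
  if (nrow(atoms) == 0) stop("no atoms left after solvent filtering in '", file, "'")
  new_structure(atoms, radii_file = radii_file)
}

#' @keywords internal
guess_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  el <- substr(nm, 1, 1)
  # digit-led hydrogen names (1HB2 etc.)
  lead_digit <- grepl("^[0-9]", nm)
  el[lead_digit] <- substr(sub("^[0-9]+", "", nm[lead_digit]), 1, 1)
  el[el == ""] <- "C"
  el
}

#' Write a Structure (or one frame) to a PDB file
#'
#' @param structure a `Structure`.
#' @param file output path.
#' @param xyz optional coordinate override: numeric vector of length
#'   3 * n_atoms (nm, bio3d ordering) or an n_atoms x 3 matrix.
#' @return the file path, invisibly.
#' @export
write_structure <- function(structure, file, xyz = NULL) {
  at <- structure$atoms
  coords <- if (is.null(xyz)) c(t(as.matrix(at[, c("x", "y", "z")]))) else
    if (is.matrix(xyz)) c(t(xyz)) else as.numeric(xyz)
  bio3d::write.pdb(file = file, xyz = coords * 10,
                   type = ifelse(at$is_hetero, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = at$chain, elesy = at$element)
  invisible(file)
}

#' Construct a Trajectory object
#'
#' @param topology a `Structure`.
#' @param xyz numeric matrix, one row per frame, 3 * n_atoms columns in
#'   bio3d ordering (x1, y1, z1, x2, ...), nm.
#' @param frame_interval_ps time between saved frames (ps).
#' @param temperature simulation temperature label (K).
#' @param label free-text trajectory label.
#' @return an object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, xyz, frame_interval_ps = 10,
                           temperature = 310, label = "") {
  stopifnot(inherits(topology, "Structure"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology$atoms)) {
    stop("frame atom count mismatch: expected ", nrow(topology$atoms),
         " atoms (", 3 * nrow(topology$atoms), " coordinates), found ",
         ncol(xyz) / 3, " atoms per frame")
  }
  stopifnot(frame_interval_ps > 0, temperature > 0)
  structure(list(topology = topology, xyz = xyz,
                 frame_interval_ps = frame_interval_ps,
                 temperature = temperature, label = label),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames x %d atoms, dt = %g ps, T = %g K\n",
              x$label, nrow(x$xyz), ncol(x$xyz) / 3,
              x$frame_interval_ps, x$temperature))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory a `Trajectory`.
#' @return integer.
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Coordinates of one frame as an n_atoms x 3 matrix (nm)
#' @param trajectory a `Trajectory`.
#' @param i frame index.
#' @return matrix.
#' @export
frame_coords <- function(trajectory, i) {
  matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Read a conformational ensemble into a Trajectory
#'
#' Supports multi-model PDB (`format = "pdb"`) and the DCD binary trajectory
#' format (`format = "dcd"`). Frames retain file order.
#'
#' @param topology a `Structure` matching the frames' atom count.
#' @param source path to the coordinate file.
#' @param format `"pdb"` or `"dcd"`; default guessed from the extension.
#' @param frame_interval_ps,temperature,label trajectory metadata.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(topology, source, format = NULL,
                            frame_interval_ps = 10, temperature = 310,
                            label = basename(source)) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(source))
    if (format == "") format <- "pdb"
  }
  xyz <- switch(tolower(format),
    pdb = {
      pdb <- bio3d::read.pdb(source, multi = TRUE, verbose = FALSE)
      m <- pdb$xyz
      if (!is.matrix(m)) m <- matrix(m, nrow = 1)
      m / 10
    },
    dcd = bio3d::read.dcd(source, verbose = FALSE) / 10,
    stop("unsupported trajectory format: ", format))
  new_trajectory(topology, xyz, frame_interval_ps, temperature, label)
}

#' Write a Trajectory as a multi-model PDB
#'
#' @param trajectory a `Trajectory`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_trajectory <- function(trajectory, file) {
  at <- trajectory$topology$atoms
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(trajectory, f) * 10
    lines <- sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$is_hetero, "HETATM", "ATOM"), seq_len(nrow(at)),
      ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name), "",
      at$resname, at$chain, at$resno, "",
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Atom selection helpers
#'
#' @param structure a `Structure`.
#' @return integer atom indices.
#' @export
select_calpha <- function(structure) {
  which(structure$atoms$name == "CA" & !structure$atoms$is_solvent)
}

#' @rdname select_calpha
#' @export
select_heavy <- function(structure) {
  which(structure$atoms$element != "H" & !structure$atoms$is_solvent)
}

#' @rdname select_calpha
#' @export
select_sidechain <- function(structure) {
  bb <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3", "HN")
  which(!structure$atoms$name %in% bb & structure$atoms$element != "H" &
          !structure$atoms$is_solvent)
}

#' @rdname select_calpha
#' @export
select_backbone <- function(structure) {
  which(structure$atoms$name %in% c("N", "CA", "C", "O") &
          !structure$atoms$is_solvent)
}
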