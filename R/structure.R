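# Extraction of transmembrane cross-section outlines from protein
# structures, and a seeded generator of synthetic PDB fixtures so the test
# suite never needs a network connection.

APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "PRO", "GLY")
SOLVENT_RESIDUES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")

#' Read heavy atoms from a PDB file
#'
#' Parses a PDB file with [bio3d::read.pdb()], keeps heavy (non-hydrogen)
#' atoms of ATOM/HETATM records excluding solvent, converts coordinates
#' from Angstrom to nm, and returns a plain atom table. Multi-model files
#' contribute model 1 only.
#'
#' @param path path to a PDB file.
#' @return data.frame with columns `element`, `x`, `y`, `z` (nm), `chain`,
#'   `resid`, `record`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("could not parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                substr(trimws(a$elety), 1, 1), a$elesy)))
  keep <- elem != "H" & elem != "D" & !(toupper(a$resid) %in% SOLVENT_RESIDUES)
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("empty structure: no heavy non-solvent atoms in '", path, "'")
  data.frame(element = elem[keep],
             x = a$x / 10, y = a$y / 10, z = a$z / 10,
             chain = a$chain, resid = a$resid, record = a$type)
}

#' Suggest the hydrophobic-belt center along z
#'
#' Median z of apolar-residue atoms: a simple proxy for the center of the
#' transmembrane hydrophobic belt of a membrane protein deposited with the
#' pore axis along z.
#'
#' @param atoms an atom table from [read_structure()].
#' @return z center (nm).
#' @export
hydrophobic_slab_center <- function(atoms) {
  sel <- toupper(atoms$resid) %in% APOLAR_RESIDUES
  if (!any(sel)) sel <- rep(TRUE, nrow(atoms))
  stats::median(atoms$z[sel])
}

#' Angular outline of a transmembrane slab
#'
#' Shrink-wrap silhouette of the cross section: atoms inside the z slab
#' are binned by polar angle about the slab centroid and each bin records
#' its maximum radial distance plus a probe radius. A convex hull would
#' erase the non-convex lobes of clover-leaf shapes, which is exactly the
#' feature of interest, hence the per-bin maximum. Empty bins are filled
#' by circular linear interpolation from their populated neighbors.
#'
#' @param atoms an atom table from [read_structure()].
#' @param z_center slab center (nm).
#' @param z_halfwidth slab half width (nm).
#' @param n_bins number of angular bins.
#' @param probe probe radius added to the atomic silhouette (nm).
#' @param center recenter the slab on its atomic centroid before binning
#'   (default TRUE); set FALSE when the pore axis is already at the origin.
#' @return data.frame with columns `theta` (bin centers, rad) and `r` (nm).
#' @export
transmembrane_outline <- function(atoms, z_center, z_halfwidth,
                                  n_bins = 120L, probe = 0.2, center = TRUE) {
  n_bins <- as.integer(n_bins)
  sel <- abs(atoms$z - z_center) <= z_halfwidth
  if (!any(sel)) stop("outline extraction failed: the z slab contains no atoms")
  x <- atoms$x[sel] - if (center) mean(atoms$x[sel]) else 0
  y <- atoms$y[sel] - if (center) mean(atoms$y[sel]) else 0
  th <- atan2(y, x) %% (2 * pi)
  rr <- sqrt(x^2 + y^2)
  bin <- pmin(floor(th / (2 * pi / n_bins)) + 1L, n_bins)
  rmax <- rep(NA_real_, n_bins)
  agg <- tapply(rr, bin, max)
  rmax[as.integer(names(agg))] <- agg
  n_empty <- sum(is.na(rmax))
  if (n_empty > n_bins / 2)
    stop("outline extraction failed: ", n_empty, " of ", n_bins,
         " angular bins are empty")
  if (n_empty > 0L) {
    # circular linear interpolation across empty runs
    idx <- which(!is.na(rmax))
    ext_x <- c(idx - n_bins, idx, idx + n_bins)
    ext_y <- rep(rmax[idx], 3)
    rmax <- stats::approx(ext_x, ext_y, xout = seq_len(n_bins))$y
  }
  data.frame(theta = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
             r = rmax + probe)
}

#' Boundary shape from a protein structure
#'
#' Composition of [read_structure()], [transmembrane_outline()] and
#' [fit_fourier()]: extracts the transmembrane silhouette of a structure
#' and fits the low-order Fourier boundary model used by the elastic
#' solver. Provenance (file, slab, probe, fit residual) is recorded in the
#' shape metadata.
#'
#' @param path PDB file path.
#' @param z_center slab center (nm); default: [hydrophobic_slab_center()].
#' @param z_halfwidth slab half width (nm).
#' @param n_bins angular bins for the outline.
#' @param probe probe radius (nm).
#' @param n_max highest harmonic fitted.
#' @return a [boundary_shape()].
#' @export
shape_from_structure <- function(path, z_center = NULL, z_halfwidth = 1.25,
                                 n_bins = 120L, probe = 0.2, n_max = 8L) {
  atoms <- read_structure(path)
  if (is.null(z_center)) z_center <- hydrophobic_slab_center(atoms)
  outl <- transmembrane_outline(atoms, z_center, z_halfwidth, n_bins, probe)
  shape <- fit_fourier(outl$theta, outl$r, n_max)
  shape$meta$source_file <- path
  shape$meta$z_center_nm <- z_center
  shape$meta$z_halfwidth_nm <- z_halfwidth
  shape$meta$probe_nm <- probe
  shape
}

#' Generate a synthetic transmembrane structure fixture
#'
#' Writes a minimal synthetic PDB file with carbon atoms scattered on a
#' radially modulated ring inside a z slab, emulating the transmembrane
#' belt of an oligomeric channel with the cross section of `shape`. Atoms
#' sit at radius `r_b(theta) * (1 - d)` with `d` uniform in
#' `[0, inward_depth]`, so the per-bin maximum recovers the boundary up to
#' a small inward bias. Intended for tests and demonstrations; clearly
#' synthetic, not a deposited structure.
#'
#' @param path output PDB path.
#' @param shape a [boundary_shape()] for the ring modulation.
#' @param n_atoms number of atoms.
#' @param z_halfwidth slab half width (nm); atoms get z uniform in the slab.
#' @param inward_depth fractional depth of the atom layer below the
#'   boundary (default 0.04).
#' @param seed RNG seed for reproducible fixtures.
#' @return the path, invisibly.
#' @export
write_synthetic_structure <- function(path, shape, n_atoms = 2000L,
                                      z_halfwidth = 1.25, inward_depth = 0.04,
                                      seed = 1L) {
  stopifnot(inherits(shape, "boundary_shape"))
  set.seed(seed)
  th <- stats::runif(n_atoms, 0, 2 * pi)
  rb <- radius_profile(shape, th)
  r <- rb * (1 - stats::runif(n_atoms, 0, inward_depth))
  x <- r * cos(th) * 10          # nm -> Angstrom
  y <- r * sin(th) * 10
  z <- stats::runif(n_atoms, -z_halfwidth, z_halfwidth) * 10
  lines <- sprintf(paste0("ATOM  %5d  CA  LEU A%4d    %8.3f%8.3f%8.3f",
                          "  1.00  0.00           C"),
                   seq_len(n_atoms), ((seq_len(n_atoms) - 1L) %% 9999L) + 1L,
                   x, y, z)
  writeLines(c("REMARK   synthetic ring fixture (not a deposited structure)",
               lines, "END"), path)
  invisible(path)
}
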