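# Synthetic input generators: every test in this package runs on
# fixtures built here, with zero network access. Toy "protein" atoms are
# random C/N/O points in a compact blob — geometry, not chemistry, is
# under test.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

# fractional placement region strictly inside the asymmetric unit of
# every registered group: no operator maps it onto itself, so symmetry
# mates of its content never collide
.asym_region <- c(0.03, 0.22)

#' Generate a toy asymmetric unit as an mmCIF file
#'
#' Writes a small synthetic crystal structure: random C/N/O "protein"
#' atoms (one atom per residue, chain A) inside a fractional region
#' chosen so that symmetry mates cannot clash, plus optional
#' crystallographic waters, ions, alternative conformations and
#' numbering gaps. Deterministic for a fixed seed.
#'
#' @param path Output mmCIF path.
#' @param n_atoms Number of polymer atoms (= residues).
#' @param cell A [cell_parameters()] object.
#' @param space_group Hermann-Mauguin name (must be registered).
#' @param seed RNG seed.
#' @param waters Number of water (HOH) residues.
#' @param ions Named integer vector/list of monatomic ions, e.g.
#'   `c(MG = 2)`.
#' @param altlocs Number of residues receiving A/B alternative
#'   conformations (occupancies 0.6/0.4).
#' @param gaps Number of single-residue numbering gaps to introduce.
#' @return `path`, invisibly.
#' @export
make_toy_asymmetric_unit <- function(path, n_atoms = 20,
                                     cell = cell_parameters(30, 30, 30),
                                     space_group = "P 1", seed = 1,
                                     waters = 0, ions = c(), altlocs = 0,
                                     gaps = 0) {
  symmetry_operations_for_group(space_group)   # errors early if unsupported
  stopifnot(n_atoms >= 1, waters >= 0, altlocs >= 0, gaps >= 0,
            altlocs <= n_atoms)
  A <- orthogonalization_matrix(cell)
  total <- n_atoms + waters + sum(unlist(ions))
  frac <- with_seed(seed, matrix(stats::runif(3 * total, .asym_region[1],
                                              .asym_region[2]),
                                 ncol = 3))
  xyz <- frac %*% t(A)
  elements <- with_seed(seed + 1, sample(c("C", "N", "O"), n_atoms,
                                         replace = TRUE))
  resnames <- with_seed(seed + 2, sample(c("ALA", "GLY", "SER", "ASP", "GLU",
                                           "HIS", "LYS", "ARG", "CYS", "TYR"),
                                         n_atoms, replace = TRUE))
  resid <- seq_len(n_atoms)
  if (gaps > 0) {
    # shift residue numbering upward after interior positions -> gaps
    pos <- round(seq(0.3, 0.7, length.out = gaps) * n_atoms)
    for (p in pos) resid[resid > p] <- resid[resid > p] + 1L
  }
  rows <- data.frame(group = "ATOM", element = elements,
                     name = paste0(elements, "A"),
                     altloc = ".", resname = resnames, chain = "A",
                     resid = resid, occ = 1,
                     x = xyz[seq_len(n_atoms), 1],
                     y = xyz[seq_len(n_atoms), 2],
                     z = xyz[seq_len(n_atoms), 3],
                     stringsAsFactors = FALSE)
  if (altlocs > 0) {
    for (k in seq_len(altlocs)) {
      rows$altloc[k] <- "A"
      rows$occ[k] <- 0.6
      alt <- rows[k, ]
      alt$altloc <- "B"; alt$occ <- 0.4
      alt$x <- alt$x + 0.3
      rows <- rbind(rows, alt)
    }
  }
  nxt <- n_atoms
  extra_res <- max(resid)
  if (waters > 0) {
    wsel <- nxt + seq_len(waters)
    rows <- rbind(rows, data.frame(
      group = "HETATM", element = "O", name = "O", altloc = ".",
      resname = "HOH", chain = "S", resid = extra_res + seq_len(waters),
      occ = 1, x = xyz[wsel, 1], y = xyz[wsel, 2], z = xyz[wsel, 3],
      stringsAsFactors = FALSE))
    nxt <- nxt + waters
    extra_res <- extra_res + waters
  }
  for (sp in names(ions)) {
    cnt <- ions[[sp]]
    if (cnt == 0) next
    isel <- nxt + seq_len(cnt)
    rows <- rbind(rows, data.frame(
      group = "HETATM", element = toupper(sp), name = toupper(sp),
      altloc = ".", resname = toupper(sp), chain = "I",
      resid = extra_res + seq_len(cnt), occ = 1,
      x = xyz[isel, 1], y = xyz[isel, 2], z = xyz[isel, 3],
      stringsAsFactors = FALSE))
    nxt <- nxt + cnt
    extra_res <- extra_res + cnt
  }
  write_toy_mmcif(rows, cell, space_group, path)
  invisible(path)
}

write_toy_mmcif <- function(rows, cell, space_group, path) {
  hdr <- c(
    "data_toy",
    "#",
    sprintf("_cell.length_a    %.4f", cell$a),
    sprintf("_cell.length_b    %.4f", cell$b),
    sprintf("_cell.length_c    %.4f", cell$c),
    sprintf("_cell.angle_alpha %.4f", cell$alpha),
    sprintf("_cell.angle_beta  %.4f", cell$beta),
    sprintf("_cell.angle_gamma %.4f", cell$gamma),
    sprintf("_symmetry.space_group_name_H-M '%s'", space_group),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.occupancy",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.pdbx_PDB_model_num")
  body <- sprintf("%-6s %5d %-2s %-4s %s %-3s %s %5d %5.2f %9.3f %9.3f %9.3f 1",
                  rows$group, seq_len(nrow(rows)), rows$element, rows$name,
                  rows$altloc, rows$resname, rows$chain, rows$resid,
                  rows$occ, rows$x, rows$y, rows$z)
  writeLines(c(hdr, body, "#"), path)
}

# composition of the three published validation crystals; cells are
# synthetic placeholders (the deposited files are not bundled), the het
# content matches the deposited entries
.reference_systems <- list(
  `1EAY` = list(space_group = "P 21 21 21",
                cell = c(50, 60, 130, 90, 90, 90),
                waters = 124, ions = c()),
  `2IS4` = list(space_group = "P 1 21 1",
                cell = c(90, 100, 110, 90, 95, 90),
                waters = 118, ions = c(MG = 2)),
  `3BCF` = list(space_group = "C 1 2 1",
                cell = c(120, 70, 85, 90, 105, 90),
                waters = 256, ions = c(CA = 4, "NA" = 1)))

#' Synthetic stand-in for a published validation crystal
#'
#' Writes a synthetic mmCIF whose space group and crystallographic
#' water/ion content mirror one of the three deposited structures the
#' workflow was validated on (1EAY: 124 waters, P 21 21 21; 2IS4: 2 Mg
#' and 118 waters, P 1 21 1; 3BCF: 4 Ca, 1 Na and 256 waters, C 1 2 1).
#' These are stand-ins, not the deposited files: coordinates and cell
#' constants are synthetic; only the hetero composition and symmetry
#' are faithful. They let the parsing and classification pipeline be
#' exercised fully offline.
#'
#' @param id One of `"1EAY"`, `"2IS4"`, `"3BCF"`.
#' @param path Output mmCIF path.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
synthetic_reference_crystal <- function(id, path, seed = 1) {
  id <- toupper(id)
  if (!id %in% names(.reference_systems))
    stop("unknown reference system: ", id, call. = FALSE)
  ref <- .reference_systems[[id]]
  make_toy_asymmetric_unit(path, n_atoms = 25,
                           cell = as_cell(ref$cell),
                           space_group = ref$space_group, seed = seed,
                           waters = ref$waters, ions = ref$ions)
}

#' Generate a synthetic box-vector trajectory table
#'
#' Writes the plain-text box table consumed by [read_box_series()]: one
#' frame per row, columns `a b c alpha beta gamma`. Frames carry
#' multiplicative volume noise: each frame's volume is the target volume
#' times `(1 + eps)` with `eps` uniform on
#' `(-sqrt(3) * relative_noise, +sqrt(3) * relative_noise)` (standard
#' deviation exactly `relative_noise`), implemented by scaling all three
#' lengths by `(1 + eps)^(1/3)` with angles fixed. The sample mean
#' volume therefore converges to the target at rate
#' `relative_noise / sqrt(n_frames)`. Deterministic for a fixed seed.
#'
#' @param path Output path.
#' @param n_frames Number of frames (>= 1).
#' @param mean_cell Target [cell_parameters()].
#' @param relative_noise Relative volume noise (>= 0).
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
make_volume_trajectory <- function(path, n_frames, mean_cell,
                                   relative_noise = 0.003, seed = 1) {
  stopifnot(n_frames >= 1, relative_noise >= 0)
  mean_cell <- as_cell(mean_cell)
  eps <- with_seed(seed, stats::runif(n_frames, -sqrt(3) * relative_noise,
                                      sqrt(3) * relative_noise))
  f <- (1 + eps)^(1 / 3)
  lines <- sprintf("%.8f %.8f %.8f %.4f %.4f %.4f",
                   mean_cell$a * f, mean_cell$b * f, mean_cell$c * f,
                   mean_cell$alpha, mean_cell$beta, mean_cell$gamma)
  writeLines(c("# a b c alpha beta gamma (Angstrom, degrees)", lines), path)
  invisible(path)
}

#' Random valid unit cell
#'
#' Draws lattice constants uniformly (lengths 10-100 Angstrom, angles
#' 60-120 degrees), rejecting geometrically impossible combinations;
#' used by property tests.
#'
#' @param seed Optional seed.
#' @return A [cell_parameters()] object.
#' @export
random_cell <- function(seed = NULL) {
  draw <- function() {
    lens <- stats::runif(3, 10, 100)
    angs <- stats::runif(3, 60, 120)
    cell <- base::structure(list(a = lens[1], b = lens[2], c = lens[3],
                                 alpha = angs[1], beta = angs[2],
                                 gamma = angs[3]),
                            class = "xtal_cell")
    if (cell_radicand(cell) > 1e-4) cell else NULL
  }
  gen <- function() {
    repeat {
      cell <- draw()
      if (!is.null(cell)) return(cell)
    }
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
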