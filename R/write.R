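# Coordinate file output (PDB / GRO) and GRO reading. Internally all
# coordinates are Cartesian Angstrom; conversion to nm happens only at
# write time, because the crystallographic transformations operate in
# Angstrom.

# output ordering expected by downstream topology generation:
# polymer chains first (original order), then ligands, ions, waters
order_for_output <- function(atoms) {
  rank <- match(atoms$het_class, c("polymer", "ligand", "ion", "water"))
  atoms[order(rank, seq_len(nrow(atoms))), , drop = FALSE]
}

#' Rotate a structure into the MD box frame
#'
#' Crystal building happens in the orthogonalization-matrix frame; MD
#' engines require the triclinic convention with the first box vector
#' along x and the second in the xy plane. This helper re-expresses all
#' coordinates in that frame (via fractional coordinates) and attaches
#' the lower-triangular box.
#'
#' @param structure An [xtal_structure()] with cell metadata.
#' @return The structure with rotated coordinates and attribute `box`
#'   (3x3 lower-triangular matrix in Angstrom, rows are box vectors).
#' @export
md_frame <- function(structure) {
  if (is.null(structure$cell))
    stop("structure carries no cell parameters", call. = FALSE)
  A <- orthogonalization_matrix(structure$cell)
  B <- t(cell_to_box(structure$cell))      # columns are box vectors
  xyz <- atom_xyz(structure)
  frac <- t(solve(A) %*% t(xyz))
  structure <- set_atom_xyz(structure, frac %*% t(B))
  attr(structure, "box") <- cell_to_box(structure$cell)
  structure
}

#' Write simulation-ready coordinates
#'
#' Writes a structure plus box vectors as a GRO or PDB file. Atoms are
#' reordered as polymer, ligands, ions, waters. GRO positions are
#' converted Angstrom to nm; the box record is emitted in nm for GRO and
#' as a CRYST1 record for PDB. PDB serial numbers are limited to 99,999;
#' larger systems must be written as GRO (the error says so rather than
#' silently wrapping serials).
#'
#' @param structure An [xtal_structure()].
#' @param box 3x3 matrix of box vectors (rows) in nm; lower-triangular
#'   per the MD convention.
#' @param path Output file path.
#' @param format `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(structure, box, path, format = c("gro", "pdb")) {
  format <- match.arg(format)
  if (nrow(structure$atoms) == 0L) stop("structure is empty", call. = FALSE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == 3L, ncol(box) == 3L)
  atoms <- order_for_output(structure$atoms)
  if (format == "gro") write_gro(atoms, box, path) else write_pdb(atoms, box, path)
  invisible(path)
}

write_gro <- function(atoms, box_nm, path) {
  n <- nrow(atoms)
  # renumber residues sequentially in output order (gro has no chain field;
  # chain identity survives through residue numbering blocks)
  resk <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "\r")
  resnum <- match(resk, unique(resk))
  lines <- character(n + 3L)
  lines[1] <- "generated by xtalmd"
  lines[2] <- sprintf("%5d", n)
  xyz_nm <- as.matrix(atoms[, c("x", "y", "z")]) / 10
  lines[3:(n + 2L)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                               resnum %% 100000L,
                               substr(atoms$resname, 1, 5),
                               substr(atoms$name, 1, 5),
                               atoms$serial %% 100000L,
                               xyz_nm[, 1], xyz_nm[, 2], xyz_nm[, 3])
  full <- c(box_nm[1, 1], box_nm[2, 2], box_nm[3, 3],
            box_nm[1, 2], box_nm[1, 3], box_nm[2, 1],
            box_nm[2, 3], box_nm[3, 1], box_nm[3, 2])
  if (max(abs(full[4:9])) < 5e-6) full <- full[1:3]
  lines[n + 3L] <- paste(sprintf("%10.5f", full), collapse = "")
  writeLines(lines, path)
}

write_pdb <- function(atoms, box_nm, path) {
  n <- nrow(atoms)
  if (n > 99999L)
    stop("PDB format cannot hold more than 99,999 atom serials; ",
         "write this system in GRO format instead", call. = FALSE)
  cell <- box_to_cell(box_nm, unit = "nm")
  lines <- character(n + 2L)
  lines[1] <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  rec <- ifelse(atoms$het_class == "polymer", "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(atoms$name) <= 3,
                  sprintf(" %-3s", atoms$name), substr(atoms$name, 1, 4))
  lines[2:(n + 1L)] <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, atoms$serial, name4, substr(atoms$altloc, 1, 1),
    substr(atoms$resname, 1, 3), substr(atoms$chain, 1, 1),
    atoms$resid %% 10000L, atoms$x, atoms$y, atoms$z,
    atoms$occupancy, 0, substr(atoms$element, 1, 2))
  lines[n + 2L] <- "END"
  writeLines(lines, path)
}

#' Read a GRO coordinate file
#'
#' Reads a single-frame GRO file back into an [xtal_structure()]
#' (coordinates converted nm to Angstrom). Chain identity is not stored
#' in GRO; all atoms are returned under chain "A" with their residue
#' numbering blocks intact.
#'
#' @param path GRO file path.
#' @return An [xtal_structure()] with attribute `box` (3x3, Angstrom).
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  rows <- lines[3:(2 + n)]
  resnum <- as.integer(substr(rows, 1, 5))
  resname <- trimws(substr(rows, 6, 10))
  name <- trimws(substr(rows, 11, 15))
  serial <- as.integer(substr(rows, 16, 20))
  x <- as.numeric(substr(rows, 21, 28)) * 10
  y <- as.numeric(substr(rows, 29, 36)) * 10
  z <- as.numeric(substr(rows, 37, 44)) * 10
  box <- parse_gro_box(lines[3 + n])
  element <- toupper(substr(name, 1, 1))
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, resid = resnum, chain = "A",
                      altloc = "", occupancy = 1,
                      x = x, y = y, z = z,
                      het = toupper(resname) %in%
                        c(.water_resnames, "SOL", .ion_elements),
                      stringsAsFactors = FALSE)
  out <- xtal_structure(atoms)
  attr(out, "box") <- box
  out
}

# gro box line: v1x v2y v3z [v1y v1z v2x v2z v3x v3y], nm -> Angstrom
parse_gro_box <- function(line) {
  v <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  box <- diag(v[1:3])
  if (length(v) >= 9) {
    box[1, 2] <- v[4]; box[1, 3] <- v[5]
    box[2, 1] <- v[6]; box[2, 3] <- v[7]
    box[3, 1] <- v[8]; box[3, 2] <- v[9]
  }
  box * 10
}
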