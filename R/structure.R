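#' @importFrom stats setNames
NULL

# residue names recognized as water, and elements recognized as monatomic
# ions when they form a single-heavy-atom hetero residue
.water_resnames <- c("HOH", "WAT", "H2O", "DOD")
.ion_elements <- c("NA", "CL", "MG", "CA", "K", "ZN", "MN", "FE")

#' Molecular structure container
#'
#' Builds the hierarchical structure object used throughout the package:
#' an ordered atom table plus unit-cell and space-group metadata. Every
#' atom is classified into exactly one hetero class (`polymer`, `water`,
#' `ion`, `ligand`); waters are recognized by residue name (HOH, WAT,
#' H2O, DOD), ions as single-heavy-atom hetero residues with a monatomic
#' element (Na, Cl, Mg, Ca, K, Zn, Mn, Fe), remaining hetero residues as
#' ligands.
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `altloc`, `occupancy`, `x`, `y`, `z`,
#'   `het` (logical: deposited as a hetero record). Coordinates are
#'   Cartesian Angstrom.
#' @param cell A [cell_parameters()] object, or NULL.
#' @param space_group Hermann-Mauguin name, or NA.
#' @param symops Optional character vector of operator triplets carried
#'   by the source file (takes precedence over the registry).
#' @param seqres Optional named list: chain id -> character vector of
#'   residue names in sequence order.
#' @return Object of class `xtal_structure`.
#' @export
xtal_structure <- function(atoms, cell = NULL, space_group = NA_character_,
                           symops = NULL, seqres = NULL) {
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "altloc", "occupancy", "x", "y", "z", "het")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite", call. = FALSE)
  occ <- atoms$occupancy
  if (any(!is.finite(occ) | occ < 0 | occ > 1))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  atoms$het_class <- classify_atoms(atoms)
  structure(list(atoms = atoms,
                 chains = unique(atoms$chain),
                 cell = cell,
                 space_group = space_group,
                 symops = symops,
                 seqres = seqres),
            class = "xtal_structure")
}

classify_atoms <- function(atoms) {
  cls <- rep("polymer", nrow(atoms))
  het <- atoms$het
  cls[het] <- "ligand"
  cls[het & toupper(atoms$resname) %in% .water_resnames] <- "water"
  # ions: hetero residues with a single heavy atom of a monatomic element
  resk <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "\r")
  heavy <- toupper(atoms$element) != "H"
  n_heavy <- tapply(heavy, resk, sum)
  for (i in which(het & cls == "ligand")) {
    if (n_heavy[[resk[i]]] == 1L && toupper(atoms$element[i]) %in% .ion_elements)
      cls[i] <- "ion"
  }
  cls
}

#' @export
print.xtal_structure <- function(x, ...) {
  tab <- table(factor(x$atoms$het_class,
                      levels = c("polymer", "water", "ion", "ligand")))
  cat(sprintf("xtal_structure: %d atoms, %d chains\n",
              nrow(x$atoms), length(x$chains)))
  cat(sprintf("  polymer %d | water %d | ion %d | ligand %d atoms\n",
              tab["polymer"], tab["water"], tab["ion"], tab["ligand"]))
  if (!is.null(x$cell))
    cat(sprintf("  cell: %.2f %.2f %.2f A / %.1f %.1f %.1f deg, group '%s'\n",
                x$cell$a, x$cell$b, x$cell$c,
                x$cell$alpha, x$cell$beta, x$cell$gamma, x$space_group))
  invisible(x)
}

#' Count residues of each hetero class
#'
#' @param structure An [xtal_structure()].
#' @return Named integer vector: number of distinct residues classified
#'   as polymer, water, ion and ligand.
#' @export
het_summary <- function(structure) {
  a <- structure$atoms
  resk <- paste(a$chain, a$resid, a$resname, sep = "\r")
  per_res <- tapply(a$het_class, resk, function(x) x[1])
  counts <- table(factor(per_res, levels = c("polymer", "water", "ion", "ligand")))
  setNames(as.integer(counts), names(counts))
}

#' Residue-level view of the ion content
#'
#' @param structure An [xtal_structure()].
#' @return Data frame with one row per ion residue: chain, resid,
#'   resname, element.
#' @export
ion_residues <- function(structure) {
  a <- structure$atoms[structure$atoms$het_class == "ion", , drop = FALSE]
  unique(a[, c("chain", "resid", "resname", "element")])
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_atom_xyz <- function(structure, xyz) {
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}
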