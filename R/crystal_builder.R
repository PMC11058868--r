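# Expansion of the asymmetric unit to the full crystallographic unit
# cell: every space-group operator, conjugated into Cartesian space, is
# applied to the deposited coordinates, and the copies are merged with
# distinct chain identifiers.

.chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Build the complete unit cell from an asymmetric unit
#'
#' Applies every symmetry operation of the structure's space group
#' (in-file operator lists take precedence over the built-in registry)
#' to the asymmetric unit. Each fractional-space Seitz pair \{R|t\} is
#' conjugated to Cartesian space (M = A R A^-1, V = A t) and the copies
#' are merged. Each copy is wrapped by whole lattice translations so its
#' geometric center lies inside the cell parallelepiped — whole-molecule
#' wrapping, so bonds are never split across the boundary. Symmetry
#' mates receive fresh chain identifiers; the mapping is recorded in the
#' build report. Coincident atoms at special positions (copies closer
#' than `special_tol`) are dropped, keeping the first occurrence, and a
#' post-build clash scan across copies is run and reported.
#'
#' @param asym An [xtal_structure()] carrying cell and space-group
#'   metadata.
#' @param max_atoms Abort if copies x atoms exceeds this limit.
#' @param clash_threshold Heavy-atom clash distance for the post-build
#'   scan (Angstrom).
#' @param special_tol Distance below which symmetry-mate atoms are
#'   treated as duplicates at a special position (Angstrom).
#' @return An [xtal_structure()] containing all copies, with cell box
#'   metadata and attribute `build_report` (list: `operators`,
#'   `chain_map`, `n_duplicates_removed`, `clashes`).
#' @export
build_unit_cell <- function(asym, max_atoms = 1e6, clash_threshold = 0.5,
                            special_tol = 0.1) {
  if (is.null(asym$cell) || is.na(asym$space_group))
    stop("asymmetric unit lacks cell or space-group metadata", call. = FALSE)
  ops <- symmetry_operations_for_group(asym$space_group, asym$symops)
  n_ops <- length(ops)
  n_atoms <- nrow(asym$atoms)
  if (n_ops * n_atoms > max_atoms)
    stop(sprintf(paste0("unit cell would contain %d atoms (%d copies x %d); ",
                        "raise max_atoms to proceed"),
                 n_ops * n_atoms, n_ops, n_atoms), call. = FALSE)
  A <- orthogonalization_matrix(asym$cell)
  Ainv <- solve(A)
  xyz0 <- atom_xyz(asym)

  used <- asym$chains
  chain_map <- list()
  copies <- vector("list", n_ops)
  for (k in seq_len(n_ops)) {
    cop <- to_cartesian_op(ops[[k]], A)
    xyz <- t(cop$M %*% t(xyz0) + cop$V)
    # wrap per molecule (chain + het residue) by geometric center
    atoms_k <- asym$atoms
    molk <- ifelse(atoms_k$het_class == "polymer", atoms_k$chain,
                   paste(atoms_k$chain, atoms_k$resid, atoms_k$resname,
                         sep = "\r"))
    for (m in unique(molk)) {
      sel <- molk == m
      ctr_frac <- Ainv %*% colMeans(xyz[sel, , drop = FALSE])
      shift <- A %*% (-floor(ctr_frac))
      xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -as.vector(shift))
    }
    atoms_k[, c("x", "y", "z")] <- xyz
    if (k > 1L) {
      remap <- character(0)
      for (ch in unique(atoms_k$chain)) {
        new_id <- setdiff(.chain_alphabet, used)[1]
        if (is.na(new_id)) new_id <- paste0(ch, k)   # alphabet exhausted
        used <- c(used, new_id)
        remap[ch] <- new_id
      }
      atoms_k$chain <- unname(remap[atoms_k$chain])
      chain_map[[k]] <- remap
    } else {
      chain_map[[k]] <- stats::setNames(unique(atoms_k$chain),
                                        unique(atoms_k$chain))
    }
    atoms_k$copy <- k
    copies[[k]] <- atoms_k
  }
  all_atoms <- do.call(rbind, copies)
  all_atoms$serial <- seq_len(nrow(all_atoms))

  # duplicates at special positions: atoms from different copies closer
  # than special_tol; keep the first occurrence
  dup <- rep(FALSE, nrow(all_atoms))
  if (n_ops > 1L) {
    xyz <- as.matrix(all_atoms[, c("x", "y", "z")])
    frac <- t(Ainv %*% t(xyz))
    # compare under lattice periodicity via fractional wrapping
    for (i in seq_len(n_atoms)) {
      rows <- i + (seq_len(n_ops) - 1L) * n_atoms   # images of source atom i
      fi <- frac[rows, , drop = FALSE]
      for (p in 2:n_ops) {
        if (dup[rows[p]]) next
        for (q in 1:(p - 1L)) {
          if (dup[rows[q]]) next
          df <- (fi[p, ] - fi[q, ]) - round(fi[p, ] - fi[q, ])
          if (sqrt(sum((A %*% df)^2)) < special_tol) { dup[rows[p]] <- TRUE; break }
        }
      }
    }
  }
  n_dup <- sum(dup)
  all_atoms <- all_atoms[!dup, , drop = FALSE]
  copy_id <- all_atoms$copy
  all_atoms$copy <- NULL

  out <- xtal_structure(all_atoms, cell = asym$cell,
                        space_group = asym$space_group, symops = asym$symops,
                        seqres = asym$seqres)
  # clash scan restricted to inter-copy pairs
  cl <- detect_clashes(out, threshold = clash_threshold)
  if (nrow(cl)) cl <- cl[copy_id[cl$i] != copy_id[cl$j], , drop = FALSE]
  attr(out, "build_report") <- list(
    operators = vapply(ops, function(o) o$xyz, ""),
    chain_map = chain_map,
    n_duplicates_removed = n_dup,
    clashes = cl)
  attr(out, "copy_id") <- copy_id
  out
}

#' Write the unit-cell build report
#'
#' Plain-text summary of the operators applied, the symmetry-mate chain
#' mapping, duplicate-atom removals at special positions, and inter-copy
#' clashes.
#'
#' @param built Result of [build_unit_cell()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_build_report <- function(built, path) {
  rep <- attr(built, "build_report")
  if (is.null(rep)) stop("no build report attached", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("unit-cell build report",
               sprintf("operators (%d):", length(rep$operators)),
               paste0("  ", rep$operators),
               "chain mapping per copy:"), con)
  for (k in seq_along(rep$chain_map))
    writeLines(sprintf("  copy %d: %s", k,
                       paste(names(rep$chain_map[[k]]), "->",
                             rep$chain_map[[k]], collapse = ", ")), con)
  writeLines(sprintf("duplicate atoms removed at special positions: %d",
                     rep$n_duplicates_removed), con)
  writeLines(sprintf("inter-copy clashes (< %.2f A): %d",
                     if (nrow(rep$clashes)) rep$clashes$threshold[1] else 0.5,
                     nrow(rep$clashes)), con)
  invisible(path)
}
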