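# Structure cleaning: one simulation-ready conformer per asymmetric unit.

#' Resolve alternative conformations
#'
#' Keeps exactly one altloc per atom. Residues named in `choice` use the
#' requested altloc id; all others follow the default policy: highest
#' summed occupancy, ties broken by alphabetically first altloc id.
#' Atoms without altlocs pass through untouched, so the operation is
#' idempotent.
#'
#' @param structure An [xtal_structure()].
#' @param choice Named list/vector mapping `"chain:resid"` keys to altloc
#'   ids, e.g. `list("A:42" = "B")`.
#' @return The structure with all altloc duplicates removed (surviving
#'   atoms keep their coordinates; their altloc field is cleared).
#' @export
select_altloc <- function(structure, choice = list()) {
  a <- structure$atoms
  has_alt <- nzchar(a$altloc)
  if (!any(has_alt) && length(choice) == 0L) return(structure)
  resk <- paste0(a$chain, ":", a$resid)
  for (key in names(choice)) {
    avail <- unique(a$altloc[resk == key & has_alt])
    if (length(avail) == 0L)
      stop(sprintf("residue %s has no alternative conformations", key),
           call. = FALSE)
    if (!choice[[key]] %in% avail)
      stop(sprintf("residue %s has no altloc '%s' (available: %s)",
                   key, choice[[key]], paste(sort(avail), collapse = ", ")),
           call. = FALSE)
  }
  keep <- rep(TRUE, nrow(a))
  for (key in unique(resk[has_alt])) {
    sel <- resk == key & has_alt
    ids <- sort(unique(a$altloc[sel]))
    pick <- if (key %in% names(choice)) {
      choice[[key]]
    } else {
      occ <- vapply(ids, function(id) sum(a$occupancy[sel & a$altloc == id]), 0)
      ids[which.max(occ)]   # which.max takes the first (alphabetical) on ties
    }
    keep[sel & a$altloc != pick] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  a$altloc <- ""
  out <- xtal_structure(a, cell = structure$cell,
                        space_group = structure$space_group,
                        symops = structure$symops, seqres = structure$seqres)
  out
}

#' Detect missing internal residues
#'
#' Scans each polymer chain for discontinuities in the residue
#' numbering. Every internal break yields one gap report; chains that
#' are complete contribute nothing. Terminal truncations (detectable
#' only when the deposited polymer sequence is available) are reported
#' as warnings via the `"truncations"` attribute, not as gaps, because
#' loop modelling and terminus capping are different repairs.
#'
#' @param structure An [xtal_structure()].
#' @return Data frame (class `gap_report`) with columns `chain`,
#'   `preceding`, `following`, `missing_count`; zero rows when complete.
#' @export
find_gaps <- function(structure) {
  a <- structure$atoms[structure$atoms$het_class == "polymer", , drop = FALSE]
  out <- data.frame(chain = character(0), preceding = integer(0),
                    following = integer(0), missing_count = integer(0),
                    stringsAsFactors = FALSE)
  trunc <- character(0)
  for (ch in unique(a$chain)) {
    res <- sort(unique(a$resid[a$chain == ch]))
    if (length(res) < 2L) next
    d <- diff(res)
    for (k in which(d > 1L)) {
      out <- rbind(out, data.frame(chain = ch, preceding = res[k],
                                   following = res[k + 1L],
                                   missing_count = d[k] - 1L,
                                   stringsAsFactors = FALSE))
    }
    sq <- structure$seqres[[ch]]
    if (!is.null(sq)) {
      n_expected <- length(sq)
      n_present <- length(res) + sum(d[d > 1L] - 1L)
      if (n_present < n_expected)
        trunc <- c(trunc, sprintf(
          "chain %s: %d of %d sequence residues span the modelled range",
          ch, n_present, n_expected))
    }
  }
  class(out) <- c("gap_report", class(out))
  attr(out, "truncations") <- trunc
  out
}

#' Write a gap manifest
#'
#' Loop building is delegated to external modelling tools; this package
#' only detects and reports. The manifest is a TSV table one row per
#' internal gap.
#'
#' @param gaps Result of [find_gaps()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gap_manifest <- function(gaps, path) {
  utils::write.table(as.data.frame(gaps), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect steric clashes
#'
#' Reports every heavy-atom pair from different residues closer than the
#' threshold (symmetric pairs once). Clashes typically arise from
#' symmetry building or externally modelled loops; they are reported,
#' never fatal.
#'
#' @param structure An [xtal_structure()].
#' @param threshold Distance threshold in Angstrom (default 0.5, a
#'   genuine-overlap criterion well below bonded distances).
#' @return Data frame with columns `i`, `j` (row indices into the atom
#'   table), `distance`, `threshold`.
#' @export
detect_clashes <- function(structure, threshold = 0.5) {
  stopifnot(threshold > 0)
  a <- structure$atoms
  heavy <- which(toupper(a$element) != "H")
  out <- data.frame(i = integer(0), j = integer(0),
                    distance = numeric(0), threshold = numeric(0))
  if (length(heavy) < 2L) return(out)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  resk <- paste(a$chain, a$resid, a$resname, sep = "\r")[heavy]
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    same_res <- resk[hit[, 1]] == resk[hit[, 2]]
    hit <- hit[!same_res, , drop = FALSE]
  }
  if (nrow(hit)) {
    out <- data.frame(i = heavy[hit[, 1]], j = heavy[hit[, 2]],
                      distance = d[hit], threshold = threshold)
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# standard intrinsic pKa values for titratable residues
.pka_table <- c(ASP = 3.65, GLU = 4.25, HIS = 6.0, CYS = 8.3,
                TYR = 10.07, LYS = 10.53, ARG = 12.48)
.acidic_residues <- c("ASP", "GLU", "CYS", "TYR")

# residue-renaming labels consumed by topology generators
.state_labels <- list(
  ASP = c(charged = "ASP", neutral = "ASH"),
  GLU = c(charged = "GLU", neutral = "GLH"),
  HIS = c(charged = "HIP", neutral = "HIE"),
  CYS = c(charged = "CYM", neutral = "CYS"),
  TYR = c(charged = "TYM", neutral = "TYR"),
  LYS = c(charged = "LYS", neutral = "LYN"),
  ARG = c(charged = "ARG", neutral = "ARN"))

#' Assign protonation states at a given pH
#'
#' Applies the standard-pKa rule to every titratable residue: an acidic
#' side chain (Asp, Glu, Cys, Tyr) is charged (deprotonated) when
#' pH > pKa; a basic side chain (His, Lys, Arg) is charged (protonated)
#' when pH < pKa; ties resolve to the charged form. Built-in pKa values:
#' Asp 3.65, Glu 4.25, His 6.0, Cys 8.3, Tyr 10.07, Lys 10.53,
#' Arg 12.48. Externally computed pKa values (e.g. from an empirical
#' predictor) can be injected per residue via `pka_override`.
#'
#' @param structure An [xtal_structure()].
#' @param pH Target pH, in (0, 14).
#' @param pka_override Named numeric vector keyed `"chain:resid"`
#'   overriding the table for specific residues.
#' @return Data frame with one row per titratable residue: `chain`,
#'   `resid`, `resname`, `pKa_used`, `pH`, `charged`, `state` (the
#'   renaming label, e.g. HIE/HIP/ASH/GLH).
#' @export
assign_protonation <- function(structure, pH, pka_override = NULL) {
  stopifnot(pH > 0, pH < 14)
  a <- structure$atoms[structure$atoms$het_class == "polymer", , drop = FALSE]
  res <- unique(a[, c("chain", "resid", "resname")])
  res <- res[res$resname %in% names(.pka_table), , drop = FALSE]
  if (nrow(res) == 0L)
    return(data.frame(chain = character(0), resid = integer(0),
                      resname = character(0), pKa_used = numeric(0),
                      pH = numeric(0), charged = logical(0),
                      state = character(0)))
  pka <- .pka_table[res$resname]
  key <- paste0(res$chain, ":", res$resid)
  if (!is.null(pka_override)) {
    hit <- key %in% names(pka_override)
    pka[hit] <- pka_override[key[hit]]
  }
  acidic <- res$resname %in% .acidic_residues
  charged <- ifelse(acidic, pH >= pka, pH <= pka)
  state <- vapply(seq_len(nrow(res)), function(k) {
    .state_labels[[res$resname[k]]][[if (charged[k]) "charged" else "neutral"]]
  }, "")
  out <- data.frame(chain = res$chain, resid = res$resid,
                    resname = res$resname, pKa_used = unname(pka), pH = pH,
                    charged = charged, state = state,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the heteroatom retention policy
#'
#' Drops crystallographic waters, ions and/or ligands that the user does
#' not want in the simulation box. Retained ions are checked against the
#' declared force-field ion list when one is given; unknown retained
#' ions trigger a warning because the MD engine expects ion parameters
#' to exist in the force field.
#'
#' @param structure An [xtal_structure()].
#' @param keep_waters,keep_ions,keep_ligands Logical retention flags.
#' @param ff_ions Optional character vector of element symbols the force
#'   field parameterises (e.g. `c("NA", "CL", "MG")`).
#' @return The filtered structure.
#' @export
apply_het_policy <- function(structure, keep_waters = TRUE, keep_ions = TRUE,
                             keep_ligands = TRUE, ff_ions = NULL) {
  a <- structure$atoms
  drop_classes <- c("water", "ion", "ligand")[!c(keep_waters, keep_ions,
                                                 keep_ligands)]
  keep <- !(a$het_class %in% drop_classes)
  if (keep_ions && !is.null(ff_ions)) {
    ions <- toupper(unique(a$element[a$het_class == "ion"]))
    unknown <- setdiff(ions, toupper(ff_ions))
    if (length(unknown))
      warning("retained ions not in the declared force-field ion list: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  xtal_structure(a[keep, , drop = FALSE], cell = structure$cell,
                 space_group = structure$space_group,
                 symops = structure$symops, seqres = structure$seqres)
}
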