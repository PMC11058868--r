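# Solvent placement: candidate waters from a pre-equilibrated template
# tile, pruned by scaled van-der-Waals overlap with the solute. The
# overlap scale factor is the calibration dial of the whole crystal
# workflow: smaller scale keeps more waters.

#' Grid of overlap scale factors
#'
#' An ordered, strictly increasing grid of scale values centered on a
#' chosen value. [default_scale_grid()] returns the standard probe grid
#' 0.53, 0.55, 0.57, 0.59, 0.61: five values around 0.57, the scale that
#' reproduces bulk water density for solvated proteins but is usually
#' too sparse for crystals.
#'
#' @param center Central scale value.
#' @param n Number of values (odd, so the center is a grid point).
#' @param step Spacing between consecutive values.
#' @return Object of class `scale_grid`: list with `values`, `center`,
#'   `step`.
#' @examples
#' default_scale_grid()$values       # 0.53 0.55 0.57 0.59 0.61
#' scale_grid(0.54, n = 3, step = 0.01)$values  # 0.53 0.54 0.55
#' @export
scale_grid <- function(center = 0.57, n = 5, step = 0.02) {
  stopifnot(center > 0, step > 0, n >= 1, n %% 2 == 1)
  half <- (n - 1) / 2
  values <- round(center + step * seq(-half, half), 10)
  if (any(values <= 0)) stop("scale grid extends to non-positive values",
                             call. = FALSE)
  structure(list(values = values, center = center, step = step),
            class = "scale_grid")
}

#' @rdname scale_grid
#' @export
default_scale_grid <- function() scale_grid(0.57, 5, 0.02)

#' @export
print.scale_grid <- function(x, ...) {
  cat("scale grid:", paste(format(x$values), collapse = " "),
      sprintf("(center %s, step %s)\n", format(x$center), format(x$step)))
  invisible(x)
}

#' Pre-equilibrated water template tile
#'
#' A synthetic cubic tile of rigid three-site waters, built in code (no
#' external solvent box is shipped). Molecules sit on a jittered lattice
#' (deterministic, internal seed): the disorder mimics an equilibrated
#' configuration, so cutting the tiling at an arbitrary box boundary
#' keeps the bulk density instead of slicing aligned lattice planes. The
#' default reproduces the canonical 216-water cube of edge 1.862 nm,
#' i.e. bulk density 216 / 1.862^3 = 33.5 molecules/nm^3.
#'
#' @param n_side Molecules per cube edge (total `n_side^3`).
#' @param edge Cube edge length in nm.
#' @param jitter Maximum lattice displacement, as a fraction of the
#'   lattice spacing (0 gives a regular grid).
#' @return Object of class `water_template`: list with `oxygen` (n x 3
#'   matrix, nm), `hydrogens` (2n x 3, nm, rows 2i-1 and 2i belong to
#'   oxygen i), `edge`, `density` (molecules/nm^3).
#' @export
water_template <- function(n_side = 6, edge = 1.862, jitter = 0.35) {
  stopifnot(n_side >= 1, edge > 0, jitter >= 0, jitter < 0.5)
  spacing <- edge / n_side
  g <- (seq_len(n_side) - 0.5) * spacing
  ox <- as.matrix(expand.grid(x = g, y = g, z = g))
  n <- nrow(ox)
  if (jitter > 0)
    ox <- ox + with_seed(7177, matrix(stats::runif(3 * n, -jitter * spacing,
                                                   jitter * spacing),
                                      ncol = 3))
  # rigid water geometry: O-H 0.09572 nm, H-O-H 104.52 degrees
  d <- 0.09572
  half <- 104.52 / 2 * pi / 180
  h1 <- c(d * sin(half),  d * cos(half), 0)
  h2 <- c(-d * sin(half), d * cos(half), 0)
  hyd <- matrix(NA_real_, 2 * n, 3)
  hyd[seq(1, 2 * n, 2), ] <- sweep(ox, 2, -h1)
  hyd[seq(2, 2 * n, 2), ] <- sweep(ox, 2, -h2)
  structure(list(oxygen = unname(ox), hydrogens = hyd, edge = edge,
                 density = n / edge^3),
            class = "water_template")
}

#' Generate candidate water positions filling a box
#'
#' Replicates the template tile over the bounding box of the (possibly
#' triclinic) cell parallelepiped and keeps the molecules whose oxygen
#' falls inside it (fractional coordinates in `[0,1)^3`). For a box
#' commensurate with the tile the kept count is exact; in general the
#' resulting bulk density matches the template density to within a few
#' percent (surface discretisation).
#'
#' @param box 3x3 matrix of box vectors (rows) in nm.
#' @param template A [water_template()].
#' @return List with `oxygen` (kept oxygens, nm), `hydrogens`
#'   (2 per oxygen, nm), `n` (molecule count).
#' @export
candidate_waters <- function(box, template = water_template()) {
  box <- as.matrix(box)
  stopifnot(nrow(box) == 3L, ncol(box) == 3L)
  if (abs(det(box)) < 1e-12) stop("degenerate box", call. = FALSE)
  edge <- template$edge
  # vertices of the parallelepiped spanned by the three box vectors
  verts <- as.matrix(expand.grid(0:1, 0:1, 0:1)) %*% box
  lo <- floor(apply(verts, 2, min) / edge)
  hi <- ceiling(apply(verts, 2, max) / edge) - 1
  shifts <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                  z = lo[3]:hi[3])) * edge
  Binv <- solve(t(box))          # cartesian -> fractional
  keep_o <- list(); keep_h <- list()
  for (s in seq_len(nrow(shifts))) {
    ox <- sweep(template$oxygen, 2, -shifts[s, ])
    frac <- ox %*% t(Binv)
    inside <- frac[, 1] >= 0 & frac[, 1] < 1 &
              frac[, 2] >= 0 & frac[, 2] < 1 &
              frac[, 3] >= 0 & frac[, 3] < 1
    if (!any(inside)) next
    keep_o[[length(keep_o) + 1L]] <- ox[inside, , drop = FALSE]
    hidx <- rep((which(inside) - 1L) * 2L, each = 2L) + c(1L, 2L)
    keep_h[[length(keep_h) + 1L]] <-
      sweep(template$hydrogens, 2, -shifts[s, ])[hidx, , drop = FALSE]
  }
  ox <- do.call(rbind, keep_o)
  hy <- do.call(rbind, keep_h)
  if (is.null(ox)) { ox <- matrix(0, 0, 3); hy <- matrix(0, 0, 3) }
  list(oxygen = ox, hydrogens = hy, n = nrow(ox))
}

# default van der Waals radii, Angstrom
.vdw_radii <- c(C = 1.7, N = 1.55, O = 1.52, H = 1.2, S = 1.8, P = 1.8,
                NA. = 2.27, CL = 1.75, MG = 1.73, CA = 2.31, K = 2.75,
                ZN = 1.39, MN = 1.97, FE = 1.94)
.water_probe_radius <- 1.4  # Angstrom, water-oxygen probe

vdw_radius <- function(elements, radii = .vdw_radii) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."        # avoid the missing-value name
  r <- radii[key]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

#' Prune candidate waters overlapping the solute
#'
#' A candidate water is removed when any of its atoms lies closer to any
#' solute heavy atom than `scale * (r_water + r_atom)`, with distances
#' computed under periodic boundary conditions (minimum over all 27
#' neighbour images of the triclinic box). Removal is per whole
#' molecule. Smaller scale therefore keeps more waters; the kept count
#' is deterministic for fixed inputs and non-increasing in scale.
#'
#' @param candidates Result of [candidate_waters()].
#' @param solute An [xtal_structure()] (coordinates in Angstrom) or NULL
#'   for an empty box.
#' @param scale Overlap scale factor (> 0).
#' @param box 3x3 box vectors (rows) in nm, for the periodic images.
#' @param radii Named van der Waals radius table in Angstrom (defaults
#'   cover C, N, O, H, S, P and common ions).
#' @return The `candidates` list filtered to the kept molecules, with
#'   `n_candidates` and `scale` recorded.
#' @export
prune_overlaps <- function(candidates, solute, scale, box,
                           radii = .vdw_radii) {
  stopifnot(scale > 0)
  n_cand <- candidates$n
  if (is.null(solute) || nrow(solute$atoms) == 0L) {
    out <- candidates
    out$n_candidates <- n_cand
    out$scale <- scale
    return(out)
  }
  box <- as.matrix(box)
  heavy <- toupper(solute$atoms$element) != "H"
  sol_xyz <- atom_xyz(solute)[heavy, , drop = FALSE] / 10   # Angstrom -> nm
  # wrap the solute into the primary cell so the 27-image search is a
  # true minimum-image computation regardless of where the solute sits
  frac <- sol_xyz %*% solve(box)   # rows x row-vector box: frac = x B^-1
  sol_xyz <- (frac - floor(frac)) %*% box
  sol_r <- vdw_radius(solute$atoms$element[heavy], radii) / 10
  probe_o <- .water_probe_radius / 10
  probe_h <- vdw_radius("H", radii) / 10

  images <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% box
  removed <- rep(FALSE, n_cand)
  watoms <- rbind(candidates$oxygen, candidates$hydrogens)
  wmol <- c(seq_len(n_cand), rep(seq_len(n_cand), each = 2))
  wprobe <- c(rep(probe_o, n_cand), rep(probe_h, 2 * n_cand))
  for (k in seq_len(nrow(sol_xyz))) {
    cut <- scale * (wprobe + sol_r[k])
    dmin2 <- rep(Inf, nrow(watoms))
    for (im in seq_len(nrow(images))) {
      dd <- sweep(watoms, 2, sol_xyz[k, ] + images[im, ])
      dmin2 <- pmin(dmin2, rowSums(dd^2))
    }
    removed[unique(wmol[dmin2 < cut^2])] <- TRUE
  }
  keep <- which(!removed)
  hidx <- rep((keep - 1L) * 2L, each = 2L) + c(1L, 2L)
  list(oxygen = candidates$oxygen[keep, , drop = FALSE],
       hydrogens = candidates$hydrogens[hidx, , drop = FALSE],
       n = length(keep), n_candidates = n_cand, scale = scale)
}

#' Plan neutralizing ions
#'
#' Number of Na+/Cl- pairs from the target salt concentration,
#' `round(concentration * water_count / 55.5)` (55.5 mol/L being the
#' molarity of pure water), plus the counter-ions that bring the total
#' system charge to exactly zero.
#'
#' @param system_charge Net solute charge in elementary charges.
#' @param water_count Number of water molecules in the box.
#' @param concentration Target salt concentration in mol/L.
#' @return Named integer vector `c(NA = ..., CL = ...)` whose net charge
#'   exactly cancels `system_charge`.
#' @examples
#' plan_ions(0, 5550, 0.15)   # 15 Na+, 15 Cl-
#' plan_ions(-4, 0, 0)        # 4 Na+, 0 Cl-
#' @export
plan_ions <- function(system_charge, water_count, concentration = 0.15) {
  stopifnot(concentration >= 0, water_count >= 0)
  system_charge <- as.integer(round(system_charge))
  n_pairs <- round(concentration * water_count / 55.5)
  n_na <- n_pairs + max(0L, -system_charge)
  n_cl <- n_pairs + max(0L, system_charge)
  if ((n_na + n_cl) > 0 && water_count < (n_na + n_cl))
    stop("cannot place ions: fewer waters than ions to insert", call. = FALSE)
  c("NA" = as.integer(n_na), "CL" = as.integer(n_cl))
}

#' Solvate a structure at a given overlap scale
#'
#' End-to-end internal solvation backend: generates candidate waters
#' from the template, prunes those overlapping the solute, converts the
#' kept molecules into SOL residues appended to the structure, and plans
#' neutralizing ions by replacing randomly chosen kept waters (seeded,
#' seed recorded in the plan). Crystallographic waters already in the
#' structure are always kept verbatim; new waters are added around them.
#'
#' @param structure An [xtal_structure()] with cell metadata; assumed to
#'   be in the MD box frame (see [md_frame()]).
#' @param scale Overlap scale factor.
#' @param template A [water_template()].
#' @param system_charge Net solute charge (elementary charges).
#' @param concentration Salt concentration, mol/L.
#' @param seed RNG seed for ion placement.
#' @return List with `structure` (solvated, ions placed) and `plan`
#'   (class `solvation_plan`: scale, n_candidates, n_kept_waters,
#'   ion_counts, target_concentration, seed).
#' @export
solvate_structure <- function(structure, scale, template = water_template(),
                              system_charge = 0, concentration = 0.15,
                              seed = 1L) {
  box_nm <- cell_to_box(structure$cell, unit = "nm")
  cand <- candidate_waters(box_nm, template)
  kept <- prune_overlaps(cand, structure, scale, box_nm)
  ions <- plan_ions(system_charge, kept$n, concentration)

  n_ion <- sum(ions)
  ion_rows <- integer(0)
  if (n_ion > 0) {
    if (kept$n < n_ion)
      stop("cannot place ions: fewer kept waters than ions", call. = FALSE)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    ion_rows <- sample(kept$n, n_ion)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  a <- structure$atoms
  next_serial <- if (nrow(a)) max(a$serial) else 0L
  next_resid <- if (nrow(a)) max(a$resid) else 0L
  water_rows <- setdiff(seq_len(kept$n), ion_rows)
  new_atoms <- list()
  rid <- next_resid
  sid <- next_serial
  for (w in water_rows) {
    rid <- rid + 1L
    o <- kept$oxygen[w, ] * 10
    h <- kept$hydrogens[c(2 * w - 1L, 2 * w), , drop = FALSE] * 10
    new_atoms[[length(new_atoms) + 1L]] <- data.frame(
      serial = sid + 1:3, name = c("OW", "HW1", "HW2"),
      element = c("O", "H", "H"), resname = "SOL", resid = rid,
      chain = "W", altloc = "", occupancy = 1,
      x = c(o[1], h[, 1]), y = c(o[2], h[, 2]), z = c(o[3], h[, 3]),
      het = TRUE, stringsAsFactors = FALSE)
    sid <- sid + 3L
  }
  ion_species <- rep(names(ions), times = ions)
  for (k in seq_along(ion_rows)) {
    rid <- rid + 1L
    sid <- sid + 1L
    o <- kept$oxygen[ion_rows[k], ] * 10
    new_atoms[[length(new_atoms) + 1L]] <- data.frame(
      serial = sid, name = ion_species[k], element = ion_species[k],
      resname = ion_species[k], resid = rid, chain = "I", altloc = "",
      occupancy = 1, x = o[1], y = o[2], z = o[3], het = TRUE,
      stringsAsFactors = FALSE)
  }
  a$het_class <- NULL   # recomputed by the constructor
  atoms <- rbind(a, do.call(rbind, new_atoms))
  out <- xtal_structure(atoms, cell = structure$cell,
                        space_group = structure$space_group,
                        symops = structure$symops, seqres = structure$seqres)
  plan <- base::structure(list(scale = scale, n_candidates = kept$n_candidates,
                         n_kept_waters = kept$n - n_ion,
                         ion_counts = as.list(ions),
                         target_concentration = concentration,
                         seed = seed,
                         crystallographic_waters_kept_verbatim = TRUE),
                    class = "solvation_plan")
  list(structure = out, plan = plan)
}

#' @export
print.solvation_plan <- function(x, ...) {
  cat(sprintf("solvation plan: scale %.3f, %d/%d waters kept, ions %s\n",
              x$scale, x$n_kept_waters, x$n_candidates,
              paste(names(x$ion_counts), unlist(x$ion_counts),
                    collapse = ", ")))
  invisible(x)
}

#' Write a solvation plan manifest
#'
#' @param plan A `solvation_plan`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_solvation_plan <- function(plan, path) {
  write_yaml_lite(unclass(plan), path)
  invisible(path)
}
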