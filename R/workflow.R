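# GROMACS workflow generation. The package generates the complete run
# recipe (bash script + .mdp parameter files + manifest); it never
# executes MD itself, so everything stays testable without the MD suite.

.workflow_steps <- c("hydrogens", "solvate", "ions", "minimize",
                     "equilibrate", "production")

.valid_config_keys <- c("structure", "forcefield", "water_model", "pH",
                        "scale_grid", "concentration", "nvt_ps", "npt_ps",
                        "production_ns", "dt_fs", "temperature_K",
                        "pressure_bar", "mdp_overrides", "seed")

default_workflow_config <- function() {
  list(structure = "crystal.gro",
       forcefield = "amber99sb-ildn",
       water_model = "tip3p",
       pH = 7.0,
       scale_grid = list(center = 0.57, n = 5, step = 0.02),
       concentration = 0.15,
       nvt_ps = 100, npt_ps = 100,
       production_ns = 20, dt_fs = 2,
       temperature_K = 300, pressure_bar = 1,
       mdp_overrides = list(),
       seed = 1)
}

# shared non-bonded settings: smooth PME, 1.0 nm real-space cutoff,
# 0.16 nm grid; LJ truncated at 1.0 nm with potential shift
mdp_common <- function() c(
  "cutoff-scheme            = Verlet",
  "coulombtype              = PME",
  "rcoulomb                 = 1.0",
  "fourierspacing           = 0.16",
  "vdwtype                  = Cut-off",
  "vdw-modifier             = Potential-shift-Verlet",
  "rvdw                     = 1.0")

mdp_minim <- function(cfg) c(
  "; energy minimization (steepest descent)",
  "integrator               = steep",
  "emtol                    = 1000.0",
  "emstep                   = 0.01",
  "nsteps                   = 50000",
  mdp_common())

mdp_md <- function(cfg, nsteps, pcoupl, posres) {
  c(sprintf("; %s", if (pcoupl) "NPT" else "NVT"),
    if (posres) "define                   = -DPOSRES",
    "integrator               = md",
    sprintf("dt                       = %.4f", cfg$dt_fs / 1000),
    sprintf("nsteps                   = %d", nsteps),
    "constraints              = h-bonds",
    "constraint-algorithm     = lincs",
    mdp_common(),
    "tcoupl                   = v-rescale",
    "tc-grps                  = System",
    "tau-t                    = 0.5",
    sprintf("ref-t                    = %g", cfg$temperature_K),
    if (pcoupl) c(
      "pcoupl                   = c-rescale",
      "pcoupltype               = anisotropic",
      "tau-p                    = 5.0",
      sprintf("ref-p                    = %s",
              paste(rep(sprintf("%g", cfg$pressure_bar), 3),
                    collapse = " ")),
      "compressibility          = 4.5e-5 4.5e-5 4.5e-5 0 0 0"),
    if (!pcoupl) "pcoupl                   = no")
}

mdp_files_for <- function(cfg) {
  ps_per_step <- cfg$dt_fs / 1000
  list(
    minimize = mdp_minim(cfg),
    nvt = mdp_md(cfg, round(cfg$nvt_ps / ps_per_step), FALSE, TRUE),
    npt = mdp_md(cfg, round(cfg$npt_ps / ps_per_step), TRUE, TRUE),
    production = mdp_md(cfg, round(cfg$production_ns * 1000 / ps_per_step),
                        TRUE, FALSE))
}

#' Render the GROMACS run recipe
#'
#' Emits, for every value of the scale grid, the six-step chain —
#' (i) adding hydrogens, (ii) adding solvent, (iii) adding ions,
#' (iv) energy minimization, (v) NVT then NPT equilibration,
#' (vi) production — as one bash script plus the .mdp parameter files
#' and a YAML manifest of all choices. The rendered output is a pure
#' function of the configuration (no timestamps). Bundled parameter
#' files encode the standard crystal setup: PME with 1.0 nm real-space
#' cutoff and 0.16 nm grid, LJ cutoff 1.0 nm, v-rescale thermostat at
#' 300 K (tau 0.5 ps), c-rescale barostat at 1 bar (tau 5.0 ps,
#' anisotropic, as the box is a unit cell), LINCS on hydrogen bonds,
#' 100 ps NVT and 100 ps NPT equilibration with heavy-atom position
#' restraints, 2 fs leap-frog steps, 20 ns production. User-supplied
#' `mdp_overrides` entries replace bundled files.
#'
#' @param config Named list of run options; unknown keys are an error.
#'   See `names(xtalmd:::default_workflow_config())` for the valid keys.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `script` (path), `mdp` (named paths),
#'   `manifest` (path), `steps` (data frame: scale, step, command).
#' @export
render_workflow <- function(config = list(), dir = ".") {
  unknown <- setdiff(names(config), .valid_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(.valid_config_keys, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(default_workflow_config(), config)
  sg <- if (inherits(cfg$scale_grid, "scale_grid")) cfg$scale_grid else
    scale_grid(cfg$scale_grid$center, cfg$scale_grid$n, cfg$scale_grid$step)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdp_dir <- file.path(dir, "mdp")
  dir.create(mdp_dir, showWarnings = FALSE)

  bundled <- mdp_files_for(cfg)
  mdp_paths <- list()   # files on disk (absolute/user paths)
  mdp_ref <- list()     # how the script refers to them (relative for bundled)
  for (nm in names(bundled)) {
    if (nm %in% names(cfg$mdp_overrides)) {
      mdp_paths[[nm]] <- cfg$mdp_overrides[[nm]]   # user file referenced as-is
      mdp_ref[[nm]] <- cfg$mdp_overrides[[nm]]
    } else {
      p <- file.path(mdp_dir, paste0(nm, ".mdp"))
      writeLines(bundled[[nm]], p)
      mdp_paths[[nm]] <- p
      mdp_ref[[nm]] <- file.path("mdp", paste0(nm, ".mdp"))
    }
  }

  steps <- list()
  lines <- c("#!/bin/bash", "set -euo pipefail",
             "# GROMACS crystal workflow rendered by xtalmd",
             sprintf("STRUCTURE=%s", cfg$structure),
             sprintf("FF=%s", cfg$forcefield),
             sprintf("WATER=%s", cfg$water_model), "")
  for (s in sg$values) {
    tag <- sprintf("scale_%s", gsub("\\.", "p", format(s)))
    lines <- c(lines, sprintf("mkdir -p %s", tag))
    cmd <- c(
      hydrogens = sprintf(
        "gmx pdb2gmx -f $STRUCTURE -o %s/conf.gro -p %s/topol.top -ff $FF -water $WATER",
        tag, tag),
      solvate = sprintf(
        "gmx solvate -cp %s/conf.gro -o %s/solv.gro -p %s/topol.top -scale %s",
        tag, tag, tag, format(s)),
      ions = sprintf(
        "gmx grompp -f %s -c %s/solv.gro -p %s/topol.top -o %s/ions.tpr && echo SOL | gmx genion -s %s/ions.tpr -o %s/ions.gro -p %s/topol.top -neutral -conc %g",
        mdp_ref$minimize, tag, tag, tag, tag, tag, tag, cfg$concentration),
      minimize = sprintf(
        "gmx grompp -f %s -c %s/ions.gro -p %s/topol.top -o %s/em.tpr && gmx mdrun -deffnm %s/em",
        mdp_ref$minimize, tag, tag, tag, tag),
      equilibrate = sprintf(
        "gmx grompp -f %s -c %s/em.gro -r %s/em.gro -p %s/topol.top -o %s/nvt.tpr && gmx mdrun -deffnm %s/nvt && gmx grompp -f %s -c %s/nvt.gro -r %s/nvt.gro -p %s/topol.top -o %s/npt.tpr && gmx mdrun -deffnm %s/npt",
        mdp_ref$nvt, tag, tag, tag, tag, tag,
        mdp_ref$npt, tag, tag, tag, tag, tag),
      production = sprintf(
        "gmx grompp -f %s -c %s/npt.gro -p %s/topol.top -o %s/prod.tpr && gmx mdrun -deffnm %s/prod",
        mdp_ref$production, tag, tag, tag, tag))
    for (nm in .workflow_steps) {
      lines <- c(lines, sprintf("# [step] scale=%s name=%s", format(s), nm),
                 cmd[[nm]])
      steps[[length(steps) + 1L]] <- data.frame(scale = s, step = nm,
                                                command = cmd[[nm]],
                                                stringsAsFactors = FALSE)
    }
    lines <- c(lines, "")
  }
  script <- file.path(dir, "run_crystal.sh")
  writeLines(lines, script)

  manifest <- file.path(dir, "manifest.yaml")
  write_yaml_lite(list(
    structure = cfg$structure, forcefield = cfg$forcefield,
    water_model = cfg$water_model, pH = cfg$pH,
    scale_values = sg$values, concentration = cfg$concentration,
    nvt_ps = cfg$nvt_ps, npt_ps = cfg$npt_ps,
    production_ns = cfg$production_ns, dt_fs = cfg$dt_fs,
    temperature_K = cfg$temperature_K, pressure_bar = cfg$pressure_bar,
    seed = cfg$seed,
    mdp = mdp_paths), manifest)

  invisible(list(script = script, mdp = mdp_paths, manifest = manifest,
                 steps = do.call(rbind, steps)))
}
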