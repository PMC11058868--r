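test_that("scale grids: default probe grid and custom arithmetic grids", {
  g <- default_scale_grid()
  expect_equal(g$values, c(0.53, 0.55, 0.57, 0.59, 0.61))
  expect_equal(g$center, 0.57)
  expect_equal(g$step, 0.02)
  expect_true(all(diff(g$values) > 0))
  expect_true(g$center %in% g$values)

  custom <- scale_grid(center = 0.54, n = 3, step = 0.01)
  expect_equal(custom$values, c(0.53, 0.54, 0.55))
  expect_error(scale_grid(0.57, n = 4), "n")
})

test_that("water template reproduces the canonical 216-water tile", {
  tpl <- water_template()
  expect_equal(nrow(tpl$oxygen), 216)
  expect_equal(tpl$edge, 1.862)
  expect_equal(tpl$density, 216 / 1.862^3)
  expect_equal(nrow(tpl$hydrogens), 432)
  # rigid geometry: O-H distance 0.09572 nm for every molecule
  d1 <- sqrt(rowSums((tpl$oxygen - tpl$hydrogens[seq(1, 432, 2), ])^2))
  expect_equal(max(abs(d1 - 0.09572)), 0, tolerance = 1e-12)
})

test_that("candidate generation fills a box at the template density", {
  tpl <- water_template()
  # empty cubic 3 nm box: kept density within 5% of the template
  cand <- candidate_waters(diag(3) * 3.0, tpl)
  dens <- cand$n / 27
  expect_lt(abs(dens - tpl$density) / tpl$density, 0.05)

  # box commensurate with exactly 8 tiles
  cand8 <- candidate_waters(diag(3) * (2 * tpl$edge), tpl)
  expect_equal(cand8$n, 8 * 216)

  # triclinic box: every kept oxygen has fractional coordinates in [0,1)^3
  box <- cell_to_box(cell_parameters(28, 30, 32, 90, 105, 90), unit = "nm")
  candt <- candidate_waters(box, tpl)
  frac <- candt$oxygen %*% t(solve(t(box)))
  expect_true(all(frac >= 0 & frac < 1))
  expect_error(candidate_waters(matrix(0, 3, 3), tpl), "degenerate")
})

test_that("pruning limits: empty solute keeps all, huge scale keeps none", {
  tpl <- water_template(4, 1.2)
  box <- diag(3) * 2.4
  cand <- candidate_waters(box, tpl)
  empty <- make_structure(matrix(numeric(0), ncol = 3))
  kept_all <- prune_overlaps(cand, empty, 0.57, box)
  expect_equal(kept_all$n, cand$n)

  solute <- make_structure(rbind(c(12, 12, 12)))   # Angstrom, box center
  kept_none <- prune_overlaps(cand, solute, 10, box)
  expect_equal(kept_none$n, 0)
})

test_that("pruning matches the brute-force minimum-image oracle", {
  set.seed(31)
  tpl <- water_template(3, 0.9)
  box <- cell_to_box(cell_parameters(11, 12, 13, 90, 101, 90), unit = "nm")
  cand <- candidate_waters(box, tpl)
  for (rep in 1:6) {
    solute <- make_structure(matrix(runif(15, 0, 10), ncol = 3),
                             element = sample(c("C", "N", "O", "S"), 5, TRUE),
                             resid = 1:5)
    scale <- sample(c(0.53, 0.57, 0.61, 1.2), 1)
    kept <- prune_overlaps(cand, solute, scale, box)
    want <- oracle_prune_kept(cand, solute, scale, box)
    got <- which(apply(cand$oxygen, 1, function(o)
      any(rowSums(sweep(kept$oxygen, 2, o)^2) < 1e-18)))
    expect_equal(got, want)
  }
})

test_that("kept-water count is non-increasing in scale on every fixture", {
  set.seed(17)
  tpl <- water_template(4, 1.2)
  for (rep in 1:4) {
    cellv <- c(runif(3, 10, 14), 90, sample(c(90, 104), 1), 90)
    cell <- cell_parameters(cellv[1], cellv[2], cellv[3],
                            cellv[4], cellv[5], cellv[6])
    box <- cell_to_box(cell, unit = "nm")
    cand <- candidate_waters(box, tpl)
    solute <- make_structure(matrix(runif(24, 2, 10), ncol = 3),
                             element = sample(c("C", "N", "O"), 8, TRUE),
                             resid = 1:8)
    counts <- vapply(default_scale_grid()$values, function(s)
      prune_overlaps(cand, solute, s, box)$n, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("pruning is invariant under lattice translation of the solute", {
  tpl <- water_template(3, 0.9)
  cell <- cell_parameters(11, 12, 13, 90, 99, 90)
  box <- cell_to_box(cell, unit = "nm")
  cand <- candidate_waters(box, tpl)
  set.seed(23)
  solute <- make_structure(matrix(runif(12, 0, 10), ncol = 3), resid = 1:4)
  k0 <- prune_overlaps(cand, solute, 0.57, box)
  lat <- as.vector(c(1, -1, 2) %*% box) * 10   # lattice vector, Angstrom
  shifted <- solute
  shifted$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(solute$atoms[, c("x", "y", "z")]), 2, -lat)
  k1 <- prune_overlaps(cand, shifted, 0.57, box)
  expect_equal(k1$n, k0$n)
  expect_equal(k1$oxygen, k0$oxygen)
})

test_that("missing vdW radius names the element", {
  tpl <- water_template(2, 0.6)
  box <- diag(3) * 1.2
  cand <- candidate_waters(box, tpl)
  odd <- make_structure(rbind(c(6, 6, 6)), element = "XX")
  expect_error(prune_overlaps(cand, odd, 0.57, box), "XX")
})

test_that("ion planning is exact arithmetic and always neutralizes", {
  expect_equal(plan_ions(0, 5550, 0.15), c("NA" = 15L, "CL" = 15L))
  expect_equal(plan_ions(-4, 1000, 0), c("NA" = 4L, "CL" = 0L))
  # +3 charge: Na - Cl = -3 with the pair baseline 15
  p <- plan_ions(3, 5550, 0.15)
  expect_equal(unname(p["NA"] - p["CL"]), -3L)
  expect_gte(min(p), 15L - 3L)
  # property: net charge is exactly zero across random cases
  set.seed(41)
  for (k in 1:25) {
    q <- sample(-8:8, 1)
    nw <- sample(100:9000, 1)
    conc <- runif(1, 0, 0.3)
    p <- plan_ions(q, nw, conc)
    expect_true(all(p >= 0))
    expect_equal(unname(q + p["NA"] - p["CL"]), 0L)
  }
  expect_error(plan_ions(-5, 2, 0), "fewer waters")
})

test_that("solvate_structure merges SOL waters, places ions, writes the plan", {
  f <- withr::local_tempfile(fileext = ".cif")
  make_toy_asymmetric_unit(f, n_atoms = 5, cell = cell_parameters(14, 14, 14),
                           space_group = "P 1", seed = 6)
  s <- md_frame(read_mmcif(f))
  solv <- solvate_structure(s, 0.57, template = water_template(3, 0.9),
                            system_charge = -2, concentration = 0.15,
                            seed = 9)
  plan <- solv$plan
  expect_s3_class(plan, "solvation_plan")
  expect_lte(plan$n_kept_waters, plan$n_candidates)
  n_ions <- sum(unlist(plan$ion_counts))
  expect_equal(sum(solv$structure$atoms$resname == "SOL") / 3,
               plan$n_kept_waters)
  expect_equal(sum(solv$structure$atoms$het_class == "ion"), n_ions)
  # determinism for fixed seed
  solv2 <- solvate_structure(s, 0.57, template = water_template(3, 0.9),
                             system_charge = -2, concentration = 0.15,
                             seed = 9)
  expect_equal(solv2$structure$atoms, solv$structure$atoms)
  # manifest round-trip
  y <- withr::local_tempfile(fileext = ".yaml")
  write_solvation_plan(plan, y)
  back <- read_yaml_lite(y)
  expect_equal(back$scale, 0.57)
  expect_equal(back$n_kept_waters, plan$n_kept_waters)
})
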