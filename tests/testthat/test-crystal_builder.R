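toy_asym <- function(space_group, cell = cell_parameters(30, 32, 34),
                     n_atoms = 8, seed = 5, ...) {
  f <- withr::local_tempfile(fileext = ".cif", .local_envir = parent.frame())
  make_toy_asymmetric_unit(f, n_atoms = n_atoms, cell = cell,
                           space_group = space_group, seed = seed, ...)
  read_mmcif(f)
}

test_that("P 1 build is the identity: one copy, coordinates unchanged", {
  s <- toy_asym("P 1", n_atoms = 3)
  b <- build_unit_cell(s)
  expect_equal(nrow(b$atoms), 3)
  expect_equal(as.matrix(b$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("copy count equals group multiplicity for all registered groups", {
  mult <- c("P 1" = 1, "P -1" = 2, "P 1 21 1" = 2, "C 1 2 1" = 4,
            "P 21 21 21" = 4, "P 21 21 2" = 4, "P 2 2 2" = 4,
            "C 2 2 21" = 8, "P 41 21 2" = 8, "P 43 21 2" = 8)
  for (g in names(mult)) {
    s <- toy_asym(g, n_atoms = 5)
    b <- build_unit_cell(s)
    expect_equal(nrow(b$atoms), 5 * mult[[g]],
                 label = sprintf("%s atom count", g))
    expect_equal(attr(b, "build_report")$n_duplicates_removed, 0)
    # copies carry distinct chain identifiers
    expect_equal(length(b$chains), mult[[g]])
  }
})

test_that("each copy maps back onto the asymmetric unit under its inverse op", {
  for (g in c("P 21 21 21", "C 1 2 1", "P 1 21 1")) {
    cell <- cell_parameters(28, 31, 37, 90, 97, 90)
    if (g == "P 21 21 21") cell <- cell_parameters(28, 31, 37)
    s <- toy_asym(g, cell = cell, n_atoms = 6, seed = 8)
    b <- build_unit_cell(s)
    ops <- symmetry_operations_for_group(g)
    A <- orthogonalization_matrix(cell)
    x0 <- as.matrix(s$atoms[, c("x", "y", "z")])
    copy_id <- attr(b, "copy_id")
    for (k in seq_along(ops)) {
      xk <- as.matrix(b$atoms[copy_id == k, c("x", "y", "z")])
      cop <- to_cartesian_op(ops[[k]], A)
      # invert the Cartesian op, then remove the whole-cell wrapping
      back <- t(solve(cop$M) %*% (t(xk) - cop$V))
      frac_diff <- t(solve(A) %*% t(back - x0))
      frac_diff <- frac_diff - round(frac_diff)
      rmsd <- sqrt(mean((frac_diff %*% t(A))^2))
      expect_lt(rmsd, 1e-6)
    }
  }
})

test_that("every copy's geometric center lies inside the cell parallelepiped", {
  s <- toy_asym("P 41 21 2", cell = cell_parameters(30, 30, 44), n_atoms = 7)
  b <- build_unit_cell(s)
  A <- orthogonalization_matrix(s$cell)
  copy_id <- attr(b, "copy_id")
  for (k in unique(copy_id)) {
    ctr <- colMeans(b$atoms[copy_id == k, c("x", "y", "z")])
    frac <- as.vector(solve(A) %*% ctr)
    expect_true(all(frac >= 0 & frac < 1))
  }
})

test_that("building commutes with translating the input by a lattice vector", {
  s <- toy_asym("P 21 21 21", n_atoms = 6, seed = 13)
  A <- orthogonalization_matrix(s$cell)
  shift <- as.vector(A %*% c(1, -2, 1))
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- sweep(as.matrix(s$atoms[, c("x", "y", "z")]),
                                        2, -shift)
  b1 <- build_unit_cell(s)
  b2 <- build_unit_cell(s2)
  expect_equal(as.matrix(b2$atoms[, c("x", "y", "z")]),
               as.matrix(b1$atoms[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("coincident symmetry-mate atoms at special positions are deduplicated", {
  # an atom exactly on the two-fold axis of P 1 2 1 (x = z = 0) maps to
  # itself; off-axis atoms do not
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resname = "ALA", resid = 1:2, chain = "A", altloc = "",
                      occupancy = 1,
                      x = c(0, 5), y = c(3, 3), z = c(0, 7),
                      het = FALSE, stringsAsFactors = FALSE)
  s <- xtal_structure(atoms, cell = cell_parameters(20, 20, 20),
                      space_group = "P 1 2 1")
  b <- build_unit_cell(s)
  expect_equal(attr(b, "build_report")$n_duplicates_removed, 1)
  expect_equal(nrow(b$atoms), 3)
})

test_that("oversized builds abort with the limit hint", {
  s <- toy_asym("P 21 21 21", n_atoms = 10)
  expect_error(build_unit_cell(s, max_atoms = 20), "max_atoms")
})

test_that("inter-copy clashes are scanned and reported", {
  s <- toy_asym("P 21 21 21", n_atoms = 6, seed = 5)
  b <- build_unit_cell(s)
  rep <- attr(b, "build_report")
  expect_true(is.data.frame(rep$clashes))
  expect_length(rep$operators, 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_build_report(b, f)
  expect_true(any(grepl("operators", readLines(f))))
})
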