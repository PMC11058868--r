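altloc_fixture <- function() {
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(5, 5, 5))
  make_structure(xyz, resid = c(1, 1, 2), altloc = c("A", "B", ""),
                 occupancy = c(0.6, 0.4, 1))
}

test_that("altloc selection follows occupancy, explicit choice, identity", {
  s <- altloc_fixture()
  # default policy: highest occupancy wins
  r <- select_altloc(s)
  expect_equal(nrow(r$atoms), 2)
  expect_equal(r$atoms$x[1], 0)        # conformer A (occ 0.6)
  expect_true(all(r$atoms$altloc == ""))
  # explicit choice of the minor conformer
  rb <- select_altloc(s, list("A:1" = "B"))
  expect_equal(rb$atoms$x[1], 0.3)
  # absent altloc id errors and lists the available ids
  expect_error(select_altloc(s, list("A:1" = "C")), "available: A, B")
  expect_error(select_altloc(s, list("A:2" = "A")), "no alternative")
  # structures without altlocs pass through unchanged, atom for atom
  plain <- make_structure(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(select_altloc(plain), plain)
  # idempotence
  expect_identical(select_altloc(r), r)
})

test_that("occupancy ties resolve to the alphabetically first altloc", {
  s <- altloc_fixture()
  s$atoms$occupancy <- c(0.5, 0.5, 1)
  r <- select_altloc(s)
  expect_equal(r$atoms$x[1], 0)        # A kept
})

test_that("gap detection reports internal discontinuities only", {
  # residues 1-10, 14-20: one gap of 3
  s <- make_structure(matrix(seq_len(51), ncol = 3),
                      resid = c(1:10, 14:20))
  g <- find_gaps(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$preceding, 10)
  expect_equal(g$following, 14)
  expect_equal(g$missing_count, 3)
  expect_equal(g$following - g$preceding, g$missing_count + 1)

  complete <- make_structure(matrix(seq_len(60), ncol = 3), resid = 1:20)
  expect_equal(nrow(find_gaps(complete)), 0)
})

test_that("gaps in two chains carry distinct chain ids (brute-force check)", {
  set.seed(9)
  resA <- setdiff(1:15, 7)
  resB <- setdiff(1:12, c(4, 5))
  s <- make_structure(matrix(runif(3 * (length(resA) + length(resB)), 0, 50),
                             ncol = 3),
                      resid = c(resA, resB),
                      chain = c(rep("A", length(resA)), rep("B", length(resB))))
  g <- find_gaps(s)
  # brute-force scan oracle
  expected <- list()
  for (ch in c("A", "B")) {
    res <- sort(unique(s$atoms$resid[s$atoms$chain == ch]))
    for (k in seq_len(length(res) - 1))
      if (res[k + 1] - res[k] > 1)
        expected[[length(expected) + 1]] <- c(ch, res[k], res[k + 1])
  }
  expect_equal(nrow(g), length(expected))
  expect_setequal(g$chain, c("A", "B"))
  for (k in seq_along(expected))
    expect_equal(unname(unlist(g[k, 1:3])), unname(expected[[k]]))
})

test_that("clash detection: threshold arithmetic and parity with the O(n^2) oracle", {
  two <- make_structure(rbind(c(0, 0, 0), c(0.3, 0, 0)), resid = c(1, 2))
  hit <- detect_clashes(two, threshold = 0.5)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 0.3)
  far <- make_structure(rbind(c(0, 0, 0), c(0.7, 0, 0)), resid = c(1, 2))
  expect_equal(nrow(detect_clashes(far, threshold = 0.5)), 0)

  # hydrogens are excluded; intra-residue pairs are excluded
  hs <- make_structure(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)),
                       element = c("C", "H", "C"), resid = c(1, 2, 1))
  expect_equal(nrow(detect_clashes(hs, threshold = 0.5)), 0)

  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    s <- make_structure(matrix(runif(3 * n, 0, 6), ncol = 3),
                        element = sample(c("C", "N", "O", "H"), n, TRUE),
                        resid = sample(1:12, n, TRUE))
    thr <- runif(1, 0.3, 1.5)
    got <- detect_clashes(s, threshold = thr)
    want <- oracle_clashes(s, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(m) paste(m[, 1], m[, 2])
      expect_setequal(key(as.matrix(got[, c("i", "j")])), key(want))
    }
  }
})

test_that("protonation follows the standard-pKa rule at representative pH", {
  res <- c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG")
  s <- make_structure(matrix(seq_len(21), ncol = 3), resid = 1:7,
                      resname = res)
  at7 <- assign_protonation(s, 7.0)
  st <- setNames(at7$state, at7$resname)
  expect_equal(st[["ASP"]], "ASP")   # deprotonated, charged
  expect_equal(st[["GLU"]], "GLU")
  expect_equal(st[["HIS"]], "HIE")   # neutral above pKa 6.0
  expect_equal(st[["LYS"]], "LYS")   # protonated, charged
  expect_equal(st[["ARG"]], "ARG")
  expect_equal(st[["CYS"]], "CYS")   # neutral below pKa 8.3
  expect_equal(st[["TYR"]], "TYR")

  at2 <- assign_protonation(s, 2.0)
  expect_true(all(!at2$charged[at2$resname %in% c("ASP", "GLU", "CYS", "TYR")]))
  expect_true(all(at2$charged[at2$resname %in% c("HIS", "LYS", "ARG")]))

  # hand evaluation of every table row at pH 13
  at13 <- assign_protonation(s, 13.0)
  st13 <- setNames(at13$charged, at13$resname)
  expect_true(st13[["ASP"]]); expect_true(st13[["GLU"]])
  expect_true(st13[["CYS"]]); expect_true(st13[["TYR"]])
  expect_false(st13[["HIS"]]); expect_false(st13[["LYS"]])  # 13 > 10.53
  expect_false(st13[["ARG"]])                               # 13 > 12.48 -> neutral

  # tie resolves to the charged form
  tie <- assign_protonation(s, 6.0)
  expect_true(setNames(tie$charged, tie$resname)[["HIS"]])
  expect_equal(setNames(tie$state, tie$resname)[["HIS"]], "HIP")
})

test_that("protonation depends only on pH and residue type", {
  res <- c("ASP", "LYS", "HIS", "GLU")
  s1 <- make_structure(matrix(1:12, ncol = 3), resid = 1:4, resname = res)
  s2 <- make_structure(matrix(1:12, ncol = 3), resid = 4:1,
                       resname = rev(res))
  a1 <- assign_protonation(s1, 5.5)
  a2 <- assign_protonation(s2, 5.5)
  m <- match(paste(a1$chain, a1$resid), paste(a2$chain, a2$resid))
  expect_equal(a1$state, a2$state[m])
})

test_that("heteroatom retention policy drops classes and flags unknown ions", {
  f <- withr::local_tempfile(fileext = ".cif")
  make_toy_asymmetric_unit(f, n_atoms = 6, cell = cell_parameters(25, 25, 25),
                           seed = 4, waters = 10, ions = c(MG = 1, ZN = 1))
  s <- read_mmcif(f)
  n0 <- nrow(s$atoms)
  no_w <- apply_het_policy(s, keep_waters = FALSE)
  expect_equal(nrow(no_w$atoms), n0 - 10)   # one O atom per water record
  bare <- apply_het_policy(s, keep_waters = FALSE, keep_ions = FALSE,
                           keep_ligands = FALSE)
  expect_true(all(bare$atoms$het_class == "polymer"))
  expect_warning(apply_het_policy(s, ff_ions = c("MG")), "ZN")
  expect_silent(apply_het_policy(s, ff_ions = c("MG", "ZN")))
})
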