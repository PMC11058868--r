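# shared helpers and independent oracles for the test suite

# build a small ad-hoc structure from minimal atom info
make_structure <- function(xyz, element = "C", resid = seq_len(nrow(xyz)),
                           chain = "A", resname = "ALA", het = FALSE,
                           name = NULL, occupancy = 1, altloc = "",
                           cell = NULL, space_group = NA_character_) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n),
    name = if (is.null(name)) rep(element, length.out = n) else
      rep(name, length.out = n),
    element = rep(element, length.out = n),
    resname = rep(resname, length.out = n),
    resid = rep(resid, length.out = n),
    chain = rep(chain, length.out = n),
    altloc = rep(altloc, length.out = n),
    occupancy = rep(occupancy, length.out = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = rep(het, length.out = n),
    stringsAsFactors = FALSE)
  xtal_structure(atoms, cell = cell, space_group = space_group)
}

# O(n^2) all-pairs clash oracle: plain loops, independent of the
# implementation under test
oracle_clashes <- function(structure, threshold) {
  a <- structure$atoms
  heavy <- which(toupper(a$element) != "H")
  resk <- paste(a$chain, a$resid, a$resname)
  hits <- list()
  for (ii in seq_along(heavy)) for (jj in seq_along(heavy)) {
    i <- heavy[ii]; j <- heavy[jj]
    if (i >= j) next
    if (resk[i] == resk[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d < threshold) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (length(hits)) do.call(rbind, hits) else matrix(0L, 0, 2)
}

# brute-force minimum-image water pruning oracle (nm), plain loops over
# all 27 periodic images
oracle_prune_kept <- function(candidates, solute, scale, box,
                              r_probe_o = 0.14, r_probe_h = 0.12) {
  radii <- c(C = 0.17, N = 0.155, O = 0.152, H = 0.12, S = 0.18, P = 0.18)
  a <- solute$atoms
  heavy <- which(toupper(a$element) != "H")
  removed <- logical(candidates$n)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (w in seq_len(candidates$n)) {
    watoms <- rbind(candidates$oxygen[w, ],
                    candidates$hydrogens[2 * w - 1, ],
                    candidates$hydrogens[2 * w, ])
    probes <- c(r_probe_o, r_probe_h, r_probe_h)
    for (k in heavy) {
      p <- c(a$x[k], a$y[k], a$z[k]) / 10
      rk <- radii[[toupper(a$element[k])]]
      for (wa in 1:3) {
        dmin <- Inf
        for (s in seq_len(nrow(shifts))) {
          img <- p + as.vector(shifts[s, ] %*% box)
          dmin <- min(dmin, sqrt(sum((watoms[wa, ] - img)^2)))
        }
        if (dmin < scale * (probes[wa] + rk)) removed[w] <- TRUE
      }
    }
  }
  which(!removed)
}
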