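#' Unit-cell parameters
#'
#' Construct and validate the six lattice constants that define the geometry
#' of a crystallographic unit cell: the lengths of the three cell vectors
#' (\eqn{a}, \eqn{b}, \eqn{c}, in Angstrom) and the angles between them
#' (\eqn{\alpha}, \eqn{\beta}, \eqn{\gamma}, in degrees).
#'
#' A valid lattice requires all lengths positive, all angles strictly
#' between 0 and 180 degrees, and a positive metric radicand
#' \deqn{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'       + 2\cos\alpha\cos\beta\cos\gamma > 0,}
#' the quantity under the square root of the triclinic volume formula.
#'
#' @param a,b,c Cell vector lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `xtal_cell`: a named list with elements
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' cell_parameters(10, 20, 30)                   # orthorhombic
#' cell_parameters(10, 10, 10, 60, 60, 60)       # rhombohedral
#' @export
cell_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma)),
    class = "xtal_cell")
  validate_cell(cell)
  cell
}

#' @export
print.xtal_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("volume: %.3f A^3\n", unit_cell_volume(x)))
  invisible(x)
}

as_cell <- function(x) {
  if (inherits(x, "xtal_cell")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 6L)
  cell_parameters(x[1], x[2], x[3], x[4], x[5], x[6])
}

# metric radicand of the triclinic volume formula; must be > 0 for a
# geometrically realizable lattice
cell_radicand <- function(cell) {
  ca <- cos_deg(cell$alpha); cb <- cos_deg(cell$beta); cg <- cos_deg(cell$gamma)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

validate_cell <- function(cell) {
  lens <- c(cell$a, cell$b, cell$c)
  angs <- c(cell$alpha, cell$beta, cell$gamma)
  if (any(!is.finite(c(lens, angs))))
    stop("cell parameters must be finite numbers", call. = FALSE)
  if (any(lens <= 0))
    stop("cell lengths must be positive", call. = FALSE)
  if (any(angs <= 0 | angs >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees", call. = FALSE)
  if (cell_radicand(cell) <= 0)
    stop("invalid lattice: 1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma) + ",
         "2 cos(alpha) cos(beta) cos(gamma) must be positive", call. = FALSE)
  invisible(cell)
}

cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)

#' Unit-cell volume
#'
#' Volume of a (possibly triclinic) unit cell from its six lattice
#' constants:
#' \deqn{V = a\,b\,c\,\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'       + 2\cos\alpha\cos\beta\cos\gamma}.}
#'
#' @param cell An [cell_parameters()] object (or a length-6 numeric vector
#'   `a, b, c, alpha, beta, gamma`).
#' @return Volume in cubic Angstrom.
#' @examples
#' unit_cell_volume(cell_parameters(10, 10, 10))            # 1000
#' unit_cell_volume(cell_parameters(10, 10, 10, 60, 60, 60))# 1000*sqrt(0.5)
#' @export
unit_cell_volume <- function(cell) {
  cell <- as_cell(cell)
  rad <- cell_radicand(cell)
  if (rad <= 0)
    stop("invalid lattice: volume radicand is not positive", call. = FALSE)
  cell$a * cell$b * cell$c * sqrt(rad)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' The upper-triangular matrix \eqn{A} mapping fractional cell coordinates
#' to Cartesian Angstrom coordinates,
#' \deqn{A = \begin{pmatrix} a & b\cos\gamma & c\cos\beta \\
#'   0 & b\sin\gamma & -c\sin\beta\cos\alpha^* \\
#'   0 & 0 & c\sin\beta\sin\alpha^* \end{pmatrix}}
#' with the reciprocal-style angle \eqn{\alpha^*} defined by
#' \deqn{\cos\alpha^* = \frac{\cos\beta\cos\gamma - \cos\alpha}
#'   {\sin\beta\sin\gamma}.}
#' The absolute determinant of \eqn{A} equals the triclinic cell volume.
#'
#' @inheritParams unit_cell_volume
#' @return A 3x3 numeric matrix with attribute `alpha_star` (degrees).
#' @examples
#' orthogonalization_matrix(cell_parameters(10, 20, 30))  # diag(10,20,30)
#' @export
orthogonalization_matrix <- function(cell) {
  cell <- as_cell(cell)
  validate_cell(cell)
  ca <- cos_deg(cell$alpha); cb <- cos_deg(cell$beta); cg <- cos_deg(cell$gamma)
  sb <- sin_deg(cell$beta);  sg <- sin_deg(cell$gamma)
  cas <- (cb * cg - ca) / (sb * sg)
  # clamp tiny numerical overshoot at right-angle degeneracies
  cas <- min(1, max(-1, cas))
  sas <- sqrt(1 - cas^2)
  A <- matrix(c(cell$a, cell$b * cg,      cell$c * cb,
                0,      cell$b * sg,     -cell$c * sb * cas,
                0,      0,                cell$c * sb * sas),
              nrow = 3, byrow = TRUE)
  attr(A, "alpha_star") <- acos(cas) * 180 / pi
  A
}

#' Cell parameters to lower-triangular MD box vectors
#'
#' Converts lattice constants to the triclinic box convention used by MD
#' engines: first vector along x, second in the xy plane, returned as the
#' rows of a 3x3 lower-triangular matrix.
#'
#' @inheritParams unit_cell_volume
#' @param unit Output length unit, `"A"` (Angstrom, default) or `"nm"`.
#' @return 3x3 matrix; row i is box vector i.
#' @export
cell_to_box <- function(cell, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  cell <- as_cell(cell)
  validate_cell(cell)
  ca <- cos_deg(cell$alpha); cb <- cos_deg(cell$beta); cg <- cos_deg(cell$gamma)
  sg <- sin_deg(cell$gamma)
  v3x <- cell$c * cb
  v3y <- cell$c * (ca - cb * cg) / sg
  v3z2 <- cell$c^2 - v3x^2 - v3y^2
  if (v3z2 <= 0) stop("invalid lattice: degenerate box", call. = FALSE)
  box <- matrix(c(cell$a,        0,            0,
                  cell$b * cg,   cell$b * sg,  0,
                  v3x,           v3y,          sqrt(v3z2)),
                nrow = 3, byrow = TRUE)
  if (unit == "nm") box <- box / 10
  box
}

#' Box vectors to cell parameters
#'
#' Recovers lattice constants from three box vectors (rows of a 3x3
#' matrix); lengths are taken as vector norms and angles from dot
#' products, so any orientation is accepted.
#'
#' @param box 3x3 numeric matrix, rows are the box vectors.
#' @param unit Length unit of `box`, `"A"` or `"nm"`; output cell is
#'   always in Angstrom.
#' @return A [cell_parameters()] object.
#' @export
box_to_cell <- function(box, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  box <- as.matrix(box)
  stopifnot(nrow(box) == 3L, ncol(box) == 3L)
  if (unit == "nm") box <- box * 10
  len <- sqrt(rowSums(box^2))
  ang <- function(i, j) acos(sum(box[i, ] * box[j, ]) / (len[i] * len[j])) * 180 / pi
  cell_parameters(len[1], len[2], len[3],
                  alpha = ang(2, 3), beta = ang(1, 3), gamma = ang(1, 2))
}
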