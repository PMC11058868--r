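#' Parse a symmetry operator triplet
#'
#' Parses a crystallographic operator-triplet string such as
#' `"-x,y+1/2,-z"` into a Seitz pair \{R|t\}: the 3x3 rotation part `R`
#' acting on fractional coordinates and the fractional translation `t`.
#' Translations are reduced mod 1 into `[0, 1)`.
#'
#' @param xyz_text Comma-separated operator triplet over tokens
#'   `x, y, z`, signs, integers and fractions (e.g. `"x+1/2,-y+1/2,-z"`).
#' @return An object of class `symop`: list with `R` (3x3 matrix),
#'   `t` (length-3 numeric in `[0,1)`), and `xyz` (the source string).
#' @examples
#' parse_symmetry_operator("x,y,z")
#' parse_symmetry_operator("-x,y+1/2,-z")
#' @export
parse_symmetry_operator <- function(xyz_text) {
  stopifnot(is.character(xyz_text), length(xyz_text) == 1L)
  parts <- strsplit(gsub("[[:space:]]", "", tolower(xyz_text)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop(sprintf("operator triplet must have 3 comma-separated components, got %d in '%s'",
                 length(parts), xyz_text), call. = FALSE)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in seq_len(3)) {
    comp <- parts[i]
    if (!nzchar(comp))
      stop(sprintf("empty component %d in operator '%s'", i, xyz_text), call. = FALSE)
    # split into signed terms: coefficient-variable or pure number/fraction
    term_rx <- "[+-]?([0-9]+(\\.[0-9]+)?(/[0-9]+)?)?[xyz]|[+-]?[0-9]+(\\.[0-9]+)?(/[0-9]+)?"
    m <- gregexpr(term_rx, comp)[[1]]
    terms <- regmatches(comp, gregexpr(term_rx, comp))[[1]]
    if (length(terms) == 0L || sum(attr(m, "match.length")) != nchar(comp))
      stop(sprintf("malformed component '%s' in operator '%s'", comp, xyz_text),
           call. = FALSE)
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      var <- regmatches(body, regexpr("[xyz]$", body))
      num <- sub("[xyz]$", "", body)
      coef <- if (!nzchar(num)) 1 else {
        if (grepl("/", num, fixed = TRUE)) {
          fr <- strsplit(num, "/", fixed = TRUE)[[1]]
          as.numeric(fr[1]) / as.numeric(fr[2])
        } else as.numeric(num)
      }
      if (length(var) == 1L) {
        j <- match(var, c("x", "y", "z"))
        R[i, j] <- R[i, j] + sign * coef
      } else {
        t[i] <- t[i] + sign * coef
      }
    }
  }
  t <- t %% 1
  op <- structure(list(R = R, t = t, xyz = xyz_text), class = "symop")
  if (abs(abs(det(R)) - 1) > 1e-9)
    stop(sprintf("operator '%s' has |det(R)| != 1", xyz_text), call. = FALSE)
  op
}

#' @export
print.symop <- function(x, ...) {
  cat("symmetry operation:", x$xyz, "\n")
  invisible(x)
}

symop_to_xyz <- function(op) {
  comp <- function(i) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r == 0) next
      v <- c("x", "y", "z")[j]
      s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "", v)
    }
    ti <- op$t[i] %% 1
    if (ti > 1e-9) {
      fr <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4",
              `0.3333333333` = "1/3", `0.6666666667` = "2/3",
              `0.1666666667` = "1/6", `0.8333333333` = "5/6")
      key <- names(fr)[which(abs(as.numeric(names(fr)) - ti) < 1e-6)]
      s <- paste0(s, "+", if (length(key)) fr[[key]] else format(ti))
    }
    s
  }
  paste(vapply(1:3, comp, ""), collapse = ",")
}

# compose two fractional-space operators: (op1 o op2)(p) = R1(R2 p + t2) + t1
compose_symops <- function(op1, op2) {
  R <- op1$R %*% op2$R
  t <- (as.vector(op1$R %*% op2$t) + op1$t) %% 1
  op <- structure(list(R = R, t = t, xyz = NA_character_), class = "symop")
  op$xyz <- symop_to_xyz(op)
  op
}

symop_equal <- function(a, b, tol = 1e-9) {
  dt <- (a$t - b$t) %% 1
  dt <- pmin(dt, 1 - dt)
  max(abs(a$R - b$R)) < tol && max(abs(dt)) < tol
}

# operator-triplet tables for the space groups supported out of the box:
# the groups of the validation systems plus common protein groups.
# Centering translations are expanded explicitly.
.space_group_registry <- list(
  "p1" = c("x,y,z"),
  "p-1" = c("x,y,z", "-x,-y,-z"),
  "p121" = c("x,y,z", "-x,y,-z"),
  "p1211" = c("x,y,z", "-x,y+1/2,-z"),
  "c121" = c("x,y,z", "-x,y,-z",
             "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "p222" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
  "p2221" = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z"),
  "p21212" = c("x,y,z", "-x,-y,z",
               "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "p212121" = c("x,y,z", "-x+1/2,-y,z+1/2",
                "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "c2221" = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z",
              "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2",
              "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "p41212" = c("x,y,z", "-x,-y,z+1/2",
               "-y+1/2,x+1/2,z+1/4", "y+1/2,-x+1/2,z+3/4",
               "-x+1/2,y+1/2,-z+1/4", "x+1/2,-y+1/2,-z+3/4",
               "y,x,-z", "-y,-x,-z+1/2"),
  "p43212" = c("x,y,z", "-x,-y,z+1/2",
               "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
               "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
               "y,x,-z", "-y,-x,-z+1/2")
)

# normalize a Hermann-Mauguin name: case-fold, drop spaces and underscores,
# so "P 21 21 21", "P212121" and "P_21_21_21" are equivalent
normalize_hm_name <- function(hm_name) {
  gsub("[[:space:]_]", "", tolower(hm_name))
}

#' Registered space groups
#'
#' Hermann-Mauguin names of the space groups with built-in operator
#' tables. Any group can still be used if the input file carries its own
#' operator-triplet list.
#'
#' @return Character vector of normalized group keys.
#' @export
registered_space_groups <- function() names(.space_group_registry)

#' Symmetry operations of a space group
#'
#' Looks up the full list of general-position operators (including
#' centering translations) for a Hermann-Mauguin space-group name in the
#' built-in registry, or parses an explicit operator-triplet list when
#' one is supplied (e.g. from the structure file itself, which takes
#' precedence).
#'
#' @param hm_name Hermann-Mauguin name, e.g. `"P 21 21 21"`. Spacing,
#'   case and underscores are ignored.
#' @param xyz_list Optional character vector of operator triplets that
#'   overrides the registry.
#' @return List of [parse_symmetry_operator()] objects.
#' @examples
#' length(symmetry_operations_for_group("P 1"))         # 1
#' length(symmetry_operations_for_group("P 21 21 21"))  # 4
#' @export
symmetry_operations_for_group <- function(hm_name, xyz_list = NULL) {
  if (!is.null(xyz_list) && length(xyz_list) > 0)
    return(lapply(xyz_list, parse_symmetry_operator))
  key <- normalize_hm_name(hm_name)
  if (!key %in% names(.space_group_registry))
    stop(sprintf(paste0("space group '%s' is not in the built-in registry ",
                        "(%s) and no in-file operator list was supplied"),
                 hm_name, paste(names(.space_group_registry), collapse = ", ")),
         call. = FALSE)
  lapply(.space_group_registry[[key]], parse_symmetry_operator)
}

#' Transform a fractional-space symmetry operation to Cartesian space
#'
#' Seitz matrices \{R|t\} act in fractional cell coordinates; to apply
#' them to Cartesian coordinates they are conjugated with the
#' orthogonalization matrix \eqn{A}:
#' \deqn{M = A R A^{-1}, \qquad V = A t.}
#'
#' @param op A [parse_symmetry_operator()] object.
#' @param A Orthogonalization matrix from [orthogonalization_matrix()].
#' @return Object of class `cartesian_symop`: list with `M` (3x3
#'   Cartesian rotation) and `V` (Cartesian translation, Angstrom).
#' @export
to_cartesian_op <- function(op, A) {
  stopifnot(inherits(op, "symop"))
  A <- as.matrix(A)
  M <- A %*% op$R %*% solve(A)
  V <- as.vector(A %*% op$t)
  structure(list(M = M, V = V, xyz = op$xyz), class = "cartesian_symop")
}
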