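# Volume-based verification of the solvent count: per-frame unit-cell
# volume, trajectory averaging, the 0.5% acceptance criterion against
# the experimental volume, and the refinement proposal when no probed
# scale passes.

#' Read a box series from a trajectory or box table
#'
#' Recovers per-frame cell parameters and volumes from either a
#' multi-frame GRO trajectory (box vectors under the lower-triangular MD
#' convention) or a plain whitespace-delimited text table with one frame
#' per row and columns `a b c alpha beta gamma` (Angstrom and degrees;
#' `#` comments allowed). Binary trajectory formats require external
#' readers and are outside this adapter.
#'
#' @param source File path; `.gro` files are treated as trajectories,
#'   anything else as a box table.
#' @return Object of class `volume_series`: data frame with columns
#'   `frame`, `a`, `b`, `c`, `alpha`, `beta`, `gamma`, `volume`
#'   (Angstrom^3) and attribute `mean_volume`.
#' @export
read_box_series <- function(source) {
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  if (grepl("\\.gro$", source, ignore.case = TRUE)) {
    cells <- read_gro_boxes(source)
  } else {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0) stop("no frames in box table: ", source,
                                 call. = FALSE)
    vals <- lapply(seq_along(lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 6 || anyNA(v))
        stop(sprintf("frame %d: expected 6 numeric columns (a b c alpha beta gamma)", i),
             call. = FALSE)
      v
    })
    cells <- do.call(rbind, vals)
  }
  df <- as.data.frame(cells)
  names(df) <- c("a", "b", "c", "alpha", "beta", "gamma")
  df$volume <- vapply(seq_len(nrow(df)), function(i)
    unit_cell_volume(as.numeric(df[i, 1:6])), 0)
  df <- cbind(frame = seq_len(nrow(df)), df)
  class(df) <- c("volume_series", class(df))
  attr(df, "mean_volume") <- mean(df$volume)
  df
}

# per-frame cell parameters from a concatenated multi-frame gro file
read_gro_boxes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cells <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    frame <- frame + 1L
    if (i + 1L > length(lines))
      stop(sprintf("frame %d: truncated trajectory", frame), call. = FALSE)
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop(sprintf("frame %d: bad atom count line", frame),
                       call. = FALSE)
    box_line <- i + 2L + n
    if (box_line > length(lines))
      stop(sprintf("frame %d: missing box record", frame), call. = FALSE)
    box <- parse_gro_box(lines[box_line])
    cell <- box_to_cell(box)
    cells[[frame]] <- c(cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                        cell$gamma)
    i <- box_line + 1L
  }
  do.call(rbind, cells)
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("volume series: %d frames, mean volume %.2f A^3\n",
              nrow(x), attr(x, "mean_volume")))
  invisible(x)
}

#' Mean volume of a series
#'
#' Arithmetic mean of the per-frame volumes, optionally discarding an
#' initial stretch of frames. All production frames are included by
#' default.
#'
#' @param series A [read_box_series()] result.
#' @param discard_initial Number of leading frames to drop.
#' @return Mean volume in Angstrom^3.
#' @export
mean_volume <- function(series, discard_initial = 0) {
  v <- series$volume
  if (discard_initial > 0) v <- v[-seq_len(min(discard_initial, length(v) - 1))]
  mean(v)
}

#' Judge the probed scale values against the experimental volume
#'
#' A scale passes when the mean simulated unit-cell volume lies within
#' `tolerance` (default 0.5%) of the experimental value. Among passing
#' scales the one with the smallest relative deviation is accepted, ties
#' broken toward the larger scale (fewer waters, cheaper system). When
#' nothing passes, a refinement grid is proposed via
#' [suggest_refinement()].
#'
#' @param mean_volumes Named numeric vector: names are scale values,
#'   entries mean volumes in Angstrom^3.
#' @param v_exp Experimental unit-cell volume, Angstrom^3.
#' @param tolerance Relative acceptance tolerance (fraction).
#' @param n_new Number of values in a proposed refinement grid.
#' @return Object of class `volume_verdict`: list with `mean_volumes`,
#'   `experimental_volume`, `relative_deviations`, `tolerance`,
#'   `accepted_scale` (numeric or NA), `proposal` (a [scale_grid()] or
#'   NULL).
#' @examples
#' evaluate_volumes(c("0.57" = 1000), v_exp = 1000)  # accepted
#' @export
evaluate_volumes <- function(mean_volumes, v_exp, tolerance = 0.005,
                             n_new = 3) {
  stopifnot(length(mean_volumes) >= 1, v_exp > 0)
  scales <- as.numeric(names(mean_volumes))
  if (anyNA(scales))
    stop("mean_volumes must be named by scale values", call. = FALSE)
  ord <- order(scales)
  scales <- scales[ord]
  mv <- as.numeric(mean_volumes)[ord]
  dev <- (mv - v_exp) / v_exp
  ok <- abs(dev) <= tolerance
  if (any(ok)) {
    cand <- which(ok)
    # round before ordering so the tie-break is immune to float noise
    # (the verdict must be invariant under rescaling all volumes)
    best <- cand[order(signif(abs(dev[cand]), 9), -scales[cand])][1]
    accepted <- scales[best]
    proposal <- NULL
  } else {
    accepted <- NA_real_
    proposal <- suggest_refinement(stats::setNames(mv, scales), v_exp,
                                   n_new = n_new)
  }
  base::structure(list(mean_volumes = stats::setNames(mv, scales),
                       experimental_volume = v_exp,
                       relative_deviations = stats::setNames(dev, scales),
                       tolerance = tolerance,
                       accepted_scale = accepted,
                       proposal = proposal),
                  class = "volume_verdict")
}

#' @export
print.volume_verdict <- function(x, ...) {
  cat(sprintf("volume check vs experimental %.2f A^3 (tolerance %.2f%%):\n",
              x$experimental_volume, 100 * x$tolerance))
  for (k in seq_along(x$mean_volumes))
    cat(sprintf("  scale %-6s mean %.2f A^3  deviation %+.3f%%\n",
                names(x$mean_volumes)[k], x$mean_volumes[k],
                100 * x$relative_deviations[k]))
  if (!is.na(x$accepted_scale)) {
    cat(sprintf("accepted scale: %s\n", format(x$accepted_scale)))
  } else {
    cat("no scale within tolerance; suggested second-iteration grid:",
        paste(format(x$proposal$values), collapse = " "), "\n")
  }
  invisible(x)
}

#' Propose a refined scale grid
#'
#' Called when no probed scale preserves the experimental volume.
#' Exploits the monotone decrease of mean volume with scale (smaller
#' scale keeps more waters, hence a larger equilibrium volume): when two
#' adjacent probed scales bracket the experimental volume, `n_new`
#' evenly spaced values strictly between them are proposed; when the
#' experimental volume lies above all means, the grid is extended below
#' the smallest scale by the original step; below all means, above the
#' largest scale. With noisy, non-monotone means the adjacent
#' opposite-sign pair with deviations nearest zero is used; failing
#' that, the grid is extended in the direction of the smallest
#' deviation.
#'
#' @inheritParams evaluate_volumes
#' @param n_new Number of proposed values.
#' @return A [scale_grid()]-classed object; proposed values never repeat
#'   a probed value.
#' @examples
#' suggest_refinement(c("0.53" = 1004, "0.55" = 992), v_exp = 1000)
#' @export
suggest_refinement <- function(mean_volumes, v_exp, n_new = 3) {
  stopifnot(n_new >= 1, v_exp > 0)
  scales <- as.numeric(names(mean_volumes))
  ord <- order(scales)
  scales <- scales[ord]
  dev <- (as.numeric(mean_volumes)[ord] - v_exp) / v_exp
  step <- if (length(scales) > 1) min(diff(scales)) else 0.02

  bracket <- NULL
  if (length(scales) > 1) {
    cross <- which(dev[-length(dev)] * dev[-1] < 0)
    if (length(cross)) {
      score <- abs(dev[cross]) + abs(dev[cross + 1])
      bracket <- cross[which.min(score)]
    }
  }
  if (!is.null(bracket)) {
    lo <- scales[bracket]; hi <- scales[bracket + 1]
    values <- seq(lo, hi, length.out = n_new + 2)[2:(n_new + 1)]
  } else if (all(dev < 0)) {
    # all volumes below experimental: need more waters -> smaller scales
    values <- scales[1] - step * rev(seq_len(n_new))
  } else if (all(dev > 0)) {
    values <- scales[length(scales)] + step * seq_len(n_new)
  } else {
    dir_down <- scales[which.min(abs(dev))] <= stats::median(scales)
    values <- if (dir_down) scales[1] - step * rev(seq_len(n_new)) else
      scales[length(scales)] + step * seq_len(n_new)
  }
  values <- round(values, 10)
  if (any(values <= 0))
    stop("refinement proposal reached non-positive scale values",
         call. = FALSE)
  base::structure(list(values = values,
                       center = values[ceiling(length(values) / 2)],
                       step = if (length(values) > 1) values[2] - values[1]
                              else step),
                  class = "scale_grid")
}

#' Write the verdict report and, if needed, the next-iteration input
#'
#' Writes a plain-text verdict report; when no scale passed, also writes
#' a YAML input file for the preparation module carrying the suggested
#' new scale values.
#'
#' @param verdict An [evaluate_volumes()] result.
#' @param path Report path.
#' @param next_input_path Where to write the next-iteration YAML (only
#'   written when a proposal exists).
#' @return `path`, invisibly.
#' @export
write_verdict_report <- function(verdict, path,
                                 next_input_path = NULL) {
  txt <- utils::capture.output(print(verdict))
  writeLines(txt, path)
  if (!is.null(verdict$proposal) && !is.null(next_input_path)) {
    write_yaml_lite(list(
      scale_values = verdict$proposal$values,
      reason = "no probed scale preserved the experimental volume",
      tolerance = verdict$tolerance,
      experimental_volume = verdict$experimental_volume), next_input_path)
  }
  invisible(path)
}
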