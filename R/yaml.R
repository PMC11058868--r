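# Minimal YAML subset used for run configurations and manifests: nested
# maps (2-space indentation), flow sequences of scalars ([a, b, c]),
# and plain scalars. No installed R package provides YAML, so this
# self-contained subset is implemented here; it round-trips everything
# the package itself writes.

yaml_scalar <- function(x) {
  if (is.logical(x)) return(ifelse(x, "true", "false"))
  if (is.numeric(x)) return(format(x, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  x <- as.character(x)
  if (grepl("[]:#{}[]", x) || grepl("^\\s|\\s$", x))
    paste0("'", gsub("'", "''", x), "'") else x
}

yaml_emit <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  out <- character(0)
  for (key in names(x)) {
    val <- x[[key]]
    if (is.list(val) && !is.null(names(val))) {
      out <- c(out, paste0(pad, key, ":"),
               yaml_emit(val, indent + 2))
    } else if (length(val) > 1 || (is.list(val) && is.null(names(val)))) {
      vals <- vapply(unlist(val), yaml_scalar, "")
      out <- c(out, paste0(pad, key, ": [", paste(vals, collapse = ", "), "]"))
    } else if (length(val) == 0) {
      out <- c(out, paste0(pad, key, ": []"))
    } else {
      out <- c(out, paste0(pad, key, ": ", yaml_scalar(val)))
    }
  }
  out
}

#' Write a YAML configuration or manifest
#'
#' Emits nested named lists as a YAML subset (block maps, flow
#' sequences, scalars).
#'
#' @param x Named list (possibly nested).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yaml_lite <- function(x, path) {
  writeLines(yaml_emit(x), path)
  invisible(path)
}

yaml_parse_scalar <- function(s) {
  s <- trimws(s)
  if (grepl("^'.*'$", s)) return(gsub("''", "'", sub("^'(.*)'$", "\\1", s)))
  if (s %in% c("true", "True", "yes")) return(TRUE)
  if (s %in% c("false", "False", "no")) return(FALSE)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

#' Read a YAML configuration
#'
#' Parses the YAML subset written by [write_yaml_lite()]: nested block
#' maps with consistent indentation, flow sequences, scalars, comments.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_yaml_lite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_block <- function(idx, indent) {
    out <- list()
    i <- 1
    while (i <= length(idx)) {
      line <- lines[idx[i]]
      this_indent <- nchar(line) - nchar(sub("^\\s*", "", line))
      if (this_indent < indent) break
      m <- regmatches(line, regexec("^\\s*([^:]+):\\s*(.*)$", line))[[1]]
      if (length(m) < 3) stop("cannot parse YAML line: ", line, call. = FALSE)
      key <- trimws(m[2]); rest <- m[3]
      if (nzchar(trimws(rest))) {
        rest <- trimws(rest)
        if (grepl("^\\[.*\\]$", rest)) {
          inner <- trimws(sub("^\\[(.*)\\]$", "\\1", rest))
          out[[key]] <- if (nzchar(inner))
            lapply(strsplit(inner, ",")[[1]], yaml_parse_scalar) else list()
          if (length(out[[key]]) && all(vapply(out[[key]], is.numeric, TRUE)))
            out[[key]] <- unlist(out[[key]])
        } else out[[key]] <- yaml_parse_scalar(rest)
        i <- i + 1
      } else {
        j <- i + 1
        while (j <= length(idx)) {
          nxt <- lines[idx[j]]
          ni <- nchar(nxt) - nchar(sub("^\\s*", "", nxt))
          if (ni <= this_indent) break
          j <- j + 1
        }
        out[[key]] <- parse_block(idx[seq(i + 1, length.out = j - i - 1)],
                                  this_indent + 1)
        i <- j
      }
    }
    out
  }
  parse_block(seq_along(lines), 0)
}
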