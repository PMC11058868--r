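# Minimal PDBx/mmCIF reader covering the categories this package needs:
# atom_site, cell, symmetry, in-file symmetry operator lists, entity_poly.
# The installed stack has no R-side mmCIF parser, so the category/loop
# grammar (items, loop_, quoted values, semicolon text blocks) is
# implemented here directly.

# split one mmCIF data line into tokens, honoring ' and " quoting
cif_tokenize_line <- function(line) {
  line <- sub("^\\s+", "", line)
  tokens <- character(0)
  while (nzchar(line)) {
    if (startsWith(line, "#")) break
    first <- substr(line, 1, 1)
    if (first %in% c("'", '"')) {
      # closing quote must be followed by whitespace or end of line
      rx <- paste0("^", first, "(([^", first, "]|", first, "\\S)*)", first,
                   "(\\s|$)")
      m <- regexpr(rx, line)
      if (m == -1) stop("unterminated quoted value in mmCIF line: ", line,
                        call. = FALSE)
      len <- attr(m, "match.length")
      val <- substr(line, 2, len - 1)
      val <- sub(paste0(first, "\\s?$"), "", val)
      tokens <- c(tokens, val)
      line <- sub("^\\s+", "", substr(line, len + 1, nchar(line)))
    } else {
      m <- regexpr("^\\S+", line)
      len <- attr(m, "match.length")
      tokens <- c(tokens, substr(line, 1, len))
      line <- sub("^\\s+", "", substr(line, len + 1, nchar(line)))
    }
  }
  tokens
}

# parse a whole file into items (named character) and loops (list of
# category -> data frame of character columns)
cif_parse <- function(lines) {
  items <- character(0)
  loops <- list()
  i <- 1L
  n <- length(lines)
  read_value_tokens <- function() {
    # reads tokens starting at line i (supports semicolon blocks);
    # returns list(tokens, next_i); used for both items and loop rows
    out <- character(0)
    while (i <= n) {
      line <- lines[i]
      if (startsWith(line, ";")) {
        block <- substring(line, 2)
        i <<- i + 1L
        while (i <= n && !startsWith(lines[i], ";")) {
          block <- paste0(block, "\n", lines[i])
          i <<- i + 1L
        }
        i <<- i + 1L  # closing ';'
        return(c(out, block))
      }
      toks <- cif_tokenize_line(line)
      i <<- i + 1L
      if (length(toks)) return(c(out, toks))
      if (i > n) break
    }
    out
  }
  while (i <= n) {
    line <- lines[i]
    trimmed <- sub("^\\s+", "", line)
    if (!nzchar(trimmed) || startsWith(trimmed, "#") ||
        grepl("^data_", trimmed)) { i <- i + 1L; next }
    if (grepl("^loop_", trimmed)) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, cif_tokenize_line(lines[i])[1])
        i <- i + 1L
      }
      rows <- list()
      buf <- character(0)
      while (i <= n) {
        t2 <- sub("^\\s+", "", lines[i])
        if (grepl("^(_|loop_|data_|#)", t2) && length(buf) == 0L) break
        vals <- read_value_tokens()
        buf <- c(buf, vals)
        while (length(buf) >= length(tags)) {
          rows[[length(rows) + 1L]] <- buf[seq_along(tags)]
          buf <- buf[-seq_along(tags)]
        }
        if (i > n) break
      }
      if (length(rows)) {
        mat <- do.call(rbind, rows)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- tags
        cat_name <- sub("\\..*$", "", tags[1])
        loops[[cat_name]] <- df
      }
    } else if (startsWith(trimmed, "_")) {
      toks <- cif_tokenize_line(trimmed)
      tag <- toks[1]
      if (length(toks) >= 2) {
        items[tag] <- toks[2]
        i <- i + 1L
      } else {
        i <- i + 1L
        val <- read_value_tokens()
        items[tag] <- if (length(val)) val[1] else NA_character_
      }
    } else {
      i <- i + 1L
    }
  }
  list(items = items, loops = loops)
}

cif_get <- function(parsed, tags) {
  for (tag in tags) {
    if (tag %in% names(parsed$items)) return(parsed$items[[tag]])
    cat_name <- sub("\\..*$", "", tag)
    lp <- parsed$loops[[cat_name]]
    if (!is.null(lp) && tag %in% names(lp)) return(lp[[tag]][1])
  }
  NULL
}

pick_col <- function(df, candidates) {
  for (cn in candidates) if (cn %in% names(df)) return(df[[cn]])
  NULL
}

#' Read a PDBx/mmCIF structure file
#'
#' Parses atomic coordinates, unit-cell constants (`_cell`) and the
#' Hermann-Mauguin space-group name
#' (`_symmetry.space_group_name_H-M`) from an mmCIF file into an
#' [xtal_structure()]. When the file carries its own symmetry operator
#' list (`_space_group_symop.operation_xyz` or
#' `_symmetry_equiv.pos_as_xyz`) it is stored and later preferred over
#' the built-in registry. Polymer sequences from `_entity_poly` are kept
#' for gap detection. Only the first model of a multi-model file is
#' read (with a warning).
#'
#' @param path Path to an mmCIF file.
#' @return An [xtal_structure()] with waters, ions and ligands
#'   classified.
#' @export
read_mmcif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- cif_parse(readLines(path, warn = FALSE))

  atom_site <- parsed$loops[["_atom_site"]]
  if (is.null(atom_site))
    stop("mmCIF file lacks the atom_site category: ", path, call. = FALSE)

  get_cell_item <- function(tag) {
    v <- cif_get(parsed, paste0("_cell.", tag))
    if (is.null(v)) v <- cif_get(parsed, paste0("_cell_", tag))
    v
  }
  cell_vals <- vapply(c("length_a", "length_b", "length_c",
                        "angle_alpha", "angle_beta", "angle_gamma"),
                      function(tag) {
                        v <- get_cell_item(tag)
                        if (is.null(v)) NA_character_ else v
                      }, "")
  if (any(is.na(cell_vals)))
    stop("mmCIF file lacks the cell category (_cell.length_*/_cell.angle_*): ",
         path, call. = FALSE)
  cell <- cell_parameters(as.numeric(cell_vals[1]), as.numeric(cell_vals[2]),
                          as.numeric(cell_vals[3]), as.numeric(cell_vals[4]),
                          as.numeric(cell_vals[5]), as.numeric(cell_vals[6]))

  sg <- cif_get(parsed, c("_symmetry.space_group_name_H-M",
                          "_space_group.name_H-M_alt",
                          "_symmetry_space_group_name_H-M"))
  if (is.null(sg))
    stop("mmCIF file lacks the symmetry category ",
         "(_symmetry.space_group_name_H-M): ", path, call. = FALSE)

  symops <- NULL
  for (tag in c("_space_group_symop.operation_xyz",
                "_symmetry_equiv.pos_as_xyz")) {
    cat_name <- sub("\\..*$", "", tag)
    lp <- parsed$loops[[cat_name]]
    if (!is.null(lp) && tag %in% names(lp)) { symops <- lp[[tag]]; break }
    single <- parsed$items[tag]
    if (!is.na(single) && !is.null(parsed$items[[tag]])) {
      symops <- parsed$items[[tag]]; break
    }
  }

  # first model only
  model <- pick_col(atom_site, "_atom_site.pdbx_PDB_model_num")
  if (!is.null(model)) {
    models <- unique(model)
    if (length(models) > 1L) {
      warning("multi-model file; keeping first model only (",
              length(models), " models present)", call. = FALSE)
      atom_site <- atom_site[model == models[1], , drop = FALSE]
    }
  }

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop(sprintf("unparsable %s in atom_site row %d: '%s'",
                   what, bad[1], x[bad[1]]), call. = FALSE)
    v
  }
  x <- num(pick_col(atom_site, "_atom_site.Cartn_x"), "x coordinate")
  y <- num(pick_col(atom_site, "_atom_site.Cartn_y"), "y coordinate")
  z <- num(pick_col(atom_site, "_atom_site.Cartn_z"), "z coordinate")
  if (is.null(x) || is.null(y) || is.null(z))
    stop("atom_site category lacks Cartn_x/y/z coordinates: ", path,
         call. = FALSE)

  group <- pick_col(atom_site, "_atom_site.group_PDB")
  if (is.null(group)) group <- rep("ATOM", nrow(atom_site))
  occ <- pick_col(atom_site, "_atom_site.occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(atom_site)) else num(occ, "occupancy")
  altloc <- pick_col(atom_site, "_atom_site.label_alt_id")
  altloc <- if (is.null(altloc)) rep("", nrow(atom_site)) else
    ifelse(altloc %in% c(".", "?"), "", altloc)
  serial <- pick_col(atom_site, "_atom_site.id")
  serial <- if (is.null(serial)) seq_len(nrow(atom_site)) else
    as.integer(num(serial, "serial"))

  resid_raw <- pick_col(atom_site, c("_atom_site.auth_seq_id",
                                     "_atom_site.label_seq_id"))
  atoms <- data.frame(
    serial = serial,
    name = pick_col(atom_site, c("_atom_site.auth_atom_id",
                                 "_atom_site.label_atom_id")),
    element = toupper(pick_col(atom_site, "_atom_site.type_symbol")),
    resname = toupper(pick_col(atom_site, c("_atom_site.auth_comp_id",
                                            "_atom_site.label_comp_id"))),
    resid = as.integer(num(resid_raw, "residue number")),
    chain = pick_col(atom_site, c("_atom_site.auth_asym_id",
                                  "_atom_site.label_asym_id")),
    altloc = altloc,
    occupancy = occ,
    x = x, y = y, z = z,
    het = group == "HETATM",
    stringsAsFactors = FALSE)

  seqres <- NULL
  ep <- parsed$loops[["_entity_poly"]]
  one_letter <- NULL
  strands <- NULL
  if (!is.null(ep)) {
    one_letter <- pick_col(ep, c("_entity_poly.pdbx_seq_one_letter_code_can",
                                 "_entity_poly.pdbx_seq_one_letter_code"))
    strands <- pick_col(ep, "_entity_poly.pdbx_strand_id")
  } else if ("_entity_poly.pdbx_seq_one_letter_code" %in% names(parsed$items)) {
    one_letter <- parsed$items[["_entity_poly.pdbx_seq_one_letter_code"]]
    strands <- parsed$items[["_entity_poly.pdbx_strand_id"]]
  }
  if (!is.null(one_letter) && !is.null(strands)) {
    seqres <- list()
    for (k in seq_along(one_letter)) {
      seq1 <- gsub("[\\s\n]", "", one_letter[k], perl = TRUE)
      for (ch in strsplit(strands[k], ",")[[1]])
        seqres[[trimws(ch)]] <- strsplit(seq1, "")[[1]]
    }
  }

  xtal_structure(atoms, cell = cell, space_group = sg,
                 symops = symops, seqres = seqres)
}

#' Fetch a structure from the wwPDB by accession
#'
#' Downloads `<id>.cif` from the wwPDB and reads it with [read_mmcif()].
#' Requires network access; all package tests run fully offline on
#' generated fixtures.
#'
#' @param id Four-character PDB accession, e.g. `"1EAY"`.
#' @param dest_dir Directory for the downloaded file.
#' @return An [xtal_structure()].
#' @export
fetch_structure <- function(id, dest_dir = tempdir()) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  dest <- file.path(dest_dir, paste0(tolower(id), ".cif"))
  url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(id))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  read_mmcif(dest)
}
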