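# Minimal core-CIF dialect: cell_length_*/cell_angle_*, symmetry operator
# loops (or a space-group symbol from the supported set), and the fractional
# atom_site loop. Unknown tags are skipped with a warning summary.

cif_tokens <- function(line) {
  # split a CIF data line into tokens, honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

cif_number <- function(x) {
  # strip standard uncertainty syntax 1.234(5)
  as.numeric(sub("\\(.*\\)$", "", x))
}

#' Read a crystal structure from a CIF file
#'
#' Parses the minimal small-molecule CIF subset: cell parameters, symmetry
#' operators (as coordinate triplets, or via a space-group symbol from the
#' set supported by [space_group_ops()]), and the fractional atom-site loop.
#' An optional nonstandard `_atom_site_charge` column supplies partial
#' charges (default 0). Unrecognised tags are ignored (one summary warning).
#'
#' @param path path to a CIF file.
#' @param quiet suppress the unknown-tag warning.
#' @return a `crystal` (see [crystal_structure()]).
#' @export
read_cif <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  scalars <- list()
  loops <- list()
  unknown <- character(0)
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^data_", ln)) {
      i <- i + 1
    } else if (identical(tolower(ln), "loop_")) {
      i <- i + 1
      tags <- character(0)
      while (i <= length(lines) && grepl("^_", lines[i])) {
        tags <- c(tags, tolower(cif_tokens(lines[i])[1]))
        i <- i + 1
      }
      vals <- list()
      while (i <= length(lines) && !grepl("^(_|loop_|data_)", lines[i], ignore.case = TRUE)) {
        vals[[length(vals) + 1]] <- cif_tokens(lines[i])
        i <- i + 1
      }
      rows <- unlist(vals)
      if (length(tags) && length(rows) %% length(tags) == 0 && length(rows) > 0) {
        mat <- matrix(rows, ncol = length(tags), byrow = TRUE)
        colnames(mat) <- tags
        loops[[length(loops) + 1]] <- mat
      }
    } else if (grepl("^_", ln)) {
      toks <- cif_tokens(ln)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        scalars[[tag]] <- paste(toks[-1], collapse = " ")
      } else if (i + 1 <= length(lines) && !grepl("^(_|loop_|data_)", lines[i + 1])) {
        scalars[[tag]] <- gsub("^['\"]|['\"]$", "", lines[i + 1])
        i <- i + 1
      }
      i <- i + 1
    } else {
      unknown <- c(unknown, ln)
      i <- i + 1
    }
  }

  need_cell <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  if (!all(need_cell %in% names(scalars))) {
    abort("CIF lacks the cell block (_cell_length_a/b/c)")
  }
  getang <- function(tag) {
    if (tag %in% names(scalars)) cif_number(scalars[[tag]]) else 90
  }
  cell <- unit_cell(
    cif_number(scalars[["_cell_length_a"]]),
    cif_number(scalars[["_cell_length_b"]]),
    cif_number(scalars[["_cell_length_c"]]),
    alpha = getang("_cell_angle_alpha"),
    beta = getang("_cell_angle_beta"),
    gamma = getang("_cell_angle_gamma")
  )

  op_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  ops <- NULL
  for (lp in loops) {
    hit <- intersect(op_tags, colnames(lp))
    if (length(hit)) {
      ops <- lapply(lp[, hit[1]], sym_op)
      break
    }
  }
  if (is.null(ops)) {
    sym_tags <- c("_symmetry_space_group_name_h-m", "_space_group_name_h-m_alt")
    sym <- NULL
    for (tg in sym_tags) if (tg %in% names(scalars)) sym <- scalars[[tg]]
    if (is.null(sym)) {
      abort("CIF lacks a symmetry block (operator loop or space-group symbol)")
    }
    ops <- space_group_ops(sym)
  }

  atom_lp <- NULL
  for (lp in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
            %in% colnames(lp))) {
      atom_lp <- lp
      break
    }
  }
  if (is.null(atom_lp)) abort("CIF lacks the atom_site loop (_atom_site_fract_*)")
  lab <- if ("_atom_site_label" %in% colnames(atom_lp)) {
    unname(atom_lp[, "_atom_site_label"])
  } else {
    paste0("A", seq_len(nrow(atom_lp)))
  }
  elem <- if ("_atom_site_type_symbol" %in% colnames(atom_lp)) {
    unname(atom_lp[, "_atom_site_type_symbol"])
  } else {
    sub("[0-9].*$", "", lab)
  }
  atoms <- tibble::tibble(
    label = lab,
    element = elem,
    x = cif_number(atom_lp[, "_atom_site_fract_x"]),
    y = cif_number(atom_lp[, "_atom_site_fract_y"]),
    z = cif_number(atom_lp[, "_atom_site_fract_z"]),
    occupancy = if ("_atom_site_occupancy" %in% colnames(atom_lp)) {
      cif_number(atom_lp[, "_atom_site_occupancy"])
    } else 1,
    charge = if ("_atom_site_charge" %in% colnames(atom_lp)) {
      cif_number(atom_lp[, "_atom_site_charge"])
    } else 0
  )

  z_value <- if ("_cell_formula_units_z" %in% names(scalars)) {
    as.integer(cif_number(scalars[["_cell_formula_units_z"]]))
  } else NULL
  z_prime <- if (!is.null(z_value)) z_value / length(ops) else 1

  if (length(unknown) && !quiet) {
    warn(sprintf("ignored %d unrecognised CIF line(s)", length(unknown)))
  }
  crystal_structure(cell, ops, atoms, z_value = z_value, z_prime = z_prime)
}

#' Write a crystal structure to a CIF file
#'
#' Emits the same minimal subset [read_cif()] understands, so
#' write-then-read round-trips all fields. Output bytes are deterministic.
#'
#' @param structure a `crystal`.
#' @param path output path.
#' @param data_name the `data_` block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path, data_name = "habitkit") {
  stopifnot(inherits(structure, "crystal"))
  cell <- structure$cell
  fmt <- function(x) sprintf("%.8f", x)
  out <- c(
    paste0("data_", data_name),
    paste("_cell_length_a", fmt(cell$a)),
    paste("_cell_length_b", fmt(cell$b)),
    paste("_cell_length_c", fmt(cell$c)),
    paste("_cell_angle_alpha", fmt(cell$alpha)),
    paste("_cell_angle_beta", fmt(cell$beta)),
    paste("_cell_angle_gamma", fmt(cell$gamma)),
    paste("_cell_formula_units_Z", structure$z_value),
    "loop_",
    "_space_group_symop_operation_xyz",
    vapply(structure$ops, function(o) sprintf("'%s'", sym_op_string(o)), character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_charge",
    sprintf("%s %s %s %s %s %s %s",
            structure$atoms$label, structure$atoms$element,
            fmt(structure$atoms$x), fmt(structure$atoms$y), fmt(structure$atoms$z),
            fmt(structure$atoms$occupancy), fmt(structure$atoms$charge))
  )
  writeLines(out, path)
  invisible(path)
}
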