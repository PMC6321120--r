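#' Parse a symmetry operator string
#'
#' Converts an operator in CIF "x,y,z" notation (e.g. `"1/2-x, 3/2-y, 1-z"`)
#' into a rotation matrix and translation vector acting on fractional
#' coordinates as `x' = R %*% x + t`. Translation components are reduced to
#' \[0, 1).
#'
#' @param text operator string with three comma-separated components.
#' @param reduce reduce translations modulo the lattice (default `TRUE`);
#'   set to `FALSE` to keep codes such as `"1-x, 2-y, 1-z"` verbatim.
#' @return A `sym_op` object: list with `R` (3x3), `t` (length 3).
#' @export
#' @examples
#' sym_op("-x, y, 1/2-z")
sym_op <- function(text, reduce = TRUE) {
  txt <- gsub("−", "-", text)      # unicode minus from typeset sources
  txt <- gsub("[[:space:]]", "", txt)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    abort(sprintf("cannot parse symmetry operator '%s': need three components", text))
  }
  if (grepl("[^xyzXYZ0-9+./,-]", txt)) {
    abort(sprintf("cannot parse symmetry operator '%s': unexpected characters", text))
  }
  rot <- matrix(0, 3, 3)
  tra <- numeric(3)
  ev <- function(expr, x, y, z) {
    env <- list2env(list(x = x, y = y, z = z, X = x, Y = y, Z = z))
    val <- tryCatch(eval(parse(text = expr), envir = env), error = function(e) NA_real_)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      abort(sprintf("cannot parse symmetry operator component '%s'", expr))
    }
    val
  }
  for (i in 1:3) {
    tra[i] <- ev(parts[i], 0, 0, 0)
    rot[i, 1] <- ev(parts[i], 1, 0, 0) - tra[i]
    rot[i, 2] <- ev(parts[i], 0, 1, 0) - tra[i]
    rot[i, 3] <- ev(parts[i], 0, 0, 1) - tra[i]
  }
  if (max(abs(rot - round(rot))) > 1e-10) {
    abort(sprintf("operator '%s' has a non-integer rotation part", text))
  }
  rot <- round(rot)
  dt <- round(det(rot))
  if (!dt %in% c(-1, 1)) {
    abort(sprintf("operator '%s' is singular or improper beyond +/-1 determinant", text))
  }
  if (reduce) tra <- tra %% 1
  structure(list(R = rot, t = tra), class = "sym_op")
}

#' @export
print.sym_op <- function(x, ...) {
  cat("<sym_op>", sym_op_string(x), "\n")
  invisible(x)
}

frac_label <- function(v) {
  # render a fractional translation as n/d with small denominator
  out <- character(length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    if (abs(x - round(x)) < 1e-9) {
      out[i] <- as.character(round(x))
      next
    }
    found <- FALSE
    for (den in c(2, 3, 4, 6, 8, 12)) {
      num <- x * den
      if (abs(num - round(num)) < 1e-9) {
        out[i] <- sprintf("%d/%d", round(num), den)
        found <- TRUE
        break
      }
    }
    if (!found) out[i] <- format(x, digits = 10)
  }
  out
}

#' Render a symmetry operator back to "x,y,z" notation
#' @param op a `sym_op`.
#' @return single string, e.g. `"1/2-x, 3/2-y, 1-z"`.
#' @export
sym_op_string <- function(op) {
  vars <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    ti <- frac_label(op$t[i])
    if (ti != "0") s <- ti
    for (j in 1:3) {
      cj <- op$R[i, j]
      if (cj == 0) next
      sgn <- if (cj > 0) "+" else "-"
      term <- if (abs(cj) == 1) vars[j] else paste0(abs(cj), vars[j])
      s <- if (s == "" && sgn == "+") term else paste0(s, sgn, term)
    }
    if (s == "") s <- "0"
    comp[i] <- s
  }
  paste(comp, collapse = ", ")
}

#' Compose two symmetry operators
#'
#' `op1 %then% op2` in the sense `x' = R1 (R2 x + t2) + t1`, translation
#' reduced modulo the lattice.
#' @param op1,op2 `sym_op` objects.
#' @return a `sym_op`.
#' @export
sym_op_compose <- function(op1, op2) {
  structure(
    list(R = op1$R %*% op2$R, t = (drop(op1$R %*% op2$t) + op1$t) %% 1),
    class = "sym_op"
  )
}

sym_op_equal <- function(op1, op2, tol = 1e-9) {
  all(op1$R == op2$R) && all(abs(((op1$t - op2$t) %% 1 + 0.5) %% 1 - 0.5) < tol)
}

#' Generators for a small set of common space groups
#'
#' Full coordinate-triplet operator lists for the space groups the synthetic
#' generators support: P1, P-1, P2\eqn{_1}/c (unique axis b) and C2/c.
#'
#' @param symbol space-group symbol, one of `"P1"`, `"P-1"`, `"P21/c"`,
#'   `"C2/c"` (spaces ignored, case kept).
#' @return list of `sym_op`.
#' @export
#' @examples
#' length(space_group_ops("C2/c"))  # 8 general positions
space_group_ops <- function(symbol) {
  key <- gsub("[[:space:]]", "", symbol)
  strings <- switch(
    key,
    "P1" = "x,y,z",
    "P-1" = c("x,y,z", "-x,-y,-z"),
    "P21/c" = c("x,y,z", "-x,1/2+y,1/2-z", "-x,-y,-z", "x,1/2-y,1/2+z"),
    "C2/c" = c(
      "x,y,z", "-x,y,1/2-z", "-x,-y,-z", "x,-y,1/2+z",
      "1/2+x,1/2+y,z", "1/2-x,1/2+y,1/2-z", "1/2-x,1/2-y,-z", "1/2+x,1/2-y,1/2+z"
    ),
    abort(sprintf("space group '%s' is not in the supported set (P1, P-1, P21/c, C2/c)", symbol))
  )
  lapply(strings, sym_op)
}

#' Laue-class rotations from a space-group operator set
#'
#' The point-group rotation parts of the operators, augmented with the
#' inversion (the Laue class governs which faces are symmetry-equivalent in
#' the diffraction/morphology sense). Derived from the operators themselves,
#' not from a symbol table.
#'
#' @param ops list of `sym_op`.
#' @return list of 3x3 integer rotation matrices, closed under inversion.
#' @export
laue_rotations <- function(ops) {
  if (length(ops) == 0) abort("empty operator set")
  rots <- lapply(ops, function(o) o$R)
  rots <- c(rots, lapply(rots, function(r) -r))
  keys <- vapply(rots, function(r) paste(r, collapse = ","), character(1))
  rots[!duplicated(keys)]
}

hkl_label <- function(hkl) {
  apply(matrix(as.integer(round(hkl)), ncol = 3), 1, paste0, collapse = "")
}

#' Parse a compact hkl label such as "11-1"
#' @param label character vector of labels, digits with optional minus signs.
#' @return integer matrix with columns h, k, l.
#' @export
parse_hkl_label <- function(label) {
  out <- t(vapply(label, function(s) {
    toks <- regmatches(s, gregexpr("-?[0-9]", s))[[1]]
    if (length(toks) != 3) abort(sprintf("cannot parse hkl label '%s'", s))
    as.integer(toks)
  }, integer(3)))
  dimnames(out) <- list(NULL, c("h", "k", "l"))
  out
}

hkl_orbit <- function(laue, hkl) {
  hkl <- as.integer(round(drop(check_hkl(hkl))))
  imgs <- t(vapply(laue, function(r) as.integer(round(drop(hkl %*% r))), integer(3)))
  unique(imgs)
}

#' Face-form multiplicity under the Laue class
#'
#' The orbit of a Miller index under the Laue rotations: its size is the
#' form multiplicity and its members are the symmetry-equivalent faces.
#'
#' @param laue list of rotation matrices from [laue_rotations()].
#' @param hkl integer vector of length 3.
#' @param cell optional [unit_cell()] used to attach `d_hkl`.
#' @return one-row tibble: `h, k, l, label, multiplicity, equivalents`
#'   (list-column of integer matrices) and `d_hkl` when a cell is given.
#' @export
face_multiplicity <- function(laue, hkl, cell = NULL) {
  if (length(laue) == 0) abort("empty operator set")
  orb <- hkl_orbit(laue, hkl)
  hkl <- as.integer(round(drop(check_hkl(hkl))))
  out <- tibble::tibble(
    h = hkl[1], k = hkl[2], l = hkl[3],
    label = hkl_label(matrix(hkl, 1)),
    multiplicity = nrow(orb),
    equivalents = list(orb)
  )
  if (!is.null(cell)) out$d_hkl <- d_spacing(cell, hkl)
  out
}

orbit_representative <- function(orb) {
  # lexicographically greatest (h, k, l)
  o <- orb[order(orb[, 1], orb[, 2], orb[, 3], decreasing = TRUE), , drop = FALSE]
  o[1, ]
}

#' Enumerate candidate growth forms down to a d-spacing floor
#'
#' All symmetry-distinct face forms with `d_hkl >= d_min`, one representative
#' per Laue orbit. The index search window `|h| <= a/d_min` (and likewise for
#' k, l) follows from the Cauchy-Schwarz bound on the reciprocal vector, so
#' the enumeration is complete. Representatives are the lexicographically
#' greatest member of each orbit; output sorted by decreasing `d_hkl`.
#'
#' @param cell a [unit_cell()].
#' @param ops list of `sym_op` (space-group operators); the Laue class is
#'   derived from their rotation parts.
#' @param d_min minimum interplanar distance in angstrom (> 0).
#' @param max_candidates safety cap on the raw index grid size.
#' @return tibble: `h, k, l, label, multiplicity, d_hkl, equivalents`.
#' @export
#' @examples
#' cell <- unit_cell(19.9960, 16.7246, 19.1703, beta = 116.319)
#' enumerate_forms(cell, space_group_ops("C2/c"), d_min = 8.5)
enumerate_forms <- function(cell, ops, d_min, max_candidates = 2e5) {
  if (!is.numeric(d_min) || d_min <= 0) abort("d_min must be positive")
  laue <- laue_rotations(ops)
  hmax <- floor(cell$a / d_min); kmax <- floor(cell$b / d_min); lmax <- floor(cell$c / d_min)
  ncand <- (2 * hmax + 1) * (2 * kmax + 1) * (2 * lmax + 1)
  if (ncand > max_candidates) {
    abort(sprintf("d_min = %g generates %.0f candidate indices, above the cap of %.0f",
                  d_min, ncand, max_candidates))
  }
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  if (nrow(grid) == 0) return(empty_form_tibble())
  d <- d_spacing(cell, grid)
  keep <- d >= d_min
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(grid) == 0) return(empty_form_tibble())

  seen <- character(0)
  rows <- list()
  ord <- order(-d)
  for (i in ord) {
    key <- paste(grid[i, ], collapse = ",")
    if (key %in% seen) next
    orb <- hkl_orbit(laue, grid[i, ])
    seen <- c(seen, apply(orb, 1, paste, collapse = ","))
    rep <- orbit_representative(orb)
    rows[[length(rows) + 1]] <- tibble::tibble(
      h = rep[1], k = rep[2], l = rep[3],
      label = hkl_label(matrix(rep, 1)),
      multiplicity = nrow(orb),
      d_hkl = d[i],
      equivalents = list(orb)
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$d_hkl))
}

empty_form_tibble <- function() {
  tibble::tibble(
    h = integer(), k = integer(), l = integer(), label = character(),
    multiplicity = integer(), d_hkl = numeric(), equivalents = list()
  )
}
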