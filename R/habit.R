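#' Center-to-face growth distances from attachment energies
#'
#' Implements the growth-morphology rule that a face's linear growth rate —
#' and hence its center-to-face distance in the steady-state habit — is
#' proportional to the magnitude of its attachment energy. Distances are
#' normalised so the fastest-growing face sits at 1.
#'
#' @param forms tibble with columns `h, k, l` and `e_att` (all the same
#'   sign, nonzero; attachment energies of bound crystals are negative).
#' @return `forms` with a `distance` column appended.
#' @export
#' @examples
#' tibble::tibble(h = c(1, 0), k = c(1, 0), l = c(0, 2),
#'                e_att = c(-214.9592, -208.9238)) |>
#'   growth_distances()
growth_distances <- function(forms) {
  forms <- tibble::as_tibble(forms)
  if (!"e_att" %in% names(forms)) abort("forms must carry an e_att column")
  e <- forms$e_att
  if (any(e == 0)) abort("attachment energies must be nonzero")
  if (length(unique(sign(e))) > 1) {
    abort("attachment energies of mixed sign are physically inconsistent input")
  }
  forms$distance <- abs(e) / max(abs(e))
  forms
}

#' BFDH center-to-face distances
#'
#' The geometric Bravais-Friedel-Donnay-Harker rule: growth distance
#' inversely proportional to the interplanar spacing, normalised so the
#' face with the smallest d-spacing sits at 1.
#'
#' @param forms tibble with a `d_hkl` column.
#' @return `forms` with a `distance` column appended.
#' @export
bfdh_distances <- function(forms) {
  forms <- tibble::as_tibble(forms)
  if (!"d_hkl" %in% names(forms)) abort("forms must carry a d_hkl column")
  if (any(forms$d_hkl <= 0)) abort("d_hkl must be positive")
  forms$distance <- (1 / forms$d_hkl) / max(1 / forms$d_hkl)
  forms
}

# deterministic direction sample for the boundedness check
fibonacci_sphere <- function(n = 64) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

expand_halfspaces <- function(forms, cell, ops = NULL) {
  bstar <- reciprocal_matrix(cell)
  has_eq <- "equivalents" %in% names(forms)
  laue <- if (!is.null(ops)) laue_rotations(ops) else NULL
  rows <- list()
  for (f in seq_len(nrow(forms))) {
    hkl <- c(forms$h[f], forms$k[f], forms$l[f])
    eq <- if (has_eq) {
      forms$equivalents[[f]]
    } else if (!is.null(laue)) {
      hkl_orbit(laue, hkl)
    } else {
      unique(rbind(hkl, -hkl))
    }
    for (r in seq_len(nrow(eq))) {
      nvec <- drop(bstar %*% eq[r, ])
      nhat <- nvec / sqrt(sum(nvec^2))
      rows[[length(rows) + 1]] <- tibble::tibble(
        form = f,
        eh = eq[r, 1], ek = eq[r, 2], el = eq[r, 3],
        nx = nhat[1], ny = nhat[2], nz = nhat[3],
        dist = forms$distance[f]
      )
    }
  }
  hs <- dplyr::bind_rows(rows)
  # drop duplicated normals (identical planes listed twice keep the first)
  key <- round(cbind(hs$nx, hs$ny, hs$nz) * 1e9)
  hs[!duplicated(key), ]
}

#' Habit polyhedron by half-space intersection
#'
#' Intersects the half-spaces \eqn{\{x : n_f \cdot x \le h_f\}} — one per
#' symmetry-equivalent face, with unit normals along the reciprocal-lattice
#' vectors and distances from [growth_distances()] or [bfdh_distances()] —
#' into a closed convex polyhedron. Vertices are enumerated over all plane
#' triples, kept when feasible, and deduplicated; each polyhedron facet is
#' attributed to the half-space whose plane it lies on. Fully occluded faces
#' remain in the report with zero area.
#'
#' @param forms tibble with columns `h, k, l`, `distance` and optionally
#'   `equivalents` (list-column of Laue-equivalent indices, as produced by
#'   [enumerate_forms()] / [face_multiplicity()]).
#' @param cell a [unit_cell()]; supplies the reciprocal-vector normals.
#' @param ops optional space-group operator list used to expand equivalents
#'   when `forms` has no `equivalents` column; with neither, each form
#'   contributes only `(hkl)` and `(-h-k-l)`.
#' @return object of class `habit_polyhedron` with elements `vertices`
#'   (n x 3 matrix), `facets` (tibble: half-space geometry, ordered vertex
#'   ids, areas) and `forms` (the input tibble with `area` and `tfa`
#'   percentage columns appended).
#' @export
wulff_polyhedron <- function(forms, cell, ops = NULL) {
  forms <- tibble::as_tibble(forms)
  if (!"distance" %in% names(forms)) {
    abort("forms must carry a distance column (use growth_distances() or bfdh_distances())")
  }
  if (any(forms$distance <= 0)) abort("growth distances must be positive")
  hs <- expand_halfspaces(forms, cell, ops)
  m <- nrow(hs)
  if (m < 4) abort("fewer than four half-spaces cannot bound a volume")
  nmat <- cbind(hs$nx, hs$ny, hs$nz)
  d <- hs$dist
  scale <- max(d)

  # boundedness: some normal must face every direction
  dirs <- rbind(nmat, -nmat, fibonacci_sphere(64), diag(3), -diag(3))
  support <- dirs %*% t(nmat)
  open_dir <- which(apply(support, 1, max) <= 1e-9)
  if (length(open_dir)) {
    u <- dirs[open_dir[1], ]
    abort(sprintf(
      "half-space set is unbounded: no face closes direction (%.3f, %.3f, %.3f)",
      u[1], u[2], u[3]))
  }

  tol <- 1e-8 * scale
  verts <- matrix(numeric(0), 0, 3)
  combos <- utils::combn(m, 3)
  for (ci in seq_len(ncol(combos))) {
    trio <- combos[, ci]
    a <- nmat[trio, , drop = FALSE]
    if (abs(det(a)) < 1e-10) next
    x <- drop(solve(a, d[trio]))
    if (all(nmat %*% x <= d + tol)) verts <- rbind(verts, x)
  }
  if (nrow(verts) < 4) abort("half-space intersection is degenerate (fewer than 4 vertices)")
  # deduplicate
  keep <- rep(TRUE, nrow(verts))
  for (i in seq_len(nrow(verts))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    if (any(rowSums((verts[prior, , drop = FALSE] -
                     matrix(verts[i, ], length(prior), 3, byrow = TRUE))^2) < tol^2)) {
      keep[i] <- FALSE
    }
  }
  verts <- verts[keep, , drop = FALSE]

  # facet polygons per half-space
  facet_rows <- list()
  for (i in seq_len(m)) {
    on_plane <- which(abs(drop(verts %*% nmat[i, ]) - d[i]) < tol)
    area <- 0
    ring <- integer(0)
    if (length(on_plane) >= 3) {
      nrm <- nmat[i, ]
      u1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u1 <- u1 - sum(u1 * nrm) * nrm
      u1 <- u1 / sqrt(sum(u1^2))
      u2 <- c(nrm[2] * u1[3] - nrm[3] * u1[2],
              nrm[3] * u1[1] - nrm[1] * u1[3],
              nrm[1] * u1[2] - nrm[2] * u1[1])
      pts <- verts[on_plane, , drop = FALSE]
      ctr <- colMeans(pts)
      px <- drop((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% u1)
      py <- drop((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% u2)
      ord <- order(atan2(py, px))
      ring <- on_plane[ord]
      xs <- px[ord]; ys <- py[ord]
      j <- c(seq_along(xs)[-1], 1)
      area <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
    }
    facet_rows[[i]] <- tibble::tibble(
      form = hs$form[i], eh = hs$eh[i], ek = hs$ek[i], el = hs$el[i],
      nx = nmat[i, 1], ny = nmat[i, 2], nz = nmat[i, 3],
      dist = d[i], area = area, vertex_ids = list(ring)
    )
  }
  facets <- dplyr::bind_rows(facet_rows)
  total <- sum(facets$area)
  if (total <= 0) abort("half-space intersection has zero surface area")
  form_area <- vapply(seq_len(nrow(forms)), function(f) {
    sum(facets$area[facets$form == f])
  }, numeric(1))
  forms$area <- form_area
  forms$tfa <- 100 * form_area / total

  structure(
    list(vertices = verts, facets = facets, forms = forms, cell = cell),
    class = "habit_polyhedron"
  )
}

#' @export
print.habit_polyhedron <- function(x, ...) {
  cat(sprintf("<habit_polyhedron> %d vertices, %d facet(s) with area, %d form(s)\n",
              nrow(x$vertices), sum(x$facets$area > 0), nrow(x$forms)))
  print(facet_area_table(x))
  invisible(x)
}

#' Per-form facet-area report
#'
#' Facet areas summed per crystallographic form and expressed as percent of
#' the total surface area (TFA), sorted by decreasing share. Occluded forms
#' are kept with a 0 entry; the TFA column sums to 100.
#'
#' @param polyhedron a `habit_polyhedron`.
#' @return tibble with the form columns of the input plus `area` and `tfa`.
#' @export
facet_area_table <- function(polyhedron) {
  stopifnot(inherits(polyhedron, "habit_polyhedron"))
  out <- polyhedron$forms
  if ("equivalents" %in% names(out)) out$equivalents <- NULL
  dplyr::arrange(out, dplyr::desc(.data$tfa))
}

#' Polyhedron volume (for glance/diagnostics)
#' @param polyhedron a `habit_polyhedron`.
#' @return volume in the cube of the distance unit.
#' @export
habit_volume <- function(polyhedron) {
  f <- polyhedron$facets
  sum(f$area * f$dist) / 3
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname facet_area_table
#' @param x a `habit_polyhedron`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.habit_polyhedron <- function(x, ...) facet_area_table(x)

#' One-row summary of a habit polyhedron
#' @param x a `habit_polyhedron`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.habit_polyhedron <- function(x, ...) {
  tibble::tibble(
    n_forms = nrow(x$forms),
    n_facets = sum(x$facets$area > 0),
    n_vertices = nrow(x$vertices),
    total_area = sum(x$facets$area),
    volume = habit_volume(x)
  )
}

#' Orthographic projection plot of a habit polyhedron
#'
#' Draws the facets visible from a view direction as filled polygons,
#' coloured by generating form — a quick visual check of which forms
#' dominate the predicted habit.
#'
#' @param object a `habit_polyhedron`.
#' @param view length-3 viewing direction (need not be normalised).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.habit_polyhedron <- function(object, view = c(1, 0.6, 0.8), ...) {
  v <- view / sqrt(sum(view^2))
  u1 <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- u1 - sum(u1 * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2],
          v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  lab <- if ("label" %in% names(object$forms)) {
    object$forms$label
  } else {
    paste0("(", object$forms$h, object$forms$k, object$forms$l, ")")
  }
  polys <- list()
  for (i in seq_len(nrow(object$facets))) {
    ids <- object$facets$vertex_ids[[i]]
    if (length(ids) < 3) next
    nrm <- c(object$facets$nx[i], object$facets$ny[i], object$facets$nz[i])
    if (sum(nrm * v) <= 0) next  # back-facing
    pts <- object$vertices[ids, , drop = FALSE]
    polys[[length(polys) + 1]] <- tibble::tibble(
      px = drop(pts %*% u1), py = drop(pts %*% u2),
      facet = i, form = lab[object$facets$form[i]]
    )
  }
  df <- dplyr::bind_rows(polys)
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py,
                                   group = .data$facet, fill = .data$form)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "form") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
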