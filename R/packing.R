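# Grid-based Kitaigorodskii-style packing coefficient and solvent-
# accessible void search. The unit cell is sampled on a uniform fractional
# grid (spacing chosen so each axis step is at most `grid` angstrom); a
# point is occupied when it lies inside any atom's van der Waals sphere,
# periodic images included. Each grid point represents an equal share
# V_cell / N_points of the cell volume.

grid_points <- function(cell, grid) {
  if (grid <= 0) abort("grid spacing must be positive")
  nx <- max(1L, ceiling(cell$a / grid))
  ny <- max(1L, ceiling(cell$b / grid))
  nz <- max(1L, ceiling(cell$c / grid))
  fx <- (seq_len(nx) - 0.5) / nx
  fy <- (seq_len(ny) - 0.5) / ny
  fz <- (seq_len(nz) - 0.5) / nz
  list(
    dims = c(nx, ny, nz),
    frac = as.matrix(expand.grid(x = fx, y = fy, z = fz))
  )
}

occupancy_mask <- function(structure, grid, radii_pad = 0, radii = NULL) {
  expanded <- expand_symmetry(structure)
  rv <- if (is.null(radii)) {
    vdw_radius(expanded$element)
  } else {
    idx <- match(expanded$element, names(radii))
    if (anyNA(idx)) {
      abort(paste("no van der Waals radius supplied for element(s):",
                  paste(unique(expanded$element[is.na(idx)]), collapse = ", ")))
    }
    unname(radii[idx])
  }
  rv <- rv + radii_pad
  gp <- grid_points(structure$cell, grid)
  m <- frac_to_cart_matrix(structure$cell)
  occ <- rep(FALSE, nrow(gp$frac))
  for (a in seq_len(nrow(expanded))) {
    d <- gp$frac - matrix(as.numeric(expanded[a, c("x", "y", "z")]),
                          nrow(gp$frac), 3, byrow = TRUE)
    d <- d - round(d)  # periodic minimum image
    cart <- d %*% t(m)
    occ <- occ | (rowSums(cart^2) <= rv[a]^2)
  }
  list(occ = occ, grid = gp)
}

#' Packing coefficient of a crystal structure
#'
#' Fraction of the unit-cell volume lying inside any atom's van der Waals
#' sphere (periodic images included), evaluated on a uniform grid — the
#' grid-based analogue of the Kitaigorodskii packing index.
#'
#' @param structure a `crystal`.
#' @param grid grid spacing in angstrom (default 0.20).
#' @param radii optional named numeric vector of van der Waals radii
#'   overriding the built-in Bondi set.
#' @return object of class `packing_result` with `coefficient`, `occupied
#'   volume`, `cell_volume`, grid dimensions.
#' @export
packing_coefficient <- function(structure, grid = 0.20, radii = NULL) {
  om <- occupancy_mask(structure, grid, radii_pad = 0, radii = radii)
  v <- cell_volume(structure$cell)
  coef <- mean(om$occ)
  structure(
    list(coefficient = coef,
         occupied_volume = coef * v,
         cell_volume = v,
         grid_dims = om$grid$dims,
         grid = grid,
         voids = NULL),
    class = "packing_result"
  )
}

#' Solvent-accessible void search
#'
#' Grid points whose distance to every atom exceeds that atom's van der
#' Waals radius plus the probe radius are probe-accessible; they are
#' clustered into connected components under 6-connectivity with periodic
#' wrap, and each cluster reported with its volume (points times the
#' per-point volume share) and fractional centroid.
#'
#' @param structure a `crystal`.
#' @param grid grid spacing in angstrom (default 0.20).
#' @param probe probe radius in angstrom (default 1.20).
#' @param radii optional named vdW radius overrides.
#' @return a `packing_result` whose `voids` tibble has one row per cluster
#'   (`void, n_points, volume, x, y, z`), plus `void_volume`, `void_count`.
#' @export
find_voids <- function(structure, grid = 0.20, probe = 1.20, radii = NULL) {
  if (probe < 0) abort("probe radius must be non-negative")
  om <- occupancy_mask(structure, grid, radii_pad = probe, radii = radii)
  v <- cell_volume(structure$cell)
  npts <- length(om$occ)
  vol_per_point <- v / npts
  free <- which(!om$occ)
  dims <- om$grid$dims

  voids <- tibble::tibble(void = integer(), n_points = integer(),
                          volume = numeric(), x = numeric(), y = numeric(),
                          z = numeric())
  if (length(free)) {
    # periodic 6-connectivity between free grid points
    idx <- arrayInd(free, dims)
    key <- function(ix) (ix[, 3] - 1) * dims[1] * dims[2] +
      (ix[, 2] - 1) * dims[1] + ix[, 1]
    free_pos <- match(seq_len(npts), free)  # linear index -> free rank
    edges <- list()
    for (axis in 1:3) {
      nb <- idx
      nb[, axis] <- nb[, axis] %% dims[axis] + 1
      nb_lin <- key(nb)
      ok <- !is.na(free_pos[nb_lin])
      if (any(ok)) {
        edges[[axis]] <- cbind(seq_along(free)[ok], free_pos[nb_lin[ok]])
      }
    }
    g <- igraph::make_empty_graph(length(free), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    comp <- igraph::components(g)$membership
    frac <- om$grid$frac[free, , drop = FALSE]
    rows <- list()
    for (cid in sort(unique(comp))) {
      sel <- comp == cid
      # centroid with periodic unwrapping via circular means per axis
      ctr <- vapply(1:3, function(ax) {
        ang <- 2 * pi * frac[sel, ax]
        (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        void = cid, n_points = sum(sel),
        volume = sum(sel) * vol_per_point,
        x = ctr[1], y = ctr[2], z = ctr[3]
      )
    }
    voids <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$volume))
    voids$void <- seq_len(nrow(voids))
  }
  structure(
    list(coefficient = NA_real_,
         blocked_fraction = mean(om$occ),  # vdW + probe inflation
         cell_volume = v,
         grid_dims = dims,
         grid = grid,
         probe = probe,
         void_volume = sum(voids$volume),
         void_count = nrow(voids),
         voids = voids),
    class = "packing_result"
  )
}

#' @export
print.packing_result <- function(x, ...) {
  cat(sprintf("<packing_result> coefficient = %s (grid %s)\n",
              ifelse(is.na(x$coefficient), "-", sprintf("%.4f", x$coefficient)),
              paste(x$grid_dims, collapse = "x")))
  if (!is.null(x$voids)) {
    cat(sprintf("  probe %.2f A: %d void cluster(s), total %.2f A^3\n",
                x$probe, x$void_count, x$void_volume))
  }
  invisible(x)
}
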