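#' Generic pair potential for lattice-energy sums
#'
#' A Lennard-Jones 12-6 potential with per-element parameters and optional
#' shifted Coulomb electrostatics. Both terms are truncated with an energy
#' shift so the pair energy is exactly zero at the cutoff. This is a generic
#' transferable potential: absolute energies depend on the parameter set, so
#' the habit stage also accepts externally computed attachment energies.
#'
#' @param elements optional character vector restricting/overriding the
#'   element table; defaults to the built-in UFF-style set.
#' @param epsilon,sigma optional numeric vectors (kcal/mol, angstrom)
#'   parallel to `elements`, overriding the defaults.
#' @param coulomb include the shifted Coulomb term `k q_i q_j (1/r - 1/rc)`
#'   with `k = 332.0637` kcal mol^-1 angstrom e^-2.
#' @param cutoff real-space cutoff in angstrom (>= 10).
#' @param combining combining rule: `"lorentz-berthelot"` (arithmetic sigma,
#'   geometric epsilon) or `"geometric"`.
#' @return object of class `pair_potential`.
#' @export
pair_potential <- function(elements = NULL, epsilon = NULL, sigma = NULL,
                           coulomb = FALSE, cutoff = 25,
                           combining = c("lorentz-berthelot", "geometric")) {
  combining <- match.arg(combining)
  if (cutoff < 10) abort("cutoff must be at least 10 angstrom")
  tab <- element_data()[, c("element", "lj_epsilon", "lj_sigma")]
  names(tab) <- c("element", "epsilon", "sigma")
  if (!is.null(elements)) {
    custom <- tibble::tibble(
      element = elements,
      epsilon = if (is.null(epsilon)) element_lookup(elements, "lj_epsilon", "LJ") else epsilon,
      sigma = if (is.null(sigma)) element_lookup(elements, "lj_sigma", "LJ") else sigma
    )
    tab <- dplyr::bind_rows(custom, dplyr::filter(tab, !.data$element %in% elements))
  }
  if (any(tab$epsilon < 0)) abort("LJ well depths must be non-negative")
  structure(
    list(table = tab, coulomb = coulomb, cutoff = cutoff, combining = combining),
    class = "pair_potential"
  )
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("<pair_potential> LJ 12-6 (%s)%s, cutoff %.1f A, %d element(s)\n",
              x$combining, if (x$coulomb) " + shifted Coulomb" else "",
              x$cutoff, nrow(x$table)))
  invisible(x)
}

COULOMB_K <- 332.0637  # kcal mol^-1 angstrom e^-2

lj_params <- function(potential, el_i, el_j) {
  tab <- potential$table
  pi_ <- match(el_i, tab$element)
  pj_ <- match(el_j, tab$element)
  if (anyNA(pi_) || anyNA(pj_)) {
    missing <- unique(c(el_i[is.na(pi_)], el_j[is.na(pj_)]))
    abort(paste("no LJ parameters for element(s):", paste(missing, collapse = ", ")))
  }
  if (potential$combining == "lorentz-berthelot") {
    sig <- (tab$sigma[pi_] + tab$sigma[pj_]) / 2
  } else {
    sig <- sqrt(tab$sigma[pi_] * tab$sigma[pj_])
  }
  list(eps = sqrt(tab$epsilon[pi_] * tab$epsilon[pj_]), sig = sig)
}

#' Pairwise interaction energy
#'
#' LJ 12-6 with combining rules plus (optionally) shifted Coulomb, truncated
#' and shifted to zero at the cutoff. Vectorised over atoms/distances.
#'
#' @param potential a [pair_potential()].
#' @param el_i,el_j element symbols.
#' @param r separation(s) in angstrom (> 0).
#' @param q_i,q_j partial charges in e (used only when the potential has
#'   `coulomb = TRUE`).
#' @return energy in kcal/mol; exactly 0 at or beyond the cutoff.
#' @export
#' @examples
#' pot <- pair_potential()
#' pair_energy(pot, "Ar", "Ar", 3.446 * 2^(1/6))  # close to -epsilon
pair_energy <- function(potential, el_i, el_j, r, q_i = 0, q_j = 0) {
  stopifnot(inherits(potential, "pair_potential"))
  if (any(r <= 0)) abort("pair distances must be positive")
  p <- lj_params(potential, el_i, el_j)
  rc <- potential$cutoff
  lj <- function(d) {
    s6 <- (p$sig / d)^6
    4 * p$eps * (s6^2 - s6)
  }
  e <- lj(r) - lj(rc)
  if (potential$coulomb) {
    e <- e + COULOMB_K * q_i * q_j * (1 / r - 1 / rc)
  }
  e[r >= rc] <- 0
  e
}

# Molecule-level interaction table: for each reference unit (one per
# independent molecule of the asymmetric unit) the summed atom-atom energy
# to every other molecule image within the cutoff, with that image's
# centroid. The slab partition of the attachment-energy step then works on
# whole molecules, so E_slice + E_att = E_cr holds by construction.
interaction_table <- function(structure, potential) {
  expanded <- expand_symmetry(structure)
  mols <- identify_molecules(expanded, structure$cell)
  # overlapping atoms anywhere in the cell invalidate the lattice sum
  if (nrow(mols) > 1) {
    xyz <- as.matrix(mols[, c("cx", "cy", "cz")])
    dd <- as.matrix(dist(xyz))
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    if (any(dd < 0.5)) {
      bad <- which(dd < 0.5, arr.ind = TRUE)[1, ]
      abort(sprintf("overlapping atoms (< 0.5 A): %s and %s",
                    mols$label[bad[1]], mols$label[bad[2]]))
    }
  }
  cents <- molecule_centroids(mols)
  m <- frac_to_cart_matrix(structure$cell)
  rc <- potential$cutoff

  # supercell range: cutoff plus molecular extent, against perpendicular widths
  spread <- max(sqrt((mols$cx - cents$cx[mols$mol])^2 +
                     (mols$cy - cents$cy[mols$mol])^2 +
                     (mols$cz - cents$cz[mols$mol])^2))
  widths <- 1 / sqrt(rowSums(solve(m)^2))
  nrep <- ceiling((rc + 2 * spread) / widths) + 1L

  shifts <- as.matrix(expand.grid(-nrep[1]:nrep[1], -nrep[2]:nrep[2], -nrep[3]:nrep[3]))
  cart_shifts <- shifts %*% t(m)
  natom <- nrow(mols)
  nimg <- nrow(shifts)

  part_xyz <- cbind(rep(mols$cx, nimg), rep(mols$cy, nimg), rep(mols$cz, nimg)) +
    cart_shifts[rep(seq_len(nimg), each = natom), ]
  part_el <- rep(mols$element, nimg)
  part_q <- rep(mols$charge, nimg)
  part_mol <- rep(mols$mol, nimg)
  part_img <- rep(seq_len(nimg), each = natom)
  home_img <- which(rowSums(abs(shifts)) == 0)

  # reference units: molecules containing identity-operator images (the Z'
  # independent growth units)
  ref_ids <- sort(unique(mols$mol[mols$op == 1]))

  pair_rows <- list()
  for (u in ref_ids) {
    ref <- mols[mols$mol == u, ]
    acc <- numeric(natom * nimg)
    near <- rep(FALSE, natom * nimg)
    for (a in seq_len(nrow(ref))) {
      dx <- part_xyz[, 1] - ref$cx[a]
      dy <- part_xyz[, 2] - ref$cy[a]
      dz <- part_xyz[, 3] - ref$cz[a]
      r2 <- dx * dx + dy * dy + dz * dz
      sel <- r2 < rc * rc & !(part_mol == u & part_img == home_img)
      if (!any(sel)) next
      r <- sqrt(r2[sel])
      if (any(r < 0.5)) {
        bad <- which(sel)[which.min(r)]
        abort(sprintf("overlapping atoms (< 0.5 A): %s and image of %s",
                      ref$label[a], mols$label[(bad - 1) %% natom + 1]))
      }
      acc[sel] <- acc[sel] +
        pair_energy(potential, ref$element[a], part_el[sel], r,
                    ref$charge[a], part_q[sel])
      near[sel] <- TRUE
    }
    if (!any(near)) next
    key <- (part_img - 1) * max(part_mol) + part_mol
    idx <- which(near | acc != 0)
    e_by_part <- rowsum(acc[idx], key[idx])
    part_keys <- as.integer(rownames(e_by_part))
    pm <- (part_keys - 1) %% max(part_mol) + 1
    pimg <- (part_keys - 1) %/% max(part_mol) + 1
    pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
      unit = u,
      partner_mol = pm,
      px = cents$cx[pm] + cart_shifts[pimg, 1],
      py = cents$cy[pm] + cart_shifts[pimg, 2],
      pz = cents$cz[pm] + cart_shifts[pimg, 3],
      energy = drop(e_by_part)
    )
  }
  list(
    units = cents[cents$mol %in% ref_ids, ],
    pairs = dplyr::bind_rows(pair_rows)
  )
}

#' Crystallization (cohesive) energy per growth unit
#'
#' Half the sum of intermolecular pair energies between a reference
#' molecular unit and all other molecule images within the cutoff, averaged
#' over the Z' independent units. Negative for a bound crystal; constant for
#' a given structure and potential, independent of the face considered.
#'
#' @param structure a `crystal`.
#' @param potential a [pair_potential()].
#' @return list of class `cohesive_energy`: `e_cr` (kcal/mol per growth
#'   unit), `per_unit` tibble, and the internal interaction table reused by
#'   [attachment_energies()].
#' @export
cohesive_energy <- function(structure, potential) {
  it <- interaction_table(structure, potential)
  per_unit <- tibble::tibble(unit = it$units$mol, e_cr = 0)
  if (nrow(it$pairs)) {
    sums <- it$pairs |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(e = sum(.data$energy) / 2, .groups = "drop")
    idx <- match(per_unit$unit, sums$unit)
    per_unit$e_cr <- ifelse(is.na(idx), 0, sums$e[idx])
  }
  structure(
    list(e_cr = mean(per_unit$e_cr), per_unit = per_unit, interactions = it),
    class = "cohesive_energy"
  )
}

#' @export
print.cohesive_energy <- function(x, ...) {
  cat(sprintf("<cohesive_energy> E_cr = %.4f kcal/mol per growth unit (%d independent unit(s))\n",
              x$e_cr, nrow(x$per_unit)))
  invisible(x)
}

#' Slice and attachment energies per face form
#'
#' For each form the interactions of the reference unit are partitioned by
#' the slab of thickness `d_hkl` containing it: partner molecules whose
#' centroid projects within half a d-spacing of the reference centroid along
#' the plane normal contribute to the slice energy, all others to the
#' attachment energy, so that `E_cr = E_slice + E_att` holds identically.
#' Whole molecules are never split across slabs.
#'
#' @param structure a `crystal`.
#' @param potential a [pair_potential()].
#' @param forms tibble from [enumerate_forms()] (columns `h, k, l, d_hkl`,
#'   plus any carried metadata).
#' @param cohesive optional precomputed [cohesive_energy()] result.
#' @return `forms` with columns `e_slice`, `e_att`, `e_cr` appended
#'   (kcal/mol per growth unit, averaged over independent units).
#' @export
attachment_energies <- function(structure, potential, forms, cohesive = NULL) {
  forms <- tibble::as_tibble(forms)
  if (any(forms$d_hkl < 0.8)) {
    abort("forms with d_hkl < 0.8 angstrom are below the resolution of the slab model")
  }
  if (is.null(cohesive)) cohesive <- cohesive_energy(structure, potential)
  it <- cohesive$interactions
  bstar <- reciprocal_matrix(structure$cell)
  units <- it$units
  pairs <- it$pairs

  e_slice <- numeric(nrow(forms))
  e_att <- numeric(nrow(forms))
  for (f in seq_len(nrow(forms))) {
    nvec <- drop(bstar %*% c(forms$h[f], forms$k[f], forms$l[f]))
    nhat <- nvec / sqrt(sum(nvec^2))
    sl <- at <- numeric(nrow(units))
    for (uu in seq_len(nrow(units))) {
      u <- units$mol[uu]
      pp <- pairs[pairs$unit == u, ]
      proj <- (pp$px - units$cx[uu]) * nhat[1] +
              (pp$py - units$cy[uu]) * nhat[2] +
              (pp$pz - units$cz[uu]) * nhat[3]
      in_slab <- abs(proj) < forms$d_hkl[f] / 2
      sl[uu] <- sum(pp$energy[in_slab]) / 2
      at[uu] <- sum(pp$energy[!in_slab]) / 2
    }
    e_slice[f] <- mean(sl)
    e_att[f] <- mean(at)
  }
  forms$e_slice <- e_slice
  forms$e_att <- e_att
  forms$e_cr <- e_slice + e_att
  forms
}
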