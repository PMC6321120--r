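# Deterministic synthetic structures with known ground truth. Defaults are
# exact and seed-free; a seed only enters when optional jitter is requested.

local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Simple-cubic Lennard-Jones toy crystal
#'
#' A single-atom simple-cubic crystal in P1: the lattice sums over its
#' neighbour shells have a closed form, which makes it the oracle substrate
#' for the cohesive/attachment-energy machinery.
#'
#' @param spacing cubic lattice spacing in angstrom.
#' @param n_cells supercell multiplier (the cell edge is
#'   `spacing * n_cells` with `n_cells^3` atoms).
#' @param element element symbol for the lattice atom.
#' @return a `crystal`.
#' @export
make_lj_crystal <- function(spacing = 4, n_cells = 1, element = "Ar") {
  if (spacing <= 0) abort("spacing must be positive")
  n <- as.integer(n_cells)
  cell <- unit_cell(spacing * n, spacing * n, spacing * n)
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  atoms <- tibble::tibble(
    label = paste0(element, seq_len(nrow(g))),
    element = element,
    x = g$i / n, y = g$j / n, z = g$k / n
  )
  crystal_structure(cell, space_group_ops("P1"), atoms, z_value = nrow(g))
}

default_template <- function() {
  # rigid planar 4-atom molecule (formaldehyde-like), coordinates in angstrom
  tibble::tibble(
    label = c("C1", "O1", "H1", "H2"),
    element = c("C", "O", "H", "H"),
    x = c(0, 0, 0.94, -0.94),
    y = c(0, 0, 0, 0),
    z = c(0, 1.22, -0.54, -0.54),
    charge = c(0.45, -0.45, 0, 0)
  )
}

#' Synthetic molecular crystal
#'
#' Places a small rigid template molecule at a general position of a
#' supported space group and expands it to the full unit cell, optionally
#' with a second independent molecule (Z' = 2). The result is validated to
#' be clash-free, with exactly `|ops| * z_prime` molecules per cell.
#'
#' @param template tibble with `label`, `element`, Cartesian `x, y, z`
#'   (angstrom) and optional `charge`; default is a rigid planar 4-atom
#'   molecule.
#' @param cell a [unit_cell()]; the default is a compact monoclinic cell
#'   sized for the default template.
#' @param space_group one of the groups known to [space_group_ops()].
#' @param z_prime 1 or 2 independent molecules.
#' @param origin,origin2 fractional positions of the molecular centres.
#' @param jitter standard deviation (angstrom) of optional Cartesian noise.
#' @param seed RNG seed used only when `jitter > 0`.
#' @return a `crystal`.
#' @export
make_molecular_crystal <- function(template = default_template(),
                                   cell = NULL,
                                   space_group = "C2/c",
                                   z_prime = 1,
                                   origin = c(0.130, 0.110, 0.120),
                                   origin2 = c(0.620, 0.360, 0.370),
                                   jitter = 0, seed = NULL) {
  if (!z_prime %in% c(1, 2)) abort("z_prime must be 1 or 2")
  if (is.null(cell)) {
    cell <- if (z_prime == 1) {
      unit_cell(13.2, 10.4, 12.0, beta = 104)
    } else {
      unit_cell(16.5, 13.0, 15.0, beta = 104)
    }
  }
  ops <- space_group_ops(space_group)
  template <- tibble::as_tibble(template)
  if (!"charge" %in% names(template)) template$charge <- 0
  m <- frac_to_cart_matrix(cell)
  minv <- solve(m)

  place <- function(tpl, orig, rotate, tag) {
    xyz <- as.matrix(tpl[, c("x", "y", "z")])
    if (rotate) {
      # fixed rotation so the second molecule is genuinely independent
      th <- pi / 3
      rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      xyz <- xyz %*% t(rz)
    }
    frac <- xyz %*% t(minv) + matrix(orig, nrow(xyz), 3, byrow = TRUE)
    tibble::tibble(
      label = paste0(tpl$label, tag),
      element = tpl$element,
      x = frac[, 1], y = frac[, 2], z = frac[, 3],
      charge = tpl$charge
    )
  }
  atoms <- place(template, origin, FALSE, "A")
  if (z_prime == 2) atoms <- dplyr::bind_rows(atoms, place(template, origin2, TRUE, "B"))

  if (jitter > 0) {
    local_seed(seed)
    noise <- matrix(stats::rnorm(3 * nrow(atoms), sd = jitter), ncol = 3) %*% t(minv)
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }

  out <- crystal_structure(cell, ops, atoms,
                           z_value = length(ops) * z_prime, z_prime = z_prime)
  validate_no_clash(out)
  out
}

validate_no_clash <- function(structure, min_dist = 1.5) {
  expanded <- expand_symmetry(structure)
  mols <- identify_molecules(expanded, structure$cell)
  n_expected <- length(structure$ops) * structure$z_prime
  if (length(unique(mols$mol)) != n_expected) {
    abort(sprintf(
      "expanded structure has %d bonded unit(s), expected %d: molecules clash or merge",
      length(unique(mols$mol)), n_expected))
  }
  # closest intermolecular approach under periodic minimum image
  m <- frac_to_cart_matrix(structure$cell)
  frac <- as.matrix(mols[, c("x", "y", "z")])
  for (i in seq_len(nrow(mols) - 1)) {
    d <- frac[(i + 1):nrow(mols), , drop = FALSE] -
      matrix(frac[i, ], nrow(mols) - i, 3, byrow = TRUE)
    d <- d - round(d)
    dist <- sqrt(rowSums((d %*% t(m))^2))
    other <- mols$mol[(i + 1):nrow(mols)] != mols$mol[i]
    bad <- which(other & dist < min_dist)
    if (length(bad)) {
      j <- i + bad[1]
      abort(sprintf("intermolecular clash: %s and %s at %.2f angstrom",
                    mols$label[i], mols$label[j], dist[bad[1]]))
    }
  }
  invisible(structure)
}

#' Puckered ring fixture by inverse Cremer-Pople construction
#'
#' Builds an N-membered ring whose out-of-plane displacements are set
#' directly from target puckering amplitudes, so [cremer_pople()] must
#' recover them exactly: atoms sit on a regular N-gon in the xy-plane with
#' `z_j = sqrt(2/N) q2 cos(phi2 + 4 pi (j-1)/N)` (plus the `q3` alternating
#' term for N = 6).
#'
#' @param n ring size, 4, 5 or 6.
#' @param q2 target amplitude in angstrom (0 gives a planar ring).
#' @param phi2 target phase in degrees.
#' @param q3 chair-type amplitude, even rings only.
#' @param bond_length target bond length in angstrom (sets the N-gon size).
#' @param jitter optional Cartesian noise sd in angstrom.
#' @param seed RNG seed used only when `jitter > 0`.
#' @return N x 3 coordinate matrix with atom labels as rownames.
#' @export
#' @examples
#' cremer_pople(make_ring_fixture(5, q2 = 0.3831, phi2 = 42.8048))
make_ring_fixture <- function(n = 5, q2 = 0, phi2 = 0, q3 = 0,
                              bond_length = 1.54, jitter = 0, seed = NULL) {
  if (!n %in% 4:6) abort("ring size must be 4, 5 or 6")
  r <- bond_length / (2 * sin(pi / n))
  amp <- sqrt(q2^2 + q3^2)
  if (amp >= r) {
    abort(sprintf("pucker amplitude %.3f exceeds bond-length feasibility (N-gon radius %.3f)",
                  amp, r))
  }
  j <- seq_len(n) - 1
  ang <- 2 * pi * j / n
  z <- sqrt(2 / n) * q2 * cos(deg2rad(phi2) + 2 * ang)
  if (n %% 2 == 0 && q3 != 0) {
    z <- z + sqrt(1 / n) * q3 * (-1)^j
  } else if (q3 != 0) {
    abort("q3 applies only to even-membered rings")
  }
  # clockwise traversal in xy so the Cremer-Pople mean-plane normal is +z
  # and the analysis recovers (q2, phi2) with the same sign convention
  coords <- cbind(r * cos(ang), -r * sin(ang), z)
  if (jitter > 0) {
    local_seed(seed)
    coords <- coords + matrix(stats::rnorm(3 * n, sd = jitter), ncol = 3)
  }
  rownames(coords) <- paste0("A", seq_len(n))
  colnames(coords) <- c("x", "y", "z")
  coords
}

hexagon_ring <- function(radius = 1.39) {
  ang <- 2 * pi * (0:5) / 6
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

#' Two-molecule contact-geometry fixture
#'
#' Builds a P1 box containing exactly two molecules realising a requested
#' contact geometry, so the corresponding detector must measure back the
#' input parameters: a hydroxyl-to-oxygen hydrogen bond (`"hbond"`), two
#' stacked six-membered carbon rings (`"pi_pi"`), or two inclined rings
#' (`"t_shaped"`).
#'
#' @param kind `"hbond"`, `"pi_pi"` or `"t_shaped"`.
#' @param d_ha,angle,d_dh hydrogen-bond geometry: H...A distance, D-H...A
#'   angle (degrees), D-H distance.
#' @param perp,offset pi-pi geometry: perpendicular ring separation and
#'   in-plane centroid offset (angstrom).
#' @param cg,dihedral centroid distance and inter-plane angle (degrees) for
#'   `"pi_pi"` (dihedral defaults 0) and `"t_shaped"`.
#' @param box edge of the cubic P1 cell, angstrom (large enough that
#'   periodic images stay outside the contact cutoffs).
#' @return a `crystal` with `z_prime = 2`.
#' @export
make_contact_pair <- function(kind = c("hbond", "pi_pi", "t_shaped"),
                              d_ha = 1.97, angle = 170, d_dh = 0.84,
                              perp = 3.4, offset = 0,
                              cg = 5.0, dihedral = 70, box = 25) {
  kind <- match.arg(kind)
  if (kind == "pi_pi" && missing(dihedral)) dihedral <- 0
  if (kind == "hbond") {
    if (angle <= 0 || angle > 180) abort("D-H...A angle must lie in (0, 180]")
    if (d_ha <= 0 || d_dh <= 0) abort("distances must be positive")
    h <- c(0, 0, 0)
    d <- c(-d_dh, 0, 0)
    u <- c(cos(pi - deg2rad(angle)), sin(pi - deg2rad(angle)), 0)
    a <- u * d_ha
    d_da <- sqrt(sum((a - d)^2))
    if (d_da > d_dh + d_ha + 1e-9) abort("triangle violation in requested geometry")
    atoms_cart <- unname(rbind(d, h, a))
    atoms <- tibble::tibble(
      label = c("O1", "H1", "O2"),
      element = c("O", "H", "O"),
      x = atoms_cart[, 1], y = atoms_cart[, 2], z = atoms_cart[, 3]
    )
  } else {
    ring1 <- hexagon_ring()
    ring2 <- hexagon_ring()
    th <- deg2rad(dihedral)
    ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
                 byrow = TRUE)
    ring2 <- ring2 %*% t(ry)
    centre2 <- if (kind == "pi_pi") c(offset, 0, perp) else c(0, 0, cg)
    ring2 <- ring2 + matrix(centre2, 6, 3, byrow = TRUE)
    atoms_cart <- unname(rbind(ring1, ring2))
    atoms <- tibble::tibble(
      label = paste0("C", 1:12),
      element = "C",
      x = atoms_cart[, 1], y = atoms_cart[, 2], z = atoms_cart[, 3]
    )
  }
  cell <- unit_cell(box, box, box)
  shift <- box / 2
  atoms$x <- (atoms$x + shift) / box
  atoms$y <- (atoms$y + shift) / box
  atoms$z <- (atoms$z + shift) / box
  crystal_structure(cell, space_group_ops("P1"), atoms,
                    z_value = 2, z_prime = 2)
}
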