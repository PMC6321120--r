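# Hydrogen-bond detection over symmetry images.
#
# Donors and hydrogens come from the asymmetric unit (identity images);
# acceptors are searched over every symmetry operator and one shell of
# lattice translations, and each hit carries the coordinate-triplet code of
# the operator (translation folded in) that generated the acceptor, in the
# style used by structure-report tables.

op_code_string <- function(op, shift) {
  sym_op_string(list(R = op$R, t = op$t + shift))
}

bonded_pairs <- function(xyz, elements, slack = 0.4) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  rc <- covalent_radius(elements)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(rowSums((xyz[(i + 1):n, , drop = FALSE] -
                       matrix(xyz[i, ], n - i, 3, byrow = TRUE))^2))
    hit <- which(d <= rc[i] + rc[(i + 1):n] + slack & d > 1e-6)
    if (length(hit)) out[[length(out) + 1]] <- cbind(i, i + hit)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Detect hydrogen bonds with symmetry codes
#'
#' Finds all D-H...A triples where the donor-bound hydrogen approaches an
#' acceptor within the distance criterion and the D-H...A angle is at least
#' `min_angle`. Donors are N/O/F/S (and optionally C, with its own, slightly
#' longer distance criterion); acceptors are N/O/F/S. Acceptors are searched
#' over all symmetry images within one shell of lattice translations. The
#' structure must contain hydrogen atoms.
#'
#' @param structure a `crystal`.
#' @param max_ha maximum H...A distance in angstrom for N/O/F/S donors.
#' @param max_ha_c maximum H...A distance for C-H donors.
#' @param min_angle minimum D-H...A angle in degrees.
#' @param donor_elements,acceptor_elements element sets for D and A.
#' @param include_c_donors also consider C-H donors.
#' @return tibble: `donor, hydrogen, acceptor, type` ("inter"/"intra"),
#'   `d_dh, d_ha, d_da` (angstrom), `angle_dha` (degrees), `symop`.
#' @export
detect_hbonds <- function(structure,
                          max_ha = 2.7, max_ha_c = 2.8, min_angle = 100,
                          donor_elements = c("N", "O", "F", "S"),
                          acceptor_elements = c("N", "O", "F", "S"),
                          include_c_donors = TRUE) {
  expanded <- expand_symmetry(structure)
  if (!any(expanded$element == "H")) {
    abort("structure contains no hydrogen atoms; cannot evaluate D-H...A geometry")
  }
  mols <- identify_molecules(expanded, structure$cell)
  m <- frac_to_cart_matrix(structure$cell)

  ref <- mols[mols$op == 1, ]
  ref_xyz <- as.matrix(ref[, c("cx", "cy", "cz")])
  bonds <- bonded_pairs(ref_xyz, ref$element)
  don_set <- donor_elements
  if (include_c_donors) don_set <- c(don_set, "C")

  dh <- list()  # donor-hydrogen bonded pairs in the reference unit(s)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1]; j <- bonds[e, 2]
    if (ref$element[i] %in% don_set && ref$element[j] == "H") {
      dh[[length(dh) + 1]] <- c(i, j)
    } else if (ref$element[j] %in% don_set && ref$element[i] == "H") {
      dh[[length(dh) + 1]] <- c(j, i)
    }
  }
  if (!length(dh)) return(empty_hbond_tibble())

  # acceptor images: every operator x one shell of lattice translations
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc_rows <- list()
  asym_frac <- as.matrix(structure$atoms[, c("x", "y", "z")])
  is_acc <- structure$atoms$element %in% acceptor_elements
  for (oi in seq_along(structure$ops)) {
    op <- structure$ops[[oi]]
    img <- asym_frac %*% t(op$R) + matrix(op$t, nrow(asym_frac), 3, byrow = TRUE)
    for (si in seq_len(nrow(shifts))) {
      sh <- shifts[si, ]
      pos <- img[is_acc, , drop = FALSE] +
        matrix(sh, sum(is_acc), 3, byrow = TRUE)
      acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
        label = structure$atoms$label[is_acc],
        element = structure$atoms$element[is_acc],
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        code = op_code_string(op, sh),
        identity = oi == 1 && all(sh == 0)
      )
    }
  }
  acc <- dplyr::bind_rows(acc_rows)
  acc_xyz <- as.matrix(acc[, c("x", "y", "z")]) %*% t(m)

  recs <- list()
  for (p in dh) {
    d_i <- p[1]; h_i <- p[2]
    dpos <- ref_xyz[d_i, ]; hpos <- ref_xyz[h_i, ]
    cut <- if (ref$element[d_i] == "C") max_ha_c else max_ha
    dv <- acc_xyz - matrix(hpos, nrow(acc_xyz), 3, byrow = TRUE)
    d_ha <- sqrt(rowSums(dv^2))
    cand <- which(d_ha <= cut & d_ha > 1.0)  # exclude covalent partners
    for (a in cand) {
      # skip the donor atom itself seen through the identity
      if (acc$identity[a] && acc$label[a] == ref$label[d_i] &&
          sqrt(sum((acc_xyz[a, ] - dpos)^2)) < 0.1) next
      v1 <- dpos - hpos
      v2 <- acc_xyz[a, ] - hpos
      ang <- rad2deg(acos(pmin(1, pmax(-1,
        sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))))
      if (ang < min_angle) next
      intra <- acc$identity[a] &&
        acc$label[a] %in% ref$label[ref$mol == ref$mol[d_i]]
      recs[[length(recs) + 1]] <- tibble::tibble(
        donor = ref$label[d_i],
        hydrogen = ref$label[h_i],
        acceptor = acc$label[a],
        type = if (intra) "intra" else "inter",
        d_dh = sqrt(sum(v1^2)),
        d_ha = d_ha[a],
        d_da = sqrt(sum((acc_xyz[a, ] - dpos)^2)),
        angle_dha = ang,
        symop = acc$code[a]
      )
    }
  }
  if (!length(recs)) return(empty_hbond_tibble())
  dplyr::distinct(dplyr::bind_rows(recs),
                  .data$donor, .data$hydrogen, .data$acceptor, .data$symop,
                  .keep_all = TRUE)
}

empty_hbond_tibble <- function() {
  tibble::tibble(
    donor = character(), hydrogen = character(), acceptor = character(),
    type = character(), d_dh = numeric(), d_ha = numeric(), d_da = numeric(),
    angle_dha = numeric(), symop = character()
  )
}
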