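#' Cremer-Pople ring-puckering parameters
#'
#' Computes the generalized ring-puckering amplitudes and phases from the
#' out-of-plane displacements `z_j` relative to the Cremer-Pople mean plane
#' (defined so that both first-harmonic sums of `z_j` vanish and
#' `sum(z_j) = 0`). For a five-membered ring this yields the single pair
#' (q2, phi2) and a conformer label (envelope on a given atom, or twist
#' between two atoms) by nearest canonical phase; for six-membered rings
#' q2, phi2 and q3 are returned. The phase convention follows the original
#' Cremer-Pople definition with atom 1 at the phase origin, so phi depends
#' on the starting atom of the ring ordering.
#'
#' @param coords N x 3 matrix of ordered ring-atom Cartesian coordinates
#'   (N >= 4), in angstrom.
#' @param labels optional atom labels used in the conformer description.
#' @return object of class `pucker`: list with `n`, `z` (displacements),
#'   `q2`, `phi2` (degrees), `q3` (even N only, else `NA`), `q_total`, and
#'   `conformer` (N = 5 only).
#' @export
#' @examples
#' ring <- make_ring_fixture(5, q2 = 0.3831, phi2 = 42.8048)
#' cremer_pople(ring)
cremer_pople <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) abort("a ring needs at least 4 atoms")
  if (is.null(labels)) {
    labels <- rownames(coords)
    if (is.null(labels)) labels <- paste0("atom", seq_len(n))
  }
  cen <- sweep(coords, 2, colMeans(coords))
  theta1 <- 2 * pi * (seq_len(n) - 1) / n
  r1 <- colSums(cen * sin(theta1))
  r2 <- colSums(cen * cos(theta1))
  nrm <- c(r1[2] * r2[3] - r1[3] * r2[2],
           r1[3] * r2[1] - r1[1] * r2[3],
           r1[1] * r2[2] - r1[2] * r2[1])
  nlen <- sqrt(sum(nrm^2))
  if (nlen < 1e-10) abort("degenerate ring: atoms are collinear")
  nrm <- nrm / nlen
  z <- drop(cen %*% nrm)

  qs <- list()
  mmax <- floor((n - 1) / 2)
  for (m in 2:mmax) {
    th <- 2 * pi * m * (seq_len(n) - 1) / n
    qc <- sqrt(2 / n) * sum(z * cos(th))
    qsn <- -sqrt(2 / n) * sum(z * sin(th))
    qs[[as.character(m)]] <- list(q = sqrt(qc^2 + qsn^2),
                                  phi = rad2deg(atan2(qsn, qc)) %% 360)
  }
  q_half <- if (n %% 2 == 0) {
    sqrt(1 / n) * sum(z * cos(pi * (seq_len(n) - 1)))
  } else NA_real_

  q2 <- qs[["2"]]$q
  phi2 <- qs[["2"]]$phi
  conformer <- if (n == 5) pucker_conformer_5(phi2, labels) else NA_character_
  q_total <- sqrt(sum(z^2))
  structure(
    list(n = n, labels = labels, z = z, q2 = q2, phi2 = phi2,
         q3 = q_half, q_total = q_total, conformer = conformer),
    class = "pucker"
  )
}

# canonical phases for N = 5 derived from the pure displacement patterns:
# a single-atom (envelope) displacement of atom k maps to
# phi2 = -144 (k - 1) deg (flap up) or that + 180 (flap down); twists lie
# midway between neighbouring envelope phases.
pucker_conformer_5 <- function(phi2, labels) {
  env_phase <- ((-(144) * (0:4)) %% 360)
  cand <- tibble::tibble(
    phase = c(env_phase, (env_phase + 180) %% 360),
    atom = rep(seq_len(5), 2),
    kind = "envelope"
  )
  tw <- sort(unique(cand$phase))
  twists <- (tw + 18) %% 360
  cand <- dplyr::bind_rows(cand, tibble::tibble(
    phase = twists, atom = NA_integer_, kind = "twist"
  ))
  dist <- pmin(abs(cand$phase - phi2), 360 - abs(cand$phase - phi2))
  best <- cand[which.min(dist), ]
  if (best$kind == "envelope") {
    sprintf("envelope on %s", labels[best$atom])
  } else {
    "twist"
  }
}

#' @export
print.pucker <- function(x, ...) {
  cat(sprintf("<pucker> N=%d  q2=%.4f A  phi2=%.4f deg", x$n, x$q2, x$phi2))
  if (!is.na(x$q3)) cat(sprintf("  q3=%.4f A", x$q3))
  if (!is.na(x$conformer)) cat(sprintf("  [%s]", x$conformer))
  cat("\n")
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch) RMSD
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired coordinate sets, via SVD of the covariance matrix with the
#' reflection corrected to a proper rotation.
#'
#' @param coords_a,coords_b N x 3 matrices (N >= 3, not all collinear) of
#'   paired coordinates; row i of `coords_a` pairs with row i of `coords_b`.
#' @param pairing optional integer vector: row i of `coords_a` pairs with
#'   row `pairing[i]` of `coords_b`.
#' @return object of class `superposition`: `rmsd` (angstrom), `rotation`
#'   (3 x 3, applied to centred `coords_b`), `translation`, `pairing`.
#' @export
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch_rmsd(a, a)$rmsd  # 0
kabsch_rmsd <- function(coords_a, coords_b, pairing = NULL) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!is.null(pairing)) b <- b[pairing, , drop = FALSE]
  if (nrow(a) != nrow(b)) abort("paired coordinate sets must have equal length")
  if (nrow(a) < 3) abort("superposition needs at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (svd(ac)$d[2] < 1e-8 * max(1, svd(ac)$d[1])) {
    abort("points are collinear; rotation is underdetermined")
  }
  h <- t(bc) %*% ac
  sv <- svd(h)
  s <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  b_fit <- bc %*% t(r)
  rmsd <- sqrt(mean(rowSums((ac - b_fit)^2)))
  structure(
    list(rmsd = rmsd, rotation = r,
         translation = ca - drop(r %*% cb),
         pairing = if (is.null(pairing)) seq_len(nrow(a)) else pairing),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.6f A over %d points\n",
              x$rmsd, length(x$pairing)))
  invisible(x)
}
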