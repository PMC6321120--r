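test_that("hydrogen-bond detection honours distance and angle criteria", {
  lin <- make_contact_pair("hbond", d_ha = 1.8, angle = 180)
  hb <- detect_hbonds(lin)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_ha, 1.8, tolerance = 1e-6)
  expect_equal(hb$angle_dha, 180, tolerance = 1e-6)
  expect_equal(hb$type, "inter")
  expect_equal(hb$symop, "x, y, z")

  bent <- make_contact_pair("hbond", d_ha = 1.8, angle = 90)
  expect_equal(nrow(detect_hbonds(bent)), 0)

  # no hydrogens at all -> explicit error
  dry <- crystal_structure(unit_cell(15, 15, 15), space_group_ops("P1"),
                           tibble::tibble(label = c("O1", "C1"),
                                          element = c("O", "C"),
                                          x = c(0.2, 0.25), y = 0.2, z = 0.2))
  expect_error(detect_hbonds(dry), "no hydrogen")
})

test_that("hydrogen-bond geometry round-trips the constructed parameters", {
  cases <- list(c(1.97, 170), c(2.5, 120), c(1.85, 155), c(2.65, 101))
  for (cs in cases) {
    cr <- make_contact_pair("hbond", d_ha = cs[1], angle = cs[2], d_dh = 0.84)
    hb <- detect_hbonds(cr)
    expect_equal(nrow(hb), 1)
    expect_equal(hb$d_dh, 0.84, tolerance = 1e-6)
    expect_equal(hb$d_ha, cs[1], tolerance = 1e-6)
    expect_equal(hb$angle_dha, cs[2], tolerance = 1e-6)
    # law of cosines on the D-H...A triangle (included angle at H)
    dda <- sqrt(0.84^2 + cs[1]^2 - 2 * 0.84 * cs[1] * cos(cs[2] * pi / 180))
    expect_equal(hb$d_da, dda, tolerance = 1e-6)
    expect_lte(hb$d_da, hb$d_dh + hb$d_ha + 1e-9)
  }
})

test_that("hydrogen bonds across symmetry images carry their generating code", {
  # hydroxyl aimed at the P-1 inversion centre: the image oxygen sits 2.60 A
  # past the hydrogen on the same line, giving a linear O-H...O contact
  cell <- unit_cell(10.5, 11, 10)
  cart <- rbind(O1 = c(1.78, 0, 0), H1 = c(0.82, 0, 0), C1 = c(2.28, 1.34, 0))
  atoms <- tibble::tibble(
    label = rownames(cart), element = c("O", "H", "C"),
    x = cart[, 1] / 10.5, y = cart[, 2] / 11, z = cart[, 3] / 10
  )
  cr <- crystal_structure(cell, space_group_ops("P-1"), atoms)
  hb <- detect_hbonds(cr)
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$donor == "O1" & hb$acceptor == "O1"))
  expect_false(any(hb$symop == "x, y, z"))
  near <- hb[which.min(hb$d_ha), ]
  expect_equal(near$d_ha, 2.60, tolerance = 1e-6)
  expect_equal(near$angle_dha, 180, tolerance = 1e-6)
  expect_equal(near$symop, "-x, -y, -z")

  # replacing the asymmetric unit by a symmetry-equivalent copy leaves the
  # geometry multiset unchanged
  op <- cr$ops[[2]]
  frac <- as.matrix(cr$atoms[, c("x", "y", "z")])
  moved <- cr$atoms
  img <- frac %*% t(op$R) + matrix(op$t, nrow(frac), 3, byrow = TRUE)
  moved$x <- img[, 1]; moved$y <- img[, 2]; moved$z <- img[, 3]
  cr2 <- crystal_structure(cr$cell, cr$ops, moved)
  hb2 <- detect_hbonds(cr2)
  key <- function(h) sort(round(c(h$d_ha, h$angle_dha, h$d_da), 6))
  expect_equal(key(hb2), key(hb))
})

test_that("ring perception finds simple, fused and multi-ring systems", {
  # cyclopentane-like single ring
  ring <- make_ring_fixture(5, q2 = 0.3)
  atoms <- tibble::tibble(label = rownames(ring), element = "C",
                          x = (ring[, 1] + 10) / 20, y = (ring[, 2] + 10) / 20,
                          z = (ring[, 3] + 10) / 20)
  cr <- crystal_structure(unit_cell(20, 20, 20), space_group_ops("P1"), atoms)
  mols <- identify_molecules(expand_symmetry(cr), cr$cell)
  rings <- perceive_rings(mols)
  expect_equal(nrow(rings), 1)
  expect_equal(rings$size, 5)
  expect_equal(c(rings$cx, rings$cy, rings$cz),
               colMeans(as.matrix(mols[match(rings$atoms[[1]], mols$label),
                                       c("cx", "cy", "cz")])),
               tolerance = 1e-9, ignore_attr = TRUE)

  # naphthalene-like fusion: 10 atoms, 11 bonds -> exactly 2 six-rings
  hexa <- function(cx) cbind(cx + 1.39 * cos(2 * pi * (0:5) / 6 + pi / 6),
                             1.39 * sin(2 * pi * (0:5) / 6 + pi / 6), 0)
  a <- hexa(0)
  b <- hexa(2 * 1.39 * cos(pi / 6))
  pts <- rbind(a, b[!apply(b, 1, function(p) {
    any(sqrt(rowSums(sweep(a, 2, p)^2)) < 0.1)
  }), ])
  expect_equal(nrow(pts), 10)
  at2 <- tibble::tibble(label = paste0("C", 1:10), element = "C",
                        x = (pts[, 1] + 12) / 25, y = (pts[, 2] + 12) / 25,
                        z = (pts[, 3] + 12) / 25)
  cr2 <- crystal_structure(unit_cell(25, 25, 25), space_group_ops("P1"), at2)
  m2 <- identify_molecules(expand_symmetry(cr2), cr2$cell)
  r2 <- perceive_rings(m2)
  expect_equal(nrow(r2), 2)
  expect_true(all(r2$size == 6))
  expect_true(all(r2$planarity_rms < 1e-9))
})

test_that("stacking classification recovers constructed pi-pi geometry", {
  # parallel coaxial rings
  cr <- classify_stacking(make_contact_pair("pi_pi", perp = 3.5, offset = 0))
  expect_equal(nrow(cr), 2)  # directional: both orderings reported
  expect_equal(cr$cg_distance, rep(3.5, 2), tolerance = 1e-6)
  expect_equal(cr$dihedral, rep(0, 2), tolerance = 1e-6)
  expect_equal(cr$slippage, rep(0, 2), tolerance = 1e-6)
  expect_true(all(cr$klass == "pi-pi"))

  # offset stack: Pythagoras by construction
  off <- classify_stacking(make_contact_pair("pi_pi", perp = 3.2, offset = 2))
  expect_equal(off$cg_distance, rep(sqrt(3.2^2 + 2^2), 2), tolerance = 1e-6)
  expect_equal(off$slippage, rep(2, 2), tolerance = 1e-6)
  # exact identity slippage^2 + d_perp^2 = cg^2
  expect_equal(off$slippage^2 + off$d_perp^2, off$cg_distance^2,
               tolerance = 1e-9)
})

test_that("inclined rings classify as T-shaped or unclassified by dihedral", {
  ts <- classify_stacking(make_contact_pair("t_shaped", cg = 5.2016, dihedral = 70))
  expect_true(all(ts$klass == "T-shaped"))
  expect_equal(ts$cg_distance, rep(5.2016, 2), tolerance = 1e-6)
  expect_equal(ts$dihedral, rep(70, 2), tolerance = 1e-6)
  expect_true(all(is.na(ts$slippage)))

  mid <- classify_stacking(make_contact_pair("t_shaped", cg = 5.0, dihedral = 40))
  expect_true(all(mid$klass == "unclassified"))
  expect_true(all(is.na(mid$slippage)))

  # beyond the centroid cutoff nothing is reported
  farpair <- classify_stacking(make_contact_pair("pi_pi", perp = 6.5, offset = 0))
  expect_equal(nrow(farpair), 0)
})

test_that("Cremer-Pople parameters satisfy their identities", {
  # planar regular pentagon
  flat <- cremer_pople(make_ring_fixture(5, q2 = 0))
  expect_equal(flat$q2, 0, tolerance = 1e-12)

  # single lifted atom: independent direct evaluation of the CP definition
  r <- 1.54 / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  pts <- cbind(r * cos(ang), -r * sin(ang), c(0.5, 0, 0, 0, 0))
  p <- cremer_pople(pts)
  cen <- sweep(pts, 2, colMeans(pts))
  rp <- colSums(cen * sin(ang)); rpp <- colSums(cen * cos(ang))
  nrm <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
           rp[3] * rpp[1] - rp[1] * rpp[3],
           rp[1] * rpp[2] - rp[2] * rpp[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  z <- drop(cen %*% nrm)
  qc <- sqrt(2 / 5) * sum(z * cos(2 * ang))
  qs <- -sqrt(2 / 5) * sum(z * sin(2 * ang))
  expect_equal(p$q2, sqrt(qc^2 + qs^2), tolerance = 1e-10)
  expect_equal(p$phi2 %% 360, (atan2(qs, qc) * 180 / pi) %% 360, tolerance = 1e-8)
  expect_equal(p$q2^2, sum(z^2), tolerance = 1e-10)

  # Parseval-type identity and cyclic relabeling
  ring <- make_ring_fixture(5, q2 = 0.3831, phi2 = 42.8048)
  p0 <- cremer_pople(ring)
  expect_equal(p0$q2^2, sum(p0$z^2), tolerance = 1e-10)
  # advancing the starting atom by s steps shifts the phase by +144 deg each
  for (s in 1:4) {
    ps <- cremer_pople(ring[c((s + 1):5, 1:s), , drop = FALSE])
    expect_equal(ps$q2, p0$q2, tolerance = 1e-10)
    expect_equal((ps$phi2 - (p0$phi2 + 144 * s)) %% 360, 0, tolerance = 1e-6)
  }

  # six-ring: q2, q3 and Parseval
  six <- cremer_pople(make_ring_fixture(6, q2 = 0.25, phi2 = 310, q3 = 0.45))
  expect_equal(six$q2, 0.25, tolerance = 1e-10)
  expect_equal(six$phi2, 310, tolerance = 1e-6)
  expect_equal(six$q3, 0.45, tolerance = 1e-10)
  expect_equal(six$q2^2 + six$q3^2, sum(six$z^2), tolerance = 1e-10)

  expect_error(cremer_pople(matrix(c(0:4, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 5, 3)),
               "collinear")
})

test_that("Kabsch superposition is exact on rigid motions and matches bio3d", {
  set.seed(42)
  a <- matrix(rnorm(21), 7, 3)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0, tolerance = 1e-12)

  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% t(rot) + matrix(c(3, -2, 5), 7, 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(a, b)$rmsd, 1e-10)
  sup <- kabsch_rmsd(a, b)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)

  # perturbed set: symmetric in arguments, invariant under common motion
  b2 <- b
  b2[1, ] <- b2[1, ] + c(0.1, 0, 0)
  r_ab <- kabsch_rmsd(a, b2)$rmsd
  expect_equal(kabsch_rmsd(b2, a)$rmsd, r_ab, tolerance = 1e-10)
  expect_equal(kabsch_rmsd(a %*% t(rot), b2 %*% t(rot))$rmsd, r_ab,
               tolerance = 1e-10)

  # independent cross-check against bio3d's fitting routine
  if (requireNamespace("bio3d", quietly = TRUE)) {
    fx <- bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b2)),
                         fixed.inds = 1:21, mobile.inds = 1:21)
    r_bio3d <- sqrt(mean(rowSums((matrix(fx, ncol = 3, byrow = TRUE) - a)^2)))
    expect_equal(r_ab, r_bio3d, tolerance = 1e-6)
  }

  expect_error(kabsch_rmsd(a[1:2, ], b[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(line, line + 1), "collinear")
})
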