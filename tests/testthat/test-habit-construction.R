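cubic_form <- function(h, k, l, distance = 1) {
  tibble::tibble(h = h, k = k, l = l, distance = distance)
}

test_that("growth distances follow |E_att| with scale invariance and sign checks", {
  f <- ref_forms()
  gd <- growth_distances(f)
  expect_equal(max(gd$distance), 1)
  expect_equal(gd$distance[1] / gd$distance[2], 214.9592 / 208.9238,
               tolerance = 1e-12)
  # uniform energies collapse to unit distances; scaling is irrelevant
  same <- growth_distances(tibble::tibble(h = 1:3, k = 0, l = 0, e_att = -5))
  expect_true(all(same$distance == 1))
  scaled <- f
  scaled$e_att <- scaled$e_att * 17.3
  expect_equal(growth_distances(scaled)$distance, gd$distance)
  mixed <- f
  mixed$e_att[2] <- -mixed$e_att[2]
  expect_error(growth_distances(mixed), "mixed sign")
})

test_that("trivial Wulff shapes are exact: cube and octahedron", {
  cub <- unit_cell(10, 10, 10)
  ops <- space_group_ops("P-1")
  # cube: three axis forms, +/- each
  cube <- wulff_polyhedron(
    dplyr::bind_rows(cubic_form(1, 0, 0), cubic_form(0, 1, 0), cubic_form(0, 0, 1)),
    cub, ops)
  expect_equal(nrow(cube$vertices), 8)
  expect_true(all(abs(cube$facets$area - 4) < 1e-9))      # (2d)^2 with d = 1
  expect_equal(cube$forms$tfa, rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(habit_volume(cube), 8, tolerance = 1e-9)
  per_facet <- 100 * cube$facets$area / sum(cube$facets$area)
  expect_equal(per_facet, rep(100 / 6, 6), tolerance = 1e-9)

  # octahedron from the cubic {111} orbit: 8 facets, 12.5% each
  laue_m3m <- lapply(list(
    "x,y,z", "y,z,x", "z,x,y", "-x,y,z", "x,-y,z", "x,y,-z",
    "y,x,z", "x,z,y", "z,y,x"
  ), function(s) sym_op(s)$R)
  orbit <- unique(do.call(rbind, lapply(
    c(laue_m3m, lapply(laue_m3m, function(r) -r)),
    function(r) as.integer(round(c(1, 1, 1) %*% r)))))
  octa_forms <- tibble::tibble(h = 1, k = 1, l = 1, distance = 1,
                               equivalents = list(orbit))
  octa <- wulff_polyhedron(octa_forms, cub)
  expect_equal(nrow(octa$facets), 8)
  expect_equal(100 * octa$facets$area / sum(octa$facets$area),
               rep(12.5, 8), tolerance = 1e-9)
  # support distance 1 along (1,1,1)/sqrt(3) -> |x|+|y|+|z| <= sqrt(3)
  expect_equal(habit_volume(octa), 4 / 3 * sqrt(3)^3, tolerance = 1e-9)
})

test_that("the reference four-form habit reproduces the printed facet areas", {
  f <- ref_forms()
  hab <- wulff_polyhedron(growth_distances(f), ref_cell())
  tab <- facet_area_table(hab)
  expect_equal(sum(tab$tfa), 100, tolerance = 1e-9)
  # deterministic construction lands on the printed values
  expect_equal(hab$forms$tfa, hab$forms$tfa_ref, tolerance = 0.02 / 57.21)
  # {110} dominates, {111} is smallest
  expect_equal(tab$label[1], "110")
  expect_equal(tab$label[nrow(tab)], "111")
})

test_that("facet percentages are invariant under global distance scaling", {
  f <- growth_distances(ref_forms())
  base <- wulff_polyhedron(f, ref_cell())$forms$tfa
  for (s in c(0.2, 3, 40)) {
    fs <- f
    fs$distance <- fs$distance * s
    expect_equal(wulff_polyhedron(fs, ref_cell())$forms$tfa, base,
                 tolerance = 1e-9)
  }
})

test_that("occluded faces keep a zero-area row and do not perturb the habit", {
  f <- growth_distances(ref_forms())
  base <- wulff_polyhedron(f, ref_cell())
  circumradius <- max(sqrt(rowSums(base$vertices^2)))
  extra <- dplyr::bind_rows(
    f,
    tibble::tibble(h = 5, k = 3, l = 2, label = "532", multiplicity = 4,
                   d_hkl = d_spacing(ref_cell(), c(5, 3, 2)),
                   equivalents = list(hkl_orbit_for_test(c(5, 3, 2))),
                   e_att = NA, tfa_ref = NA, distance = circumradius * 1.05)
  )
  hab2 <- wulff_polyhedron(extra, ref_cell())
  expect_equal(hab2$forms$tfa[1:4], base$forms$tfa, tolerance = 1e-9)
  expect_equal(hab2$forms$tfa[5], 0)
  tab <- facet_area_table(hab2)
  expect_true("532" %in% tab$label)  # reported, not dropped
})

test_that("polyhedron facet normals honour the interfacial-angle law", {
  f <- growth_distances(ref_forms())
  hab <- wulff_polyhedron(f, ref_cell())
  fac <- hab$facets[hab$facets$area > 0, ]
  for (i in seq_len(nrow(fac) - 1)) {
    for (j in seq(i + 1, nrow(fac))) {
      n1 <- c(fac$nx[i], fac$ny[i], fac$nz[i])
      n2 <- c(fac$nx[j], fac$ny[j], fac$nz[j])
      ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
      expect_equal(ang,
                   interfacial_angle(ref_cell(),
                                     c(fac$eh[i], fac$ek[i], fac$el[i]),
                                     c(fac$eh[j], fac$ek[j], fac$el[j])),
                   tolerance = 1e-6)
    }
  }
})

test_that("BFDH distances follow 1/d with exact ratios", {
  cub <- unit_cell(10, 10, 10)
  forms <- tibble::tibble(h = c(1, 1), k = c(0, 1), l = 0)
  forms$d_hkl <- d_spacing(cub, as.matrix(forms))
  bf <- bfdh_distances(forms)
  expect_equal(bf$distance[2] / bf$distance[1], sqrt(2), tolerance = 1e-12)

  f <- bfdh_distances(ref_forms())
  # largest d ((110)) grows slowest -> smallest distance
  expect_equal(which.min(f$distance), 1)
  eq <- bfdh_distances(tibble::tibble(h = 1:2, k = 0, l = 0, d_hkl = c(3, 3)))
  expect_equal(eq$distance, c(1, 1))
})

test_that("unbounded or under-determined half-space sets are rejected", {
  cub <- unit_cell(10, 10, 10)
  # two opposite faces only
  expect_error(
    wulff_polyhedron(cubic_form(0, 0, 1), cub),
    "fewer than four")
  # prism open along z: normals all in the xy plane
  open_set <- dplyr::bind_rows(
    cubic_form(1, 0, 0), cubic_form(0, 1, 0), cubic_form(1, 1, 0),
    cubic_form(1, -1, 0))
  expect_error(wulff_polyhedron(open_set, cub), "unbounded")
})
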