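test_that("a minimal P1 CIF parses to one operator and one site", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_min",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "O1 O 0.1 0.2 0.3"
  ), path)
  cr <- read_cif(path)
  expect_length(cr$ops, 1)
  expect_equal(nrow(cr$atoms), 1)
  expect_equal(cr$atoms$x, 0.1)
  expect_equal(cr$atoms$occupancy, 1)
})

test_that("a CIF declaring C2/c operators recovers all 8 of them", {
  path <- withr::local_tempfile(fileext = ".cif")
  ops <- vapply(space_group_ops("C2/c"), sym_op_string, character(1))
  writeLines(c(
    "data_c2c",
    "_cell_length_a 19.9960",
    "_cell_length_b 16.7246",
    "_cell_length_c 19.1703",
    "_cell_angle_beta 116.319",
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("'%s'", ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 C 0.13 0.11 0.12"
  ), path)
  cr <- read_cif(path)
  expect_length(cr$ops, 8)
  # unicode-minus operator strings also parse
  expect_equal(sym_op("1/2−x, 3/2−y, 1−z", reduce = FALSE)$t,
               c(0.5, 1.5, 1))
})

test_that("write then re-parse is the identity on all fields", {
  cr <- make_molecular_crystal(z_prime = 2)
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(cr, path)
  cr2 <- read_cif(path)
  expect_equal(cr2$cell$a, cr$cell$a, tolerance = 1e-6)
  expect_equal(cr2$cell$beta, cr$cell$beta, tolerance = 1e-6)
  expect_equal(length(cr2$ops), length(cr$ops))
  for (i in seq_along(cr$ops)) {
    expect_true(all(cr2$ops[[i]]$R == cr$ops[[i]]$R))
    expect_equal(cr2$ops[[i]]$t, cr$ops[[i]]$t, tolerance = 1e-6)
  }
  expect_equal(cr2$atoms$label, cr$atoms$label)
  expect_equal(cr2$atoms$x, cr$atoms$x, tolerance = 1e-6)
  expect_equal(cr2$atoms$charge, cr$atoms$charge, tolerance = 1e-6)
  expect_equal(cr2$z_value, cr$z_value)
})

test_that("malformed CIF input fails with a named block or operator", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_a 10"), path)
  expect_error(read_cif(path), "cell block")
  writeLines(c(
    "data_x", "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x, y, z'"
  ), path)
  expect_error(read_cif(path), "atom_site")
  expect_error(sym_op("x, y"), "three components")
  expect_error(sym_op("x, y, q+z"), "q")
  expect_error(sym_op("2x, y, z"), "cannot parse")
})

test_that("parsed operator sets close under composition", {
  for (sg in c("P-1", "P21/c", "C2/c")) {
    ops <- space_group_ops(sg)
    for (i in seq_along(ops)) {
      for (j in seq_along(ops)) {
        comp <- sym_op_compose(ops[[i]], ops[[j]])
        hits <- vapply(ops, function(o) {
          all(o$R == comp$R) && all(abs(((o$t - comp$t) %% 1 + 0.5) %% 1 - 0.5) < 1e-9)
        }, logical(1))
        expect_true(any(hits), label = sprintf("%s: op%d o op%d closes", sg, i, j))
      }
    }
  }
})

test_that("symmetry expansion has the right counts and merges special positions", {
  # P1: identity only
  atoms <- tibble::tibble(label = paste0("C", 1:3), element = "C",
                          x = c(0.1, 0.2, 0.3), y = 0.1, z = 0.1)
  p1 <- crystal_structure(unit_cell(10, 10, 10), space_group_ops("P1"), atoms)
  ex <- expand_symmetry(p1)
  expect_equal(nrow(ex), 3)
  expect_true(all(ex$symop == "x, y, z"))

  # C2/c general position: 8 images
  g <- crystal_structure(unit_cell(15, 12, 14, beta = 100), space_group_ops("C2/c"),
                         tibble::tibble(label = "C1", element = "C",
                                        x = 0.13, y = 0.11, z = 0.12))
  expect_equal(nrow(expand_symmetry(g)), 8)

  # atom on the P-1 inversion centre collapses to one site
  s <- crystal_structure(unit_cell(10, 10, 10), space_group_ops("P-1"),
                         tibble::tibble(label = "C1", element = "C",
                                        x = 0, y = 0, z = 0))
  expect_equal(nrow(expand_symmetry(s)), 1)

  # Z' = 2 molecular crystal: 16 molecules worth of sites
  mc <- make_molecular_crystal(z_prime = 2)
  expect_equal(nrow(expand_symmetry(mc)), 16 * 4)
})

test_that("molecule identification finds units, centroids and identical copies", {
  # two well-separated diatomics
  atoms <- tibble::tibble(
    label = c("N1", "N2", "O1", "O2"), element = c("N", "N", "O", "O"),
    x = c(0.10, 0.14, 0.60, 0.64), y = 0.2, z = 0.2
  )
  cr <- crystal_structure(unit_cell(30, 30, 30), space_group_ops("P1"), atoms)
  mols <- identify_molecules(expand_symmetry(cr), cr$cell)
  expect_equal(length(unique(mols$mol)), 2)
  expect_equal(sort(table(mols$mol)), sort(table(c(1, 1, 2, 2))), ignore_attr = TRUE)

  # water-like triatomic: one unit, centroid = coordinate mean
  w <- tibble::tibble(
    label = c("O1", "H1", "H2"), element = c("O", "H", "H"),
    x = c(0.5, 0.5 + 0.96 / 20, 0.5 - 0.24 / 20),
    y = c(0.5, 0.5, 0.5 + 0.93 / 20), z = 0.5
  )
  cw <- crystal_structure(unit_cell(20, 20, 20), space_group_ops("P1"), w)
  mw <- identify_molecules(expand_symmetry(cw), cw$cell)
  expect_equal(length(unique(mw$mol)), 1)
  cen <- molecule_centroids(mw)
  expect_equal(c(cen$cx, cen$cy, cen$cz),
               colMeans(as.matrix(mw[, c("cx", "cy", "cz")])), ignore_attr = TRUE)

  # all symmetry copies of the C2/c fixture share one internal distance set
  mc <- make_molecular_crystal()
  mm <- identify_molecules(expand_symmetry(mc), mc$cell)
  dists <- lapply(split(mm, mm$mol), function(u) {
    sort(round(dist(as.matrix(u[, c("cx", "cy", "cz")])), 9))
  })
  expect_equal(length(dists), 8)
  for (d in dists[-1]) expect_equal(d, dists[[1]], ignore_attr = TRUE)
})

test_that("a periodically infinite bonded network is flagged, not split", {
  # chain of C atoms 1.5 A apart wrapping around a 3 A axis
  atoms <- tibble::tibble(label = c("C1", "C2"), element = "C",
                          x = c(0, 0.5), y = 0.25, z = 0.25)
  cr <- crystal_structure(unit_cell(3, 20, 20), space_group_ops("P1"), atoms)
  expect_error(identify_molecules(expand_symmetry(cr), cr$cell),
               "periodically infinite")
})
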