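# Shared fixtures: the monoclinic cell and face-energy table of the
# reference pseudouridine-analogue structure, used as the worked example.

ref_cell <- function() unit_cell(19.9960, 16.7246, 19.1703, beta = 116.319)

ref_forms <- function(cell = ref_cell()) {
  laue <- laue_rotations(space_group_ops("C2/c"))
  forms <- dplyr::bind_rows(
    face_multiplicity(laue, c(1, 1, 0), cell),
    face_multiplicity(laue, c(0, 0, 2), cell),
    face_multiplicity(laue, c(1, 1, -1), cell),
    face_multiplicity(laue, c(1, 1, 1), cell)
  )
  forms$e_att <- c(-214.9592, -208.9238, -299.1849, -255.0837)
  forms$tfa_ref <- c(57.21, 27.50, 12.71, 2.58)
  forms
}

# independent reciprocal-metric evaluation used as a brute-force oracle
oracle_d_spacing <- function(cell, hkl) {
  al <- cell$alpha * pi / 180; be <- cell$beta * pi / 180; ga <- cell$gamma * pi / 180
  g <- matrix(c(
    cell$a^2, cell$a * cell$b * cos(ga), cell$a * cell$c * cos(be),
    cell$a * cell$b * cos(ga), cell$b^2, cell$b * cell$c * cos(al),
    cell$a * cell$c * cos(be), cell$b * cell$c * cos(al), cell$c^2
  ), 3, 3)
  gstar <- solve(g)
  1 / sqrt(drop(t(hkl) %*% gstar %*% hkl))
}

oracle_interfacial_angle <- function(cell, h1, h2) {
  al <- cell$alpha * pi / 180; be <- cell$beta * pi / 180; ga <- cell$gamma * pi / 180
  g <- matrix(c(
    cell$a^2, cell$a * cell$b * cos(ga), cell$a * cell$c * cos(be),
    cell$a * cell$b * cos(ga), cell$b^2, cell$b * cell$c * cos(al),
    cell$a * cell$c * cos(be), cell$b * cell$c * cos(al), cell$c^2
  ), 3, 3)
  gs <- solve(g)
  num <- drop(t(h1) %*% gs %*% h2)
  den <- sqrt(drop(t(h1) %*% gs %*% h1) * drop(t(h2) %*% gs %*% h2))
  acos(max(-1, min(1, num / den))) * 180 / pi
}

hkl_orbit_for_test <- function(hkl) {
  laue <- laue_rotations(space_group_ops("C2/c"))
  face_multiplicity(laue, hkl)$equivalents[[1]]
}

# two-atom crystal in a large P1 box, for isolation/cutoff tests
two_atom_crystal <- function(separation, box = 80, element = "Ar") {
  atoms <- tibble::tibble(
    label = paste0(element, 1:2), element = element,
    x = c(0.25, 0.25 + separation / box), y = 0.25, z = 0.25
  )
  crystal_structure(unit_cell(box, box, box), space_group_ops("P1"), atoms,
                    z_value = 2, z_prime = 2)
}
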