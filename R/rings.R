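# Ring perception (smallest set of smallest rings) and ring-ring stacking
# classification. SSSR is computed Horton-style: candidate cycles are the
# shortest cycles through each edge, selected greedily by length under GF(2)
# independence of their edge-incidence vectors until the cycle-space rank
# m - n + c is reached.

ls_plane_normal <- function(pts) {
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen)
  nrm <- sv$v[, 3]
  list(centroid = ctr, normal = nrm,
       rms = sqrt(mean(drop(cen %*% nrm)^2)))
}

sssr_cycles <- function(edge_mat, n_vertices, max_size) {
  g <- igraph::make_empty_graph(n_vertices, directed = FALSE)
  g <- igraph::add_edges(g, t(edge_mat))
  n_cyc <- igraph::ecount(g) - n_vertices + igraph::components(g)$no
  if (n_cyc <= 0) return(list())
  cand <- list()
  for (e in seq_len(nrow(edge_mat))) {
    u <- edge_mat[e, 1]; v <- edge_mat[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = u, to = v, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 3 || length(path) > max_size) next
    cand[[length(cand) + 1]] <- path
  }
  if (!length(cand)) return(list())
  cand <- cand[order(lengths(cand))]
  # GF(2) greedy selection on edge-incidence vectors
  edge_key <- paste(pmin(edge_mat[, 1], edge_mat[, 2]),
                    pmax(edge_mat[, 1], edge_mat[, 2]))
  basis <- list()
  chosen <- list()
  to_vec <- function(path) {
    vec <- logical(nrow(edge_mat))
    nv <- length(path)
    for (i in seq_len(nv)) {
      a <- path[i]; b <- path[if (i == nv) 1 else i + 1]
      vec[match(paste(min(a, b), max(a, b)), edge_key)] <- TRUE
    }
    vec
  }
  for (path in cand) {
    if (length(chosen) >= n_cyc) break
    vec <- to_vec(path)
    red <- vec
    for (b in basis) {
      piv <- which(b)[1]
      if (red[piv]) red <- xor(red, b)
    }
    if (any(red)) {
      basis[[length(basis) + 1]] <- red
      chosen[[length(chosen) + 1]] <- path
    }
  }
  chosen
}

#' Perceive rings and their centroids
#'
#' Finds the smallest set of smallest rings (up to `max_size` atoms) in each
#' molecular unit, and reports for each ring its ordered atom labels,
#' unweighted centroid, least-squares plane normal and planarity RMS.
#'
#' @param mols tibble from [identify_molecules()] (needs `mol`, `label`,
#'   `element` and Cartesian `cx, cy, cz`).
#' @param max_size largest ring size perceived (default 6).
#' @return tibble: `ring, mol, size, atoms` (list of ordered labels),
#'   `cx, cy, cz` (centroid), `normal` (list of unit 3-vectors),
#'   `planarity_rms`.
#' @export
perceive_rings <- function(mols, max_size = 6) {
  mols <- tibble::as_tibble(mols)
  out <- list()
  rid <- 0
  for (u in sort(unique(mols$mol))) {
    sub <- mols[mols$mol == u, ]
    xyz <- as.matrix(sub[, c("cx", "cy", "cz")])
    bonds <- bonded_pairs(xyz, sub$element)
    if (!nrow(bonds)) next
    cycles <- sssr_cycles(bonds, nrow(sub), max_size)
    for (path in cycles) {
      rid <- rid + 1
      pl <- ls_plane_normal(xyz[path, , drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        ring = rid, mol = u, size = length(path),
        atoms = list(sub$label[path]),
        cx = pl$centroid[1], cy = pl$centroid[2], cz = pl$centroid[3],
        normal = list(pl$normal),
        planarity_rms = pl$rms
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      ring = integer(), mol = integer(), size = integer(), atoms = list(),
      cx = numeric(), cy = numeric(), cz = numeric(), normal = list(),
      planarity_rms = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

#' Classify ring-ring stacking interactions
#'
#' Pairs every ring of the reference (identity) molecules with every ring
#' image under the space-group operators and one shell of lattice
#' translations. Pairs with centroid-centroid distance below `max_cg` are
#' reported with the dihedral angle between ring planes (folded to
#' \[0, 90\] degrees) and classified: face-to-face pi-pi when the dihedral
#' is below `pipi_angle` (slippage = in-plane offset of the partner centroid
#' with respect to the first ring's normal, so
#' slippage^2 + d_perp^2 = cg^2), T-shaped when the dihedral is at least
#' `t_angle`, otherwise unclassified. Slippage is reported only for pi-pi
#' pairs; records are directional (ring_i's normal defines the slippage),
#' so Cg(i)...Cg(j) and Cg(j)...Cg(i) may differ.
#'
#' @param structure a `crystal`.
#' @param max_cg centroid-centroid cutoff, angstrom.
#' @param pipi_angle dihedral cutoff for pi-pi, degrees.
#' @param t_angle minimum dihedral for T-shaped, degrees.
#' @param max_size largest ring size perceived.
#' @return tibble: `ring_i, ring_j, atoms_i, atoms_j, cg_distance, dihedral,
#'   slippage, klass, symop`.
#' @export
classify_stacking <- function(structure, max_cg = 6.0, pipi_angle = 20,
                              t_angle = 60, max_size = 6) {
  expanded <- expand_symmetry(structure)
  mols <- identify_molecules(expanded, structure$cell)
  ref <- mols[mols$op == 1, ]
  if (!nrow(ref)) abort("no identity-operator atoms in the expanded structure")
  ref_rings <- perceive_rings(ref, max_size = max_size)
  if (!nrow(ref_rings)) {
    return(empty_stacking_tibble())
  }
  m <- frac_to_cart_matrix(structure$cell)
  minv <- solve(m)

  # ring images: transform the ring atoms of the reference through every
  # operator and translation shell, recomputing centroid and plane
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ref$row_id <- seq_len(nrow(ref))
  images <- list()
  for (ri in seq_len(nrow(ref_rings))) {
    sub <- ref[ref$mol == ref_rings$mol[ri], ]
    idx <- match(ref_rings$atoms[[ri]], sub$label)
    pts_frac <- as.matrix(sub[idx, c("xu", "yu", "zu")])
    for (oi in seq_along(structure$ops)) {
      op <- structure$ops[[oi]]
      img <- pts_frac %*% t(op$R) + matrix(op$t, nrow(pts_frac), 3, byrow = TRUE)
      for (si in seq_len(nrow(shifts))) {
        pts <- (img + matrix(shifts[si, ], nrow(img), 3, byrow = TRUE)) %*% t(m)
        pl <- ls_plane_normal(pts)
        images[[length(images) + 1]] <- tibble::tibble(
          ring = ref_rings$ring[ri],
          cx = pl$centroid[1], cy = pl$centroid[2], cz = pl$centroid[3],
          normal = list(pl$normal),
          code = op_code_string(op, shifts[si, ]),
          identity = oi == 1 && all(shifts[si, ] == 0)
        )
      }
    }
  }
  imgs <- dplyr::bind_rows(images)

  recs <- list()
  for (ri in seq_len(nrow(ref_rings))) {
    ci <- c(ref_rings$cx[ri], ref_rings$cy[ri], ref_rings$cz[ri])
    ni <- ref_rings$normal[[ri]]
    dvec <- cbind(imgs$cx - ci[1], imgs$cy - ci[2], imgs$cz - ci[3])
    cg <- sqrt(rowSums(dvec^2))
    cand <- which(cg < max_cg & !(imgs$identity & imgs$ring == ref_rings$ring[ri]))
    for (a in cand) {
      nj <- imgs$normal[[a]]
      cosd <- abs(sum(ni * nj))
      dihedral <- rad2deg(acos(pmin(1, cosd)))
      d_perp <- abs(sum(dvec[a, ] * ni))
      slip <- if (dihedral < pipi_angle) sqrt(max(0, cg[a]^2 - d_perp^2)) else NA_real_
      klass <- if (dihedral < pipi_angle) "pi-pi"
               else if (dihedral >= t_angle) "T-shaped"
               else "unclassified"
      recs[[length(recs) + 1]] <- tibble::tibble(
        ring_i = ref_rings$ring[ri],
        ring_j = imgs$ring[a],
        atoms_i = list(ref_rings$atoms[[ri]]),
        atoms_j = list(ref_rings$atoms[[imgs$ring[a]]]),
        cg_distance = cg[a],
        dihedral = dihedral,
        d_perp = d_perp,
        slippage = slip,
        klass = klass,
        symop = imgs$code[a]
      )
    }
  }
  if (!length(recs)) return(empty_stacking_tibble())
  dplyr::bind_rows(recs)
}

empty_stacking_tibble <- function() {
  tibble::tibble(
    ring_i = integer(), ring_j = integer(), atoms_i = list(), atoms_j = list(),
    cg_distance = numeric(), dihedral = numeric(), d_perp = numeric(),
    slippage = numeric(), klass = character(), symop = character()
  )
}
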