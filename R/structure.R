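#' Crystal structure container
#'
#' Bundles a unit cell, a space-group operator list, and the asymmetric-unit
#' atom sites (fractional coordinates) into the universal input record of the
#' package. Atom sites live in a tibble so the usual dplyr verbs apply.
#'
#' @param cell a [unit_cell()].
#' @param ops list of `sym_op` (use [space_group_ops()] for common groups).
#' @param atoms tibble/data frame with columns `label`, `element`, `x`, `y`,
#'   `z` (fractional) and optionally `occupancy` (default 1) and `charge`
#'   (partial charge in e, default 0).
#' @param z_value formula units per cell (Z); defaults to
#'   `length(ops) * z_prime`.
#' @param z_prime independent molecules in the asymmetric unit (default 1).
#' @return object of class `crystal`.
#' @export
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' atoms <- tibble::tibble(label = "O1", element = "O", x = 0.1, y = 0.2, z = 0.3)
#' crystal_structure(cell, space_group_ops("P1"), atoms)
crystal_structure <- function(cell, ops, atoms, z_value = NULL, z_prime = 1) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!length(ops) || !all(vapply(ops, inherits, logical(1), "sym_op"))) {
    abort("ops must be a non-empty list of sym_op objects")
  }
  atoms <- tibble::as_tibble(atoms)
  need <- c("label", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste("atom table lacks column(s):", paste(miss, collapse = ", ")))
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (any(atoms$occupancy <= 0 | atoms$occupancy > 1)) {
    abort("occupancies must lie in (0, 1]")
  }
  covalent_radius(unique(atoms$element))  # errors on unknown elements
  atoms <- atoms[, c("label", "element", "x", "y", "z", "occupancy", "charge")]
  if (is.null(z_value)) z_value <- length(ops) * z_prime
  structure(
    list(cell = cell, ops = ops, atoms = atoms,
         z_value = z_value, z_prime = z_prime),
    class = "crystal"
  )
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("<crystal> %d asymmetric-unit atom(s), %d symmetry operator(s), Z=%s, Z'=%s\n",
              nrow(x$atoms), length(x$ops), x$z_value, x$z_prime))
  print(x$cell)
  invisible(x)
}

#' Consistency check between Z, Z' and the operator count
#'
#' For molecules on fully general positions, Z must equal the number of
#' space-group operators times Z'.
#'
#' @param structure a `crystal`.
#' @return `TRUE`/`FALSE`, invisibly a message attribute describing the check.
#' @export
z_consistent <- function(structure) {
  expected <- length(structure$ops) * structure$z_prime
  ok <- expected == structure$z_value
  structure(ok, message = sprintf("Z = %d, |ops| x Z' = %d x %s = %d",
                                  structure$z_value, length(structure$ops),
                                  structure$z_prime, expected))
}

frac_to_cart <- function(cell, frac) {
  frac <- matrix(as.numeric(as.matrix(frac)), ncol = 3)
  frac %*% t(frac_to_cart_matrix(cell))
}

#' Expand the asymmetric unit to the full unit cell
#'
#' Applies every symmetry operator to every asymmetric-unit atom, wraps the
#' images into \[0, 1), and merges images closer than `merge_tol` angstrom
#' (Cartesian, minimum-image) as special-position duplicates. Each surviving
#' site keeps the coordinate-triplet text of the operator that generated it.
#'
#' @param structure a `crystal`.
#' @param merge_tol special-position merge tolerance in angstrom.
#' @return tibble: `label, element, x, y, z, occupancy, charge, site`
#'   (asymmetric-unit row index), `op` (operator index), `symop` (operator
#'   text).
#' @export
expand_symmetry <- function(structure, merge_tol = 0.3) {
  stopifnot(inherits(structure, "crystal"))
  atoms <- structure$atoms
  ops <- structure$ops
  frac <- as.matrix(atoms[, c("x", "y", "z")])
  pieces <- vector("list", length(ops))
  for (i in seq_along(ops)) {
    op_i <- ops[[i]]
    img <- (frac %*% t(op_i$R) +
              matrix(rep(op_i$t, each = nrow(frac)), ncol = 3)) %% 1
    code <- sym_op_string(op_i)
    pieces[[i]] <- tibble::tibble(
      label = atoms$label, element = atoms$element,
      x = img[, 1], y = img[, 2], z = img[, 3],
      occupancy = atoms$occupancy, charge = atoms$charge,
      site = seq_len(nrow(atoms)), op = i,
      symop = code
    )
  }
  out <- dplyr::bind_rows(pieces)
  # merge special-position duplicates per asymmetric site
  m <- frac_to_cart_matrix(structure$cell)
  keep <- rep(TRUE, nrow(out))
  for (s in seq_len(nrow(atoms))) {
    idx <- which(out$site == s)
    if (length(idx) < 2) next
    fr <- as.matrix(out[idx, c("x", "y", "z")])
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1)) {
        if (!keep[idx[b]]) next
        d <- fr[a, ] - fr[b, ]
        d <- d - round(d)
        if (sqrt(sum((m %*% d)^2)) < merge_tol) {
          keep[idx[a]] <- FALSE
          break
        }
      }
    }
  }
  out[keep, ]
}

#' Partition expanded sites into bonded molecular units
#'
#' Builds the covalent bond graph with the distance criterion
#' `d(i, j) <= r_cov(i) + r_cov(j) + 0.4` angstrom under periodic
#' minimum-image distances, then labels connected components. Coordinates
#' are unwrapped so every molecule is contiguous (not split across cell
#' boundaries); a component whose bond cycles carry a nonzero net lattice
#' shift is a periodically infinite network and raises an error.
#'
#' @param sites tibble from [expand_symmetry()] (or any tibble with
#'   `label`, `element` and fractional `x, y, z`).
#' @param cell the [unit_cell()] the coordinates refer to.
#' @param bond_slack additive slack on the covalent-radius sum, angstrom.
#' @return the input tibble with columns `mol` (unit id), unwrapped
#'   fractional `xu, yu, zu` and Cartesian `cx, cy, cz` appended.
#' @export
identify_molecules <- function(sites, cell, bond_slack = 0.4) {
  sites <- tibble::as_tibble(sites)
  n <- nrow(sites)
  if (n == 0) abort("no atom sites supplied")
  frac <- as.matrix(sites[, c("x", "y", "z")])
  m <- frac_to_cart_matrix(cell)
  rc <- covalent_radius(sites$element)

  # an atom bonded to its own lattice translate is already infinite
  cell_shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nonzero <- rowSums(abs(cell_shifts)) > 0
  shortest_lattice <- min(sqrt(rowSums((cell_shifts[nonzero, ] %*% t(m))^2)))
  self_bonded <- 2 * rc + bond_slack >= shortest_lattice
  if (any(self_bonded)) {
    abort(sprintf(
      "atoms %s belong to a periodically infinite bonded network (bonded to their own lattice image)",
      paste(unique(sites$label[self_bonded]), collapse = ", ")))
  }

  # bond detection over every lattice image within one shell: a pair may be
  # bonded through more than one image in a small cell, and those multiple
  # edges are what reveal periodically infinite networks
  edges <- list()
  shifts <- list()
  if (n > 1) {
    for (si in seq_len(nrow(cell_shifts))) {
      e <- cell_shifts[si, ]
      for (i in seq_len(n - 1)) {
        d <- frac[(i + 1):n, , drop = FALSE] -
          matrix(frac[i, ] - e, n - i, 3, byrow = TRUE)
        dist <- sqrt(rowSums((d %*% t(m))^2))
        cut <- rc[i] + rc[(i + 1):n] + bond_slack
        hit <- which(dist <= cut & dist > 1e-6)
        if (length(hit)) {
          edges[[length(edges) + 1]] <- cbind(i, i + hit)
          shifts[[length(shifts) + 1]] <- matrix(e, length(hit), 3, byrow = TRUE)
        }
      }
    }
  }
  edge_mat <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2)
  shift_mat <- if (length(shifts)) do.call(rbind, shifts) else matrix(0, 0, 3)

  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edge_mat)) g <- igraph::add_edges(g, t(edge_mat))
  comp <- igraph::components(g)$membership

  # unwrap by BFS over the bond graph; shift[j] - shift[i] must match the
  # minimum-image shift on every bond or the unit is periodically infinite
  unwrap <- matrix(NA_real_, n, 3)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edge_mat))) {
    i <- edge_mat[e, 1]; j <- edge_mat[e, 2]
    adj[[i]] <- c(adj[[i]], list(list(j = j, s = shift_mat[e, ])))
    adj[[j]] <- c(adj[[j]], list(list(j = i, s = -shift_mat[e, ])))
  }
  for (root in seq_len(n)) {
    if (!is.na(unwrap[root, 1])) next
    unwrap[root, ] <- frac[root, ]
    queue <- root
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (nb in adj[[i]]) {
        pos <- frac[nb$j, ] + nb$s + round(unwrap[i, ] - frac[i, ])
        if (is.na(unwrap[nb$j, 1])) {
          unwrap[nb$j, ] <- pos
          queue <- c(queue, nb$j)
        } else if (max(abs(unwrap[nb$j, ] - pos)) > 1e-6) {
          abort(sprintf(
            "atoms %s and %s belong to a periodically infinite bonded network",
            sites$label[i], sites$label[nb$j]))
        }
      }
    }
  }
  cart <- unwrap %*% t(m)
  out <- sites
  out$mol <- as.integer(comp)
  out$xu <- unwrap[, 1]; out$yu <- unwrap[, 2]; out$zu <- unwrap[, 3]
  out$cx <- cart[, 1]; out$cy <- cart[, 2]; out$cz <- cart[, 3]
  out
}

#' Per-molecule summary of a partitioned structure
#' @param mols tibble from [identify_molecules()].
#' @return tibble: `mol, n_atoms, cx, cy, cz` (Cartesian centroid, angstrom).
#' @export
molecule_centroids <- function(mols) {
  mols |>
    dplyr::group_by(.data$mol) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      cx = mean(.data$cx), cy = mean(.data$cy), cz = mean(.data$cz),
      .groups = "drop"
    )
}
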