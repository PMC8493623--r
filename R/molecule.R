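#' Construct a molecule
#'
#' A molecule is an ordered table of Cartesian atoms plus a bond list. Atoms
#' carry their generator bookkeeping: the originating asymmetric-unit site
#' label, the symmetry-operation index and the integer cell translation that
#' produced them.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `label`, `site`, `op`, `tx`, `ty`, `tz`. Masses are filled in
#'   from the element table unless a `mass` column is supplied.
#' @param bonds two-column integer matrix of atom indices, or `NULL` to infer
#'   them from geometry with [infer_bonds()].
#' @param residue_id 1-based index of this molecule within the asymmetric unit.
#' @return an object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, residue_id = 1L) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$label)) atoms$label <- paste0(atoms$element, seq_len(nrow(atoms)))
  if (is.null(atoms$mass)) atoms$mass <- atomic_mass(atoms$element)
  for (col in c("site", "op", "tx", "ty", "tz")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- if (col == "op") 1L else 0L
  }
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  structure(list(atoms = atoms, bonds = bonds, residue_id = as.integer(residue_id)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  tab <- table(x$atoms$element)
  formula <- paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = "")
  cat(sprintf("<molecule %d> %s: %d atoms, %d bonds\n",
              x$residue_id, formula, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

.atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Infer covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded when their distance is below the sum of covalent
#' radii plus `slack`. Hydrogen is capped at a single bond, to its nearest
#' heavy atom; H-H bonds are never formed.
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` columns.
#' @param slack bond-detection slack in Angstrom.
#' @return two-column integer matrix of bonded index pairs (i < j).
#' @export
infer_bonds <- function(atoms, slack = 0.40) {
  n <- nrow(atoms)
  if (n == 0) stop("no atoms")
  if (n == 1) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  xyz <- .atom_xyz(atoms)
  rc <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  thresh <- outer(rc, rc, "+") + slack
  is_h <- atoms$element == "H"
  cand <- d < thresh & upper.tri(d)
  cand[is_h, is_h] <- FALSE
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  keep <- rep(TRUE, nrow(idx))
  # hydrogen: keep only the nearest partner
  for (h in which(is_h)) {
    rows <- which(idx[, 1] == h | idx[, 2] == h)
    if (length(rows) > 1) {
      dists <- d[cbind(idx[rows, 1], idx[rows, 2])]
      keep[rows[-which.min(dists)]] <- FALSE
    }
  }
  out <- idx[keep, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Remove coincident atoms
#'
#' Symmetry expansion places atoms on special positions onto themselves;
#' such duplicates are dropped, the earlier-listed atom winning.
#'
#' @param atoms data.frame with `x`, `y`, `z`.
#' @param tolerance coincidence distance in Angstrom.
#' @param verbose report how many atoms were dropped.
#' @return the surviving atoms, original order preserved.
#' @export
drop_coincident <- function(atoms, tolerance = 0.15, verbose = FALSE) {
  stopifnot(tolerance > 0)
  n <- nrow(atoms)
  if (n < 2) return(atoms)
  d <- as.matrix(stats::dist(.atom_xyz(atoms)))
  keep <- rep(TRUE, n)
  for (j in 2:n) {
    if (any(keep[1:(j - 1)] & d[1:(j - 1), j] < tolerance)) keep[j] <- FALSE
  }
  if (verbose && any(!keep)) {
    message(sum(!keep), " coincident atom(s) dropped")
  }
  atoms[keep, , drop = FALSE]
}

.identity_op_index <- function(operations) {
  for (op in operations) {
    if (all(abs(op$rotation - diag(3)) < 1e-8) && all(abs(op$translation) < 1e-8)) {
      return(op$index)
    }
  }
  stop("operation list does not contain the identity")
}

#' Complete molecules from the asymmetric unit
#'
#' Grows chemically complete molecules by applying space-group operations and
#' lattice translations to the asymmetric-unit sites until the bond graph
#' closes. Atoms that land on already-present atoms (special positions) are
#' dropped, keeping the first generator. Each connected set of asymmetric-unit
#' sites yields one molecule (residue).
#'
#' @param structure a `crystal_structure` from [parse_cif()].
#' @param slack covalent bond slack in Angstrom (see [infer_bonds()]).
#' @param tolerance coincidence tolerance in Angstrom.
#' @param max_shell abort with a "polymeric" error if a molecule extends more
#'   than this many cells from its seed (infinite connectivity).
#' @param allow_disorder if `FALSE` (default), sites with occupancy < 1 are an
#'   error.
#' @return list of `molecule` objects with `residue_id` 1, 2, ...
#' @export
complete_molecules <- function(structure, slack = 0.40, tolerance = 0.15,
                               max_shell = 4L, allow_disorder = FALSE) {
  s <- structure
  if (!allow_disorder && any(s$sites$occupancy < 1 - 1e-9)) {
    stop("structure has disordered sites (occupancy < 1): ",
         paste(s$sites$label[s$sites$occupancy < 1 - 1e-9], collapse = ", "),
         "; pass allow_disorder = TRUE to override")
  }
  nsite <- nrow(s$sites)
  site_frac <- as.matrix(s$sites[, c("fx", "fy", "fz")])
  rc <- covalent_radius(s$sites$element)
  m <- cell_matrix(s$cell)
  ops <- s$operations

  # all (site, op) base images in fractional coordinates
  nop <- length(ops)
  base <- vector("list", nop)
  for (k in seq_len(nop)) base[[k]] <- apply_symop(ops[[k]], site_frac)

  id_op <- .identity_op_index(ops)
  consumed <- rep(FALSE, nsite)
  molecules <- list()
  shifts27 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

  while (any(!consumed)) {
    seed <- which(!consumed)[1]
    at <- data.frame(site = seed, op = id_op, tx = 0L, ty = 0L, tz = 0L,
                     fx = site_frac[seed, 1], fy = site_frac[seed, 2],
                     fz = site_frac[seed, 3], stringsAsFactors = FALSE)
    frontier <- 1L
    while (length(frontier) > 0) {
      new_rows <- list()
      for (ai in frontier) {
        fa <- as.numeric(at[ai, c("fx", "fy", "fz")])
        ca <- as.numeric(m %*% fa)
        for (k in seq_len(nop)) {
          bs <- base[[k]]
          n0 <- round(matrix(fa, nsite, 3, byrow = TRUE) - bs)
          for (sh in seq_len(nrow(shifts27))) {
            nn <- n0 + matrix(shifts27[sh, ], nsite, 3, byrow = TRUE)
            q <- bs + nn
            cq <- t(m %*% t(q))
            dd <- sqrt(rowSums((cq - matrix(ca, nsite, 3, byrow = TRUE))^2))
            hit <- which(dd >= tolerance & dd < rc[at$site[ai]] + rc + slack)
            for (hs in hit) {
              # skip if this image is already present in the molecule
              fq <- q[hs, ]
              cqs <- cq[hs, ]
              present <- FALSE
              allc <- t(m %*% t(as.matrix(at[, c("fx", "fy", "fz")])))
              if (any(sqrt(rowSums((allc - matrix(cqs, nrow(at), 3, byrow = TRUE))^2)) < tolerance)) {
                present <- TRUE
              }
              if (!present && length(new_rows) > 0) {
                prev <- do.call(rbind, new_rows)
                pc <- t(m %*% t(as.matrix(prev[, c("fx", "fy", "fz")])))
                if (any(sqrt(rowSums((pc - matrix(cqs, nrow(prev), 3, byrow = TRUE))^2)) < tolerance)) {
                  present <- TRUE
                }
              }
              if (!present) {
                if (any(abs(fq - site_frac[seed, ]) > max_shell + 1)) {
                  stop(sprintf(
                    "polymeric connectivity: bond from site %s reaches beyond %d cells (bridging bond %s-%s)",
                    s$sites$label[at$site[ai]], max_shell,
                    s$sites$label[at$site[ai]], s$sites$label[hs]))
                }
                new_rows[[length(new_rows) + 1L]] <- data.frame(
                  site = hs, op = k, tx = nn[hs, 1], ty = nn[hs, 2], tz = nn[hs, 3],
                  fx = fq[1], fy = fq[2], fz = fq[3], stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
      if (length(new_rows) > 0) {
        new_df <- do.call(rbind, new_rows)
        start <- nrow(at) + 1L
        at <- rbind(at, new_df)
        frontier <- start:nrow(at)
      } else {
        frontier <- integer(0)
      }
    }
    cart <- t(m %*% t(as.matrix(at[, c("fx", "fy", "fz")])))
    atoms <- data.frame(
      label = s$sites$label[at$site],
      element = s$sites$element[at$site],
      x = cart[, 1], y = cart[, 2], z = cart[, 3],
      site = at$site, op = at$op,
      tx = as.integer(at$tx), ty = as.integer(at$ty), tz = as.integer(at$tz),
      stringsAsFactors = FALSE
    )
    atoms <- drop_coincident(atoms, tolerance)
    atoms$label <- make.unique(atoms$label, sep = "_")
    mol <- molecule(atoms, residue_id = length(molecules) + 1L)
    ncomp <- .n_components(nrow(mol$atoms), mol$bonds)
    if (ncomp != 1) {
      warning(sprintf("molecule %d has %d disconnected fragments", mol$residue_id, ncomp))
    }
    molecules[[length(molecules) + 1L]] <- mol
    consumed[unique(at$site)] <- TRUE
  }
  molecules
}

.n_components <- function(n, bonds) {
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- find(bonds[r, 1]); b <- find(bonds[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

#' Default neutron X-H normalization targets
#'
#' Mean internuclear X-H distances from neutron diffraction, in Angstrom.
#'
#' @return named numeric vector (by donor element).
#' @export
default_h_table <- function() {
  c(C = 1.089, N = 1.015, O = 0.993, B = 1.180)
}

#' Normalize hydrogen positions to neutron-derived bond lengths
#'
#' Each hydrogen is moved along its existing X-H bond direction so that the
#' X-H distance equals the table value for element X. Heavy atoms never move.
#' Elements absent from the table leave their hydrogens untouched.
#'
#' @param mol a [molecule()].
#' @param table named numeric vector of target X-H lengths (Angstrom); see
#'   [default_h_table()].
#' @return the molecule with updated hydrogen coordinates.
#' @export
normalize_h <- function(mol, table = default_h_table()) {
  if (any(table <= 0.8 | table >= 1.3)) {
    stop("implausible X-H normalization length; expected (0.8, 1.3) Angstrom")
  }
  atoms <- mol$atoms
  is_h <- atoms$element == "H"
  if (!any(is_h)) {
    message("no hydrogen atoms; normalization skipped")
    return(mol)
  }
  bonds <- mol$bonds
  for (h in which(is_h)) {
    rows <- which(bonds[, 1] == h | bonds[, 2] == h)
    if (length(rows) == 0) {
      stop("hydrogen atom ", atoms$label[h], " has no bonded heavy atom")
    }
    partner <- setdiff(as.integer(bonds[rows[1], ]), h)
    x_el <- atoms$element[partner]
    if (!(x_el %in% names(table))) next
    v <- as.numeric(atoms[h, c("x", "y", "z")]) - as.numeric(atoms[partner, c("x", "y", "z")])
    len <- sqrt(sum(v^2))
    if (len < 1e-9) stop("degenerate X-H bond at ", atoms$label[h])
    newpos <- as.numeric(atoms[partner, c("x", "y", "z")]) + v / len * table[[x_el]]
    atoms[h, c("x", "y", "z")] <- as.list(newpos)
  }
  mol$atoms <- atoms
  mol
}

#' Mass-weighted centroid of a molecule
#'
#' @param mol a [molecule()].
#' @return Cartesian 3-vector (Angstrom) satisfying sum(m_i (r_i - c)) = 0.
#' @export
mass_weighted_centroid <- function(mol) {
  xyz <- .atom_xyz(mol$atoms)
  w <- mol$atoms$mass
  unname(colSums(xyz * w) / sum(w))
}

#' Enforce the Pixel-format 200-atom capacity
#'
#' @param mol a [molecule()].
#' @param limit maximum atom count for Pixel-format export.
#' @return `mol`, invisibly, if within capacity.
#' @export
check_pixel_capacity <- function(mol, limit = 200L) {
  if (nrow(mol$atoms) > limit) {
    stop(sprintf("molecule %d has %d atoms, exceeding the %d-atom Pixel capacity",
                 mol$residue_id, nrow(mol$atoms), limit))
  }
  invisible(mol)
}
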