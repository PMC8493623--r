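#' Brute-force supercell pair enumeration (oracle)
#'
#' Independent reference path for [enumerate_pairs()]: every molecule is
#' transformed atom by atom over all operations and all cell translations in
#' a +-`shell` supercell, its mass-weighted centroid is recomputed from the
#' transformed atoms, and Cartesian centroid distances are measured directly.
#' Intentionally shares no enumeration or centroid-propagation logic with the
#' production path.
#'
#' @param structure a `crystal_structure`.
#' @param molecules completed molecules.
#' @param cutoff centroid cutoff in Angstrom.
#' @param shell supercell half-width in cells.
#' @return data.frame `ref`, `neighbor`, `op`, `tx`, `ty`, `tz`, `distance`,
#'   sorted like a pair table.
#' @export
brute_force_pairs <- function(structure, molecules, cutoff, shell = 3L) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  cents <- lapply(molecules, mass_weighted_centroid)
  grid <- as.matrix(expand.grid(tx = -shell:shell, ty = -shell:shell, tz = -shell:shell))
  rows <- list()
  for (r in seq_along(molecules)) {
    cr <- cents[[r]]
    for (s in seq_along(molecules)) {
      for (k in seq_along(structure$operations)) {
        for (g in seq_len(nrow(grid))) {
          img <- symmetry_image(structure, molecules[[s]], k, grid[g, ])
          ci <- mass_weighted_centroid(img)
          d <- sqrt(sum((ci - cr)^2))
          if (d > 1e-8 && d <= cutoff + 1e-9) {
            rows[[length(rows) + 1L]] <- data.frame(
              ref = r, neighbor = s, op = k,
              tx = grid[g, 1], ty = grid[g, 2], tz = grid[g, 3],
              distance = d)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(ref = integer(0), neighbor = integer(0), op = integer(0),
                      tx = integer(0), ty = integer(0), tz = integer(0),
                      distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$ref, out$neighbor, out$op, out$tx, out$ty, out$tz), ]
  rownames(out) <- NULL
  out
}

#' Brute-force molecule completion (oracle)
#'
#' Expands every asymmetric-unit site over all operations and a +-`shell`
#' supercell, deduplicates coincident positions, and returns the connected
#' components of the resulting atom cloud as data.frames of Cartesian atoms.
#' Used to cross-check [complete_molecules()].
#'
#' @param structure a `crystal_structure`.
#' @param shell supercell half-width.
#' @param slack,tolerance bond slack and coincidence tolerance (Angstrom).
#' @return list of data.frames (element, x, y, z), one per component.
#' @export
brute_force_molecules <- function(structure, shell = 2L, slack = 0.40,
                                  tolerance = 0.15) {
  sites <- structure$sites
  grid <- as.matrix(expand.grid(-shell:shell, -shell:shell, -shell:shell))
  frac_all <- list()
  elem_all <- character(0)
  for (k in seq_along(structure$operations)) {
    base <- apply_symop(structure$operations[[k]],
                        as.matrix(sites[, c("fx", "fy", "fz")]))
    for (g in seq_len(nrow(grid))) {
      frac_all[[length(frac_all) + 1L]] <- sweep(base, 2, grid[g, ], "+")
      elem_all <- c(elem_all, sites$element)
    }
  }
  frac <- do.call(rbind, frac_all)
  cart <- frac_to_cart(structure$cell, frac)
  atoms <- data.frame(element = elem_all, x = cart[, 1], y = cart[, 2], z = cart[, 3],
                      stringsAsFactors = FALSE)
  atoms <- drop_coincident(atoms, tolerance)
  # connected components by covalent distance
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
  rc <- covalent_radius(atoms$element)
  adj <- d < outer(rc, rc, "+") + slack & d > 1e-9
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    stack <- i
    while (length(stack) > 0) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[a] > 0) next
      comp[a] <- cur
      stack <- c(stack, which(adj[a, ] & comp == 0))
    }
  }
  lapply(seq_len(cur), function(cid) atoms[comp == cid, , drop = FALSE])
}

.toy_names <- c("p1_single", "pminus1_dimer", "p21c_small", "inversion_half",
                "screw_chain", "translation_stack", "zprime4")

.toy_structure <- function(name) {
  mk <- function(cell, xyz, sites, sg) {
    ops <- lapply(seq_along(xyz), function(i) parse_symop_xyz(xyz[i], i))
    structure(list(cell = cell, operations = ops, sites = sites,
                   space_group_name = sg, z_prime_hint = NA_integer_),
              class = "crystal_structure")
  }
  site_df <- function(label, element, frac) {
    data.frame(label = label, element = element,
               fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
               occupancy = 1, stringsAsFactors = FALSE)
  }
  # helper: local Cartesian atom block anchored at a fractional offset
  anchor <- function(cell, offset_frac, cart_local) {
    sweep(cart_to_frac(cell, cart_local), 2, offset_frac, "+")
  }
  switch(name,
    p1_single = {
      cell <- unit_cell(9, 9, 9)
      mk(cell, "x, y, z",
         site_df("C1", "C", matrix(c(0.1, 0.2, 0.3), 1)), "P 1")
    },
    pminus1_dimer = {
      # CO molecule close to the inversion centre at the origin: the
      # inversion dimer is a vdW contact pair, translation images are not
      cell <- unit_cell(9.5, 9.5, 9.5, 92, 94, 88)
      local <- matrix(c(0, 0, 0,
                        1.128, 0, 0), 2, 3, byrow = TRUE)
      frac <- anchor(cell, c(0.13, 0.10, 0.11), local)
      mk(cell, c("x, y, z", "-x, -y, -z"),
         site_df(c("C1", "O1"), c("C", "O"), frac), "P -1")
    },
    p21c_small = {
      cell <- unit_cell(9.6, 10.4, 11.2, 90, 93, 90)
      local <- matrix(c(0, 0, 0,        # C
                        1.22, 0, 0,     # O
                        -0.55, 0.94, 0, # H
                        -0.55, -0.94, 0), 4, 3, byrow = TRUE)
      frac <- anchor(cell, c(0.22, 0.16, 0.19), local)
      mk(cell, c("x, y, z", "-x, 1/2+y, 1/2-z", "-x, -y, -z", "x, 1/2-y, 1/2+z"),
         site_df(c("C1", "O1", "H1", "H2"), c("C", "O", "H", "H"), frac),
         "P 21/c")
    },
    inversion_half = {
      # CO2 with the carbon exactly on the inversion centre: the asymmetric
      # unit holds half the molecule and completion must drop the coincident
      # central atom
      cell <- unit_cell(9.4, 9.8, 10.2)
      frac <- rbind(c(0, 0, 0),
                    anchor(cell, c(0, 0, 0), matrix(c(1.16, 0, 0), 1)))
      mk(cell, c("x, y, z", "-x, -y, -z"),
         site_df(c("C1", "O1"), c("C", "O"), frac), "P -1")
    },
    screw_chain = {
      # rod-shaped HO-C-O molecule whose O-H points at the 2_1 screw image
      # of its acceptor oxygen: hydrogen-bond chain along b, period 2
      cell <- unit_cell(9.0, 8.6, 9.2)
      cart <- matrix(c(0.6, 0.0, 0.4,    # O acceptor
                       0.0, 0.74, 0.0,   # C linker
                       -0.6, 1.48, -0.4, # O donor
                       -0.6, 2.45, -0.4),# H on donor, pointing +b
                     4, 3, byrow = TRUE)
      # anchored on the screw axis (x = z = 0) so the screw image of the
      # acceptor sits 1.85 A beyond the donor hydrogen along +b
      frac <- anchor(cell, c(0.0, 0.05, 0.0), cart)
      mk(cell, c("x, y, z", "-x, 1/2+y, -z"),
         site_df(c("O1", "C1", "O2", "H1"), c("O", "C", "O", "H"), frac),
         "P 21")
    },
    translation_stack = {
      # 6-carbon rod spanning most of a: +-a translation images are in vdW
      # contact (stack along a), nothing else is
      cell <- unit_cell(9.0, 8.8, 9.4)
      xs <- 1.35 * (0:5)
      cart <- cbind(xs, rep(0, 6), rep(0, 6))
      frac <- anchor(cell, c(0.02, 0.3, 0.35), cart)
      mk(cell, "x, y, z",
         site_df(paste0("C", 1:6), rep("C", 6), frac), "P 1")
    },
    zprime4 = {
      # four independent CO molecules (Z' = 4) in P1
      cell <- unit_cell(9.3, 9.7, 10.1, 91, 89, 92)
      one <- function(off, dirv) {
        dirv <- dirv / sqrt(sum(dirv^2))
        anchor(cell, off, rbind(c(0, 0, 0), 1.128 * dirv))
      }
      frac <- rbind(one(c(0.10, 0.15, 0.10), c(1, 0, 0)),
                    one(c(0.60, 0.20, 0.35), c(0, 1, 0)),
                    one(c(0.25, 0.65, 0.60), c(0, 0, 1)),
                    one(c(0.70, 0.70, 0.85), c(1, 1, 0)))
      mk(cell, "x, y, z",
         site_df(paste0(rep(c("C", "O"), 4), rep(1:4, each = 2)),
                 rep(c("C", "O"), 4), frac), "P 1")
    },
    stop("unknown fixture name ", dQuote(name), "; available: ",
         paste(.toy_names, collapse = ", "))
  )
}

#' Generate a toy crystal fixture
#'
#' Seven named fixtures cover the symmetry situations exercised by the test
#' suite: `p1_single`, `pminus1_dimer`, `p21c_small`, `inversion_half`
#' (half-molecule on an inversion centre), `screw_chain` (2_1-screw
#' hydrogen-bond chain), `translation_stack` (vdW stack along a) and
#' `zprime4` (four independent residues). Cells are at least ~8.5 Angstrom in
#' every interplanar spacing so a +-3 supercell provably covers a 25 Angstrom
#' centroid scan. The ground-truth pair list is computed at generation time
#' by the independent brute-force oracle.
#'
#' @param name fixture name (see above).
#' @param cutoff centroid cutoff for the bundled ground-truth pair list.
#' @return list with `name`, `structure`, `cif` (text), `molecules`
#'   (completed), `ground_truth` (data.frame from [brute_force_pairs()]).
#' @export
make_toy_crystal <- function(name, cutoff = 15) {
  s <- .toy_structure(name)
  molecules <- complete_molecules(s)
  list(name = name, structure = s, cif = write_cif(s, name),
       molecules = molecules,
       ground_truth = brute_force_pairs(s, molecules, cutoff))
}

#' @rdname make_toy_crystal
#' @export
toy_crystal_names <- function() .toy_names

# ---------------------------------------------------------------------------
# Gaussian-blob cubes with analytic interaction energies
# ---------------------------------------------------------------------------

#' Build a synthetic Gaussian-blob electron-density cube
#'
#' The density is a sum of isotropic normalized Gaussians,
#' rho(r) = sum_k nelec_k N(r; center_k, sigma_k), sampled on a regular grid.
#' The grid must resolve the narrowest Gaussian with at least 6 voxels per
#' standard deviation.
#'
#' @param centers k x 3 matrix of blob centers (Angstrom).
#' @param sigmas standard deviations (Angstrom), length k.
#' @param nelec integrated electron count per blob, length k.
#' @param origin grid origin (Angstrom).
#' @param spacing voxel edge (Angstrom; cubic voxels).
#' @param counts integer 3-vector of grid points per axis.
#' @param nuclei optional data.frame (znum, q, x, y, z) of point nuclei.
#' @return list with `cube` (a `density_cube`) and `spec` (the blob
#'   parameters, for [gaussian_cloud_energy()]).
#' @export
make_gaussian_cube <- function(centers, sigmas, nelec, origin, spacing, counts,
                               nuclei = NULL) {
  centers <- matrix(centers, ncol = 3)
  k <- nrow(centers)
  stopifnot(length(sigmas) == k, length(nelec) == k)
  if (spacing > min(sigmas) / 6 + 1e-12) {
    stop(sprintf("under-resolved grid: spacing %.4f exceeds sigma/6 = %.4f",
                 spacing, min(sigmas) / 6))
  }
  counts <- as.integer(counts)
  gx <- origin[1] + (seq_len(counts[1]) - 1) * spacing
  gy <- origin[2] + (seq_len(counts[2]) - 1) * spacing
  gz <- origin[3] + (seq_len(counts[3]) - 1) * spacing
  values <- array(0, dim = counts)
  for (i in seq_len(k)) {
    s <- sigmas[i]
    norm1 <- 1 / (sqrt(2 * pi) * s)
    fx <- norm1 * exp(-(gx - centers[i, 1])^2 / (2 * s^2))
    fy <- norm1 * exp(-(gy - centers[i, 2])^2 / (2 * s^2))
    fz <- norm1 * exp(-(gz - centers[i, 3])^2 / (2 * s^2))
    values <- values + nelec[i] * (fx %o% fy %o% fz)
  }
  if (is.null(nuclei)) {
    nuclei <- data.frame(znum = integer(0), q = numeric(0),
                         x = numeric(0), y = numeric(0), z = numeric(0))
  }
  cube <- structure(list(
    origin = origin, axes = diag(3) * spacing, counts = counts,
    values = values, nuclei = nuclei,
    comments = c("pixkit synthetic Gaussian-blob density",
                 sprintf("total electron charge %.8f e", sum(nelec)))),
    class = "density_cube")
  list(cube = cube,
       spec = list(centers = centers, sigmas = sigmas, nelec = nelec,
                   nuclei = nuclei))
}

#' Closed-form Coulomb interaction of two Gaussian-blob clouds
#'
#' Each cloud is a set of isotropic Gaussian electron blobs (charge -nelec)
#' plus optional point nuclei. The interaction of two spherical Gaussian
#' charges is K q1 q2 erf(R / sqrt(2 (s1^2 + s2^2))) / R; a point charge is a
#' zero-width Gaussian.
#'
#' @param spec_a,spec_b blob specs as returned by [make_gaussian_cube()].
#' @param shift_b Cartesian displacement applied to cloud b (Angstrom).
#' @return energy in kJ/mol.
#' @export
gaussian_cloud_energy <- function(spec_a, spec_b, shift_b = c(0, 0, 0)) {
  expand <- function(sp) {
    q <- -sp$nelec
    pos <- matrix(sp$centers, ncol = 3)
    sg <- sp$sigmas
    if (!is.null(sp$nuclei) && nrow(sp$nuclei) > 0) {
      q <- c(q, sp$nuclei$q)
      pos <- rbind(pos, as.matrix(sp$nuclei[, c("x", "y", "z")]))
      sg <- c(sg, rep(0, nrow(sp$nuclei)))
    }
    list(q = q, pos = pos, sg = sg)
  }
  a <- expand(spec_a)
  b <- expand(spec_b)
  e <- 0
  for (i in seq_along(a$q)) {
    for (j in seq_along(b$q)) {
      dvec <- b$pos[j, ] + shift_b - a$pos[i, ]
      r <- sqrt(sum(dvec^2))
      seff2 <- a$sg[i]^2 + b$sg[j]^2
      if (r < 1e-12) stop("coincident charge centers in analytic energy")
      f <- if (seff2 < 1e-24) 1 else .erf(r / sqrt(2 * seff2))
      e <- e + a$q[i] * b$q[j] * f / r
    }
  }
  coulomb_constant() * e
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# ---------------------------------------------------------------------------
# Tripalmitin (capacity fixture)
# ---------------------------------------------------------------------------

# NeRF placement: position of atom D bonded to A (length dist), with angle
# D-A-B and dihedral D-A-B-C
.place_atom <- function(a, b, c_, dist, angle, dihedral) {
  deg <- pi / 180
  ab <- a - b
  ab <- ab / sqrt(sum(ab^2))
  cb <- b - c_
  n <- c(cb[2] * ab[3] - cb[3] * ab[2],
         cb[3] * ab[1] - cb[1] * ab[3],
         cb[1] * ab[2] - cb[2] * ab[1])
  if (sqrt(sum(n^2)) < 1e-9) stop("collinear reference atoms in NeRF placement")
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * ab[3] - n[3] * ab[2],
         n[3] * ab[1] - n[1] * ab[3],
         n[1] * ab[2] - n[2] * ab[1])
  th <- angle * deg
  ph <- dihedral * deg
  d_local <- dist * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  a + d_local[1] * ab + d_local[2] * m + d_local[3] * n
}

#' Build an idealized tripalmitin molecule
#'
#' Tripalmitin is the triglyceride of palmitic acid: a glycerol backbone
#' esterified with three C16 acyl chains, C51 H98 O6, 155 atoms, acyclic.
#' The geometry uses standard bond lengths and angles with extended (anti)
#' chains fanning out from the backbone; only topology and counts are
#' meaningful, not the conformation.
#'
#' @return a [molecule()] with 155 atoms and 154 inferred bonds.
#' @export
build_tripalmitin <- function() {
  atoms <- list()
  add <- function(element, pos, label) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      label = label, element = element, x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
    pos
  }
  # glycerol backbone zigzag in the xy-plane
  c1 <- add("C", c(0, 0, 0), "C1")
  c2 <- add("C", c(1.53, 0, 0), "C2")
  c3 <- add("C", .place_atom(c2, c1, c(0, 1, 0), 1.53, 112, 0), "C3")

  acyl <- function(o_pos, g_pos, ref_pos, tag) {
    # ester: O -> C(=O) -> alpha C -> 14 more chain carbons, all anti
    cc <- .place_atom(o_pos, g_pos, ref_pos, 1.36, 117, 180)
    add("C", cc, paste0("C", tag, "1"))
    oo <- .place_atom(cc, o_pos, g_pos, 1.20, 122, 0)
    add("O", oo, paste0("O", tag, "c"))
    prev2 <- o_pos; prev1 <- cc
    for (i in 2:16) {
      nxt <- .place_atom(prev1, prev2, if (i == 2) g_pos else prev3, 1.53, 113, 180)
      add("C", nxt, paste0("C", tag, i))
      if (i >= 2 && i <= 15) {
        # methylene hydrogens for C2..C15 (C16 gets a methyl below)
        h1 <- .place_atom(nxt, prev1, prev2, 1.095, 109.5, 60)
        h2 <- .place_atom(nxt, prev1, prev2, 1.095, 109.5, -60)
        if (i < 16) { add("H", h1, paste0("H", tag, i, "a")); add("H", h2, paste0("H", tag, i, "b")) }
      }
      prev3 <- prev2; prev2 <- prev1; prev1 <- nxt
    }
    # terminal methyl on C16
    for (k in 1:3) {
      h <- .place_atom(prev1, prev2, prev3, 1.095, 109.5, c(60, 180, -60)[k])
      add("H", h, paste0("H", tag, "16", letters[k]))
    }
  }

  # ester oxygens and backbone hydrogens
  o1 <- add("O", .place_atom(c1, c2, c3, 1.43, 109.5, 180), "O1")
  add("H", .place_atom(c1, c2, c3, 1.09, 109.5, 60), "H1a")
  add("H", .place_atom(c1, c2, c3, 1.09, 109.5, -60), "H1b")
  o2 <- add("O", .place_atom(c2, c1, c3, 1.43, 109.5, 120), "O2")
  add("H", .place_atom(c2, c1, c3, 1.09, 109.5, -120), "H2")
  o3 <- add("O", .place_atom(c3, c2, c1, 1.43, 109.5, 180), "O3")
  add("H", .place_atom(c3, c2, c1, 1.09, 109.5, 60), "H3a")
  add("H", .place_atom(c3, c2, c1, 1.09, 109.5, -60), "H3b")

  acyl(o1, c1, c2, "a")
  acyl(o2, c2, c1, "b")
  acyl(o3, c3, c2, "c")

  molecule(do.call(rbind, atoms))
}
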