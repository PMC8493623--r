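#' Generate the symmetry image of a molecule
#'
#' Applies operation `op_index` plus an integer cell translation to a
#' molecule's Cartesian atoms (via fractional coordinates). Bonds and labels
#' are carried over.
#'
#' @param structure a `crystal_structure`.
#' @param mol a [molecule()].
#' @param op_index 1-based operation number.
#' @param t integer cell translation 3-vector.
#' @return the transformed molecule.
#' @export
symmetry_image <- function(structure, mol, op_index, t = c(0L, 0L, 0L)) {
  op <- structure$operations[[op_index]]
  frac <- cart_to_frac(structure$cell, .atom_xyz(mol$atoms))
  frac2 <- apply_symop(op, frac, t)
  cart <- frac_to_cart(structure$cell, frac2)
  mol$atoms$x <- cart[, 1]
  mol$atoms$y <- cart[, 2]
  mol$atoms$z <- cart[, 3]
  mol
}

#' Exponential hydrogen-bond energy model
#'
#' E(d) = -A exp(-B d) for the H...acceptor distance d. The default constants
#' are calibrated so that E(1.7 A) = -30 and E(2.2 A) = -10 kJ/mol, an
#' order-of-magnitude anchor for moderate O-H...O bonds; they are
#' configuration, not a published parameterization.
#'
#' @param A prefactor in kJ/mol (> 0).
#' @param B decay constant in 1/Angstrom (> 0).
#' @param weak_threshold bonds with |E| below this (kJ/mol) trigger a
#'   weak-hydrogen-bond warning.
#' @return an object of class `hbond_model`.
#' @export
hbond_model <- function(A = 30 * exp(1.7 * log(3) / 0.5),
                        B = log(3) / 0.5,
                        weak_threshold = 10) {
  stopifnot(A > 0, B > 0, weak_threshold > 0)
  structure(list(A = A, B = B, weak_threshold = weak_threshold),
            class = "hbond_model")
}

#' @rdname hbond_model
#' @param d_HA H...acceptor distance in Angstrom.
#' @param model an `hbond_model`.
#' @return estimated energy in kJ/mol (negative, stabilizing).
#' @export
hbond_energy <- function(d_HA, model = hbond_model()) {
  stopifnot(all(d_HA > 0))
  -model$A * exp(-model$B * d_HA)
}

.hb_elements <- c("N", "O", "S", "F", "Cl")

.scan_hbonds_one_way <- function(don_mol, acc_mol, don_res, acc_res,
                                 model, angle_min, donors, acceptors) {
  atoms_d <- don_mol$atoms
  atoms_a <- acc_mol$atoms
  bonds <- don_mol$bonds
  out <- list()
  hs <- which(atoms_d$element == "H")
  acc_idx <- which(atoms_a$element %in% acceptors)
  if (length(hs) == 0 || length(acc_idx) == 0) return(out)
  r_h <- vdw_radius("H")
  for (h in hs) {
    rows <- which(bonds[, 1] == h | bonds[, 2] == h)
    if (length(rows) == 0) next
    d_at <- setdiff(as.integer(bonds[rows[1], ]), h)
    if (!(atoms_d$element[d_at] %in% donors)) next
    hp <- as.numeric(atoms_d[h, c("x", "y", "z")])
    dp <- as.numeric(atoms_d[d_at, c("x", "y", "z")])
    for (a in acc_idx) {
      ap <- as.numeric(atoms_a[a, c("x", "y", "z")])
      d_ha <- sqrt(sum((ap - hp)^2))
      if (d_ha >= r_h + vdw_radius(atoms_a$element[a])) next
      if (d_ha < 1e-6) next
      v1 <- dp - hp
      v2 <- ap - hp
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < angle_min) next
      out[[length(out) + 1L]] <- data.frame(
        donor = atoms_d$label[d_at], h = atoms_d$label[h],
        acceptor = atoms_a$label[a],
        donor_residue = don_res, acceptor_residue = acc_res,
        d_HA = d_ha, d_DA = sqrt(sum((ap - dp)^2)), angle_DHA = ang,
        energy = hbond_energy(d_ha, model), stringsAsFactors = FALSE)
    }
  }
  out
}

#' Detect intermolecular hydrogen bonds across a pair table
#'
#' A hydrogen bond is indicated when an H...acceptor distance lies inside the
#' sum of the van der Waals radii, the donor and acceptor elements are in the
#' allowed sets, and the D-H...A angle is at least `angle_min`. Both
#' directions of each pair row are scanned and each bond is tagged with the
#' row's ORTEP code, so a physical bond is listed under both of a pair's
#' mutually inverse rows (once per directed neighbor relation, like the pair
#' table itself).
#'
#' @param pairs a `pair_table` from [enumerate_pairs()].
#' @param molecules the completed (and H-normalized) molecules the table was
#'   built from.
#' @param model an [hbond_model()].
#' @param donors,acceptors allowed donor/acceptor element sets.
#' @param angle_min minimum D-H...A angle in degrees.
#' @return data.frame of hydrogen bonds (one row per bond) with a `pair_row`
#'   index and `code` column.
#' @export
detect_hbonds <- function(pairs, molecules, model = hbond_model(),
                          donors = .hb_elements, acceptors = .hb_elements,
                          angle_min = 120) {
  structure <- attr(pairs, "structure")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ref_mol <- molecules[[pairs$ref[i]]]
    nb_mol <- symmetry_image(structure, molecules[[pairs$neighbor[i]]],
                             pairs$op[i], c(pairs$tx[i], pairs$ty[i], pairs$tz[i]))
    found <- c(
      .scan_hbonds_one_way(ref_mol, nb_mol, pairs$ref[i], pairs$neighbor[i],
                           model, angle_min, donors, acceptors),
      .scan_hbonds_one_way(nb_mol, ref_mol, pairs$neighbor[i], pairs$ref[i],
                           model, angle_min, donors, acceptors)
    )
    if (length(found) > 0) {
      df <- do.call(rbind, found)
      df$pair_row <- i
      df$code <- pairs$code[i]
      out[[length(out) + 1L]] <- df
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(0), h = character(0),
                      acceptor = character(0), donor_residue = integer(0),
                      acceptor_residue = integer(0), d_HA = numeric(0),
                      d_DA = numeric(0), angle_DHA = numeric(0),
                      energy = numeric(0), pair_row = integer(0),
                      code = character(0)))
  }
  do.call(rbind, out)
}

#' Van der Waals contact fraction between two molecules
#'
#' The fraction of atoms of each molecule lying closer than the sum of the
#' van der Waals radii plus `margin` to any atom of the other molecule.
#' `margin = 0` recovers the strict vdW-overlap criterion.
#'
#' @param molA,molB [molecule()]s in a common Cartesian frame.
#' @param margin widening of the vdW criterion in Angstrom (default 1).
#' @return numeric vector `c(fraction_ref, fraction_neighbor)`, each in [0,1].
#' @export
contact_fraction <- function(molA, molB, margin = 1.0) {
  stopifnot(margin >= 0)
  xa <- .atom_xyz(molA$atoms)
  xb <- .atom_xyz(molB$atoms)
  ra <- vdw_radius(molA$atoms$element)
  rb <- vdw_radius(molB$atoms$element)
  d <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  gap <- d - outer(ra, rb, "+")
  inA <- apply(gap < margin, 1, any)
  inB <- apply(gap < margin, 2, any)
  c(fraction_ref = mean(inA), fraction_neighbor = mean(inB))
}

#' Contact fractions for every row of a pair table
#'
#' @param pairs a `pair_table`.
#' @param molecules completed molecules.
#' @param margin see [contact_fraction()].
#' @return data.frame with `pair_row`, `code`, `fraction_ref`,
#'   `fraction_neighbor`, `margin`.
#' @export
contact_fractions <- function(pairs, molecules, margin = 1.0) {
  structure <- attr(pairs, "structure")
  n <- nrow(pairs)
  fr <- numeric(n); fn <- numeric(n)
  for (i in seq_len(n)) {
    nb_mol <- symmetry_image(structure, molecules[[pairs$neighbor[i]]],
                             pairs$op[i], c(pairs$tx[i], pairs$ty[i], pairs$tz[i]))
    f <- contact_fraction(molecules[[pairs$ref[i]]], nb_mol, margin)
    fr[i] <- f[1]; fn[i] <- f[2]
  }
  data.frame(pair_row = seq_len(n), code = pairs$code,
             fraction_ref = fr, fraction_neighbor = fn, margin = margin,
             stringsAsFactors = FALSE)
}

.primitive_vector <- function(t) {
  t <- as.integer(round(t))
  g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), abs(t[t != 0]))
  v <- t %/% g
  # canonical sign: first nonzero component positive
  if (v[which(v != 0)[1]] < 0) v <- -v
  v
}

#' Detect 1D packing motifs (chains and stacks)
#'
#' Builds the quotient graph of molecules under symmetry, restricted to
#' hydrogen-bonded edges (chain motifs) or to edges whose contact fraction
#' reaches `stack_threshold` (stack motifs). A 1D motif is reported when a
#' closed walk composes to a pure lattice translation t != 0; the motif
#' direction is the primitive reduction of t and the period is the number of
#' molecules in the repeat.
#'
#' @param pairs a `pair_table`.
#' @param hbonds output of [detect_hbonds()].
#' @param contacts output of [contact_fractions()].
#' @param stack_threshold minimum contact fraction for a stack edge.
#' @param max_period longest closed walk considered.
#' @return data.frame with `kind`, `dx`, `dy`, `dz` (primitive direction),
#'   `period`, `codes` (participating ORTEP codes, "+"-joined).
#' @export
detect_1d_motifs <- function(pairs, hbonds, contacts,
                             stack_threshold = 0.30, max_period = 4) {
  structure <- attr(pairs, "structure")
  empty <- data.frame(kind = character(0), dx = integer(0), dy = integer(0),
                      dz = integer(0), period = integer(0), codes = character(0))
  if (nrow(pairs) == 0) return(empty)
  edge_sets <- list(
    "hydrogen-bond chain" = unique(hbonds$pair_row),
    "vdW contact stack" = contacts$pair_row[
      pmax(contacts$fraction_ref, contacts$fraction_neighbor) >= stack_threshold]
  )
  motifs <- list()
  for (kind in names(edge_sets)) {
    rows <- edge_sets[[kind]]
    if (length(rows) == 0) next
    edges <- pairs[rows, , drop = FALSE]
    found <- list()  # keyed by direction
    walk <- function(cur_res, g, depth, start, codes) {
      if (depth > max_period) return(invisible())
      for (e in seq_len(nrow(edges))) {
        if (edges$ref[e] != cur_res) next
        ge <- structure$operations[[edges$op[e]]]
        gshift <- c(edges$tx[e], edges$ty[e], edges$tz[e])
        gmap <- symop(ge$rotation %*% g$rotation,
                      as.numeric(ge$rotation %*% (g$translation + g$shift)) +
                        ge$translation + gshift, 0L)
        codes2 <- c(codes, edges$code[e])
        nxt <- edges$neighbor[e]
        if (nxt == start && all(abs(gmap$rotation - diag(3)) < 1e-8)) {
          tt <- gmap$translation + gmap$shift
          if (all(abs(tt - round(tt)) < 1e-8) && any(abs(round(tt)) > 0)) {
            dirv <- .primitive_vector(round(tt))
            key <- paste(dirv, collapse = ",")
            per <- depth
            if (is.null(found[[key]]) || found[[key]]$period > per) {
              found[[key]] <<- list(direction = dirv, period = per,
                                    codes = paste(codes2, collapse = "+"))
            }
          }
        }
        if (depth < max_period) walk(nxt, gmap, depth + 1L, start, codes2)
      }
    }
    for (start in unique(edges$ref)) {
      walk(start, symop(diag(3), c(0, 0, 0), 0L), 1L, start, character(0))
    }
    for (f in found) {
      motifs[[length(motifs) + 1L]] <- data.frame(
        kind = kind, dx = f$direction[1], dy = f$direction[2],
        dz = f$direction[3], period = f$period, codes = f$codes,
        stringsAsFactors = FALSE)
    }
  }
  if (length(motifs) == 0) return(empty)
  out <- do.call(rbind, motifs)
  rownames(out) <- NULL
  out
}

#' Assemble the driver list of important pairs
#'
#' The union of all hydrogen-bonded pair codes and all pair codes whose
#' contact fraction reaches `driver_threshold`, deduplicated and sorted by
#' descending estimated importance (strongest hydrogen bond first, then
#' contact fraction).
#'
#' @param pairs a `pair_table`.
#' @param hbonds output of [detect_hbonds()].
#' @param contacts output of [contact_fractions()].
#' @param driver_threshold minimum contact fraction for a contact-driven entry.
#' @return data.frame with `pair_row`, `code`, `reason`, `hb_energy`,
#'   `contact`.
#' @export
build_driver_list <- function(pairs, hbonds, contacts, driver_threshold = 0.20) {
  hb_rows <- unique(hbonds$pair_row)
  hb_best <- if (nrow(hbonds) > 0)
    tapply(hbonds$energy, hbonds$pair_row, min) else numeric(0)
  ct <- contacts[pmax(contacts$fraction_ref, contacts$fraction_neighbor) >=
                   driver_threshold, , drop = FALSE]
  rows <- sort(unique(c(hb_rows, ct$pair_row)))
  if (length(rows) == 0) {
    warning("no qualifying driver pairs (no hydrogen bonds, no contacts above threshold)")
    return(data.frame(pair_row = integer(0), code = character(0),
                      reason = character(0), hb_energy = numeric(0),
                      contact = numeric(0)))
  }
  cmax <- pmax(contacts$fraction_ref, contacts$fraction_neighbor)
  names(cmax) <- contacts$pair_row
  out <- data.frame(
    pair_row = rows,
    code = pairs$code[rows],
    reason = vapply(rows, function(r) {
      h <- r %in% hb_rows
      c_ <- r %in% ct$pair_row
      if (h && c_) "hbond+contact" else if (h) "hbond" else "contact"
    }, ""),
    hb_energy = vapply(rows, function(r)
      if (as.character(r) %in% names(hb_best)) hb_best[[as.character(r)]] else NA_real_,
      0),
    contact = cmax[as.character(rows)],
    stringsAsFactors = FALSE)
  ord <- order(ifelse(is.na(out$hb_energy), 0, out$hb_energy),
               -ifelse(is.na(out$contact), 0, out$contact))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Half-sum lattice-energy estimate
#'
#' Computes, for each reference residue, half the sum of the total pair
#' energies of all its neighbor images, and averages over residues. The table
#' must carry a `total` energy column (kJ/mol); grouped tables (see
#' [pair_multiplicities()]) may carry energies on representatives only, which
#' are then propagated within each group.
#'
#' @param pairs a `pair_table` with a `total` column.
#' @return energy in kJ/mol (0 with a warning for an empty table).
#' @export
lattice_energy_estimate <- function(pairs) {
  if (nrow(pairs) == 0) {
    warning("empty pair list; lattice-energy estimate is 0")
    return(0)
  }
  if (is.null(pairs$total)) stop("pair table has no 'total' energy column")
  tot <- pairs$total
  if (!is.null(pairs$group) && anyNA(tot)) {
    for (g in unique(pairs$group)) {
      idx <- which(pairs$group == g)
      have <- idx[!is.na(tot[idx])]
      if (length(have) > 0) tot[idx] <- tot[have[1]]
    }
  }
  if (anyNA(tot)) {
    bad <- which(is.na(tot))[1]
    stop(sprintf("pair %s (row %d) has no attached energy",
                 ifelse(is.na(pairs$code[bad]), "<uncoded>", pairs$code[bad]), bad))
  }
  per_res <- tapply(tot, pairs$ref, function(e) 0.5 * sum(e))
  mean(per_res)
}

#' Warnings for weak hydrogen bonds
#'
#' @param hbonds output of [detect_hbonds()].
#' @param model an [hbond_model()] supplying `weak_threshold`.
#' @return character vector of warning messages (empty if none).
#' @export
weak_hbond_warning <- function(hbonds, model = hbond_model()) {
  if (nrow(hbonds) == 0) return(character(0))
  weak <- abs(hbonds$energy) < model$weak_threshold
  sprintf("weak hydrogen bond %s-%s...%s (%.2f A, %.1f kJ/mol)",
          hbonds$donor[weak], hbonds$h[weak], hbonds$acceptor[weak],
          hbonds$d_HA[weak], hbonds$energy[weak])
}

#' Run the full indicative structure analysis
#'
#' Centroid pair scan, hydrogen-bond detection with exponential energy
#' estimates, van der Waals contact fractions, 1D motif detection, driver
#' list and (when pair energies are supplied) a half-sum lattice-energy
#' estimate.
#'
#' @param structure a `crystal_structure`.
#' @param molecules completed molecules; computed with [complete_molecules()]
#'   and [normalize_h()] when `NULL`.
#' @param cutoff centroid scan limit in Angstrom.
#' @param model an [hbond_model()].
#' @param margin contact-fraction margin in Angstrom.
#' @param stack_threshold,driver_threshold motif / driver contact thresholds.
#' @param energies optional numeric vector of total pair energies (kJ/mol),
#'   one per pair-table row, enabling the lattice-energy estimate.
#' @return an `indicative_report` list: `pairs`, `hbonds`, `contacts`,
#'   `motifs`, `drivers`, `warnings`, `lattice_energy_estimate` (NA unless
#'   energies supplied).
#' @export
indicative_analysis <- function(structure, molecules = NULL, cutoff = 20,
                                model = hbond_model(), margin = 1.0,
                                stack_threshold = 0.30, driver_threshold = 0.20,
                                energies = NULL) {
  if (is.null(molecules)) {
    molecules <- complete_molecules(structure)
    molecules <- lapply(molecules, function(m)
      if (any(m$atoms$element == "H")) normalize_h(m) else m)
  }
  pairs <- enumerate_pairs(structure, molecules, cutoff)
  pairs <- pair_multiplicities(pairs)
  hbonds <- detect_hbonds(pairs, molecules, model)
  contacts <- contact_fractions(pairs, molecules, margin)
  motifs <- detect_1d_motifs(pairs, hbonds, contacts, stack_threshold)
  drivers <- withCallingHandlers(
    build_driver_list(pairs, hbonds, contacts, driver_threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  warnings <- weak_hbond_warning(hbonds, model)
  if (nrow(drivers) == 0) {
    warnings <- c(warnings, "no qualifying driver pairs found")
  }
  est <- NA_real_
  if (!is.null(energies)) {
    if (length(energies) != nrow(pairs)) {
      stop("energies must have one value per pair-table row")
    }
    pairs$total <- energies
    est <- lattice_energy_estimate(pairs)
  }
  structure2 <- list(pairs = pairs, hbonds = hbonds, contacts = contacts,
                     motifs = motifs, drivers = drivers, warnings = warnings,
                     lattice_energy_estimate = est)
  class(structure2) <- "indicative_report"
  structure2
}

#' @export
print.indicative_report <- function(x, ...) {
  cat("Indicative structure analysis\n")
  cat(sprintf("  %d pairs in centroid scan\n", nrow(x$pairs)))
  if (nrow(x$hbonds) > 0) {
    cat("  strongest hydrogen bonds:\n")
    hb <- x$hbonds[order(x$hbonds$energy), ]
    for (i in seq_len(min(5, nrow(hb)))) {
      cat(sprintf("    %s-%s...%s  %.3f A  %.1f kJ/mol  code %s\n",
                  hb$donor[i], hb$h[i], hb$acceptor[i], hb$d_HA[i],
                  hb$energy[i], hb$code[i]))
    }
  } else cat("  no hydrogen bonds detected\n")
  if (nrow(x$contacts) > 0) {
    ct <- x$contacts[order(-pmax(x$contacts$fraction_ref, x$contacts$fraction_neighbor)), ]
    cat("  highest vdW contact fractions:\n")
    for (i in seq_len(min(5, nrow(ct)))) {
      cat(sprintf("    code %s  %.2f / %.2f\n", ct$code[i],
                  ct$fraction_ref[i], ct$fraction_neighbor[i]))
    }
  }
  if (nrow(x$motifs) > 0) {
    for (i in seq_len(nrow(x$motifs))) {
      cat(sprintf("  1D motif: %s along (%d %d %d), period %d\n",
                  x$motifs$kind[i], x$motifs$dx[i], x$motifs$dy[i],
                  x$motifs$dz[i], x$motifs$period[i]))
    }
  } else cat("  no 1D motifs detected\n")
  for (w in x$warnings) cat("  WARNING:", w, "\n")
  if (!is.na(x$lattice_energy_estimate)) {
    cat(sprintf("  lattice-energy estimate: %.1f kJ/mol\n", x$lattice_energy_estimate))
  }
  invisible(x)
}
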