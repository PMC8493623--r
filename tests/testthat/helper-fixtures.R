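# shared test helpers: tiny CIF builders and independent oracles

# minimal CIF text with given cell, xyz strings and atom rows
mini_cif <- function(cell = c(9, 9, 9, 90, 90, 90),
                     xyz = "x, y, z",
                     atoms = "C1 C 0.0 0.0 0.0",
                     sg = "P 1",
                     sym_tag = "_symmetry_equiv_pos_as_xyz") {
  paste(c(
    "data_mini",
    sprintf("_symmetry_space_group_name_H-M '%s'", sg),
    sprintf("_cell_length_a %s", cell[1]),
    sprintf("_cell_length_b %s", cell[2]),
    sprintf("_cell_length_c %s", cell[3]),
    sprintf("_cell_angle_alpha %s", cell[4]),
    sprintf("_cell_angle_beta %s", cell[5]),
    sprintf("_cell_angle_gamma %s", cell[6]),
    "loop_",
    sym_tag,
    sprintf("'%s'", xyz),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    atoms,
    ""), collapse = "\n")
}

# canonical sort key for comparing pair enumerations
pair_key <- function(d) sort(paste(d$ref, d$neighbor, d$op, d$tx, d$ty, d$tz))

expect_same_pairs <- function(a, b, tol = 1e-8) {
  expect_identical(pair_key(a), pair_key(b))
  expect_lt(max(c(0, abs(sort(a$distance) - sort(b$distance)))), tol)
}

# independent all-pairs contact-fraction oracle (plain double loop)
oracle_contact_fraction <- function(molA, molB, margin) {
  nA <- nrow(molA$atoms); nB <- nrow(molB$atoms)
  hitA <- logical(nA); hitB <- logical(nB)
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      d <- sqrt(sum((as.numeric(molA$atoms[i, c("x", "y", "z")]) -
                     as.numeric(molB$atoms[j, c("x", "y", "z")]))^2))
      thr <- vdw_radius(molA$atoms$element[i]) + vdw_radius(molB$atoms$element[j]) + margin
      if (d < thr) { hitA[i] <- TRUE; hitB[j] <- TRUE }
    }
  }
  c(mean(hitA), mean(hitB))
}

# independent donor-H/acceptor triple scan for hydrogen bonds between two
# placed molecules (returns count)
oracle_hbond_count <- function(don_mol, acc_mol, angle_min = 120,
                               els = c("N", "O", "S", "F", "Cl")) {
  n <- 0L
  at_d <- don_mol$atoms; at_a <- acc_mol$atoms
  for (h in which(at_d$element == "H")) {
    rows <- which(don_mol$bonds[, 1] == h | don_mol$bonds[, 2] == h)
    if (length(rows) == 0) next
    dd <- setdiff(as.integer(don_mol$bonds[rows[1], ]), h)
    if (!(at_d$element[dd] %in% els)) next
    hp <- as.numeric(at_d[h, c("x", "y", "z")])
    dp <- as.numeric(at_d[dd, c("x", "y", "z")])
    for (a in which(at_a$element %in% els)) {
      ap <- as.numeric(at_a[a, c("x", "y", "z")])
      dha <- sqrt(sum((ap - hp)^2))
      if (dha >= vdw_radius("H") + vdw_radius(at_a$element[a])) next
      v1 <- dp - hp; v2 <- ap - hp
      cosang <- max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))
      ang <- acos(cosang) * 180 / pi
      if (ang >= angle_min) n <- n + 1L
    }
  }
  n
}
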