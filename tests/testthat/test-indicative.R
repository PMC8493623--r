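test_that("hydrogen-bond energy model is anchored, monotone and sign-definite", {
  m <- hbond_model()
  # anchors: E(1.7) = -30, E(2.2) = -10 => B = ln(3)/0.5, A = 30 exp(1.7 B)
  expect_equal(m$B, log(3) / 0.5, tolerance = 1e-12)
  expect_equal(hbond_energy(1.7, m), -30, tolerance = 1e-9)
  expect_equal(hbond_energy(2.2, m), -10, tolerance = 1e-9)
  expect_true(hbond_energy(1.7, m) < hbond_energy(2.0, m))
  expect_true(hbond_energy(2.0, m) < hbond_energy(2.5, m))
  expect_true(hbond_energy(2.5, m) < 0)
  expect_equal(hbond_energy(1e6, m), 0, tolerance = 1e-12)
})

test_that("hydrogen-bond detection matches a brute-force triple scan with decoys", {
  # two hand-built molecules in a big P1 cell: three planted bonds plus
  # donor-element, distance, angle and acceptor-element decoys
  cell <- unit_cell(40, 40, 40)
  don <- data.frame(
    label = c("O1", "H1", "N1", "H2", "C1", "H3", "O2", "H4", "O3", "H5",
              "O4", "H6", "O5", "H7"),
    element = c("O", "H", "N", "H", "C", "H", "O", "H", "O", "H", "O", "H",
                "O", "H"),
    x = c(0, 0.97,  0, 1.00,  0, 1.09,  0, 0.97,  0, 0.97,  0, 0.97,
          0, 0.97),
    y = c(0, 0,     3, 3,     6, 6,     9, 9,    12, 12,   15, 15,
          18, 18),
    z = 0)
  don_bonds <- cbind(seq(1, 13, 2), seq(2, 14, 2))
  acc <- data.frame(
    label = paste0("B", 1:7),
    element = c("O",   "O",    "O",    "O",    "O",     "C",   "O"),
    x =       c(2.77,  2.60,   2.99,   3.87,   0.97,    2.77,  2.87),
    y =       c(0,     3.45,   6,      9,      13.5,    15,    18),
    z = 0)
  don_mol <- molecule(don, bonds = don_bonds, residue_id = 1L)
  acc_mol <- molecule(acc, bonds = matrix(integer(0), ncol = 2), residue_id = 2L)
  s <- structure(list(cell = cell,
                      operations = list(parse_symop_xyz("x, y, z", 1)),
                      sites = data.frame(label = "X", element = "C",
                                         fx = 0, fy = 0, fz = 0, occupancy = 1),
                      space_group_name = "P 1", z_prime_hint = 2L),
                 class = "crystal_structure")
  pairs <- enumerate_pairs(s, list(don_mol, acc_mol), 15)
  hb <- detect_hbonds(pairs, list(don_mol, acc_mol))
  # a physical bond is tagged once per directed pair row; restrict to the
  # 1 -> 2 row for comparison against the single-pair oracle scan
  direct <- hb[hb$pair_row == which(pairs$ref == 1 & pairs$neighbor == 2), ]
  # oracle: independent geometric triple scan of the placed molecules
  expect_equal(nrow(direct), oracle_hbond_count(don_mol, acc_mol))
  # exactly the three planted bonds: O1-H1...B1, N1-H2...B2, O5-H7...B7;
  # nothing from the C-H donor (C1), the 2.9 A distance decoy (O2), the
  # 90-degree angle decoy (O3) or the carbon acceptor decoy (O4)
  expect_equal(nrow(direct), 3)
  expect_setequal(direct$donor, c("O1", "N1", "O5"))
  expect_false("C1" %in% direct$donor)
  expect_false("O2" %in% direct$donor)
  expect_false("O3" %in% direct$donor)
  expect_false("O4" %in% direct$donor)
  expect_true(all(direct$d_HA < direct$d_DA))
  expect_true(all(direct$energy < 0))
})

test_that("contact fractions match the all-pairs oracle and are monotone in margin", {
  a <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
  b <- molecule(data.frame(element = "C", x = 2, y = 0, z = 0))
  expect_equal(unname(contact_fraction(a, b)), c(1, 1))
  b10 <- molecule(data.frame(element = "C", x = 10, y = 0, z = 0))
  expect_equal(unname(contact_fraction(a, b10)), c(0, 0))

  set.seed(5)
  mk <- function(n, off) molecule(data.frame(
    element = sample(c("C", "O", "N", "H"), n, replace = TRUE),
    x = runif(n, 0, 6) + off, y = runif(n, 0, 6), z = runif(n, 0, 6)),
    bonds = matrix(integer(0), ncol = 2))
  ma <- mk(20, 0); mb <- mk(20, 6)
  for (margin in c(0, 0.5, 1, 2)) {
    expect_equal(unname(contact_fraction(ma, mb, margin)),
                 oracle_contact_fraction(ma, mb, margin))
  }
  f <- vapply(c(0, 0.5, 1, 2, 4), function(m) contact_fraction(ma, mb, m)[1], 0)
  expect_true(!is.unsorted(f))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("1D motifs: translation stack, inversion dimer, screw chain", {
  st <- indicative_analysis(make_toy_crystal("translation_stack", cutoff = 5)$structure)
  stacks <- st$motifs[st$motifs$kind == "vdW contact stack", ]
  expect_equal(nrow(stacks), 1)
  expect_equal(unlist(stacks[1, c("dx", "dy", "dz")], use.names = FALSE), c(1, 0, 0))
  expect_equal(stacks$period, 1)

  dim_ <- indicative_analysis(make_toy_crystal("pminus1_dimer", cutoff = 5)$structure)
  expect_equal(nrow(dim_$motifs), 0)
  # ...even though the inversion dimer itself is a strong contact
  expect_gte(max(pmax(dim_$contacts$fraction_ref, dim_$contacts$fraction_neighbor)), 0.3)

  sc <- indicative_analysis(make_toy_crystal("screw_chain", cutoff = 5)$structure)
  chains <- sc$motifs[sc$motifs$kind == "hydrogen-bond chain", ]
  expect_equal(nrow(chains), 1)
  expect_equal(unlist(chains[1, c("dx", "dy", "dz")], use.names = FALSE), c(0, 1, 0))
  expect_equal(chains$period, 2)
})

test_that("the screw chain percolates through an explicit 5-cell walk", {
  # compose the screw operation five times from the fixture's own generators
  fx <- make_toy_crystal("screw_chain", cutoff = 5)
  s <- fx$structure
  mol <- fx$molecules[[1]]
  mol <- normalize_h(mol)
  imgs <- list(mol)
  g <- symop(diag(3), c(0, 0, 0))
  for (k in 1:5) {
    g <- pixkit:::compose_symops(s$operations[[2]], g)
    img <- mol
    frac2 <- apply_symop(g, cart_to_frac(s$cell, pixkit:::.atom_xyz(mol$atoms)),
                         shift = g$shift)
    cart <- frac_to_cart(s$cell, frac2)
    img$atoms[, c("x", "y", "z")] <- cart
    imgs[[k + 1]] <- img
  }
  # consecutive images must be hydrogen-bond linked (H...O inside vdW sum)
  for (k in 1:5) {
    n_fwd <- oracle_hbond_count(imgs[[k]], imgs[[k + 1]])
    n_bwd <- oracle_hbond_count(imgs[[k + 1]], imgs[[k]])
    expect_gte(n_fwd + n_bwd, 1)
  }
  # net translation after two steps is one cell along b
  g2 <- pixkit:::compose_symops(s$operations[[2]], s$operations[[2]])
  expect_equal(g2$rotation, diag(3), ignore_attr = TRUE)
  expect_equal(g2$translation + g2$shift, c(0, 1, 0))
})

test_that("driver lists take the union of H-bond and contact pairs, ranked", {
  pairs <- data.frame(ref = 1, neighbor = 1, op = 1,
                      tx = c(1, -1, 0, 0), ty = c(0, 0, 1, -1), tz = 0,
                      code = c("65501", "45501", "56501", "54501"),
                      distance = c(5, 5, 7, 7))
  hb <- data.frame(pair_row = c(1L, 3L), energy = c(-25, -12))
  contacts <- data.frame(pair_row = 1:4, code = pairs$code,
                         fraction_ref = c(0.4, 0.1, 0.25, 0.1),
                         fraction_neighbor = c(0.35, 0.1, 0.2, 0.05))
  dl <- build_driver_list(pairs, hb, contacts, driver_threshold = 0.20)
  # union: rows 1 (hbond+contact), 3 (hbond+contact), and none else above 0.2
  expect_equal(dl$pair_row, c(1L, 3L))
  expect_equal(dl$reason, c("hbond+contact", "hbond+contact"))
  # hand-ranked: strongest H-bond first
  expect_equal(dl$hb_energy, c(-25, -12))

  # mixed fixture: 2 hbond rows + 2 contact rows, one overlapping -> 3 entries
  hb2 <- data.frame(pair_row = c(1L, 2L), energy = c(-25, -18))
  contacts2 <- contacts
  contacts2$fraction_ref <- c(0.4, 0.1, 0.3, 0.05)
  dl2 <- build_driver_list(pairs, hb2, contacts2)
  expect_equal(nrow(dl2), 3)
  expect_equal(dl2$pair_row, c(1L, 2L, 3L))

  expect_warning(
    dl0 <- build_driver_list(pairs, hb[0, ], contacts[0, ]),
    "no qualifying")
  expect_equal(nrow(dl0), 0)
})

test_that("half-sum lattice-energy estimate and its invariances", {
  six <- data.frame(ref = 1, total = rep(-10, 6))
  expect_equal(lattice_energy_estimate(six), -30)
  expect_warning(e0 <- lattice_energy_estimate(six[0, ]), "empty")
  expect_equal(e0, 0)
  # two residues with asymmetric pair lists: hand-computed per-residue
  # half-sums (-15 and -15) average to -15
  two <- data.frame(ref = c(1, 1, 2), total = c(-10, -20, -30))
  expect_equal(lattice_energy_estimate(two), -15)
  # missing energy names the pair
  bad <- data.frame(ref = 1, total = c(-10, NA), code = c("65501", "45501"))
  expect_error(lattice_energy_estimate(bad), "45501")
  # invariant under inverse-twin relabeling (row order permutation)
  fx <- make_toy_crystal("p21c_small", cutoff = 5)
  tab <- pair_multiplicities(enumerate_pairs(fx$structure, fx$molecules, 12))
  tab$total <- -100 * exp(-tab$distance / 4)  # symmetric in the distance
  e1 <- lattice_energy_estimate(tab)
  perm <- sample(nrow(tab))
  e2 <- lattice_energy_estimate(tab[perm, ])
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("weak hydrogen bonds are warned about below the threshold, strictly", {
  m <- hbond_model(weak_threshold = 10)
  hb <- data.frame(donor = c("O1", "O2", "O3"), h = c("H1", "H2", "H3"),
                   acceptor = c("O9", "O9", "O9"),
                   d_HA = c(2.5, 1.7, 2.0), energy = c(-5, -30, -10))
  w <- weak_hbond_warning(hb, m)
  expect_length(w, 1)
  expect_match(w, "O1-H1")
  expect_length(weak_hbond_warning(hb[0, ], m), 0)
})

test_that("indicative_analysis assembles a full report with an estimate", {
  fx <- make_toy_crystal("screw_chain", cutoff = 5)
  mols <- lapply(complete_molecules(fx$structure), normalize_h)
  pairs <- enumerate_pairs(fx$structure, mols, 20)
  rep_ <- indicative_analysis(fx$structure, molecules = mols, cutoff = 20,
                              energies = -50 * exp(-pairs$distance / 5))
  expect_s3_class(rep_, "indicative_report")
  expect_gt(nrow(rep_$hbonds), 0)
  expect_gt(nrow(rep_$drivers), 0)
  expect_lt(rep_$lattice_energy_estimate, 0)
  out <- capture.output(print(rep_))
  expect_true(any(grepl("hydrogen-bond chain", out)))
})
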