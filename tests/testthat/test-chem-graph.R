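# SMILES parsing, featurization and the three adjacency maps.

test_that("small molecules produce the expected graph topology", {
  g <- smiles_to_graph("C")
  expect_equal(g$n_atoms, 1L)
  expect_equal(g$n_bonds, 0L)
  expect_length(g$atom_neighbors[[1]], 0L)

  g <- smiles_to_graph("CC")
  expect_equal(g$n_atoms, 2L)
  expect_equal(g$n_bonds, 1L)
  expect_length(g$bond_neighbors[[1]], 0L)

  # cyclopropane: the triangle graph, enumerated by hand
  g <- smiles_to_graph("C1CC1")
  expect_equal(g$n_atoms, 3L)
  expect_equal(g$n_bonds, 3L)
  for (e in 1:3) {
    expect_setequal(g$bond_neighbors[[e]], setdiff(1:3, e))
  }
  for (v in 1:3) {
    expect_length(g$incident_bonds[[v]], 2L)
    expect_setequal(g$atom_neighbors[[v]], setdiff(1:3, v))
  }
})

test_that("atom features carry aromaticity, element and hydrogen information", {
  n_el <- length(dtakit:::ELEMENTS)
  arom_bit <- function(g, v) g$atom_features[v, atom_feature_dim()]
  g <- smiles_to_graph("C")
  expect_equal(arom_bit(g, 1), 0)
  expect_equal(g$atom_features[1, 1], 1)   # carbon slot
  g <- smiles_to_graph("c1ccccc1")
  expect_equal(unname(sapply(1:6, function(v) arom_bit(g, v))), rep(1, 6))
  # methane carries 4 implicit hydrogens; benzene carbons carry 1
  h_block <- n_el + length(dtakit:::DEGREES) + length(dtakit:::CHARGES) + 1L
  gm <- smiles_to_graph("C")
  expect_equal(unname(which(gm$atom_features[1, h_block + 1:5] == 1)), 5L)
  expect_equal(unname(which(g$atom_features[1, h_block + 1:5] == 1)), 2L)
  # unsupported element lands in the reserved "other" slot
  gs <- smiles_to_graph("[SiH3]C")
  si <- which(gs$elements == "Si")
  expect_equal(unname(gs$atom_features[si, n_el]), 1)
})

test_that("bond features encode order, ring membership and conjugation", {
  feat <- function(s, b = 1) smiles_to_graph(s)$bond_features[b, ]
  single <- feat("CC")
  expect_equal(unname(single[1:4]), c(1, 0, 0, 0))
  expect_equal(unname(single[6]), 0)            # no ring
  dbl <- feat("C=C")
  expect_equal(unname(dbl[1:4]), c(0, 1, 0, 0))
  expect_equal(unname(feat("C#C")[1:4]), c(0, 0, 1, 0))
  ring <- smiles_to_graph("C1CC1")$bond_features
  expect_equal(unname(ring[, 6]), rep(1, 3))    # all ring bonds
  arom <- smiles_to_graph("c1ccccc1")$bond_features
  expect_equal(unname(arom[, 4]), rep(1, 6))    # aromatic slot
})

test_that("every feature row is binary with one-hot blocks summing to one", {
  spec <- synthetic_spec(n_pairs = 25, mol_atom_range = c(2, 9), seed = 42)
  n_el <- length(dtakit:::ELEMENTS)
  blocks <- list(
    seq_len(n_el),
    n_el + seq_along(dtakit:::DEGREES),
    n_el + length(dtakit:::DEGREES) + seq_len(length(dtakit:::CHARGES) + 1L),
    n_el + length(dtakit:::DEGREES) + length(dtakit:::CHARGES) + 1L +
      seq_along(dtakit:::NUM_HS),
    n_el + length(dtakit:::DEGREES) + length(dtakit:::CHARGES) + 1L +
      length(dtakit:::NUM_HS) + seq_along(dtakit:::HYBRIDIZATIONS)
  )
  for (s in gen_molecules(spec)) {
    g <- smiles_to_graph(s)
    expect_true(all(g$atom_features %in% c(0, 1)))
    expect_true(all(g$bond_features %in% c(0, 1)))
    for (bl in blocks) {
      expect_equal(unname(rowSums(g$atom_features[, bl, drop = FALSE])),
                   rep(1, g$n_atoms))
    }
    if (g$n_bonds > 0) {
      expect_equal(unname(rowSums(g$bond_features[, 1:4, drop = FALSE])),
                   rep(1, g$n_bonds))
    }
  }
})

test_that("adjacency maps satisfy the structural invariants", {
  spec <- synthetic_spec(n_pairs = 25, mol_atom_range = c(2, 10), seed = 43)
  for (s in gen_molecules(spec)) {
    g <- smiles_to_graph(s)
    for (v in seq_len(g$n_atoms)) {
      # symmetry and degree consistency
      for (u in g$atom_neighbors[[v]]) {
        expect_true(v %in% g$atom_neighbors[[u]])
      }
      expect_equal(length(g$incident_bonds[[v]]),
                   length(g$atom_neighbors[[v]]))
      for (b in g$incident_bonds[[v]]) {
        expect_true(v %in% g$endpoints[b, ])
      }
    }
    for (b in seq_len(g$n_bonds)) {
      expect_false(b %in% g$bond_neighbors[[b]])
      for (nb in g$bond_neighbors[[b]]) {
        expect_length(intersect(g$endpoints[b, ], g$endpoints[nb, ]), 1L)
      }
    }
  }
})

test_that("parsing is deterministic and spelling-independent", {
  g1 <- smiles_to_graph("c1ccccc1O")
  g2 <- smiles_to_graph("c1ccccc1O")
  expect_identical(g1, g2)
  # alternative spellings of the same molecules give identical graphs
  spellings <- random_spellings(fixture_smiles, n_per = 2L, seed = 3L)
  for (k in seq_along(fixture_smiles)) {
    ref <- smiles_to_graph(fixture_smiles[k])
    for (sp in spellings[[k]]) {
      alt <- smiles_to_graph(sp)
      expect_identical(alt, ref)
    }
  }
})

test_that("invalid input raises typed errors", {
  expect_error(smiles_to_graph("not-a-smiles(("),
               class = "dtakit_error_parse")
  expect_error(smiles_to_graph(""), class = "dtakit_error_input")
  expect_error(smiles_to_graph(c("C", "CC")), class = "dtakit_error_input")
})

test_that("the batch SMILES reader keeps going past bad lines", {
  f <- tempfile()
  writeLines(c("CCO", "", "qq((", "c1ccccc1"), f)
  out <- read_smiles_file(f)
  expect_equal(nrow(out), 3L)            # blank line skipped
  expect_equal(out$ok, c(TRUE, FALSE, TRUE))
  expect_equal(out$graph[[3]]$n_atoms, 6L)
})
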