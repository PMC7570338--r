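test_that("molfile parsing recovers counts, atoms, bonds and charges", {
  fx <- make_named_fixture("benzene_kekuleA")
  g <- parse_molfile(fx$molfile)
  expect_equal(nrow(g$atoms), 6)
  expect_equal(nrow(g$bonds), 6)
  expect_true(all(g$atoms$charge == 0))
  expect_setequal(g$bonds$order, c(1L, 2L))
})

test_that("M CHG property lines override the atom-block charge column", {
  lines <- c("chg_test", "", "",
             "  6  5  0  0  0  0  0  0  0  0999 V2000")
  atom <- "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0"
  lines <- c(lines, rep(atom, 6),
             sprintf("%3d%3d  1  0  0  0  0", 1:5, 2:6),
             "M  CHG  1   4  -1",
             "M  END")
  g <- parse_molfile(lines)
  expect_equal(g$atoms$charge[4], -1L)   # internal index 3
  expect_true(all(g$atoms$charge[-4] == 0L))
})

test_that("malformed molfiles produce informative parse errors", {
  fx <- make_named_fixture("benzene_kekuleA")
  lines <- strsplit(fx$molfile, "\n")[[1]]
  bad_bond <- lines
  bad_bond[11] <- "  1  9  1  0  0  0  0"   # atom 9 of 6
  expect_error(parse_molfile(bad_bond), "nonexistent atom")
  bad_counts <- lines
  bad_counts[4] <- "  x  y  0  0  0  0  0  0  0  0999 V2000"
  expect_error(parse_molfile(bad_counts), "counts line")
  v3 <- lines
  v3[4] <- sub("V2000", "V3000", v3[4])
  expect_error(parse_molfile(v3), "V3000")
  expect_error(parse_molfile(lines[1:7]), "truncated")
})

test_that("JSON round trip reproduces every fixture field for field", {
  for (nm in fixture_names()) {
    g <- make_named_fixture(nm)$graph
    g2 <- mol_from_json(mol_to_json(g))
    expect_true(mol_graph_equal(g, g2), label = paste("json round trip", nm))
  }
  expect_equal(n_atoms(mol_from_json('{"atoms": [], "bonds": []}')), 0)
  expect_error(mol_from_json('{"atoms": []}'), "bonds")
})

test_that("molfile round trip reproduces every fixture graph", {
  for (nm in fixture_names()) {
    g <- parse_molfile(make_named_fixture(nm)$molfile)
    g2 <- parse_molfile(write_molfile(g))
    expect_true(mol_graph_equal(g, g2), label = paste("molfile round trip", nm))
    g3 <- parse_molfile(write_molfile(g2))
    expect_true(mol_graph_equal(g2, g3))
  }
})

test_that("implicit hydrogen counts follow charge-adjusted default valences", {
  methane <- hgraph("C", NULL)
  expect_equal(sum(add_implicit_hydrogens(methane)$atoms$element == "H"), 4)
  benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  bh <- add_implicit_hydrogens(benzene)
  expect_equal(sum(bh$atoms$element == "H"), 6)
  hydroxide <- hgraph("O", NULL, charges = -1L)
  expect_equal(sum(add_implicit_hydrogens(hydroxide)$atoms$element == "H"), 1)
  ammonium <- hgraph("N", NULL, charges = 1L)
  expect_equal(sum(add_implicit_hydrogens(ammonium)$atoms$element == "H"), 4)
  expect_error(add_implicit_hydrogens(hgraph("Zz", NULL)), "Zz")
})

test_that("hydrogen addition preserves heavy-atom indices and is idempotent", {
  g <- make_named_fixture("glycerol")$graph
  gh <- add_implicit_hydrogens(g)
  expect_identical(gh$atoms$element[1:6], g$atoms$element)
  expect_identical(gh$atoms$index[1:6], g$atoms$index)
  expect_true(all(gh$atoms$element[-(1:6)] == "H"))
  expect_true(mol_graph_equal(add_implicit_hydrogens(gh), gh))
})

test_that("graph invariants are enforced and components split correctly", {
  expect_error(hgraph(c("C", "C"), list(c(0, 0, 1))), "self bonds")
  expect_error(hgraph(c("C", "C"), list(c(0, 1, 1), c(1, 0, 2))), "duplicate")
  salt <- hgraph(c("C", "C", "O"), list(c(0, 1, 1)))
  comps <- graph_components(salt)
  expect_equal(comps, list(c(0L, 1L), 2L))
})
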