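biphenyl <- function() {
  bonds <- c(
    lapply(1:6, function(k) c(k - 1L, k %% 6L, c(2, 1, 2, 1, 2, 1)[k])),
    lapply(1:6, function(k) c(6L + k - 1L, 6L + k %% 6L, c(2, 1, 2, 1, 2, 1)[k])),
    list(c(3L, 6L, 1L))
  )
  hgraph(rep("C", 12), bonds, source_id = "biphenyl")
}

test_that("labeled extraction fuses ring systems and splits linked rings", {
  naph <- make_named_fixture("naphthaleneA")$graph
  frags <- extract_labeled_substructures(naph, 0:9)
  expect_length(frags, 1)
  expect_identical(frags[[1]]$atom_indices, 0:9)

  bp <- biphenyl()
  frags <- extract_labeled_substructures(bp, 0:11)
  expect_length(frags, 2)
  expect_equal(sort(lengths(lapply(frags, `[[`, "atom_indices"))), c(6L, 6L))

  expect_identical(extract_labeled_substructures(naph, integer(0)), list())
})

test_that("reference detection matches rings through Kekule variation", {
  lib <- default_aromatic_library()
  tol <- make_named_fixture("toluene")$graph
  frags <- detect_by_reference(tol, lib)
  expect_length(frags, 1)
  expect_identical(frags[[1]]$atom_indices, 0:5)   # ring only, not the methyl

  benz_only <- reference_library(list(make_named_fixture("benzene_kekuleA")$graph))
  furan_q <- make_named_fixture("furan_like")$graph
  expect_length(detect_by_reference(furan_q, benz_only), 0)

  for (variant in c("benzene_kekuleA", "benzene_kekuleB")) {
    frags <- detect_by_reference(make_named_fixture(variant)$graph, benz_only)
    expect_length(frags, 1)
    expect_identical(frags[[1]]$atom_indices, 0:5)
  }
})

test_that("a fully saturated ring never matches an aromatic reference", {
  lib <- default_aromatic_library()
  cyclohexane <- hgraph(rep("C", 6),
                        lapply(1:6, function(k) c(k - 1L, k %% 6L, 1L)))
  expect_length(detect_by_reference(cyclohexane, lib), 0)
})

test_that("reference detection agrees with a brute-force mapping oracle", {
  benz <- make_named_fixture("benzene_kekuleA")$graph
  lib1 <- reference_library(list(benz))
  queries <- list(
    toluene = make_named_fixture("toluene")$graph,
    naphthalene = make_named_fixture("naphthaleneA")$graph,
    furan_like = make_named_fixture("furan_like")$graph,
    biphenyl = biphenyl()
  )
  for (nm in names(queries)) {
    q <- queries[[nm]]
    oracle_sets <- brute_subgraph_matches(lib1$entries[[1]]$fragment, q)
    got <- detect_by_reference(q, lib1)
    got_atoms <- sort(unique(unlist(lapply(got, `[[`, "atom_indices"))))
    oracle_atoms <- sort(unique(unlist(oracle_sets)))
    expect_identical(got_atoms, oracle_atoms, label = paste("oracle", nm))
  }
})

test_that("the O/S heuristic aromatizes only rings of labeled carbons", {
  fq <- make_named_fixture("furan_like")
  frags <- detect_heuristic(fq$graph)
  expect_length(frags, 1)
  expect_identical(frags[[1]]$atom_indices, 0:4)
  g2 <- normalize_aromatic_bonds(fq$graph, frags)
  expect_true(g2$atoms$is_aromatic[1])   # the oxygen, index 0

  dx <- make_named_fixture("dioxin_flanked")
  expect_length(detect_heuristic(dx$graph), 0)

  thp <- hgraph(c("O", rep("C", 5)),
                lapply(1:6, function(k) c(k - 1L, k %% 6L, 1L)))
  expect_length(detect_heuristic(thp), 0)
})

test_that("aromatic normalization is idempotent and Kekule-invariant", {
  ga <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  gb <- aromatize(make_named_fixture("benzene_kekuleB")$graph)
  gb$source_id <- ga$source_id
  expect_identical(write_molfile(ga), write_molfile(gb))
  expect_identical(write_molfile(aromatize(ga)), write_molfile(ga))

  tol <- aromatize(make_named_fixture("toluene")$graph)
  expect_equal(sum(tol$bonds$order == 4L), 6)
  methyl_bond <- tol$bonds[tol$bonds$a == 0L & tol$bonds$b == 6L, ]
  expect_equal(methyl_bond$order, 1L)

  g <- make_named_fixture("glycerol")$graph
  expect_true(mol_graph_equal(normalize_aromatic_bonds(g, list()), g))
})

test_that("cis/trans labels follow the 2-D cross-product rule", {
  bc <- assign_double_bond_stereo(
    add_implicit_hydrogens(make_named_fixture("butene_cis")$graph))
  bt <- assign_double_bond_stereo(
    add_implicit_hydrogens(make_named_fixture("butene_trans")$graph))
  expect_equal(bc$bonds$cis_trans[bc$bonds$order == 2L], "cis")
  expect_equal(bt$bonds$cis_trans[bt$bonds$order == 2L], "trans")

  # terminal alkene: no eligible substituent on the CH2 end
  propene <- hgraph(c("C", "C", "C"), list(c(0, 1, 2), c(1, 2, 1)))
  propene$atoms$x <- c(0, 1, 1.5); propene$atoms$y <- c(0, 0, 0.87)
  ph <- assign_double_bond_stereo(add_implicit_hydrogens(propene))
  expect_true(all(ph$bonds$cis_trans == "none"))

  # ring-internal double bond is never labeled
  cyclohexene <- hgraph(rep("C", 6),
                        lapply(1:6, function(k) c(k - 1L, k %% 6L,
                                                  if (k == 1) 2L else 1L)))
  ch <- assign_double_bond_stereo(add_implicit_hydrogens(cyclohexene))
  expect_true(all(ch$bonds$cis_trans == "none"))

  flat <- make_named_fixture("butene_cis")$graph
  flat$atoms$x <- 0; flat$atoms$y <- 0
  expect_error(assign_double_bond_stereo(flat), "geometry")
})
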