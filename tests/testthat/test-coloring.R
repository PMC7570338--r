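test_that("zero-layer strings encode exactly the enabled layers", {
  o_neutral <- list(element = "O", charge = 0L, stereo_parity = 0L,
                    mass_delta = 0L)
  o_anion <- list(element = "O", charge = -1L, stereo_parity = 0L,
                  mass_delta = 0L)
  expect_equal(zero_layer_color(o_neutral, loose_cfg), "O")
  expect_equal(zero_layer_color(o_anion, loose_cfg), "O")
  expect_match(zero_layer_color(o_anion, tight_cfg), "O")
  expect_match(zero_layer_color(o_anion, tight_cfg), "c-1", fixed = TRUE)
  expect_false(zero_layer_color(o_anion, tight_cfg) ==
                 zero_layer_color(o_neutral, tight_cfg))
  rgrp <- list(element = "R#", charge = 0L, stereo_parity = 0L, mass_delta = 0L)
  expect_equal(zero_layer_color(rgrp, loose_cfg), "R#")
})

test_that("coloring collapses symmetric atoms and separates distinct ones", {
  benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  cb <- color_molecule(benzene, loose_cfg)
  expect_length(unique(cb$full), 1)

  gly <- color_molecule(make_named_fixture("glycerol")$graph, loose_cfg)
  expect_identical(color_classes(gly),
                   list(c(0L, 2L), 1L, c(3L, 5L), 4L))

  prop <- color_molecule(make_named_fixture("n_propanol")$graph, loose_cfg)
  expect_identical(color_classes(prop), list(0L, 1L, 2L, 3L))

  single <- hgraph("C", NULL)
  cs <- color_molecule(single, loose_cfg)
  expect_equal(unname(cs$full), "C")
})

test_that("symmetry validation passes true symmetry and vacuous cases", {
  benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  cb <- color_atoms(benzene, loose_cfg)
  rep1 <- validate_symmetry(benzene, cb, loose_cfg)
  expect_length(rep1$invalid_groups, 0)
  expect_length(rep1$groups, 1)

  prop <- make_named_fixture("n_propanol")$graph
  cp <- color_atoms(prop, loose_cfg)
  rep2 <- validate_symmetry(prop, cp, loose_cfg)
  expect_length(rep2$invalid_groups, 0)
  expect_identical(recolor(prop, cp, rep2, loose_cfg), cp)
})

test_that("pseudosymmetric atoms are flagged and repaired by recoloring", {
  fx <- make_named_fixture("pseudosym_triring")
  weak <- coloring_config("loose", min_rounds = 2, max_rounds = 2)
  cw <- color_atoms(fx$graph, weak)
  a <- as.character(fx$target_atoms[1]); b <- as.character(fx$target_atoms[2])
  expect_identical(cw$full[[a]], cw$full[[b]])

  rep1 <- validate_symmetry(fx$graph, cw, weak)
  flagged <- vapply(rep1$invalid_groups,
                    function(v) all(fx$target_atoms %in% v), logical(1))
  expect_true(any(flagged))

  cr <- recolor(fx$graph, cw, rep1, weak)
  expect_false(identical(cr$full[[a]], cr$full[[b]]))
  expect_length(validate_symmetry(fx$graph, cr, weak)$invalid_groups, 0)
  expect_identical(color_classes(cr), symmetry_orbits(fx$graph, loose_cfg))
  # declared truth: no symmetric atoms at all
  expect_identical(color_classes(cr), as.list(0:15))
})

test_that("final color classes equal automorphism orbits on random molecules", {
  for (s in 1:40) {
    g <- random_molecule(s, 8 + (s %% 18))
    for (cfg in list(loose_cfg, tight_cfg)) {
      expect_identical(color_classes(color_molecule(g, cfg)),
                       symmetry_orbits(g, cfg),
                       label = paste("orbits seed", s, cfg$mode))
    }
  }
})

test_that("the orbit oracle itself behaves on known cases", {
  benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  expect_identical(symmetry_orbits(benzene, loose_cfg), list(0:5))
  expect_identical(symmetry_orbits(make_named_fixture("glycerol")$graph,
                                   loose_cfg),
                   list(c(0L, 2L), 1L, c(3L, 5L), 4L))
  big <- random_molecule(1, 20)
  expect_error(symmetry_orbits(big, loose_cfg, max_atoms = 10), "limited")
})

test_that("identifier multiset is invariant under atom relabeling", {
  for (s in 1:10) {
    g <- random_molecule(s, 12)
    base <- sort(unname(color_molecule(g, loose_cfg)$full))
    perm <- permute_atoms(g, rev(g$atoms$index))
    expect_identical(sort(unname(color_molecule(perm, loose_cfg)$full)), base)
  }
})

test_that("tight classes refine loose classes", {
  for (s in c(3, 7, 11, 19)) {
    g <- random_molecule(s, 15)
    g$atoms$charge[which(g$atoms$element == "O")[1]] <- -1L
    cl <- color_molecule(g, loose_cfg)$full
    ct <- color_molecule(g, tight_cfg)$full
    # atoms sharing a tight color must share the loose color
    for (grp in split(names(ct), ct)) {
      expect_length(unique(cl[grp]), 1)
    }
  }
})

test_that("explicit hydrogens never change heavy-atom identifiers", {
  for (nm in c("glycerol", "n_propanol", "toluene")) {
    g <- make_named_fixture(nm)$graph
    ch <- color_molecule(add_implicit_hydrogens(g), loose_cfg)
    c0 <- color_molecule(g, loose_cfg)
    expect_identical(ch$full[names(c0$full)], c0$full)
  }
})

test_that("coloring is deterministic", {
  g <- random_molecule(42, 18)
  expect_identical(color_molecule(g, tight_cfg), color_molecule(g, tight_cfg))
})
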