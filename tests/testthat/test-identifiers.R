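fake_coloring <- function(full) {
  structure(list(zero_layer = full, full = full, rounds_used = 0L,
                 config = coloring_config("loose")),
            class = "atom_coloring")
}

test_that("compound identifiers render sorted (count)[color] substrings", {
  benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
  ci <- identify_compound(benzene, loose_cfg)
  expect_match(ci$text, "^\\(6\\)\\[")
  expect_equal(nrow(ci$classes), 1)
  expect_equal(ci$classes$count, 6L)

  # whole rendered substrings are the sort keys: "(1)[b]" < "(2)[a]"
  ci2 <- compound_identifier(fake_coloring(c(`0` = "b", `1` = "a", `2` = "a")))
  expect_equal(ci2$text, "(1)[b](2)[a]")

  expect_error(compound_identifier(fake_coloring(character(0))), "empty")
})

test_that("identifier parsing inverts rendering, including escapes", {
  p <- parse_identifier("(6)[X]")
  expect_equal(as.data.frame(p), data.frame(color = "X", count = 6L))
  p2 <- parse_identifier("(1)[b](2)[a]")
  expect_equal(p2$color, c("b", "a"))
  expect_equal(p2$count, c(1L, 2L))
  expect_error(parse_identifier("(0)[a]"), ">= 1")
  expect_error(parse_identifier("(2)[a"), "position")
  expect_error(parse_identifier("junk"), "position 1")

  tricky <- compound_identifier(fake_coloring(c(`0` = "x[y]z", `1` = "w")))
  back <- parse_identifier(tricky$text)
  expect_setequal(back$color, c("x[y]z", "w"))
})

test_that("class counts always sum to the number of colorable atoms", {
  for (s in 1:8) {
    g <- random_molecule(s, 10 + s)
    ci <- identify_compound(g, loose_cfg)
    expect_equal(sum(ci$classes$count), nrow(g$atoms))
  }
})

test_that("atom-permuted copies share one identifier text", {
  g <- random_molecule(5, 14)
  base <- id_text(g, loose_cfg)
  for (k in 1:20) {
    perm <- molcolor:::with_seed(k, sample(nrow(g$atoms)) - 1L)
    expect_identical(id_text(permute_atoms(g, perm), loose_cfg), base)
  }
})

test_that("indexing groups permuted duplicates and reports ambiguity", {
  g1 <- make_named_fixture("glycerol")$graph
  g2 <- make_named_fixture("n_propanol")$graph
  idx <- build_index(list(A = g1, B = g2), loose_cfg)
  expect_equal(nrow(idx), 2)
  expect_true(all(lengths(idx$ids) == 1))

  dup <- permute_atoms(g1, rev(g1$atoms$index))
  idx2 <- build_index(list(A = g1, B = g2, C = dup), loose_cfg)
  expect_equal(nrow(idx2), 2)
  amb <- ambiguous_identifiers(idx2)
  expect_equal(nrow(amb), 1)
  expect_identical(amb$ids[[1]], c("A", "C"))
})

test_that("charge isomers merge under loose and split under tight", {
  a <- make_named_fixture("charge_pairA")$graph
  b <- make_named_fixture("charge_pairB")$graph
  loose_idx <- build_index(list(A = a, B = b), loose_cfg)
  expect_equal(nrow(loose_idx), 1)
  expect_identical(loose_idx$ids[[1]], c("A", "B"))
  tight_idx <- build_index(list(A = a, B = b), tight_cfg)
  expect_equal(nrow(tight_idx), 2)
})

test_that("indexing is order-independent", {
  gs <- lapply(1:6, function(s) random_molecule(s, 10))
  names(gs) <- paste0("M", 1:6)
  i1 <- build_index(gs, loose_cfg)
  i2 <- build_index(rev(gs), loose_cfg)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
})

test_that("the display hash implements 32-bit FNV-1a", {
  # published offset basis for the empty string
  expect_equal(color_hash(""), "811c9dc5")
  expect_match(color_hash("(6)[C]"), "^[0-9a-f]{8}$")
  expect_false(color_hash("(6)[C]") == color_hash("(6)[N]"))
})
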