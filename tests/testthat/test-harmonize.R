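pair_tb <- function(...) tibble::tibble(...)

test_that("EC parsing enforces the wildcard-suffix grammar", {
  e <- ec_parse("1.1.1.1")
  expect_equal(e$depth, 4L)
  w <- ec_parse("2.3.1.-")
  expect_equal(w$depth, 3L)
  expect_equal(w$levels, c("2", "3", "1", "-"))
  expect_warning(expect_null(ec_parse("-.-.-.-")), "unparseable")
  expect_warning(expect_null(ec_parse("1.-.1.1")), "unparseable")
  expect_warning(expect_null(ec_parse("ec one")), "unparseable")
})

test_that("matching emits the Cartesian product within shared keys", {
  gs <- list(glycerol = make_named_fixture("glycerol")$graph,
             propanol = make_named_fixture("n_propanol")$graph)
  dupR1 <- permute_atoms(gs$glycerol, rev(gs$glycerol$atoms$index))
  iL <- build_index(list(gly = gs$glycerol, pro = gs$propanol), loose_cfg)
  iR <- build_index(list(glyR1 = gs$glycerol, glyR2 = dupR1), loose_cfg)
  p <- match_compounds(iL, iR, mode = "loose")
  expect_equal(nrow(p), 2)            # 1 left x 2 right, ambiguity preserved
  expect_setequal(p$right_id, c("glyR1", "glyR2"))
  expect_true(all(p$left_id == "gly"))

  # symmetry: transposing inputs transposes pairs
  pT <- match_compounds(iR, iL, mode = "loose")
  expect_identical(sort(paste(pT$right_id, pT$left_id)),
                   sort(paste(p$left_id, p$right_id)))

  iEmpty <- build_index(list(only = random_molecule(99, 9)), loose_cfg)
  expect_equal(nrow(match_compounds(iL, iEmpty, mode = "loose")), 0)

  iTight <- build_index(list(gly = gs$glycerol), tight_cfg)
  expect_error(match_compounds(iTight, iL), "configurations")
})

test_that("cross-reference confirmation covers shared and direct-link ids", {
  pairs <- pair_tb(left_id = c("L1", "L2", "L3"),
                   right_id = c("R1", "R2", "R3"),
                   mode = "loose")
  xl <- pair_tb(compound_id = c("L1", "L3"),
                namespace = c("CHEBI", "CHEBI"),
                foreign_id = c("CHEBI:100", "CHEBI:300"))
  xr <- pair_tb(compound_id = c("R1", "R2", "R3"),
                namespace = c("CHEBI", "LEFTDB", "CHEBI"),
                foreign_id = c("CHEBI:100", "L2", "CHEBI:999"))
  out <- confirm_with_ids(pairs, xl, xr)
  expect_identical(out$id_confirmed, c(TRUE, TRUE, FALSE))
})

test_that("EC validation applies prefix logic, wildcards and buckets", {
  pairs <- pair_tb(left_id = c("L1", "L2", "L3", "L4"),
                   right_id = c("R1", "R2", "R3", "R4"),
                   mode = "loose")
  rl <- pair_tb(reaction_id = c("a", "b", "d"),
                ec = c("1.1.1.1", "2.3.1.-", "1.1.1.1"),
                participants = c("L1", "L2", "L4"))
  rr <- pair_tb(reaction_id = c("x", "y", "z"),
                ec = c("1.1.1.2", "2.3.1.9", "1.1.1.1"),
                participants = c("R1", "R2", "R4"))
  out <- validate_with_ec(pairs, rl, rr)
  expect_identical(out$reaction_status,
                   c("ec3_verified",     # 1.1.1.1 vs 1.1.1.2
                     "ec3_verified",     # wildcard caps at 3 levels
                     "no_reactions",     # L3 joins nothing
                     "ec4_verified"))    # full 4-level agreement

  # unparseable EC: reaction kept, treated as EC-less
  rl2 <- pair_tb(reaction_id = "a", ec = "bogus", participants = "L1")
  rr2 <- pair_tb(reaction_id = "x", ec = "1.1.1.1", participants = "R1")
  expect_warning(
    out2 <- validate_with_ec(pairs[1, ], rl2, rr2), "unparseable")
  expect_equal(out2$reaction_status, "in_reactions")
})

test_that("ec4 status implies the 3-level test would also pass", {
  db <- make_database_pair(seed = 3, n_compounds = 10, noise = "atom_reorder")
  rep <- harmonize_databases(db$left, db$right, modes = "loose")
  p <- tidy(rep)
  lmap <- molcolor:::compound_ec_map(read_database(db$left)$reactions)
  rmap <- molcolor:::compound_ec_map(read_database(db$right)$reactions)
  for (i in which(p$reaction_status == "ec4_verified")) {
    el <- lmap$ecs[[p$left_id[i]]]; er <- rmap$ecs[[p$right_id[i]]]
    agree3 <- any(vapply(el, function(a) any(vapply(er, function(b)
      molcolor:::ec_agree(a, b, 3L), logical(1))), logical(1)))
    expect_true(agree3)
  }
})

test_that("harmonization recovers planted truth on a generated pair", {
  db <- make_database_pair(seed = 2, n_compounds = 12,
                           noise = c("kekule_flip", "charge_shift",
                                     "atom_reorder", "unmatched_extras"))
  rep <- harmonize_databases(db$left, db$right)
  pairs <- dplyr::arrange(tidy(rep), left_id)
  truth <- dplyr::arrange(db$truth, left_id)
  expect_identical(as.data.frame(pairs), as.data.frame(truth))

  # superset property: every tight pair also matches under loose
  iL <- build_index(lapply(read_database(db$left)$compounds, aromatize),
                    loose_cfg)
  iR <- build_index(lapply(read_database(db$right)$compounds, aromatize),
                    loose_cfg)
  loose_pairs <- match_compounds(iL, iR, mode = "loose")
  tight_keys <- paste(pairs$left_id[pairs$mode == "tight"],
                      pairs$right_id[pairs$mode == "tight"])
  expect_true(all(tight_keys %in%
                    paste(loose_pairs$left_id, loose_pairs$right_id)))
})

test_that("empty and single-mode runs degrade gracefully", {
  d <- tempfile("emptydb"); dir.create(file.path(d, "L"), recursive = TRUE)
  dir.create(file.path(d, "R"))
  rep <- harmonize_databases(file.path(d, "L"), file.path(d, "R"))
  expect_equal(nrow(tidy(rep)), 0)
  expect_equal(nrow(rep$counts), 0)

  db <- make_database_pair(seed = 4, n_compounds = 6, noise = "atom_reorder")
  rep_t <- harmonize_databases(db$left, db$right, modes = "tight")
  expect_true(all(tidy(rep_t)$mode == "tight"))
  expect_equal(nrow(tidy(rep_t)), 6)
})
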