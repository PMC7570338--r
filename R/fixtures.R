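# Deterministic molecule and database generators. Every fixture is built in
# code (no stored binaries) and ships its declared ground truth: orbit
# partitions for molecules, correspondence/mode/status tables for database
# pairs.

ring_xy <- function(cx, cy, n = 6L, r = 1, start = 90) {
  ang <- (start + (0:(n - 1)) * 360 / n) * pi / 180
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

build_graph <- function(elements, bonds, xy = NULL, charges = NULL,
                        stereo = NULL, source_id = "") {
  n <- length(elements)
  if (is.null(xy)) xy <- ring_xy(0, 0, n, r = max(1, n / 4))
  if (is.null(charges)) charges <- rep(0L, n)
  if (is.null(stereo)) stereo <- rep(0L, n)
  bm <- do.call(rbind, bonds)
  mol_graph(
    tibble::tibble(index = seq_len(n) - 1L, element = elements,
                   charge = as.integer(charges),
                   stereo_parity = as.integer(stereo), mass_delta = 0L,
                   x = xy[, 1], y = xy[, 2], z = 0,
                   is_aromatic = FALSE),
    if (is.null(bm)) NULL else
      tibble::tibble(a = as.integer(bm[, 1]), b = as.integer(bm[, 2]),
                     order = as.integer(bm[, 3]), wedge = 0L,
                     cis_trans = "none"),
    source_id = source_id
  )
}

ring_bonds <- function(idx, orders) {
  n <- length(idx)
  lapply(seq_len(n), function(k) {
    c(idx[k], idx[k %% n + 1L], orders[k])
  })
}

#' Names of the built-in molecule fixtures
#' @return Character vector accepted by [make_named_fixture()].
#' @export
fixture_names <- function() {
  c("benzene_kekuleA", "benzene_kekuleB", "naphthalene", "naphthaleneA",
    "naphthaleneB", "toluene", "furan_like", "dioxin_flanked", "glycerol",
    "n_propanol", "butene_cis", "butene_trans", "pseudosym_triring",
    "charge_pairA", "charge_pairB")
}

#' Build a named test molecule with its declared ground truth
#'
#' Returns small molecules with known symmetry properties: Kekule-variant
#' benzene and naphthalene drawings, a pseudosymmetric tri-ring molecule
#' whose repair path needs validation + recoloring, a charge-discrepant
#' pair, cis/trans butenes with constructed geometry, and heteroaromatic
#' test cases for the O/S ring heuristic.
#'
#' @param name One of [fixture_names()].
#' @return A list with `name`, `graph` (a `mol_graph`), `molfile` (its
#'   serialization), `orbits` (declared loose heavy-atom orbit partition,
#'   0-based, on the aromatic-normalized form), and, where relevant,
#'   `aromatic_atoms` (pre-labeled aromatic atom indices) and
#'   `target_atoms` (the pseudosymmetric pair).
#' @export
make_named_fixture <- function(name) {
  fx <- switch(
    name,
    benzene_kekuleA = {
      g <- build_graph(rep("C", 6), ring_bonds(0:5, c(2, 1, 2, 1, 2, 1)),
                       ring_xy(0, 0), source_id = "benzene_kekuleA")
      list(graph = g, orbits = list(0:5))
    },
    benzene_kekuleB = {
      g <- build_graph(rep("C", 6), ring_bonds(0:5, c(1, 2, 1, 2, 1, 2)),
                       ring_xy(0, 0), source_id = "benzene_kekuleB")
      list(graph = g, orbits = list(0:5))
    },
    naphthalene = ,
    naphthaleneA = {
      list(graph = naphthalene_graph("A"),
           orbits = list(c(0L, 1L), c(2L, 5L, 6L, 9L), c(3L, 4L, 7L, 8L)))
    },
    naphthaleneB = {
      list(graph = naphthalene_graph("B"),
           orbits = list(c(0L, 1L), c(2L, 5L, 6L, 9L), c(3L, 4L, 7L, 8L)))
    },
    toluene = {
      xy <- rbind(ring_xy(0, 0), c(0, 2))
      g <- build_graph(rep("C", 7),
                       c(ring_bonds(0:5, c(2, 1, 2, 1, 2, 1)),
                         list(c(0, 6, 1))),
                       xy, source_id = "toluene")
      list(graph = g,
           orbits = list(0L, c(1L, 5L), c(2L, 4L), 3L, 6L))
    },
    furan_like = {
      g <- build_graph(c("O", rep("C", 4)),
                       list(c(0, 1, 1), c(1, 2, 2), c(2, 3, 1),
                            c(3, 4, 2), c(4, 0, 1)),
                       ring_xy(0, 0, 5), source_id = "furan_like")
      g$atoms$is_aromatic[2:5] <- TRUE   # the four carbons, pre-labeled
      list(graph = g, orbits = list(0L, c(1L, 4L), c(2L, 3L)),
           aromatic_atoms = 1:4)
    },
    dioxin_flanked = {
      mid <- ring_xy(0, 0)
      phL <- ring_xy(-2.8, 0.6)
      phR <- ring_xy(2.8, -0.6)
      els <- c("O", "C", "C", "O", "C", "C", rep("C", 12))
      bonds <- c(
        list(c(0, 1, 1), c(1, 2, 2), c(2, 3, 1), c(3, 4, 1),
             c(4, 5, 2), c(5, 0, 1)),
        ring_bonds(6:11, c(2, 1, 2, 1, 2, 1)),
        ring_bonds(12:17, c(2, 1, 2, 1, 2, 1)),
        list(c(1, 6, 1), c(4, 12, 1))
      )
      g <- build_graph(els, bonds, rbind(mid, phL, phR),
                       source_id = "dioxin_flanked")
      g$atoms$is_aromatic[7:18] <- TRUE  # the two flanking phenyls
      list(graph = g,
           orbits = list(c(0L, 3L), c(1L, 4L), c(2L, 5L), c(6L, 12L),
                         c(7L, 11L, 13L, 17L), c(8L, 10L, 14L, 16L),
                         c(9L, 15L)),
           aromatic_atoms = c(6:17))
    },
    glycerol = {
      xy <- rbind(cbind(0:2, 0), cbind(0:2, 1))
      g <- build_graph(c("C", "C", "C", "O", "O", "O"),
                       list(c(0, 1, 1), c(1, 2, 1), c(0, 3, 1),
                            c(1, 4, 1), c(2, 5, 1)),
                       xy, source_id = "glycerol")
      list(graph = g, orbits = list(c(0L, 2L), 1L, c(3L, 5L), 4L))
    },
    n_propanol = {
      g <- build_graph(c("C", "C", "C", "O"),
                       list(c(0, 1, 1), c(1, 2, 1), c(2, 3, 1)),
                       cbind(0:3, 0), source_id = "n_propanol")
      list(graph = g, orbits = list(0L, 1L, 2L, 3L))
    },
    butene_cis = {
      xy <- rbind(c(-0.5, 0.866), c(0, 0), c(1, 0), c(1.5, 0.866))
      g <- build_graph(c("C", "C", "C", "C"),
                       list(c(0, 1, 1), c(1, 2, 2), c(2, 3, 1)),
                       xy, source_id = "butene_cis")
      list(graph = g, orbits = list(c(0L, 3L), c(1L, 2L)))
    },
    butene_trans = {
      xy <- rbind(c(-0.5, 0.866), c(0, 0), c(1, 0), c(1.5, -0.866))
      g <- build_graph(c("C", "C", "C", "C"),
                       list(c(0, 1, 1), c(1, 2, 2), c(2, 3, 1)),
                       xy, source_id = "butene_trans")
      list(graph = g, orbits = list(c(0L, 3L), c(1L, 2L)))
    },
    pseudosym_triring = {
      # Central spiro atom X(0) joins two mutually symmetric saturated
      # rings A (1..5, entry N at 1) and B (6..10, entry N at 6); a third
      # ring C (11..15, O at 11) hangs off ring A at atom 3, breaking the
      # A/B symmetry. Ring-internal mirror flips are killed by the N and O
      # placements, so no two atoms are symmetric, yet the two N atoms see
      # identical neighborhoods for two BFS shells.
      els <- c("C", "N", "C", "C", "C", "C", "N", "C", "C", "C", "C",
               "O", "C", "C", "C", "C")
      bonds <- c(
        ring_bonds(0:5, rep(1, 6)),
        list(c(0, 6, 1), c(6, 7, 1), c(7, 8, 1), c(8, 9, 1),
             c(9, 10, 1), c(10, 0, 1)),
        list(c(3, 11, 1), c(11, 12, 1), c(12, 13, 1), c(13, 14, 1),
             c(14, 15, 1), c(15, 3, 1))
      )
      xy <- rbind(c(0, 0), ring_xy(-1.5, 1, 5, start = 0),
                  ring_xy(-1.5, -1, 5, start = 0),
                  ring_xy(1.8, 1.2, 5, start = 180))
      g <- build_graph(els, bonds, xy, source_id = "pseudosym_triring")
      list(graph = g, orbits = as.list(0:15), target_atoms = c(1L, 6L))
    },
    charge_pairA = {
      g <- build_graph(c("C", "C", "O", "O"),
                       list(c(0, 1, 1), c(1, 2, 1), c(1, 3, 1)),
                       rbind(c(0, 0), c(1, 0), c(2, 0.7), c(2, -0.7)),
                       source_id = "charge_pairA")
      list(graph = g, orbits = list(0L, 1L, c(2L, 3L)))
    },
    charge_pairB = {
      g <- build_graph(c("C", "C", "O", "O"),
                       list(c(0, 1, 1), c(1, 2, 1), c(1, 3, 1)),
                       rbind(c(0, 0), c(1, 0), c(2, 0.7), c(2, -0.7)),
                       charges = c(0, 0, 0, -1),
                       source_id = "charge_pairB")
      list(graph = g, orbits = list(0L, 1L, c(2L, 3L)))
    },
    rlang::abort(paste0("unknown fixture name '", name, "'; see fixture_names()"))
  )
  fx$name <- name
  fx$molfile <- write_molfile(fx$graph)
  fx
}

naphthalene_graph <- function(kekule = c("A", "B")) {
  kekule <- match.arg(kekule)
  xy <- rbind(
    c(0, 0.5), c(0, -0.5),
    c(-0.866, 1), c(-1.732, 0.5), c(-1.732, -0.5), c(-0.866, -1),
    c(0.866, 1), c(1.732, 0.5), c(1.732, -0.5), c(0.866, -1)
  )
  orders <- if (kekule == "A") {
    c(2, 1, 2, 1, 2, 1, 1, 2, 1, 2, 1)
  } else {
    c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1)
  }
  bonds <- list(
    c(0, 1, orders[1]),
    c(0, 2, orders[2]), c(2, 3, orders[3]), c(3, 4, orders[4]),
    c(4, 5, orders[5]), c(5, 1, orders[6]),
    c(0, 6, orders[7]), c(6, 7, orders[8]), c(7, 8, orders[9]),
    c(8, 9, orders[10]), c(9, 1, orders[11])
  )
  build_graph(rep("C", 10), bonds, xy,
              source_id = paste0("naphthalene", kekule))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

#' Generate a connected, chemically plausible random heavy-atom molecule
#'
#' Grows a random tree over elements C/N/O/S/P respecting default valences,
#' optionally upgrades some bonds to double bonds, and closes rings with
#' extra edges where spare valence allows. Deterministic per seed across
#' platforms.
#'
#' @param seed Integer seed.
#' @param n_atoms Number of heavy atoms (2 to 30).
#' @param ring_probability Probability of each attempted ring closure.
#' @return A `mol_graph`.
#' @export
random_molecule <- function(seed, n_atoms, ring_probability = 0.3) {
  if (n_atoms < 2 || n_atoms > 30) {
    rlang::abort("n_atoms must be between 2 and 30")
  }
  with_seed(seed, {
    valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)
    els <- sample(names(valence), n_atoms, replace = TRUE,
                  prob = c(0.55, 0.15, 0.15, 0.1, 0.05))
    free <- valence[els]
    bonds <- list()
    bonded <- matrix(FALSE, n_atoms, n_atoms)
    for (i in 2:n_atoms) {
      cand <- which(free[seq_len(i - 1)] >= 1L)
      if (length(cand) == 0) {
        # dead end (all earlier valences used); restart deterministically
        return(random_molecule(seed + 104729L, n_atoms, ring_probability))
      }
      j <- cand[sample.int(length(cand), 1)]
      order <- 1L
      remaining <- n_atoms - i
      spare <- sum(free) - 2L
      if (free[j] >= 2L && free[i] >= 2L && spare - 2L >= remaining &&
          stats::runif(1) < 0.2) {
        order <- 2L
      }
      bonds <- c(bonds, list(c(i - 1L, j - 1L, order)))
      bonded[i, j] <- bonded[j, i] <- TRUE
      free[i] <- free[i] - order
      free[j] <- free[j] - order
    }
    attempts <- max(1L, n_atoms %/% 4L)
    for (k in seq_len(attempts)) {
      if (stats::runif(1) >= ring_probability) next
      have <- which(free >= 1L)
      if (length(have) < 2) next
      prs <- utils::combn(have, 2)
      ok <- !bonded[cbind(prs[1, ], prs[2, ])]
      prs <- prs[, ok, drop = FALSE]
      if (ncol(prs) == 0) next
      pick <- prs[, sample.int(ncol(prs), 1)]
      bonds <- c(bonds, list(c(pick[1] - 1L, pick[2] - 1L, 1L)))
      bonded[pick[1], pick[2]] <- bonded[pick[2], pick[1]] <- TRUE
      free[pick[1]] <- free[pick[1]] - 1L
      free[pick[2]] <- free[pick[2]] - 1L
    }
    build_graph(els, bonds, source_id = paste0("RND", seed))
  })
}

#' Permute the atom order of a molecular graph
#'
#' Relabels atoms so that old index `i` becomes `perm[i + 1]`; atoms are
#' re-sorted by new index and bond rows re-sorted canonically. Coloring and
#' compound identifiers are invariant under this operation.
#'
#' @param g A `mol_graph`.
#' @param perm An integer permutation of `0:(n_atoms - 1)` (new index per
#'   old index, 0-based).
#' @return The relabeled `mol_graph`.
#' @export
permute_atoms <- function(g, perm) {
  n <- nrow(g$atoms)
  if (length(perm) != n || !setequal(perm, g$atoms$index)) {
    rlang::abort("perm must be a permutation of the atom indices")
  }
  atoms <- g$atoms
  atoms$index <- as.integer(perm[match(atoms$index, g$atoms$index)])
  atoms <- atoms[order(atoms$index), ]
  bonds <- g$bonds
  if (nrow(bonds) > 0) {
    map <- stats::setNames(as.integer(perm), g$atoms$index)
    bonds$a <- unname(map[as.character(bonds$a)])
    bonds$b <- unname(map[as.character(bonds$b)])
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
    bonds <- bonds[order(bonds$a, bonds$b), ]
  }
  mol_graph(atoms, bonds, source_id = g$source_id)
}

#' Generate a pair of toy databases with planted ground truth
#'
#' Writes two database directories (per-compound molfiles plus
#' `reactions.tsv` and `crossrefs.tsv`) whose compounds correspond one to
#' one up to representation noise, and returns the planted correspondence
#' table with the expected match mode, id confirmation and reaction status
#' per pair. Noise classes: `kekule_flip` (alternative Kekule drawing of
#' aromatic rings), `charge_shift` (one formal charge differs; matches
#' become loose-only), `atom_reorder` (atom index permutation),
#' `stereo_drop` (atom stereo parity removed on one side; loose-only), and
#' `unmatched_extras` (compounds present in only one database). Base
#' compounds are guaranteed pairwise-distinct loose identifiers so the
#' planted table is the exact expected harmonization result.
#'
#' @param seed Integer seed.
#' @param n_compounds Number of corresponding compounds planted (>= 4).
#' @param noise Character subset of
#'   `c("kekule_flip", "charge_shift", "atom_reorder", "stereo_drop",
#'   "unmatched_extras")`.
#' @param dir Parent directory to create `left/` and `right/` under.
#' @param lib Reference library used for the distinctness guarantee.
#' @return A list with `left`, `right` (directory paths) and `truth`
#'   (tibble: `left_id`, `right_id`, `mode`, `id_confirmed`,
#'   `reaction_status`).
#' @export
make_database_pair <- function(seed, n_compounds = 50,
                               noise = c("kekule_flip", "charge_shift",
                                         "atom_reorder", "unmatched_extras"),
                               dir = tempfile("dbpair"),
                               lib = default_aromatic_library()) {
  noise <- match.arg(noise, c("kekule_flip", "charge_shift", "atom_reorder",
                              "stereo_drop", "unmatched_extras"),
                     several.ok = TRUE)
  if (n_compounds < 4) rlang::abort("n_compounds must be at least 4")
  loose <- coloring_config("loose")
  loose_id <- function(g) identify_compound(aromatize(g, lib = lib), loose)$text

  aromatic_bases <- list(
    list(A = make_named_fixture("benzene_kekuleA")$graph,
         B = make_named_fixture("benzene_kekuleB")$graph),
    list(A = naphthalene_graph("A"), B = naphthalene_graph("B"))
  )
  graphsA <- list(); graphsB <- list(); seen <- character(0)
  for (k in seq_along(aromatic_bases)) {
    if (length(graphsA) >= n_compounds) break
    graphsA <- c(graphsA, list(aromatic_bases[[k]]$A))
    graphsB <- c(graphsB, list(aromatic_bases[[k]]$B))
    seen <- c(seen, loose_id(aromatic_bases[[k]]$A))
  }
  sub_seed <- seed * 1000L
  while (length(graphsA) < n_compounds) {
    sub_seed <- sub_seed + 1L
    n_at <- 6L + (sub_seed %% 13L)
    g <- random_molecule(sub_seed, n_at)
    key <- loose_id(g)
    if (key %in% seen) next
    seen <- c(seen, key)
    graphsA <- c(graphsA, list(g))
    graphsB <- c(graphsB, list(g))
  }

  dirL <- file.path(dir, "left"); dirR <- file.path(dir, "right")
  dir.create(dirL, recursive = TRUE, showWarnings = FALSE)
  dir.create(dirR, recursive = TRUE, showWarnings = FALSE)

  struct_noise <- intersect(noise, c("kekule_flip", "charge_shift",
                                     "atom_reorder", "stereo_drop"))
  if (length(struct_noise) == 0) struct_noise <- "atom_reorder"
  statuses <- c("ec4_verified", "ec3_verified", "ec3_wildcard",
                "in_reactions", "no_reactions")

  truth <- NULL
  rxnL <- NULL; rxnR <- NULL; xrfL <- NULL; xrfR <- NULL
  for (i in seq_len(n_compounds)) {
    lid <- sprintf("L%03d", i); rid <- sprintf("R%03d", i)
    gL <- graphsA[[i]]; gR <- graphsB[[i]]
    nz <- struct_noise[(i - 1L) %% length(struct_noise) + 1L]
    mode <- "tight"
    if (nz == "charge_shift") {
      pos <- which(gR$atoms$element %in% c("O", "N", "S"))
      if (length(pos) == 0) pos <- 1L
      gR$atoms$charge[pos[length(pos)]] <-
        if (gR$atoms$element[pos[length(pos)]] == "N") 1L else -1L
      mode <- "loose"
    } else if (nz == "stereo_drop") {
      gL$atoms$stereo_parity[1] <- 1L
      mode <- "loose"
    } else if (nz == "atom_reorder") {
      perm <- with_seed(seed + i, sample(nrow(gR$atoms)) - 1L)
      gR <- permute_atoms(gR, perm)
    } # kekule_flip: gR already the alternative drawing (or identical)
    gL$source_id <- lid; gR$source_id <- rid
    writeLines(write_molfile(gL), file.path(dirL, paste0(lid, ".mol")))
    writeLines(write_molfile(gR), file.path(dirR, paste0(rid, ".mol")))

    st <- statuses[(i - 1L) %% length(statuses) + 1L]
    base_ec <- sprintf("%d.%d.%d.%d", (i %% 6) + 1L, (i %% 3) + 1L,
                       (i %% 4) + 1L, (i %% 9) + 1L)
    ec3 <- sub("\\.[0-9]+$", "", base_ec)
    if (st == "ec4_verified") {
      rxnL <- rbind(rxnL, c(sprintf("RL%03d", i), base_ec, lid))
      rxnR <- rbind(rxnR, c(sprintf("RR%03d", i), base_ec, rid))
      expected <- "ec4_verified"
    } else if (st == "ec3_verified") {
      rxnL <- rbind(rxnL, c(sprintf("RL%03d", i), base_ec, lid))
      rxnR <- rbind(rxnR, c(sprintf("RR%03d", i),
                            paste0(ec3, ".", (i %% 9) + 2L), rid))
      expected <- "ec3_verified"
    } else if (st == "ec3_wildcard") {
      rxnL <- rbind(rxnL, c(sprintf("RL%03d", i), paste0(ec3, ".-"), lid))
      rxnR <- rbind(rxnR, c(sprintf("RR%03d", i), base_ec, rid))
      expected <- "ec3_verified"
    } else if (st == "in_reactions") {
      rxnL <- rbind(rxnL, c(sprintf("RL%03d", i), base_ec, lid))
      rxnR <- rbind(rxnR, c(sprintf("RR%03d", i),
                            sprintf("%d.%d.%d.%d", (i %% 6) + 2L,
                                    (i %% 3) + 1L, (i %% 4) + 1L,
                                    (i %% 9) + 1L), rid))
      expected <- "in_reactions"
    } else {
      expected <- "no_reactions"
    }

    confirmed <- FALSE
    if (i %% 2 == 0) {
      ref <- sprintf("CHEBI:%d", 1000 + i)
      xrfL <- rbind(xrfL, c(lid, "CHEBI", ref))
      xrfR <- rbind(xrfR, c(rid, "CHEBI", ref))
      confirmed <- TRUE
    } else if (i %% 5 == 1) {
      xrfR <- rbind(xrfR, c(rid, "LEFTDB", lid))
      confirmed <- TRUE
    }
    truth <- rbind(truth, data.frame(left_id = lid, right_id = rid,
                                     mode = mode, id_confirmed = confirmed,
                                     reaction_status = expected,
                                     stringsAsFactors = FALSE))
  }

  if ("unmatched_extras" %in% noise) {
    extra_seed <- seed * 7919L
    for (side in c("L", "R")) {
      added <- 0L
      while (added < 3L) {
        extra_seed <- extra_seed + 1L
        g <- random_molecule(extra_seed, 5L + (extra_seed %% 11L))
        key <- loose_id(g)
        if (key %in% seen) next
        seen <- c(seen, key)
        added <- added + 1L
        id <- sprintf("%sX%02d", side, added)
        g$source_id <- id
        out <- if (side == "L") dirL else dirR
        writeLines(write_molfile(g), file.path(out, paste0(id, ".mol")))
      }
    }
  }

  write_tsv0 <- function(m, cols, path) {
    df <- if (is.null(m)) {
      stats::setNames(as.data.frame(matrix(character(0), 0, length(cols)),
                                    stringsAsFactors = FALSE), cols)
    } else {
      stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv0(rxnL, c("reaction_id", "ec", "participants"),
             file.path(dirL, "reactions.tsv"))
  write_tsv0(rxnR, c("reaction_id", "ec", "participants"),
             file.path(dirR, "reactions.tsv"))
  write_tsv0(xrfL, c("compound_id", "namespace", "foreign_id"),
             file.path(dirL, "crossrefs.tsv"))
  write_tsv0(xrfR, c("compound_id", "namespace", "foreign_id"),
             file.path(dirR, "crossrefs.tsv"))

  list(left = dirL, right = dirR, truth = tibble::as_tibble(truth))
}
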