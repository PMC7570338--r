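# Shared helpers for the molcolor test suite. Fixtures are generated in
# code; nothing is read from disk except the bundled aromatic library.

loose_cfg <- coloring_config("loose")
tight_cfg <- coloring_config("tight")

# quick heavy-atom graph builder for hand-made cases
hgraph <- function(elements, bonds, charges = NULL, source_id = "test") {
  n <- length(elements)
  atoms <- tibble::tibble(
    index = seq_len(n) - 1L, element = elements,
    charge = if (is.null(charges)) 0L else as.integer(charges),
    stereo_parity = 0L, mass_delta = 0L,
    x = cos(2 * pi * seq_len(n) / n), y = sin(2 * pi * seq_len(n) / n),
    z = 0, is_aromatic = FALSE
  )
  bm <- if (is.null(bonds)) NULL else do.call(rbind, bonds)
  mol_graph(atoms,
            if (is.null(bm)) NULL else
              tibble::tibble(a = as.integer(bm[, 1]), b = as.integer(bm[, 2]),
                             order = as.integer(bm[, 3]), wedge = 0L,
                             cis_trans = "none"),
            source_id = source_id)
}

# Brute-force subgraph isomorphism oracle, independent of the igraph-backed
# implementation: enumerates every injective vertex mapping of the pattern
# into the target that respects element symbols, adjacency, and the
# {1,2,4}-interchangeable bond-order classes. Returns unique matched target
# atom sets (0-based).
brute_subgraph_matches <- function(pattern, target) {
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  if (np > nt) return(list())
  emat <- function(g) {
    n <- nrow(g$atoms)
    m <- matrix(0L, n, n)
    for (k in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[k]
      cls <- if (o == 3L) 2L else 1L
      m[g$bonds$a[k] + 1L, g$bonds$b[k] + 1L] <- cls
      m[g$bonds$b[k] + 1L, g$bonds$a[k] + 1L] <- cls
    }
    m
  }
  ep <- emat(pattern); et <- emat(target)
  elp <- pattern$atoms$element; elt <- target$atoms$element
  out <- list()
  perm <- integer(np); used <- logical(nt)
  recurse <- function(d) {
    if (d > np) {
      key <- paste(sort(perm - 1L), collapse = ",")
      out[[key]] <<- sort(perm - 1L)
      return(invisible())
    }
    for (j in seq_len(nt)) {
      if (used[j] || elt[j] != elp[d]) next
      ok <- TRUE
      for (p in seq_len(d - 1)) {
        if (ep[d, p] != et[j, perm[p]]) { ok <- FALSE; break }
      }
      if (!ok) next
      perm[d] <<- j; used[j] <<- TRUE
      recurse(d + 1)
      used[j] <<- FALSE
    }
  }
  recurse(1)
  unname(out)
}

# identifier text of a graph under a config, without normalization
id_text <- function(g, cfg) identify_compound(g, cfg)$text
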