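mol_to_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  if (nrow(g$bonds) > 0) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$a + 1L, g$bonds$b + 1L))
  }
  ig
}

# 0-based indices of bonds that lie on at least one cycle (non-bridges).
cycle_bond_rows <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ig <- mol_to_igraph(g)
  br <- as.integer(igraph::bridges(ig))
  setdiff(seq_len(nrow(g$bonds)), br)
}

# Smallest rings (<= max_size) of a molecular graph: for every cycle bond,
# the shortest cycle through it. Returned as a deduplicated list of sorted
# 0-based atom-index vectors. Adequate ring perception for heterocycle
# heuristics; not a full SSSR solver.
smallest_rings <- function(g, max_size = 8L) {
  rows <- cycle_bond_rows(g)
  if (length(rows) == 0) return(list())
  ig <- mol_to_igraph(g)
  rings <- list()
  for (k in rows) {
    a <- g$bonds$a[k] + 1L; b <- g$bonds$b[k] + 1L
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(a, b)))
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = a, to = b)$vpath[[1]])
    if (length(sp) == 0) next
    ring <- sort(as.integer(sp) - 1L)
    if (length(ring) > max_size) next
    key <- paste(ring, collapse = ",")
    rings[[key]] <- ring
  }
  unname(rings)
}

new_aromatic_substructure <- function(fragment, atom_indices, origin) {
  structure(list(fragment = fragment,
                 atom_indices = sort(as.integer(atom_indices)),
                 origin = origin),
            class = "aromatic_substructure")
}

#' @export
print.aromatic_substructure <- function(x, ...) {
  cat("<aromatic_substructure> ", length(x$atom_indices), " atoms (",
      x$origin, ")\n", sep = "")
  invisible(x)
}

# Build the fragment graph induced by an atom set, keeping only bonds that
# lie on a cycle of the induced subgraph, so every fragment bond is a ring
# bond (bridges such as a biphenyl linker are dropped). Fragment atoms are
# re-indexed 0..k-1; the original indices are carried alongside.
induced_ring_fragment <- function(g, atom_set, origin) {
  atom_set <- sort(as.integer(atom_set))
  amap <- match(atom_set, g$atoms$index)
  sub_atoms <- g$atoms[amap, ]
  keep_bond <- g$bonds$a %in% atom_set & g$bonds$b %in% atom_set
  sub_bonds <- g$bonds[keep_bond, ]
  remap <- stats::setNames(seq_along(atom_set) - 1L, atom_set)
  sub_atoms$index <- seq_along(atom_set) - 1L
  if (nrow(sub_bonds) > 0) {
    sub_bonds$a <- unname(remap[as.character(sub_bonds$a)])
    sub_bonds$b <- unname(remap[as.character(sub_bonds$b)])
  }
  frag <- mol_graph(sub_atoms, sub_bonds, source_id = g$source_id)
  keep_rows <- cycle_bond_rows(frag)
  frag$bonds <- frag$bonds[keep_rows, ]
  frag
}

#' Extract fused aromatic substructures from labeled atoms
#'
#' Given the set of atoms annotated as aromatic (e.g., from KCF-style
#' per-atom labels or set by fixtures), returns the induced ring systems:
#' one fragment per connected component after bridge bonds of the induced
#' subgraph are dropped, so fused ring systems come out as single fragments
#' while ring systems joined only by a linker bond stay separate.
#'
#' @param g A `mol_graph`.
#' @param aromatic_atoms Integer vector of 0-based atom indices.
#' @return A list of `aromatic_substructure` objects (empty for no labels).
#' @export
extract_labeled_substructures <- function(g, aromatic_atoms) {
  aromatic_atoms <- sort(unique(as.integer(aromatic_atoms)))
  if (length(aromatic_atoms) == 0) return(list())
  if (!all(aromatic_atoms %in% g$atoms$index)) {
    rlang::abort("aromatic_atoms contains indices not in the graph")
  }
  whole <- induced_ring_fragment(g, aromatic_atoms, origin = "labeled")
  comps <- graph_components(whole)
  lapply(comps, function(cc) {
    orig <- aromatic_atoms[cc + 1L]
    new_aromatic_substructure(induced_ring_fragment(g, orig, "labeled"),
                              orig, origin = "labeled")
  })
}

#' Build a reference library of aromatic substructures
#'
#' Entries are deduplicated by their loose compound coloring identifier, so
#' the same ring system drawn two ways enters once.
#'
#' @param fragments A list of `mol_graph` fragments (each a fused aromatic
#'   system with bonds normalized or in any Kekule drawing).
#' @return A `reference_library` object.
#' @export
reference_library <- function(fragments) {
  cfg <- coloring_config("loose")
  seen <- character(0)
  entries <- list()
  for (fr in fragments) {
    # key computed on an aromatic-normalized copy so Kekule variants of the
    # same ring system deduplicate to one entry
    frn <- fr
    rows <- cycle_bond_rows(frn)
    rows <- rows[frn$bonds$order[rows] %in% c(1L, 2L, 4L)]
    frn$bonds$order[rows] <- 4L
    key <- compound_identifier(color_molecule(frn, cfg))$text
    if (key %in% seen) next
    seen <- c(seen, key)
    entries <- c(entries, list(new_aromatic_substructure(
      fr, fr$atoms$index, origin = fr$source_id)))
  }
  structure(list(entries = entries), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("<reference_library> ", length(x$entries), " aromatic substructures\n",
      sep = "")
  invisible(x)
}

#' Read a reference library from a directory of molfile fragments
#' @param dir Directory containing `.mol` fragment files.
#' @return A [reference_library()].
#' @export
read_reference_library <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mol$", full.names = TRUE))
  reference_library(lapply(files, read_molfile))
}

#' The bundled default aromatic reference library
#'
#' A small curated set (benzene, pyridine, pyrrole, furan, thiophene,
#' imidazole, naphthalene) shipped with the package for tests and small
#' runs; production users supply their own, larger library directory.
#'
#' @return A [reference_library()].
#' @export
default_aromatic_library <- function() {
  read_reference_library(system.file("extdata", "aromatics",
                                     package = "molcolor", mustWork = TRUE))
}

# element -> integer color codes shared between a pattern and a target so
# VF2 vertex colors line up.
element_codes <- function(...) {
  els <- unique(unlist(list(...)))
  stats::setNames(seq_along(els), els)
}

# Bond-order equivalence class for reference matching: single, double and
# aromatic orders are interchangeable inside candidate rings so Kekule and
# aromatic drawings both match; triple bonds stay distinct.
order_class <- function(order) ifelse(order == 3L, 2L, 1L)

#' Detect aromatic substructures by reference-library matching
#'
#' Finds every atom set of `g` onto which some library entry maps by
#' subgraph isomorphism respecting element symbols, with bond orders
#' compared under the \{1, 2, 4\} equivalence so Kekule and aromatic
#' drawings both match. A candidate match must contain at least one double
#' or aromatic bond (a fully saturated ring is never aromatic). Overlapping
#' matches are fused into maximal fragments. Matching runs on igraph's VF2
#' implementation.
#'
#' @param g A `mol_graph`.
#' @param lib A [reference_library()].
#' @return A list of `aromatic_substructure` objects.
#' @export
detect_by_reference <- function(g, lib) {
  if (length(lib$entries) == 0) rlang::abort("reference library is empty")
  if (nrow(g$bonds) == 0) return(list())
  codes <- element_codes(g$atoms$element,
                         unlist(lapply(lib$entries,
                                       function(e) e$fragment$atoms$element)))
  tg <- mol_to_igraph(g)
  igraph::V(tg)$color <- unname(codes[g$atoms$element])
  igraph::E(tg)$color <- order_class(g$bonds$order)
  g_unsat <- g$bonds$order %in% c(2L, 4L)
  bkey <- paste(pmin(g$bonds$a, g$bonds$b), pmax(g$bonds$a, g$bonds$b))
  unsat_keys <- bkey[g_unsat]
  matches <- list()
  for (entry in lib$entries) {
    fr <- entry$fragment
    if (nrow(fr$atoms) > nrow(g$atoms)) next
    pg <- mol_to_igraph(fr)
    igraph::V(pg)$color <- unname(codes[fr$atoms$element])
    igraph::E(pg)$color <- order_class(fr$bonds$order)
    maps <- igraph::subgraph_isomorphisms(pattern = pg, target = tg,
                                          method = "vf2")
    for (m in maps) {
      tatoms <- sort(as.integer(m) - 1L)
      # the image of the pattern's bonds, in target keys
      img_keys <- vapply(seq_len(nrow(fr$bonds)), function(k) {
        a <- as.integer(m)[fr$bonds$a[k] + 1L] - 1L
        b <- as.integer(m)[fr$bonds$b[k] + 1L] - 1L
        paste(min(a, b), max(a, b))
      }, character(1))
      if (!any(img_keys %in% unsat_keys)) next
      matches[[paste(tatoms, collapse = ",")]] <- tatoms
    }
  }
  matches <- unname(matches)
  if (length(matches) == 0) return(list())
  # fuse overlapping matches into maximal fragments
  fused <- list()
  for (s in matches) {
    hit <- which(vapply(fused, function(f) length(intersect(f, s)) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      fused <- c(fused, list(s))
    } else {
      merged <- sort(unique(c(unlist(fused[hit]), s)))
      fused <- c(fused[-hit], list(merged))
    }
  }
  fused <- fused[order(vapply(fused, min, integer(1)))]
  lapply(fused, function(atoms) {
    new_aromatic_substructure(induced_ring_fragment(g, atoms, "reference"),
                              atoms, origin = "reference")
  })
}

#' Heuristic aromatization of O/S atoms in otherwise-aromatic rings
#'
#' Databases leave heteroatom aromatic types undefined for oxygen and
#' sulfur. For each smallest ring (size <= `max_ring`) containing O or S in
#' which every other member is an aromatic-labeled carbon or nitrogen, the
#' O/S atoms are marked aromatic and the ring emitted as a fragment. Rings
#' whose carbons carry no aromatic labels are left alone, so a saturated or
#' quinoid O-containing ring flanked by aromatic systems is not aromatized.
#'
#' @param g A `mol_graph` whose `is_aromatic` flags reflect prior detection.
#' @param max_ring Ring-size cap for the heuristic (default 8).
#' @return A list of `aromatic_substructure` objects with origin
#'   `"heuristic"` (possibly empty).
#' @export
detect_heuristic <- function(g, max_ring = 8L) {
  rings <- smallest_rings(g, max_size = max_ring)
  out <- list()
  for (ring in rings) {
    pos <- match(ring, g$atoms$index)
    els <- g$atoms$element[pos]
    arom <- g$atoms$is_aromatic[pos]
    os <- els %in% c("O", "S")
    if (!any(os)) next
    others_ok <- all(els[!os] %in% c("C", "N")) && all(arom[!os])
    if (!others_ok || all(os)) next
    out <- c(out, list(new_aromatic_substructure(
      induced_ring_fragment(g, ring, "heuristic"), ring,
      origin = "heuristic")))
  }
  out
}

#' Normalize aromatic bonds inside detected fragments
#'
#' Every bond of each fragment (ring bonds with both endpoints inside one
#' fused system) is set to order 4 and its endpoints flagged aromatic; all
#' other bonds are untouched. Idempotent, and the step that makes two Kekule
#' drawings of one compound render byte-identical graphs.
#'
#' @param g A `mol_graph`.
#' @param frags A list of `aromatic_substructure` objects for `g`.
#' @return The normalized `mol_graph`.
#' @export
normalize_aromatic_bonds <- function(g, frags) {
  if (length(frags) == 0) return(g)
  blk <- bond_lookup(g)
  for (fr in frags) {
    orig <- fr$atom_indices
    fb <- fr$fragment$bonds
    if (nrow(fb) == 0) next
    keys <- paste(pmin(orig[fb$a + 1L], orig[fb$b + 1L]),
                  pmax(orig[fb$a + 1L], orig[fb$b + 1L]))
    rows <- unname(blk[keys])
    if (anyNA(rows)) rlang::abort("fragment bond not present in parent graph")
    g$bonds$order[rows] <- 4L
    g$atoms$is_aromatic[match(unique(c(g$bonds$a[rows], g$bonds$b[rows])),
                              g$atoms$index)] <- TRUE
  }
  g
}

#' Detect and normalize aromatic substructures in one call
#'
#' Reference-library detection, then the O/S ring heuristic on the
#' intermediate labels, then bond normalization.
#'
#' @param g A `mol_graph`.
#' @param lib A [reference_library()]; defaults to the bundled set.
#' @param heuristic Run the O/S heuristic after reference matching.
#' @return The normalized `mol_graph`.
#' @export
aromatize <- function(g, lib = default_aromatic_library(), heuristic = TRUE) {
  frags <- detect_by_reference(g, lib)
  g <- normalize_aromatic_bonds(g, frags)
  if (heuristic) {
    extra <- detect_heuristic(g)
    g <- normalize_aromatic_bonds(g, extra)
  }
  g
}

#' Assign cis/trans labels to acyclic double bonds from 2-D geometry
#'
#' For each acyclic order-2 bond whose endpoints each carry at least one
#' non-hydrogen, non-partner substituent, a reference substituent is picked
#' on each end (lowest element token, ties by lowest index) and the sign of
#' the cross product of the substituent vector with the double-bond axis is
#' compared across the two ends: same sign is cis, opposite is trans, and a
#' collinear substituent (normalized cross product below 1e-6) yields none.
#' Requires explicit hydrogens (see [add_implicit_hydrogens()]) so that
#' substituent counts are complete, and planar coordinates.
#'
#' @param g A `mol_graph` with coordinates.
#' @return `g` with the bonds' `cis_trans` column filled in.
#' @export
assign_double_bond_stereo <- function(g) {
  if (nrow(g$bonds) == 0) return(g)
  xy <- cbind(g$atoms$x, g$atoms$y)
  if (anyNA(xy) || all(abs(sweep(xy, 2, xy[1, ])) < 1e-12)) {
    rlang::abort("coordinates are missing or degenerate; supply 2-D geometry before assigning double-bond stereo")
  }
  adj <- adjacency_list(g)
  in_cycle <- logical(nrow(g$bonds))
  in_cycle[cycle_bond_rows(g)] <- TRUE
  coord <- function(i) c(g$atoms$x[i + 1L], g$atoms$y[i + 1L])
  pick_ref <- function(center, partner) {
    subs <- setdiff(adj[[center + 1L]], partner)
    subs <- subs[g$atoms$element[subs + 1L] != "H"]
    if (length(subs) == 0) return(NA_integer_)
    key <- order(g$atoms$element[subs + 1L], subs)
    subs[key[1]]
  }
  cross_sign <- function(axis, v) {
    na <- sqrt(sum(axis^2)); nv <- sqrt(sum(v^2))
    if (na < 1e-12 || nv < 1e-12) return(0)
    cr <- (axis[1] * v[2] - axis[2] * v[1]) / (na * nv)
    if (abs(cr) < 1e-6) 0 else sign(cr)
  }
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 2L || in_cycle[k]) next
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    ra <- pick_ref(a, b); rb <- pick_ref(b, a)
    if (is.na(ra) || is.na(rb)) next
    axis <- coord(b) - coord(a)
    sa <- cross_sign(axis, coord(ra) - coord(a))
    sb <- cross_sign(axis, coord(rb) - coord(b))
    if (sa == 0 || sb == 0) next
    g$bonds$cis_trans[k] <- if (sa == sb) "cis" else "trans"
  }
  g
}
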