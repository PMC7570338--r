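#' Coloring configuration
#'
#' Controls which chemical information layers enter atom color strings.
#' The `"loose"` preset keeps only atom type and bond type, absorbing
#' cross-database inconsistencies in charge, stereochemistry and isotope
#' annotation; the `"tight"` preset switches every chemical layer on.
#' Atom type is always included. Hydrogens are excluded from coloring and
#' neighborhood expansion by default because databases disagree on how many
#' hydrogens a molfile carries.
#'
#' @param mode `"loose"` or `"tight"` preset.
#' @param use_bond_type,use_charge,use_atom_stereo,use_bond_stereo,use_isotope
#'   Optional flag overrides of the preset.
#' @param include_hydrogen Include explicit hydrogens in coloring and
#'   expansion (default `FALSE`).
#' @param min_rounds Number of BFS expansion rounds run for every atom before
#'   the uniqueness check (default 3), guarding against early stopping.
#' @param max_rounds Hard cap on expansion rounds. The default (`Inf`)
#'   disables the cap; finite values deliberately weaken the coloring and
#'   exist to exercise the validation/recoloring repair path.
#'
#' @return A `coloring_config` list.
#' @export
coloring_config <- function(mode = c("loose", "tight"),
                            use_bond_type = NULL, use_charge = NULL,
                            use_atom_stereo = NULL, use_bond_stereo = NULL,
                            use_isotope = NULL, include_hydrogen = FALSE,
                            min_rounds = 3L, max_rounds = Inf) {
  mode <- match.arg(mode)
  tight <- identical(mode, "tight")
  cfg <- list(
    mode = mode,
    use_atom_type = TRUE,
    use_bond_type = if (is.null(use_bond_type)) TRUE else use_bond_type,
    use_charge = if (is.null(use_charge)) tight else use_charge,
    use_atom_stereo = if (is.null(use_atom_stereo)) tight else use_atom_stereo,
    use_bond_stereo = if (is.null(use_bond_stereo)) tight else use_bond_stereo,
    use_isotope = if (is.null(use_isotope)) tight else use_isotope,
    include_hydrogen = isTRUE(include_hydrogen),
    min_rounds = as.integer(min_rounds),
    max_rounds = max_rounds
  )
  structure(cfg, class = "coloring_config")
}

config_equal <- function(c1, c2) {
  keys <- c("use_atom_type", "use_bond_type", "use_charge", "use_atom_stereo",
            "use_bond_stereo", "use_isotope", "include_hydrogen")
  all(vapply(keys, function(k) identical(c1[[k]], c2[[k]]), logical(1)))
}

#' Zero-layer color of an atom
#'
#' The atom's own-information string: the seed of its full identifier and
#' the token it contributes to neighbors' expansions. Enabled layers are
#' rendered in the fixed field order element | charge | atom stereo |
#' isotope, joined by `|`; disabled layers are omitted entirely, so the
#' string is injective over the enabled information.
#'
#' @param atom A one-row atoms tibble (or list with `element`, `charge`,
#'   `stereo_parity`, `mass_delta`).
#' @param cfg A [coloring_config()].
#' @return A string.
#' @export
zero_layer_color <- function(atom, cfg) {
  zero_layer_vec(atom$element, atom$charge, atom$stereo_parity,
                 atom$mass_delta, cfg)
}

zero_layer_vec <- function(element, charge, stereo, iso, cfg) {
  parts <- list(element)
  if (cfg$use_charge) parts <- c(parts, list(paste0("c", charge)))
  if (cfg$use_atom_stereo) parts <- c(parts, list(paste0("s", stereo)))
  if (cfg$use_isotope) parts <- c(parts, list(paste0("i", iso)))
  do.call(paste, c(parts, sep = "|"))
}

# Bond descriptor token: order 1..3 verbatim, aromatic = "a"; when bond
# stereochemistry is enabled a cis/trans suffix is appended.
bond_token_vec <- function(order, cis_trans, cfg) {
  tok <- ifelse(order == 4L, "a", as.character(order))
  if (!cfg$use_bond_type) tok <- rep("b", length(order))
  if (cfg$use_bond_stereo) {
    suffix <- ifelse(cis_trans == "cis", "c",
                     ifelse(cis_trans == "trans", "t", ""))
    tok <- paste0(tok, suffix)
  }
  tok
}

# Shared precomputation for coloring, validation and recoloring: the set of
# colorable atom indices, neighbor lists restricted to that set, per-atom
# zero-layer strings and a bond-token lookup keyed "min max" (0-based).
coloring_env <- function(g, cfg) {
  atoms <- g$atoms
  keep <- if (cfg$include_hydrogen) atoms$index else atoms$index[atoms$element != "H"]
  keep_set <- logical(nrow(atoms))
  keep_set[keep + 1L] <- TRUE
  zl_all <- zero_layer_vec(atoms$element, atoms$charge, atoms$stereo_parity,
                           atoms$mass_delta, cfg)
  adj <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) adj[[i]] <- integer()
  btok <- character(0)
  if (nrow(g$bonds) > 0) {
    toks <- bond_token_vec(g$bonds$order, g$bonds$cis_trans, cfg)
    keys <- paste(pmin(g$bonds$a, g$bonds$b), pmax(g$bonds$a, g$bonds$b))
    btok <- stats::setNames(toks, keys)
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      if (keep_set[a + 1L] && keep_set[b + 1L]) {
        adj[[a + 1L]] <- c(adj[[a + 1L]], b)
        adj[[b + 1L]] <- c(adj[[b + 1L]], a)
      }
    }
  }
  adj <- lapply(adj, sort)
  list(keep = keep, adj = adj, zl = zl_all, btok = btok)
}

bond_tok <- function(env, i, j) {
  env$btok[[paste(min(i, j), max(i, j))]]
}

# Entry descriptor of a frontier atom: the sorted concatenation of the
# tokens of every bond linking it to the already-visited set at the moment
# it entered the frontier. Deterministic and permutation-invariant.
entry_descriptor <- function(env, j, visited) {
  nb <- env$adj[[j + 1L]]
  nb <- nb[visited[nb + 1L]]
  toks <- vapply(nb, function(k) bond_tok(env, j, k), character(1))
  paste(sort(toks, method = "radix"), collapse = "")
}

# One BFS shell advance for a single atom's expansion state. `state` holds
# visited (logical over all atoms), frontier (0-based indices) and entry
# (descriptor per frontier atom, aligned). Returns the updated state.
advance_frontier <- function(env, state) {
  visited <- state$visited
  visited[state$frontier + 1L] <- TRUE
  cand <- unique(unlist(lapply(state$frontier,
                               function(j) env$adj[[j + 1L]]), use.names = FALSE))
  cand <- sort(cand[!visited[cand + 1L]])
  entry <- vapply(cand, function(k) entry_descriptor(env, k, visited), character(1))
  list(visited = visited, frontier = cand, entry = entry)
}

new_state <- function(env, i, n_all) {
  visited <- logical(n_all)
  visited[i + 1L] <- TRUE
  frontier <- env$adj[[i + 1L]]
  entry <- vapply(frontier, function(j) entry_descriptor(env, j, visited),
                  character(1))
  list(visited = visited, frontier = frontier, entry = entry)
}

# The bracketed layer string contributed by the current frontier, using a
# caller-chosen token per frontier atom (zero-layer for coloring, full
# identifier for recoloring). Members are sorted lexicographically (C
# locale) so the result is canonical under atom relabeling.
layer_string <- function(state, member_tokens, open = "(", close = ")") {
  parts <- paste0(state$entry, ":", member_tokens)
  paste0(open, paste(sort(parts, method = "radix"), collapse = ","), close)
}

#' Color every atom of a molecular graph
#'
#' The neighborhood-specific BFS coloring. Each atom starts from its
#' zero-layer string; every round appends a bracketed, sorted layer of
#' (connecting-bond token, neighbor zero-layer) pairs for the atom's current
#' BFS frontier, then advances the frontier to unvisited
#' neighbors-of-frontier. All atoms get `min_rounds` rounds; afterwards only
#' atoms whose identifier is still shared keep extending, until every
#' identifier is unique or the frontier is exhausted. Symmetric atoms, which
#' see identical shells forever, necessarily end with equal identifiers.
#'
#' @param g A `mol_graph` (normalize aromatics first for cross-database
#'   stable results).
#' @param cfg A [coloring_config()].
#' @return An `atom_coloring` object with fields `zero_layer`, `full`
#'   (character vectors named by 0-based atom index), `rounds_used` and
#'   `config`.
#' @export
color_atoms <- function(g, cfg = coloring_config("loose")) {
  env <- coloring_env(g, cfg)
  keep <- env$keep
  n_all <- nrow(g$atoms)
  zl <- stats::setNames(env$zl[keep + 1L], keep)
  ids <- zl
  states <- lapply(keep, function(i) new_state(env, i, n_all))
  names(states) <- as.character(keep)
  active <- rep(TRUE, length(keep))
  rounds <- 0L
  repeat {
    if (rounds >= cfg$max_rounds) break
    if (rounds >= cfg$min_rounds) {
      shared <- ids %in% ids[duplicated(ids)]
      active <- active & shared
    }
    live <- which(active & vapply(states, function(s) length(s$frontier) > 0,
                                  logical(1)))
    if (length(live) == 0) break
    for (k in live) {
      st <- states[[k]]
      ids[k] <- paste0(ids[k], layer_string(st, env$zl[st$frontier + 1L]))
      states[[k]] <- advance_frontier(env, st)
    }
    rounds <- rounds + 1L
  }
  structure(list(zero_layer = zl, full = ids, rounds_used = rounds,
                 config = cfg),
            class = "atom_coloring")
}

#' @export
print.atom_coloring <- function(x, ...) {
  cat("<atom_coloring> ", length(x$full), " atoms, ",
      length(unique(x$full)), " color classes, ",
      x$rounds_used, " rounds (", x$config$mode, ")\n", sep = "")
  invisible(x)
}

#' Group atoms by shared identifier and test true neighborhood equivalence
#'
#' For every group of atoms sharing a full identifier, BFS shells are
#' expanded simultaneously from each member and, at every layer, the sorted
#' multisets of (zero-layer string, connecting-bond descriptor) pairs are
#' compared. Any mismatch at any layer, down to exhaustion of the whole
#' graph, marks the group invalid: its members are pseudosymmetric, not
#' symmetric.
#'
#' @param g A `mol_graph`.
#' @param colors An [color_atoms()] result for `g` under `cfg`.
#' @param cfg The same [coloring_config()] used to produce `colors`.
#' @return A `symmetry_report`: list with `groups` (list of integer vectors
#'   of 0-based atom indices partitioning the colorable atoms) and
#'   `invalid_groups` (the subset failing neighbor equivalence).
#' @export
validate_symmetry <- function(g, colors, cfg = colors$config) {
  env <- coloring_env(g, cfg)
  keep <- env$keep
  n_all <- nrow(g$atoms)
  groups <- split(keep, colors$full[as.character(keep)])
  groups <- unname(groups)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  invalid <- list()
  for (grp in groups) {
    if (length(grp) < 2) next
    states <- lapply(grp, function(i) new_state(env, i, n_all))
    ok <- TRUE
    repeat {
      sizes <- vapply(states, function(s) length(s$frontier), integer(1))
      if (any(sizes != sizes[1])) { ok <- FALSE; break }
      if (sizes[1] == 0) break
      sigs <- vapply(states, function(s) {
        layer_string(s, env$zl[s$frontier + 1L])
      }, character(1))
      if (length(unique(sigs)) > 1) { ok <- FALSE; break }
      states <- lapply(states, function(s) advance_frontier(env, s))
    }
    if (!ok) invalid <- c(invalid, list(grp))
  }
  structure(list(groups = groups, invalid_groups = invalid),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("<symmetry_report> ", length(x$groups), " classes, ",
      length(x$invalid_groups), " invalid\n", sep = "")
  invisible(x)
}

#' Recolor pseudosymmetric atoms using full-identifier layers
#'
#' For each invalid group the BFS name extension is rerun for its members,
#' but each frontier atom now contributes its full identifier instead of its
#' zero-layer string — the richer token that distinguishes neighborhoods the
#' zero-layer shortcut conflated. Extension runs in lockstep only until the
#' members' accumulated strings diverge (or the graph is exhausted; members
#' still equal at that point are left equal and must survive re-validation).
#' All other atoms' identifiers are untouched. The returned map is
#' re-validated and an error naming the offending atoms is raised if any
#' group still fails.
#'
#' @param g A `mol_graph`.
#' @param colors The [color_atoms()] result.
#' @param report The [validate_symmetry()] report for `colors`.
#' @param cfg The same [coloring_config()].
#' @return An updated `atom_coloring` that passes validation.
#' @export
recolor <- function(g, colors, report, cfg = colors$config) {
  if (length(report$invalid_groups) == 0) return(colors)
  env <- coloring_env(g, cfg)
  n_all <- nrow(g$atoms)
  full_by_idx <- character(n_all)
  full_by_idx[as.integer(names(colors$full)) + 1L] <- colors$full
  ids <- colors$full
  for (grp in report$invalid_groups) {
    states <- lapply(grp, function(i) new_state(env, i, n_all))
    acc <- ids[as.character(grp)]
    repeat {
      if (length(unique(acc)) == length(acc)) break
      live <- vapply(states, function(s) length(s$frontier) > 0, logical(1))
      if (!any(live)) break
      for (k in seq_along(grp)) {
        s <- states[[k]]
        if (length(s$frontier) == 0) next
        acc[k] <- paste0(acc[k],
                         layer_string(s, full_by_idx[s$frontier + 1L],
                                      open = "{", close = "}"))
        states[[k]] <- advance_frontier(env, s)
      }
    }
    ids[as.character(grp)] <- acc
  }
  out <- structure(list(zero_layer = colors$zero_layer, full = ids,
                        rounds_used = colors$rounds_used, config = cfg),
                   class = "atom_coloring")
  check <- validate_symmetry(g, out, cfg)
  if (length(check$invalid_groups) > 0) {
    bad <- paste(vapply(check$invalid_groups,
                        function(v) paste(v, collapse = ","), character(1)),
                 collapse = "; ")
    rlang::abort(paste0("recoloring failed to separate asymmetric atoms: ", bad))
  }
  out
}

#' Full coloring pipeline: color, validate, recolor, re-validate
#'
#' The complete procedure guaranteeing that symmetric atoms share an
#' identifier and asymmetric atoms end with unique identifiers.
#'
#' @inheritParams color_atoms
#' @return An `atom_coloring` whose classes equal the symmetry classes.
#' @export
color_molecule <- function(g, cfg = coloring_config("loose")) {
  colors <- color_atoms(g, cfg)
  report <- validate_symmetry(g, colors, cfg)
  if (length(report$invalid_groups) > 0) {
    colors <- recolor(g, colors, report, cfg)
  }
  colors
}

#' Exact automorphism orbits of a colored molecular graph
#'
#' An independent oracle for the central symmetry guarantee: computes the
#' orbits of the automorphism group of the graph restricted to colorable
#' atoms, where automorphisms must preserve adjacency, every enabled atom
#' layer and every enabled bond layer. Implemented by backtracking search
#' over vertex mappings with iterated-refinement pruning — entirely separate
#' from the BFS coloring code path.
#'
#' @param g A `mol_graph`.
#' @param cfg A [coloring_config()] (decides which layers automorphisms
#'   must respect and whether hydrogens participate).
#' @param max_atoms Feasibility bound on colorable atoms (default 30).
#' @return A list of integer vectors (0-based atom indices), the orbit
#'   partition, ordered by smallest member.
#' @export
symmetry_orbits <- function(g, cfg = coloring_config("loose"), max_atoms = 30L) {
  atoms <- g$atoms
  keep <- if (cfg$include_hydrogen) atoms$index else atoms$index[atoms$element != "H"]
  n <- length(keep)
  if (n > max_atoms) {
    rlang::abort(paste0("orbit oracle limited to ", max_atoms,
                        " colorable atoms; got ", n))
  }
  if (n == 0) return(list())
  pos <- match(keep, atoms$index)
  vinv <- zero_layer_vec(atoms$element[pos], atoms$charge[pos],
                         atoms$stereo_parity[pos], atoms$mass_delta[pos], cfg)
  emat <- matrix("", n, n)
  if (nrow(g$bonds) > 0) {
    toks <- bond_token_vec(g$bonds$order, g$bonds$cis_trans, cfg)
    for (k in seq_len(nrow(g$bonds))) {
      ia <- match(g$bonds$a[k], keep)
      ib <- match(g$bonds$b[k], keep)
      if (!is.na(ia) && !is.na(ib)) {
        emat[ia, ib] <- toks[k]
        emat[ib, ia] <- toks[k]
      }
    }
  }
  # iterated refinement (stable neighborhood signatures) for pruning only
  cls <- match(vinv, unique(vinv))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- which(emat[i, ] != "")
      paste(cls[i],
            paste(sort(paste0(emat[i, nb], ":", cls[nb]), method = "radix"),
                  collapse = ","))
    }, character(1))
    newcls <- match(sig, unique(sig))
    if (identical(newcls, cls)) break
    cls <- newcls
  }
  compatible <- function(i, j) cls[i] == cls[j]
  # first-solution backtracking search for an automorphism with i0 -> j0
  find_auto <- function(i0, j0) {
    perm <- rep(NA_integer_, n)
    used <- logical(n)
    assign_order <- order(cls, seq_len(n))
    assign_order <- c(i0, setdiff(assign_order, i0))
    bt <- function(d) {
      if (d > n) return(perm)
      i <- assign_order[d]
      cands <- if (i == i0) j0 else which(!used & cls == cls[i])
      for (j in cands) {
        ok <- TRUE
        for (p in assign_order[seq_len(d - 1)]) {
          if (emat[i, p] != emat[j, perm[p]]) { ok <- FALSE; break }
        }
        if (!ok) next
        perm[i] <<- j; used[j] <<- TRUE
        res <- bt(d + 1)
        if (!is.null(res)) return(res)
        perm[i] <<- NA_integer_; used[j] <<- FALSE
      }
      NULL
    }
    bt(1)
  }
  parent <- seq_len(n)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find_root(i); rj <- find_root(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (c0 in unique(cls)) {
    members <- which(cls == c0)
    r <- members[1]
    for (j in members[-1]) {
      if (find_root(r) == find_root(j)) next
      perm <- find_auto(r, j)
      if (!is.null(perm)) {
        for (i in seq_len(n)) union2(i, perm[i])
      }
    }
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  orb <- lapply(unique(roots), function(rt) sort(keep[roots == rt]))
  orb[order(vapply(orb, min, integer(1)))]
}

#' Color classes of an atom coloring as an orbit-style partition
#'
#' @param colors An `atom_coloring`.
#' @return A list of sorted integer vectors of 0-based atom indices sharing
#'   a full identifier, ordered by smallest member.
#' @export
color_classes <- function(colors) {
  idx <- as.integer(names(colors$full))
  cl <- split(idx, colors$full)
  cl <- lapply(unname(cl), sort)
  cl[order(vapply(cl, min, integer(1)))]
}
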