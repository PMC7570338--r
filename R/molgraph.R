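#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Atom-block charge column codes of the V2000 format (column value -> charge).
.molfile_charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                           `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# Default valences used when adding implicit hydrogens. R-group tokens and
# metals deliberately carry valence 0: they are colorable placeholders that
# never receive hydrogens. Effective valence = default + formal charge.
.default_valences <- c(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = 3L, S = 2L, Cl = 1L, Se = 2L, As = 3L, Br = 1L, I = 1L,
  R = 0L, `R#` = 0L, `*` = 0L, X = 0L,
  Li = 0L, Na = 0L, K = 0L, Rb = 0L, Cs = 0L, Mg = 0L, Ca = 0L, Sr = 0L,
  Ba = 0L, Fe = 0L, Zn = 0L, Cu = 0L, Mn = 0L, Co = 0L, Ni = 0L, Mo = 0L,
  W = 0L, V = 0L, Cr = 0L, Cd = 0L, Hg = 0L, Ag = 0L, Au = 0L, Pt = 0L,
  Pd = 0L, Al = 0L, Sn = 0L, Pb = 0L, Ti = 0L
)

#' Construct a molecular graph
#'
#' A `mol_graph` is the container every algorithm in molcolor operates on:
#' an atoms tibble, a bonds tibble, and the originating compound identifier.
#' Atom indices are 0-based internally; molfile serialization converts to the
#' 1-based convention of the V2000 format.
#'
#' @param atoms Tibble with columns `index` (0-based integer), `element`
#'   (periodic-table symbol or R-group token), `charge` (elementary charge
#'   units), `stereo_parity` (molfile atom-block code), `mass_delta`
#'   (isotope offset, molfile convention), `x`, `y`, `z` (coordinates, used
#'   only for stereo geometry), `is_aromatic` (set by perception).
#' @param bonds Tibble with columns `a`, `b` (0-based endpoint indices),
#'   `order` (1, 2, 3, or 4 = aromatic), `wedge` (molfile stereo code),
#'   `cis_trans` (`"none"`, `"cis"`, or `"trans"`, set by perception).
#' @param source_id Originating compound identifier string.
#'
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms = NULL, bonds = NULL, source_id = "") {
  empty_atoms <- tibble(
    index = integer(), element = character(), charge = integer(),
    stereo_parity = integer(), mass_delta = integer(),
    x = double(), y = double(), z = double(), is_aromatic = logical()
  )
  empty_bonds <- tibble(
    a = integer(), b = integer(), order = integer(),
    wedge = integer(), cis_trans = character()
  )
  if (is.null(atoms)) atoms <- empty_atoms
  if (is.null(bonds)) bonds <- empty_bonds
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  for (col in names(empty_atoms)) {
    if (!col %in% names(atoms)) {
      atoms[[col]] <- if (nrow(atoms) == 0) empty_atoms[[col]] else
        switch(col,
               charge = 0L, stereo_parity = 0L, mass_delta = 0L,
               x = 0, y = 0, z = 0, is_aromatic = FALSE,
               abort(paste0("atoms is missing required column '", col, "'")))
    }
  }
  for (col in names(empty_bonds)) {
    if (!col %in% names(bonds)) {
      bonds[[col]] <- if (nrow(bonds) == 0) empty_bonds[[col]] else
        switch(col,
               wedge = 0L, cis_trans = "none",
               abort(paste0("bonds is missing required column '", col, "'")))
    }
  }
  atoms <- atoms[names(empty_atoms)]
  bonds <- bonds[names(empty_bonds)]
  atoms$index <- as.integer(atoms$index)
  atoms$charge <- as.integer(atoms$charge)
  atoms$stereo_parity <- as.integer(atoms$stereo_parity)
  atoms$mass_delta <- as.integer(atoms$mass_delta)
  bonds$a <- as.integer(bonds$a)
  bonds$b <- as.integer(bonds$b)
  bonds$order <- as.integer(bonds$order)
  bonds$wedge <- as.integer(bonds$wedge)
  g <- structure(list(atoms = atoms, bonds = bonds,
                      source_id = as.character(source_id)[1]),
                 class = "mol_graph")
  validate_mol_graph(g)
}

#' Validate the invariants of a molecular graph
#'
#' Checks index uniqueness, non-empty element symbols, bond endpoint
#' validity, the absence of self bonds and of duplicate bonds per unordered
#' atom pair. Called by the constructor and usable after any mutation.
#'
#' @param g A `mol_graph`.
#' @return `g`, invisibly unchanged, or an error describing the violation.
#' @export
validate_mol_graph <- function(g) {
  a <- g$atoms; b <- g$bonds
  if (anyDuplicated(a$index)) abort("atom indices must be unique")
  if (nrow(a) > 0 && any(!nzchar(a$element))) abort("atom elements must be non-empty")
  if (nrow(b) > 0) {
    if (any(b$a == b$b)) abort("self bonds are not allowed")
    ok <- b$a %in% a$index & b$b %in% a$index
    if (!all(ok)) {
      abort(paste0("bond ", which(!ok)[1], " references a nonexistent atom"))
    }
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) abort("duplicate bond between one atom pair")
    if (!all(b$order %in% 1:4)) abort("bond orders must be in 1..4")
  }
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", if (nzchar(x$source_id)) x$source_id else "(unnamed)",
      ": ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param g A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

# Adjacency as a list indexed by position (atom index + 1); each entry is an
# integer vector of 0-based neighbor indices. Symmetric by construction.
adjacency_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      adj[[a + 1L]] <- c(adj[[a + 1L]], b)
      adj[[b + 1L]] <- c(adj[[b + 1L]], a)
    }
  }
  adj
}

# Bond attribute lookup keyed "min max" (0-based); returns a named list of
# vectors aligned with g$bonds rows.
bond_lookup <- function(g) {
  key <- paste(pmin(g$bonds$a, g$bonds$b), pmax(g$bonds$a, g$bonds$b))
  stats::setNames(seq_along(key), key)
}

#' Parse an MDL molfile (V2000) into a molecular graph
#'
#' Reads the counts line, atom block, bond block, and the `M  CHG` / `M  ISO`
#' property lines. Property-block charges override the atom-block charge
#' column, per the molfile standard: the presence of any `M  CHG` line resets
#' all atom-block charges before applying the listed values. Molfile 1-based
#' atom numbers are mapped to 0-based internal indices.
#'
#' @param text A molfile document: a single string (possibly with embedded
#'   newlines) or a character vector of lines.
#' @param source_id Compound identifier; defaults to the molfile title line.
#' @return A [mol_graph()].
#' @export
parse_molfile <- function(text, source_id = NULL) {
  if (length(text) == 1 && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  if (length(lines) < 4) abort("molfile truncated: no counts line (line 4)")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    abort("V3000 molfiles are not supported; supply a V2000 document")
  }
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    abort("malformed counts line at line 4")
  }
  atom_lines <- lines[4 + seq_len(natoms)]
  if (natoms > 0 && (length(atom_lines) < natoms || anyNA(atom_lines))) {
    abort(paste0("truncated atom block: expected ", natoms, " atoms"))
  }
  parse_atom <- function(ln, lineno) {
    x <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(ln, 21, 30)))
    el <- trimws(substr(ln, 32, 34))
    md <- suppressWarnings(as.integer(substr(ln, 35, 36)))
    cc <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    sp <- suppressWarnings(as.integer(substr(ln, 40, 42)))
    if (is.na(x) || is.na(y) || is.na(z) || !nzchar(el)) {
      abort(paste0("malformed atom line at line ", lineno))
    }
    list(x = x, y = y, z = z, element = el,
         mass_delta = if (is.na(md)) 0L else md,
         charge_code = if (is.na(cc)) 0L else cc,
         stereo_parity = if (is.na(sp)) 0L else sp)
  }
  atoms <- lapply(seq_len(natoms), function(i) parse_atom(atom_lines[i], 4 + i))
  bond_lines <- lines[4 + natoms + seq_len(nbonds)]
  if (nbonds > 0 && (length(bond_lines) < nbonds || anyNA(bond_lines))) {
    abort(paste0("truncated bond block: expected ", nbonds, " bonds"))
  }
  parse_bond <- function(ln, lineno) {
    a <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    b <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    w <- suppressWarnings(as.integer(substr(ln, 10, 12)))
    if (is.na(a) || is.na(b) || is.na(o)) {
      abort(paste0("malformed bond line at line ", lineno))
    }
    if (a < 1 || a > natoms || b < 1 || b > natoms) {
      abort(paste0("bond references nonexistent atom at line ", lineno))
    }
    list(a = a - 1L, b = b - 1L, order = o, wedge = if (is.na(w)) 0L else w)
  }
  bonds <- lapply(seq_len(nbonds), function(i) parse_bond(bond_lines[i], 4 + natoms + i))

  charges <- vapply(atoms, function(a) {
    code <- as.character(a$charge_code)
    if (code %in% names(.molfile_charge_codes)) .molfile_charge_codes[[code]] else 0L
  }, integer(1))
  mass_deltas <- vapply(atoms, function(a) a$mass_delta, integer(1))

  prop_lines <- lines[seq_along(lines) > 4 + natoms + nbonds]
  parse_prop_pairs <- function(ln) {
    n <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (is.na(n) || n < 1) return(NULL)
    out <- matrix(NA_integer_, nrow = n, ncol = 2)
    for (k in seq_len(n)) {
      off <- 10 + (k - 1) * 8
      out[k, 1] <- suppressWarnings(as.integer(substr(ln, off, off + 3)))
      out[k, 2] <- suppressWarnings(as.integer(substr(ln, off + 4, off + 7)))
    }
    out
  }
  chg_lines <- grep("^M  CHG", prop_lines, value = TRUE)
  iso_lines <- grep("^M  ISO", prop_lines, value = TRUE)
  if (length(chg_lines) > 0) {
    charges[] <- 0L
    for (ln in chg_lines) {
      prs <- parse_prop_pairs(ln)
      for (k in seq_len(nrow(prs))) {
        idx <- prs[k, 1]
        if (is.na(idx) || idx < 1 || idx > natoms) {
          abort("M  CHG line references a nonexistent atom")
        }
        charges[idx] <- prs[k, 2]
      }
    }
  }
  if (length(iso_lines) > 0) {
    mass_deltas[] <- 0L
    for (ln in iso_lines) {
      prs <- parse_prop_pairs(ln)
      for (k in seq_len(nrow(prs))) {
        idx <- prs[k, 1]
        if (is.na(idx) || idx < 1 || idx > natoms) {
          abort("M  ISO line references a nonexistent atom")
        }
        mass_deltas[idx] <- prs[k, 2]
      }
    }
  }

  title <- trimws(lines[1])
  if (is.null(source_id)) source_id <- title
  atoms_tb <- tibble(
    index = seq_len(natoms) - 1L,
    element = vapply(atoms, `[[`, character(1), "element"),
    charge = charges,
    stereo_parity = vapply(atoms, `[[`, integer(1), "stereo_parity"),
    mass_delta = mass_deltas,
    x = vapply(atoms, `[[`, double(1), "x"),
    y = vapply(atoms, `[[`, double(1), "y"),
    z = vapply(atoms, `[[`, double(1), "z"),
    is_aromatic = rep(FALSE, natoms)
  )
  bonds_tb <- tibble(
    a = vapply(bonds, `[[`, integer(1), "a"),
    b = vapply(bonds, `[[`, integer(1), "b"),
    order = vapply(bonds, `[[`, integer(1), "order"),
    wedge = vapply(bonds, `[[`, integer(1), "wedge"),
    cis_trans = rep("none", nbonds)
  )
  mol_graph(atoms_tb, bonds_tb, source_id = source_id)
}

#' Read a molfile from disk
#' @param path Path to a `.mol` file.
#' @param source_id Compound identifier; defaults to the file's title line,
#'   falling back to the file name without extension.
#' @return A [mol_graph()].
#' @export
read_molfile <- function(path, source_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  g <- parse_molfile(lines, source_id = source_id)
  if (!nzchar(g$source_id)) {
    g$source_id <- sub("\\.mol$", "", basename(path))
  }
  g
}

#' Serialize a molecular graph to MDL molfile (V2000) text
#'
#' Charges and isotope offsets are written as `M  CHG` / `M  ISO` property
#' lines (the atom-block charge column is left 0), which is lossless under
#' the property-block-overrides rule honored by [parse_molfile()].
#'
#' @param g A `mol_graph`.
#' @return A single string containing the molfile document.
#' @export
write_molfile <- function(g) {
  natoms <- nrow(g$atoms); nbonds <- nrow(g$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds)
  atom_lines <- vapply(seq_len(natoms), function(i) {
    a <- g$atoms[i, ]
    sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d%3d  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element, 0L, 0L, a$stereo_parity)
  }, character(1))
  bond_lines <- vapply(seq_len(nbonds), function(k) {
    b <- g$bonds[k, ]
    sprintf("%3d%3d%3d%3d  0  0  0", b$a + 1L, b$b + 1L, b$order, b$wedge)
  }, character(1))
  prop_block <- function(tag, idx, val) {
    out <- character(0)
    while (length(idx) > 0) {
      take <- seq_len(min(8, length(idx)))
      pairs <- paste0(sprintf("%4d%4d", idx[take], val[take]), collapse = "")
      out <- c(out, sprintf("M  %s%3d%s", tag, length(take), pairs))
      idx <- idx[-take]; val <- val[-take]
    }
    out
  }
  chg <- which(g$atoms$charge != 0L)
  iso <- which(g$atoms$mass_delta != 0L)
  props <- c(
    prop_block("CHG", chg, g$atoms$charge[chg]),
    prop_block("ISO", iso, g$atoms$mass_delta[iso])
  )
  paste(c(g$source_id, "  molcolor", "", counts,
          atom_lines, bond_lines, props, "M  END"),
        collapse = "\n")
}

#' Serialize a molecular graph to the molcolor JSON dialect
#'
#' The dialect is a single object with keys `source_id`, `atoms` (array of
#' atom objects) and `bonds` (array of bond objects); see
#' `system.file("extdata/mol-graph-schema.json", package = "molcolor")`.
#'
#' @param g A `mol_graph`.
#' @return A JSON string.
#' @export
mol_to_json <- function(g) {
  doc <- list(source_id = g$source_id,
              atoms = g$atoms, bonds = g$bonds)
  as.character(jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA))
}

#' Deserialize a molecular graph from the molcolor JSON dialect
#' @param text A JSON string produced by [mol_to_json()] or conforming to the
#'   shipped schema.
#' @return A [mol_graph()].
#' @export
mol_from_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyDataFrame = TRUE),
                  error = function(e) abort(paste0("invalid JSON: ", conditionMessage(e))))
  if (!is.list(doc) || !all(c("atoms", "bonds") %in% names(doc))) {
    abort("JSON document must contain 'atoms' and 'bonds' keys")
  }
  atoms <- doc$atoms; bonds <- doc$bonds
  if (length(atoms) == 0) atoms <- NULL
  if (length(bonds) == 0) bonds <- NULL
  if (!is.null(atoms) && !all(c("index", "element") %in% names(atoms))) {
    abort("each atom object requires 'index' and 'element'")
  }
  if (!is.null(bonds) && !all(c("a", "b", "order") %in% names(bonds))) {
    abort("each bond object requires 'a', 'b' and 'order'")
  }
  mol_graph(atoms, bonds,
            source_id = if (!is.null(doc$source_id)) doc$source_id else "")
}

#' Compare two molecular graphs field by field
#'
#' Equality up to coordinate tolerance; atom and bond order matter (use after
#' round trips, not as a structural isomorphism test).
#'
#' @param g1,g2 `mol_graph` objects.
#' @param tol Coordinate tolerance.
#' @return Logical.
#' @export
mol_graph_equal <- function(g1, g2, tol = 1e-9) {
  a1 <- g1$atoms; a2 <- g2$atoms
  b1 <- g1$bonds; b2 <- g2$bonds
  if (nrow(a1) != nrow(a2) || nrow(b1) != nrow(b2)) return(FALSE)
  num_cols <- c("x", "y", "z")
  id_cols <- setdiff(names(a1), num_cols)
  if (!identical(as.data.frame(a1[id_cols]), as.data.frame(a2[id_cols]))) return(FALSE)
  if (nrow(a1) > 0 &&
      max(abs(as.matrix(a1[num_cols]) - as.matrix(a2[num_cols]))) > tol) return(FALSE)
  identical(as.data.frame(b1), as.data.frame(b2))
}

#' Add implicit hydrogens to every heavy atom
#'
#' Each heavy atom gains `max(0, default_valence + charge - bond_order_sum)`
#' hydrogens, bonded by single bonds and appended after all heavy atoms, so
#' original indices are unchanged. Aromatic bonds (order 4) contribute 1.5 to
#' the order sum, floored per atom after summation, which reproduces one
#' hydrogen per benzene carbon without Kekule information. The operation is
#' idempotent.
#'
#' @param g A `mol_graph`.
#' @return A `mol_graph` with explicit hydrogens.
#' @export
add_implicit_hydrogens <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0) return(g)
  unknown <- setdiff(unique(g$atoms$element), names(.default_valences))
  if (length(unknown) > 0) {
    abort(paste0("no default valence for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  order_sum <- numeric(n)
  if (nrow(g$bonds) > 0) {
    contrib <- ifelse(g$bonds$order == 4L, 1.5, as.numeric(g$bonds$order))
    for (k in seq_len(nrow(g$bonds))) {
      order_sum[g$bonds$a[k] + 1L] <- order_sum[g$bonds$a[k] + 1L] + contrib[k]
      order_sum[g$bonds$b[k] + 1L] <- order_sum[g$bonds$b[k] + 1L] + contrib[k]
    }
  }
  order_sum <- floor(order_sum)
  valence <- .default_valences[g$atoms$element] + g$atoms$charge
  n_h <- pmax(0L, as.integer(valence - order_sum))
  n_h[g$atoms$element == "H"] <- 0L
  total_h <- sum(n_h)
  if (total_h == 0) return(g)
  h_idx <- n - 1L + seq_len(total_h)
  parents <- rep(g$atoms$index, n_h)
  h_atoms <- tibble(
    index = h_idx, element = "H", charge = 0L, stereo_parity = 0L,
    mass_delta = 0L,
    x = g$atoms$x[parents + 1L], y = g$atoms$y[parents + 1L],
    z = g$atoms$z[parents + 1L], is_aromatic = FALSE
  )
  h_bonds <- tibble(a = parents, b = h_idx, order = 1L, wedge = 0L,
                    cis_trans = "none")
  mol_graph(dplyr::bind_rows(g$atoms, h_atoms),
            dplyr::bind_rows(g$bonds, h_bonds),
            source_id = g$source_id)
}

#' Connected components of a molecular graph
#'
#' Multi-fragment entries (salts) are legal; algorithms that are
#' per-component use this split. Uses igraph's component machinery.
#'
#' @param g A `mol_graph`.
#' @return A list of integer vectors of 0-based atom indices, one per
#'   component, each sorted ascending; components ordered by smallest member.
#' @export
graph_components <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0) return(list())
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(g$bonds) > 0) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$a + 1L, g$bonds$b + 1L))
  }
  comp <- igraph::components(ig)$membership
  out <- lapply(sort(unique(comp)), function(cc) sort(which(comp == cc) - 1L))
  out[order(vapply(out, min, integer(1)))]
}
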