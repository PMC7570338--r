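#' Derive the ordered compound coloring identifier from an atom coloring
#'
#' Atoms sharing a full identifier collapse into one color class; each class
#' renders as `(count)[color]`; the rendered substrings are sorted
#' lexicographically as whole strings (so counts participate in the order)
#' and concatenated. Identical molecules up to atom reordering yield
#' identical text. Square brackets occurring inside a color string are
#' escaped with a backslash so parsing is unambiguous.
#'
#' @param colors A finalized `atom_coloring` (from [color_molecule()]).
#' @param mode Identifier mode label; defaults to the coloring config's mode.
#' @return A `compound_identifier`: list with `text`, `classes` (tibble of
#'   `color`, `count` in canonical order) and `mode`.
#' @export
compound_identifier <- function(colors, mode = colors$config$mode) {
  if (length(colors$full) == 0) {
    rlang::abort("empty color map: compound has no colorable atoms")
  }
  tab <- table(colors$full)
  esc <- function(s) gsub("(\\[|\\])", "\\\\\\1", s)
  rendered <- paste0("(", as.integer(tab), ")[", esc(names(tab)), "]")
  ord <- order(rendered, method = "radix")
  classes <- tibble::tibble(color = names(tab)[ord],
                            count = as.integer(tab)[ord])
  structure(list(text = paste(rendered[ord], collapse = ""),
                 classes = classes, mode = mode),
            class = "compound_identifier")
}

#' @export
print.compound_identifier <- function(x, ...) {
  cat("<compound_identifier> [", x$mode, "] ", nrow(x$classes),
      " classes, ", sum(x$classes$count), " atoms\n", sep = "")
  cat(substr(x$text, 1, 70),
      if (nchar(x$text) > 70) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Compound coloring identifier of a molecular graph
#'
#' Convenience wrapper: runs the full coloring pipeline and renders the
#' compound identifier. Normalize aromatics first when comparing across
#' databases.
#'
#' @param g A `mol_graph`.
#' @param cfg A [coloring_config()].
#' @return A `compound_identifier`.
#' @export
identify_compound <- function(g, cfg = coloring_config("loose")) {
  compound_identifier(color_molecule(g, cfg))
}

#' Parse a compound coloring identifier string
#'
#' Inverse of the `(n)[color]` rendering: `parse_identifier(x$text)`
#' reproduces `x$classes`, and rendering the parsed classes reproduces the
#' canonical string. Escaped brackets inside colors are unescaped.
#'
#' @param text An identifier string.
#' @return A tibble with columns `color` and `count`.
#' @export
parse_identifier <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  pos <- 1L
  n <- nchar(text)
  colors <- character(0); counts <- integer(0)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^\\((\\d+)\\)\\[((?:[^][\\\\]|\\\\.)*)\\]", rest))[[1]]
    if (length(m) == 0) {
      rlang::abort(paste0("cannot parse identifier at position ", pos,
                          ": '", substr(rest, 1, 20), "'"))
    }
    count <- as.integer(m[2])
    if (count < 1) {
      rlang::abort(paste0("class count must be >= 1 at position ", pos))
    }
    colors <- c(colors, gsub("\\\\(\\[|\\])", "\\1", m[3]))
    counts <- c(counts, count)
    pos <- pos + nchar(m[1])
  }
  if (length(colors) == 0) rlang::abort("empty identifier string")
  tibble::tibble(color = colors, count = counts)
}

#' Stable short hash of an identifier string
#'
#' Identifier strings are unbounded; this 32-bit FNV-1a hash, rendered as 8
#' hex digits, is provided for display and indexing only. Equality of
#' identifiers is always defined on the full string, never the hash.
#'
#' @param text A character vector of identifier strings.
#' @return A character vector of 8-digit hex hashes.
#' @export
color_hash <- function(text) {
  # 32-bit arithmetic carried in doubles, split into 16-bit halves to stay
  # inside exact double precision
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  mul32 <- function(a, p) {
    hi <- (a %/% 65536 * p) %% 65536
    (hi * 65536 + (a %% 65536) * p) %% 4294967296
  }
  vapply(text, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- mul32(xor32(h, b), 16777619)
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

#' Index a compound collection by compound coloring identifier
#'
#' Colors every compound under one configuration and groups compound ids by
#' identifier text. Keys holding more than one id form the within-database
#' ambiguity report: structurally indistinguishable entries at this
#' specificity. A compound whose coloring fails is skipped with a warning.
#'
#' @param compounds A named list of `mol_graph` objects (names are compound
#'   ids), pre-normalized for aromatics.
#' @param cfg A [coloring_config()].
#' @return A `compound_index`: tibble with columns `identifier` and `ids`
#'   (list-column of compound id vectors), with the config in
#'   `attr(, "config")`.
#' @export
build_index <- function(compounds, cfg = coloring_config("loose")) {
  ids <- names(compounds)
  if (is.null(ids) || any(!nzchar(ids))) {
    rlang::abort("compounds must be a named list of mol_graph objects")
  }
  keys <- character(length(compounds))
  ok <- logical(length(compounds))
  for (i in seq_along(compounds)) {
    keys[i] <- tryCatch({
      ok[i] <- TRUE
      identify_compound(compounds[[i]], cfg)$text
    }, error = function(e) {
      ok[i] <<- FALSE
      rlang::warn(paste0("skipping compound '", ids[i], "': ",
                         conditionMessage(e)))
      NA_character_
    })
  }
  keep <- which(ok)
  tb <- tibble::tibble(identifier = keys[keep], id = ids[keep])
  out <- tb |>
    dplyr::group_by(.data$identifier) |>
    dplyr::summarise(ids = list(sort(.data$id)), .groups = "drop") |>
    dplyr::arrange(.data$identifier)
  attr(out, "config") <- cfg
  class(out) <- c("compound_index", class(out))
  out
}

#' Within-database ambiguity report of an index
#'
#' @param index A [build_index()] result.
#' @return The subset of index rows whose identifier maps to more than one
#'   compound id.
#' @export
ambiguous_identifiers <- function(index) {
  index[lengths(index$ids) > 1, ]
}
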