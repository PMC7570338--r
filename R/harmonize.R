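#' Parse an Enzyme Commission number
#'
#' Accepts 1 to 4 dot-separated tokens; each token is a positive integer or
#' the wildcard `-`, and wildcards may only pad the suffix (the `2.3.1.-`
#' style both databases print). The specified depth is the count of leading
#' non-wildcard tokens.
#'
#' @param text EC string, e.g. `"1.1.1.1"` or `"2.3.1.-"`.
#' @return A list with `levels` (character tokens) and `depth` (integer), or
#'   `NULL` with a warning when the string is unparseable.
#' @export
ec_parse <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  toks <- strsplit(text, ".", fixed = TRUE)[[1]]
  ok_tok <- grepl("^([0-9]+|-)$", toks)
  wild <- toks == "-"
  suffix_ok <- !is.unsorted(wild)  # wildcards only after all numbers
  if (length(toks) < 1 || length(toks) > 4 || !all(ok_tok) || !suffix_ok ||
      all(wild)) {
    rlang::warn(paste0("unparseable EC number '", text, "'; treated as no EC"))
    return(NULL)
  }
  list(levels = toks, depth = sum(!wild))
}

# agreement of two parsed ECs at >= k leading levels
ec_agree <- function(e1, e2, k) {
  if (is.null(e1) || is.null(e2)) return(FALSE)
  if (e1$depth < k || e2$depth < k) return(FALSE)
  identical(e1$levels[seq_len(k)], e2$levels[seq_len(k)])
}

#' Read a toy database directory
#'
#' Layout mirrors how compound databases distribute entries: one molfile per
#' compound named `<compound_id>.mol`, plus optional `reactions.tsv`
#' (columns `reaction_id`, `ec` — comma-separated list, `-` wildcards
#' allowed — and `participants`, semicolon-separated compound ids) and
#' `crossrefs.tsv` (columns `compound_id`, `namespace`, `foreign_id`).
#'
#' @param dir Database directory path.
#' @return A list with `compounds` (named list of `mol_graph`), `reactions`
#'   and `crossrefs` tibbles, and `name`.
#' @export
read_database <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mol$", full.names = TRUE))
  compounds <- lapply(files, read_molfile)
  names(compounds) <- vapply(compounds, function(g) g$source_id, character(1))
  read_tsv0 <- function(path, cols) {
    if (!file.exists(path)) {
      return(tibble::as_tibble(stats::setNames(
        rep(list(character(0)), length(cols)), cols)))
    }
    tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character")
    missing <- setdiff(cols, names(tb))
    if (length(missing) > 0) {
      rlang::abort(paste0(basename(path), " is missing column(s): ",
                          paste(missing, collapse = ", ")))
    }
    tibble::as_tibble(tb[cols])
  }
  list(
    compounds = compounds,
    reactions = read_tsv0(file.path(dir, "reactions.tsv"),
                          c("reaction_id", "ec", "participants")),
    crossrefs = read_tsv0(file.path(dir, "crossrefs.tsv"),
                          c("compound_id", "namespace", "foreign_id")),
    name = basename(dir)
  )
}

#' Match compounds across two identifier indexes
#'
#' Emits one candidate correspondence pair per (left compound, right
#' compound) sharing an identifier key — the full Cartesian product within a
#' key, so one-to-many mappings stay visible for downstream disambiguation.
#'
#' @param index_left,index_right [build_index()] results built under the
#'   same coloring configuration.
#' @param mode Label recorded on the emitted pairs (`"tight"` or `"loose"`).
#' @return A tibble with columns `left_id`, `right_id`, `mode`.
#' @export
match_compounds <- function(index_left, index_right,
                            mode = attr(index_left, "config")$mode) {
  cfgL <- attr(index_left, "config"); cfgR <- attr(index_right, "config")
  if (!config_equal(cfgL, cfgR)) {
    rlang::abort("indexes were built under different coloring configurations")
  }
  shared <- intersect(index_left$identifier, index_right$identifier)
  if (length(shared) == 0) {
    return(tibble::tibble(left_id = character(0), right_id = character(0),
                          mode = character(0)))
  }
  rows <- lapply(shared, function(key) {
    l <- index_left$ids[[match(key, index_left$identifier)]]
    r <- index_right$ids[[match(key, index_right$identifier)]]
    tidyr::expand_grid(left_id = l, right_id = r)
  })
  out <- dplyr::bind_rows(rows)
  out$mode <- mode
  dplyr::arrange(out, .data$left_id, .data$right_id)
}

#' Confirm candidate pairs with database cross-references
#'
#' A pair is id-confirmed when the two compounds share at least one
#' (namespace, foreign id) entry, or when one side's foreign id in the
#' partner's namespace equals the partner's own compound id (the
#' direct-link case where one database cites the other's native ids).
#'
#' @param pairs A tibble of pairs (from [match_compounds()]).
#' @param crossrefs_left,crossrefs_right Tibbles with columns
#'   `compound_id`, `namespace`, `foreign_id`.
#' @return `pairs` with a logical `id_confirmed` column.
#' @export
confirm_with_ids <- function(pairs, crossrefs_left, crossrefs_right) {
  confirmed <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$left_id[i]; r <- pairs$right_id[i]
    xl <- crossrefs_left[crossrefs_left$compound_id == l, ]
    xr <- crossrefs_right[crossrefs_right$compound_id == r, ]
    shared <- nrow(dplyr::inner_join(xl[c("namespace", "foreign_id")],
                                     xr[c("namespace", "foreign_id")],
                                     by = c("namespace", "foreign_id"))) > 0
    direct <- any(xr$foreign_id == l) || any(xl$foreign_id == r)
    confirmed[i] <- shared || direct
  }
  pairs$id_confirmed <- confirmed
  pairs
}

# map compound id -> list of parsed ECs over all reactions it joins, plus a
# participation flag
compound_ec_map <- function(reactions) {
  has_rxn <- character(0)
  ecs <- list()
  for (i in seq_len(nrow(reactions))) {
    parts <- strsplit(reactions$participants[i], ";", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    ec_strings <- strsplit(reactions$ec[i], ",", fixed = TRUE)[[1]]
    ec_strings <- trimws(ec_strings[nzchar(trimws(ec_strings))])
    parsed <- Filter(Negate(is.null), lapply(ec_strings, ec_parse))
    has_rxn <- union(has_rxn, parts)
    for (p in parts) {
      ecs[[p]] <- c(ecs[[p]], parsed)
    }
  }
  list(has_rxn = has_rxn, ecs = ecs)
}

#' Validate candidate pairs with reaction EC numbers
#'
#' Matched compounds should take part in the same kind of reaction. Per
#' pair: if either side participates in no reaction the status is
#' `no_reactions`; otherwise `in_reactions`, upgraded to `ec3_verified`
#' when some EC (specified to at least 3 levels) attached to a left-side
#' reaction agrees with a right-side EC on the first three levels, and to
#' `ec4_verified` when two fully specified ECs agree on all four. A
#' wildcard fourth level therefore caps verification at three levels.
#'
#' @param pairs A tibble of pairs.
#' @param reactions_left,reactions_right Reaction tibbles (see
#'   [read_database()]).
#' @return `pairs` with a `reaction_status` column.
#' @export
validate_with_ec <- function(pairs, reactions_left, reactions_right) {
  ml <- compound_ec_map(reactions_left)
  mr <- compound_ec_map(reactions_right)
  status <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$left_id[i]; r <- pairs$right_id[i]
    if (!(l %in% ml$has_rxn) || !(r %in% mr$has_rxn)) {
      status[i] <- "no_reactions"
      next
    }
    el <- ml$ecs[[l]]; er <- mr$ecs[[r]]
    ec3 <- FALSE; ec4 <- FALSE
    for (a in el) {
      for (b in er) {
        if (ec_agree(a, b, 3L)) ec3 <- TRUE
        if (a$depth == 4L && b$depth == 4L && ec_agree(a, b, 4L)) ec4 <- TRUE
      }
    }
    status[i] <- if (ec4) "ec4_verified" else if (ec3) "ec3_verified" else "in_reactions"
  }
  pairs$reaction_status <- status
  pairs
}

#' Summarize tight and loose harmonization runs
#'
#' Deduplicates pairs matched under both modes (the tight claim wins),
#' counts pairs per mode, id confirmation and reaction status, and reports
#' the one-to-many ambiguity counts. On identical normalized inputs, loose
#' pairs are a superset of tight pairs, so deduplication never loses a
#' correspondence.
#'
#' @param pairs_tight,pairs_loose Pair tibbles carrying `mode`,
#'   `id_confirmed` and `reaction_status` columns; either may be `NULL` for
#'   a single-mode run.
#' @return A `harmonization_report`: list with `pairs` (deduplicated,
#'   tight-wins), `counts` (tibble mode x id_confirmed x reaction_status
#'   with `n`) and `ambiguity` (tibble of one-to-many counts per side and
#'   mode).
#' @export
harmonization_report <- function(pairs_tight = NULL, pairs_loose = NULL) {
  empty <- tibble::tibble(left_id = character(0), right_id = character(0),
                          mode = character(0), id_confirmed = logical(0),
                          reaction_status = character(0))
  fill_cols <- function(p) {
    if (is.null(p)) return(empty)
    if (!"id_confirmed" %in% names(p)) p$id_confirmed <- NA
    if (!"reaction_status" %in% names(p)) p$reaction_status <- NA_character_
    p
  }
  pt <- fill_cols(pairs_tight); pl <- fill_cols(pairs_loose)
  key_t <- paste(pt$left_id, pt$right_id, sep = "\r")
  key_l <- paste(pl$left_id, pl$right_id, sep = "\r")
  pl <- pl[!(key_l %in% key_t), ]
  pairs <- dplyr::bind_rows(pt, pl)
  counts <- pairs |>
    dplyr::count(.data$mode, .data$id_confirmed, .data$reaction_status,
                 name = "n") |>
    dplyr::arrange(.data$mode, .data$id_confirmed, .data$reaction_status)
  amb <- function(p, side, other) {
    if (nrow(p) == 0) {
      return(tibble::tibble(mode = character(0), side = character(0),
                            n_multi = integer(0)))
    }
    p |>
      dplyr::group_by(.data$mode, id = .data[[side]]) |>
      dplyr::summarise(k = dplyr::n_distinct(.data[[other]]),
                       .groups = "drop") |>
      dplyr::group_by(.data$mode) |>
      dplyr::summarise(n_multi = sum(.data$k > 1), .groups = "drop") |>
      dplyr::mutate(side = side, .after = "mode")
  }
  ambiguity <- dplyr::bind_rows(amb(pairs, "left_id", "right_id"),
                                amb(pairs, "right_id", "left_id"))
  structure(list(pairs = pairs, counts = counts, ambiguity = ambiguity),
            class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report> ", nrow(x$pairs), " pairs\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Harmonize two compound databases end to end
#'
#' Reads both database directories, normalizes aromatic substructures in
#' every compound (reference library + O/S heuristic), builds tight and
#' loose identifier indexes, matches compounds (tight first, then loose),
#' classifies pairs by cross-reference confirmation and reaction EC
#' validation, and assembles the summary report.
#'
#' @param left_dir,right_dir Database directories (see [read_database()]).
#' @param lib A [reference_library()]; defaults to the bundled set.
#' @param modes Character subset of `c("tight", "loose")`.
#' @return A [harmonization_report()].
#' @export
harmonize_databases <- function(left_dir, right_dir,
                                lib = default_aromatic_library(),
                                modes = c("tight", "loose")) {
  modes <- match.arg(modes, several.ok = TRUE)
  dbL <- read_database(left_dir)
  dbR <- read_database(right_dir)
  dbL$compounds <- lapply(dbL$compounds, aromatize, lib = lib)
  dbR$compounds <- lapply(dbR$compounds, aromatize, lib = lib)
  run_mode <- function(mode) {
    cfg <- coloring_config(mode)
    iL <- build_index(dbL$compounds, cfg)
    iR <- build_index(dbR$compounds, cfg)
    p <- match_compounds(iL, iR, mode = mode)
    p <- confirm_with_ids(p, dbL$crossrefs, dbR$crossrefs)
    validate_with_ec(p, dbL$reactions, dbR$reactions)
  }
  pt <- if ("tight" %in% modes) run_mode("tight") else NULL
  pl <- if ("loose" %in% modes) run_mode("loose") else NULL
  harmonization_report(pt, pl)
}
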