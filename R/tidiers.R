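#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an atom coloring into one row per atom
#'
#' @param x An `atom_coloring`.
#' @param ... Unused.
#' @return A tibble with `index` (0-based atom index), `zero_layer`, `color`
#'   (the full identifier) and `color_hash` (display hash).
#' @export
tidy.atom_coloring <- function(x, ...) {
  idx <- as.integer(names(x$full))
  tibble::tibble(index = idx,
                 zero_layer = unname(x$zero_layer[as.character(idx)]),
                 color = unname(x$full),
                 color_hash = color_hash(unname(x$full))) |>
    dplyr::arrange(.data$index)
}

#' One-row summary of an atom coloring
#'
#' @param x An `atom_coloring`.
#' @param ... Unused.
#' @return A tibble with `n_atoms`, `n_classes`, `rounds_used`, `mode`.
#' @export
glance.atom_coloring <- function(x, ...) {
  tibble::tibble(n_atoms = length(x$full),
                 n_classes = length(unique(x$full)),
                 rounds_used = x$rounds_used,
                 mode = x$config$mode)
}

#' Tidy a compound identifier into its color classes
#'
#' @param x A `compound_identifier`.
#' @param ... Unused.
#' @return The canonical classes tibble (`color`, `count`).
#' @export
tidy.compound_identifier <- function(x, ...) x$classes

#' One-row summary of a compound identifier
#'
#' @param x A `compound_identifier`.
#' @param ... Unused.
#' @return A tibble with `mode`, `n_classes`, `n_atoms`, `hash`.
#' @export
glance.compound_identifier <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_classes = nrow(x$classes),
                 n_atoms = sum(x$classes$count), hash = color_hash(x$text))
}

#' Tidy a harmonization report into its pair table
#'
#' @param x A `harmonization_report`.
#' @param ... Unused.
#' @return The deduplicated pairs tibble.
#' @export
tidy.harmonization_report <- function(x, ...) x$pairs

#' One-row summary of a harmonization report
#'
#' @param x A `harmonization_report`.
#' @param ... Unused.
#' @return A tibble counting pairs overall, per mode, id-confirmed and
#'   EC-verified.
#' @export
glance.harmonization_report <- function(x, ...) {
  p <- x$pairs
  tibble::tibble(
    n_pairs = nrow(p),
    n_tight = sum(p$mode == "tight"),
    n_loose = sum(p$mode == "loose"),
    n_id_confirmed = sum(p$id_confirmed %in% TRUE),
    n_ec3 = sum(p$reaction_status %in% c("ec3_verified", "ec4_verified")),
    n_ec4 = sum(p$reaction_status %in% "ec4_verified")
  )
}

#' Draw a molecular graph
#'
#' A structure diagram from the graph's 2-D coordinates: bonds as segments
#' (double/triple bonds doubled, aromatic dashed) and atoms as element
#' labels, charges appended as superscript-style suffixes.
#'
#' @param object A `mol_graph`.
#' @param label_indices Also print 0-based atom indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mol_graph <- function(object, label_indices = FALSE, ...) {
  atoms <- object$atoms
  bonds <- object$bonds
  seg <- NULL
  if (nrow(bonds) > 0) {
    seg <- tibble::tibble(
      x = atoms$x[bonds$a + 1L], y = atoms$y[bonds$a + 1L],
      xend = atoms$x[bonds$b + 1L], yend = atoms$y[bonds$b + 1L],
      order = factor(bonds$order, levels = 1:4,
                     labels = c("single", "double", "triple", "aromatic"))
    )
  }
  lab <- atoms$element
  lab[atoms$charge > 0] <- paste0(lab[atoms$charge > 0], "+")
  lab[atoms$charge < 0] <- paste0(lab[atoms$charge < 0], "-")
  if (label_indices) lab <- paste0(lab, "[", atoms$index, "]")
  p <- ggplot2::ggplot()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$order),
      linewidth = 0.5, color = "grey30")
  }
  p +
    ggplot2::geom_label(
      data = atoms,
      ggplot2::aes(x = .data$x, y = .data$y),
      label = lab, label.size = 0, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$source_id)
}

#' Plot harmonization pair counts
#'
#' Bar chart of correspondence pairs per reaction status, split by match
#' mode and id confirmation.
#'
#' @param object A `harmonization_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.harmonization_report <- function(object, ...) {
  counts <- object$counts
  counts$id_confirmed <- ifelse(counts$id_confirmed %in% TRUE,
                                "ID-confirmed", "possible")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$reaction_status, y = .data$n,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~id_confirmed) +
    ggplot2::labs(x = "reaction status", y = "pairs", fill = "mode") +
    ggplot2::theme_minimal()
}
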