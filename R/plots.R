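# ggplot2 visualisations for the main result types. Layout/styling only;
# every quantity displayed is computed by the analysis functions.

#' Plot contact time profiles
#'
#' Time series of per-frame protein-lipid contact counts, optionally split
#' into segments (e.g. N-terminal vs C-terminal residues).
#'
#' @inheritParams contact_series
#' @param segments Named list of residue-number vectors, one panel per
#'   entry; `NULL` plots the whole protein.
#' @return A ggplot object.
#' @export
plot_contact_series <- function(contacts, segments = NULL, species = "PIP2",
                                n_frames = NULL) {
  if (is.null(segments)) segments <- list(all = NULL)
  df <- purrr::imap(segments, function(res, nm) {
    contact_series(contacts, residues = res, species = species, n_frames = n_frames) |>
      dplyr::mutate(segment = nm)
  }) |> dplyr::bind_rows()
  df$segment <- factor(df$segment, levels = names(segments))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$n_contacts)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$segment), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = "heavy-atom contacts") +
    ggplot2::theme_minimal()
}

#' Plot per-residue contact means with block SE bars
#'
#' @param table A tibble from [residue_table()].
#' @return A ggplot object.
#' @export
plot_residue_contacts <- function(table) {
  df <- dplyr::mutate(table,
    label = stats::reorder(
      paste0(.data$residue_name, .data$residue_number),
      .data$mean_contacts
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean_contacts)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$domain)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_contacts - .data$se_contacts,
        ymax = .data$mean_contacts + .data$se_contacts
      ),
      width = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean heavy-atom contacts (block SE)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mem_contacts <- function(object, ...) {
  plot_contact_series(object, species = "all", ...)
}

#' Plot an interaction network
#'
#' Bipartite layout with node size proportional to degree, residues as one
#' shape and lipid molecules (coloured by species) as another; connected
#' components are the clusters.
#'
#' @param object A `mem_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mem_network <- function(object, ...) {
  g <- object$graph
  nodes <- object$nodes
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::theme_void())
  }
  set.seed(42)
  lay <- igraph::layout_with_fr(g)
  nd <- dplyr::mutate(nodes,
    x = lay[match(.data$node, igraph::V(g)$name), 1],
    y = lay[match(.data$node, igraph::V(g)$name), 2]
  )
  ed <- object$edges |>
    dplyr::mutate(
      from = residue_node_id(.data$chain_id, .data$residue_number),
      to = lipid_node_id(.data$lipid_molecule)
    ) |>
    dplyr::left_join(dplyr::select(nd, node, x0 = "x", y0 = "y"), by = c(from = "node")) |>
    dplyr::left_join(dplyr::select(nd, node, x1 = "x", y1 = "y"), by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$weight
      ),
      color = "grey60"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(
        x = .data$x, y = .data$y, size = .data$degree,
        shape = .data$kind,
        color = ifelse(.data$kind == "lipid", .data$species, "residue")
      )
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_size(range = c(2, 8)) +
    ggplot2::labs(color = NULL, shape = NULL, size = "degree") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
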