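#' Tidy a condensed subnetwork
#'
#' @param x A `condensed_subnetwork` from [select_top_links()].
#' @param ... Unused.
#' @return The selected-edge tibble (`from`, `to`, `link_score`, `direction`,
#'   `component`).
#' @method tidy condensed_subnetwork
#' @export
tidy.condensed_subnetwork <- function(x, ...) tibble::as_tibble(x$edges)

#' One-row summary of a condensed subnetwork
#'
#' @inheritParams tidy.condensed_subnetwork
#' @return Tibble with `n_edges`, `n_up`, `n_down`, `n_genes`,
#'   `n_components`, `largest_component`.
#' @method glance condensed_subnetwork
#' @export
glance.condensed_subnetwork <- function(x, ...) {
  comps <- network_components(x)
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_up = sum(x$edges$direction == "up"),
    n_down = sum(x$edges$direction == "down"),
    n_genes = nrow(x$nodes),
    n_components = length(comps),
    largest_component = if (length(comps)) lengths(comps)[1] else 0L
  )
}

#' @export
print.condensed_subnetwork <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<condensed_subnetwork> %d edges (%d up, %d down), %d genes, %d component(s)\n",
              g$n_edges, g$n_up, g$n_down, g$n_genes, g$n_components))
  print(x$edges, n = 8)
  invisible(x)
}

#' Tidy K/L solutions into a long node table
#'
#' @param x A `kpm_solutions` object.
#' @param ... Unused.
#' @return Tibble with one row per (solution, gene): `rank`, `size`, `gene`,
#'   `exception`.
#' @method tidy kpm_solutions
#' @export
tidy.kpm_solutions <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(rank = integer(0), size = integer(0),
                          gene = character(0), exception = logical(0)))
  }
  purrr::pmap(list(x$rank, x$size, x$nodes, x$exception_nodes),
              function(r, s, nodes, exc) {
                tibble::tibble(rank = r, size = s, gene = nodes,
                               exception = nodes %in% exc)
              }) |> purrr::list_rbind()
}

#' One-row summary of K/L solutions
#'
#' @inheritParams tidy.kpm_solutions
#' @return Tibble with `n_solutions`, `best_size`, `K`, `L`, `solver`.
#' @method glance kpm_solutions
#' @export
glance.kpm_solutions <- function(x, ...) {
  tibble::tibble(
    n_solutions = nrow(x),
    best_size = if (nrow(x)) x$size[1] else 0L,
    K = attr(x, "K"),
    L = attr(x, "L"),
    solver = attr(x, "solver")
  )
}

#' Plot a condensed subnetwork
#'
#' Force-directed layout with edges colored by direction of differential
#' regulation (up in the case group: red; down: green, the usual convention
#' for these condensation plots).
#'
#' @param object A `condensed_subnetwork`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot condensed_subnetwork
#' @export
autoplot.condensed_subnetwork <- function(object, ...) {
  edges <- object$edges
  g <- as_igraph(object)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  seg <- edges |>
    dplyr::left_join(nodes, by = c(from = "gene")) |>
    dplyr::left_join(nodes, by = c(to = "gene"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$direction),
      linewidth = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$gene),
                       vjust = -0.8, size = 2.8) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#1e8449")) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "regulation")
}

#' Waterfall plot of link scores
#'
#' Ranks all edges by link score; the tails are the condensation candidates.
#'
#' @param ls Link-score tibble from [compute_link_scores()].
#' @return A ggplot object.
#' @export
plot_link_scores <- function(ls) {
  d <- dplyr::arrange(tibble::as_tibble(ls), dplyr::desc(.data$link_score))
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$link_score)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "interaction rank", y = "link score (log2)") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Horizontal bars of -log10 p for the most enriched terms.
#'
#' @param object An `enrichment_result` from [enrich()].
#' @param n Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n = 15, ...) {
  d <- head(tibble::as_tibble(object), n)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p.value), .data$term,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e86c1", `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL, fill = "BH < alpha") +
    ggplot2::theme_minimal()
}

#' Heatmap of an indicator matrix
#'
#' Genes by case samples; filled cells mark significant differential
#' expression of the gene in that case.
#'
#' @param ind Indicator matrix tibble from [build_indicator_matrix()].
#' @return A ggplot object.
#' @export
plot_indicator_matrix <- function(ind) {
  long <- tidyr::pivot_longer(tibble::as_tibble(ind), -"gene",
                              names_to = "case", values_to = "active")
  ggplot2::ggplot(long, ggplot2::aes(.data$case, .data$gene,
                                     fill = factor(.data$active))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "#21618c"),
                               labels = c("inactive", "active")) +
    ggplot2::labs(x = "case sample", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
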