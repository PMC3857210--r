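#' Read and confidence-filter a STRING-style links table
#'
#' Parses a links table with `protein1`/`protein2` columns and per-channel
#' confidence scores, keeps an interaction when its confidence reaches
#' `threshold` in at least one of the selected evidence channels (or, with
#' `combined = TRUE`, when the combined score over the selected channels
#' does), canonicalizes edge direction, drops self-loops, and collapses
#' duplicate rows keeping the per-channel maximum.
#'
#' Channel columns scored on STRING's integer 0-1000 scale are detected
#' (integer-valued with maximum > 1) and divided by 1000.
#'
#' @param path Path to a whitespace- or tab-delimited links table with a
#'   header line.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.85.
#' @param channels Evidence channels to consider; default
#'   `c("experimental", "database", "textmining")`.
#' @param combined If `TRUE`, filter on the combined score
#'   `1 - prod(1 - s_c)` over the selected channels instead of the per-channel
#'   maximum.
#' @return An edge tibble with columns `from`, `to` (canonical `from < to`)
#'   and one numeric column per channel.
#' @export
read_string_edges <- function(path, threshold = 0.85,
                              channels = c("experimental", "database", "textmining"),
                              combined = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  delim <- if (grepl("\t", first)) "\t" else " "
  tab <- readr::read_delim(path, delim = delim, trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (!all(c("protein1", "protein2") %in% names(tab))) {
    abort("links table must have `protein1` and `protein2` columns")
  }
  missing <- setdiff(channels, names(tab))
  if (length(missing)) {
    abort(sprintf("missing channel column(s): %s", paste(missing, collapse = ", ")))
  }
  edges <- tibble::tibble(from = as.character(tab$protein1),
                          to = as.character(tab$protein2))
  for (ch in channels) {
    v <- as.numeric(tab[[ch]])
    if (anyNA(v)) abort(sprintf("non-numeric scores in channel '%s'", ch))
    if (max(v) > 1 && all(abs(v - round(v)) < 1e-9)) v <- v / 1000
    if (any(v < 0 | v > 1)) abort(sprintf("channel '%s' scores outside [0, 1]", ch))
    edges[[ch]] <- v
  }
  edges <- canonicalize_edges(edges)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(channels), max), .groups = "drop")
  score <- if (combined) {
    1 - Reduce(`*`, lapply(channels, function(ch) 1 - edges[[ch]]))
  } else {
    do.call(pmax, lapply(channels, function(ch) edges[[ch]]))
  }
  edges <- edges[score >= threshold, , drop = FALSE]
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  if (nrow(edges) == 0) warn("no interaction passed the confidence filter; returning an empty network")
  edges
}

#' Attach effect signs from a STRING-style actions table
#'
#' Optional annotation: adds an `effect` column
#' (`"stimulation"`/`"inhibition"`/`"unknown"`) to an edge tibble from a table
#' with `item_a`, `item_b`, `mode` columns (mode `"activation"` maps to
#' stimulation). Signs never affect scoring; they only decorate exports.
#'
#' @param edges Edge tibble (`from`, `to`).
#' @param actions Data frame with columns `item_a`, `item_b`, `mode`.
#' @return `edges` with an `effect` column.
#' @export
annotate_effects <- function(edges, actions) {
  stopifnot(is.data.frame(actions))
  if (!all(c("item_a", "item_b", "mode") %in% names(actions))) {
    names(actions)[1:3] <- c("item_a", "item_b", "mode")
  }
  act <- tibble::tibble(key = edge_key(as.character(actions$item_a),
                                       as.character(actions$item_b)),
                        mode = tolower(as.character(actions$mode)))
  act$effect <- dplyr::case_when(
    act$mode %in% c("activation", "stimulation") ~ "stimulation",
    act$mode == "inhibition" ~ "inhibition",
    TRUE ~ "unknown"
  )
  ord <- c(stimulation = 1, inhibition = 2, unknown = 3)
  act <- act[order(ord[act$effect]), ]
  act <- act[!duplicated(act$key), ]
  idx <- match(edge_key(edges$from, edges$to), act$key)
  edges$effect <- ifelse(is.na(idx), "unknown", act$effect[idx])
  edges
}

#' Restrict a network to genes with expression
#'
#' Intersects the network's node set with the genes of a group-mean table,
#' drops edges losing an endpoint, and attaches the per-node group means.
#'
#' @param edges Edge tibble (`from`, `to`, optional score columns).
#' @param gm Group-mean table from [group_means()] (`gene`, `mean_ref`,
#'   `mean_case`).
#' @return An `annotated_network`: a list with `nodes` (tibble `gene`,
#'   `mean_ref`, `mean_case`) and `edges`.
#' @export
map_expression_to_network <- function(edges, gm) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  stopifnot(is.data.frame(gm), all(c("gene", "mean_ref", "mean_case") %in% names(gm)))
  net_genes <- union(edges$from, edges$to)
  keep <- intersect(net_genes, gm$gene)
  if (length(keep) == 0) abort("no network gene has expression data (identifier namespaces disjoint?)")
  kept_edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  inform(sprintf("mapped %d of %d network genes; dropped %d of %d edges",
                 length(keep), length(net_genes),
                 nrow(edges) - nrow(kept_edges), nrow(edges)))
  nodes <- gm[gm$gene %in% keep, , drop = FALSE]
  nodes <- dplyr::arrange(tibble::as_tibble(nodes), .data$gene)
  structure(list(nodes = nodes, edges = tibble::as_tibble(kept_edges)),
            class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  cat(sprintf("<annotated_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$edges, n = 5)
  invisible(x)
}

as_igraph <- function(x) {
  if (inherits(x, "annotated_network")) {
    g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                       vertices = x$nodes)
  } else if (inherits(x, "condensed_subnetwork")) {
    g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                       vertices = x$nodes)
  } else if (is.data.frame(x)) {
    g <- igraph::graph_from_data_frame(x, directed = FALSE)
  } else {
    abort("cannot coerce this object to a graph")
  }
  g
}

#' Write a network to SIF or GraphML
#'
#' SIF rows use the relation `pp`, or the edge's `effect` label when present.
#' GraphML carries all edge columns (channel scores, link scores, direction)
#' and node columns (`mean_ref`, `mean_case`) as attributes.
#'
#' @param x An edge tibble, [map_expression_to_network()] result, or
#'   [select_top_links()] result.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  edges <- if (is.data.frame(x)) x else x$edges
  if (format == "sif") {
    rel <- if ("effect" %in% names(edges)) edges$effect else rep("pp", nrow(edges))
    rel[is.na(rel) | rel == "unknown"] <- "pp"
    writeLines(if (nrow(edges)) paste(edges$from, rel, edges$to) else character(0), path)
  } else {
    g <- as_igraph(x)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return An edge tibble with any stored edge attributes; node attributes
#'   (`mean_ref`, `mean_case`) are attached as a `nodes` attribute when
#'   present.
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  nd <- igraph::as_data_frame(g, what = "vertices")
  edges <- canonicalize_edges(tibble::as_tibble(ed))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  if ("name" %in% names(nd)) names(nd)[names(nd) == "name"] <- "gene"
  nd <- tibble::as_tibble(nd)
  if ("gene" %in% names(nd)) nd <- dplyr::arrange(nd, .data$gene)
  attr(edges, "nodes") <- nd
  edges
}
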