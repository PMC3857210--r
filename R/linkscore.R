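#' Per-edge link scores
#'
#' For an interaction between genes i and j with positive group-mean
#' expression, the link score is the log2 fold change of the product of the
#' endpoint means:
#' \deqn{LS_{ij} = \log_2 \frac{\bar{x}^{case}_i \, \bar{x}^{case}_j}
#'                             {\bar{x}^{ref}_i \, \bar{x}^{ref}_j}}
#' i.e. the sum of the endpoint log2 fold changes. Positive scores mean the
#' interaction is up-regulated in the case group; the score is invariant to a
#' common rescaling of all intensities. A difference-of-products variant
#' (`method = "difference"`, not scale-invariant) is available for
#' comparison.
#'
#' @param an Annotated network from [map_expression_to_network()].
#' @param method `"log_ratio"` (default) or `"difference"`.
#' @return A tibble with one row per edge: `from`, `to`, `link_score`.
#' @export
compute_link_scores <- function(an, method = c("log_ratio", "difference")) {
  method <- match.arg(method)
  stopifnot(inherits(an, "annotated_network"))
  nodes <- an$nodes
  bad <- nodes$gene[nodes$mean_ref <= 0 | nodes$mean_case <= 0]
  if (length(bad)) {
    abort(sprintf("non-positive group mean for gene(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  i <- match(an$edges$from, nodes$gene)
  j <- match(an$edges$to, nodes$gene)
  ls <- if (method == "log_ratio") {
    (log2(nodes$mean_case[i]) + log2(nodes$mean_case[j])) -
      (log2(nodes$mean_ref[i]) + log2(nodes$mean_ref[j]))
  } else {
    nodes$mean_case[i] * nodes$mean_case[j] - nodes$mean_ref[i] * nodes$mean_ref[j]
  }
  out <- tibble::tibble(from = an$edges$from, to = an$edges$to, link_score = ls)
  attr(out, "nodes") <- nodes
  out
}

#' Condense a network to its most differentially regulated interactions
#'
#' Selects the `k_up` edges with the largest positive link scores and the
#' `k_down` edges with the most negative, the differential-network
#' condensation step. Ties are broken deterministically by canonical edge
#' identifier. If fewer edges of a sign exist than requested, the selection
#' is clamped with a warning.
#'
#' @param ls Link-score tibble from [compute_link_scores()] (columns `from`,
#'   `to`, `link_score`).
#' @param k_up,k_down Numbers of up- and down-regulated interactions to keep
#'   (both default 16).
#' @return A `condensed_subnetwork`: list with `edges` (selected edges with
#'   `direction` and connected-`component` labels), `nodes` (distinct genes,
#'   with group means when available), `k_up`, `k_down`.
#' @export
select_top_links <- function(ls, k_up = 16, k_down = 16) {
  stopifnot(is.data.frame(ls), all(c("from", "to", "link_score") %in% names(ls)))
  stopifnot(k_up >= 0, k_down >= 0)
  if (!all(is.finite(ls$link_score))) abort("link scores must be finite")
  id <- paste(ls$from, ls$to)
  up_pool <- which(ls$link_score > 0)
  down_pool <- which(ls$link_score < 0)
  if (k_up > length(up_pool)) {
    warn(sprintf("only %d up-regulated edge(s) available; clamping k_up", length(up_pool)))
    k_up <- length(up_pool)
  }
  if (k_down > length(down_pool)) {
    warn(sprintf("only %d down-regulated edge(s) available; clamping k_down", length(down_pool)))
    k_down <- length(down_pool)
  }
  up <- up_pool[order(-ls$link_score[up_pool], id[up_pool])][seq_len(k_up)]
  down <- down_pool[order(ls$link_score[down_pool], id[down_pool])][seq_len(k_down)]
  edges <- ls[c(up, down), , drop = FALSE]
  edges$direction <- rep(c("up", "down"), c(k_up, k_down))
  edges <- tibble::as_tibble(edges)
  comp <- component_labels(edges)
  edges$component <- comp[paste(edges$from, edges$to)]
  genes <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(gene = genes)
  nm <- attr(ls, "nodes")
  if (!is.null(nm)) {
    nodes <- dplyr::left_join(nodes, nm, by = "gene")
  }
  structure(list(edges = edges, nodes = nodes, k_up = k_up, k_down = k_down),
            class = "condensed_subnetwork")
}

# integer component label per edge (keyed by "from to"), components numbered
# by decreasing size then lexicographic smallest member
component_labels <- function(edges) {
  if (nrow(edges) == 0) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE)
  cm <- igraph::components(g)$membership
  sets <- split(names(cm), cm)
  ord <- order(-lengths(sets), vapply(sets, min, character(1)))
  relabel <- integer(length(sets))
  relabel[ord] <- seq_along(sets)
  lab <- relabel[cm[edges$from]]
  setNames(as.integer(lab), paste(edges$from, edges$to))
}

#' Connected components of a subnetwork
#'
#' @param x A `condensed_subnetwork`, an edge tibble, or a `kpm_solutions`
#'   object (components of its top solution's induced subgraph).
#' @return A list of character vectors (node sets), sorted by decreasing size
#'   then lexicographically by smallest member.
#' @export
network_components <- function(x) {
  edges <- if (is.data.frame(x)) x else x$edges
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE)
  cm <- igraph::components(g)$membership
  sets <- lapply(split(names(cm), cm), sort)
  sets <- unname(sets)
  sets[order(-lengths(sets), vapply(sets, min, character(1)))]
}

log2_activity <- function(m, from, to) {
  log2(m[from, , drop = FALSE]) + log2(m[to, , drop = FALSE])
}

#' Test interactions for differential regulation
#'
#' The per-sample activity of an interaction (i, j) is
#' `log2 x_i + log2 x_j`; each edge's activity is compared between the two
#' groups with a two-tailed t-test (Welch by default) and the p-values are
#' Benjamini-Hochberg adjusted across the supplied edge set.
#'
#' @param expr Gene-level linear-scale expression tibble.
#' @param groups Sample group labels (see [group_means()]).
#' @param edges Data frame of edges (`from`, `to`) whose endpoints are genes
#'   of `expr`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param var_equal Use Student's pooled-variance t-test instead of Welch.
#' @param ref,case Optional group labels (see [group_means()]).
#' @return A tibble per edge: `from`, `to`, `estimate` (case minus reference
#'   mean activity, log2 units), `statistic`, `p.value`, `q.value`,
#'   `significant`.
#' @export
test_interaction_shifts <- function(expr, groups, edges, alpha = 0.05,
                                    var_equal = FALSE, ref = NULL, case = NULL) {
  m <- validate_expr(expr)
  g <- resolve_groups(groups, colnames(m), ref = ref, case = case)
  if (length(g$ref_samples) < 2 || length(g$case_samples) < 2) {
    abort("each group needs at least two samples for a t-test")
  }
  edges <- if (is.data.frame(edges)) edges else edges$edges
  missing <- setdiff(unique(c(edges$from, edges$to)), rownames(m))
  if (length(missing)) {
    abort(sprintf("edge endpoint(s) absent from the expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  res <- purrr::map2(edges$from, edges$to, function(i, j) {
    a <- log2(m[i, ]) + log2(m[j, ])
    tt <- t.test(a[g$case_samples], a[g$ref_samples], var.equal = var_equal)
    tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                   statistic = unname(tt$statistic), p.value = tt$p.value)
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(from = edges$from, to = edges$to), res)
  out$q.value <- p.adjust(out$p.value, method = "BH")
  out$significant <- out$q.value < alpha
  out
}

#' Test genes for differential expression
#'
#' Two-tailed t-test (Welch by default) of each gene's log2 expression
#' between the groups, BH-adjusted across the supplied gene set, reporting
#' the fraction of significant genes (the statistic used to contrast
#' interaction-level and gene-level signal in a condensed subnetwork).
#'
#' @inheritParams test_interaction_shifts
#' @param genes Character vector of genes of `expr` (defaults to all).
#' @return A tibble per gene (`gene`, `estimate`, `statistic`, `p.value`,
#'   `q.value`, `significant`) with attribute `fraction_significant`; read it
#'   with [fraction_significant()].
#' @export
test_gene_de <- function(expr, groups, genes = NULL, alpha = 0.05,
                         var_equal = FALSE, ref = NULL, case = NULL) {
  m <- validate_expr(expr)
  g <- resolve_groups(groups, colnames(m), ref = ref, case = case)
  if (length(g$ref_samples) < 2 || length(g$case_samples) < 2) {
    abort("each group needs at least two samples for a t-test")
  }
  genes <- genes %||% rownames(m)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    abort(sprintf("gene(s) absent from the expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lm2 <- log2(m[genes, , drop = FALSE])
  res <- purrr::map(genes, function(i) {
    tt <- t.test(lm2[i, g$case_samples], lm2[i, g$ref_samples],
                 var.equal = var_equal)
    tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                   statistic = unname(tt$statistic), p.value = tt$p.value)
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(tibble::tibble(gene = genes), res)
  out$q.value <- p.adjust(out$p.value, method = "BH")
  out$significant <- out$q.value < alpha
  attr(out, "fraction_significant") <- mean(out$significant)
  out
}

#' Fraction of significantly differentially expressed genes
#'
#' @param x Result of [test_gene_de()].
#' @return The fraction of tested genes with BH-adjusted p below the alpha
#'   used.
#' @export
fraction_significant <- function(x) {
  attr(x, "fraction_significant") %||% mean(x$significant)
}
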