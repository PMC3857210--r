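#' Run the differential-network condensation pipeline
#'
#' Chains the standard analysis: group-wise means of a gene-level
#' linear-scale matrix, restriction of the confidence-filtered network to
#' genes with expression, per-edge link scores, condensation to the `k_up` +
#' `k_down` most differentially regulated interactions, and interaction- and
#' gene-level significance tests on the selected subnetwork.
#'
#' @param expr Gene-level linear-scale expression tibble (already quantile
#'   normalized / probe collapsed as appropriate).
#' @param groups Sample group labels (see [group_means()]).
#' @param network Edge tibble, e.g. from [read_string_edges()] or
#'   [generate_network()].
#' @param k_up,k_down Interactions to keep per direction (default 16 each).
#' @param alpha Significance level for the tests (default 0.05).
#' @param ref,case Optional group labels (see [group_means()]).
#' @return A list of class `condense_result`: `annotated` (the expression-
#'   restricted network), `link_scores`, `subnetwork`
#'   (`condensed_subnetwork`), `interaction_tests`, `gene_tests`, and
#'   `summary` (one-row tibble: mapped genes/edges, subnetwork composition,
#'   fraction of subnetwork genes significantly differentially expressed).
#' @export
condense_network <- function(expr, groups, network, k_up = 16, k_down = 16,
                             alpha = 0.05, ref = NULL, case = NULL) {
  gm <- group_means(expr, groups, ref = ref, case = case)
  an <- map_expression_to_network(network, gm)
  ls <- compute_link_scores(an)
  cs <- select_top_links(ls, k_up = k_up, k_down = k_down)
  it <- test_interaction_shifts(expr, groups, cs$edges, alpha = alpha,
                                ref = ref, case = case)
  gt <- test_gene_de(expr, groups, cs$nodes$gene, alpha = alpha,
                     ref = ref, case = case)
  g <- glance(cs)
  summary <- tibble::tibble(
    n_mapped_genes = nrow(an$nodes),
    n_mapped_edges = nrow(an$edges),
    n_edges_selected = g$n_edges,
    n_subnetwork_genes = g$n_genes,
    n_components = g$n_components,
    n_significant_interactions = sum(it$significant),
    fraction_genes_significant = fraction_significant(gt)
  )
  structure(list(annotated = an, link_scores = ls, subnetwork = cs,
                 interaction_tests = it, gene_tests = gt, summary = summary),
            class = "condense_result")
}

#' @export
print.condense_result <- function(x, ...) {
  cat("<condense_result>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname condense_network
#' @param x A `condense_result`.
#' @param ... Unused.
#' @method glance condense_result
#' @export
glance.condense_result <- function(x, ...) x$summary
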