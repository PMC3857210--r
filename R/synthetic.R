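#' Generate a random interaction network
#'
#' Produces a connected simple undirected graph with per-channel confidence
#' scores drawn uniformly in `[0.85, 1]`, so the default confidence filter
#' keeps every edge. Two models: preferential attachment (`"scale_free"`,
#' `density_param` = edges added per node) and Erdos-Renyi
#' (`"erdos_renyi"`, `density_param` < 1 read as edge probability, >= 1 as
#' total edge count). A disconnected draw is stitched together by linking a
#' random member of each extra component to the giant one.
#'
#' @param n_nodes Number of genes (>= 2); names are `g001`, `g002`, ...
#' @param model `"scale_free"` or `"erdos_renyi"`.
#' @param density_param Density control, see above.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A canonical edge tibble: `from`, `to`, `experimental`, `database`,
#'   `textmining`.
#' @export
generate_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                             density_param = 2, seed = 1) {
  model <- match.arg(model)
  if (n_nodes < 2) abort("need at least two nodes")
  g <- with_seed(derive_seed(seed, "network"), {
    if (model == "scale_free") {
      m <- max(1L, round(density_param))
      igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    } else {
      if (density_param < 1) {
        if (density_param <= 0) abort("edge probability must be positive")
        igraph::sample_gnp(n_nodes, p = density_param)
      } else {
        m <- round(density_param)
        if (m > choose(n_nodes, 2)) abort("more edges requested than a simple graph allows")
        if (m < n_nodes - 1) abort("too few edges for a connected graph")
        igraph::sample_gnm(n_nodes, m = m)
      }
    }
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n_nodes))
  cmp <- igraph::components(g)
  if (cmp$no > 1) {
    g <- with_seed(derive_seed(seed, "network_stitch"), {
      giant <- which.max(cmp$csize)
      pick1 <- function(x) x[sample.int(length(x), 1)]
      for (comp in setdiff(seq_len(cmp$no), giant)) {
        a <- pick1(which(cmp$membership == comp))
        b <- pick1(which(cmp$membership == giant))
        g <- igraph::add_edges(g, c(a, b))
      }
      g
    })
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- canonicalize_edges(tibble::as_tibble(ed))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  scores <- with_seed(derive_seed(seed, "channels"), {
    matrix(runif(3 * nrow(edges), 0.85, 1), ncol = 3)
  })
  edges$experimental <- scores[, 1]
  edges$database <- scores[, 2]
  edges$textmining <- scores[, 3]
  edges
}

#' Pick planted edges with disjoint, unconfounded endpoints
#'
#' Selects `n_up + n_down` network edges to plant. Endpoints are pairwise
#' disjoint across all planted edges (no gene carries conflicting
#' directions), and within each direction the chosen edges form an induced
#' matching: no other network edge connects two endpoints of the same
#' direction. Without the latter constraint an incidental edge between two
#' up-shifted genes would be exactly as differentially regulated as a
#' planted edge, making edge-level recovery ill-defined.
#'
#' @param edges Network edge tibble.
#' @param n_up,n_down Numbers of up- and down-regulated edges to plant.
#' @param seed Integer seed; shuffled greedy selection with up to 100
#'   deterministic restarts.
#' @return A tibble `from`, `to`, `direction`.
#' @export
plant_edges <- function(edges, n_up, n_down, seed = 1) {
  need <- n_up + n_down
  stopifnot(need >= 0)
  if (need == 0) {
    return(tibble::tibble(from = character(0), to = character(0),
                          direction = character(0)))
  }
  nbr <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  attempt <- function(ord) {
    used <- character(0)
    used_dir <- list(up = character(0), down = character(0))
    picked <- integer(0)
    dirs <- character(0)
    for (k in ord) {
      if (length(picked) == need) break
      a <- edges$from[k]
      b <- edges$to[k]
      if (a %in% used || b %in% used) next
      d <- if (sum(dirs == "up") < n_up) "up" else "down"
      touches <- unique(c(nbr[[a]], nbr[[b]]))
      if (any(touches %in% used_dir[[d]])) {
        # try the other direction before rejecting the edge
        d2 <- setdiff(c("up", "down"), d)
        if (sum(dirs == d2) < (if (d2 == "up") n_up else n_down) &&
            !any(touches %in% used_dir[[d2]])) {
          d <- d2
        } else next
      }
      picked <- c(picked, k)
      dirs <- c(dirs, d)
      used <- c(used, a, b)
      used_dir[[d]] <- c(used_dir[[d]], a, b)
    }
    if (length(picked) < need) NULL else list(picked = picked, dirs = dirs)
  }
  res <- NULL
  for (try in seq_len(100)) {
    ord <- with_seed(derive_seed(seed, paste0("plant", try)), sample(nrow(edges)))
    res <- attempt(ord)
    if (!is.null(res)) break
  }
  if (is.null(res)) {
    abort(sprintf("could not plant %d unconfounded endpoint-disjoint edges", need))
  }
  out <- edges[res$picked, c("from", "to")]
  out$direction <- res$dirs
  out <- tibble::as_tibble(out)
  dplyr::arrange(out, dplyr::desc(.data$direction), .data$from, .data$to)
}

#' Generate a two-group expression matrix with planted edges
#'
#' Emulates the structure of a two-group (e.g. non-responder vs responder)
#' microarray study. Per-gene baseline log2 intensity is drawn once from
#' Normal(8, 1.5) and shared across samples; per-entry noise is
#' Normal(0, `sigma`) on the log2 scale. For each planted edge both endpoint
#' genes are shifted by `+effect` (direction `"up"`) or `-effect`
#' (`"down"`) log2 units in a carrier subset of the case group of size
#' `round(carrier_fraction * n_case)` — a carrier fraction below 1 models
#' case heterogeneity, where only some responders carry each signal. The
#' matrix is exported on the linear scale (`2^value`).
#'
#' A gene that is an endpoint of several same-direction planted edges is
#' shifted once per carrier (the union of the edges' carrier sets);
#' endpoints with conflicting directions are an error.
#'
#' @param edges Network edge tibble; planted edges must belong to it.
#' @param n_ref,n_case Group sizes (defaults 182 and 48, an unbalanced
#'   cohort).
#' @param planted Tibble `from`, `to`, `direction` (e.g. from
#'   [plant_edges()]); `NULL` plants nothing.
#' @param effect Endpoint shift in log2 units (> 0), default 1.5.
#' @param carrier_fraction Fraction of case samples carrying each planted
#'   signal, default 1.
#' @param sigma Noise standard deviation on the log2 scale, default 0.3.
#' @param seed Integer seed.
#' @param shared_carriers Draw one carrier set shared by all planted edges
#'   (a coherent case subtype) instead of one per edge.
#' @return A list with `expr` (linear-scale expression tibble), `groups`
#'   (tibble `sample`, `group` with labels `"nonresponder"`/`"responder"`),
#'   and `truth` (a `synthetic_truth` object: planted edges, carrier sets,
#'   generator parameters).
#' @export
generate_expression <- function(edges, n_ref = 182, n_case = 48, planted = NULL,
                                effect = 1.5, carrier_fraction = 1, sigma = 0.3,
                                seed = 1, shared_carriers = FALSE) {
  stopifnot(n_ref >= 1, n_case >= 1, sigma > 0,
            carrier_fraction >= 0, carrier_fraction <= 1)
  genes <- sort(unique(c(edges$from, edges$to)))
  ref_ids <- sprintf("N%03d", seq_len(n_ref))
  case_ids <- sprintf("R%03d", seq_len(n_case))
  samples <- c(ref_ids, case_ids)
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(c("from", "to", "direction") %in% names(planted)))
    planted <- canonicalize_edges(tibble::as_tibble(planted))
    if (!all(edge_key(planted$from, planted$to) %in% edge_key(edges$from, edges$to))) {
      abort("planted edges must exist in the network")
    }
    if (!all(planted$direction %in% c("up", "down"))) {
      abort('planted directions must be "up" or "down"')
    }
    long <- tibble::tibble(gene = c(planted$from, planted$to),
                           direction = rep(planted$direction, 2))
    conflict <- long |>
      dplyr::distinct() |>
      dplyr::count(.data$gene) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflict)) {
      abort(sprintf("conflicting planted directions for gene(s): %s",
                    paste(conflict$gene, collapse = ", ")))
    }
  } else {
    planted <- tibble::tibble(from = character(0), to = character(0),
                              direction = character(0))
  }
  if (effect <= 0 && nrow(planted) > 0) abort("`effect` must be positive")
  baseline <- with_seed(derive_seed(seed, "baseline"),
                        rnorm(length(genes), mean = 8, sd = 1.5))
  noise <- with_seed(derive_seed(seed, "noise"),
                     matrix(rnorm(length(genes) * length(samples), 0, sigma),
                            nrow = length(genes)))
  log2m <- baseline + noise
  dimnames(log2m) <- list(genes, samples)
  n_carriers <- round(carrier_fraction * n_case)
  carriers <- list()
  if (nrow(planted) > 0 && n_carriers > 0) {
    carriers <- with_seed(derive_seed(seed, "carriers"), {
      if (shared_carriers) {
        shared <- sort(sample(case_ids, n_carriers))
        rep(list(shared), nrow(planted))
      } else {
        lapply(seq_len(nrow(planted)), function(.) sort(sample(case_ids, n_carriers)))
      }
    })
    names(carriers) <- paste(planted$from, planted$to, sep = "--")
    shift_sets <- list()
    for (k in seq_len(nrow(planted))) {
      s <- if (planted$direction[k] == "up") effect else -effect
      for (gn in c(planted$from[k], planted$to[k])) {
        prev <- shift_sets[[gn]] %||% character(0)
        new_carr <- setdiff(carriers[[k]], prev)
        log2m[gn, new_carr] <- log2m[gn, new_carr] + s
        shift_sets[[gn]] <- c(prev, new_carr)
      }
    }
  }
  expr <- new_expr_tbl(2^log2m, "linear")
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("nonresponder", "responder"),
                                       c(n_ref, n_case)))
  truth <- structure(list(
    planted = dplyr::mutate(planted, effect = if (nrow(planted)) effect else numeric(0)),
    carriers = carriers,
    params = list(n_ref = n_ref, n_case = n_case, effect = effect,
                  carrier_fraction = carrier_fraction, sigma = sigma,
                  seed = seed, shared_carriers = shared_carriers)
  ), class = "synthetic_truth")
  list(expr = expr, groups = groups, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper reproducing the package's benchmark scenario: a
#' connected random network, an unbalanced two-group expression matrix, and
#' planted up-/down-regulated interactions with a configurable carrier
#' fraction. Defaults give 100 genes, 250 edges, 182 reference vs 48 case
#' samples, 8 + 8 planted edges with endpoint effect 1.5 log2 and noise
#' sigma 0.3.
#'
#' @param n_genes,n_edges Network size.
#' @param model Network model passed to [generate_network()].
#' @param n_up,n_down Planted edges per direction.
#' @inheritParams generate_expression
#' @return A list: `network` (edge tibble), `expr`, `groups`, `truth`.
#' @export
simulate_study <- function(n_genes = 100, n_edges = 250, n_ref = 182, n_case = 48,
                           n_up = 8, n_down = 8, effect = 1.5, sigma = 0.3,
                           carrier_fraction = 1, model = "erdos_renyi", seed = 1,
                           shared_carriers = FALSE) {
  net <- generate_network(n_genes, model = model, density_param = n_edges, seed = seed)
  planted <- plant_edges(net, n_up = n_up, n_down = n_down, seed = seed)
  sim <- generate_expression(net, n_ref = n_ref, n_case = n_case,
                             planted = planted, effect = effect,
                             carrier_fraction = carrier_fraction, sigma = sigma,
                             seed = seed, shared_carriers = shared_carriers)
  c(list(network = net), sim)
}

#' Score recovery of planted edges
#'
#' Direction-aware edge-level precision and recall of a condensed subnetwork
#' against the planted truth: a selected edge counts as recovered when it
#' matches a planted edge and its direction.
#'
#' @param cs A `condensed_subnetwork` from [select_top_links()] (or an edge
#'   tibble with `from`, `to`, `direction`).
#' @param truth A `synthetic_truth` from [generate_expression()].
#' @return A one-row tibble: `precision` (`NA` when nothing was selected),
#'   `recall`, `n_selected`, `n_planted`, `n_matched`.
#' @export
score_recovery <- function(cs, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sel <- if (is.data.frame(cs)) cs else cs$edges
  stopifnot(all(c("from", "to", "direction") %in% names(sel)))
  planted <- truth$planted
  sel_key <- paste(edge_key(sel$from, sel$to), sel$direction)
  pl_key <- paste(edge_key(planted$from, planted$to), planted$direction)
  n_matched <- length(intersect(sel_key, pl_key))
  tibble::tibble(
    precision = if (nrow(sel) == 0) NA_real_ else n_matched / nrow(sel),
    recall = if (nrow(planted) == 0) NA_real_ else n_matched / nrow(planted),
    n_selected = nrow(sel),
    n_planted = nrow(planted),
    n_matched = n_matched
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted edge(s); n_ref = %d, n_case = %d, effect = %g log2, sigma = %g, carrier_fraction = %g\n",
              nrow(x$planted), x$params$n_ref, x$params$n_case,
              x$params$effect, x$params$carrier_fraction, x$params$sigma))
  invisible(x)
}
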