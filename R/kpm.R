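#' Build the per-case indicator matrix
#'
#' Marks which genes are significantly differentially expressed in which case
#' sample (e.g. which responder), relative to the reference group. After
#' per-sample standardization, each case value is tested against the
#' reference group's gene-wise mean and sample standard deviation with a
#' two-tailed z-test: entry 1 iff
#' `|x - mean_ref| / sd_ref >= qnorm(1 - alpha/2)` (1.959964 at alpha 0.05).
#'
#' @param expr Standardized expression tibble (apply [standardize_samples()]
#'   first).
#' @param groups Sample group labels (see [group_means()]); the case group
#'   provides the columns of the indicator matrix.
#' @param alpha Two-tailed significance level, default 0.05.
#' @param ref,case Optional group labels (see [group_means()]).
#' @return A tibble with a `gene` column and one 0/1 column per case sample,
#'   carrying attributes `alpha` and `case`. Genes with zero reference
#'   variance get all-zero rows with a warning.
#' @export
build_indicator_matrix <- function(expr, groups, alpha = 0.05,
                                   ref = NULL, case = NULL) {
  m <- validate_expr(expr, require_linear = FALSE)
  if (!identical(expr_scale(expr), "standardized")) {
    abort("`expr` must be standardized; apply standardize_samples() first")
  }
  g <- resolve_groups(groups, colnames(m), ref = ref, case = case)
  if (length(g$ref_samples) < 2) abort("need at least two reference samples")
  ref_m <- m[, g$ref_samples, drop = FALSE]
  mu <- rowMeans(ref_m)
  s <- apply(ref_m, 1, sd)
  zcrit <- qnorm(1 - alpha / 2)
  cz <- (m[, g$case_samples, drop = FALSE] - mu) / s
  ind <- (abs(cz) >= zcrit) * 1L
  if (any(s == 0)) {
    zero <- rownames(m)[s == 0]
    warn(sprintf("zero reference variance for gene(s) %s; indicator set to 0",
                 paste(head(zero, 5), collapse = ", ")))
    ind[s == 0, ] <- 0L
  }
  out <- new_expr_tbl(ind, "standardized")
  attr(out, "expr_scale") <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "case") <- g$case
  out
}

ind_matrix <- function(ind) {
  m <- as_expr_matrix(ind)
  if (!all(m %in% c(0, 1))) abort("indicator matrix entries must be 0 or 1")
  m
}

#' Per-gene activity under a case-exception budget
#'
#' A gene is active when it is differentially expressed in all but at most
#' `L` case samples.
#'
#' @param ind Indicator matrix tibble from [build_indicator_matrix()].
#' @param L Case-exception budget, `0 <= L <=` number of cases.
#' @return A tibble `gene`, `n_active`, `n_exceptions`, `active`.
#' @export
node_activity <- function(ind, L) {
  m <- ind_matrix(ind)
  n_cases <- ncol(m)
  stopifnot(L >= 0, L <= n_cases)
  n_active <- as.integer(rowSums(m))
  tibble::tibble(gene = rownames(m),
                 n_active = n_active,
                 n_exceptions = n_cases - n_active,
                 active = (n_cases - n_active) <= L)
}

# Shared per-node data for the solvers. Network genes missing from the
# indicator matrix are inactive (exception candidates) with zero active
# entries.
kpm_node_data <- function(edges, ind, L) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  m <- ind_matrix(ind)
  n_cases <- ncol(m)
  stopifnot(L >= 0, L <= n_cases)
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (length(nodes) == 0) abort("the network has no edges")
  n_act <- setNames(integer(length(nodes)), nodes)
  hit <- intersect(nodes, rownames(m))
  n_act[hit] <- as.integer(rowSums(m[hit, , drop = FALSE]))
  exceptions <- n_cases - n_act
  active <- exceptions <= L
  adj <- vector("list", length(nodes))
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  keep <- fi != ti
  for (k in which(keep)) {
    adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
    adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  list(nodes = nodes, adj = adj, active = unname(active),
       active_entries = unname(n_act), exceptions = unname(exceptions),
       n_cases = n_cases)
}

rank_kpm_sets <- function(sets, nd, K, L, top_n, solver) {
  if (length(sets) == 0) {
    out <- tibble::tibble(rank = integer(0), size = integer(0),
                          n_exception_nodes = integer(0),
                          total_active = integer(0),
                          nodes = list(), exception_nodes = list())
  } else {
    keys <- vapply(sets, function(s) paste(sort(nd$nodes[s]), collapse = "|"), character(1))
    dup <- duplicated(keys)
    sets <- sets[!dup]
    keys <- keys[!dup]
    size <- lengths(sets)
    total_active <- vapply(sets, function(s) sum(nd$active_entries[s]), numeric(1))
    ord <- order(-size, -total_active, keys)
    take <- head(ord, top_n)
    out <- tibble::tibble(
      rank = seq_along(take),
      size = as.integer(size[take]),
      n_exception_nodes = vapply(sets[take], function(s) sum(!nd$active[s]), integer(1)),
      total_active = as.integer(total_active[take]),
      nodes = lapply(sets[take], function(s) sort(nd$nodes[s])),
      exception_nodes = lapply(sets[take], function(s) sort(nd$nodes[s[!nd$active[s]]]))
    )
  }
  structure(out, K = K, L = L, solver = solver, n_cases = nd$n_cases,
            class = c("kpm_solutions", class(out)))
}

#' Exact K/L active-subgraph solver
#'
#' Enumerates every connected induced subgraph that contains at least one
#' active gene and at most `K` inactive (exception) genes, where a gene is
#' active when differentially expressed in all but at most `L` cases
#' (individual-node-exception semantics). Returns the `top_n` largest
#' distinct node sets, ranked by size, then total active indicator entries,
#' then lexicographically. Exact but exponential in the worst case: intended
#' for small instances (default limit 25 nodes) and as the reference for the
#' greedy solver.
#'
#' @param edges Edge tibble (`from`, `to`).
#' @param ind Indicator matrix tibble from [build_indicator_matrix()].
#' @param K Node-exception budget (number of inactive genes allowed).
#' @param L Case-exception budget per gene.
#' @param top_n Number of solutions to return (default 20).
#' @param max_nodes Refuse instances with more nodes than this (default 25).
#' @return A `kpm_solutions` tibble (possibly empty when no gene is active).
#' @export
solve_ines_exact <- function(edges, ind, K, L, top_n = 20, max_nodes = 25) {
  stopifnot(K >= 0, top_n >= 1)
  nd <- kpm_node_data(edges, ind, L)
  n <- length(nd$nodes)
  if (n > max_nodes) {
    abort(sprintf("instance has %d nodes (> %d); use solve_ines_greedy()", n, max_nodes))
  }
  env <- new.env(parent = emptyenv())
  env$sets <- vector("list", 4096)
  env$count <- 0L
  cap <- 200000L
  record <- function(s) {
    env$count <- env$count + 1L
    if (env$count > cap) {
      abort("exact enumeration exceeded its subset cap; use solve_ines_greedy()")
    }
    if (env$count > length(env$sets)) {
      env$sets <- c(env$sets, vector("list", length(env$sets)))
    }
    env$sets[[env$count]] <- s
  }
  active <- nd$active
  adj <- nd$adj
  # rec: emit S and all connected feasible supersets reachable via ext,
  # never touching forb. Each set is emitted exactly once.
  rec <- function(S, inact, ext, forb) {
    record(S)
    while (length(ext) > 0) {
      u <- ext[1]
      ext <- ext[-1]
      inact_u <- inact + !active[u]
      if (inact_u <= K) {
        forb_u <- forb
        forb_u[u] <- TRUE
        nb <- adj[[u]]
        nb <- nb[!forb_u[nb] & !nb %in% S & !nb %in% ext]
        rec(c(S, u), inact_u, c(ext, nb), forb_u)
      }
      forb[u] <- TRUE
    }
  }
  starts <- which(active)
  forb0 <- rep(FALSE, n)
  for (v in starts) {
    forb_v <- forb0
    nb <- adj[[v]][!forb_v[adj[[v]]] & adj[[v]] != v]
    rec(v, 0L, nb, forb_v)
    forb0[v] <- TRUE  # later starts may not contain earlier active nodes
  }
  rank_kpm_sets(env$sets[seq_len(env$count)], nd, K, L, top_n, "exact")
}

#' Greedy K/L active-subgraph solver
#'
#' Deterministic seeded replacement for a metaheuristic search: from each
#' active seed gene (visited in a seed-controlled random order), repeatedly
#' adds the feasible neighboring gene that most increases the solution —
#' preferring active genes, then genes adjacent to the most not-yet-included
#' active genes, breaking remaining ties lexicographically — until no
#' feasible neighbor remains. Inactive genes are added only while the `K`
#' budget allows.
#'
#' @inheritParams solve_ines_exact
#' @param seed Integer seed controlling the seed-node visiting order.
#' @param restarts Number of active seed genes to grow from (default: all).
#' @return A `kpm_solutions` tibble of the `top_n` distinct solutions found.
#' @export
solve_ines_greedy <- function(edges, ind, K, L, top_n = 20, seed = 1,
                              restarts = NULL) {
  stopifnot(K >= 0, top_n >= 1)
  nd <- kpm_node_data(edges, ind, L)
  n <- length(nd$nodes)
  active <- nd$active
  adj <- nd$adj
  seeds <- which(active)
  if (length(seeds) > 1) {
    seeds <- with_seed(derive_seed(seed, "kpm_greedy"), sample(seeds))
  }
  if (!is.null(restarts)) seeds <- head(seeds, restarts)
  grow <- function(v) {
    inS <- rep(FALSE, n)
    inS[v] <- TRUE
    used_k <- as.integer(!active[v])
    repeat {
      boundary <- unique(unlist(adj[inS]))
      boundary <- boundary[!inS[boundary]]
      if (used_k >= K) boundary <- boundary[active[boundary]]
      if (length(boundary) == 0) break
      gain <- vapply(boundary, function(u) {
        nb <- adj[[u]]
        sum(active[nb] & !inS[nb])
      }, numeric(1))
      ord <- order(-active[boundary], -gain, nd$nodes[boundary])
      u <- boundary[ord[1]]
      inS[u] <- TRUE
      used_k <- used_k + as.integer(!active[u])
    }
    which(inS)
  }
  sets <- lapply(seeds, grow)
  rank_kpm_sets(sets, nd, K, L, top_n, "greedy")
}

#' Validate a K/L subgraph solution
#'
#' Independent check of the individual-node-exception constraints: the
#' induced subgraph is connected, contains at most `K` inactive genes, at
#' least one active gene, and every non-exception gene misses at most `L`
#' cases.
#'
#' @param nodes Character vector of genes.
#' @param edges Edge tibble of the network.
#' @param ind Indicator matrix tibble.
#' @param K,L Constraint budgets.
#' @return `TRUE` if all constraints hold, otherwise `FALSE` with a `reason`
#'   attribute.
#' @export
validate_kpm_solution <- function(nodes, edges, ind, K, L) {
  fail <- function(why) structure(FALSE, reason = why)
  if (length(nodes) == 0) return(fail("empty node set"))
  net_nodes <- unique(c(edges$from, edges$to))
  if (!all(nodes %in% net_nodes)) return(fail("node not in network"))
  sub <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[c("from", "to")], directed = FALSE,
                                     vertices = nodes)
  if (igraph::components(g)$no != 1) return(fail("induced subgraph not connected"))
  m <- ind_matrix(ind)
  n_cases <- ncol(m)
  exc <- setNames(rep(n_cases, length(nodes)), nodes)
  hit <- intersect(nodes, rownames(m))
  exc[hit] <- n_cases - rowSums(m[hit, , drop = FALSE])
  inactive <- exc > L
  if (sum(inactive) > K) return(fail("more than K exception nodes"))
  if (all(inactive)) return(fail("no active node"))
  TRUE
}

#' Smallest case-exception budget reaching a target subnetwork size
#'
#' Solution size is monotone non-decreasing in `L`, so the minimal `L` for
#' which the solver returns a subnetwork of at least `target_size` genes is
#' found by binary search over `[0, n_cases]`.
#'
#' @inheritParams solve_ines_exact
#' @param target_size Required solution size (>= 1).
#' @param solver `"auto"` (exact up to `max_nodes` nodes, else greedy),
#'   `"exact"`, or `"greedy"`.
#' @param seed Seed forwarded to the greedy solver.
#' @return The minimal `L` as an integer, or `NA` (with a message) when the
#'   target is unattainable even at `L = n_cases`.
#' @export
min_L_for_size <- function(edges, ind, K, target_size, solver = c("auto", "exact", "greedy"),
                           seed = 1, max_nodes = 25) {
  solver <- match.arg(solver)
  stopifnot(target_size >= 1)
  n_cases <- ncol(ind_matrix(ind))
  n_nodes <- length(unique(c(edges$from, edges$to)))
  use_exact <- switch(solver, exact = TRUE, greedy = FALSE,
                      auto = n_nodes <= max_nodes)
  best_size <- function(L) {
    sol <- if (use_exact) {
      solve_ines_exact(edges, ind, K = K, L = L, top_n = 1, max_nodes = max_nodes)
    } else {
      solve_ines_greedy(edges, ind, K = K, L = L, top_n = 1, seed = seed)
    }
    if (nrow(sol) == 0) 0L else sol$size[1]
  }
  if (best_size(n_cases) < target_size) {
    inform(sprintf("target size %d unattainable even at L = %d", target_size, n_cases))
    return(NA_integer_)
  }
  lo <- 0L
  hi <- n_cases
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (best_size(mid) >= target_size) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' @export
print.kpm_solutions <- function(x, ...) {
  cat(sprintf("<kpm_solutions> %d solution(s) [K = %d, L = %d, solver = %s]\n",
              nrow(x), attr(x, "K"), attr(x, "L"), attr(x, "solver")))
  if (nrow(x)) {
    print(tibble::as_tibble(x[c("rank", "size", "n_exception_nodes", "total_active")]), n = 10)
  }
  invisible(x)
}
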