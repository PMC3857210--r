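# Independent oracles and fixture builders used across the test files.
# Oracles are deliberately naive re-computations that share no code with the
# package internals.

# quantile normalization oracle for matrices without ties: each column's
# values are replaced, rank-wise, by the across-column means of the sorted
# values
qn_oracle <- function(m) {
  sorted_means <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- sorted_means
  out
}

# expression tibble from a plain matrix (genes x samples)
expr_from_matrix <- function(m, scale = "linear") {
  out <- tibble::as_tibble(m, rownames = "gene")
  attr(out, "expr_scale") <- scale
  out
}

mat_of <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  rownames(m) <- expr$gene
  m
}

# tiny deterministic two-group expression fixture
tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4, 2, 2, 8, 6), nrow = 2, byrow = FALSE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3", "s4")))
  expr_from_matrix(m)
}

tiny_groups <- function() {
  tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                 group = c("A", "A", "B", "B"))
}

# random annotated network built directly (bypasses the file readers)
random_annotated <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(genes, 2))
  take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- tibble::tibble(from = pairs[take, 1], to = pairs[take, 2])
  nodes <- tibble::tibble(gene = genes,
                          mean_ref = runif(n_nodes, 0.5, 20),
                          mean_case = runif(n_nodes, 0.5, 20))
  structure(list(nodes = nodes, edges = edges), class = "annotated_network")
}

# random K/L instance: small graph plus a random indicator matrix
random_kpm_instance <- function(n_nodes, n_cases, seed, p_edge = 0.35,
                                p_active = 0.5) {
  set.seed(seed)
  genes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
  ind_m <- matrix(rbinom(n_nodes * n_cases, 1, p_active), nrow = n_nodes,
                  dimnames = list(genes, sprintf("c%02d", seq_len(n_cases))))
  ind <- tibble::as_tibble(ind_m, rownames = "gene")
  list(edges = edges, ind = ind)
}

# brute-force K/L solver: enumerate every node subset by bitmask, keep
# connected ones with >= 1 active node and <= K inactive, rank by size,
# total active entries, then lexicographic node-set key
brute_kpm <- function(edges, ind, K, L, top_n = 20) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  stopifnot(n <= 16)
  m <- mat_of(ind)
  n_cases <- ncol(m)
  n_act <- setNames(rep(0, n), nodes)
  hit <- intersect(nodes, rownames(m))
  n_act[hit] <- rowSums(m[hit, , drop = FALSE])
  active <- (n_cases - n_act) <= L
  bit <- bitwShiftL(1L, 0:(n - 1))
  nbrmask <- integer(n)
  fi <- match(edges$from, nodes)
  ti <- match(edges$to, nodes)
  for (k in seq_along(fi)) {
    if (fi[k] == ti[k]) next
    nbrmask[fi[k]] <- bitwOr(nbrmask[fi[k]], bit[ti[k]])
    nbrmask[ti[k]] <- bitwOr(nbrmask[ti[k]], bit[fi[k]])
  }
  sets <- list()
  size <- integer(0)
  tot <- numeric(0)
  key <- character(0)
  for (s in seq_len(2^n - 1)) {
    members <- which(bitwAnd(s, bit) != 0L)
    if (!any(active[members])) next
    if (sum(!active[members]) > K) next
    reach <- bit[members[1]]
    repeat {
      nxt <- reach
      for (v in members) {
        if (bitwAnd(reach, bit[v]) != 0L) nxt <- bitwOr(nxt, bitwAnd(nbrmask[v], s))
      }
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach != s) next
    i <- length(sets) + 1L
    sets[[i]] <- nodes[members]
    size[i] <- length(members)
    tot[i] <- sum(n_act[members])
    key[i] <- paste(nodes[members], collapse = "|")
  }
  ord <- order(-size, -tot, key)
  lapply(head(ord, top_n), function(i) sets[[i]])
}

# hypergeometric upper-tail probability by direct enumeration
hyper_tail_oracle <- function(overlap, set_size, bg_size, query_size) {
  i <- overlap:min(set_size, query_size)
  sum(choose(set_size, i) * choose(bg_size - set_size, query_size - i)) /
    choose(bg_size, query_size)
}

# Benjamini-Hochberg step-up by its textbook definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# write an edge tibble as a STRING-style links file
write_links_file <- function(edges, path, delim = "\t") {
  hdr <- paste(c("protein1", "protein2", "experimental", "database", "textmining"),
               collapse = delim)
  rows <- apply(edges, 1, paste, collapse = delim)
  writeLines(c(hdr, rows), path)
  path
}
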