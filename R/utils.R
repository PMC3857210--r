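# Internal helpers shared across modules.

# Expression tibbles carry a `gene` key column plus one numeric column per
# sample, and an "expr_scale" attribute ("linear" or "standardized").

new_expr_tbl <- function(mat, scale = c("linear", "standardized")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  out <- tibble::as_tibble(mat, rownames = "gene")
  attr(out, "expr_scale") <- scale
  out
}

as_expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (!is.numeric(m)) abort("expression columns must all be numeric")
  rownames(m) <- expr$gene
  m
}

expr_scale <- function(expr) attr(expr, "expr_scale") %||% "linear"

validate_expr <- function(expr, require_linear = TRUE, arg = "expr") {
  if (!is.data.frame(expr) || !"gene" %in% names(expr)) {
    abort(sprintf("`%s` must be a data frame with a `gene` column", arg))
  }
  if (anyDuplicated(expr$gene)) {
    abort(sprintf("duplicate gene identifiers in `%s`: %s", arg,
                  paste(unique(expr$gene[duplicated(expr$gene)]), collapse = ", ")))
  }
  m <- as_expr_matrix(expr)
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers")
  if (anyNA(m)) abort("missing expression values are not supported")
  if (require_linear) {
    if (identical(expr_scale(expr), "standardized")) {
      abort(sprintf("`%s` is standardized; a linear-scale matrix is required", arg))
    }
    if (any(m <= 0)) {
      bad <- which(m <= 0, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "non-positive intensity for gene '%s', sample '%s'; linear-scale values must be > 0 (set `floor` on read to clamp)",
        rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
  }
  invisible(m)
}

# Group label tables: columns `sample`, `group`, exactly two labels. Returns
# list(ref=, case=, ref_samples=, case_samples=) after checking coverage.
resolve_groups <- function(groups, samples, ref = NULL, case = NULL) {
  if (!is.data.frame(groups) || ncol(groups) < 2) {
    abort("`groups` must be a data frame with columns `sample` and `group`")
  }
  if (!all(c("sample", "group") %in% names(groups))) {
    names(groups)[1:2] <- c("sample", "group")
  }
  groups <- dplyr::distinct(groups, .data$sample, .data$group)
  if (anyDuplicated(groups$sample)) abort("a sample is assigned to more than one group")
  missing <- setdiff(samples, groups$sample)
  if (length(missing)) {
    abort(sprintf("unlabelled samples: %s", paste(head(missing, 5), collapse = ", ")))
  }
  groups <- groups[groups$sample %in% samples, , drop = FALSE]
  labs <- sort(unique(as.character(groups$group)))
  if (length(labs) != 2) {
    abort(sprintf("expected exactly two group labels among the matrix samples, found %d", length(labs)))
  }
  ref <- ref %||% labs[1]
  case <- case %||% setdiff(labs, ref)
  if (!ref %in% labs || !case %in% labs || identical(ref, case)) {
    abort("`ref` and `case` must name the two distinct group labels")
  }
  ref_samples <- groups$sample[groups$group == ref]
  case_samples <- groups$sample[groups$group == case]
  if (!length(ref_samples) || !length(case_samples)) {
    abort(sprintf("group with zero samples: '%s'", if (length(ref_samples)) case else ref))
  }
  list(ref = ref, case = case, ref_samples = ref_samples, case_samples = case_samples)
}

# Canonical undirected edge representation: from < to lexicographically.
canonicalize_edges <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges
}

edge_key <- function(from, to) paste(pmin(from, to), pmax(from, to), sep = "\r")

# Deterministic per-operation RNG streams derived from one user seed, so that
# adding an operation never perturbs the draws of existing ones.
derive_seed <- function(seed, stream) {
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 65521
  as.integer(((as.numeric(seed) %% 65521) * 69421 + h * 7919 + 1) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
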