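#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate members within a set are counted once.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with attributes `descriptions`
#'   (named character) and `collection` (file stem).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d: expected name, description and at least one gene", bad[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate set name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2), nm)
  attr(sets, "collection") <- sub("\\.gmt$", "", basename(path), ignore.case = TRUE)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a query
#' gene set relative to a background universe, with the one-sided
#' hypergeometric upper-tail probability `P[X >= overlap]` and
#' Benjamini-Hochberg adjustment across sets. Sets are intersected with the
#' background before testing; depletion is not tested.
#'
#' @param query Character vector of genes; must be a subset of `background`.
#' @param sets Named list of character vectors, e.g. from [read_gmt()].
#' @param background Character vector: the gene universe (e.g. the genes of
#'   the annotated network, the sampling frame of the subnetwork methods).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return An `enrichment_result` tibble sorted by increasing p-value:
#'   `term`, `overlap`, `set_size`, `query_size`, `bg_size`, `p.value`,
#'   `q.value`, `significant`, `genes` (list column of overlapping genes).
#' @export
enrich <- function(query, sets, background, alpha = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(query) == 0) abort("`query` is empty")
  if (!all(query %in% background)) {
    abort(sprintf("query gene(s) outside the background: %s",
                  paste(head(setdiff(query, background), 5), collapse = ", ")))
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  N <- length(background)
  q <- length(query)
  res <- purrr::imap(sets, function(members, nm) {
    s <- intersect(unique(members), background)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    tibble::tibble(term = nm, overlap = k, set_size = length(s),
                   query_size = q, bg_size = N, p.value = p,
                   genes = list(sort(ov)))
  }) |> purrr::list_rbind()
  res$q.value <- p.adjust(res$p.value, method = "BH")
  res$significant <- res$q.value < alpha
  res <- dplyr::arrange(res, .data$p.value, .data$term)
  res <- res[, c("term", "overlap", "set_size", "query_size", "bg_size",
                 "p.value", "q.value", "significant", "genes")]
  class(res) <- c("enrichment_result", class(res))
  res
}
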