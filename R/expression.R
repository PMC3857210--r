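#' Read an expression table
#'
#' Reads a delimited probe- or gene-level expression table into a tidy
#' expression tibble (one `gene` identifier column plus one numeric column per
#' sample). Values are expected on the linear scale (strictly positive
#' intensities); downstream functions apply log2 where the statistics require
#' it.
#'
#' @param path Path to a TSV or CSV file with one header line. The first
#'   column holds row identifiers.
#' @param orientation `"genes"` if rows are genes/probes (the default),
#'   `"samples"` if the file is transposed.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @param floor Optional positive floor applied to all intensities
#'   (`pmax(x, floor)`). By default zero or negative intensities are an error;
#'   pass e.g. `floor = 1e-6` to clamp instead.
#'
#' @return A tibble with a `gene` column and one numeric column per sample,
#'   flagged as linear scale.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t4", "g2\t2\t6"), p)
#' read_expression(p)
read_expression <- function(path, orientation = c("genes", "samples"),
                            delim = NULL, floor = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) abort("expression table needs an identifier column and at least one value column")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate row identifiers: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  cols <- names(raw)[-1]
  if (anyDuplicated(cols)) abort("duplicate column identifiers")
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(cols),
              dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    v0 <- raw[[j + 1]]
    v <- suppressWarnings(as.numeric(v0))
    bad <- which(is.na(v) & !is.na(v0))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                    v0[bad[1]], ids[bad[1]], cols[j]))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value at row '%s', column '%s'",
                    ids[which(is.na(v))[1]], cols[j]))
    }
    m[, j] <- v
  }
  if (orientation == "samples") m <- t(m)
  if (!is.null(floor)) {
    stopifnot(is.numeric(floor), floor > 0)
    m <- pmax(m, floor)
  }
  out <- new_expr_tbl(m, "linear")
  validate_expr(out)
  out
}

#' Write an expression tibble to TSV
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expr(expr, require_linear = FALSE)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' vector of across-sample means of the rank-ordered values. Within-column
#' rank order is preserved; tied values receive the mean of the rank-means
#' they span. Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr Linear-scale expression tibble with at least two samples.
#' @return Quantile-normalized expression tibble (linear scale).
#' @export
quantile_normalize <- function(expr) {
  m <- validate_expr(expr)
  if (ncol(m) < 2) abort("quantile normalization needs at least two samples")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  new_expr_tbl(qn, "linear")
}

#' Collapse probe-level rows to gene level
#'
#' Averages the probes mapping to each gene: a gene's value in a sample is the
#' arithmetic mean of its probes' values in that sample. Probes absent from
#' the map, and probes mapping ambiguously to more than one gene, are dropped
#' (with a message reporting the counts).
#'
#' @param expr Probe-level expression tibble (the `gene` column holds probe
#'   identifiers).
#' @param probe_map Data frame with columns `probe` and `gene` (first two
#'   columns are used if named differently).
#' @return Gene-level expression tibble on the same scale.
#' @export
collapse_probes <- function(expr, probe_map) {
  m <- validate_expr(expr, require_linear = FALSE)
  if (!is.data.frame(probe_map) || ncol(probe_map) < 2) {
    abort("`probe_map` must be a data frame with columns `probe` and `gene`")
  }
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    names(probe_map)[1:2] <- c("probe", "gene")
  }
  pm <- dplyr::distinct(probe_map, .data$probe, .data$gene)
  ambiguous <- unique(pm$probe[duplicated(pm$probe)])
  if (length(ambiguous)) {
    inform(sprintf("dropping %d probe(s) mapping to more than one gene", length(ambiguous)))
    pm <- pm[!pm$probe %in% ambiguous, , drop = FALSE]
  }
  pm <- pm[pm$probe %in% rownames(m), , drop = FALSE]
  unmapped <- sum(!rownames(m) %in% pm$probe)
  if (unmapped > 0) inform(sprintf("dropping %d unmapped probe(s)", unmapped))
  if (nrow(pm) == 0) abort("no probe of the matrix is present in the probe map")
  sub <- m[pm$probe, , drop = FALSE]
  sums <- rowsum(sub, group = pm$gene)
  counts <- as.vector(table(pm$gene)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  new_expr_tbl(out, expr_scale(expr))
}

#' Group-wise mean expression
#'
#' Averages each gene's expression within the reference group (e.g.
#' non-responders) and the case group (e.g. responders), on the linear scale.
#'
#' @param expr Gene-level linear-scale expression tibble.
#' @param groups Data frame with columns `sample` and `group` labelling every
#'   sample of `expr` into exactly two groups.
#' @param ref,case Group labels to use as reference and case. Default: the
#'   lexicographically first label is the reference.
#' @return A tibble with columns `gene`, `mean_ref`, `mean_case` and
#'   attributes `ref`/`case` naming the groups.
#' @export
group_means <- function(expr, groups, ref = NULL, case = NULL) {
  m <- validate_expr(expr)
  g <- resolve_groups(groups, colnames(m), ref = ref, case = case)
  out <- tibble::tibble(
    gene = rownames(m),
    mean_ref = unname(rowMeans(m[, g$ref_samples, drop = FALSE])),
    mean_case = unname(rowMeans(m[, g$case_samples, drop = FALSE]))
  )
  attr(out, "ref") <- g$ref
  attr(out, "case") <- g$case
  out
}

#' Standardize each sample to mean 0, variance 1
#'
#' Per-sample z-scoring across genes (sample variance, divisor n-1), as used
#' before building the per-case indicator matrix.
#'
#' @param expr Expression tibble with at least two genes.
#' @return Expression tibble flagged as standardized.
#' @export
standardize_samples <- function(expr) {
  m <- validate_expr(expr, require_linear = FALSE)
  if (nrow(m) < 2) abort("standardization needs at least two genes per sample")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant expression in sample(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  z <- scale(m, center = TRUE, scale = sds)
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  new_expr_tbl(z, "standardized")
}

#' Read a GEO series-matrix file
#'
#' Minimal reader for the plain-text series-matrix format: extracts the value
#' table between the `!series_matrix_table_begin/end` markers and, optionally,
#' a `!Sample_characteristics_ch1` line matching a pattern (used to derive
#' group labels such as responder status).
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @param characteristics_pattern Optional regular expression; the first
#'   characteristics line matching it is returned per sample.
#' @return A list with `expr` (linear-scale expression tibble) and
#'   `characteristics` (tibble `sample`, `value`, or `NULL`).
#' @export
read_series_matrix <- function(path, characteristics_pattern = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    abort("no series-matrix value table found")
  }
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(gsub('"', "", lines[(beg + 1):(end - 1)], fixed = TRUE), tf)
  expr <- read_expression(tf, orientation = "genes")
  chars <- NULL
  if (!is.null(characteristics_pattern)) {
    cand <- grep("^!Sample_characteristics", lines, value = TRUE)
    hit <- grep(characteristics_pattern, cand, value = TRUE)
    if (length(hit)) {
      vals <- gsub('"', "", strsplit(hit[1], "\t", fixed = TRUE)[[1]][-1], fixed = TRUE)
      samples <- setdiff(names(expr), "gene")
      if (length(vals) == length(samples)) {
        chars <- tibble::tibble(sample = samples, value = vals)
      } else {
        warn("characteristics line length does not match sample count; ignored")
      }
    }
  }
  list(expr = expr, characteristics = chars)
}
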