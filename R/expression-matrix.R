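# Expression matrices: genes x samples tibbles carrying a unit tag.
# Units: "scaled_estimate" (RSEM within-sample transcript frequencies,
# values in [0, 1]), "TPM" (transcripts per million), "log2TPM".

EXPR_UNITS <- c("scaled_estimate", "TPM", "log2TPM")

#' Construct an expression matrix tibble
#'
#' An expression matrix is a tibble whose first column is `gene_id` and whose
#' remaining columns are one numeric column per sample, with the measurement
#' unit recorded in the `"unit"` attribute. Abundance units
#' (`scaled_estimate`, `TPM`) must be non-negative; `scaled_estimate` values,
#' being within-sample transcript frequencies, must not exceed 1.
#'
#' @param x A data frame with a `gene_id` character column and numeric sample
#'   columns.
#' @param unit One of `"scaled_estimate"`, `"TPM"`, `"log2TPM"`.
#' @return A tibble of class `expr_tbl` with attribute `unit`.
#' @export
expression_matrix <- function(x, unit) {
  unit <- rlang::arg_match(unit, EXPR_UNITS)
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    rlang::abort("expression matrix needs a `gene_id` column.",
      class = "refstab_input_error"
    )
  }
  x <- dplyr::relocate(x, "gene_id")
  if (ncol(x) < 2L) {
    rlang::abort("expression matrix needs at least one sample column.",
      class = "refstab_input_error"
    )
  }
  if (anyDuplicated(x$gene_id)) {
    rlang::abort("duplicate gene ids.", class = "refstab_input_error")
  }
  if (anyDuplicated(names(x))) {
    rlang::abort("duplicate sample ids.", class = "refstab_input_error")
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (nrow(x) > 0L && !is.numeric(vals)) {
    rlang::abort("sample columns must be numeric.", class = "refstab_input_error")
  }
  if (unit %in% c("scaled_estimate", "TPM") && any(vals < 0, na.rm = TRUE)) {
    rlang::abort(paste0(unit, " values must be non-negative."),
      class = "refstab_domain_error"
    )
  }
  if (unit == "scaled_estimate" && any(vals > 1, na.rm = TRUE)) {
    rlang::abort("scaled_estimate values are frequencies and must be <= 1.",
      class = "refstab_domain_error"
    )
  }
  attr(x, "unit") <- unit
  class(x) <- c("expr_tbl", class(x))
  x
}

#' Unit of an expression matrix
#' @param x An `expr_tbl`.
#' @return The unit string.
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

expr_replace_values <- function(x, m, unit) {
  out <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = x$gene_id),
    tibble::as_tibble(m)
  ))
  attr(out, "unit") <- unit
  class(out) <- c("expr_tbl", class(tibble::tibble()))
  out
}

check_unit <- function(x, expected, op) {
  u <- expr_unit(x)
  if (is.null(u) || !identical(u, expected)) {
    rlang::abort(
      sprintf(
        "%s() expects a matrix in %s units, got %s.",
        op, expected, if (is.null(u)) "<untagged>" else u
      ),
      class = "refstab_unit_error"
    )
  }
  invisible(x)
}

#' Convert RSEM scaled_estimate values to TPM
#'
#' RSEM's `scaled_estimate` is the estimated frequency of a transcript among
#' all sequenced transcripts of the sample; multiplying by one million
#' (`1e6`) yields transcripts per million.
#'
#' @param x An `expr_tbl` in `scaled_estimate` units.
#' @return An `expr_tbl` in `TPM` units, same shape.
#' @export
#' @examples
#' m <- expression_matrix(
#'   data.frame(gene_id = "g1", s1 = 2.5e-6),
#'   unit = "scaled_estimate"
#' )
#' to_tpm(m)$s1 # 2.5
to_tpm <- function(x) {
  check_unit(x, "scaled_estimate", "to_tpm")
  expr_replace_values(x, expr_values(x) * 1e6, "TPM")
}

#' Log2-transform a TPM matrix
#'
#' Positive TPM values become `log2(TPM)`. Zeros have no defined logarithm
#' and become `NA`, a sentinel that automatically fails every screening
#' criterion downstream; no pseudocount is added because usable reference
#' genes must be robustly expressed in all samples anyway.
#'
#' @param x An `expr_tbl` in `TPM` units.
#' @return An `expr_tbl` in `log2TPM` units.
#' @export
log2_transform <- function(x) {
  check_unit(x, "TPM", "log2_transform")
  m <- expr_values(x)
  if (any(m < 0, na.rm = TRUE)) {
    rlang::abort("negative TPM values have no logarithm.",
      class = "refstab_domain_error"
    )
  }
  out <- m
  out[m == 0] <- NA_real_
  out[m > 0] <- log2(m[m > 0])
  expr_replace_values(x, out, "log2TPM")
}

#' Read one or more RSEM `genes.results`-style files
#'
#' Each file is tab-delimited with a header row and at least a gene-id column
#' and a `scaled_estimate` column; one file corresponds to one sample. Files
#' are merged by gene id with an outer join; a gene absent from a file gets 0
#' in that sample.
#'
#' @param paths Character vector of file paths.
#' @param sample_ids Sample names; defaults to the file base names.
#' @param gene_col,value_col Column names in the files.
#' @return An `expr_tbl` in `scaled_estimate` units.
#' @export
read_rsem_genes <- function(paths, sample_ids = NULL,
                            gene_col = "gene_id",
                            value_col = "scaled_estimate") {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths)) {
    rlang::abort("`sample_ids` must match `paths` in length.",
      class = "refstab_input_error"
    )
  }
  tabs <- purrr::map2(paths, sample_ids, function(p, s) {
    tb <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    if (!all(c(gene_col, value_col) %in% names(tb))) {
      rlang::abort(
        sprintf("file %s lacks columns %s/%s.", p, gene_col, value_col),
        class = "refstab_parse_error"
      )
    }
    tibble::tibble(
      gene_id = as.character(tb[[gene_col]]),
      sample_id = s,
      value = as.numeric(tb[[value_col]])
    )
  })
  long <- dplyr::bind_rows(tabs)
  wide <- tidyr::pivot_wider(long,
    names_from = "sample_id", values_from = "value",
    values_fill = 0
  )
  expression_matrix(wide, unit = "scaled_estimate")
}

#' Read / write a generic genes x samples matrix
#'
#' Delimited text with the gene id in the first column and sample ids in the
#' header. The delimiter is inferred from the file extension (`.csv` comma,
#' otherwise tab).
#'
#' @param path File path.
#' @param unit Unit tag to attach on read.
#' @param x An `expr_tbl` to write.
#' @return `read_expression_matrix()` returns an `expr_tbl`;
#'   `write_expression_matrix()` returns `x` invisibly.
#' @export
read_expression_matrix <- function(path, unit) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tb <- reader(path, show_col_types = FALSE, progress = FALSE)
  names(tb)[1] <- "gene_id"
  tb$gene_id <- as.character(tb$gene_id)
  expression_matrix(tb, unit = unit)
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(x, path) {
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  writer(as.data.frame(x), path)
  invisible(x)
}
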