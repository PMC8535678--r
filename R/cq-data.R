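# Long-format Cq (quantification-cycle) datasets with sample metadata.
#
# A Cq dataset is a tibble with one row per reaction: gene_id, sample_id,
# replicate, cq, plus optional metadata columns (culture, passage,
# condition). Missing reactions are absent rows, never Cq = 0.

CONDITIONS <- c("normoxia", "acute_24h", "acute_72h", "chronic")

#' Assemble a Cq dataset
#'
#' Validates and joins long-format Cq records with per-sample metadata.
#' Cq values must lie in (0, `max_cycles`]; a reaction that did not cross
#' threshold is simply absent from the table.
#'
#' @param cq A data frame with columns `gene_id`, `sample_id`, `replicate`,
#'   `cq`.
#' @param metadata Optional data frame with `sample_id` plus any of
#'   `culture`, `passage`, `condition`; joined onto the records.
#' @param max_cycles Upper bound of the instrument's cycle range (default 40).
#' @return A tibble of class `cq_tbl`.
#' @export
cq_dataset <- function(cq, metadata = NULL, max_cycles = 40) {
  cq <- tibble::as_tibble(cq)
  need <- c("gene_id", "sample_id", "replicate", "cq")
  if (!all(need %in% names(cq))) {
    rlang::abort(
      paste0("Cq table needs columns: ", paste(need, collapse = ", ")),
      class = "refstab_input_error"
    )
  }
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0) || any(cq$cq > max_cycles)) {
    rlang::abort(
      sprintf("Cq values must lie in (0, %s]; absent reactions are absent rows.", max_cycles),
      class = "refstab_domain_error"
    )
  }
  if (anyDuplicated(cq[, c("gene_id", "sample_id", "replicate")])) {
    rlang::abort("duplicate (gene, sample, replicate) records.",
      class = "refstab_input_error"
    )
  }
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!"sample_id" %in% names(metadata)) {
      rlang::abort("metadata needs a `sample_id` column.",
        class = "refstab_input_error"
      )
    }
    if (anyDuplicated(metadata$sample_id)) {
      rlang::abort("duplicate sample ids in metadata.",
        class = "refstab_input_error"
      )
    }
    if ("condition" %in% names(metadata) &&
      !all(metadata$condition %in% CONDITIONS)) {
      rlang::abort(
        paste0("condition must be one of: ", paste(CONDITIONS, collapse = ", ")),
        class = "refstab_input_error"
      )
    }
    cq <- dplyr::left_join(cq, metadata, by = "sample_id")
  }
  class(cq) <- c("cq_tbl", class(cq))
  cq
}

#' Collapse technical replicates
#'
#' Averages the technical replicates of each (gene, sample) pair to a single
#' mean Cq; triplicate reactions must be summarized before any stability
#' analysis. The replicate SD and count are retained as quality metadata;
#' single replicates pass through unchanged.
#'
#' @param data A `cq_tbl` (replicate-level).
#' @return A tibble of class `cq_tbl`, one row per (gene, sample), with
#'   columns `cq` (mean), `cq_sd` (replicate SD, NA for singletons),
#'   `n_replicates`, and any metadata columns carried along.
#' @export
collapse_replicates <- function(data) {
  meta_cols <- intersect(c("culture", "passage", "condition"), names(data))
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene_id", "sample_id", meta_cols)))) |>
    dplyr::summarise(
      cq_sd = stats::sd(.data$cq),
      n_replicates = dplyr::n(),
      cq = mean(.data$cq),
      .groups = "drop"
    ) |>
    dplyr::relocate("gene_id", "sample_id", "cq", "cq_sd", "n_replicates") |>
    dplyr::arrange(.data$gene_id, .data$sample_id)
  class(out) <- c("cq_tbl", class(out))
  out
}

# Collapsed Cq tibble -> genes x samples matrix (NA where absent).
cq_matrix <- function(data) {
  wide <- tidyr::pivot_wider(
    data[, c("gene_id", "sample_id", "cq")],
    names_from = "sample_id", values_from = "cq"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m[, order(colnames(m)), drop = FALSE][order(rownames(m)), , drop = FALSE]
}

#' Amplification-efficiency table
#'
#' Per-gene amplification efficiency E, expressed as fold amplification per
#' cycle (2 = perfect doubling). Genes missing from the table default to
#' E = 2 with a warning. Efficiencies outside (1, 2.2] are implausible for
#' real assays and trigger a warning.
#'
#' @param x A data frame with columns `gene_id` and `efficiency`, or a named
#'   numeric vector.
#' @return A named numeric vector of class `efficiency_table`.
#' @export
efficiency_table <- function(x) {
  if (is.data.frame(x)) {
    e <- stats::setNames(as.numeric(x$efficiency), x$gene_id)
  } else {
    e <- x
  }
  if (is.null(names(e)) || anyDuplicated(names(e))) {
    rlang::abort("efficiencies must be uniquely named by gene.",
      class = "refstab_input_error"
    )
  }
  if (any(e <= 1)) {
    rlang::abort("amplification efficiency must exceed 1 fold/cycle.",
      class = "refstab_efficiency_error"
    )
  }
  if (any(e > 2.2)) {
    rlang::warn("efficiencies > 2.2 fold/cycle are implausible; check units.")
  }
  structure(e, class = "efficiency_table")
}

# Resolve efficiencies for a set of genes; absent genes default to 2.
resolve_efficiencies <- function(genes, eff = NULL) {
  e <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(eff)) {
    if (!inherits(eff, "efficiency_table")) eff <- efficiency_table(eff)
    known <- intersect(genes, names(eff))
    e[known] <- unclass(eff)[known]
    absent <- setdiff(genes, names(eff))
    if (length(absent)) {
      rlang::warn(paste0(
        "no efficiency for ", paste(absent, collapse = ", "),
        "; assuming perfect doubling (E = 2)."
      ))
    }
  }
  e
}

#' Convert Cq values to relative quantities
#'
#' Per gene, `RQ = E ^ (min(Cq) - Cq)`: the sample with the lowest Cq (the
#' most template) gets RQ = 1 and everything else falls in (0, 1]. The
#' reference point is presentation only — any fixed per-gene reference
#' cancels in every log-ratio the stability algorithms take.
#'
#' @param data A collapsed `cq_tbl`.
#' @param eff Optional [efficiency_table()]; genes not listed get E = 2.
#' @return Genes x samples numeric matrix of relative quantities.
#' @export
cq_to_rq <- function(data, eff = NULL) {
  m <- cq_matrix(data)
  e <- resolve_efficiencies(rownames(m), eff)
  sweep_min <- apply(m, 1L, min, na.rm = TRUE)
  e[rownames(m)]^(sweep_min - m)
}

#' Read long-format Cq and metadata files
#'
#' `read_cq_long()` reads a delimited file with columns gene, sample,
#' replicate, cq (extra columns kept); `read_sample_metadata()` reads the
#' per-sample design table. Delimiter inferred from extension (`.csv`
#' comma, else tab).
#'
#' @param path File path.
#' @param metadata_path Optional metadata file joined on read.
#' @return A `cq_tbl` / metadata tibble.
#' @export
read_cq_long <- function(path, metadata_path = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  tb <- reader(path, show_col_types = FALSE, progress = FALSE)
  md <- if (!is.null(metadata_path)) read_sample_metadata(metadata_path)
  cq_dataset(tb, metadata = md)
}

#' @rdname read_cq_long
#' @export
read_sample_metadata <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  reader(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cq_long
#' @param data A `cq_tbl` to write.
#' @export
write_cq_long <- function(data, path) {
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  writer(as.data.frame(data), path)
  invisible(data)
}
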