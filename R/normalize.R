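# Efficiency-corrected relative quantification of genes of interest
# against multi-gene normalization factors, with calibrator handling and
# NF acceptability checks.

#' Efficiency-corrected relative quantity
#'
#' `RQ = E ^ (Cq_cal - Cq_sample)`: one cycle earlier than the calibrator
#' means E-fold more template.
#'
#' @param cq_cal Calibrator Cq (cycles).
#' @param cq_sample Sample Cq (cycles).
#' @param e Amplification efficiency (fold/cycle), must exceed 1.
#' @return Relative quantity (dimensionless).
#' @export
#' @examples
#' relative_quantity(20, 19, 2) # 2
relative_quantity <- function(cq_cal, cq_sample, e) {
  if (any(e <= 1)) {
    rlang::abort("amplification efficiency must exceed 1 fold/cycle.",
      class = "refstab_efficiency_error"
    )
  }
  e^(cq_cal - cq_sample)
}

#' Multi-reference normalization factor
#'
#' Geometric mean of the reference genes' relative quantities in a sample.
#'
#' @param reference_rqs Numeric vector of RQs, all > 0.
#' @return The normalization factor.
#' @export
#' @examples
#' normalization_factor(c(2, 4, 8)) # 4
normalization_factor <- function(reference_rqs) {
  geomean(reference_rqs)
}

#' Normalize genes of interest against reference-gene subsets
#'
#' Efficiency-corrected multi-reference quantification: for every gene of
#' interest, reference subset and sample, computes the gene's relative
#' quantity against the calibrator sample (`RQ = E^(Cq_cal - Cq)`), the
#' normalization factor (geometric mean of the subset's reference RQs in
#' that sample), the normalized relative quantity `NRQ = RQ / NF`, and
#' `log2fc = log2(NRQ)` relative to the calibrator (whose row is exactly 0
#' by construction). With all efficiencies equal to 2 and a single
#' reference this reduces to the classical 2^-ddCt. NF outliers per
#' [nf_outlier_check()] are flagged per (subset, sample).
#'
#' @param data A collapsed or replicate-level `cq_tbl` containing the genes
#'   of interest and all reference genes.
#' @param goi Character vector of genes of interest.
#' @param references Character vector of selected reference genes.
#' @param calibrator Sample id used as calibrator (e.g. the first passage).
#' @param eff Optional [efficiency_table()]; unlisted genes get E = 2.
#' @param k Reference-subset size; default 3 (triplets). All
#'   `choose(length(references), k)` subsets are evaluated.
#' @param subsets Explicit list of reference subsets, overriding `k`.
#' @param nf_fold_limit Acceptability bound for [nf_outlier_check()].
#' @return A tibble of class `normalization_result`: `goi`, `subset_id`,
#'   `subset`, `sample_id`, `rq`, `nf`, `nrq`, `log2fc`, `nf_outlier`.
#' @export
normalize_goi <- function(data, goi, references, calibrator,
                          eff = NULL, k = 3L, subsets = NULL,
                          nf_fold_limit = 2) {
  m <- as_cq_matrix(data)
  need <- union(goi, references)
  absent <- setdiff(need, rownames(m))
  if (length(absent)) {
    rlang::abort(
      paste0("genes absent from the Cq data: ", paste(absent, collapse = ", ")),
      class = "refstab_missing_data_error"
    )
  }
  if (!calibrator %in% colnames(m)) {
    rlang::abort(
      paste0("calibrator sample '", calibrator, "' not in the data."),
      class = "refstab_calibrator_error"
    )
  }
  if (is.null(subsets)) subsets <- enumerate_subsets(references, k)
  e <- resolve_efficiencies(need, eff)

  # RQ of every needed gene vs the calibrator sample
  rq <- e[need]^(m[need, calibrator] - m[need, , drop = FALSE])

  out <- purrr::imap(subsets, function(refs, i) {
    nf <- apply(rq[refs, , drop = FALSE], 2L, geomean)
    outl <- nf_outlier_check(nf, fold_limit = nf_fold_limit)
    purrr::map(goi, function(g) {
      nrq_s <- rq[g, ] / nf
      log2fc_s <- log2(nrq_s) - log2(nrq_s[[calibrator]])
      tibble::tibble(
        goi = g,
        subset_id = paste0("T", i),
        subset = paste(refs, collapse = "+"),
        sample_id = colnames(m),
        rq = unname(rq[g, ]),
        nf = unname(nf),
        nrq = unname(nrq_s),
        log2fc = unname(log2fc_s),
        nf_outlier = unname(outl)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(out, "calibrator") <- calibrator
  attr(out, "references") <- references
  class(out) <- c("normalization_result", class(out))
  out
}

#' Check normalization factors for outlying samples
#'
#' A sample's NF should sit within `fold_limit`-fold of the average NF
#' (geometric mean by default — NFs are multiplicative quantities; an
#' arithmetic-mean dialect is available). Outlying NFs point to problems
#' with input amount, quality, or an unstable reference gene.
#'
#' @param nf Named numeric vector of normalization factors per sample.
#' @param fold_limit Acceptability bound, conventionally 2 to 3; default 2.
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return Logical vector: `TRUE` where the sample's NF is outside the
#'   acceptability band.
#' @export
nf_outlier_check <- function(nf, fold_limit = 2,
                             average = c("geometric", "arithmetic")) {
  average <- rlang::arg_match(average)
  if (length(nf) == 0L) {
    rlang::abort("`nf` must be non-empty.", class = "refstab_input_error")
  }
  if (!isTRUE(fold_limit >= 1)) {
    rlang::abort("`fold_limit` must be >= 1.", class = "refstab_config_error")
  }
  centre <- if (average == "geometric") geomean(nf) else mean(nf)
  nf > fold_limit * centre | nf < centre / fold_limit
}

#' Amplification efficiency from a standard (calibration) curve
#'
#' Least-squares fit of mean Cq against log10 template quantity across a
#' dilution series. The amplification efficiency is `E = 10^(-1/slope)`;
#' a perfect doubling assay has slope ~ -3.32 cycles per 10-fold dilution.
#'
#' @param log10_quantity Numeric vector of log10 template quantities.
#' @param cq Mean Cq at each dilution.
#' @return A list of class `calibration_curve`: `slope` (cycles per log10
#'   unit), `intercept`, `r2`, `efficiency`, `percent_efficiency`
#'   (100% = perfect doubling), and the fitted `model`.
#' @export
#' @examples
#' curve <- efficiency_from_curve(c(1, 2, 3, 4), c(30, 26.7, 23.4, 20.1))
#' curve$efficiency
efficiency_from_curve <- function(log10_quantity, cq) {
  if (length(unique(log10_quantity)) < 3L) {
    rlang::abort("need >= 3 distinct dilution levels.",
      class = "refstab_input_error"
    )
  }
  fit <- stats::lm(cq ~ log10_quantity)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    rlang::abort("calibration-curve slope must be negative (Cq falls as template rises).",
      class = "refstab_invalid_curve_error"
    )
  }
  e <- 10^(-1 / slope)
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r2 = summary(fit)$r.squared,
      efficiency = e,
      percent_efficiency = 100 * (e - 1),
      model = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> slope %.4f cycles/log10, E = %.4f (%.1f%%), R2 = %.4f\n",
    x$slope, x$efficiency, x$percent_efficiency, x$r2
  ))
  invisible(x)
}

#' @export
tidy.normalization_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "calibrator") <- NULL
  attr(out, "references") <- NULL
  out
}

#' @export
glance.normalization_result <- function(x, ...) {
  tibble::tibble(
    n_goi = length(unique(x$goi)),
    n_subsets = length(unique(x$subset_id)),
    n_samples = length(unique(x$sample_id)),
    n_nf_outliers = sum(x$nf_outlier[!duplicated(paste(x$subset_id, x$sample_id))]),
    calibrator = attr(x, "calibrator")
  )
}

#' Plot normalized fold changes
#'
#' log2 fold change of each gene of interest across samples, one line per
#' reference subset; the calibrator sits at 0.
#'
#' @param object A `normalization_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalization_result <- function(object, ...) {
  df <- tidy.normalization_result(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$log2fc,
    group = .data$subset_id, colour = .data$subset_id
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$goi)) +
    ggplot2::labs(
      x = NULL, y = "log2 fold change vs calibrator",
      colour = "reference subset"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
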