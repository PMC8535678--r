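# RefFinder-style consensus ranking, exclusion rules, culture combination
# and reference-subset enumeration.

#' Exclusion thresholds for candidate reference genes
#'
#' Cut-offs used to flag candidates before (or after) consensus ranking:
#' too lowly expressed (mean Cq above `cq_low_expression`), too highly
#' expressed (mean Cq below `cq_high_expression`, the rRNA situation),
#' too variable (CV% above `cv_max_pct` on the linear RQ scale), or poorly
#' correlated with the BestKeeper index (`r < bestkeeper_r_min`).
#'
#' @param cq_low_expression Cycles; default 28.
#' @param cq_high_expression Cycles; default 15.
#' @param cv_max_pct Percent; default 50.
#' @param bestkeeper_r_min Pearson r; default 0.8.
#' @return A list of class `exclusion_thresholds`.
#' @export
exclusion_thresholds <- function(cq_low_expression = 28,
                                 cq_high_expression = 15,
                                 cv_max_pct = 50,
                                 bestkeeper_r_min = 0.8) {
  if (!isTRUE(cq_high_expression < cq_low_expression)) {
    rlang::abort("need cq_high_expression < cq_low_expression.",
      class = "refstab_config_error"
    )
  }
  structure(
    list(
      cq_low_expression = cq_low_expression,
      cq_high_expression = cq_high_expression,
      cv_max_pct = cv_max_pct,
      bestkeeper_r_min = bestkeeper_r_min
    ),
    class = "exclusion_thresholds"
  )
}

#' Flag candidate genes against the exclusion rules
#'
#' Evaluates every gene of a collapsed Cq dataset against the exclusion
#' thresholds, drawing CV% and BestKeeper correlation from the supplied
#' stability results (computing them on the fly if absent). Flags are
#' advisory: pair with [reffinder_consensus()] in two-pass mode to mirror
#' an exclude-then-re-rank workflow.
#'
#' @param data A collapsed or replicate-level `cq_tbl`.
#' @param stability Optional named list of `stability_result` objects (as
#'   from [stability_all()]); `cv` and `bestkeeper` entries are used.
#' @param thresholds An [exclusion_thresholds()] object.
#' @param eff Optional [efficiency_table()] for the CV% computation.
#' @return A tibble with one row per gene: `gene_id`, `mean_cq`, `cv_pct`,
#'   `bestkeeper_r`, logical flag columns, `excluded` and a list-column
#'   `exclusion_reasons`.
#' @export
apply_exclusions <- function(data, stability = NULL,
                             thresholds = exclusion_thresholds(),
                             eff = NULL) {
  if (!inherits(thresholds, "exclusion_thresholds")) {
    rlang::abort("`thresholds` must come from exclusion_thresholds().",
      class = "refstab_config_error"
    )
  }
  m <- as_cq_matrix(data)
  cv_res <- stability$cv %||% stability_cv(data, eff = eff)
  bk_res <- stability$bestkeeper %||% stability_bestkeeper(data)

  genes <- sort(rownames(m))
  mean_cq <- rowMeans(m)[genes]
  cv_pct <- cv_res$statistic[genes]
  bk <- bk_res$extras$summary
  r <- stats::setNames(bk$r, bk$gene_id)[genes]

  out <- tibble::tibble(
    gene_id = genes,
    mean_cq = unname(mean_cq),
    cv_pct = unname(cv_pct),
    bestkeeper_r = unname(r),
    low_expression = unname(mean_cq > thresholds$cq_low_expression),
    high_expression = unname(mean_cq < thresholds$cq_high_expression),
    high_cv = unname(!is.na(cv_pct) & cv_pct > thresholds$cv_max_pct),
    low_index_correlation = unname(!is.na(r) & r < thresholds$bestkeeper_r_min),
    missing_data = FALSE
  )
  out$excluded <- out$low_expression | out$high_expression | out$high_cv |
    out$low_index_correlation | out$missing_data
  reason_cols <- c(
    "low_expression", "high_expression", "high_cv",
    "low_index_correlation", "missing_data"
  )
  out$exclusion_reasons <- purrr::pmap(
    out[reason_cols],
    function(...) reason_cols[c(...)]
  )
  out
}

rank_map_from <- function(x) {
  if (inherits(x, "stability_result")) {
    return(x$ranks)
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(x)
  }
  rlang::abort("rank lists must be stability_result objects or named numeric vectors.",
    class = "refstab_input_error"
  )
}

#' RefFinder-style consensus ranking
#'
#' Aggregates the per-method ranks into a comprehensive ranking by the
#' geometric mean of each gene's ranks, as the RefFinder web tool does over
#' its four source algorithms (comparative dCt, BestKeeper, geNorm,
#' NormFinder). CV% does not enter the aggregation; it participates in the
#' exclusion rules only. With `exclusions` supplied and
#' `mode = "two_pass"`, flagged genes are removed and the statistics are
#' recomputed on the survivors before aggregation.
#'
#' @param x A named list of `stability_result` objects (or named rank
#'   vectors), or a collapsed `cq_tbl` from which the four methods are run.
#' @param methods Methods included in the aggregation.
#' @param exclusions Optional tibble from [apply_exclusions()].
#' @param mode `"single_pass"` keeps flagged genes in the ranking (flags
#'   reported only); `"two_pass"` removes them and re-ranks the rest.
#' @param ... Passed to [stability_all()] when `x` is a dataset.
#' @return A tibble of class `consensus_ranking`: `gene_id`, one
#'   `rank_<method>` column per method, `geomean_rank`, `final_rank` (NA
#'   for excluded genes), `excluded`, `exclusion_reasons`.
#' @export
reffinder_consensus <- function(x,
                                methods = c("delta_ct", "bestkeeper", "genorm", "normfinder"),
                                exclusions = NULL,
                                mode = c("single_pass", "two_pass"),
                                ...) {
  mode <- rlang::arg_match(mode)
  excluded_ids <- character()
  if (!is.null(exclusions)) {
    excluded_ids <- exclusions$gene_id[exclusions$excluded]
  }

  if (!is.list(x) || inherits(x, "data.frame")) {
    data <- x
    if (mode == "two_pass" && length(excluded_ids)) {
      data <- dplyr::filter(data, !.data$gene_id %in% excluded_ids)
    }
    x <- stability_all(data, methods = methods, ...)
  } else if (mode == "two_pass" && length(excluded_ids)) {
    rlang::abort(
      "two-pass re-ranking needs the dataset, not precomputed results.",
      class = "refstab_config_error"
    )
  }

  missing_methods <- setdiff(methods, names(x))
  if (length(missing_methods)) {
    rlang::abort(
      paste0("no ranks for method(s): ", paste(missing_methods, collapse = ", ")),
      class = "refstab_config_error"
    )
  }
  rank_maps <- purrr::map(x[methods], rank_map_from)

  gene_sets <- purrr::map(rank_maps, names)
  common <- gene_sets[[1]]
  for (gs in gene_sets[-1]) {
    if (!setequal(gs, common)) {
      diff <- union(setdiff(gs, common), setdiff(common, gs))
      rlang::abort(
        paste0(
          "methods rank different gene sets; symmetric difference: ",
          paste(sort(diff), collapse = ", ")
        ),
        class = "refstab_alignment_error"
      )
    }
  }
  genes <- sort(common)

  rank_tb <- tibble::tibble(gene_id = genes)
  for (m in methods) {
    rank_tb[[paste0("rank_", m)]] <- unname(rank_maps[[m]][genes])
  }
  rank_mat <- as.matrix(rank_tb[, -1, drop = FALSE])
  geo <- apply(rank_mat, 1L, geomean)

  out <- rank_tb
  out$geomean_rank <- geo
  out$excluded <- out$gene_id %in% excluded_ids
  out$exclusion_reasons <- purrr::map(out$gene_id, function(g) {
    if (!is.null(exclusions) && g %in% excluded_ids) {
      exclusions$exclusion_reasons[[match(g, exclusions$gene_id)]]
    } else {
      character()
    }
  })
  out$final_rank <- NA_real_
  keep <- !out$excluded
  if (any(keep)) {
    out$final_rank[keep] <- rank(out$geomean_rank[keep], ties.method = "average")
  }
  out <- out[order(out$final_rank, out$gene_id), ]
  attr(out, "methods") <- methods
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Combine consensus rankings from replicate cultures
#'
#' Cumulative ranking across two (or more) replicate cultures: each gene's
#' score is the geometric mean of its final ranks in the individual
#' cultures, re-ranked ascending. Symmetric in its arguments.
#'
#' @param ... Two or more `consensus_ranking` tibbles over the same
#'   surviving gene set.
#' @return A tibble of class `consensus_ranking` with `cumulative_score`
#'   and `final_rank`.
#' @export
combine_cultures <- function(...) {
  rankings <- list(...)
  if (length(rankings) < 2L) {
    rlang::abort("need at least two rankings to combine.",
      class = "refstab_input_error"
    )
  }
  sets <- purrr::map(rankings, function(r) r$gene_id[!is.na(r$final_rank)])
  genes <- sets[[1]]
  for (gs in sets[-1]) {
    if (!setequal(gs, genes)) {
      diff <- union(setdiff(gs, genes), setdiff(genes, gs))
      rlang::abort(
        paste0(
          "rankings cover different gene sets; symmetric difference: ",
          paste(sort(diff), collapse = ", ")
        ),
        class = "refstab_alignment_error"
      )
    }
  }
  genes <- sort(genes)
  rank_mat <- vapply(rankings, function(r) {
    stats::setNames(r$final_rank, r$gene_id)[genes]
  }, numeric(length(genes)))
  score <- apply(as.matrix(rank_mat), 1L, geomean)
  out <- tibble::tibble(
    gene_id = genes,
    cumulative_score = unname(score),
    final_rank = unname(rank(score, ties.method = "average"))
  )
  out <- out[order(out$final_rank, out$gene_id), ]
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Enumerate reference-gene subsets
#'
#' All unordered subsets of size `k` from the selected reference genes, in
#' deterministic lexicographic order — e.g. the 10 triplets of 5 references.
#'
#' @param genes Character vector of gene ids.
#' @param k Subset size.
#' @return A list of character vectors, each sorted, `choose(length(genes), k)`
#'   in total.
#' @export
enumerate_subsets <- function(genes, k) {
  if (k > length(genes) || k < 1L) {
    rlang::abort(
      sprintf("subset size %s out of range for %d genes.", k, length(genes)),
      class = "refstab_range_error"
    )
  }
  combos <- utils::combn(sort(genes), k, simplify = FALSE)
  combos[order(purrr::map_chr(combos, paste, collapse = "\r"))]
}

#' @export
tidy.consensus_ranking <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "methods") <- NULL
  out
}

#' Plot a consensus ranking
#'
#' Geometric-mean rank per gene, most stable first; excluded genes shown in
#' grey.
#'
#' @param object A `consensus_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_ranking <- function(object, ...) {
  df <- tidy.consensus_ranking(object)
  ycol <- if ("geomean_rank" %in% names(df)) "geomean_rank" else "cumulative_score"
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gene_id, y = .data[[ycol]],
    fill = .data$excluded
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "grey70")) +
    ggplot2::labs(
      x = NULL, y = "geometric mean of method ranks",
      title = "Consensus (RefFinder-style) ranking"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
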