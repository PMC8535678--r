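# Candidate reference-gene screening on log2(TPM) matrices.
#
# Three criteria: (I) medium-to-high expression, mean log2(TPM) >= mean_min;
# (II) low variance, SD(log2 TPM) <= sd_max; (III) no exceptional expression,
# no sample value differing from the gene's mean by a factor of fold_bound
# or more. Passing genes are ranked by CV% (ascending).

#' Screening criteria
#'
#' Thresholds for the three candidate-screening criteria on the log2(TPM)
#' scale.
#'
#' @param mean_min Minimum mean log2(TPM) (criterion I). Default 5.
#' @param sd_max Maximum SD of log2(TPM) (criterion II). Default 1.
#' @param fold_bound Multiplicative bound for the outlier criterion III.
#'   Default 2: every value must satisfy `mean / 2 <= x <= 2 * mean`.
#' @param outlier_rule How criterion III reads the factor-of-two bound:
#'   `"ratio"` (default) bounds the log2(TPM) values themselves
#'   multiplicatively; `"log_offset"` instead requires
#'   `|x - mean| < log2(fold_bound)`, i.e. less than a `fold_bound`-fold
#'   change on the TPM scale.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(mean_min = 5, sd_max = 1, fold_bound = 2,
                            outlier_rule = c("ratio", "log_offset"),
                            sd_type = c("sample", "population")) {
  outlier_rule <- rlang::arg_match(outlier_rule)
  sd_type <- rlang::arg_match(sd_type)
  if (!isTRUE(mean_min > 0) || !isTRUE(sd_max > 0) || !isTRUE(fold_bound > 1)) {
    rlang::abort(
      "need mean_min > 0, sd_max > 0 and fold_bound > 1.",
      class = "refstab_config_error"
    )
  }
  structure(
    list(
      mean_min = mean_min, sd_max = sd_max, fold_bound = fold_bound,
      outlier_rule = outlier_rule, sd_type = sd_type
    ),
    class = "screen_criteria"
  )
}

#' Screen genes for reference-gene candidacy
#'
#' Applies the three screening criteria to every gene of a log2(TPM) matrix
#' and ranks the passing genes by CV% (100 * SD / mean on the log2 scale,
#' lower = more stable). Genes with undefined values (zero TPM upstream)
#' fail all criteria. Rank ties are broken lexicographically by gene id so
#' ranks are a strict permutation of the passing genes.
#'
#' @param x An `expr_tbl` in `log2TPM` units with >= 2 samples.
#' @param criteria A [screen_criteria()] object.
#' @return A tibble of class `screen_result` with one row per gene:
#'   `gene_id`, `mean_log2tpm`, `sd_log2tpm`, `cv_pct`, `pass_mean`,
#'   `pass_sd`, `pass_no_outlier`, `pass_all`, `rank` (NA for failing genes).
#' @export
screen_reference_candidates <- function(x, criteria = screen_criteria()) {
  check_unit(x, "log2TPM", "screen_reference_candidates")
  if (!inherits(criteria, "screen_criteria")) {
    rlang::abort("`criteria` must come from screen_criteria().",
      class = "refstab_config_error"
    )
  }
  m <- expr_values(x)
  if (ncol(m) < 2L) {
    rlang::abort("need >= 2 samples for an SD to exist.",
      class = "refstab_input_error"
    )
  }
  if (nrow(m) == 0L) {
    out <- tibble::tibble(
      gene_id = character(), mean_log2tpm = numeric(),
      sd_log2tpm = numeric(), cv_pct = numeric(),
      pass_mean = logical(), pass_sd = logical(),
      pass_no_outlier = logical(), pass_all = logical(),
      rank = integer()
    )
    attr(out, "criteria") <- criteria
    class(out) <- c("screen_result", class(out))
    return(out)
  }
  n <- ncol(m)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  if (criteria$sd_type == "population") {
    sdv <- sdv * sqrt((n - 1) / n)
  }
  cv <- 100 * sdv / mu
  defined <- !is.na(mu) & !is.na(sdv)

  pass_mean <- defined & mu >= criteria$mean_min
  pass_sd <- defined & sdv <= criteria$sd_max
  fb <- criteria$fold_bound
  no_outlier <- if (criteria$outlier_rule == "ratio") {
    apply(m >= mu / fb & m <= fb * mu, 1L, all)
  } else {
    apply(abs(m - mu) < log2(fb), 1L, all)
  }
  pass_no_outlier <- defined & !is.na(no_outlier) & no_outlier
  pass_all <- pass_mean & pass_sd & pass_no_outlier

  out <- tibble::tibble(
    gene_id = rownames(m),
    mean_log2tpm = unname(mu),
    sd_log2tpm = unname(sdv),
    cv_pct = unname(cv),
    pass_mean = unname(pass_mean),
    pass_sd = unname(pass_sd),
    pass_no_outlier = unname(pass_no_outlier),
    pass_all = unname(pass_all),
    rank = NA_integer_
  )
  passing <- which(out$pass_all)
  if (length(passing)) {
    ord <- passing[order(out$cv_pct[passing], out$gene_id[passing])]
    out$rank[ord] <- seq_along(ord)
  }
  attr(out, "criteria") <- criteria
  class(out) <- c("screen_result", class(out))
  out
}

#' Pick candidate genes from a screening ranking
#'
#' Reproduces the candidate-slicing step of the screening workflow: named
#' picks verified to fall inside a rank window, whole-window slices, and
#' seeded uniform draws from a window (e.g. "3 genes sampled from the top
#' 400 ranks"). The result is the union of all picks, deterministic for a
#' fixed seed.
#'
#' @param result A `screen_result`.
#' @param picks A list; each element is a list with `from` and `to` (rank
#'   window, inclusive) plus either `genes` (named picks), `sample`
#'   (how many to draw uniformly from the window), or neither (take the
#'   whole window).
#' @param seed Integer seed for the sampled picks.
#' @return Character vector of gene ids, in pick order, without duplicates.
#' @export
select_candidates <- function(result, picks, seed = 1L) {
  if (!inherits(result, "screen_result")) {
    rlang::abort("`result` must be a screen_result.", class = "refstab_input_error")
  }
  ranked <- result[!is.na(result$rank), c("gene_id", "rank")]
  ranked <- ranked[order(ranked$rank), ]
  n_ranked <- nrow(ranked)
  chosen <- character()
  with_seed(seed, {
    for (p in picks) {
      from <- p$from %||% 1L
      to <- p$to
      if (is.null(to) || to > n_ranked || from < 1L || from > to) {
        rlang::abort(
          sprintf(
            "rank window [%s, %s] outside the %d ranked genes.",
            from, if (is.null(to)) "?" else to, n_ranked
          ),
          class = "refstab_range_error"
        )
      }
      window <- ranked$gene_id[from:to]
      got <- if (!is.null(p$genes)) {
        missing <- setdiff(p$genes, window)
        if (length(missing)) {
          rlang::abort(
            paste0(
              "named genes not in rank window: ",
              paste(missing, collapse = ", ")
            ),
            class = "refstab_range_error"
          )
        }
        p$genes
      } else if (!is.null(p$sample)) {
        if (p$sample > length(window)) {
          rlang::abort("cannot sample more genes than the window holds.",
            class = "refstab_range_error"
          )
        }
        sample(window, p$sample)
      } else {
        window
      }
      chosen <- c(chosen, got)
    }
  })
  unique(chosen)
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_pass_mean = sum(x$pass_mean),
    n_pass_sd = sum(x$pass_sd),
    n_pass_no_outlier = sum(x$pass_no_outlier),
    n_pass_all = sum(x$pass_all)
  )
}

#' @export
tidy.screen_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "criteria") <- NULL
  out
}

#' Plot a screening result
#'
#' Mean log2(TPM) against CV% with the pass/fail status of each gene; the
#' familiar funnel of screening plots, with the mean threshold drawn.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  crit <- attr(object, "criteria")
  df <- tidy.screen_result(object)
  df <- df[!is.na(df$cv_pct), ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$mean_log2tpm, y = .data$cv_pct,
      colour = .data$pass_all
    )
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = crit$mean_min, linetype = 2) +
    ggplot2::labs(
      x = "mean log2(TPM)", y = "CV%", colour = "passes screen",
      title = "Reference-candidate screen"
    ) +
    ggplot2::theme_minimal()
}
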