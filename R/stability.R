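# The five reference-gene stability algorithms:
#   CV%            — coefficient of variation of relative quantities
#   geNorm         — M-value (mean pairwise SD of log-ratios), stepwise
#                    exclusion, pairwise variation V(n/n+1)
#   NormFinder     — model-based intra/intergroup variance decomposition
#   BestKeeper     — dispersion of Cq and correlation with the BestKeeper
#                    index (per-sample geometric mean Cq)
#   comparative dCt — mean SD of pairwise Cq differences
#
# All operate on replicate-collapsed data; every statistic is oriented so
# that lower = more stable.

STABILITY_METHODS <- c("cv", "genorm", "normfinder", "bestkeeper", "delta_ct")

new_stability_result <- function(method, statistic, extras = list(),
                                 lower_is_better = TRUE, ranks = NULL) {
  if (is.null(ranks)) {
    ranks <- stats::setNames(rep(NA_real_, length(statistic)), names(statistic))
    ok <- !is.na(statistic)
    if (any(ok)) ranks[ok] <- rank(statistic[ok], ties.method = "average")
  }
  structure(
    list(
      method = method,
      statistic = statistic,
      lower_is_better = lower_is_better,
      ranks = ranks,
      extras = extras
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result: ", x$method, ">\n", sep = "")
  print(tidy.stability_result(x), ...)
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method,
    gene_id = names(x$statistic),
    statistic = unname(x$statistic),
    rank = unname(x$ranks)
  )
  dplyr::arrange(out, .data$rank, .data$gene_id)
}

#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_genes = length(x$statistic),
    most_stable = names(x$statistic)[order(x$ranks, names(x$statistic))][1],
    min_statistic = min(x$statistic, na.rm = TRUE),
    max_statistic = max(x$statistic, na.rm = TRUE)
  )
}

#' Plot a stability result
#'
#' Bar chart of the per-gene stability statistic, ordered most to least
#' stable (lower bars = more stable).
#'
#' @param object A `stability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_result <- function(object, ...) {
  df <- tidy.stability_result(object)
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$statistic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "stability statistic (lower = more stable)",
      title = paste0("Stability: ", object$method)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# Accept a collapsed cq_tbl, a replicate-level cq_tbl (collapsed on the
# fly), or a ready genes x samples matrix.
as_cq_matrix <- function(data) {
  if (is.matrix(data)) {
    return(stopifnot_complete(data))
  }
  if ("replicate" %in% names(data) &&
    anyDuplicated(data[, c("gene_id", "sample_id")])) {
    data <- collapse_replicates(data)
  }
  stopifnot_complete(cq_matrix(data))
}

# Matrix of log2 relative quantities from data + efficiencies.
as_log_rq <- function(data, eff = NULL) {
  if (is.matrix(data)) {
    rq <- data
    stopifnot_complete(rq, "RQ")
    if (any(rq <= 0)) {
      rlang::abort("relative quantities must be positive.",
        class = "refstab_domain_error"
      )
    }
    return(log2(rq))
  }
  m <- as_cq_matrix(data)
  e <- resolve_efficiencies(rownames(m), eff)
  log2e <- log2(e[rownames(m)])
  mins <- apply(m, 1L, min)
  (mins - m) * log2e
}

#' geNorm stability (M-value, stepwise exclusion, V series)
#'
#' For each gene j the M-value is the mean, over all other genes k, of the
#' standard deviation across samples of the pairwise log2 expression ratio
#' log2(RQ_j / RQ_k). Genes sharing regulation have constant ratios and low
#' M; lower M = more stable. The ranking comes from stepwise exclusion:
#' repeatedly drop the gene with the largest M and recompute until two genes
#' remain; those two share ranks 1-2 (reported as 1.5 each). The pairwise
#' variation V(n/n+1) is the SD across samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the geometric mean of the top-n
#' genes' relative quantities; it guides how many reference genes suffice.
#'
#' @param data A collapsed `cq_tbl`, replicate-level `cq_tbl`, or a
#'   genes x samples matrix of relative quantities (values > 0).
#' @param eff Optional [efficiency_table()] used when `data` holds Cq values.
#' @return A `stability_result` with `statistic` = full-panel M values and
#'   `extras$removal_order`, `extras$removal_m`, `extras$v_series`.
#' @export
stability_genorm <- function(data, eff = NULL) {
  y <- as_log_rq(data, eff) # genes x samples, log2 RQ
  g <- nrow(y)
  if (g < 3L || ncol(y) < 2L) {
    rlang::abort("geNorm needs >= 3 genes and >= 2 samples.",
      class = "refstab_input_error"
    )
  }

  m_values <- function(mat) {
    gg <- nrow(mat)
    vapply(seq_len(gg), function(j) {
      sds <- vapply(setdiff(seq_len(gg), j), function(k) {
        stats::sd(mat[j, ] - mat[k, ])
      }, numeric(1))
      mean(sds)
    }, numeric(1))
  }

  full_m <- stats::setNames(m_values(y), rownames(y))

  remaining <- y
  removal_order <- character()
  removal_m <- numeric()
  while (nrow(remaining) > 2L) {
    m <- m_values(remaining)
    worst <- which(m == max(m))
    # deterministic tie-break: drop the lexicographically last id
    worst <- worst[order(rownames(remaining)[worst])]
    worst <- worst[length(worst)]
    removal_order <- c(removal_order, rownames(remaining)[worst])
    removal_m <- c(removal_m, m[worst])
    remaining <- remaining[-worst, , drop = FALSE]
  }
  final_pair <- sort(rownames(remaining))
  pair_m <- stats::sd(remaining[1, ] - remaining[2, ])

  ranks <- stats::setNames(numeric(g), names(full_m))
  ranks[final_pair] <- 1.5
  if (length(removal_order)) {
    ranks[rev(removal_order)] <- 2 + seq_along(removal_order)
  }

  # V series follows the stepwise ranking: top-n = final pair + latest
  # removed genes. RQ on the linear scale for the geometric means.
  order_best_first <- c(final_pair, rev(removal_order))
  rq <- 2^y
  v_series <- numeric(0)
  if (g >= 3L) {
    ns <- 2:(g - 1)
    v_series <- vapply(ns, function(n) {
      nf_n <- apply(rq[order_best_first[1:n], , drop = FALSE], 2L, geomean)
      nf_n1 <- apply(rq[order_best_first[1:(n + 1)], , drop = FALSE], 2L, geomean)
      stats::sd(log2(nf_n / nf_n1))
    }, numeric(1))
    names(v_series) <- paste0("V", ns, "/", ns + 1)
  }

  new_stability_result(
    "genorm", full_m,
    ranks = ranks,
    extras = list(
      removal_order = removal_order,
      removal_m = removal_m,
      final_pair = final_pair,
      final_pair_m = pair_m,
      v_series = v_series,
      ranking_order = order_best_first
    )
  )
}

#' NormFinder stability
#'
#' Model-based stability on log2 relative quantities. Each sample's mean
#' over genes (the common loading/amount effect) is subtracted first.
#' Without groups the stability value is simply the SD across samples of
#' these sample-centered quantities. With groups, each gene's intragroup
#' variance is estimated from the residual mean square with a bias
#' correction that removes the contamination introduced by sample-centering
#' (factor k/(k-2) and the cross-gene term sum(s^2)/(k(k-1)) for k genes),
#' the intergroup deviation of each gene's group mean is shrunk by an
#' empirical-Bayes factor, and the gene's stability is the average over
#' groups of |shrunk intergroup deviation| + sqrt(intragroup variance /
#' group size). Lower = more stable.
#'
#' @param data A collapsed `cq_tbl`, replicate-level `cq_tbl`, or a
#'   genes x samples matrix of relative quantities.
#' @param group Optional grouping: `"condition"` (or another metadata
#'   column) when `data` is a tibble, or a vector of group labels, one per
#'   sample (matrix input). `NULL` = ungrouped.
#' @param eff Optional [efficiency_table()].
#' @return A `stability_result`; grouped runs expose
#'   `extras$intragroup_sd` and `extras$intergroup_dev` (genes x groups).
#' @export
stability_normfinder <- function(data, group = NULL, eff = NULL) {
  y <- as_log_rq(data, eff)
  groups <- NULL
  if (!is.null(group)) {
    if (is.character(group) && length(group) == 1L && !is.matrix(data) &&
      group %in% names(data)) {
      md <- dplyr::distinct(
        data[, c("sample_id", group)]
      )
      groups <- stats::setNames(as.character(md[[group]]), md$sample_id)
      groups <- groups[colnames(y)]
    } else {
      if (length(group) != ncol(y)) {
        rlang::abort("`group` must give one label per sample.",
          class = "refstab_grouping_error"
        )
      }
      groups <- stats::setNames(as.character(group), colnames(y))
    }
    if (any(table(groups) < 2L)) {
      rlang::abort("every group needs >= 2 samples.",
        class = "refstab_grouping_error"
      )
    }
  }

  z <- sweep(y, 2L, colMeans(y)) # remove per-sample loading effect
  k <- nrow(z)

  if (is.null(groups)) {
    stat <- apply(z, 1L, stats::sd)
    return(new_stability_result("normfinder", stat))
  }

  if (k < 3L) {
    rlang::abort("grouped NormFinder needs >= 3 genes.",
      class = "refstab_input_error"
    )
  }
  glevels <- sort(unique(groups))
  ng <- vapply(glevels, function(g) sum(groups == g), integer(1))
  n_total <- ncol(z)

  group_mean <- vapply(glevels, function(g) {
    rowMeans(z[, groups == g, drop = FALSE])
  }, numeric(k)) # genes x groups
  gene_mean <- as.numeric(group_mean %*% (ng / n_total)) # weighted overall

  # residual MS per gene x group, then unbiased intragroup variance
  s2 <- vapply(glevels, function(g) {
    sub <- z[, groups == g, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2) / (ng[g] - 1L)
  }, numeric(k))
  sigma2 <- sweep(s2, 2L, colSums(s2) / (k * (k - 1L))) * k / (k - 2L)
  sigma2 <- pmax(sigma2, 0)

  d <- sweep(group_mean, 1L, gene_mean) # intergroup deviations
  v <- sweep(sigma2, 2L, ng, "/") # sampling variance of d
  gamma2 <- max(mean(d^2) - mean(v), 0) # spread of true deviations
  shrink <- if (gamma2 > 0) gamma2 / (gamma2 + v) else 0 * v
  d_tilde <- d * shrink

  per_group <- abs(d_tilde) + sqrt(v)
  stat <- rowMeans(per_group)
  names(stat) <- rownames(z)

  new_stability_result(
    "normfinder", stat,
    extras = list(
      groups = groups,
      intragroup_sd = sqrt(sigma2),
      intergroup_dev = d_tilde,
      gamma2 = gamma2
    )
  )
}

#' BestKeeper stability
#'
#' Works directly on the Cq scale. Per gene it reports the mean Cq, the
#' dispersion SD(+/-Cq) — by the original tool's convention the mean
#' absolute deviation from the arithmetic mean, with a plain-SD dialect
#' switch — and CV% = 100 * dispersion / mean. The BestKeeper index (BI) is
#' the per-sample geometric mean of all candidate genes' Cq values; each
#' gene's Pearson correlation r (and two-sided p) with BI is reported and
#' feeds the exclusion rules. The primary statistic is the dispersion
#' (lower = more stable); zero-variance genes or a constant BI give an
#' undefined r, reported as NA.
#'
#' @param data A collapsed or replicate-level `cq_tbl`, or a genes x samples
#'   Cq matrix.
#' @param dispersion `"mad"` (mean absolute deviation, BestKeeper's
#'   convention, default) or `"sd"`.
#' @return A `stability_result` with `extras$summary` (per-gene tibble) and
#'   `extras$index` (BI per sample).
#' @export
stability_bestkeeper <- function(data, dispersion = c("mad", "sd")) {
  dispersion <- rlang::arg_match(dispersion)
  m <- as_cq_matrix(data)
  if (nrow(m) < 2L || ncol(m) < 3L) {
    rlang::abort("BestKeeper needs >= 2 genes and >= 3 samples.",
      class = "refstab_input_error"
    )
  }
  mean_cq <- rowMeans(m)
  disp <- if (dispersion == "mad") {
    rowMeans(abs(m - mean_cq))
  } else {
    apply(m, 1L, stats::sd)
  }
  cv_pct <- 100 * disp / mean_cq
  bi <- apply(m, 2L, geomean)

  cors <- purrr::map(rownames(m), function(g) {
    x <- m[g, ]
    if (stats::sd(x) == 0 || stats::sd(bi) == 0) {
      return(list(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, bi, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
  })

  summary_tb <- tibble::tibble(
    gene_id = rownames(m),
    mean_cq = unname(mean_cq),
    dispersion = unname(disp),
    cv_pct = unname(cv_pct),
    r = purrr::map_dbl(cors, "r"),
    p = purrr::map_dbl(cors, "p")
  )

  new_stability_result(
    "bestkeeper", stats::setNames(disp, rownames(m)),
    extras = list(
      summary = summary_tb,
      index = bi,
      dispersion_type = dispersion
    )
  )
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample difference
#' dCt = Cq_j - Cq_k is formed; the pair score is its SD across samples,
#' and gene j's stability is the mean pair score over all other genes k.
#' Two genes tracking each other keep a constant difference and score 0.
#'
#' @param data A collapsed or replicate-level `cq_tbl`, or a genes x samples
#'   Cq matrix.
#' @return A `stability_result` with `extras$pair_sd` (genes x genes matrix
#'   of pairwise SDs).
#' @export
stability_delta_ct <- function(data) {
  m <- as_cq_matrix(data)
  g <- nrow(m)
  if (g < 2L || ncol(m) < 2L) {
    rlang::abort("comparative dCt needs >= 2 genes and >= 2 samples.",
      class = "refstab_input_error"
    )
  }
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g)) {
    for (k in seq_len(g)) {
      if (j != k) pair_sd[j, k] <- stats::sd(m[j, ] - m[k, ])
    }
  }
  stat <- rowSums(pair_sd) / (g - 1L)
  new_stability_result("delta_ct", stat, extras = list(pair_sd = pair_sd))
}

#' CV% stability
#'
#' Coefficient of variation per gene, 100 * SD / mean. The default scale is
#' the linear relative quantity (RQ) scale: fold-level variation, where a
#' ">50%" exclusion threshold is meaningful. A `"cq"` scale switch computes
#' CV% of the raw Cq values instead.
#'
#' @param data A collapsed or replicate-level `cq_tbl`, or a genes x samples
#'   Cq matrix.
#' @param scale `"linear_rq"` (default) or `"cq"`.
#' @param eff Optional [efficiency_table()] for the RQ conversion.
#' @return A `stability_result`.
#' @export
stability_cv <- function(data, scale = c("linear_rq", "cq"), eff = NULL) {
  scale <- rlang::arg_match(scale)
  vals <- if (scale == "cq") {
    as_cq_matrix(data)
  } else {
    2^as_log_rq(data, eff)
  }
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  stat <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
  names(stat) <- rownames(vals)
  if (anyNA(stat)) {
    rlang::warn("CV% undefined for genes with zero mean; reported as NA.")
  }
  new_stability_result("cv", stat, extras = list(scale = scale))
}

#' Run all five stability algorithms
#'
#' Convenience wrapper running CV%, geNorm, NormFinder, BestKeeper and
#' comparative dCt on the same collapsed dataset.
#'
#' @param data A collapsed or replicate-level `cq_tbl`.
#' @param eff Optional [efficiency_table()].
#' @param group Optional NormFinder grouping (see
#'   [stability_normfinder()]); by default `"condition"` is used when the
#'   data carry a condition column with more than one level, the usual
#'   situation once hypoxic arms join the normoxic passages.
#' @param methods Which methods to run.
#' @return Named list of `stability_result` objects.
#' @export
stability_all <- function(data, eff = NULL, group = NULL,
                          methods = STABILITY_METHODS) {
  methods <- match.arg(methods, STABILITY_METHODS, several.ok = TRUE)
  if (is.null(group) && !is.matrix(data) && "condition" %in% names(data) &&
    length(unique(data$condition)) > 1L) {
    group <- "condition"
  }
  res <- list()
  if ("cv" %in% methods) res$cv <- stability_cv(data, eff = eff)
  if ("genorm" %in% methods) res$genorm <- stability_genorm(data, eff = eff)
  if ("normfinder" %in% methods) {
    res$normfinder <- stability_normfinder(data, group = group, eff = eff)
  }
  if ("bestkeeper" %in% methods) res$bestkeeper <- stability_bestkeeper(data)
  if ("delta_ct" %in% methods) res$delta_ct <- stability_delta_ct(data)
  res
}
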