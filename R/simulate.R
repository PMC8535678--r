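# Synthetic Cq datasets and expression matrices with the statistical
# structure the analysis assumes: gene-specific baselines, per-sample
# loading offsets shared by all genes, condition-specific regulation of
# designated unstable genes, gene-specific biological noise, and
# technical-replicate noise.

#' Sample design for a simulated qPCR study
#'
#' One row per sample slot: culture, passage, condition. The default is
#' the serial-passage design of the emulated study — two replicate
#' cultures (S1, S2) over five consecutive passages (p7..p11) in normoxia,
#' optionally extended with acute (24 h, 72 h) and chronic hypoxia arms.
#'
#' @param cultures Culture labels.
#' @param passages Passage labels.
#' @param conditions Conditions to include; hypoxic arms are added as extra
#'   samples per culture at the final passage.
#' @return A tibble with `sample_id`, `culture`, `passage`, `condition`.
#' @export
cq_sim_design <- function(cultures = c("S1", "S2"),
                          passages = paste0("p", 7:11),
                          conditions = "normoxia") {
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  base <- tidyr::expand_grid(
    culture = cultures, passage = passages,
    condition = "normoxia"
  )
  hyp <- tidyr::expand_grid(
    culture = cultures,
    passage = passages[length(passages)],
    condition = setdiff(conditions, "normoxia")
  )
  out <- dplyr::bind_rows(
    if ("normoxia" %in% conditions) base,
    hyp
  )
  out$sample_id <- paste(out$culture, out$passage, out$condition, sep = "_")
  dplyr::relocate(out, "sample_id")
}

#' Specification of a synthetic Cq dataset
#'
#' The generative model per gene g, sample s, replicate r is
#' `Cq = mu_g - phi_s - beta_{g, cond(s)} + eps_{g,s} + eta_{g,s,r}` with
#' `phi_s ~ N(0, sample_loading_sd^2)` a loading offset common to all genes
#' of the sample, `eps ~ N(0, gene_noise_sd_g^2)` gene-specific biological
#' noise, `eta ~ N(0, tech_noise_sd^2)` technical-replicate noise, and
#' `beta` the condition effect in cycles (positive beta = induction: fewer
#' cycles to threshold). Designated stable genes have beta identically 0.
#'
#' @param baseline_cq Named numeric vector: baseline Cq per gene (cycles).
#' @param gene_noise_sd Biological noise SD per gene (cycles); recycled.
#' @param condition_effects Data frame with `gene_id`, `condition`, `beta`
#'   (cycles), or NULL for no regulation.
#' @param sample_loading_sd SD of the common per-sample loading offset
#'   (cycles); default 0.3, a realistic pipetting/input spread.
#' @param tech_noise_sd Technical replicate SD (cycles); default 0.1,
#'   typical for triplicate qPCR.
#' @param replicates Technical replicates per reaction; default 3.
#' @param design Sample design tibble from [cq_sim_design()].
#' @param max_cycles Instrument range; simulated values are clipped into
#'   (0, max_cycles] and clips are counted.
#' @return A list of class `cq_sim_spec`.
#' @export
cq_sim_spec <- function(baseline_cq,
                        gene_noise_sd = 0.2,
                        condition_effects = NULL,
                        sample_loading_sd = 0.3,
                        tech_noise_sd = 0.1,
                        replicates = 3L,
                        design = cq_sim_design(),
                        max_cycles = 40) {
  if (is.null(names(baseline_cq)) || anyDuplicated(names(baseline_cq))) {
    rlang::abort("`baseline_cq` must be uniquely named by gene.",
      class = "refstab_config_error"
    )
  }
  n_genes <- length(baseline_cq)
  gene_noise_sd <- rep_len(gene_noise_sd, n_genes)
  names(gene_noise_sd) <- names(baseline_cq)
  if (any(gene_noise_sd < 0) || sample_loading_sd < 0 || tech_noise_sd < 0 ||
    replicates < 1L) {
    rlang::abort("SDs must be >= 0 and replicates >= 1.",
      class = "refstab_config_error"
    )
  }
  if (!is.null(condition_effects)) {
    condition_effects <- tibble::as_tibble(condition_effects)
    need <- c("gene_id", "condition", "beta")
    if (!all(need %in% names(condition_effects))) {
      rlang::abort("condition_effects needs gene_id, condition, beta.",
        class = "refstab_config_error"
      )
    }
    bad <- setdiff(condition_effects$gene_id, names(baseline_cq))
    if (length(bad)) {
      rlang::abort(paste0("condition effects for unknown genes: ", paste(bad, collapse = ", ")),
        class = "refstab_config_error"
      )
    }
  }
  structure(
    list(
      baseline_cq = baseline_cq,
      gene_noise_sd = gene_noise_sd,
      condition_effects = condition_effects,
      sample_loading_sd = sample_loading_sd,
      tech_noise_sd = tech_noise_sd,
      replicates = as.integer(replicates),
      design = tibble::as_tibble(design),
      max_cycles = max_cycles
    ),
    class = "cq_sim_spec"
  )
}

#' Default candidate-gene panel for simulations
#'
#' Baseline Cq values for a panel of candidate reference genes, spanning
#' the realistic range from abundant rRNA-like transcripts (15 cycles) to
#' weakly expressed candidates (30 cycles). Default size 25, the panel
#' size of the emulated study.
#'
#' @param n_genes Panel size.
#' @return Named numeric vector of baseline Cq values.
#' @export
default_cq_panel <- function(n_genes = 25L) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  stats::setNames(seq(15, 30, length.out = n_genes), genes)
}

#' Simulate a replicate-level Cq dataset
#'
#' Draws Cq values under the generative model of [cq_sim_spec()]. The
#' default specification reproduces the emulated study design: 25 candidate
#' genes, 2 cultures x 5 passages in normoxia, 3 technical replicates
#' (750 reactions collapsing to 250 mean Cq values).
#'
#' @param spec A [cq_sim_spec()]; default panel of 25 genes.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A replicate-level `cq_tbl` with metadata columns. The attribute
#'   `n_clipped` counts values clipped into the instrument range, and
#'   `truth` stores the spec.
#' @export
simulate_cq <- function(spec = cq_sim_spec(default_cq_panel()), seed = 1L) {
  if (!inherits(spec, "cq_sim_spec")) {
    rlang::abort("`spec` must come from cq_sim_spec().",
      class = "refstab_config_error"
    )
  }
  genes <- names(spec$baseline_cq)
  design <- spec$design
  n_s <- nrow(design)

  beta <- matrix(0, length(genes), n_s, dimnames = list(genes, design$sample_id))
  if (!is.null(spec$condition_effects)) {
    for (i in seq_len(nrow(spec$condition_effects))) {
      ce <- spec$condition_effects[i, ]
      beta[ce$gene_id, design$condition == ce$condition] <- ce$beta
    }
  }

  with_seed(seed, {
    # standard normals scaled afterwards: the RNG stream is identical for
    # any SD settings, so runs differing only in one noise component are
    # comparable draw by draw
    phi <- stats::rnorm(n_s) * spec$sample_loading_sd
    eps <- matrix(
      stats::rnorm(length(genes) * n_s) * rep(spec$gene_noise_sd, n_s),
      length(genes), n_s
    )
    mu <- spec$baseline_cq - beta + eps # genes x samples
    mu <- sweep(mu, 2L, phi, "-")
    recs <- tidyr::expand_grid(
      gene_id = genes, sample_id = design$sample_id,
      replicate = seq_len(spec$replicates)
    )
    idx <- cbind(
      match(recs$gene_id, genes),
      match(recs$sample_id, design$sample_id)
    )
    eta <- stats::rnorm(nrow(recs)) * spec$tech_noise_sd
    cq <- mu[idx] + eta
    clipped_hi <- cq > spec$max_cycles
    clipped_lo <- cq <= 0
    cq[clipped_hi] <- spec$max_cycles
    cq[clipped_lo] <- .Machine$double.eps
    recs$cq <- cq
    out <- cq_dataset(recs,
      metadata = design[, c("sample_id", "culture", "passage", "condition")],
      max_cycles = spec$max_cycles
    )
    n_clipped <- sum(clipped_hi) + sum(clipped_lo)
    if (n_clipped > 0) {
      rlang::inform(sprintf("%d simulated Cq value(s) clipped into (0, %s].", n_clipped, spec$max_cycles))
    }
    attr(out, "n_clipped") <- n_clipped
    attr(out, "truth") <- spec
    out
  })
}

#' Simulate a log2(TPM) expression matrix with planted screening outcomes
#'
#' Constructs a matrix in which `n_pass` genes satisfy all three screening
#' criteria and, per criterion, a requested number of genes violate exactly
#' that criterion: `fail_mean` genes sit below the mean threshold (but are
#' tight and outlier-free), `fail_sd` genes exceed the SD bound (while
#' keeping every value inside the outlier band), and `fail_outlier` genes
#' contain one exceptional sample beyond the factor-of-two band while
#' keeping mean and SD within bounds. The planted labels are the ground
#' truth for screening-recovery tests.
#'
#' Violating only the outlier criterion forces the exceptional value to be
#' at least as large as the gene mean while contributing less than the SD
#' bound (its SD contribution is ~ excess / sqrt(n)), which requires
#' `n_samples >= 40` when `fail_outlier > 0` (the emulated screening matrix
#' has 82 samples).
#'
#' @param n_pass Genes passing all criteria.
#' @param n_fail_per_criterion Length-3 vector (or named
#'   `c(mean=, sd=, outlier=)`): genes violating exactly criterion I, II,
#'   III respectively.
#' @param n_samples Number of samples; default 82.
#' @param criteria The [screen_criteria()] the construction targets.
#' @param seed Integer seed.
#' @return An `expr_tbl` in `log2TPM` units with attribute `truth`, a
#'   tibble of gene labels (`pass`, `fail_mean`, `fail_sd`, `fail_outlier`).
#' @export
simulate_expression <- function(n_pass,
                                n_fail_per_criterion = c(mean = 0, sd = 0, outlier = 0),
                                n_samples = 82L,
                                criteria = screen_criteria(),
                                seed = 1L) {
  nf <- rep_len(as.integer(n_fail_per_criterion), 3L)
  if (n_pass < 0 || any(nf < 0)) {
    rlang::abort("gene counts must be >= 0.", class = "refstab_config_error")
  }
  if (nf[3] > 0 && n_samples < 40L) {
    rlang::abort(
      "violating only the outlier criterion needs >= 40 samples (SD bound).",
      class = "refstab_config_error"
    )
  }
  n <- n_samples
  # alternating pattern, exactly centered: mean 0, bounded max deviation
  pattern <- rep_len(c(-1, 1), n)
  pattern <- pattern - mean(pattern)
  pattern_sd <- stats::sd(pattern)

  make_gene <- function(mu, target_sd) {
    # exact mean mu; SD = target_sd with bounded deviations (|d| <= ~target_sd)
    mu + pattern / pattern_sd * target_sd
  }

  with_seed(seed, {
    rows <- list()
    labels <- list()
    add <- function(label, count, maker) {
      if (count == 0L) {
        return()
      }
      for (i in seq_len(count)) {
        g <- sprintf("%s_%02d", label, i)
        rows[[g]] <<- maker()
        labels[[g]] <<- label
      }
    }
    sd_ok <- min(0.5, criteria$sd_max / 2)
    add("pass", n_pass, function() {
      make_gene(stats::runif(1, criteria$mean_min + 0.5, criteria$mean_min + 5), sd_ok)
    })
    add("fail_mean", nf[1], function() {
      make_gene(stats::runif(1, criteria$mean_min - 2, criteria$mean_min - 0.5), sd_ok)
    })
    add("fail_sd", nf[2], function() {
      # SD above the bound, deviations well inside the fold band
      mu <- stats::runif(1, criteria$mean_min + 2, criteria$mean_min + 4)
      make_gene(mu, criteria$sd_max * 1.8)
    })
    add("fail_outlier", nf[3], function() {
      # one exceptional value: excess d gives SD = d/sqrt(n) (kept at
      # 0.9 * sd_max) while pushing the value past fold_bound * mean
      d <- 0.9 * criteria$sd_max * sqrt(n)
      base <- criteria$mean_min + 0.05 - d / n
      v <- rep(base, n)
      v[sample.int(n, 1)] <- base + d
      v
    })
    genes <- names(rows) %||% character()
    m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, n)
    df <- tibble::as_tibble(
      as.data.frame(m),
      .name_repair = ~ sprintf("sample_%02d", seq_len(n))
    )
    df <- dplyr::bind_cols(tibble::tibble(gene_id = genes), df)
    out <- expression_matrix(df, unit = "log2TPM")
    attr(out, "truth") <- tibble::tibble(
      gene_id = genes,
      label = unlist(labels, use.names = FALSE) %||% character()
    )
    out
  })
}
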