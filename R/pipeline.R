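# File-based orchestration of the workflow stages: simulate -> screen ->
# stability/consensus -> normalize. Each stage reads/writes plain delimited
# text so runs are reproducible and inspectable; a JSON config document
# drives full-pipeline runs. A thin command-line front end over these
# functions ships in inst/scripts/refstab.

#' Pipeline configuration
#'
#' A single configuration object (serializable to/from JSON) holding the
#' stage parameters: screening criteria, exclusion thresholds, stability
#' methods, calibrator, reference-subset size and seed.
#'
#' @param screen_criteria A [screen_criteria()] object.
#' @param exclusion_thresholds An [exclusion_thresholds()] object.
#' @param methods Stability methods to run.
#' @param calibrator Calibrator sample id (for the normalize stage).
#' @param k Reference-subset size; default 3.
#' @param seed Integer seed used by every stochastic stage.
#' @param exclusion_mode `"two_pass"` (exclude then re-rank, default) or
#'   `"single_pass"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(screen_criteria = refstab::screen_criteria(),
                            exclusion_thresholds = refstab::exclusion_thresholds(),
                            methods = STABILITY_METHODS,
                            calibrator = NULL,
                            k = 3L,
                            seed = 1L,
                            exclusion_mode = c("two_pass", "single_pass")) {
  exclusion_mode <- rlang::arg_match(exclusion_mode)
  if (k < 1L) {
    rlang::abort("`k` must be >= 1.", class = "refstab_config_error")
  }
  structure(
    list(
      screen_criteria = screen_criteria,
      exclusion_thresholds = exclusion_thresholds,
      methods = match.arg(methods, STABILITY_METHODS, several.ok = TRUE),
      calibrator = calibrator,
      k = as.integer(k),
      seed = as.integer(seed),
      exclusion_mode = exclusion_mode
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    screen_criteria = do.call(screen_criteria, as.list(raw$screen_criteria %||% list())),
    exclusion_thresholds = do.call(exclusion_thresholds, as.list(raw$exclusion_thresholds %||% list())),
    methods = raw$methods %||% STABILITY_METHODS,
    calibrator = raw$calibrator,
    k = raw$k %||% 3L,
    seed = raw$seed %||% 1L,
    exclusion_mode = raw$exclusion_mode %||% "two_pass"
  )
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(config)
}

#' Run the screening stage on a matrix file
#'
#' Reads an expression matrix, converts scaled_estimate to TPM and to
#' log2(TPM) as needed, screens, writes the screen report TSV, and logs the
#' per-criterion attrition counts (input / per-criterion failures / passing)
#' so every reported row reconciles with the input.
#'
#' @param matrix_path Path to a genes x samples matrix file.
#' @param out_path Output TSV path (default: alongside input).
#' @param unit Unit of the input matrix.
#' @param config A [pipeline_config()].
#' @return The `screen_result`, invisibly; the attrition counts are
#'   attached as attribute `attrition`.
#' @export
run_screen <- function(matrix_path, out_path = NULL,
                       unit = c("scaled_estimate", "TPM", "log2TPM"),
                       config = pipeline_config()) {
  unit <- rlang::arg_match(unit)
  x <- read_expression_matrix(matrix_path, unit = unit)
  if (expr_unit(x) == "scaled_estimate") x <- to_tpm(x)
  if (expr_unit(x) == "TPM") x <- log2_transform(x)
  res <- screen_reference_candidates(x, config$screen_criteria)
  attrition <- c(
    input = nrow(res),
    fail_mean = sum(!res$pass_mean),
    fail_sd = sum(!res$pass_sd),
    fail_outlier = sum(!res$pass_no_outlier),
    pass_all = sum(res$pass_all)
  )
  rlang::inform(sprintf(
    "screen: %d genes in, %d fail mean, %d fail SD, %d fail outlier, %d pass",
    attrition["input"], attrition["fail_mean"], attrition["fail_sd"],
    attrition["fail_outlier"], attrition["pass_all"]
  ))
  if (!is.null(out_path)) {
    readr::write_tsv(tidy.screen_result(res), out_path)
  }
  attr(res, "attrition") <- attrition
  invisible(res)
}

#' Run the stability + consensus stage on Cq files
#'
#' Reads the long-format Cq table and metadata, collapses replicates, runs
#' the configured stability methods, applies the exclusion rules, builds
#' the consensus ranking, and writes one TSV per method plus the consensus
#' table.
#'
#' @param cq_path Long-format Cq file (gene, sample, replicate, cq).
#' @param metadata_path Per-sample metadata file.
#' @param out_dir Output directory for the report TSVs (NULL = no files).
#' @param efficiency_path Optional per-gene efficiency file.
#' @param config A [pipeline_config()].
#' @return A list with `collapsed`, `stability` (list), `exclusions`,
#'   `consensus`, invisibly.
#' @export
run_stability <- function(cq_path, metadata_path = NULL, out_dir = NULL,
                          efficiency_path = NULL,
                          config = pipeline_config()) {
  data <- read_cq_long(cq_path, metadata_path)
  eff <- if (!is.null(efficiency_path)) {
    efficiency_table(readr::read_tsv(efficiency_path,
      show_col_types = FALSE, progress = FALSE
    ))
  }
  collapsed <- collapse_replicates(data)
  rlang::inform(sprintf(
    "stability: %d reactions collapsed to %d mean Cq values (%d genes x %d samples)",
    nrow(data), nrow(collapsed),
    length(unique(collapsed$gene_id)), length(unique(collapsed$sample_id))
  ))
  stab <- stability_all(collapsed, eff = eff, methods = config$methods)
  exclusions <- apply_exclusions(collapsed,
    stability = stab,
    thresholds = config$exclusion_thresholds, eff = eff
  )
  n_excl <- sum(exclusions$excluded)
  rlang::inform(sprintf(
    "exclusions: %d of %d genes flagged (%s)",
    n_excl, nrow(exclusions),
    if (n_excl) {
      paste(exclusions$gene_id[exclusions$excluded], collapse = ", ")
    } else {
      "none"
    }
  ))
  consensus_methods <- intersect(
    c("delta_ct", "bestkeeper", "genorm", "normfinder"), config$methods
  )
  consensus <- reffinder_consensus(
    collapsed,
    methods = consensus_methods,
    exclusions = exclusions, mode = config$exclusion_mode, eff = eff
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(stab)) {
      readr::write_tsv(
        tidy.stability_result(stab[[nm]]),
        file.path(out_dir, paste0("stability_", nm, ".tsv"))
      )
    }
    cons_flat <- tidy.consensus_ranking(consensus)
    cons_flat$exclusion_reasons <- purrr::map_chr(
      cons_flat$exclusion_reasons, paste,
      collapse = ";"
    )
    readr::write_tsv(cons_flat, file.path(out_dir, "consensus.tsv"))
    excl_flat <- exclusions
    excl_flat$exclusion_reasons <- purrr::map_chr(
      excl_flat$exclusion_reasons, paste,
      collapse = ";"
    )
    readr::write_tsv(excl_flat, file.path(out_dir, "exclusions.tsv"))
  }
  invisible(list(
    collapsed = collapsed, stability = stab,
    exclusions = exclusions, consensus = consensus
  ))
}

#' Run the normalization stage on Cq files
#'
#' Reads Cq data, collapses replicates, and normalizes the configured genes
#' of interest against all k-subsets of the reference genes, writing the
#' tidy result table.
#'
#' @param cq_path Long-format Cq file containing GOIs and references.
#' @param goi Genes of interest.
#' @param references Selected reference genes.
#' @param out_path Output TSV (NULL = no file).
#' @param metadata_path,efficiency_path Optional companion files.
#' @param config A [pipeline_config()]; must carry a `calibrator`.
#' @return The `normalization_result`, invisibly.
#' @export
run_normalize <- function(cq_path, goi, references, out_path = NULL,
                          metadata_path = NULL, efficiency_path = NULL,
                          config = pipeline_config()) {
  if (is.null(config$calibrator)) {
    rlang::abort("config must name a calibrator sample.",
      class = "refstab_calibrator_error"
    )
  }
  data <- read_cq_long(cq_path, metadata_path)
  eff <- if (!is.null(efficiency_path)) {
    efficiency_table(readr::read_tsv(efficiency_path,
      show_col_types = FALSE, progress = FALSE
    ))
  }
  collapsed <- collapse_replicates(data)
  res <- normalize_goi(collapsed,
    goi = goi, references = references,
    calibrator = config$calibrator, eff = eff, k = config$k
  )
  rlang::inform(sprintf(
    "normalize: %d GOI(s) x %d subset(s) x %d sample(s) = %d rows",
    length(unique(res$goi)), length(unique(res$subset_id)),
    length(unique(res$sample_id)), nrow(res)
  ))
  if (!is.null(out_path)) readr::write_tsv(tidy.normalization_result(res), out_path)
  invisible(res)
}

#' Run the full simulated workflow end to end
#'
#' Simulates a Cq dataset under the default study design, writes the input
#' files, then runs the stability/consensus and normalization stages from
#' those files. Deterministic for a fixed config seed.
#'
#' @param out_dir Directory for inputs and reports.
#' @param config A [pipeline_config()].
#' @param sim_spec Optional [cq_sim_spec()] for the candidate panel.
#' @param goi_spec Optional [cq_sim_spec()] for the genes of interest.
#' @param n_references How many top consensus genes to use as references.
#' @return A list with the stage results, invisibly.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         sim_spec = cq_sim_spec(default_cq_panel()),
                         goi_spec = NULL, n_references = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cq(sim_spec, seed = config$seed)
  cq_path <- file.path(out_dir, "cq_long.tsv")
  md_path <- file.path(out_dir, "sample_metadata.tsv")
  write_cq_long(sim[, c("gene_id", "sample_id", "replicate", "cq")], cq_path)
  readr::write_tsv(
    dplyr::distinct(sim[, c("sample_id", "culture", "passage", "condition")]),
    md_path
  )
  jsonlite::write_json(
    list(
      baseline_cq = as.list(sim_spec$baseline_cq),
      gene_noise_sd = as.list(sim_spec$gene_noise_sd),
      sample_loading_sd = sim_spec$sample_loading_sd,
      tech_noise_sd = sim_spec$tech_noise_sd,
      replicates = sim_spec$replicates,
      seed = config$seed
    ),
    file.path(out_dir, "simulation_spec.json"),
    auto_unbox = TRUE, digits = NA
  )

  stab <- run_stability(cq_path, md_path,
    out_dir = file.path(out_dir, "stability"), config = config
  )
  ranked <- stab$consensus$gene_id[!is.na(stab$consensus$final_rank)]
  references <- utils::head(ranked, n_references)

  goi_res <- NULL
  if (!is.null(goi_spec)) {
    goi_sim <- simulate_cq(goi_spec, seed = config$seed + 1L)
    combined <- dplyr::bind_rows(sim, goi_sim)
    comb_path <- file.path(out_dir, "cq_with_goi.tsv")
    write_cq_long(
      combined[, c("gene_id", "sample_id", "replicate", "cq")], comb_path
    )
    calibrator <- config$calibrator %||% sort(unique(sim$sample_id))[1]
    config$calibrator <- calibrator
    goi_res <- run_normalize(
      comb_path,
      goi = names(goi_spec$baseline_cq),
      references = references,
      out_path = file.path(out_dir, "normalization.tsv"),
      metadata_path = md_path, config = config
    )
  }
  invisible(list(
    simulation = sim, stability = stab,
    references = references, normalization = goi_res
  ))
}
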