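# Candidate screening on expression matrices.

make_expr <- function(m, unit) {
  df <- tibble::as_tibble(m, rownames = "gene_id")
  expression_matrix(df, unit = unit)
}

test_that("scaled_estimate -> TPM is a x1e6 rescale and round-trips", {
  m <- matrix(c(2.5e-6, 0, 1e-6, 4e-7), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))
  )
  x <- make_expr(m, "scaled_estimate")
  tpm <- to_tpm(x)
  expect_identical(expr_unit(tpm), "TPM")
  expect_equal(unname(as.matrix(tpm[, -1])), unname(m * 1e6))
  # exact round trip
  expect_equal(unname(as.matrix(tpm[, -1])) / 1e6, unname(m))
  # unit guards
  expect_error(to_tpm(tpm), class = "refstab_unit_error")
  expect_error(log2_transform(x), class = "refstab_unit_error")
})

test_that("log2 transform maps positives to log2 and zeros to a failing sentinel", {
  m <- matrix(c(2.5, 1, 0, 8), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))
  )
  lg <- log2_transform(make_expr(m, "TPM"))
  vals <- as.matrix(as.data.frame(lg)[, -1])
  rownames(vals) <- lg$gene_id
  expect_equal(vals["a", "s1"], log2(2.5))
  expect_equal(vals["b", "s1"], 0)
  expect_true(is.na(vals["a", "s2"]))
  # the sentinel gene fails every criterion
  res <- screen_reference_candidates(lg)
  expect_false(any(unlist(res[res$gene_id == "a", c("pass_mean", "pass_sd", "pass_no_outlier", "pass_all")])))
})

test_that("the three screening criteria behave at their boundaries", {
  m <- rbind(
    const6 = c(6, 6, 6, 6), # passes everything, CV 0
    lowmean = c(4.9, 4.7, 5.1, 4.9), # mean < 5
    in_band = c(6, 6, 6, 13), # 13 <= 2*7.75 -> no outlier
    in_band2 = c(6, 6, 6, 16), # 16 < 2*8.5 and 6 > 8.5/2 -> no outlier
    outlier = c(2, 8, 8, 8) # 2 < 6.5/2 -> outlier
  )
  colnames(m) <- paste0("s", 1:4)
  res <- screen_reference_candidates(make_expr(m, "log2TPM"))
  res <- tibble::column_to_rownames(as.data.frame(res), "gene_id")
  expect_true(res["const6", "pass_all"])
  expect_equal(res["const6", "cv_pct"], 0)
  expect_equal(res["const6", "rank"], 1L)
  expect_false(res["lowmean", "pass_mean"])
  expect_false(res["lowmean", "pass_all"])
  expect_true(res["lowmean", "pass_sd"])
  expect_true(res["in_band", "pass_no_outlier"])
  expect_true(res["in_band2", "pass_no_outlier"])
  expect_false(res["outlier", "pass_no_outlier"])
})

test_that("the log-offset dialect of the outlier rule flags 2-fold TPM changes", {
  m <- rbind(g1 = c(6, 6, 6, 7.5), g2 = c(6, 6, 6, 6.5))
  colnames(m) <- paste0("s", 1:4)
  strict <- screen_reference_candidates(
    make_expr(m, "log2TPM"),
    screen_criteria(outlier_rule = "log_offset")
  )
  # g1 deviates 1.125 > 1 log2 unit from its mean; g2 does not
  expect_false(strict$pass_no_outlier[strict$gene_id == "g1"])
  expect_true(strict$pass_no_outlier[strict$gene_id == "g2"])
  # under the literal multiplicative reading both pass
  lit <- screen_reference_candidates(make_expr(m, "log2TPM"))
  expect_true(all(lit$pass_no_outlier))
})

test_that("screening is invariant under sample permutation and ranks follow CV%", {
  ex <- simulate_expression(8, c(2, 2, 2), n_samples = 50, seed = 11)
  res <- screen_reference_candidates(ex)
  perm <- ex[, c(1, sample(2:ncol(ex)))]
  attr(perm, "unit") <- "log2TPM"
  class(perm) <- class(ex)
  res2 <- screen_reference_candidates(perm)
  expect_equal(
    res[, c("gene_id", "mean_log2tpm", "sd_log2tpm", "cv_pct", "rank")],
    res2[, c("gene_id", "mean_log2tpm", "sd_log2tpm", "cv_pct", "rank")]
  )
  # ranks are a permutation of 1..n_pass, ascending in cv_pct
  passing <- res[!is.na(res$rank), ]
  expect_setequal(passing$rank, seq_len(nrow(passing)))
  ord <- passing[order(passing$rank), ]
  expect_true(all(diff(ord$cv_pct) >= 0))
})

test_that("inflating a passing gene's SD never improves its CV rank", {
  ex <- simulate_expression(6, c(0, 0, 0), n_samples = 40, seed = 3)
  res <- screen_reference_candidates(ex)
  target <- res$gene_id[which.min(res$rank)]
  m <- as.matrix(as.data.frame(ex)[, -1])
  rownames(m) <- ex$gene_id
  i <- match(target, rownames(m))
  m[i, ] <- mean(m[i, ]) + (m[i, ] - mean(m[i, ])) * 1.8 # inflate SD, keep mean
  res2 <- screen_reference_candidates(make_expr(m, "log2TPM"))
  expect_true(res2$pass_all[res2$gene_id == target])
  expect_gte(
    res2$rank[res2$gene_id == target],
    res$rank[res$gene_id == target]
  )
})

test_that("select_candidates honours named slices and seeded draws", {
  ex <- simulate_expression(20, c(0, 0, 0), n_samples = 40, seed = 7)
  res <- screen_reference_candidates(ex)
  ranked <- res$gene_id[order(res$rank)]
  named <- select_candidates(
    res,
    list(
      list(from = 1, to = 10, genes = ranked[c(1, 3, 5)]),
      list(from = 11, to = 20, genes = ranked[c(12, 15)])
    )
  )
  expect_identical(named, ranked[c(1, 3, 5, 12, 15)])
  s1 <- select_candidates(res, list(list(from = 1, to = 20, sample = 3)), seed = 99)
  s2 <- select_candidates(res, list(list(from = 1, to = 20, sample = 3)), seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, 3)
  expect_identical(select_candidates(res, list()), character())
  expect_error(
    select_candidates(res, list(list(from = 1, to = 21))),
    class = "refstab_range_error"
  )
})

test_that("RSEM-style per-sample files merge by gene with zero fill", {
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "tumorA.rsem.genes.results")
  f2 <- file.path(tmp, "tumorB.rsem.genes.results")
  readr::write_tsv(tibble::tibble(
    gene_id = c("TP53|7157", "ACTB|60"),
    raw_count = c(10, 2000),
    scaled_estimate = c(2e-6, 8e-5)
  ), f1)
  readr::write_tsv(tibble::tibble(
    gene_id = c("ACTB|60", "GAPDH|2597"),
    raw_count = c(1500, 900),
    scaled_estimate = c(6e-5, 3e-5)
  ), f2)
  x <- read_rsem_genes(c(f1, f2), sample_ids = c("A", "B"))
  expect_identical(expr_unit(x), "scaled_estimate")
  expect_setequal(x$gene_id, c("TP53|7157", "ACTB|60", "GAPDH|2597"))
  # outer join: absent gene/sample combinations are 0
  expect_equal(x$B[x$gene_id == "TP53|7157"], 0)
  expect_equal(x$A[x$gene_id == "GAPDH|2597"], 0)
  tpm <- to_tpm(x)
  expect_equal(tpm$A[tpm$gene_id == "ACTB|60"], 80)
})
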