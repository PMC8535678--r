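# Exclusion rules, RefFinder aggregation, culture combination and subset
# enumeration.

test_that("exclusion rules flag the documented situations", {
  # g_low: weak expression; g_high: rRNA-like; g_cv: wildly variable;
  # g_ok: unremarkable
  m <- rbind(
    g_low = c(29, 29.4, 28.6, 29.2, 28.8),
    g_high = c(7.4, 7.6, 7.5, 7.3, 7.7),
    g_cv = c(20, 26, 20, 26, 23), # RQ swings ~64-fold
    g_ok = c(22, 22.2, 21.8, 22.1, 21.9)
  )
  colnames(m) <- paste0("s", 1:5)
  excl <- apply_exclusions(cq_tbl_from_matrix(m))
  reasons <- stats::setNames(excl$exclusion_reasons, excl$gene_id)
  excl <- tibble::column_to_rownames(as.data.frame(
    excl[, c("gene_id", "low_expression", "high_expression", "high_cv", "excluded")]
  ), "gene_id")
  expect_true(excl["g_low", "low_expression"])
  expect_true(excl["g_high", "high_expression"])
  expect_true(excl["g_cv", "high_cv"])
  expect_true("high_cv" %in% reasons[["g_cv"]])
  # the unremarkable gene draws none of the expression/variability flags
  expect_false(any(unlist(excl["g_ok", c("low_expression", "high_expression", "high_cv")])))
  expect_error(
    exclusion_thresholds(cq_low_expression = 10, cq_high_expression = 15),
    class = "refstab_config_error"
  )
})

test_that("a CV% of 86.6 on the linear RQ scale draws the high-cv flag", {
  # Cq chosen so RQ at E=2 is (1, 1, 4) -> CV ~ 86.6% > 50
  m <- rbind(g1 = 20 - log2(c(1, 1, 4)), g2 = c(20, 20.1, 19.9))
  colnames(m) <- paste0("s", 1:3)
  excl <- apply_exclusions(cq_tbl_from_matrix(m))
  expect_true(excl$high_cv[excl$gene_id == "g1"])
  expect_equal(excl$cv_pct[excl$gene_id == "g1"], 100 * sqrt(3) / 2, tolerance = 1e-9)
})

test_that("BestKeeper correlation below the threshold flags a gene", {
  set.seed(8)
  common <- rnorm(10, 22, 1)
  m <- rbind(
    tracks1 = common + 0.1 * rnorm(10, 0, 0.05),
    tracks2 = common + 0.1 * rnorm(10, 0, 0.05),
    tracks3 = common + 0.1 * rnorm(10, 0, 0.05),
    anti = 22 - 0.8 * (common - 22) # moves against the index
  )
  colnames(m) <- paste0("s", 1:10)
  excl <- apply_exclusions(cq_tbl_from_matrix(m))
  expect_true(excl$low_index_correlation[excl$gene_id == "anti"])
  expect_false(any(excl$low_index_correlation[excl$gene_id != "anti"]))
})

test_that("RefFinder aggregation is the geometric mean of four method ranks", {
  ranks <- list(
    delta_ct = c(a = 1, b = 2, c = 3, d = 4),
    bestkeeper = c(a = 1, b = 3, c = 2, d = 4),
    genorm = c(a = 1, b = 2, c = 4, d = 3),
    normfinder = c(a = 1, b = 2, c = 3, d = 4)
  )
  cons <- reffinder_consensus(ranks)
  expect_equal(cons$geomean_rank[cons$gene_id == "a"], 1)
  expect_equal(cons$final_rank[cons$gene_id == "a"], 1)
  expect_equal(
    cons$geomean_rank[cons$gene_id == "b"],
    (2 * 3 * 2 * 2)^(1 / 4)
  )
  # (1,2,3,4) across the four methods -> 24^(1/4)
  ranks2 <- list(
    delta_ct = c(a = 1, b = 2), bestkeeper = c(a = 2, b = 1),
    genorm = c(a = 3, b = 4), normfinder = c(a = 4, b = 3)
  )
  cons2 <- reffinder_consensus(ranks2)
  expect_equal(cons2$geomean_rank, rep(24^(1 / 4), 2), tolerance = 1e-12)
  expect_equal(round(24^(1 / 4), 4), 2.2134)
  # symmetric ranks tie; resolved deterministically by gene id
  expect_equal(cons2$gene_id, c("a", "b"))
  expect_equal(cons2$final_rank, c(1.5, 1.5))
})

test_that("aggregation ignores method and gene ordering and is monotone", {
  ranks <- list(
    delta_ct = c(a = 2, b = 1, c = 3),
    bestkeeper = c(b = 2, c = 3, a = 1),
    genorm = c(c = 1, a = 3, b = 2),
    normfinder = c(a = 2, c = 1, b = 3)
  )
  cons <- reffinder_consensus(ranks)
  cons_rev <- reffinder_consensus(rev(ranks),
    methods = rev(c("delta_ct", "bestkeeper", "genorm", "normfinder"))
  )
  expect_equal(
    cons$geomean_rank[order(cons$gene_id)],
    cons_rev$geomean_rank[order(cons_rev$gene_id)]
  )
  # improving one rank never worsens the geomean
  better <- ranks
  better$genorm["a"] <- 1
  cons_b <- reffinder_consensus(better)
  expect_lte(
    cons_b$geomean_rank[cons_b$gene_id == "a"],
    cons$geomean_rank[cons$gene_id == "a"]
  )
  # mismatched gene sets are an alignment error naming the difference
  bad <- ranks
  bad$genorm <- c(a = 1, b = 2, d = 3)
  expect_error(reffinder_consensus(bad),
    regexp = "c, d",
    class = "refstab_alignment_error"
  )
})

test_that("two-pass exclusion removes flagged genes before re-ranking", {
  sim <- simulate_cq(seed = 21)
  col <- collapse_replicates(sim)
  # force one mid-panel gene to look lowly expressed (baseline ~22 cycles)
  col$cq[col$gene_id == "G12"] <- col$cq[col$gene_id == "G12"] + 10
  excl <- apply_exclusions(col)
  expect_true(excl$excluded[excl$gene_id == "G12"])
  cons2 <- suppressMessages(
    reffinder_consensus(col, exclusions = excl, mode = "two_pass")
  )
  expect_false("G12" %in% cons2$gene_id)
  cons1 <- suppressMessages(
    reffinder_consensus(col, exclusions = excl, mode = "single_pass")
  )
  expect_true("G12" %in% cons1$gene_id)
  expect_true(is.na(cons1$final_rank[cons1$gene_id == "G12"]))
  expect_true("low_expression" %in% cons1$exclusion_reasons[[match("G12", cons1$gene_id)]])
})

test_that("culture combination takes the geometric mean of final ranks", {
  a <- tibble::tibble(gene_id = c("x", "y", "z"), final_rank = c(1, 2, 3))
  b <- tibble::tibble(gene_id = c("x", "y", "z"), final_rank = c(1, 8, 2))
  class(a) <- class(b) <- c("consensus_ranking", class(tibble::tibble()))
  comb <- combine_cultures(a, b)
  expect_equal(comb$cumulative_score[comb$gene_id == "x"], 1)
  expect_equal(comb$cumulative_score[comb$gene_id == "y"], 4) # sqrt(16)
  expect_equal(comb$final_rank[comb$gene_id == "x"], 1)
  # symmetric in its arguments; self-combination reproduces the ordering
  comb_rev <- combine_cultures(b, a)
  expect_equal(comb, comb_rev)
  self <- combine_cultures(a, a)
  expect_equal(self$final_rank, a$final_rank[match(self$gene_id, a$gene_id)])
})

test_that("subset enumeration yields all k-combinations in sorted order", {
  genes5 <- c("HSP90AB1", "DAD1", "PFN1", "RPL13A", "PUM1")
  trip <- enumerate_subsets(genes5, 3)
  expect_length(trip, 10) # choose(5, 3)
  expect_length(enumerate_subsets(letters[1:4], 3), 4)
  expect_length(enumerate_subsets(letters[1:3], 3), 1)
  expect_false(any(duplicated(purrr::map_chr(trip, paste, collapse = "|"))))
  expect_true(all(purrr::map_lgl(trip, function(s) identical(s, sort(s)))))
  # deterministic lexicographic order
  expect_identical(trip, enumerate_subsets(rev(genes5), 3))
  expect_error(enumerate_subsets(letters[1:3], 4), class = "refstab_range_error")
})
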