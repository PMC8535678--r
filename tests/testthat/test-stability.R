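# The five stability algorithms against independent oracles and their
# documented invariances.

test_that("geNorm M values match the brute-force pairwise oracle", {
  for (seed in 1:20) {
    g <- sample(3:6, 1)
    s <- sample(4:10, 1)
    rq <- random_rq(g, s, seed)
    res <- stability_genorm(rq)
    expect_equal(unname(res$statistic), oracle_genorm_m(rq), tolerance = 1e-12)
  }
})

test_that("geNorm removes an artificially noisy gene first and ranks the rest", {
  set.seed(42)
  base <- matrix(rep(runif(8, -1, 1), each = 4), 4, 8, byrow = TRUE)
  rq <- 2^rbind(
    stable1 = base[1, ], stable2 = base[2, ], stable3 = base[3, ],
    noisy = base[4, ] + rnorm(8, 0, 1.5)
  )
  colnames(rq) <- paste0("s", 1:8)
  res <- stability_genorm(rq)
  expect_identical(res$extras$removal_order[1], "noisy")
  expect_equal(unname(res$ranks["noisy"]), 4)
  expect_setequal(res$extras$final_pair, names(res$ranks)[res$ranks == 1.5])
  # V series: G - 2 entries, all non-negative
  expect_length(res$extras$v_series, nrow(rq) - 2)
  expect_true(all(res$extras$v_series >= 0))
})

test_that("proportional RQ vectors contribute zero pairwise SD in geNorm", {
  rq <- rbind(
    a = c(1, 0.5, 0.25, 0.8),
    b = 3 * c(1, 0.5, 0.25, 0.8), # proportional to a
    c = c(0.9, 0.3, 0.7, 0.2)
  )
  colnames(rq) <- paste0("s", 1:4)
  m <- stability_genorm(rq)$statistic
  # a and b differ only in the c-pair; their M values coincide
  expect_equal(unname(m["a"]), unname(m["b"]), tolerance = 1e-12)
  expect_equal(unname(m["a"]), sd(log2(rq["a", ] / rq["c", ])) / 2, tolerance = 1e-12)
})

test_that("ungrouped NormFinder equals the SD of sample-centered quantities", {
  for (seed in 1:10) {
    rq <- random_rq(5, 8, seed + 100)
    res <- stability_normfinder(rq)
    expect_equal(unname(res$statistic), unname(oracle_normfinder(rq)),
      tolerance = 1e-12
    )
  }
  # a gene constant in an otherwise sample-centered matrix is perfectly stable
  y <- rbind(g1 = rep(0, 6), g2 = c(-1, 1, -1, 1, -1, 1), g3 = c(1, -1, 1, -1, 1, -1))
  colnames(y) <- paste0("s", 1:6)
  res <- stability_normfinder(2^y)
  expect_equal(unname(res$statistic["g1"]), 0)
  expect_equal(unname(res$ranks["g1"]), 1)
})

test_that("grouped NormFinder penalizes a condition-shifted gene", {
  # zero-noise genes, one with a 2-cycle shift in the chronic group
  s <- 12
  groups <- rep(c("normoxia", "chronic"), each = s / 2)
  y <- rbind(
    g1 = rep(0, s), g2 = rep(1, s), g3 = rep(-1, s), g4 = rep(0.5, s),
    shifted = c(rep(0, s / 2), rep(2, s / 2))
  )
  colnames(y) <- paste0("s", seq_len(s))
  res <- stability_normfinder(2^y, group = groups)
  stat <- res$statistic
  expect_true(all(stat["shifted"] > stat[c("g1", "g2", "g3", "g4")]))
  expect_error(
    stability_normfinder(2^y, group = c("a", rep("b", s - 1))),
    class = "refstab_grouping_error"
  )
})

test_that("BestKeeper reports the index, dispersion, CV% and correlations", {
  m <- rbind(
    g1 = c(16, 17, 18, 19),
    g2 = 25 / 16 * c(16, 17, 18, 19) # proportional: BI is proportional too
  )
  colnames(m) <- paste0("s", 1:4)
  res <- stability_bestkeeper(m)
  # index = per-sample geometric mean of Cq
  expect_equal(unname(res$extras$index["s1"]), sqrt(16 * 25), tolerance = 1e-12)
  # both genes are affine-positive transforms of the index -> r = 1
  expect_equal(res$extras$summary$r, c(1, 1), tolerance = 1e-9)
  # mean 20, mean absolute deviation 1 -> CV% = 5
  m2 <- rbind(g1 = c(19, 21, 19, 21), g2 = c(18, 22, 24, 16))
  colnames(m2) <- paste0("s", 1:4)
  res2 <- stability_bestkeeper(m2)
  s1 <- res2$extras$summary[res2$extras$summary$gene_id == "g1", ]
  expect_equal(s1$dispersion, 1)
  expect_equal(s1$cv_pct, 5)
  # plain-SD dialect
  res3 <- stability_bestkeeper(m2, dispersion = "sd")
  expect_equal(unname(res3$statistic["g1"]), sd(c(19, 21, 19, 21)))
  # zero-variance gene: r undefined, still ranked by dispersion
  m3 <- rbind(g1 = c(20, 20, 20), g2 = c(18, 22, 20))
  colnames(m3) <- paste0("s", 1:3)
  res4 <- stability_bestkeeper(m3)
  expect_true(is.na(res4$extras$summary$r[res4$extras$summary$gene_id == "g1"]))
  expect_equal(unname(res4$ranks["g1"]), 1)
})

test_that("comparative dCt matches the exhaustive pairwise oracle", {
  for (seed in 1:20) {
    g <- sample(2:6, 1)
    s <- sample(3:10, 1)
    cq <- random_cq(g, s, seed + 200)
    res <- stability_delta_ct(cq)
    expect_equal(unname(res$statistic), oracle_delta_ct(cq), tolerance = 1e-12)
  }
  # constant offset between two genes -> both stabilities 0
  m <- rbind(g1 = c(20, 22, 21), g2 = c(23, 25, 24))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(unname(stability_delta_ct(m)$statistic), c(0, 0))
})

test_that("noise strictly inflates the comparative dCt statistic on average", {
  base <- random_cq(4, 5, 999)
  clean <- mean(replicate(100, {
    stability_delta_ct(base)$statistic[["g01"]]
  }))
  set.seed(4242)
  noisy <- mean(replicate(100, {
    m <- base
    m[1, ] <- m[1, ] + rnorm(5, 0, 1)
    stability_delta_ct(m)$statistic[["g01"]]
  }))
  expect_gt(noisy, clean)
})

test_that("CV% stability works on both scales and flags undefined means", {
  # linear RQ values (1, 1, 4): mean 2, SD sqrt(3) -> CV ~ 86.60
  rq <- rbind(g1 = c(1, 1, 4), g2 = c(1, 1, 1))
  colnames(rq) <- paste0("s", 1:3)
  cv_oracle <- 100 * sd(c(1, 1, 4)) / 2
  expect_equal(cv_oracle, 100 * sqrt(3) / 2, tolerance = 1e-12)
  # same values reached from Cq at E = 2: Cq = 20 - log2(RQ)
  res <- stability_cv(cq_tbl_from_matrix(20 - log2(rq)))
  expect_equal(unname(res$statistic["g1"]), cv_oracle, tolerance = 1e-12)
  expect_equal(unname(res$statistic["g2"]), 0)
  res_cq <- stability_cv(rbind(g1 = c(19, 21, 20), g2 = c(20, 20, 20)), scale = "cq")
  expect_equal(unname(res_cq$statistic["g1"]), 100 * sd(c(19, 21, 20)) / 20)
})

test_that("a shared per-sample shift moves BestKeeper but not the log-ratio methods", {
  cq <- random_cq(5, 8, 31)
  shifted <- cq
  shifted[, 3] <- shifted[, 3] + 1.7 # same shift for every gene in sample 3
  # log-ratio based methods run from Cq at equal efficiencies
  expect_equal(
    unname(stability_genorm(cq_tbl_from_matrix(cq))$statistic),
    unname(stability_genorm(cq_tbl_from_matrix(shifted))$statistic),
    tolerance = 1e-9
  )
  expect_equal(
    unname(stability_delta_ct(cq)$statistic),
    unname(stability_delta_ct(shifted)$statistic),
    tolerance = 1e-9
  )
  expect_equal(
    unname(stability_normfinder(cq_tbl_from_matrix(cq))$statistic),
    unname(stability_normfinder(cq_tbl_from_matrix(shifted))$statistic),
    tolerance = 1e-9
  )
  expect_false(isTRUE(all.equal(
    unname(stability_bestkeeper(cq)$statistic),
    unname(stability_bestkeeper(shifted)$statistic),
    tolerance = 1e-9
  )))
})

test_that("all five methods are invariant to gene and sample permutation", {
  cq <- random_cq(5, 7, 77)
  set.seed(7)
  perm <- cq[sample(nrow(cq)), sample(ncol(cq))]
  run_all <- function(m) {
    d <- cq_tbl_from_matrix(m)
    list(
      cv = stability_cv(d),
      genorm = stability_genorm(d),
      normfinder = stability_normfinder(d),
      bestkeeper = stability_bestkeeper(m),
      delta_ct = stability_delta_ct(m)
    )
  }
  a <- run_all(cq)
  b <- run_all(perm)
  for (nm in names(a)) {
    genes <- names(a[[nm]]$statistic)
    expect_equal(a[[nm]]$statistic[genes], b[[nm]]$statistic[genes],
      tolerance = 1e-9, label = nm
    )
  }
})

test_that("statistics are non-negative and ranks follow the statistic", {
  cq <- random_cq(6, 9, 123)
  d <- cq_tbl_from_matrix(cq)
  stab <- list(
    stability_cv(d), stability_genorm(d),
    stability_normfinder(d),
    stability_bestkeeper(cq), stability_delta_ct(cq)
  )
  for (res in stab) {
    expect_true(all(res$statistic >= 0), label = res$method)
    if (res$method == "genorm") {
      # stepwise ranking: shared 1.5 for the final pair, then 3..G
      expect_setequal(unname(res$ranks), c(1.5, 1.5, 3:length(res$ranks)))
    } else {
      expect_setequal(unname(sort(res$ranks)), seq_along(res$ranks))
      ord <- order(res$statistic)
      expect_true(all(diff(res$ranks[ord]) >= 0), label = res$method)
    }
  }
})

test_that("incomplete matrices are rejected with the offending cells named", {
  m <- random_cq(3, 4, 9)
  m[2, 3] <- NA
  expect_error(stability_genorm(m),
    regexp = "g02/s03",
    class = "refstab_missing_data_error"
  )
  expect_error(stability_delta_ct(m), class = "refstab_missing_data_error")
})
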