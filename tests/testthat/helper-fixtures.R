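# Shared fixtures and independent oracles.

# Random positive RQ matrix (genes x samples), seeded.
random_rq <- function(g, s, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(g * s, 0, 1), g, s,
    dimnames = list(sprintf("g%02d", seq_len(g)), sprintf("s%02d", seq_len(s)))
  )
  m
}

# Random Cq matrix in a realistic cycle range.
random_cq <- function(g, s, seed) {
  set.seed(seed)
  matrix(runif(g * s, 15, 30), g, s,
    dimnames = list(sprintf("g%02d", seq_len(g)), sprintf("s%02d", seq_len(s)))
  )
}

# Collapsed cq_tbl from a genes x samples matrix.
cq_tbl_from_matrix <- function(m) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "gene_id"),
    -gene_id,
    names_to = "sample_id", values_to = "cq"
  )
  long$replicate <- 1L
  cq_dataset(long)
}

# --- independent oracles -------------------------------------------------

# geNorm M by direct enumeration of all pairs.
oracle_genorm_m <- function(rq) {
  y <- log2(rq)
  g <- nrow(y)
  vapply(seq_len(g), function(j) {
    mean(vapply(
      setdiff(seq_len(g), j),
      function(k) sd(y[j, ] - y[k, ]), numeric(1)
    ))
  }, numeric(1))
}

# comparative dCt by exhaustive pairwise SDs.
oracle_delta_ct <- function(cq) {
  g <- nrow(cq)
  vapply(seq_len(g), function(j) {
    mean(vapply(
      setdiff(seq_len(g), j),
      function(k) sd(cq[j, ] - cq[k, ]), numeric(1)
    ))
  }, numeric(1))
}

# ungrouped NormFinder: SD of sample-centered log2 quantities.
oracle_normfinder <- function(rq) {
  y <- log2(rq)
  z <- sweep(y, 2, colMeans(y))
  apply(z, 1, sd)
}

# The simulation spec used for the planted-stability recovery checks:
# 3 designated stable genes, 6 noisy, 3 hypoxia-regulated, over the
# 2-culture serial-passage design with hypoxic arms.
recovery_sim_spec <- function() {
  genes <- c(sprintf("STB%d", 1:3), sprintf("NSY%d", 1:6), sprintf("REG%d", 1:3))
  baseline <- stats::setNames(seq(18, 26, length.out = 12), genes)
  noise <- stats::setNames(
    c(rep(0.05, 3), seq(0.5, 1.2, length.out = 6), rep(0.1, 3)), genes
  )
  ce <- tidyr::expand_grid(
    gene_id = sprintf("REG%d", 1:3),
    condition = c("acute_24h", "acute_72h", "chronic")
  )
  ce$beta <- c(1.5, 2, -1.5)[match(ce$gene_id, sprintf("REG%d", 1:3))]
  cq_sim_spec(
    baseline,
    gene_noise_sd = noise, condition_effects = ce,
    design = cq_sim_design(
      conditions = c("normoxia", "acute_24h", "acute_72h", "chronic")
    )
  )
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
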