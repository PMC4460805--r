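test_that("site-pattern counting excludes gaps and ambiguity codes", {
  expect_equal(count_site_patterns("ACGT", "ACGT"), list(n = 4L, ts = 0L, tv = 0L))
  expect_equal(count_site_patterns("AAAA", "GAAC"), list(n = 4L, ts = 1L, tv = 1L))
  # the gap and the N fall in the same column here, so one column is dropped
  expect_equal(count_site_patterns("AC-T", "ACNT")$n, 3L)
  # gap column and N column in distinct positions: two columns dropped
  expect_equal(count_site_patterns("A-CT", "ANCN")$n, 2L)
  expect_equal(count_site_patterns("acgt", "ACGT")$n, 4L)
  expect_error(count_site_patterns("ACG", "ACGT"), "equal length")
})

test_that("K2P follows the closed form and flags the undefined domain", {
  expect_equal(kimura_k2p(list(n = 100, ts = 0, tv = 0))$d, 0)
  d <- kimura_k2p(list(n = 100, ts = 10, tv = 5))
  expect_equal(d$d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)), tolerance = 1e-12)
  expect_equal(d$d, 0.170181, tolerance = 1e-6)
  # P = 0.5, Q = 0: log argument hits zero
  sat <- kimura_k2p(list(n = 100, ts = 50, tv = 0))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))
  expect_error(kimura_k2p(list(n = 0, ts = 0, tv = 0)), "no comparable sites")
})

test_that("K2P distance is strictly increasing in P and in Q", {
  n <- 1000
  grid <- seq(0.01, 0.2, by = 0.01)
  dP <- vapply(grid, function(p) {
    kimura_k2p(list(n = n, ts = round(p * n), tv = 50))$d
  }, numeric(1))
  expect_true(all(diff(dP) > 0))
  dQ <- vapply(grid, function(q) {
    kimura_k2p(list(n = n, ts = 100, tv = round(q * n)))$d
  }, numeric(1))
  expect_true(all(diff(dQ) > 0))
})

test_that("for tiny divergence d approaches P + Q", {
  for (x in list(c(5, 5), c(10, 5), c(2, 8))) {
    n <- 1000
    d <- kimura_k2p(list(n = n, ts = x[1], tv = x[2]))
    expect_lte(abs(d$d - (d$P + d$Q)), 0.001)
  }
})

test_that("K2P recovers planted substitution parameters over 100 simulated pairs", {
  set.seed(31)
  target <- -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1))
  ds <- vapply(1:100, function(i) {
    pair <- simulate_seq_pair(2000L, 0.1, 0.05)
    kimura_k2p(count_site_patterns(pair$ref, pair$query))$d
  }, numeric(1))
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - target), 2 * se + 1e-9)
})

test_that("equal-rate simulation agrees with the Jukes-Cantor closed form", {
  # substitution probability 0.09 split evenly across the three targets
  set.seed(32)
  p_sub <- 0.09
  d_jc <- -3 / 4 * log(1 - 4 / 3 * p_sub)
  ds <- vapply(1:50, function(i) {
    pair <- simulate_seq_pair(3000L, p_sub / 3, 2 * p_sub / 3)
    kimura_k2p(count_site_patterns(pair$ref, pair$query))$d
  }, numeric(1))
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - d_jc), 3 * se + 1e-9)
})

test_that("K2P matches the ape K80 estimator on gap-free pairs", {
  skip_if_not_installed("ape")
  set.seed(33)
  for (i in 1:10) {
    pair <- simulate_seq_pair(1500L, stats::runif(1, 0.02, 0.12),
                              stats::runif(1, 0.01, 0.08))
    mine <- kimura_k2p(count_site_patterns(pair$ref, pair$query))$d
    bin <- ape::as.DNAbin(rbind(
      strsplit(tolower(pair$ref), "")[[1]], strsplit(tolower(pair$query), "")[[1]]
    ))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("per-gene rates pool exon projections and flag poor coverage", {
  # identical ortholog -> d = 0
  g <- make_gene("g", "c", "+", c(0L, 200L), c(100L, 300L))
  blocks <- make_block("c", 0L, strrep("ACGT", 75), strrep("ACGT", 75))
  r <- gene_evolutionary_rates(g, blocks)
  expect_equal(r$d, 0)
  expect_equal(r$n, 200L)  # both exons fully covered
  expect_false(r$low_confidence)
  # no aligned exon bases -> missing
  far <- make_gene("h", "c", "+", 5000L, 5400L)
  r2 <- gene_evolutionary_rates(far, blocks)
  expect_true(is.na(r2$d))
  expect_true(r2$low_confidence)
})

test_that("simulated exon alignments recover the planted K2P distance", {
  set.seed(34)
  cfg <- sim_config(seed = 99L, n_chroms = 1L, chrom_len = 500000L,
                    n_linc_genes = 40L, n_pc_genes = 10L,
                    exon_len = c(400L, 800L), rate_rho = 0)
  sim <- simulate_genome(cfg)
  blocks <- simulate_orthologs(sim)
  rates <- gene_evolutionary_rates(sim$linc_genes, blocks)
  target <- -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1))
  ok <- !is.na(rates$d) & !rates$low_confidence
  # pooled over >= 10 kb of exon alignment the mean lands within 3 SE
  pooled_n <- sum(rates$n[ok])
  expect_gt(pooled_n, 10000)
  se <- stats::sd(rates$d[ok]) / sqrt(sum(ok))
  expect_lt(abs(mean(rates$d[ok]) - target), 3 * se + 1e-9)
})
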