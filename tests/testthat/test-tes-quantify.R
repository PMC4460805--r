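test_that("coverage is an interval union, clipped to the regions", {
  regions <- tibble::tibble(chrom = "c", start = 0L, end = 100L)
  tes <- make_tes("c", c(10L, 20L), c(30L, 50L))
  cov <- te_coverage(regions, tes)
  expect_equal(cov$te_nt, 40L)
  expect_equal(cov$fraction, 0.40)
  # no TEs -> 0; empty region -> NA fraction distinct from 0
  expect_equal(te_coverage(regions, tes[0, ])$fraction, 0)
  empty_cov <- te_coverage(regions[0, ] %>%
                             dplyr::mutate(region_class = character()), tes)
  expect_equal(nrow(empty_cov), 0L)
  # TE spanning the region boundary contributes only overlapping bases
  spill <- make_tes("c", 90L, 150L)
  expect_equal(te_coverage(regions, spill)$te_nt, 10L)
})

test_that("coverage equals the per-base oracle on random small instances", {
  set.seed(7)
  for (i in 1:200) {
    n_reg <- sample(1:4, 1)
    rs <- sample(0:150, n_reg)
    regions <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n_reg, replace = TRUE),
      start = rs, end = rs + sample(5:60, n_reg, replace = TRUE)
    ) %>% lincte:::iv_reduce()
    n_te <- sample(0:6, 1)
    ts <- sample(0:180, max(n_te, 1))[seq_len(n_te)]
    tes <- make_tes(sample(c("c1", "c2"), n_te, replace = TRUE),
                    ts, ts + sample(3:50, n_te, replace = TRUE))
    cov <- te_coverage(regions, tes)
    expect_identical(sum(cov$te_nt), coverage_oracle(regions, tes))
  }
})

test_that("per-gene TES fractions match the per-base oracle", {
  g <- make_gene("g", "c", "+", c(0L, 600L), c(500L, 1100L))
  tes <- make_tes("c", c(100L, 520L), c(350L, 580L))  # 250 exonic + 0 intronic
  pg <- tes_fraction_per_gene(g, tes)
  expect_equal(pg$tes_fraction, 0.25)
  # intron-only TE counts zero
  expect_equal(tes_fraction_per_gene(g, make_tes("c", 510L, 590L))$tes_fraction, 0)
  set.seed(8)
  for (i in 1:50) {
    widths <- sample(20:80, 3, replace = TRUE)
    gaps <- sample(10:100, 3, replace = TRUE)
    starts <- cumsum(gaps + c(0L, widths[-3]))
    g <- make_gene("g", "c", "+", starts, starts + widths)
    n_te <- sample(1:5, 1)
    ts <- sample(0:400, n_te)
    tes <- make_tes("c", ts, ts + sample(5:60, n_te, replace = TRUE))
    pg <- tes_fraction_per_gene(g, tes)
    oracle <- coverage_oracle(gene_exons(g)[, c("chrom", "start", "end")], tes)
    expect_identical(pg$te_nt, oracle)
  }
})

test_that("per-class attribution gives shared bases to the higher score", {
  regions <- tibble::tibble(chrom = "c", start = 0L, end = 200L)
  tes <- make_tes("c", c(10L, 40L), c(60L, 90L), te_class = c("SINE", "LINE"),
                  sw_score = c(2000L, 1000L))
  cc <- te_class_coverage(regions, tes)
  expect_equal(cc$te_nt[cc$te_class == "SINE"], 50L)  # [10,60) all SINE (higher score)
  expect_equal(cc$te_nt[cc$te_class == "LINE"], 30L)  # [60,90) remainder
  expect_equal(sum(cc$te_nt), te_coverage(regions, tes)$te_nt)
  # score tie -> earlier record wins the shared bases
  tie <- make_tes("c", c(10L, 40L), c(60L, 90L), te_class = c("SINE", "LINE"),
                  sw_score = 1000L)
  cct <- te_class_coverage(regions, tie)
  expect_equal(cct$te_nt[cct$te_class == "SINE"], 50L)
  # record_sum double counts the overlap
  rs <- te_class_coverage(regions, tes, method = "record_sum")
  expect_equal(rs$te_nt[rs$te_class == "SINE"], 50L)
  expect_equal(rs$te_nt[rs$te_class == "LINE"], 50L)
})

test_that("adding a TE never decreases coverage, and duplication scales counts", {
  set.seed(9)
  regions <- tibble::tibble(chrom = "c1", start = 0L, end = 500L)
  ts <- sample(0:450, 8)
  tes <- make_tes("c1", ts, ts + sample(10:60, 8, replace = TRUE))
  for (k in 1:7) {
    a <- te_coverage(regions, tes[seq_len(k), ])$te_nt
    b <- te_coverage(regions, tes[seq_len(k + 1), ])$te_nt
    expect_gte(b, a)
  }
  # duplicate everything on a second chromosome: fractions unchanged, counts doubled
  regions2 <- dplyr::bind_rows(regions, dplyr::mutate(regions, chrom = "c2"))
  tes2 <- dplyr::bind_rows(tes, dplyr::mutate(tes, chrom = "c2", te_id = te_id + 100L))
  c1 <- te_coverage(regions, tes)
  c2 <- te_coverage(regions2, tes2)
  expect_equal(c2$te_nt, 2L * c1$te_nt)
  expect_equal(c2$fraction, c1$fraction)
})

test_that("fraction histograms use half-open bins with a closed last bin", {
  h <- histogram_fractions(c(0.1, 0.15, 0.5))
  expect_equal(h$count, c(2L, 0L, 1L, 0L, 0L))
  expect_equal(histogram_fractions(1.0)$count, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(histogram_fractions(numeric())$count, rep(0L, 5))
  expect_equal(histogram_fractions(0.2)$count, c(0L, 1L, 0L, 0L, 0L))
  expect_error(histogram_fractions(1.2), "\\[0, 1\\]")
})

test_that("contingency tables are (TES, TE-free) nucleotide counts per group", {
  a <- list(te_nt = 40, total_nt = 100)
  b <- list(te_nt = 10, total_nt = 100)
  m <- make_contingency(a, b)
  expect_equal(unname(m), matrix(c(40, 60, 10, 90), 2, byrow = TRUE))
  same <- make_contingency(a, a)
  expect_equal(same[1, ], same[2, ])
})

test_that("two-sided Fisher matches enumeration, including the worked cases", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(c(10, 90, 10, 90), 2, byrow = TRUE)), 1)
  expect_message(
    p0 <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
    "zero margin"
  )
  expect_equal(p0, 1)
  set.seed(10)
  for (i in 1:150) {
    cells <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(1 / 4, 4)))
    tab <- matrix(cells, 2)
    p <- suppressMessages(fisher_exact_two_sided(tab))
    expect_equal(p, fisher_enum_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
    # symmetric under row swap and column swap
    expect_equal(p, suppressMessages(fisher_exact_two_sided(tab[2:1, ])),
                 tolerance = 1e-12)
    expect_equal(p, suppressMessages(fisher_exact_two_sided(tab[, 2:1])),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with chi-square within an order of magnitude on large tables", {
  tabs <- list(
    matrix(c(400, 600, 450, 550), 2, byrow = TRUE),
    matrix(c(300, 700, 360, 640), 2, byrow = TRUE),
    matrix(c(1000, 1000, 1080, 920), 2, byrow = TRUE)
  )
  for (tab in tabs) {
    pf <- fisher_exact_two_sided(tab)
    pc <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    expect_lt(abs(log10(pf) - log10(pc)), 1)
  }
})

test_that("genome-wide fraction is the TE union over the genome length", {
  tes <- make_tes("c", c(0L, 50L), c(100L, 120L), te_class = c("SINE", "LINE"))
  gf <- genome_te_fraction(tes, 1000L)
  expect_equal(gf$fraction[gf$te_class == "ALL"], 0.12)
  expect_equal(gf$fraction[gf$te_class == "SINE"], 0.1)
  expect_equal(nrow(genome_te_fraction(tes[0, ], 1000L)), 1L)
  set.seed(11)
  ts <- sample(0:9000, 30)
  rtes <- make_tes("g", ts, ts + sample(20:300, 30, replace = TRUE))
  genome_iv <- tibble::tibble(chrom = "g", start = 0L, end = 10000L)
  expect_equal(
    genome_te_fraction(rtes, 10000L)$fraction[1],
    coverage_oracle(genome_iv, rtes) / 10000
  )
})
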