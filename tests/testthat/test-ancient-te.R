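test_that("projection selects reference columns plus internal insertions", {
  # TE inside a gapless block
  blk <- make_block("c", 0L, strrep("A", 50), strrep("A", 50))
  pr <- project_interval_alignment(blk, "c", 10L, 20L)
  expect_equal(pr$columns, 10L)
  expect_equal(pr$gap_cols, 0L)
  # no overlapping block -> absent
  expect_null(project_interval_alignment(blk, "c", 100L, 120L))
  expect_null(project_interval_alignment(blk, "other", 10L, 20L))
  # ref AC--GT / query ACTTGT over all 4 ref bases: 6 columns, 2 gap columns
  blk2 <- make_block("c", 10L, "AC--GT", "ACTTGT")
  pr2 <- project_interval_alignment(blk2, "c", 10L, 14L)
  expect_equal(pr2$columns, 6L)
  expect_equal(pr2$gap_cols, 2L)
  expect_equal(pr2$gap_cols / pr2$columns, 1 / 3)
  # ref-gap columns outside the selected reference span are excluded
  pr3 <- project_interval_alignment(blk2, "c", 10L, 12L)  # bases A, C only
  expect_equal(pr3$columns, 2L)
  expect_equal(pr3$ref_gapped, "AC")
})

test_that("multi-block TEs concatenate per-block projections", {
  blocks <- dplyr::bind_rows(
    make_block("c", 0L, strrep("A", 10), strrep("G", 10)),
    make_block("c", 30L, strrep("C", 10), strrep("C", 10))
  )
  pr <- project_interval_alignment(blocks, "c", 5L, 35L)
  expect_equal(pr$columns, 10L)  # 5 from each block; [10,30) unaligned
  expect_equal(pr$ref_cols, 10L)
  te <- make_tes("c", 5L, 35L)
  tbl <- project_te_alignment(te, blocks)
  expect_equal(tbl$columns, 10L)
  expect_equal(tbl$te_id, 1L)
})

test_that("reference non-gap columns equal the TE-block overlap on random layouts", {
  set.seed(21)
  for (i in 1:100) {
    n_blk <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 400, by = 50), n_blk))
    blocks <- purrr::map_dfr(starts, function(s) {
      w <- sample(10:40, 1)
      ref <- strsplit(paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = ""), "")[[1]]
      # sprinkle ref gaps (query insertions)
      gapped <- unlist(purrr::map(ref, function(ch) {
        if (stats::runif(1) < 0.15) c(ch, "-") else ch
      }))
      qry <- sample(c("A", "C", "G", "T"), length(gapped), TRUE)
      make_block("c", s, paste(gapped, collapse = ""), paste(qry, collapse = ""))
    })
    s <- sample(0:400, 1)
    te <- make_tes("c", s, s + sample(10:120, 1))
    pr <- project_te_alignment(te, blocks)
    span <- nchar(gsub("-", "", blocks$ref_text))
    ov <- sum(pmax(0, pmin(te$end, blocks$ref_start + span) -
                     pmax(te$start, blocks$ref_start)))
    if (is.null(pr)) {
      expect_equal(ov, 0L)
    } else {
      expect_equal(pr$ref_cols, ov)
    }
  }
})

test_that("ancient classification applies strict length and indel thresholds", {
  mk <- function(cols, indel) {
    tibble::tibble(te_id = 1L, columns = cols, gap_cols = round(cols * indel),
                   ref_cols = cols, indel_fraction = indel,
                   ref_gapped = "", query_gapped = "")
  }
  te <- make_tes("c", 0L, 10L)
  cases <- list(
    list(150L, 0.04, TRUE, TRUE),    # stringent and relaxed
    list(150L, 0.10, FALSE, TRUE),   # relaxed only
    list(100L, 0.0, FALSE, FALSE),   # "longer than 100" is strict
    list(150L, 0.05, FALSE, TRUE),   # stringent bound is strict
    list(150L, 0.25, FALSE, TRUE),   # relaxed bound is inclusive
    list(150L, 0.26, FALSE, FALSE)
  )
  for (cs in cases) {
    call <- classify_ancient(te, mk(cs[[1]], cs[[2]]))
    expect_equal(call$ancient_stringent, cs[[3]])
    expect_equal(call$ancient_relaxed, cs[[4]])
  }
  # absent projection -> lineage-specific
  none <- classify_ancient(te, mk(150L, 0)[0, ])
  expect_false(none$ancient_stringent)
  expect_false(none$ancient_relaxed)
})

test_that("lowering indel thresholds never increases ancient counts", {
  set.seed(22)
  tes <- make_tes("c", seq(0L, 290L, by = 10L), seq(5L, 295L, by = 10L))
  proj <- tibble::tibble(
    te_id = tes$te_id,
    columns = sample(60:200, nrow(tes), TRUE),
    gap_cols = 0L, ref_cols = 0L,
    indel_fraction = stats::runif(nrow(tes), 0, 0.4),
    ref_gapped = "", query_gapped = ""
  )
  prev <- Inf
  for (thr in c(0.25, 0.15, 0.05, 0.01)) {
    p <- analysis_params(ancient_max_indel_stringent = thr,
                         ancient_max_indel_relaxed = thr)
    n <- sum(classify_ancient(tes, proj, p)$ancient_relaxed)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("TEs are attributed to their maximal-overlap region class", {
  rs <- dplyr::bind_rows(
    tibble::tibble(region_class = "EXON", chrom = "c", start = 100L, end = 200L),
    tibble::tibble(region_class = "INTRON", chrom = "c", start = 200L, end = 400L),
    tibble::tibble(region_class = "PROMOTER", chrom = "c", start = 0L, end = 100L)
  )
  # 40 bases exon, 60 bases intron -> INTRON
  te1 <- make_tes("c", 160L, 260L)
  expect_equal(assign_region_class(te1, rs)$region_class, "INTRON")
  # exact tie exon/promoter -> PROMOTER
  te2 <- make_tes("c", 80L, 120L)
  expect_equal(assign_region_class(te2, rs)$region_class, "PROMOTER")
  # outside all regions -> NA (dropped downstream)
  te3 <- make_tes("c", 500L, 600L)
  expect_true(is.na(assign_region_class(te3, rs)$region_class))
})

test_that("ancient fractions per region feed pairwise Fisher tests", {
  calls <- dplyr::bind_rows(
    tibble::tibble(te_id = 1:100, region_class = "PROMOTER",
                   ancient_stringent = rep(c(TRUE, FALSE), c(30, 70)),
                   ancient_relaxed = rep(c(TRUE, FALSE), c(30, 70))),
    tibble::tibble(te_id = 101:200, region_class = "INTRON",
                   ancient_stringent = rep(c(TRUE, FALSE), c(10, 90)),
                   ancient_relaxed = rep(c(TRUE, FALSE), c(10, 90)))
  )
  res <- ancient_fraction_by_region(calls, mode = "stringent")
  br <- res$by_region
  expect_equal(br$fraction[br$region_class == "PROMOTER"], 0.30)
  expect_equal(br$fraction[br$region_class == "INTRON"], 0.10)
  expect_true(is.na(br$fraction[br$region_class == "EXON"]))
  p <- res$tests$p_value[res$tests$comparison == "PROMOTER_vs_INTRON"]
  expect_equal(p, fisher_enum_oracle(30, 70, 10, 90), tolerance = 1e-12)
  expect_true(is.na(res$tests$p_value[res$tests$comparison == "EXON_vs_INTRON"]))
  # all ancient -> fraction 1 everywhere, p = 1
  all_anc <- calls %>% dplyr::mutate(ancient_stringent = TRUE)
  res2 <- ancient_fraction_by_region(all_anc, mode = "stringent")
  expect_equal(res2$by_region$fraction[c(1, 3)], c(1, 1))
  expect_equal(res2$tests$p_value[1], 1)
})

test_that("stringent ancient calls are a subset of relaxed calls on simulated data", {
  calls <- default_ancient_calls()
  expect_true(all(calls$ancient_relaxed[calls$ancient_stringent]))
  expect_true(all(calls$indel_fraction >= 0 & calls$indel_fraction <= 1, na.rm = TRUE))
})
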