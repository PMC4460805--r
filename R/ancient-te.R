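# Projection of TE intervals through cross-species pairwise alignments and
# ancient vs lineage-specific classification.

# Per-column reference coordinate of a gapped text: NA at gap columns,
# 0-based genomic position otherwise.
ref_coords <- function(ref_text, ref_start) {
  chars <- strsplit(ref_text, "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  pos <- rep(NA_integer_, length(chars))
  pos[nongap] <- ref_start + seq_len(sum(nongap)) - 1L
  pos
}

project_one_block <- function(block, start, end) {
  rc <- ref_coords(block$ref_text, block$ref_start)
  sel <- which(!is.na(rc) & rc >= start & rc < end)
  if (length(sel) == 0L) return(NULL)
  cols <- min(sel):max(sel)  # includes ref-gap columns strictly between
  list(
    ref = substring(block$ref_text, min(sel), max(sel)),
    query = substring(block$query_text, min(sel), max(sel)),
    n_ref = length(sel)
  )
}

#' Project a genomic interval through pairwise alignment blocks
#'
#' Selects all alignment columns whose reference coordinate lies in
#' `[start, end)`, plus query-insertion (reference-gap) columns strictly
#' between the first and last selected reference columns within each block.
#' Intervals spanning several blocks concatenate their per-block
#' projections; stretches with no block coverage contribute no columns.
#'
#' @param blocks Alignment-block tibble ([read_maf()]).
#' @param chrom,start,end Reference interval, 0-based half-open.
#' @return `NULL` when no block overlaps the interval, else a list with
#'   `ref_gapped`, `query_gapped`, `columns`, `gap_cols` (columns where
#'   either row is a gap), `ref_cols` (reference non-gap columns).
#' @export
project_interval_alignment <- function(blocks, chrom, start, end) {
  span <- nchar(gsub("-", "", blocks$ref_text))
  keep <- blocks$ref_chrom == chrom & blocks$ref_start < end &
    blocks$ref_start + span > start
  project_interval_core(blocks[keep, , drop = FALSE], start, end)
}

# core projection over pre-filtered candidate blocks (base-R hot path)
project_interval_core <- function(cand, start, end) {
  if (nrow(cand) == 0L) return(NULL)
  if (any(nchar(cand$ref_text) != nchar(cand$query_text))) {
    stop("inconsistent block texts: ref and query gapped lengths differ")
  }
  cand <- cand[order(cand$ref_start), , drop = FALSE]
  parts <- purrr::compact(purrr::map(seq_len(nrow(cand)), function(i) {
    project_one_block(cand[i, ], start, end)
  }))
  if (length(parts) == 0L) return(NULL)
  ref <- paste(purrr::map_chr(parts, "ref"), collapse = "")
  qry <- paste(purrr::map_chr(parts, "query"), collapse = "")
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(qry, "", fixed = TRUE)[[1]]
  list(
    ref_gapped = ref, query_gapped = qry,
    columns = nchar(ref),
    gap_cols = sum(rc == "-" | qc == "-"),
    ref_cols = sum(rc != "-")
  )
}

#' Project one TE annotation through alignment blocks
#'
#' @param te A single-row TE annotation tibble.
#' @param blocks Alignment-block tibble.
#' @return One-row tibble `te_id`, `columns`, `gap_cols`, `ref_cols`,
#'   `indel_fraction`, `ref_gapped`, `query_gapped`, or `NULL` when the TE
#'   overlaps no block (lineage-specific downstream).
#' @export
project_te_alignment <- function(te, blocks) {
  pr <- project_interval_alignment(blocks, te$chrom, te$start, te$end)
  if (is.null(pr)) return(NULL)
  tibble::tibble(
    te_id = te$te_id, columns = pr$columns, gap_cols = pr$gap_cols,
    ref_cols = pr$ref_cols, indel_fraction = pr$gap_cols / pr$columns,
    ref_gapped = pr$ref_gapped, query_gapped = pr$query_gapped
  )
}

#' Project many TEs through alignment blocks
#'
#' Vectorised wrapper around [project_te_alignment()] using a single
#' overlap join; TEs with no block coverage are absent from the result.
#'
#' @param tes TE annotation tibble.
#' @param blocks Alignment-block tibble.
#' @return Tibble with one row per projected TE (columns as in
#'   [project_te_alignment()]).
#' @export
project_te_alignments <- function(tes, blocks) {
  empty <- tibble::tibble(
    te_id = integer(), columns = integer(), gap_cols = integer(),
    ref_cols = integer(), indel_fraction = numeric(),
    ref_gapped = character(), query_gapped = character()
  )
  if (nrow(tes) == 0L || nrow(blocks) == 0L) return(empty)
  blocks <- blocks %>%
    mutate(ref_span = nchar(gsub("-", "", .data$ref_text)))
  bl_gr <- as_granges(tibble::tibble(
    chrom = blocks$ref_chrom, start = blocks$ref_start,
    end = blocks$ref_start + blocks$ref_span
  ))
  te_gr <- as_granges(tes[, c("chrom", "start", "end")])
  lv <- union(GenomeInfoDb::seqlevels(bl_gr), GenomeInfoDb::seqlevels(te_gr))
  GenomeInfoDb::seqlevels(bl_gr) <- lv
  GenomeInfoDb::seqlevels(te_gr) <- lv
  hits <- GenomicRanges::findOverlaps(te_gr, bl_gr)
  if (length(hits) == 0L) return(empty)
  by_te <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  purrr::map_dfr(names(by_te), function(ti) {
    i <- as.integer(ti)
    project_te_alignment(tes[i, ], blocks[by_te[[ti]], ])
  })
}

#' Classify projected TE alignments as ancient or lineage-specific
#'
#' A TE is ancient-stringent when its orthologous alignment has strictly
#' more than `ancient_min_cols` columns and a gap-column fraction strictly
#' below the stringent threshold; ancient-relaxed additionally admits gap
#' fractions up to (and including) the relaxed threshold. TEs without any
#' projection are lineage-specific (both flags `FALSE`).
#'
#' @param tes TE annotation tibble (every TE to be classified).
#' @param projections Output of [project_te_alignments()].
#' @param params [analysis_params()].
#' @return Tibble `te_id`, `aligned`, `columns`, `indel_fraction`,
#'   `ancient_stringent`, `ancient_relaxed`.
#' @export
classify_ancient <- function(tes, projections, params = analysis_params()) {
  base <- tibble::tibble(te_id = tes$te_id) %>%
    left_join(
      projections %>% select("te_id", "columns", "indel_fraction"),
      by = "te_id"
    ) %>%
    mutate(aligned = !is.na(.data$columns))
  base %>%
    mutate(
      ancient_stringent = .data$aligned &
        .data$columns > params$ancient_min_cols &
        .data$indel_fraction < params$ancient_max_indel_stringent,
      ancient_relaxed = .data$aligned &
        .data$columns > params$ancient_min_cols &
        .data$indel_fraction <= params$ancient_max_indel_relaxed,
      ancient_stringent = tidyr::replace_na(.data$ancient_stringent, FALSE),
      ancient_relaxed = tidyr::replace_na(.data$ancient_relaxed, FALSE)
    ) %>%
    select("te_id", "aligned", "columns", "indel_fraction",
           "ancient_stringent", "ancient_relaxed")
}

#' Assign each TE to the region class it mostly overlaps
#'
#' Element-level attribution for ancient-TE counting: the region class with
#' maximal base overlap wins; exact ties break by the priority PROMOTER >
#' EXON > INTRON; TEs overlapping no region get `NA` and are dropped from
#' downstream counts.
#'
#' @param tes TE annotation tibble.
#' @param region_sets Output of [build_region_sets()].
#' @return Tibble `te_id`, `region_class`.
#' @export
assign_region_class <- function(tes, region_sets) {
  if (nrow(tes) == 0L) {
    return(tibble::tibble(te_id = integer(), region_class = character()))
  }
  priority <- c(PROMOTER = 1L, EXON = 2L, INTRON = 3L)
  ov <- purrr::map_dfr(REGION_CLASSES, function(rc) {
    rs <- region_sets[region_sets$region_class == rc, c("chrom", "start", "end")]
    if (nrow(rs) == 0L) return(NULL)
    rs_gr <- as_granges(rs)
    te_gr <- as_granges(tes[, c("chrom", "start", "end")])
    lv <- union(GenomeInfoDb::seqlevels(rs_gr), GenomeInfoDb::seqlevels(te_gr))
    GenomeInfoDb::seqlevels(rs_gr) <- lv
    GenomeInfoDb::seqlevels(te_gr) <- lv
    hits <- GenomicRanges::findOverlaps(te_gr, rs_gr)
    if (length(hits) == 0L) return(NULL)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      te_gr[S4Vectors::queryHits(hits)], rs_gr[S4Vectors::subjectHits(hits)]
    ))
    tibble::tibble(
      te_row = S4Vectors::queryHits(hits), region_class = rc, overlap = w
    ) %>%
      group_by(.data$te_row, .data$region_class) %>%
      summarise(overlap = sum(.data$overlap), .groups = "drop")
  })
  if (nrow(ov) == 0L) {
    return(tibble::tibble(te_id = tes$te_id, region_class = NA_character_))
  }
  best <- ov %>%
    mutate(prio = priority[.data$region_class]) %>%
    group_by(.data$te_row) %>%
    arrange(desc(.data$overlap), .data$prio, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  tibble::tibble(te_id = tes$te_id, te_row = seq_len(nrow(tes))) %>%
    left_join(best %>% select("te_row", "region_class"), by = "te_row") %>%
    select("te_id", "region_class")
}

#' Ancient-TE fractions per region class with pairwise Fisher tests
#'
#' Counts ancient vs lineage-specific TEs per region class and tests
#' promoter-vs-intron and exon-vs-intron enrichment with the two-sided
#' Fisher exact test on `[[ancient_A, lineage_A], [ancient_B, lineage_B]]`.
#'
#' @param calls Ancient calls joined with region classes: tibble holding
#'   `te_id`, `region_class`, `ancient_stringent`, `ancient_relaxed` (rows
#'   with `NA` region class are dropped).
#' @param mode `"stringent"` or `"relaxed"`.
#' @return A list with `by_region` (tibble `region_class`,
#'   `ancient_count`, `lineage_count`, `fraction`) and `tests` (tibble
#'   `comparison`, `p_value`).
#' @export
ancient_fraction_by_region <- function(calls, mode = c("stringent", "relaxed")) {
  mode <- match.arg(mode)
  flag <- if (mode == "stringent") "ancient_stringent" else "ancient_relaxed"
  calls <- calls %>% filter(!is.na(.data$region_class))
  by_region <- tibble::tibble(region_class = REGION_CLASSES) %>%
    left_join(
      calls %>%
        group_by(.data$region_class) %>%
        summarise(
          ancient_count = sum(.data[[flag]]),
          lineage_count = sum(!.data[[flag]]),
          .groups = "drop"
        ),
      by = "region_class"
    ) %>%
    mutate(
      ancient_count = as.integer(tidyr::replace_na(.data$ancient_count, 0L)),
      lineage_count = as.integer(tidyr::replace_na(.data$lineage_count, 0L)),
      n = .data$ancient_count + .data$lineage_count,
      fraction = ifelse(.data$n == 0L, NA_real_, .data$ancient_count / .data$n)
    ) %>%
    select(-"n")
  pair_p <- function(a, b) {
    ra <- by_region[by_region$region_class == a, ]
    rb <- by_region[by_region$region_class == b, ]
    if (ra$ancient_count + ra$lineage_count == 0L ||
        rb$ancient_count + rb$lineage_count == 0L) {
      return(NA_real_)
    }
    fisher_exact_two_sided(matrix(
      c(ra$ancient_count, ra$lineage_count, rb$ancient_count, rb$lineage_count),
      nrow = 2, byrow = TRUE
    ))
  }
  tests <- tibble::tibble(
    comparison = c("PROMOTER_vs_INTRON", "EXON_vs_INTRON"),
    p_value = c(pair_p("PROMOTER", "INTRON"), pair_p("EXON", "INTRON"))
  )
  list(by_region = by_region, tests = tests)
}
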