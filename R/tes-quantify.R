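# Nucleotide-level TES coverage, per-gene fractions, and Fisher exact tests
# on nucleotide contingency tables.

filter_tes <- function(tes, te_classes = NULL, include_nonte = FALSE) {
  out <- tes
  if (!include_nonte) out <- filter(out, .data$te_class != "NON_TE")
  if (!is.null(te_classes)) out <- filter(out, .data$te_class %in% te_classes)
  out
}

#' Nucleotide-level TES coverage of region sets
#'
#' Counts, per region class, the nucleotides covered by the union of all
#' (optionally class-filtered) TE annotations intersected with the regions.
#' Overlapping TE records never double count; TEs spanning a region boundary
#' contribute only their overlapping bases. `NON_TE` records (simple
#' repeats, low complexity, structural RNAs) are excluded unless
#' `include_nonte = TRUE`.
#'
#' @param region_sets Tibble `region_class`, `chrom`, `start`, `end` of
#'   disjoint intervals ([build_region_sets()]), or any interval tibble (a
#'   single pseudo-class `ALL` is then used).
#' @param tes TE annotation tibble ([read_repeatmasker_out()]).
#' @param te_classes Optional character vector restricting to given TE
#'   classes (e.g. `"SINE"`).
#' @param include_nonte Count `NON_TE` records as TES.
#' @return Tibble `region_class`, `total_nt`, `te_nt`, `fraction`. A class
#'   with `total_nt = 0` gets `fraction = NA` (undefined, distinct from 0).
#' @export
#' @examples
#' regions <- tibble::tibble(region_class = "ALL", chrom = "c", start = 0L, end = 100L)
#' tes <- tibble::tibble(te_id = 1:2, chrom = "c", start = c(10L, 20L),
#'                       end = c(30L, 50L), te_class = "SINE")
#' te_coverage(regions, tes) # union [10,50): 40 nt, fraction 0.4
te_coverage <- function(region_sets, tes, te_classes = NULL,
                        include_nonte = FALSE) {
  if (!"region_class" %in% names(region_sets)) {
    region_sets <- mutate(region_sets, region_class = "ALL")
  }
  if (nrow(region_sets) == 0L) {
    return(tibble::tibble(region_class = character(), total_nt = integer(),
                          te_nt = integer(), fraction = numeric()))
  }
  tes <- filter_tes(tes, te_classes, include_nonte)
  te_merged <- iv_reduce(tes[, c("chrom", "start", "end")])
  region_sets %>%
    group_by(.data$region_class) %>%
    group_modify(function(df, key) {
      total <- iv_total_nt(df)
      cov <- iv_total_nt(iv_intersect(df, te_merged))
      tibble::tibble(
        total_nt = total, te_nt = cov,
        fraction = if (total == 0L) NA_real_ else cov / total
      )
    }) %>%
    ungroup()
}

#' Per-TE-class coverage with score-based attribution
#'
#' Splits covered nucleotides among TE classes. With `method = "union"`
#' (default) each covered base is attributed to exactly one TE class: where
#' records of different classes overlap, the higher `sw_score` wins the
#' shared bases (tie: earlier record, i.e. lower `te_id`), mirroring
#' RepeatMasker's preference for higher-scoring matches; class totals then
#' sum to the union coverage. With `method = "record_sum"` every record's
#' overlap is summed without de-duplication.
#'
#' @inheritParams te_coverage
#' @param method `"union"` or `"record_sum"`.
#' @return Tibble `region_class`, `te_class`, `te_nt`, `fraction` (of the
#'   class total nucleotides).
#' @export
te_class_coverage <- function(region_sets, tes, method = c("union", "record_sum"),
                              include_nonte = FALSE) {
  method <- match.arg(method)
  if (!"region_class" %in% names(region_sets)) {
    region_sets <- mutate(region_sets, region_class = "ALL")
  }
  if (nrow(region_sets) == 0L) {
    return(tibble::tibble(region_class = character(), te_class = character(),
                          te_nt = integer(), fraction = numeric()))
  }
  tes <- filter_tes(tes, NULL, include_nonte)
  totals <- region_sets %>%
    group_by(.data$region_class) %>%
    summarise(total_nt = sum(.data$end - .data$start), .groups = "drop")
  per_region <- region_sets %>%
    group_by(.data$region_class) %>%
    group_modify(~ class_coverage_one(.x, tes, method)) %>%
    ungroup()
  per_region %>%
    left_join(totals, by = "region_class") %>%
    mutate(fraction = ifelse(.data$total_nt == 0L, NA_real_,
                             .data$te_nt / .data$total_nt)) %>%
    select("region_class", "te_class", "te_nt", "fraction")
}

class_coverage_one <- function(regions, tes, method) {
  classes <- sort(unique(tes$te_class))
  if (length(classes) == 0L || nrow(regions) == 0L) {
    return(tibble::tibble(te_class = classes, te_nt = integer(length(classes))))
  }
  if (method == "record_sum") {
    nt <- purrr::map_int(classes, function(cl) {
      rec <- tes[tes$te_class == cl, ]
      sum(purrr::map_int(seq_len(nrow(rec)), function(i) {
        iv_total_nt(iv_intersect(rec[i, c("chrom", "start", "end")], regions))
      }))
    })
    return(tibble::tibble(te_class = classes, te_nt = nt))
  }
  # union with attribution: disjoin all clipped fragments, give each
  # fragment to the best-scoring overlapping record
  reg_gr <- as_granges(regions)
  te_gr <- as_granges(tes[, c("chrom", "start", "end")])
  lv <- union(GenomeInfoDb::seqlevels(reg_gr), GenomeInfoDb::seqlevels(te_gr))
  GenomeInfoDb::seqlevels(reg_gr) <- lv
  GenomeInfoDb::seqlevels(te_gr) <- lv
  hits <- GenomicRanges::findOverlaps(te_gr, reg_gr)
  if (length(hits) == 0L) {
    return(tibble::tibble(te_class = classes, te_nt = integer(length(classes))))
  }
  clipped <- GenomicRanges::pintersect(
    te_gr[S4Vectors::queryHits(hits)], reg_gr[S4Vectors::subjectHits(hits)]
  )
  clip_te <- S4Vectors::queryHits(hits)
  frag <- GenomicRanges::disjoin(clipped)
  fh <- GenomicRanges::findOverlaps(frag, clipped)
  cand <- tibble::tibble(
    frag = S4Vectors::queryHits(fh),
    te_row = clip_te[S4Vectors::subjectHits(fh)]
  ) %>%
    mutate(
      score = tes$sw_score[.data$te_row],
      te_id = tes$te_id[.data$te_row]
    ) %>%
    group_by(.data$frag) %>%
    arrange(desc(.data$score), .data$te_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  assigned <- tibble::tibble(
    te_class = tes$te_class[cand$te_row],
    width = GenomicRanges::width(frag)[cand$frag]
  ) %>%
    group_by(.data$te_class) %>%
    summarise(te_nt = sum(.data$width), .groups = "drop")
  tibble::tibble(te_class = classes) %>%
    left_join(assigned, by = "te_class") %>%
    mutate(te_nt = as.integer(tidyr::replace_na(.data$te_nt, 0L)))
}

#' Per-gene TES fraction over concatenated exons
#'
#' Union TE coverage of each gene's exons divided by the mature length.
#'
#' @param genes Gene-model tibble.
#' @param tes TE annotation tibble.
#' @param include_nonte Count `NON_TE` records as TES.
#' @return Tibble `gene_id`, `mature_length`, `te_nt`, `tes_fraction`.
#' @export
tes_fraction_per_gene <- function(genes, tes, include_nonte = FALSE) {
  tes <- filter_tes(tes, NULL, include_nonte)
  te_merged <- iv_reduce(tes[, c("chrom", "start", "end")])
  ex <- gene_exons(genes)
  cov <- if (nrow(ex) == 0L || nrow(te_merged) == 0L) {
    tibble::tibble(gene_id = character(), te_nt = integer())
  } else {
    # one overlap join: TEs are merged/disjoint and exons within a gene are
    # disjoint, so summed clip widths equal the per-gene union coverage
    ex_gr <- as_granges(ex[, c("chrom", "start", "end")])
    te_gr <- as_granges(te_merged)
    lv <- union(GenomeInfoDb::seqlevels(ex_gr), GenomeInfoDb::seqlevels(te_gr))
    GenomeInfoDb::seqlevels(ex_gr) <- lv
    GenomeInfoDb::seqlevels(te_gr) <- lv
    hits <- GenomicRanges::findOverlaps(ex_gr, te_gr)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      ex_gr[S4Vectors::queryHits(hits)], te_gr[S4Vectors::subjectHits(hits)]
    ))
    tibble::tibble(gene_id = ex$gene_id[S4Vectors::queryHits(hits)], w = w) %>%
      group_by(.data$gene_id) %>%
      summarise(te_nt = sum(.data$w), .groups = "drop")
  }
  genes %>%
    select("gene_id", "mature_length") %>%
    left_join(cov, by = "gene_id") %>%
    mutate(
      te_nt = as.integer(tidyr::replace_na(.data$te_nt, 0L)),
      tes_fraction = .data$te_nt / .data$mature_length
    )
}

#' Histogram of per-gene TES fractions
#'
#' Bins `[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1]` by default (the
#' last bin is closed so a fraction of exactly 1 is counted).
#'
#' @param fractions Numeric vector of fractions in `[0, 1]`.
#' @param params [analysis_params()]; `histogram_bin` sets the bin width.
#' @return Tibble `bin_lo`, `bin_hi`, `count`, `share`.
#' @export
histogram_fractions <- function(fractions, params = analysis_params()) {
  if (any(is.na(fractions)) || any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  w <- params$histogram_bin
  breaks <- seq(0, 1, by = w)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  idx <- pmin(findInterval(fractions, breaks, left.open = FALSE), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    count = counts,
    share = if (length(fractions) == 0L) rep(NA_real_, length(counts)) else counts / length(fractions)
  )
}

#' Assemble a 2x2 nucleotide contingency table from two coverage rows
#'
#' Row per group: (nucleotides in TES, TE-free nucleotides).
#'
#' @param cov_a,cov_b Single rows of a [te_coverage()] result (or any list
#'   with `te_nt` and `total_nt`).
#' @return Integer matrix `2 x 2`.
#' @export
make_contingency <- function(cov_a, cov_b) {
  m <- matrix(
    c(cov_a$te_nt, cov_a$total_nt - cov_a$te_nt,
      cov_b$te_nt, cov_b$total_nt - cov_b$te_nt),
    nrow = 2, byrow = TRUE,
    dimnames = list(NULL, c("in_category", "not_in_category"))
  )
  storage.mode(m) <- "double"  # nucleotide counts can exceed .Machine$integer.max in sums
  if (any(m < 0)) stop("contingency counts must be non-negative")
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass definition: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' relative tolerance of 1e-7 for probability ties, as in standard
#' statistical suites). A table with a zero row or column margin returns
#' p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = groups, columns =
#'   in/not-in category), e.g. from [make_contingency()].
#' @return The two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)) # 2/252
fisher_exact_two_sided <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_   # column-1 margin
  n <- b + d    # column-2 margin
  k <- a + b    # row-1 margin
  if (m == 0 || n == 0 || k == 0 || (c_ + d) == 0) {
    message("fisher_exact_two_sided: zero margin, returning p = 1")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Genome-wide TES fraction
#'
#' Union TE-covered nucleotides over the whole genome length, overall and
#' per TE class.
#'
#' @param tes TE annotation tibble.
#' @param genome_total_nt Total genome length in nt (> 0).
#' @param include_nonte Count `NON_TE` records as TES.
#' @return Tibble `te_class`, `te_nt`, `fraction`, with a leading `ALL` row
#'   for the union over classes.
#' @export
genome_te_fraction <- function(tes, genome_total_nt, include_nonte = FALSE) {
  stopifnot(genome_total_nt > 0)
  tes <- filter_tes(tes, NULL, include_nonte)
  all_nt <- iv_total_nt(iv_reduce(tes[, c("chrom", "start", "end")]))
  per_class <- if (nrow(tes) == 0L) {
    tibble::tibble(te_class = character(), te_nt = integer())
  } else {
    tes %>%
      group_by(.data$te_class) %>%
      group_modify(~ tibble::tibble(
        te_nt = iv_total_nt(iv_reduce(.x[, c("chrom", "start", "end")]))
      )) %>%
      ungroup()
  }
  bind_rows(
    tibble::tibble(te_class = "ALL", te_nt = all_nt),
    per_class
  ) %>%
    mutate(fraction = .data$te_nt / genome_total_nt)
}
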