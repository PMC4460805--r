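# Promoter/exon/intron partitioning and lincRNA selection filters.

REGION_CLASSES <- c("PROMOTER", "EXON", "INTRON")

#' Analysis parameters
#'
#' Bundles the tunable thresholds of the analysis with their defaults: core
#' promoters are the 100 bp immediately upstream of the TSS; lincRNA
#' transcripts shorter than 200 nt are removed; an orthologous TE alignment
#' is ancient when it exceeds 100 columns with a gap-column fraction below
#' 5\% (stringent) or at most 25\% (relaxed); the TATA window of interest is
#' -35..-25 relative to the TSS.
#'
#' @param promoter_len Promoter length in nt upstream of the TSS.
#' @param min_linc_len Minimum mature (summed-exon) lincRNA length in nt;
#'   transcripts strictly shorter are removed.
#' @param ancient_min_cols Minimum alignment columns (strict `>`) for an
#'   ancient call.
#' @param ancient_max_indel_stringent Strict upper bound (`<`) on the
#'   gap-column fraction for the stringent ancient call.
#' @param ancient_max_indel_relaxed Inclusive upper bound (`<=`) for the
#'   relaxed ancient call.
#' @param tata_region Length-2 integer vector of TSS-relative offsets
#'   (inclusive) defining the TATA window.
#' @param histogram_bin Bin width for per-gene TES-fraction histograms.
#' @param tata_motif IUPAC consensus scanned for in promoters.
#' @param low_conf_sites Genes whose pooled alignment has fewer comparable
#'   sites than this are flagged low-confidence.
#' @param include_nonte If `TRUE`, `NON_TE` records (simple repeats etc.)
#'   are counted as TES; default excludes them.
#' @return A list of class `lincte_params`.
#' @export
analysis_params <- function(promoter_len = 100L,
                            min_linc_len = 200L,
                            ancient_min_cols = 100L,
                            ancient_max_indel_stringent = 0.05,
                            ancient_max_indel_relaxed = 0.25,
                            tata_region = c(-35L, -25L),
                            histogram_bin = 0.2,
                            tata_motif = "TATAWAW",
                            low_conf_sites = 50L,
                            include_nonte = FALSE) {
  stopifnot(
    promoter_len > 0L, min_linc_len > 0L, ancient_min_cols > 0L,
    ancient_max_indel_stringent > 0, ancient_max_indel_relaxed > 0,
    ancient_max_indel_stringent <= ancient_max_indel_relaxed,
    histogram_bin > 0, length(tata_region) == 2L, tata_region[1] <= tata_region[2]
  )
  structure(
    list(
      promoter_len = as.integer(promoter_len),
      min_linc_len = as.integer(min_linc_len),
      ancient_min_cols = as.integer(ancient_min_cols),
      ancient_max_indel_stringent = ancient_max_indel_stringent,
      ancient_max_indel_relaxed = ancient_max_indel_relaxed,
      tata_region = as.integer(tata_region),
      histogram_bin = histogram_bin,
      tata_motif = tata_motif,
      low_conf_sites = as.integer(low_conf_sites),
      include_nonte = include_nonte
    ),
    class = "lincte_params"
  )
}

#' Derive introns from gene models
#'
#' One intron between each adjacent exon pair: `[exon_i.end,
#' exon_(i+1).start)`. Single-exon genes contribute nothing.
#'
#' @param genes Gene-model tibble.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`, one row per
#'   intron.
#' @export
derive_introns <- function(genes) {
  empty <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer()
  )
  if (nrow(genes) == 0L) return(empty)
  multi <- genes[genes$n_exons > 1L, ]
  if (nrow(multi) == 0L) return(empty)
  purrr::pmap_dfr(
    multi[, c("gene_id", "chrom", "strand", "exon_start", "exon_end")],
    function(gene_id, chrom, strand, exon_start, exon_end) {
      n <- length(exon_start)
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = exon_end[-n], end = exon_start[-1]
      )
    }
  )
}

#' Derive strand-aware core promoters
#'
#' For `+` genes the promoter is `[TSS - promoter_len, TSS)` with the TSS at
#' the first exon start; for `-` genes it is `[span_end, span_end +
#' promoter_len)`. Promoters are clipped to the chromosome; genes whose
#' promoter is entirely off-chromosome are returned with zero width and
#' flagged.
#'
#' @param genes Gene-model tibble.
#' @param params [analysis_params()].
#' @param chrom_lens Named integer vector of chromosome lengths.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`, `clipped`,
#'   `empty`.
#' @export
derive_promoters <- function(genes, params = analysis_params(), chrom_lens) {
  if (nrow(genes) == 0L) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), clipped = logical(), empty = logical()
    ))
  }
  L <- params$promoter_len
  cl <- unname(chrom_lens[genes$chrom])
  if (any(is.na(cl))) stop("chromosome length missing for some genes")
  raw_start <- ifelse(genes$strand == "+", genes$span_start - L, genes$span_end)
  raw_end <- raw_start + L
  start <- pmax(raw_start, 0L)
  end <- pmin(raw_end, cl)
  end <- pmax(end, start)
  tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = as.integer(start), end = as.integer(end),
    clipped = start != raw_start | end != raw_end,
    empty = start == end
  )
}

#' Select intergenic lincRNA candidates
#'
#' Retains candidates whose genomic span (first exon start to last exon end)
#' overlaps no protein-coding gene span and whose mature length (sum of exon
#' lengths) is at least `min_linc_len`; input order is preserved.
#'
#' @param candidates Candidate lincRNA gene-model tibble.
#' @param pc_genes Protein-coding gene-model tibble.
#' @param params [analysis_params()].
#' @return The retained subset of `candidates`.
#' @export
select_intergenic_lincrnas <- function(candidates, pc_genes,
                                       params = analysis_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  long_enough <- candidates$mature_length >= params$min_linc_len
  if (nrow(pc_genes) == 0L) return(candidates[long_enough, ])
  cand_gr <- as_granges(tibble::tibble(
    chrom = candidates$chrom, start = candidates$span_start,
    end = candidates$span_end
  ))
  pc_gr <- as_granges(tibble::tibble(
    chrom = pc_genes$chrom, start = pc_genes$span_start, end = pc_genes$span_end
  ))
  hits <- GenomicRanges::countOverlaps(cand_gr, pc_gr)
  keep <- long_enough & hits == 0L
  n_short <- sum(!long_enough)
  n_ov <- sum(long_enough & hits > 0L)
  if (n_short + n_ov > 0L) {
    message(sprintf(
      "select_intergenic_lincrnas: removed %d short (< %d nt) and %d pc-overlapping candidates",
      n_short, params$min_linc_len, n_ov
    ))
  }
  candidates[keep, ]
}

#' Build disjoint promoter/exon/intron region sets
#'
#' Unions per-gene regions across genes, then enforces the class precedence
#' EXON > INTRON > PROMOTER so every base is counted in exactly one class
#' (a base exonic in one gene and intronic in another is exonic).
#'
#' @param genes Gene-model tibble (typically the selected lincRNA or
#'   protein-coding set).
#' @param params [analysis_params()].
#' @param chrom_lens Named integer vector of chromosome lengths.
#' @return Tibble `region_class`, `chrom`, `start`, `end` of disjoint sorted
#'   intervals covering each class exactly once.
#' @seealso [region_totals()]
#' @export
build_region_sets <- function(genes, params = analysis_params(), chrom_lens) {
  cols <- c("chrom", "start", "end")
  if (nrow(genes) == 0L) {
    return(tibble::tibble(
      region_class = character(), chrom = character(),
      start = integer(), end = integer()
    ))
  }
  exon <- iv_reduce(gene_exons(genes)[, cols])
  intron <- derive_introns(genes)[, cols]
  intron <- if (nrow(intron)) iv_setdiff(intron, exon) else intron
  prom <- derive_promoters(genes, params, chrom_lens) %>% filter(!.data$empty)
  prom <- if (nrow(prom)) {
    iv_setdiff(iv_setdiff(prom[, cols], exon), derive_introns(genes)[, cols])
  } else prom[, cols]
  bind_rows(
    mutate(exon, region_class = "EXON"),
    mutate(intron, region_class = "INTRON"),
    mutate(prom, region_class = "PROMOTER")
  ) %>%
    select("region_class", "chrom", "start", "end") %>%
    arrange(.data$region_class, .data$chrom, .data$start)
}

#' Total nucleotides per region class
#'
#' @param region_sets Output of [build_region_sets()].
#' @return Tibble `region_class`, `total_nt`.
#' @export
region_totals <- function(region_sets) {
  region_sets %>%
    group_by(.data$region_class) %>%
    summarise(total_nt = sum(.data$end - .data$start), .groups = "drop")
}

#' Region sets as BED6 lines
#'
#' @param region_sets Output of [build_region_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_bed6 <- function(region_sets, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t.",
    region_sets$chrom, region_sets$start, region_sets$end,
    region_sets$region_class
  )
  writeLines(lines, path)
  invisible(path)
}
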