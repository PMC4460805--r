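# Readers and writers for the standard formats the pipeline touches.
# Every parser converts to the internal 0-based half-open convention on the
# way in and back to the native convention on the way out.

NON_TE_FAMILIES <- c(
  "Simple_repeat", "Low_complexity", "Satellite", "rRNA", "tRNA",
  "snRNA", "srpRNA", "scRNA", "Unknown"
)

#' Map a RepeatMasker class/family string to a TE class
#'
#' The prefix before `/` in `LINE`, `SINE`, `LTR`, `DNA` maps to that class;
#' simple/low-complexity/structural-RNA families map to `NON_TE` (excluded
#' from all TES totals by default, since they are repeats but not
#' transposon-derived); anything else maps to `OTHER`.
#'
#' @param class_family Character vector of RepeatMasker class/family strings,
#'   e.g. `"SINE/Alu"`.
#' @return Character vector over `LINE`, `SINE`, `LTR`, `DNA`, `OTHER`,
#'   `NON_TE`.
#' @export
#' @examples
#' te_class_from_family(c("LINE/L1", "SINE/Alu", "Simple_repeat", "RC/Helitron"))
te_class_from_family <- function(class_family) {
  prefix <- sub("/.*$", "", class_family)
  dplyr::case_when(
    prefix %in% c("LINE", "SINE", "LTR", "DNA") ~ prefix,
    class_family %in% NON_TE_FAMILIES | prefix %in% NON_TE_FAMILIES ~ "NON_TE",
    TRUE ~ "OTHER"
  )
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the classic RepeatMasker `.out` layout: two header lines, one blank
#' line, then whitespace-delimited records. The 1-based inclusive
#' `begin`/`end` coordinates are converted to 0-based half-open; strand `C`
#' (complement) becomes `-`.
#'
#' @param path Path to a `.out` file (or a connection-readable text file).
#' @return A tibble with one row per repeat record: `te_id` (file ordinal),
#'   `chrom`, `start`, `end`, `strand`, `sw_score`, `pct_div`, `pct_del`,
#'   `pct_ins`, `repeat_name`, `class_family`, `te_class`.
#' @seealso [write_repeatmasker_out()], [te_class_from_family()]
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- if (length(lines) >= 3L) lines[-(1:3)] else character()
  body_ln <- seq_along(lines)[-seq_len(min(3L, length(lines)))]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- body_ln[keep]
  if (length(body) == 0L) {
    return(tibble::tibble(
      te_id = integer(), chrom = character(), start = integer(), end = integer(),
      strand = character(), sw_score = integer(), pct_div = numeric(),
      pct_del = numeric(), pct_ins = numeric(), repeat_name = character(),
      class_family = character(), te_class = character()
    ))
  }
  fields <- strsplit(trimws(body), "\\s+")
  short <- lengths(fields) < 11L
  if (any(short)) {
    stop(sprintf("RepeatMasker record too short at line %d", body_ln[which(short)[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:11], character(11)))
  begin <- suppressWarnings(as.integer(m[, 6]))
  end <- suppressWarnings(as.integer(m[, 7]))
  bad <- is.na(begin) | is.na(end)
  if (any(bad)) {
    stop(sprintf("non-integer coordinates at line %d", body_ln[which(bad)[1]]))
  }
  rev_coord <- begin > end
  if (any(rev_coord)) {
    stop(sprintf("begin > end at line %d", body_ln[which(rev_coord)[1]]))
  }
  tibble::tibble(
    te_id = seq_along(begin),
    chrom = m[, 5], start = begin - 1L, end = end,
    strand = ifelse(m[, 9] == "C", "-", "+"),
    sw_score = as.integer(m[, 1]),
    pct_div = as.numeric(m[, 2]), pct_del = as.numeric(m[, 3]),
    pct_ins = as.numeric(m[, 4]),
    repeat_name = m[, 10], class_family = m[, 11]
  ) %>%
    mutate(te_class = te_class_from_family(.data$class_family)) %>%
    select(
      "te_id", "chrom", "start", "end", "strand", "sw_score",
      "pct_div", "pct_del", "pct_ins", "repeat_name", "class_family", "te_class"
    )
}

#' Write TE annotations as a RepeatMasker .out file
#'
#' Inverse of [read_repeatmasker_out()]: emits the two header lines, a blank
#' line, and one whitespace-aligned record per row with 1-based inclusive
#' coordinates and strand `C` for `-`.
#'
#' @param tes TE annotation tibble as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(tes, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  rec <- sprintf(
    "%5d %5.1f %4.1f %4.1f  %s %8d %8d (0) %s  %-15s %-20s 1 %d (0) %d",
    tes$sw_score, tes$pct_div, tes$pct_del, tes$pct_ins, tes$chrom,
    tes$start + 1L, tes$end, ifelse(tes$strand == "-", "C", "+"),
    tes$repeat_name, tes$class_family, tes$end - tes$start, tes$te_id
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Reconstructs exon chains from `blockCount`/`blockSizes`/`blockStarts`.
#' BED is already 0-based half-open so no coordinate shift is applied.
#'
#' @param path Path to a 12-column BED file.
#' @return A gene-model tibble with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `span_start`, `span_end`, `mature_length`, `n_exons`, and
#'   list-columns `exon_start`, `exon_end` (integer vectors per gene).
#' @seealso [write_bed12()], [gene_exons()]
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_gene_tbl())
  fields <- strsplit(lines, "\t")
  parse_one <- function(f, ln) {
    if (length(f) < 12L) stop(sprintf("BED12 record with %d columns at line %d", length(f), ln))
    chrom_start <- as.integer(f[2])
    n <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != n || length(starts) != n) {
      stop(sprintf("blockCount %d does not match sizes/starts lists at line %d", n, ln))
    }
    ex_start <- chrom_start + starts
    ex_end <- ex_start + sizes
    if (is.unsorted(ex_start, strictly = TRUE) || any(ex_start[-1] < ex_end[-n])) {
      stop(sprintf("overlapping or unsorted blocks at line %d", ln))
    }
    tibble::tibble(
      gene_id = f[4], chrom = f[1], strand = f[6],
      span_start = ex_start[1], span_end = ex_end[n],
      mature_length = sum(sizes), n_exons = n,
      exon_start = list(ex_start), exon_end = list(ex_end)
    )
  }
  purrr::map2_dfr(fields, seq_along(fields), parse_one)
}

empty_gene_tbl <- function() {
  tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    span_start = integer(), span_end = integer(), mature_length = integer(),
    n_exons = integer(), exon_start = list(), exon_end = list()
  )
}

#' Write gene models as BED12
#'
#' @param genes Gene-model tibble as returned by [read_bed12()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  lines <- purrr::pmap_chr(genes, function(gene_id, chrom, strand, span_start,
                                           span_end, mature_length, n_exons,
                                           exon_start, exon_end, ...) {
    paste(
      chrom, span_start, span_end, gene_id, 0L, strand, span_start, span_end,
      "0,0,0", n_exons,
      paste0(paste(exon_end - exon_start, collapse = ","), ","),
      paste0(paste(exon_start - span_start, collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' Exons of gene models as a long interval tibble
#'
#' @param genes Gene-model tibble.
#' @return Tibble with one row per exon: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank`.
#' @export
gene_exons <- function(genes) {
  if (nrow(genes) == 0L) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), exon_rank = integer()
    ))
  }
  genes %>%
    select("gene_id", "chrom", "strand", "exon_start", "exon_end") %>%
    mutate(exon_rank = purrr::map(.data$exon_start, seq_along)) %>%
    tidyr::unnest(c("exon_start", "exon_end", "exon_rank")) %>%
    rename(start = "exon_start", end = "exon_end")
}

#' Read pairwise alignment blocks from a MAF file
#'
#' Uses the first two `s` lines of every `a` block (reference first, query
#' second). MAF starts are 0-based; a query `s` line on the `-` strand is
#' normalised to + strand coordinates as `srcSize - start - size`.
#'
#' @param path Path to a MAF file.
#' @return A tibble of alignment blocks: `ref_chrom`, `ref_start`,
#'   `ref_text`, `query_chrom`, `query_start`, `query_strand`, `query_text`.
#' @seealso [write_maf()]
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  a_idx <- grep("^a( |$)", lines)
  if (length(a_idx) == 0L) {
    return(tibble::tibble(
      ref_chrom = character(), ref_start = integer(), ref_text = character(),
      query_chrom = character(), query_start = integer(),
      query_strand = character(), query_text = character()
    ))
  }
  # block membership of every s line, then take the first two per block
  is_s <- grepl("^s ", lines)
  s_idx <- which(is_s)
  block_of <- findInterval(s_idx, a_idx)
  orphan <- block_of == 0L
  if (any(orphan)) stop(sprintf("s line outside any block at line %d", s_idx[which(orphan)[1]]))
  by_block <- split(s_idx, block_of)
  n_s <- vapply(by_block, length, integer(1))
  covered <- as.integer(names(by_block))
  if (length(covered) < length(a_idx) || any(n_s < 2L)) {
    bad <- setdiff(seq_along(a_idx), covered[n_s >= 2L])[1]
    stop(sprintf("MAF block at line %d has fewer than two s lines", a_idx[bad]))
  }
  first_two <- unlist(lapply(by_block, function(v) v[1:2]))
  f <- strsplit(trimws(lines[first_two]), "\\s+")
  malformed <- lengths(f) < 7L
  if (any(malformed)) {
    stop(sprintf("malformed s line at line %d", first_two[which(malformed)[1]]))
  }
  m <- t(vapply(f, function(x) x[1:7], character(7)))
  ref <- m[seq(1, nrow(m), by = 2L), , drop = FALSE]
  qry <- m[seq(2, nrow(m), by = 2L), , drop = FALSE]
  uneq <- nchar(ref[, 7]) != nchar(qry[, 7])
  if (any(uneq)) {
    stop(sprintf("unequal gapped text lengths in MAF block at line %d",
                 a_idx[which(uneq)[1]]))
  }
  q_start <- as.integer(qry[, 3])
  q_size <- as.integer(qry[, 4])
  q_src_size <- as.integer(qry[, 6])
  minus <- qry[, 5] == "-"
  q_start[minus] <- q_src_size[minus] - q_start[minus] - q_size[minus]
  tibble::tibble(
    ref_chrom = ref[, 2], ref_start = as.integer(ref[, 3]), ref_text = ref[, 7],
    query_chrom = qry[, 2], query_start = q_start,
    query_strand = qry[, 5], query_text = qry[, 7]
  )
}

#' Write pairwise alignment blocks as MAF
#'
#' @param blocks Alignment-block tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ref_size <- nchar(gsub("-", "", b$ref_text))
    qry_size <- nchar(gsub("-", "", b$query_text))
    writeLines(c(
      "",
      "a score=0",
      sprintf("s %s %d %d + %d %s", b$ref_chrom, b$ref_start, ref_size,
              b$ref_start + ref_size, b$ref_text),
      sprintf("s %s %d %d %s %d %s", b$query_chrom, b$query_start, qry_size,
              b$query_strand, b$query_start + qry_size, b$query_text)
    ), con)
  }
  invisible(path)
}

#' Read a genome FASTA into a named character vector of sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write a rectangular report table as TSV
#'
#' Numeric columns are rounded to 6 significant digits so that reports are
#' byte-stable across platforms; row order is preserved as given.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(table, path) {
  table <- table %>% mutate(across(where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
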