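#' @importFrom rlang .data
#' @import dplyr
#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open [start, end), as in BED.
# All converters to/from 1-based formats (RepeatMasker, IRanges) live at the
# boundary; everything in between assumes this single convention.

#' Build an interval tibble
#'
#' Constructs and validates a tibble of genomic intervals in the package's
#' internal convention (0-based half-open, like BED).
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, exclusive; must satisfy `start < end`.
#' @param strand Optional strand vector in `+`, `-`, `.`.
#' @return A tibble with columns `chrom`, `start`, `end` (and `strand` if
#'   supplied).
#' @export
#' @examples
#' interval_tbl("chr1", 0L, 100L)
interval_tbl <- function(chrom, start, end, strand = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be non-negative")
  if (any(start >= end)) stop("interval must satisfy start < end")
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
    out$strand <- strand
  }
  out
}

# tibble(chrom,start,end) -> GRanges (strand ignored for set arithmetic)
as_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_tbl <- function(gr) {
  if (length(gr) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Union-merge intervals into disjoint sorted form.
iv_reduce <- function(df) {
  granges_tbl(GenomicRanges::reduce(as_granges(df))) %>%
    arrange(.data$chrom, .data$start)
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  ga <- as_granges(a)
  gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  granges_tbl(GenomicRanges::intersect(ga, gb)) %>%
    arrange(.data$chrom, .data$start)
}

iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0L) return(iv_reduce(a))
  ga <- as_granges(a)
  gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  granges_tbl(GenomicRanges::setdiff(ga, gb)) %>%
    arrange(.data$chrom, .data$start)
}

iv_total_nt <- function(df) {
  if (nrow(df) == 0L) return(0L)
  sum(df$end - df$start)
}
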