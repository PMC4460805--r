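# Kimura 2-parameter distances from pairwise gapped alignments and per-gene
# evolutionary rates over concatenated exon alignments.

#' Count site patterns of a pairwise gapped alignment
#'
#' Columns with a gap or any non-ACGT character (N, IUPAC ambiguity) in
#' either row are excluded from the comparable sites. A<->G and C<->T
#' differences are transitions; every other mismatch is a transversion.
#'
#' @param ref_gapped,query_gapped Equal-length aligned texts.
#' @return A list `n` (comparable sites), `ts`, `tv`.
#' @export
#' @examples
#' count_site_patterns("AAAA", "GAAC") # n = 4, ts = 1, tv = 1
count_site_patterns <- function(ref_gapped, query_gapped) {
  if (nchar(ref_gapped) != nchar(query_gapped)) {
    stop("aligned texts must have equal length")
  }
  r <- strsplit(toupper(ref_gapped), "", fixed = TRUE)[[1]]
  q <- strsplit(toupper(query_gapped), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  ok <- r %in% acgt & q %in% acgt
  r <- r[ok]; q <- q[ok]
  diff <- r != q
  pair <- paste0(r[diff], q[diff])
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  list(n = sum(ok), ts = ts, tv = sum(diff) - ts)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` with `P = ts/n` (transition
#' proportion) and `Q = tv/n` (transversion proportion). When a logarithm
#' or square-root argument is non-positive the distance is saturated and
#' flagged undefined rather than returned as infinity.
#'
#' @param counts Site-pattern counts from [count_site_patterns()] (list
#'   with `n > 0`, `ts`, `tv`).
#' @return One-row tibble `n`, `P`, `Q`, `d`, `defined`.
#' @export
#' @examples
#' kimura_k2p(list(n = 100, ts = 10, tv = 5)) # d = 0.1701812
kimura_k2p <- function(counts) {
  if (counts$n <= 0) stop("no comparable sites: distance undefined")
  P <- counts$ts / counts$n
  Q <- counts$tv / counts$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- w1 > 0 && w2 > 0
  tibble::tibble(
    n = counts$n, P = P, Q = Q,
    d = if (defined) -0.5 * log(w1 * sqrt(w2)) else NA_real_,
    defined = defined
  )
}

#' Per-gene evolutionary rate from concatenated exon alignments
#'
#' Projects every exon of each gene through the alignment blocks, pools the
#' site-pattern counts and returns one K2P distance per gene. Genes with no
#' aligned exon bases get `NA`; genes with fewer comparable sites than
#' `params$low_conf_sites` are flagged low-confidence.
#'
#' @param genes Gene-model tibble.
#' @param blocks Alignment-block tibble ([read_maf()]).
#' @param params [analysis_params()].
#' @return Tibble `gene_id`, `n`, `P`, `Q`, `d`, `defined`,
#'   `low_confidence`.
#' @export
gene_evolutionary_rates <- function(genes, blocks, params = analysis_params()) {
  ex <- gene_exons(genes)
  # one overlap join between exons and block reference spans up front
  ex_blocks <- vector("list", nrow(ex))
  if (nrow(ex) > 0L && nrow(blocks) > 0L) {
    span <- nchar(gsub("-", "", blocks$ref_text))
    bl_gr <- as_granges(tibble::tibble(
      chrom = blocks$ref_chrom, start = blocks$ref_start,
      end = blocks$ref_start + span
    ))
    ex_gr <- as_granges(ex[, c("chrom", "start", "end")])
    lv <- union(GenomeInfoDb::seqlevels(bl_gr), GenomeInfoDb::seqlevels(ex_gr))
    GenomeInfoDb::seqlevels(bl_gr) <- lv
    GenomeInfoDb::seqlevels(ex_gr) <- lv
    hits <- GenomicRanges::findOverlaps(ex_gr, bl_gr)
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    ex_blocks[as.integer(names(sp))] <- sp
  }
  pool <- function(rows) {
    tot <- c(n = 0L, ts = 0L, tv = 0L)
    for (i in rows) {
      pr <- project_interval_core(blocks[ex_blocks[[i]], , drop = FALSE],
                                  ex$start[i], ex$end[i])
      if (is.null(pr)) next
      cnt <- count_site_patterns(pr$ref_gapped, pr$query_gapped)
      tot <- tot + c(cnt$n, cnt$ts, cnt$tv)
    }
    tot
  }
  rows_by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  per_gene <- purrr::imap_dfr(rows_by_gene, function(rows, gid) {
    tot <- pool(rows)
    res <- if (tot[["n"]] == 0L) {
      tibble::tibble(n = 0L, P = NA_real_, Q = NA_real_, d = NA_real_,
                     defined = FALSE)
    } else {
      kimura_k2p(list(n = tot[["n"]], ts = tot[["ts"]], tv = tot[["tv"]]))
    }
    mutate(res, gene_id = gid, .before = 1)
  }) %>%
    mutate(low_confidence = .data$n < params$low_conf_sites)
  genes %>%
    select("gene_id") %>%
    left_join(per_gene, by = "gene_id")
}
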