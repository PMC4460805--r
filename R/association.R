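# Expression summarisation and TES-content correlations.

#' Median log2 expression across tissues
#'
#' Median of the log2-transformed tissue intensities per gene (for an even
#' number of tissues, the mean of the two central values). Any non-positive
#' intensity is an error: no silent pseudo-count is applied.
#'
#' @param expr Tibble with `gene_id` and one numeric column per tissue.
#' @return Tibble `gene_id`, `n_tissues`, `median_log2`.
#' @export
median_log2_expression <- function(expr) {
  vals <- expr %>% select(-"gene_id")
  if (ncol(vals) < 1L) stop("at least one tissue column required")
  m <- as.matrix(vals)
  if (any(m <= 0)) stop("all tissue intensities must be positive")
  tibble::tibble(
    gene_id = expr$gene_id,
    n_tissues = ncol(m),
    median_log2 = apply(log2(m), 1, stats::median)
  )
}

#' RPKM: reads per kilobase of transcript per million mapped reads
#'
#' `10^9 * C / (N * L)` for read count `C`, library size `N` and transcript
#' length `L` in nt.
#'
#' @param counts Tibble with `gene_id`, `read_count`, `gene_length_nt`.
#' @param library_size Total mapped reads (> 0); defaults to the sum of
#'   `read_count`.
#' @return Tibble `gene_id`, `rpkm`, `log2_rpkm` (`NA` where the count is
#'   zero).
#' @export
#' @examples
#' rpkm(tibble::tibble(gene_id = "g", read_count = 1000, gene_length_nt = 2000),
#'      library_size = 1e6) # rpkm 500
rpkm <- function(counts, library_size = sum(counts$read_count)) {
  if (any(counts$gene_length_nt <= 0)) stop("gene_length_nt must be positive")
  if (library_size <= 0) stop("library_size must be positive")
  counts %>%
    mutate(
      rpkm = 1e9 * .data$read_count / (library_size * .data$gene_length_nt),
      log2_rpkm = ifelse(.data$rpkm > 0, log2(.data$rpkm), NA_real_)
    ) %>%
    select("gene_id", "rpkm", "log2_rpkm")
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Product-moment correlation with `p` from `t = r sqrt((n-2)/(1-r^2))`
#' against Student's t with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return One-row tibble `n`, `r`, `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    n = length(x), r = unname(ct$estimate), p = ct$p.value
  )
}

#' TES-content correlations over a gene feature table
#'
#' Computes the Pearson correlation of per-gene exonic TES fraction against
#' the evolutionary rate and against each supplied expression summary,
#' dropping incomplete rows pairwise.
#'
#' @param feature_table Tibble with `gene_id`, `tes_fraction`, and any of
#'   `evo_rate`, plus further numeric summary columns (e.g. `median_log2`,
#'   `log2_rpkm`).
#' @param pairings Character vector of column names to pair with
#'   `tes_fraction`; defaults to every numeric column except `tes_fraction`.
#' @return Tibble `pairing`, `n`, `r`, `p`; pairings with fewer than 3
#'   complete rows are skipped with a message.
#' @export
run_association <- function(feature_table, pairings = NULL) {
  if (is.null(pairings)) {
    pairings <- setdiff(
      names(feature_table)[purrr::map_lgl(feature_table, is.numeric)],
      c("tes_fraction")
    )
  }
  purrr::map_dfr(pairings, function(col) {
    ok <- stats::complete.cases(feature_table$tes_fraction, feature_table[[col]])
    if (sum(ok) < 3L) {
      message(sprintf("run_association: pairing '%s' skipped (%d complete rows)",
                      col, sum(ok)))
      return(NULL)
    }
    pearson_with_p(feature_table$tes_fraction[ok], feature_table[[col]][ok]) %>%
      mutate(pairing = paste0("tes_fraction_vs_", col), .before = 1)
  })
}
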