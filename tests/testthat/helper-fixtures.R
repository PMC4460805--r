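# Shared builders, independent oracles and memoised large fixtures.

# -- builders -----------------------------------------------------------------

make_gene <- function(gene_id, chrom, strand, exon_start, exon_end) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    span_start = exon_start[1], span_end = exon_end[length(exon_end)],
    mature_length = sum(exon_end - exon_start),
    n_exons = length(exon_start),
    exon_start = list(as.integer(exon_start)),
    exon_end = list(as.integer(exon_end))
  )
}

make_tes <- function(chrom, start, end, te_class = "SINE", sw_score = 1000L,
                     strand = "+") {
  n <- length(start)
  tibble::tibble(
    te_id = seq_len(n), chrom = rep_len(chrom, n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n), sw_score = rep_len(as.integer(sw_score), n),
    pct_div = 10, pct_del = 1, pct_ins = 1,
    repeat_name = "syn", class_family = rep_len(te_class, n),
    te_class = rep_len(te_class, n)
  )
}

make_block <- function(chrom, ref_start, ref_text, query_text,
                       query_start = 0L, query_strand = "+") {
  tibble::tibble(
    ref_chrom = chrom, ref_start = as.integer(ref_start), ref_text = ref_text,
    query_chrom = paste0("q_", chrom), query_start = as.integer(query_start),
    query_strand = query_strand, query_text = query_text
  )
}

# -- independent oracles ------------------------------------------------------

# per-base boolean-marking coverage: nucleotides inside `regions` covered by
# the union of `tes`
coverage_oracle <- function(regions, tes) {
  total <- 0L
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    t_ <- tes[tes$chrom == ch, ]
    L <- max(c(r$end, t_$end, 1L))
    in_region <- logical(L)
    in_te <- logical(L)
    for (i in seq_len(nrow(r))) in_region[(r$start[i] + 1L):r$end[i]] <- TRUE
    for (i in seq_len(nrow(t_))) in_te[(t_$start[i] + 1L):t_$end[i]] <- TRUE
    total <- total + sum(in_region & in_te)
  }
  total
}

# full hypergeometric enumeration of the two-sided Fisher p via choose()
fisher_enum_oracle <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b; N <- m + n
  if (m == 0 || n == 0 || k == 0 || (c_ + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(N, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# independent direct-summation Pearson r
pearson_direct <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# independent substitution simulator for K2P recovery tests
simulate_seq_pair <- function(L, P, Q) {
  bases <- c("A", "C", "G", "T")
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  ref <- sample(bases, L, replace = TRUE)
  qry <- ref
  u <- stats::runif(L)
  is_ts <- u < P
  is_tv <- !is_ts & u < P + Q
  qry[is_ts] <- ts_map[ref[is_ts]]
  if (any(is_tv)) {
    qry[is_tv] <- vapply(ref[is_tv], function(b) sample(tv_map[[b]], 1), character(1))
  }
  list(ref = paste(ref, collapse = ""), query = paste(qry, collapse = ""))
}

# -- memoised large fixtures (built once per test run) ------------------------

.lincte_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.lincte_cache$sim)) {
    .lincte_cache$sim <- simulate_genome(sim_config())
  }
  .lincte_cache$sim
}

default_blocks <- function() {
  if (is.null(.lincte_cache$blocks)) {
    .lincte_cache$blocks <- simulate_orthologs(default_sim())
  }
  .lincte_cache$blocks
}

default_run <- function() {
  if (is.null(.lincte_cache$run)) {
    dir <- file.path(tempdir(), "lincte-default-run")
    .lincte_cache$run <- suppressMessages(
      run_full(run_config(), outdir = dir)
    )
  }
  .lincte_cache$run
}

# ancient calls for the default simulated genome
default_ancient_calls <- function() {
  if (is.null(.lincte_cache$calls)) {
    sim <- default_sim()
    proj <- project_te_alignments(
      dplyr::filter(sim$tes, te_class != "NON_TE"), default_blocks()
    )
    rs <- build_region_sets(sim$linc_genes, analysis_params(), sim$chrom_lens)
    .lincte_cache$calls <- classify_ancient(sim$tes, proj) %>%
      dplyr::left_join(assign_region_class(sim$tes, rs), by = "te_id")
  }
  .lincte_cache$calls
}
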