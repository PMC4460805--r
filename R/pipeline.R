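# Full-pipeline orchestration: simulate (or read) inputs, partition,
# quantify, classify ancient TEs, estimate rates, correlate, scan TATA,
# and write one report directory.

#' Pipeline run configuration
#'
#' Either synthetic mode (a [sim_config()] inline, the default) or file
#' mode with paths to all inputs.
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL` in file mode.
#' @param inputs In file mode, a named list of paths: `genome`, `linc_bed`,
#'   `pc_bed`, `te_out`, `maf`, and optionally `expr_array`, `expr_counts`.
#' @param params An [analysis_params()].
#' @return A list of class `lincte_run_config`.
#' @export
run_config <- function(sim = sim_config(), inputs = NULL,
                       params = analysis_params()) {
  if (is.null(sim) && is.null(inputs)) {
    stop("either a sim_config or input paths must be given")
  }
  if (!is.null(inputs)) {
    needed <- c("genome", "linc_bed", "pc_bed", "te_out", "maf")
    missing <- setdiff(needed, names(inputs))
    if (length(missing)) stop("missing input paths: ", paste(missing, collapse = ", "))
  }
  structure(list(sim = sim, inputs = inputs, params = params),
            class = "lincte_run_config")
}

stage_msg <- function(fmt, ...) message(sprintf(paste0("[lincte] ", fmt), ...))

#' Run the full TES analysis pipeline
#'
#' Orchestrates the complete analysis and writes a report directory with
#' `fig1_fractions.tsv` (region-class TES fractions with pairwise Fisher
#' p-values, lincRNA and protein-coding sets, raw and Bonferroni-adjusted
#' columns), `fig34_classes.tsv` (per-TE-class fractions with SINE-vs-LINE
#' and LTR-vs-LINE Fisher p-values, plus whole-genome rows),
#' `fig2_correlation.tsv` (TES fraction vs evolutionary rate),
#' `figS2_expression.tsv` (TES fraction vs expression summaries),
#' `fig5_ancient.tsv` (ancient-TE fractions per region class, stringent
#' and relaxed), `figS1_histogram.tsv` (per-gene TES-fraction histogram),
#' `figS3_tata.tsv` (TATA positional profile), and `manifest.json`.
#'
#' In synthetic mode the simulated inputs are first written to
#' `outdir/inputs/` and then read back through the package's own parsers,
#' so a run exercises every I/O path end to end.
#'
#' @param config A [run_config()].
#' @param outdir Report directory (created if needed).
#' @return A list of class `lincte_run` holding every report table, the
#'   output paths and the manifest, invisibly.
#' @export
run_full <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "lincte_run_config"))
  t_start <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  timings <- list()
  clock <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if (!is.null(config$sim)) {
    stage_msg("simulating synthetic inputs (seed %d)", config$sim$seed)
    input_dir <- file.path(outdir, "inputs")
    clock("simulate", {
      sim <- simulate_genome(config$sim)
      blocks0 <- simulate_orthologs(sim)
      expr0 <- simulate_expression(sim)
      write_sim(sim, input_dir, blocks = blocks0, expr = expr0)
    })
    inputs <- list(
      genome = file.path(input_dir, "genome.fa"),
      linc_bed = file.path(input_dir, "linc.bed"),
      pc_bed = file.path(input_dir, "pc.bed"),
      te_out = file.path(input_dir, "te.out"),
      maf = file.path(input_dir, "ortholog.maf"),
      expr_array = file.path(input_dir, "expr_array.tsv"),
      expr_counts = file.path(input_dir, "expr_counts.tsv")
    )
    library_size <- config$sim$library_size
  } else {
    inputs <- config$inputs
    library_size <- NULL
  }

  stage_msg("reading inputs")
  genome <- clock("read_genome", read_genome_fasta(inputs$genome))
  chrom_lens <- vapply(genome, nchar, integer(1))
  linc_raw <- read_bed12(inputs$linc_bed)
  pc_genes <- read_bed12(inputs$pc_bed)
  tes <- read_repeatmasker_out(inputs$te_out)
  blocks <- clock("read_maf", read_maf(inputs$maf))
  stage_msg("inputs: %d lincRNA candidates, %d pc genes, %d TE records, %d alignment blocks",
            nrow(linc_raw), nrow(pc_genes), nrow(tes), nrow(blocks))

  linc <- select_intergenic_lincrnas(linc_raw, pc_genes, params)
  stage_msg("selected %d/%d intergenic lincRNAs (>= %d nt)",
            nrow(linc), nrow(linc_raw), params$min_linc_len)

  gene_sets <- list(lincRNA = linc, protein_coding = pc_genes)
  regions <- purrr::map(gene_sets, build_region_sets, params = params,
                        chrom_lens = chrom_lens)

  # --- region-class TES fractions + Fisher (Fig 1 style) ---
  fig1 <- clock("fig1", purrr::imap_dfr(regions, function(rs, nm) {
    cov <- te_coverage(rs, tes, include_nonte = params$include_nonte)
    pair_p <- function(a, b) {
      fisher_exact_two_sided(make_contingency(
        cov[cov$region_class == a, ], cov[cov$region_class == b, ]
      ))
    }
    cov %>% mutate(
      gene_set = nm,
      fisher_p_vs_intron = purrr::map_dbl(.data$region_class, function(rc) {
        if (rc == "INTRON") NA_real_ else pair_p(rc, "INTRON")
      }),
      fisher_p_vs_intron_bonferroni = pmin(.data$fisher_p_vs_intron * 2, 1)
    )
  }) %>% select("gene_set", dplyr::everything()))

  # --- per-TE-class fractions + Fisher (Figs 3-4 style) ---
  fig34 <- clock("fig34", {
    per_set <- purrr::imap_dfr(regions, function(rs, nm) {
      covc <- te_class_coverage(rs, tes, include_nonte = params$include_nonte)
      tot <- region_totals(rs)
      cov_all <- te_coverage(rs, tes, include_nonte = params$include_nonte)
      covc %>%
        left_join(tot, by = "region_class") %>%
        left_join(cov_all %>% select("region_class", all_te_nt = "te_nt"),
                  by = "region_class") %>%
        mutate(gene_set = nm)
    })
    genome_rows <- genome_te_fraction(tes, sum(chrom_lens),
                                      include_nonte = params$include_nonte) %>%
      filter(.data$te_class != "ALL") %>%
      mutate(
        gene_set = "whole_genome", region_class = "GENOME",
        total_nt = sum(chrom_lens),
        all_te_nt = genome_te_fraction(tes, sum(chrom_lens))$te_nt[1]
      )
    class_p <- function(df, cls_a, cls_b) {
      te_free <- df$total_nt[1] - df$all_te_nt[1]
      a_nt <- df$te_nt[df$te_class == cls_a]
      b_nt <- df$te_nt[df$te_class == cls_b]
      if (length(a_nt) == 0L || length(b_nt) == 0L) return(NA_real_)
      fisher_exact_two_sided(matrix(c(a_nt, te_free, b_nt, te_free),
                                    nrow = 2, byrow = TRUE))
    }
    bind_rows(per_set, genome_rows) %>%
      group_by(.data$gene_set, .data$region_class) %>%
      group_modify(function(df, key) {
        df %>% mutate(
          fisher_p_sine_vs_line = class_p(df, "SINE", "LINE"),
          fisher_p_ltr_vs_line = class_p(df, "LTR", "LINE")
        )
      }) %>%
      ungroup() %>%
      select("gene_set", "region_class", "te_class", "te_nt", "fraction",
             "fisher_p_sine_vs_line", "fisher_p_ltr_vs_line")
  })

  # --- per-gene TES fractions + histogram (Fig S1 style) ---
  per_gene <- tes_fraction_per_gene(linc, tes, include_nonte = params$include_nonte)
  figs1 <- histogram_fractions(per_gene$tes_fraction, params)

  # --- evolutionary rates + correlation (Fig 2 style) ---
  stage_msg("estimating per-gene evolutionary rates")
  rates <- clock("rates", gene_evolutionary_rates(linc, blocks, params))
  feature_tbl <- per_gene %>%
    select("gene_id", "tes_fraction") %>%
    left_join(rates %>% select("gene_id", evo_rate = "d"), by = "gene_id")
  fig2 <- run_association(feature_tbl, pairings = "evo_rate")

  # --- expression correlations (Fig S2 style) ---
  figs2 <- clock("expression", {
    expr_tbl <- feature_tbl %>% select("gene_id", "tes_fraction")
    have_any <- FALSE
    if (!is.null(inputs$expr_array) && file.exists(inputs$expr_array)) {
      arr <- readr::read_tsv(inputs$expr_array, show_col_types = FALSE,
                             progress = FALSE)
      expr_tbl <- expr_tbl %>%
        left_join(median_log2_expression(arr), by = "gene_id") %>%
        select(-dplyr::any_of("n_tissues"))
      have_any <- TRUE
    }
    if (!is.null(inputs$expr_counts) && file.exists(inputs$expr_counts)) {
      cnt <- readr::read_tsv(inputs$expr_counts, show_col_types = FALSE,
                             progress = FALSE)
      ls <- if (is.null(library_size)) sum(cnt$read_count) else library_size
      expr_tbl <- expr_tbl %>%
        left_join(rpkm(cnt, library_size = ls) %>% select("gene_id", "log2_rpkm"),
                  by = "gene_id")
      have_any <- TRUE
    }
    if (have_any) run_association(
      expr_tbl, pairings = intersect(c("median_log2", "log2_rpkm"), names(expr_tbl))
    ) else tibble::tibble(pairing = character(), n = integer(),
                          r = numeric(), p = numeric())
  })

  # --- ancient TEs (Fig 5 style) ---
  stage_msg("classifying ancient TEs")
  fig5 <- clock("ancient", {
    proj <- project_te_alignments(filter_tes(tes, NULL, params$include_nonte), blocks)
    calls <- classify_ancient(tes, proj, params) %>%
      left_join(assign_region_class(tes, regions$lincRNA), by = "te_id")
    purrr::map_dfr(c("stringent", "relaxed"), function(md) {
      res <- ancient_fraction_by_region(calls, mode = md)
      res$by_region %>%
        mutate(mode = md) %>%
        left_join(
          tibble::tibble(
            region_class = c("PROMOTER", "EXON"),
            fisher_p_vs_intron = res$tests$p_value
          ),
          by = "region_class"
        )
    }) %>% select("mode", dplyr::everything())
  })

  # --- TATA scan (Fig S3 style) ---
  figs3 <- clock("tata", {
    promoters <- extract_promoter_seqs(linc, genome, params)
    profile <- tata_positional_profile(promoters, motif = params$tata_motif)
    profile
  })
  tata_frac <- {
    promoters <- extract_promoter_seqs(linc, genome, params)
    tata_containing_fraction(promoters, params, motif = params$tata_motif)
  }

  out_paths <- c(
    fig1_fractions = file.path(outdir, "fig1_fractions.tsv"),
    fig34_classes = file.path(outdir, "fig34_classes.tsv"),
    fig2_correlation = file.path(outdir, "fig2_correlation.tsv"),
    figS2_expression = file.path(outdir, "figS2_expression.tsv"),
    fig5_ancient = file.path(outdir, "fig5_ancient.tsv"),
    figS1_histogram = file.path(outdir, "figS1_histogram.tsv"),
    figS3_tata = file.path(outdir, "figS3_tata.tsv")
  )
  write_report_tsv(fig1, out_paths["fig1_fractions"])
  write_report_tsv(fig34, out_paths["fig34_classes"])
  write_report_tsv(fig2, out_paths["fig2_correlation"])
  write_report_tsv(figs2, out_paths["figS2_expression"])
  write_report_tsv(fig5, out_paths["fig5_ancient"])
  write_report_tsv(figs1, out_paths["figS1_histogram"])
  write_report_tsv(figs3, out_paths["figS3_tata"])

  manifest <- list(
    tool = "lincte",
    version = as.character(utils::packageVersion("lincte")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    mode = if (!is.null(config$sim)) "synthetic" else "files",
    params = unclass(params),
    sim_config = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    input_digests = {
      d <- tools::md5sum(unlist(inputs))
      as.list(stats::setNames(unname(d), basename(names(d))))
    },
    output_digests = {
      d <- tools::md5sum(unname(out_paths))
      as.list(stats::setNames(unname(d), basename(names(d))))
    },
    stage_rows = list(
      linc_candidates = nrow(linc_raw), linc_selected = nrow(linc),
      pc_genes = nrow(pc_genes), te_records = nrow(tes),
      alignment_blocks = nrow(blocks)
    ),
    stage_runtimes_sec = timings,
    total_runtime_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  res <- structure(
    list(
      fig1_fractions = fig1, fig34_classes = fig34, fig2_correlation = fig2,
      figS2_expression = figs2, fig5_ancient = fig5, figS1_histogram = figs1,
      figS3_tata = figs3, tata_containing_fraction = tata_frac,
      per_gene = per_gene, rates = rates,
      outdir = outdir, paths = out_paths, manifest = manifest
    ),
    class = "lincte_run"
  )
  stage_msg("done in %.1f s", manifest$total_runtime_sec)
  invisible(res)
}

#' @export
print.lincte_run <- function(x, ...) {
  cat("<lincte_run>\n")
  cat("  report directory:", x$outdir, "\n")
  cat("  lincRNAs analysed:", nrow(x$per_gene), "\n")
  cat("  region TES fractions (lincRNA):\n")
  f <- x$fig1_fractions %>% filter(.data$gene_set == "lincRNA")
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %-9s %.4f\n", f$region_class[i], f$fraction[i]))
  }
  invisible(x)
}

#' Tidy the region-class TES fractions of a pipeline run
#'
#' @param x A `lincte_run`.
#' @param ... Unused.
#' @return The `fig1_fractions` tibble (gene set, region class, total and
#'   TE-covered nucleotides, fraction, Fisher p-values).
#' @importFrom generics tidy
#' @export
tidy.lincte_run <- function(x, ...) x$fig1_fractions

#' One-row summary of a pipeline run
#'
#' @param x A `lincte_run`.
#' @param ... Unused.
#' @return One-row tibble: gene counts, TES gene share below 20\%, TATA
#'   fraction, rate correlation, runtime.
#' @importFrom generics glance
#' @export
glance.lincte_run <- function(x, ...) {
  tibble::tibble(
    n_linc = nrow(x$per_gene),
    share_below_20pct_tes = x$figS1_histogram$share[1],
    tata_containing_fraction = x$tata_containing_fraction,
    r_tes_vs_rate = if (nrow(x$fig2_correlation)) x$fig2_correlation$r[1] else NA_real_,
    runtime_sec = x$manifest$total_runtime_sec
  )
}
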