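# Seeded synthetic-genome generator with planted truth: gene models with
# promoter/exon/intron compartments carrying target per-class TE densities,
# ortholog alignments with controlled substitution and gap rates splitting
# TEs into ancient and lineage-specific populations, and expression values
# with a controlled correlation to per-gene TES content.

TE_CLASSES <- c("LINE", "SINE", "LTR", "DNA")
CLASS_FAMILY <- c(
  LINE = "LINE/L1", SINE = "SINE/Alu", LTR = "LTR/ERVK",
  DNA = "DNA/hAT-Charlie", NON_TE = "Simple_repeat"
)
REPEAT_NAME <- c(
  LINE = "L1_syn", SINE = "Alu_syn", LTR = "ERVK_syn",
  DNA = "Charlie_syn", NON_TE = "(TA)n"
)

#' Simulation configuration
#'
#' All planted truths of the synthetic genome in one seeded configuration.
#' Defaults define the package's reference study conditions: a ~7 Mb
#' three-chromosome genome with 1000 lincRNA and 200 protein-coding genes,
#' per-compartment TES densities ordered intron (0.35) > exon (0.20) >
#' promoter (0.10) with SINE enrichment and LINE depletion in exons and
#' promoters, ancient-TE probabilities ordered promoter (0.5) > exon
#' (0.35) > intron (0.15), ortholog divergence at transition/transversion
#' site probabilities (0.10, 0.05), ~2\% gap columns inside ancient TEs,
#' a TES-vs-expression correlation of -0.25, and a TATA box planted at
#' offset -30 in 25\% of promoters.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_chroms,chrom_len Number and length (nt) of chromosomes.
#' @param n_linc_genes,n_pc_genes Gene counts per set.
#' @param exons_per_gene,exon_len,intron_len,intergenic_gap Uniform ranges
#'   (length-2 integer vectors) for gene architecture.
#' @param promoter_len Promoter length in nt.
#' @param te_density Named list over compartments `PROMOTER`, `EXON`,
#'   `INTRON`, `INTERGENIC`; each a named numeric vector of target coverage
#'   fractions per TE class (may include `NON_TE` for simple repeats).
#' @param te_len Uniform range of planted TE lengths (nt).
#' @param promoter_te_cover Uniform range of in-promoter bases covered by a
#'   promoter TE (the TE body extends upstream into intergenic sequence so
#'   that it can exceed 100 aligned columns).
#' @param te_gap Uniform range of spacing between planted TEs.
#' @param ancient_prob Named probabilities (per compartment) that a planted
#'   TE is ancient, i.e. retained in the ortholog alignment.
#' @param ortho_P,ortho_Q Per-site transition/transversion substitution
#'   probabilities of the simulated ortholog.
#' @param rate_rho Target correlation between per-gene TES fraction and the
#'   per-gene substitution-rate multiplier (0 = uniform rates).
#' @param ancient_gap_frac Per-site probability of a gap column inside
#'   ancient TEs.
#' @param expr_rho Target population correlation between per-gene TES
#'   fraction and the latent log2 expression.
#' @param n_tissues,noise_sd Microarray mode: number of tissues and the
#'   per-tissue log2 noise standard deviation.
#' @param library_size RNA-seq mode total mapped reads.
#' @param tata_frac,tata_offset Fraction of promoters with a planted
#'   `TATAAAA` and its TSS-relative start offset.
#' @return A list of class `lincte_sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chroms = 3L,
                       chrom_len = 2400000L,
                       n_linc_genes = 1000L,
                       n_pc_genes = 200L,
                       exons_per_gene = c(2L, 5L),
                       exon_len = c(150L, 600L),
                       intron_len = c(400L, 1500L),
                       intergenic_gap = c(1000L, 2500L),
                       promoter_len = 100L,
                       te_density = list(
                         PROMOTER = c(LINE = 0.01, SINE = 0.06, LTR = 0.02, DNA = 0.01),
                         EXON = c(LINE = 0.04, SINE = 0.10, LTR = 0.04, DNA = 0.02),
                         INTRON = c(LINE = 0.18, SINE = 0.08, LTR = 0.06, DNA = 0.03),
                         INTERGENIC = c(LINE = 0.20, SINE = 0.10, LTR = 0.07,
                                        DNA = 0.03, NON_TE = 0.02)
                       ),
                       te_len = c(120L, 350L),
                       promoter_te_cover = c(30L, 70L),
                       te_gap = c(20L, 150L),
                       ancient_prob = c(PROMOTER = 0.5, EXON = 0.35,
                                        INTRON = 0.15, INTERGENIC = 0.2),
                       ortho_P = 0.10,
                       ortho_Q = 0.05,
                       rate_rho = 0.3,
                       ancient_gap_frac = 0.02,
                       expr_rho = -0.25,
                       n_tissues = 20L,
                       noise_sd = 0.5,
                       library_size = 2e7,
                       tata_frac = 0.25,
                       tata_offset = -30L) {
  cfg <- as.list(environment())
  dens_sums <- vapply(te_density, sum, numeric(1))
  if (any(dens_sums > 0.95)) stop("per-compartment TE densities must sum to <= 0.95")
  if (any(unlist(te_density) < 0)) stop("TE densities must be non-negative")
  if (abs(expr_rho) >= 1 || abs(rate_rho) >= 1) stop("|rho| must be < 1")
  if (ortho_P + ortho_Q >= 1) stop("ortho_P + ortho_Q must be < 1")
  if (any(ancient_prob < 0 | ancient_prob > 1)) stop("ancient_prob must be in [0,1]")
  structure(cfg, class = "lincte_sim_config")
}

runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Pack TEs left-to-right into shuffled intervals until per-class deficits
# (in covered nt) are met; deterministic given the RNG state.
pack_tes <- function(intervals, deficits, len_range, gap_range,
                     nonte_len_range = c(30L, 80L)) {
  out <- list()
  if (nrow(intervals) == 0L || all(deficits <= 0)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), te_class = character()))
  }
  ord <- sample.int(nrow(intervals))
  for (i in ord) {
    if (all(deficits <= 0)) break
    pos <- intervals$start[i]
    iv_end <- intervals$end[i]
    repeat {
      open <- names(deficits)[deficits > 0]
      if (length(open) == 0L) break
      pos <- pos + runif_int(1L, gap_range)
      cls <- if (length(open) == 1L) open else {
        sample(open, 1L, prob = deficits[open])
      }
      lr <- if (cls == "NON_TE") nonte_len_range else len_range
      len <- runif_int(1L, lr)
      # clamp the final TE of a class to its remaining deficit so planted
      # coverage overshoots the target by less than one minimum TE length
      if (deficits[cls] < len) len <- max(lr[1], ceiling(deficits[cls]))
      if (pos + len > iv_end) break
      out[[length(out) + 1L]] <- list(
        chrom = intervals$chrom[i], start = pos, end = pos + len, te_class = cls
      )
      deficits[cls] <- deficits[cls] - len
      pos <- pos + len
    }
  }
  if (any(deficits > 2L * mean(len_range))) {
    stop("infeasible TE densities: compartment cannot hold the target coverage")
  }
  purrr::map_dfr(out, tibble::as_tibble)
}

place_genes <- function(cfg) {
  n_total <- cfg$n_linc_genes + cfg$n_pc_genes
  set_labels <- sample(c(
    rep("linc", cfg$n_linc_genes), rep("pc", cfg$n_pc_genes)
  ))
  margin <- 500L + cfg$promoter_len + cfg$te_len[2]
  genes <- vector("list", n_total)
  gi <- 0L
  for (ch in seq_len(cfg$n_chroms)) {
    pos <- margin + runif_int(1L, cfg$intergenic_gap)
    chrom <- paste0("chr", ch)
    while (gi < n_total) {
      n_ex <- runif_int(1L, cfg$exons_per_gene)
      ex_lens <- runif_int(n_ex, cfg$exon_len)
      in_lens <- if (n_ex > 1L) runif_int(n_ex - 1L, cfg$intron_len) else integer()
      span <- sum(ex_lens) + sum(in_lens)
      if (pos + span > cfg$chrom_len - margin) break
      starts <- pos + cumsum(c(0L, ex_lens[-n_ex] + in_lens))
      gi <- gi + 1L
      genes[[gi]] <- tibble::tibble(
        gene_id = sprintf("%s_%04d", set_labels[gi], gi),
        gene_set = set_labels[gi],
        chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        span_start = pos, span_end = pos + span,
        mature_length = sum(ex_lens), n_exons = n_ex,
        exon_start = list(starts), exon_end = list(starts + ex_lens)
      )
      pos <- pos + span + runif_int(1L, cfg$intergenic_gap)
    }
  }
  if (gi < n_total) {
    stop("infeasible configuration: genome too small to place all genes")
  }
  bind_rows(genes)
}

# One TE per selected promoter, covering `cover` upstream-most promoter
# bases and extending further upstream into intergenic sequence.
pack_promoter_tes <- function(prom, deficits, cfg) {
  out <- list()
  ord <- sample.int(nrow(prom))
  for (i in ord) {
    open <- names(deficits)[deficits > 0]
    if (length(open) == 0L) break
    cover <- runif_int(1L, cfg$promoter_te_cover)
    len <- runif_int(1L, cfg$te_len)
    cls <- if (length(open) == 1L) open else sample(open, 1L, prob = deficits[open])
    if (deficits[cls] < cover) {
      cover <- max(cfg$promoter_te_cover[1], ceiling(deficits[cls]))
    }
    if (prom$strand[i] == "+") {
      te_end <- prom$start[i] + cover
      te_start <- te_end - len
    } else {
      te_start <- prom$end[i] - cover
      te_end <- te_start + len
    }
    if (te_start < 0L) next
    out[[length(out) + 1L]] <- list(
      chrom = prom$chrom[i], start = te_start, end = te_end,
      te_class = cls, covered = cover
    )
    deficits[cls] <- deficits[cls] - cover
  }
  if (any(deficits > 2L * mean(cfg$promoter_te_cover))) {
    stop("infeasible promoter TE density")
  }
  purrr::map_dfr(out, tibble::as_tibble)
}

#' Simulate a genome with planted TE annotations and gene models
#'
#' Places lincRNA and protein-coding genes without span overlap, then
#' plants non-overlapping TEs per (gene set, compartment) until each target
#' coverage is reached (within one TE length), draws each TE's ancient
#' flag from the compartment's `ancient_prob`, and writes a `TATAAAA` at
#' the configured offset into a fraction of promoters. Identical
#' configurations (including the seed) yield identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lincte_sim`: `genome` (named sequences),
#'   `linc_genes`, `pc_genes` (gene-model tibbles), `tes` (TE annotation
#'   tibble), `truth` (per-TE tibble with `te_id`, `compartment`,
#'   `gene_set`, `te_class`, `ancient`, `covered_nt`), `chrom_lens`, `cfg`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  params <- analysis_params(promoter_len = cfg$promoter_len)
  chrom_lens <- stats::setNames(
    rep(cfg$chrom_len, cfg$n_chroms), paste0("chr", seq_len(cfg$n_chroms))
  )
  genes <- place_genes(cfg)
  proms <- derive_promoters(genes, params, chrom_lens) %>%
    mutate(gene_set = genes$gene_set)

  planted <- list()
  for (gs in c("linc", "pc")) {
    sub <- genes[genes$gene_set == gs, ]
    exon_iv <- gene_exons(sub)[, c("chrom", "start", "end")]
    intron_iv <- derive_introns(sub)[, c("chrom", "start", "end")]
    for (comp in c("EXON", "INTRON")) {
      iv <- if (comp == "EXON") exon_iv else intron_iv
      dens <- cfg$te_density[[comp]]
      deficits <- dens * iv_total_nt(iv)
      tes <- pack_tes(iv, deficits, cfg$te_len, cfg$te_gap)
      if (nrow(tes)) {
        planted[[length(planted) + 1L]] <- tes %>%
          mutate(compartment = comp, gene_set = gs,
                 covered = .data$end - .data$start)
      }
    }
    pr <- proms %>% filter(.data$gene_set == gs, !.data$empty)
    dens <- cfg$te_density$PROMOTER
    deficits <- dens * sum(pr$end - pr$start)
    ptes <- pack_promoter_tes(pr, deficits, cfg)
    if (nrow(ptes)) {
      planted[[length(planted) + 1L]] <- ptes %>%
        mutate(compartment = "PROMOTER", gene_set = gs)
    }
  }

  # intergenic: complement of gene spans, promoters and promoter-TE bodies
  planted_iv <- if (length(planted)) {
    bind_rows(planted) %>% select("chrom", "start", "end")
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  }
  occupied <- bind_rows(
    tibble::tibble(chrom = genes$chrom, start = genes$span_start, end = genes$span_end),
    proms %>% filter(!.data$empty) %>% select("chrom", "start", "end"),
    planted_iv
  )
  chrom_iv <- tibble::tibble(
    chrom = names(chrom_lens), start = 0L, end = unname(chrom_lens)
  )
  free_iv <- iv_setdiff(chrom_iv, occupied)
  dens <- cfg$te_density$INTERGENIC
  deficits <- dens * iv_total_nt(free_iv)
  itas <- pack_tes(free_iv, deficits, cfg$te_len, cfg$te_gap)
  if (nrow(itas)) {
    planted[[length(planted) + 1L]] <- itas %>%
      mutate(compartment = "INTERGENIC", gene_set = NA_character_,
             covered = .data$end - .data$start)
  }

  tes_all <- if (length(planted)) bind_rows(planted) else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   te_class = character(), compartment = character(),
                   gene_set = character(), covered = integer())
  }
  tes_all <- tes_all %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(te_id = seq_len(dplyr::n()))
  is_te <- tes_all$te_class != "NON_TE"
  ancient <- rep(NA, nrow(tes_all))
  ancient[is_te] <- stats::runif(sum(is_te)) <
    cfg$ancient_prob[tes_all$compartment[is_te]]

  tes <- tes_all %>%
    mutate(
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
      sw_score = sample(300:5000, dplyr::n(), replace = TRUE),
      pct_div = round(stats::runif(dplyr::n(), 1, 35), 1),
      pct_del = round(stats::runif(dplyr::n(), 0, 8), 1),
      pct_ins = round(stats::runif(dplyr::n(), 0, 8), 1),
      repeat_name = unname(REPEAT_NAME[.data$te_class]),
      class_family = unname(CLASS_FAMILY[.data$te_class])
    ) %>%
    select("te_id", "chrom", "start", "end", "strand", "sw_score",
           "pct_div", "pct_del", "pct_ins", "repeat_name", "class_family",
           "te_class")
  truth <- tes_all %>%
    mutate(ancient = ancient) %>%
    select("te_id", "chrom", "start", "end", "te_class", "compartment",
           "gene_set", "ancient", covered_nt = "covered")

  genome <- stats::setNames(
    vapply(chrom_lens, rand_seq, character(1)), names(chrom_lens)
  )
  genome <- plant_tata(genome, genes, cfg)

  structure(
    list(
      genome = genome,
      linc_genes = genes %>% filter(.data$gene_set == "linc") %>% select(-"gene_set"),
      pc_genes = genes %>% filter(.data$gene_set == "pc") %>% select(-"gene_set"),
      tes = tes, truth = truth, chrom_lens = chrom_lens, cfg = cfg
    ),
    class = "lincte_sim"
  )
}

plant_tata <- function(genome, genes, cfg) {
  motif <- "TATAAAA"
  k <- nchar(motif)
  rc_motif <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  pick <- stats::runif(nrow(genes)) < cfg$tata_frac
  for (i in which(pick)) {
    ch <- genes$chrom[i]
    o <- cfg$tata_offset
    if (genes$strand[i] == "+") {
      s0 <- genes$span_start[i] + o  # 0-based genomic start of motif
      substr(genome[[ch]], s0 + 1L, s0 + k) <- motif
    } else {
      s0 <- genes$span_end[i] - o - k
      substr(genome[[ch]], s0 + 1L, s0 + k) <- rc_motif
    }
  }
  genome
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

mutate_chars <- function(chars, p_ts, p_tv) {
  u <- stats::runif(length(chars))
  out <- chars
  ts <- u < p_ts
  tv <- !ts & u < p_ts + p_tv
  out[ts] <- TRANSITION[chars[ts]]
  if (any(tv)) {
    pick <- stats::runif(sum(tv)) < 0.5
    tv_targets <- t(vapply(chars[tv], function(b) TRANSVERSION[[b]], character(2)))
    out[tv] <- ifelse(pick, tv_targets[, 1], tv_targets[, 2])
  }
  out
}

#' Simulate ortholog alignment blocks for a synthetic genome
#'
#' The query species is derived by per-site substitution (transition with
#' probability `ortho_P`, transversion with `ortho_Q`); gap columns are
#' planted independently per site at `ancient_gap_frac` inside ancient TEs.
#' Alignment blocks cover all exons and all ancient TE bodies; lineage-
#' specific TE intervals are excluded, so they project to nothing. With
#' `rate_rho != 0`, each gene's exonic substitution rate is modulated by a
#' factor correlated with its planted TES fraction.
#'
#' @param sim A [simulate_genome()] result.
#' @return Alignment-block tibble in the [read_maf()] schema.
#' @export
simulate_orthologs <- function(sim) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 1L)
  all_genes <- bind_rows(
    sim$linc_genes %>% mutate(gene_set = "linc"),
    sim$pc_genes %>% mutate(gene_set = "pc")
  )
  exon_iv <- gene_exons(all_genes)[, c("gene_id", "chrom", "start", "end")]
  ancient_iv <- sim$truth %>%
    filter(!is.na(.data$ancient), .data$ancient) %>%
    select("chrom", "start", "end")
  lineage_iv <- sim$truth %>%
    filter(is.na(.data$ancient) | !.data$ancient) %>%
    select("chrom", "start", "end")
  alignable <- iv_setdiff(
    bind_rows(exon_iv[, c("chrom", "start", "end")], ancient_iv),
    lineage_iv
  )
  gap_iv <- iv_reduce(ancient_iv)

  # per-gene substitution-rate multipliers tied to planted TES fraction
  t0 <- cfg$ortho_P + cfg$ortho_Q
  if (cfg$rate_rho != 0) {
    f <- tes_fraction_per_gene(all_genes, sim$tes)$tes_fraction
    z <- if (stats::sd(f) > 0) as.numeric(scale(f)) else rep(0, length(f))
    lat <- cfg$rate_rho * z +
      sqrt(1 - cfg$rate_rho^2) * stats::rnorm(length(z))
    mult <- pmin(pmax(1 + 0.6 * lat, 0.2), 2.2)
  } else {
    mult <- rep(1, nrow(all_genes))
  }
  names(mult) <- all_genes$gene_id

  # one overlap join up front instead of per-block filtering
  al_gr <- as_granges(alignable)
  overlap_rows <- function(iv) {
    if (nrow(iv) == 0L) return(vector("list", nrow(alignable)))
    gr <- as_granges(iv[, c("chrom", "start", "end")])
    lv <- union(GenomeInfoDb::seqlevels(al_gr), GenomeInfoDb::seqlevels(gr))
    a <- al_gr; GenomeInfoDb::seqlevels(a) <- lv
    GenomeInfoDb::seqlevels(gr) <- lv
    h <- GenomicRanges::findOverlaps(a, gr)
    out <- vector("list", nrow(alignable))
    sp <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    out[as.integer(names(sp))] <- sp
    out
  }
  ex_hits <- overlap_rows(exon_iv)
  gap_hits <- overlap_rows(gap_iv)

  n_b <- nrow(alignable)
  ref_texts <- character(n_b)
  qry_texts <- character(n_b)
  q_starts <- integer(n_b)
  al_chrom <- alignable$chrom
  al_start <- alignable$start
  al_end <- alignable$end
  q_offset <- stats::setNames(rep(0L, length(sim$chrom_lens)), names(sim$chrom_lens))
  for (i in seq_len(n_b)) {
    ch <- al_chrom[i]
    s <- al_start[i]
    e <- al_end[i]
    ref <- strsplit(substring(sim$genome[[ch]], s + 1L, e), "", fixed = TRUE)[[1]]
    L <- length(ref)
    # per-position rates: background, scaled inside each gene's exons
    p_ts <- rep(cfg$ortho_P, L)
    p_tv <- rep(cfg$ortho_Q, L)
    ex_here <- exon_iv[ex_hits[[i]], ]
    for (j in seq_len(nrow(ex_here))) {
      m <- mult[ex_here$gene_id[j]]
      lo <- max(ex_here$start[j], s) - s + 1L
      hi <- min(ex_here$end[j], e) - s
      p_ts[lo:hi] <- cfg$ortho_P * m
      p_tv[lo:hi] <- cfg$ortho_Q * m
    }
    qry <- mutate_chars(ref, p_ts, p_tv)
    gaps_here <- gap_iv[gap_hits[[i]], ]
    for (j in seq_len(nrow(gaps_here))) {
      lo <- max(gaps_here$start[j], s) - s + 1L
      hi <- min(gaps_here$end[j], e) - s
      idx <- lo:hi
      drop <- idx[stats::runif(length(idx)) < cfg$ancient_gap_frac]
      qry[drop] <- "-"
    }
    q_len <- sum(qry != "-")
    ref_texts[i] <- paste(ref, collapse = "")
    qry_texts[i] <- paste(qry, collapse = "")
    q_starts[i] <- q_offset[[ch]]
    q_offset[[ch]] <- q_offset[[ch]] + q_len
  }
  tibble::tibble(
    ref_chrom = al_chrom, ref_start = al_start, ref_text = ref_texts,
    query_chrom = paste0("q_", al_chrom), query_start = q_starts,
    query_strand = "+", query_text = qry_texts
  )
}

#' Simulate expression with a controlled TES-content correlation
#'
#' Gene-level latent log2 expression is constructed so its population
#' correlation with the per-gene TES fraction equals `expr_rho`; microarray
#' tissue intensities add per-tissue log-normal noise, and RNA-seq counts
#' are Poisson draws whose expected RPKM follows the latent expression.
#'
#' @param sim A [simulate_genome()] result.
#' @return A list with `array` (tibble `gene_id`, `tissue_1` ...),
#'   `counts` (tibble `gene_id`, `read_count`, `gene_length_nt`) and
#'   `library_size`.
#' @export
simulate_expression <- function(sim) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 2L)
  genes <- sim$linc_genes
  f <- tes_fraction_per_gene(genes, sim$tes)$tes_fraction
  n <- length(f)
  z <- if (stats::sd(f) > 0) as.numeric(scale(f)) else rep(0, n)
  rho <- cfg$expr_rho
  latent <- 8 + 2 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  tissue <- matrix(
    2^(latent + stats::rnorm(n * cfg$n_tissues, sd = cfg$noise_sd)),
    nrow = n
  )
  colnames(tissue) <- paste0("tissue_", seq_len(cfg$n_tissues))
  array_tbl <- bind_cols(tibble::tibble(gene_id = genes$gene_id),
                         tibble::as_tibble(tissue))
  lambda <- 1e-9 * cfg$library_size * genes$mature_length * 2^latent
  counts_tbl <- tibble::tibble(
    gene_id = genes$gene_id,
    read_count = stats::rpois(n, lambda),
    gene_length_nt = genes$mature_length
  )
  list(array = array_tbl, counts = counts_tbl, library_size = cfg$library_size)
}

#' Simulate a gene feature table with planted correlations
#'
#' Direct table-level generator for testing the association stage: TES
#' fractions drawn from a right-skewed Beta distribution, an evolutionary
#' rate and an expression summary built so their population correlations
#' with the TES fraction equal `rho_rate` and `rho_expr`.
#'
#' @param n Number of genes.
#' @param rho_rate,rho_expr Planted population correlations.
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `tes_fraction`, `evo_rate`,
#'   `expression_summary`.
#' @export
simulate_feature_table <- function(n, rho_rate = 0.3, rho_expr = -0.25,
                                   seed = 1L) {
  stopifnot(abs(rho_rate) < 1, abs(rho_expr) < 1, n >= 3)
  set.seed(seed)
  x <- stats::rbeta(n, 0.8, 3)
  z <- as.numeric(scale(x))
  y1 <- rho_rate * z + sqrt(1 - rho_rate^2) * stats::rnorm(n)
  y2 <- rho_expr * z + sqrt(1 - rho_expr^2) * stats::rnorm(n)
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    tes_fraction = x,
    evo_rate = pmax(0.17 + 0.04 * y1, 1e-4),
    expression_summary = 8 + 2 * y2
  )
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits `genome.fa`, `linc.bed`, `pc.bed`, `te.out`, `ortholog.maf`,
#' `expr_array.tsv`, `expr_counts.tsv` and `truth.tsv` under `dir`.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @param blocks Optional precomputed [simulate_orthologs()] result.
#' @param expr Optional precomputed [simulate_expression()] result.
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, dir, blocks = NULL, expr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(blocks)) blocks <- simulate_orthologs(sim)
  if (is.null(expr)) expr <- simulate_expression(sim)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    linc = file.path(dir, "linc.bed"),
    pc = file.path(dir, "pc.bed"),
    te = file.path(dir, "te.out"),
    maf = file.path(dir, "ortholog.maf"),
    expr_array = file.path(dir, "expr_array.tsv"),
    expr_counts = file.path(dir, "expr_counts.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(sim$genome, paths["genome"])
  write_bed12(sim$linc_genes, paths["linc"])
  write_bed12(sim$pc_genes, paths["pc"])
  write_repeatmasker_out(sim$tes, paths["te"])
  write_maf(blocks, paths["maf"])
  write_report_tsv(expr$array, paths["expr_array"])
  write_report_tsv(expr$counts, paths["expr_counts"])
  write_report_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
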