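pad_promoter <- function(motif_at, motif = "TATAAAA", L = 100L, fill = "G") {
  # motif_at: TSS-relative start offset of the motif
  i <- motif_at + L + 1L  # 1-based position in the sequence
  paste0(strrep(fill, i - 1L), motif, strrep(fill, L - (i - 1L) - nchar(motif)))
}

test_that("IUPAC matching reports TSS-relative start offsets", {
  seq31 <- pad_promoter(-31L)
  expect_equal(find_tata(seq31), -31L)
  expect_equal(find_tata(strrep("G", 100)), integer())
  # TATATAT matches TATAWAW with W = T
  expect_equal(find_tata(paste0(strrep("G", 50), "TATATAT", strrep("G", 43))), -50L)
  # N never matches
  expect_equal(find_tata(sub("TATAAAA", "TATANAA", seq31)), integer())
  # overlapping matches are all reported (10-mer at positions 81-90)
  expect_equal(find_tata(paste0(strrep("C", 80), "TATATATATA", strrep("C", 10))),
               c(-20L, -18L))
  expect_error(find_tata("ACGT", motif = "TAZA"), "unknown IUPAC")
})

test_that("positional profile counts promoters with a match per offset", {
  proms <- tibble::tibble(
    gene_id = c("a", "b"), sequence = rep(pad_promoter(-30L), 2), length = 100L
  )
  prof <- tata_positional_profile(proms)
  expect_equal(prof$offset, seq(-100L, -7L))
  expect_equal(prof$frequency[prof$offset == -30L], 1)
  expect_equal(sum(prof$frequency), 1)
  expect_error(tata_positional_profile(proms[0, ]), "empty")
})

test_that("a motif planted in 25% of promoters is recovered at its offset", {
  set.seed(51)
  n <- 1000L
  rand_prom <- function() paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  seqs <- vapply(seq_len(n), function(i) rand_prom(), character(1))
  planted <- stats::runif(n) < 0.25
  seqs[planted] <- vapply(which(planted), function(i) {
    s <- seqs[i]
    paste0(substr(s, 1, 70), "TATAAAA", substr(s, 78, 100))  # starts at -30
  }, character(1))
  proms <- tibble::tibble(gene_id = as.character(seq_len(n)),
                          sequence = seqs, length = 100L)
  prof <- tata_positional_profile(proms)
  f30 <- prof$frequency[prof$offset == -30L]
  se3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(f30 - 0.25), se3 + 0.01)  # small background on top of the plant
  frac <- tata_containing_fraction(proms)
  expect_lt(abs(frac - 0.25), se3 + 0.02)
  # uniform random promoters: no offset dominates
  rand_only <- tibble::tibble(gene_id = as.character(1:1000),
                              sequence = vapply(1:1000, function(i) rand_prom(),
                                                character(1)),
                              length = 100L)
  prof0 <- tata_positional_profile(rand_only)
  expect_lt(max(prof0$frequency), 5 * max(mean(prof0$frequency), 1 / 1000))
})

test_that("the containing fraction only counts matches inside the window", {
  none <- tibble::tibble(gene_id = "a", sequence = strrep("C", 100), length = 100L)
  expect_equal(tata_containing_fraction(none), 0)
  at40 <- tibble::tibble(gene_id = "a", sequence = pad_promoter(-40L), length = 100L)
  expect_equal(tata_containing_fraction(at40), 0)
  at30 <- tibble::tibble(gene_id = "a", sequence = pad_promoter(-30L), length = 100L)
  expect_equal(tata_containing_fraction(at30), 1)
  # boundaries are inclusive
  expect_equal(tata_containing_fraction(
    tibble::tibble(gene_id = "a", sequence = pad_promoter(-35L), length = 100L)), 1)
  expect_equal(tata_containing_fraction(
    tibble::tibble(gene_id = "a", sequence = pad_promoter(-25L), length = 100L)), 1)
  expect_equal(tata_containing_fraction(
    tibble::tibble(gene_id = "a", sequence = pad_promoter(-24L), length = 100L)), 0)
})

test_that("minus-strand promoters are the reverse complement of the + slice", {
  set.seed(52)
  genome <- stats::setNames(
    paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""), "chr1"
  )
  path <- withr::local_tempfile()
  write_genome_fasta(genome, path)
  genome2 <- read_genome_fasta(path)
  expect_equal(genome2, genome)
  gplus <- make_gene("p", "chr1", "+", 1000L, 1400L)
  gminus <- make_gene("m", "chr1", "-", 2000L, 2400L)
  proms <- extract_promoter_seqs(dplyr::bind_rows(gplus, gminus), genome2)
  expect_equal(proms$sequence[1], unname(substring(genome, 901, 1000)))
  plus_slice <- unname(substring(genome, 2401, 2500))
  expect_equal(
    proms$sequence[2],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_slice)))
  )
  # planted TATA in the simulator surfaces on both strands at the same offset
  sim <- simulate_genome(sim_config(seed = 13, n_chroms = 1,
                                    chrom_len = 200000L, n_linc_genes = 20L,
                                    n_pc_genes = 5L, tata_frac = 1))
  pr <- extract_promoter_seqs(sim$linc_genes, sim$genome)
  hits <- purrr::map(pr$sequence, find_tata)
  expect_true(all(purrr::map_lgl(hits, ~ -30L %in% .x)))
})
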