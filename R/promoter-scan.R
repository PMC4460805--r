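# TATA-box scanning of core promoter sequences and the positional
# match-frequency profile.

# IUPAC nucleotide codes -> regex character classes over A,C,G,T only.
# N in the subject sequence therefore never matches any pattern position.
IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_REGEX))
  if (length(bad)) stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  paste0(IUPAC_REGEX[chars], collapse = "")
}

#' Extract promoter sequences on the gene's sense strand
#'
#' Returns each gene's promoter written 5' to 3' on the sense strand, so
#' that the last base sits at TSS-relative offset -1. Promoters on `-`
#' genes are the reverse complement of the genomic + strand slice.
#'
#' @param genes Gene-model tibble.
#' @param genome Named character vector of chromosome sequences
#'   ([read_genome_fasta()]).
#' @param params [analysis_params()].
#' @return Tibble `gene_id`, `sequence`, `length`; genes with clipped
#'   (shorter) or empty promoters are dropped with a message so the
#'   profile stays length-uniform.
#' @export
extract_promoter_seqs <- function(genes, genome, params = analysis_params()) {
  chrom_lens <- vapply(genome, nchar, integer(1))
  prom <- derive_promoters(genes, params, chrom_lens)
  full <- prom %>% filter(!.data$empty, .data$end - .data$start == params$promoter_len)
  n_drop <- nrow(prom) - nrow(full)
  if (n_drop > 0L) {
    message(sprintf("extract_promoter_seqs: dropped %d clipped/empty promoters", n_drop))
  }
  seqs <- substring(genome[full$chrom], full$start + 1L, full$end)
  minus <- full$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus]))
    )
  }
  tibble::tibble(
    gene_id = full$gene_id,
    sequence = unname(seqs),
    length = full$end - full$start
  )
}

#' Find IUPAC motif matches in a promoter sequence
#'
#' Scans every window of the motif length; offsets are reported relative to
#' the TSS with the promoter's last base at -1, and refer to the 5'-most
#' base of the match. Overlapping matches are all reported; `N` in the
#' sequence never matches.
#'
#' @param sequence Promoter sequence (sense strand, TSS at the right end).
#' @param motif IUPAC pattern, default the TATA consensus `TATAWAW`.
#' @return Integer vector of match start offsets (possibly empty).
#' @export
#' @examples
#' find_tata(paste0(strrep("G", 60), "TATAAAA", strrep("G", 33))) # -40
find_tata <- function(sequence, motif = "TATAWAW") {
  rx <- iupac_to_regex(motif)
  L <- nchar(sequence)
  k <- nchar(motif)
  # lookahead so overlapping matches are all found
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m) - L - 1L
}

#' Positional TATA match-frequency profile over promoters
#'
#' For each TSS-relative offset, the share of promoters with a motif match
#' starting there.
#'
#' @param promoters Output of [extract_promoter_seqs()] (uniform length).
#' @param motif IUPAC pattern.
#' @return Tibble `offset`, `n_matching`, `frequency`, covering offsets
#'   `-L .. -(motif length)`.
#' @export
tata_positional_profile <- function(promoters, motif = "TATAWAW") {
  if (nrow(promoters) == 0L) stop("empty promoter list")
  L <- unique(promoters$length)
  if (length(L) != 1L) stop("promoters must have uniform length")
  k <- nchar(motif)
  offsets <- seq(-L, -k)
  hits <- purrr::map(promoters$sequence, find_tata, motif = motif)
  counts <- table(factor(unlist(purrr::map(hits, unique)), levels = offsets))
  tibble::tibble(
    offset = offsets,
    n_matching = as.integer(counts),
    frequency = as.integer(counts) / nrow(promoters)
  )
}

#' Fraction of TATA-containing promoters
#'
#' Share of promoters with at least one motif match whose start offset lies
#' inside the TSS-relative window `params$tata_region` (inclusive).
#'
#' @param promoters Output of [extract_promoter_seqs()].
#' @param params [analysis_params()]; `tata_region` defaults to -35..-25.
#' @param motif IUPAC pattern.
#' @return A single fraction in `[0, 1]`.
#' @export
tata_containing_fraction <- function(promoters, params = analysis_params(),
                                     motif = "TATAWAW") {
  if (nrow(promoters) == 0L) return(NA_real_)
  lo <- params$tata_region[1]
  hi <- params$tata_region[2]
  has <- purrr::map_lgl(promoters$sequence, function(s) {
    off <- find_tata(s, motif)
    any(off >= lo & off <= hi)
  })
  mean(has)
}
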