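## Fixture builders shared across test files. Everything is generated in
## code; no stored data.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

## a small genome: 2 chromosomes, 10 domains each, 1 Mb domains
tinyConfig <- function(...) {
  args <- modifyList(list(chromosome_lengths = c(chr1 = 10e6, chr2 = 10e6),
                          n_domains_per_chrom = 10L,
                          resolution = 500000,
                          n_snps = 12L, n_loci = 8L, shared_fraction = 0.2,
                          n_eqtls = 200L, sequencing_depth = 10, seed = 42L),
                     list(...))
  do.call(syntheticConfig, args)
}

## a single-chromosome contact map from explicit triplets
toyMap <- function(n_bins, triplets, kind = "raw", resolution = 40000,
                   chrom = "chr1") {
  bins <- binTable(setNames(n_bins * resolution, chrom), resolution)
  ContactMap(bins, triplets, kind = kind)
}

## a bead model from explicit coordinates; one chromosome per bead by
## default so inter-chromosomal masking keeps everything
manualModel <- function(coords, chrom = NULL, nucleusRadius = 10) {
  n <- nrow(coords)
  if (is.null(chrom)) chrom <- paste0("chr", seq_len(n))
  lens <- tapply(rep(2e6, n), chrom, sum)
  beads <- GRanges(chrom, IRanges(start = 1, end = 1e6))
  beads$domain_id <- paste0("d", seq_len(n))
  beads$haplotype <- "A"
  beads$bead_id <- paste0("d", seq_len(n), "_A")
  BeadModel(beads, coords, nucleusRadius = nucleusRadius)
}

## brute-force O(n*m) overlap counter (1-based closed GRanges semantics)
bruteOverlapCount <- function(query, subject) {
  vapply(seq_along(query), function(i) {
    sum(as.character(seqnames(subject)) == as.character(seqnames(query))[i] &
          start(subject) <= end(query)[i] &
          end(subject) >= start(query)[i])
  }, numeric(1))
}
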