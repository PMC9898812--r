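# shared internal helpers

# round half away from zero (printed-style percentages; R's round() is
# banker's rounding, which would turn e.g. 0.75 into 0.8 vs 0.85 into 0.8)
half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

round_to_unit <- function(x, unit) floor(x / unit + 0.5) * unit

# sample a single integer from an inclusive range given as c(lo, hi) or a scalar
sample_range <- function(rng, n = 1L) {
  if (length(rng) == 1L) rng <- c(rng, rng)
  vals <- seq.int(rng[[1]], rng[[2]])
  if (length(vals) == 1L) rep(as.integer(vals), n) else as.integer(sample(vals, n, replace = TRUE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

comp_chr <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

nonstop_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
}

# substring of a chromosome string in 0-based half-open coordinates
seq_at <- function(chrom_seq, start0, end0) substr(chrom_seq, start0 + 1L, end0)

base_at <- function(chrom_seq, pos0) substr(chrom_seq, pos0 + 1L, pos0 + 1L)

`%||%` <- rlang::`%||%`
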