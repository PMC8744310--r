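# Small constructors shared across test files.

mk_tx <- function(id, exons, strand = "+", gene = "g1", chrom = "chr1",
                  cds = NULL, source = "reference") {
  transcript_model(id, gene, chrom, strand,
                   matrix(exons, ncol = 2, byrow = TRUE),
                   cds = cds, source = source)
}

# a three-exon reference gene on +: exons [100,200) [300,400) [500,600)
ref3 <- function(strand = "+", cds = NULL) {
  annotation(list(mk_tx("r1", c(100, 200, 300, 400, 500, 600),
                        strand = strand, cds = cds)))
}

# deterministic tiny simulated world reused by several files
small_cfg <- function(seed = 11, ...) {
  args <- list(seed = seed, n_genes = 40, chrom_length = 4e5, n_chroms = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# codon-safe chromosome: repeating GCA has no stop codon in any frame
gca_chrom <- function(n_codons) strrep("GCA", n_codons)

plant <- function(seq, pos1, replacement) {
  # overwrite bases of a chromosome string at 1-based pos1
  paste0(substr(seq, 1, pos1 - 1), replacement,
         substr(seq, pos1 + nchar(replacement), nchar(seq)))
}
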