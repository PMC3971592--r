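# shared toy fixtures, built in code

code13 <- genetic_code(13)

# 30-bp toy genome with two 10-bp genes at [0,10) and [20,30)
toy_two_gene_genome <- function() {
  seqs <- paste(rep(c("ATGAAATTAG", "GGGGGCCCCC", "ATGTTTAAAG"), 1), collapse = "")
  mito_genome("toy1", seqs, data.frame(
    name = c("g1", "g2"), category = c("tRNA", "tRNA"),
    start = c(0L, 20L), end = c(10L, 30L), strand = "+",
    reading_offset = 0L, incomplete_stop = "none"), species = "Toy sp")
}

# small annotated genome with one PCG (with stop), one tRNA, one rRNA
toy_pcg_genome <- function(incomplete = "none") {
  cds <- "ATGAAACCTTGG"               # M K P W under code 13
  stop <- switch(incomplete, none = "TAA", T = "T", TA = "TA")
  trna <- strrep("ACGT", 5)
  rrna <- strrep("GATC", 8)
  ncr <- "TTTTTTTTTAC"
  seqs <- paste0(cds, stop, trna, ncr, rrna)
  n1 <- nchar(cds) + nchar(stop)
  mito_genome("toy2", seqs, data.frame(
    name = c("cox1", "trnA", "rrnS"),
    category = c("PCG", "tRNA", "rRNA"),
    start = c(0L, n1, n1 + 20L + nchar(ncr)),
    end = c(n1, n1 + 20L, n1 + 20L + nchar(ncr) + 32L),
    strand = "+", reading_offset = 0L,
    incomplete_stop = c(incomplete, "none", "none")), species = "Toy sp")
}

fixture_structures <- function() {
  read_cloverleaf(system.file("extdata", "trna_structures_synthetic.txt",
                              package = "mitorate"))
}
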