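test_that("NCR features are synthesized for every inter-gene gap", {
  g <- add_ncr_features(toy_two_gene_genome())
  ncr <- g$features[g$features$category == "NCR", ]
  expect_equal(nrow(ncr), 1L)
  expect_equal(ncr$start, 10L)
  expect_equal(ncr$end, 20L)

  # a single gene spanning the whole sequence leaves no gaps
  g2 <- mito_genome("toy", strrep("ACGT", 10), data.frame(
    name = "rrnL", category = "rRNA", start = 0L, end = 40L, strand = "+",
    reading_offset = 0L, incomplete_stop = "none"))
  expect_equal(sum(add_ncr_features(g2)$features$category == "NCR"), 0L)
})

test_that("GenBank round trip reproduces sequence and features", {
  g <- add_ncr_features(toy_pcg_genome())
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path, add_ncrs = FALSE)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$length, g$length)
  expect_equal(g2$features[c("name", "category", "start", "end", "strand",
                             "reading_offset", "incomplete_stop")],
               g$features[c("name", "category", "start", "end", "strand",
                            "reading_offset", "incomplete_stop")])
})

test_that("GenBank round trip preserves incomplete stops and wrapped features", {
  g <- toy_pcg_genome(incomplete = "TA")
  # add an origin-wrapping tRNA
  g$features <- rbind(g$features, data.frame(
    name = "trnW", category = "tRNA", start = g$length - 4L, end = 4L,
    strand = "-", reading_offset = 0L, incomplete_stop = "none"))
  g <- mito_genome(g$accession, g$sequence, g$features, species = g$species)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path, add_ncrs = FALSE)
  w <- g2$features[g2$features$name == "trnW", ]
  expect_equal(c(w$start, w$end, w$strand), c(g$length - 4L, 4L, "-"))
  p <- g2$features[g2$features$name == "cox1", ]
  expect_equal(p$incomplete_stop, "TA")
})

test_that("malformed GenBank input gives informative errors", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  x 10 bp", "FEATURES", "     CDS   3..x", "ORIGIN",
               "1 acgtacgtac", "//"), path)
  expect_error(read_genbank(path), "malformed")
  writeLines(c("LOCUS  x 10 bp", "FEATURES", "     CDS   1..9"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("extract_regions removes stops, classifies sites and counts NCR", {
  g <- add_ncr_features(toy_pcg_genome())
  p <- extract_regions(g, code13)
  expect_equal(p$pcg_codons, "ATGAAACCTTGG")   # terminal TAA removed
  expect_equal(nchar(p$pcg_codons) %% 3, 0)
  expect_equal(p$site_class, rep(c("P1", "P2", "P3"), 4))
  expect_equal(p$ncr_total_len,
               g$length - sum(with(g$features[g$features$category != "NCR", ],
                                   end - start)))
  # incomplete stop is trimmed before the codon-multiple check
  gi <- add_ncr_features(toy_pcg_genome(incomplete = "TA"))
  expect_equal(extract_regions(gi, code13)$pcg_codons, "ATGAAACCTTGG")
})

test_that("extract_regions is independent of feature order and errors on bad frames", {
  g <- add_ncr_features(toy_pcg_genome())
  g_shuffled <- mito_genome(g$accession, g$sequence,
                            g$features[rev(seq_len(nrow(g$features))), ],
                            species = g$species)
  expect_identical(extract_regions(g, code13)[c("pcg_codons", "trna_concat",
                                                "rrna_concat", "ncr_total_len")],
                   extract_regions(g_shuffled, code13)[c("pcg_codons", "trna_concat",
                                                         "rrna_concat", "ncr_total_len")])
  bad <- g
  bad$features$end[bad$features$name == "cox1"] <- 14L  # length 14, not codon multiple
  expect_error(extract_regions(mito_genome("x", g$sequence, bad$features), code13),
               "codon multiple")
})

test_that("feature lengths tile simulated genomes exactly", {
  gp <- simulate_genome_pair(sim_config(seed = 5, n_pcg_codons = 200,
                                        n_trnas = 6, rrna_len = 300, ncr_len = 60))
  for (g in list(gp$a, gp$b)) {
    f <- g$features
    expect_equal(sum(f$end - f$start), g$length)
  }
})

test_that("protein-guided back-translation expands and masks columns", {
  # identical CDSs, gapless alignment: all columns unmasked
  aln <- build_codon_alignment("ATGAAATTT", "ATGAAATTT", code = code13)
  expect_false(any(aln$mask))
  expect_equal(aln$codons_a, aln$codons_b)

  # "MA-F" vs "MAGF": 4 codon columns, column 3 masked by the gap
  cds_a <- "ATGGCTTTT"      # M A F
  cds_b <- "ATGGCTGGATTT"   # M A G F
  aln <- build_codon_alignment(cds_a, cds_b, c("MA-F", "MAGF"), code13)
  expect_length(aln$codons_a, 4L)
  expect_equal(aln$codons_a[3], "---")
  expect_equal(which(aln$mask), 3L)

  # trailing incomplete stop is excluded before back-translation
  aln2 <- build_codon_alignment("ATGGCTTTTTA", "ATGGCTTTT", c("MAF", "MAF"), code13)
  expect_length(aln2$codons_a, 3L)

  # translation mismatch is reported at the first disagreeing residue
  expect_error(build_codon_alignment(cds_a, cds_b, c("MA-F", "MACF"), code13),
               "mismatch")
})
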