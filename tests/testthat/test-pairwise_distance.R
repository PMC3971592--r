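test_that("p-distance counts differences under pairwise deletion", {
  expect_equal(p_distance("ACGTACGTAC", "ACGTACGTAC")$p_distance, 0)

  # 10 columns, 2 mismatches, 1 gap column -> 2/9
  a <- "ACGTACGTAC"
  b <- "ACCTAC-TAA"
  rec <- p_distance(a, b)
  expect_equal(rec$n_sites, 9L)
  expect_equal(rec$n_diff, 2L)
  expect_equal(rec$p_distance, 2 / 9)

  # case-insensitive; ambiguity codes excluded
  expect_equal(p_distance("acgt", "ACGT")$p_distance, 0)
  expect_equal(p_distance("ACGN", "ACTT")$n_sites, 3L)

  expect_error(p_distance("----", "ACGT"), "zero comparable")
})

test_that("p-distance is symmetric and zero on self", {
  set.seed(42)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE), collapse = "")
    if (!any(strsplit(a, "")[[1]] != "-" & strsplit(b, "")[[1]] != "-")) next
    expect_equal(p_distance(a, b)$p_distance, p_distance(b, a)$p_distance)
  }
  expect_equal(p_distance("ACGT", "ACGT")$p_distance, 0)
})

test_that("p-distance matches a brute-force column count on random fixtures", {
  set.seed(7)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "T", "-", "N"), 200, TRUE,
                prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04))
    b <- sample(c("A", "C", "G", "T", "-", "N"), 200, TRUE,
                prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04))
    n <- d <- 0L
    for (k in 1:200) {  # independent brute-force oracle
      if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
        n <- n + 1L
        if (a[k] != b[k]) d <- d + 1L
      }
    }
    rec <- p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(rec$n_sites, n)
    expect_equal(rec$n_diff, d)
  }
})

test_that("region table splits codon positions and P12+P3 recovers PCG", {
  gp <- simulate_genome_pair(sim_config(seed = 9, n_pcg_codons = 400,
                                        n_trnas = 4, rrna_len = 200,
                                        ncr_len = 40, regime = "intermediate"))
  pa <- extract_regions(gp$a, code13); pb <- extract_regions(gp$b, code13)
  d <- region_distance_table(pa, pb)
  d <- split(d, d$region)
  expect_equal(d$P12$n_sites + d$P3$n_sites, d$PCG$n_sites)
  expect_equal(d$P12$n_diff + d$P3$n_diff, d$PCG$n_diff)
})

test_that("substitutions only at third positions yield P12 = 0 and P3 > 0", {
  set.seed(3)
  n <- 60L
  cods <- sample(c("CCA", "GGA", "TCA", "ACA"), n, TRUE)
  a <- paste(cods, collapse = "")
  # mutate every third position to a synonymous alternative (NNA -> NNG)
  bv <- strsplit(a, "")[[1]]
  bv[seq(3, 3 * n, 3)] <- "G"
  b <- paste(bv, collapse = "")
  cls <- rep(c("P1", "P2", "P3"), n)
  p12 <- p_distance(a, b, mask = cls == "P3")
  p3 <- p_distance(a, b, mask = cls != "P3")
  expect_equal(p12$p_distance, 0)
  expect_gt(p3$p_distance, 0)
})

test_that("an intraspecies simulated pair evolves fastest at P3", {
  gp <- simulate_genome_pair(sim_config(seed = 21, n_pcg_codons = 1200,
                                        n_trnas = 8, rrna_len = 600,
                                        ncr_len = 100, regime = "intermediate"))
  pa <- extract_regions(gp$a, code13); pb <- extract_regions(gp$b, code13)
  d <- region_distance_table(pa, pb)
  expect_gt(d$p_distance[d$region == "P3"], d$p_distance[d$region == "P12"])
  expect_gt(d$p_distance[d$region == "P3"], d$p_distance[d$region == "tRNA"])
})
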