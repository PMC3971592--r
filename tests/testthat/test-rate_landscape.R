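toy_meta <- function(dn) {
  # pair ids of the form "<speciesA>|<speciesB>"; intraspecies pairs use a
  # shared species label encoded in the name
  data.frame(pair_id = names(dn),
             species_a = sub("\\|.*", "", names(dn)),
             species_b = sub(".*\\|", "", names(dn)),
             pair_level = ifelse(grepl("^intra", names(dn)),
                                 "intraspecies", "congeneric"),
             stringsAsFactors = FALSE)
}

test_that("the dN gap report does exact min/max bookkeeping", {
  dn <- c("intraA|intraA2" = 0.01, "congX|congY" = 0.50)
  meta <- toy_meta(dn)
  meta$species_a <- c("A", "X"); meta$species_b <- c("A", "Y")
  g <- dn_gap_report(dn, meta)
  expect_equal(g$delta, 0.49)
  expect_equal(g$max_intra_pair, "intraA|intraA2")
  expect_equal(g$min_congeneric_pair, "congX|congY")
  expect_false(g$no_gap)

  # excluding the lowest congeneric pair raises the delta
  dn2 <- c(dn, "congX|congZ" = 0.80)
  meta2 <- toy_meta(dn2)
  g2 <- dn_gap_report(dn2, meta2, exclude = "congX|congY")
  expect_gt(g2$delta, g$delta)
  expect_equal(g2$delta, 0.79)

  # overlap is reported as a negative delta, never clamped
  dn3 <- c("intraA|intraA2" = 0.2, "congX|congY" = 0.1)
  g3 <- dn_gap_report(dn3, toy_meta(dn3))
  expect_equal(g3$delta, -0.1)
  expect_true(g3$no_gap)

  expect_error(dn_gap_report(dn, meta, exclude = "congX|congY"), "congeneric")
})

test_that("intermediate-pair flags isolate the in-between regime", {
  mkmeta <- function(pairs, species_a, species_b) {
    data.frame(pair_id = pairs, species_a = species_a, species_b = species_b,
               pair_level = ifelse(species_a == species_b, "intraspecies",
                                   "congeneric"), stringsAsFactors = FALSE)
  }
  # one intraspecies pair at 10x the others and 1/10 of the congeneric floor
  dn <- c(p1 = 0.001, p2 = 0.0012, p3 = 0.01, c1 = 0.1, c2 = 0.3)
  meta <- mkmeta(names(dn), c("A", "B", "C", "A", "B"),
                 c("A", "B", "C", "D", "E"))
  fl <- flag_intermediate_pairs(dn, meta)
  expect_equal(fl$pair_id[fl$flagged], "p3")

  # all intraspecies dN equal -> nothing flagged
  dn2 <- c(p1 = 0.01, p2 = 0.01, p3 = 0.01, c1 = 0.5)
  meta2 <- mkmeta(names(dn2), c("A", "B", "C", "A"), c("A", "B", "C", "D"))
  expect_false(any(flag_intermediate_pairs(dn2, meta2)$flagged))

  # invariant to pair order and to uniform rescaling
  fl_scaled <- flag_intermediate_pairs(dn * 37, meta)
  expect_equal(fl$flagged, fl_scaled$flagged)
  perm <- c(4, 2, 5, 1, 3)
  fl_perm <- flag_intermediate_pairs(dn[perm], meta[perm, ])
  expect_equal(fl_perm[order(fl_perm$pair_id), "flagged"],
               fl[order(fl$pair_id), "flagged"])
})

test_that("the grouped-distance gap separates labelled clades", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 0.10
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 0.10
  g <- grouped_distance_gap(d, c("g1", "g1", "g2", "g2"))
  expect_equal(g$gap, 0.10)
  expect_equal(g$max_within, 0)

  expect_error(grouped_distance_gap(d, rep("g1", 4)), "2 groups")
  # singleton groups contribute no within distances
  g2 <- grouped_distance_gap(d[1:3, 1:3], c("g1", "g1", "g2"))
  expect_equal(g2$min_between, 0.10)
})

test_that("grouped gap is positive on a simulated barcode-style cohort", {
  coh <- simulate_cohort(n_species = 3, n_samples_per_species = 2,
                         intermediate_sample = FALSE,
                         cfg = sim_config(seed = 15, n_pcg_codons = 300,
                                          n_trnas = 4, rrna_len = 200,
                                          ncr_len = 40))
  parts <- lapply(coh$genomes, extract_regions)
  n <- length(parts)
  d <- matrix(0, n, n, dimnames = list(names(parts), names(parts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- p_distance(parts[[i]]$pcg_codons,
                                     parts[[j]]$pcg_codons)$p_distance
  }
  g <- grouped_distance_gap(d, coh$metadata$species)
  expect_gt(g$gap, 0)
})

test_that("saturation points pair observed with inferred divergence", {
  fits <- list(
    intra = structure(list(dS = 0.4, dN = 0.02, t12 = 0.015, t3 = 0.5),
                      class = "codon_fit"),
    cong = structure(list(dS = 3.5, dN = 0.2, t12 = 0.12, t3 = 2.8),
                     class = "codon_fit"),
    zero = structure(list(dS = 0, dN = 0, t12 = 0, t3 = 0),
                     class = "codon_fit"))
  distances <- rbind(
    data.frame(pair_id = "intra", region = c("P12", "P3"),
               p_distance = c(0.012, 0.3), n_sites = 100, n_diff = 1),
    data.frame(pair_id = "cong", region = c("P12", "P3"),
               p_distance = c(0.1, 0.6), n_sites = 100, n_diff = 10),
    data.frame(pair_id = "zero", region = c("P12", "P3"),
               p_distance = c(0, 0), n_sites = 100, n_diff = 0))
  ng <- list(intra = list(pS = 0.3, pN = 0.012),
             cong = list(pS = 0.6, pN = 0.1),
             zero = list(pS = 0, pN = 0))
  tab <- saturation_table(fits, distances, ng)
  expect_false(any(tab$saturated[tab$pair_id == "intra"]))
  expect_true(all(tab$saturated[tab$pair_id == "cong" &
                                  tab$region %in% c("P3", "PCG-syn")]))
  z <- tab[tab$pair_id == "zero", ]
  expect_true(all(z$observed == 0 & z$inferred == 0))
  expect_true(all(tab$inferred >= tab$observed))
})
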