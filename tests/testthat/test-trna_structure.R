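test_that("cloverleaf parsing derives pairs and enforces invariants", {
  st <- fixture_structures()
  k <- st$trnK
  expect_equal(nrow(k$pairs), 7 + 4 + 5 + 5)
  # paired positions carry stem labels, each position in at most one pair
  expect_true(all(grepl("stem", k$element[c(k$pairs)])))
  expect_equal(anyDuplicated(c(k$pairs)), 0L)
  # anticodon inside the AC loop, flanked by loop positions
  expect_length(k$anticodon, 3L)
  expect_true(all(k$element[k$anticodon] == "AC-loop"))

  expect_error(parse_cloverleaf("ACGTACGT", "AAAaaDDd"), "unbalanced")
  expect_error(parse_cloverleaf("ACGT", "AaAa"), "interleaved")
  expect_error(parse_cloverleaf("ACG", "AAAA"), "length")
})

test_that("stem events classify as compensatory or mispairing", {
  st <- fixture_structures()
  k <- st$trnK
  a <- k$sequence
  # first AA-stem pair is G:C; replace by A:T in b -> compensatory
  pr <- k$pairs[1, ]
  bv <- strsplit(a, "")[[1]]
  bv[pr[1]] <- "A"; bv[pr[2]] <- "T"
  prof <- classify_trna_substitutions(a, paste(bv, collapse = ""), k)
  expect_equal(prof$stem_total, 1L)
  expect_equal(prof$compensatory, 1L)
  expect_equal(prof$noncompensatory, 0L)

  # single-sided change creating a mispair -> noncompensatory
  bv2 <- strsplit(a, "")[[1]]
  bv2[pr[1]] <- "A"
  prof2 <- classify_trna_substitutions(a, paste(bv2, collapse = ""), k)
  expect_equal(prof2$stem_total, 1L)
  expect_equal(prof2$noncompensatory, 1L)

  # identical tRNAs: every count zero
  prof0 <- classify_trna_substitutions(a, a, k)
  expect_equal(prof0$n_diff, 0L)
  expect_equal(prof0$stem_total + sum(prof0$subs) + sum(prof0$indels), 0)
})

test_that("every differing column lands in exactly one element bucket", {
  st <- fixture_structures()
  for (seed in 1:5) {
    sim <- simulate_trna_pair(st$trnK, rna_t = 0.1, c = 0.7, seed = seed)
    prof <- classify_trna_substitutions(sim$a, sim$b, sim$ann)
    expect_equal(sum(prof$subs), prof$n_diff)
    expect_equal(prof$compensatory + prof$noncompensatory, prof$stem_total)
  }
})

test_that("indel columns are attributed to their reference element", {
  st <- fixture_structures()
  k <- st$trnK
  a <- k$sequence
  # delete two D-loop bases from b (gap in the aligned b row)
  dl <- which(k$element == "D-loop")[1:2]
  bv <- strsplit(a, "")[[1]]; bv[dl] <- "-"
  prof <- classify_trna_substitutions(a, paste(bv, collapse = ""), k)
  expect_equal(unname(prof$indels["D-loop"]), 2)
  expect_equal(sum(prof$indels), 2)
})

test_that("the anomaly screen reproduces the packaged tRNA-like flag sets", {
  st <- fixture_structures()
  expect_equal(nrow(trna_like_anomalies(st$trnK)), 0L)
  expect_equal(nrow(trna_like_anomalies(st$`trnL(UUR)`)), 0L)
  expect_setequal(trna_like_anomalies(st$K2)$anomaly,
                  c("missing_T_arm", "purine_before_anticodon",
                    "AA_stem_base_mispair"))
  expect_setequal(trna_like_anomalies(st$K3)$anomaly,
                  c("missing_D_AC_spacer", "AA_stem_base_mispair"))
  expect_setequal(trna_like_anomalies(st$L2)$anomaly, "AA_stem_excess_mispairs")
})

test_that("per-tRNA divergence summarizes pairwise distances", {
  st <- fixture_structures()
  sets <- list(s1 = c(trnK = st$trnK$sequence, trnL = st$`trnL(UUR)`$sequence),
               s2 = c(trnK = st$trnK$sequence, trnL = st$`trnL(UUR)`$sequence))
  d <- per_trna_divergence(sets)
  expect_true(all(d$max_pct == 0))

  bv <- strsplit(st$trnK$sequence, "")[[1]]
  bv[10] <- setdiff(c("A", "C", "G", "T"), bv[10])[1]
  sets$s2["trnK"] <- paste(bv, collapse = "")
  d2 <- per_trna_divergence(sets)
  expect_gt(d2$max_pct[d2$trna == "trnK"], 0)
  expect_equal(d2$max_pct[d2$trna == "trnL"], 0)
})

test_that("the classifier recovers the simulated compensation probability", {
  st <- fixture_structures()
  for (cc in c(0.9, 1)) {
    events <- comp <- 0
    seed <- 0
    while (events < 1000) {
      seed <- seed + 1
      sim <- simulate_trna_pair(st$trnK, rna_t = 0.12, c = cc, seed = 7000 + seed)
      prof <- classify_trna_substitutions(sim$a, sim$b, sim$ann)
      events <- events + prof$stem_total
      comp <- comp + prof$compensatory
    }
    expect_lt(abs(comp / events - cc), 0.05)
  }
  # at c = 1 every simulated stem event is compensatory by construction
  sim1 <- simulate_trna_pair(st$trnK, rna_t = 0.3, c = 1, seed = 12)
  expect_equal(sim1$n_comp, sim1$n_events)
  # zero rate -> identical pair
  sim0 <- simulate_trna_pair(st$trnK, rna_t = 0, c = 0.9, seed = 1)
  expect_identical(sim0$a, sim0$b)
})
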