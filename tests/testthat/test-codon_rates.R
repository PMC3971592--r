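test_that("F3x4 frequencies follow position-specific composition", {
  # uniform nucleotide composition at every position -> all sense codons 1/62
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  fr <- f3x4_frequencies(all64, code13)
  expect_length(fr, 62L)
  expect_equal(unname(fr), rep(1 / 62, 62), tolerance = 1e-9)
  expect_equal(sum(fr), 1)

  # hand-computed products for a two-codon pool: AAA and AAT each ~1/2
  fr2 <- f3x4_frequencies(c("AAA", "AAT"), code13)
  expect_equal(unname(fr2[c("AAA", "AAT")]), c(0.5, 0.5), tolerance = 1e-6)
  # zero-composition states floor at 1e-10 before renormalization
  expect_true(all(fr2[setdiff(names(fr2), c("AAA", "AAT"))] < 1e-9))
})

test_that("the GY94 generator satisfies its structural invariants", {
  fr <- f3x4_frequencies(simulate_codon_pair(400, 0.3, seed = 1)$caln, code13)
  for (par in list(c(2, 0.1), c(5, 1), c(0.5, 3))) {
    m <- build_gy94_matrix(par[1], par[2], fr, code13)
    expect_lt(max(abs(rowSums(m$q))), 1e-12)
    flux <- m$freqs * m$q             # detailed balance: pi_i q_ij == pi_j q_ji
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    pi <- m$freqs
    expect_equal(-sum(pi * diag(m$q)), 1, tolerance = 1e-12)
    # rates are zero between codons differing at more than one position
    sc <- code13$sense_codons
    dist1 <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    idx <- cbind(sample(62, 40, TRUE), sample(62, 40, TRUE))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (i != j && dist1(sc[i], sc[j]) > 1) expect_identical(m$q[i, j], 0)
    }
  }
})

test_that("rates are ordered by kappa, omega and target frequency", {
  # with omega=1, kappa=1 and uniform frequencies all neighbor rates are equal
  m1 <- build_gy94_matrix(1, 1, NULL, code13)
  off <- m1$q[m1$q > 0]
  expect_equal(max(off), min(off), tolerance = 1e-12)

  # TTT->TTC (syn transition) vs TTT->TTA (nonsyn transversion, code 13)
  fr <- f3x4_frequencies(simulate_codon_pair(400, 0.3, seed = 2)$caln, code13)
  m <- build_gy94_matrix(2, 0.1, fr, code13)
  i <- match("TTT", code13$sense_codons)
  jC <- match("TTC", code13$sense_codons); jA <- match("TTA", code13$sense_codons)
  expect_equal(m$q[i, jC] / m$q[i, jA],
               (2 / 0.1) * unname(m$freqs["TTC"] / m$freqs["TTA"]),
               tolerance = 1e-10)
})

test_that("transition probabilities are stochastic from t = 0 to t = 200", {
  m <- build_gy94_matrix(2, 0.2, NULL, code13)
  expect_equal(gy94_probability(m, 0), diag(62), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (t in c(0.01, 0.5, 5, 200)) {
    p <- gy94_probability(m, t)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("identical sequences fit to zero divergence", {
  sim <- simulate_codon_pair(200, t = 0, seed = 3)
  f <- fit_pairwise(sim$caln, code13)
  expect_lt(f$t, 1e-5)
  expect_equal(f$dN, 0, tolerance = 1e-5)
  expect_equal(f$dS, 0, tolerance = 1e-5)
})

test_that("ML fit recovers simulation parameters and dominates its starts", {
  sim <- simulate_codon_pair(1500, t = 0.3, kappa = 2, omega = 0.1, seed = 11)
  f <- fit_pairwise(sim$caln, code13)
  expect_true(f$converged)
  expect_gte(f$lnL, max(f$lnL_starts) - 1e-6)
  expect_equal(f$t, 0.3, tolerance = 0.15)
  expect_equal(f$omega, 0.1, tolerance = 0.35)
  expect_equal(f$omega, f$dN / f$dS, tolerance = 1e-6)
  expect_equal(f$rhoS + f$rhoN, 1, tolerance = 1e-12)
  expect_equal(f$S + f$N, 3 * f$n_codons_used)
})

test_that("estimates are invariant to codon-column order", {
  sim <- simulate_codon_pair(600, t = 0.2, omega = 0.15, seed = 13)
  f1 <- fit_pairwise(sim$caln, code13)
  perm <- sample(length(sim$caln$codons_a))
  shuf <- structure(list(codons_a = sim$caln$codons_a[perm],
                         codons_b = sim$caln$codons_b[perm],
                         mask = sim$caln$mask[perm]), class = "codon_alignment")
  f2 <- fit_pairwise(shuf, code13)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-6)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-6)
})

test_that("NG86 counting handles canonical hand cases", {
  mk <- function(a, b) structure(list(codons_a = a, codons_b = b,
                                      mask = rep(FALSE, length(a))),
                                 class = "codon_alignment")
  ident <- ng86_estimate(mk(c("ATG", "AAA"), c("ATG", "AAA")), code13)
  expect_equal(c(ident$dN, ident$dS), c(0, 0))

  # TTT vs TTC: both Phe under code 13 -> the single difference is synonymous
  one <- ng86_estimate(mk("TTT", "TTC"), code13)
  expect_equal(one$dN, 0)
  expect_gt(one$pS, 0)
  expect_equal(one$Sd, 1)
  # on a single codon the synonymous proportion saturates (pS = 3 > 3/4),
  # so the Jukes-Cantor-corrected dS is reported as NaN by design
  expect_true(is.nan(one$dS))
  # diluted with identical codons the correction is finite and positive
  many <- ng86_estimate(mk(c("TTT", rep("AAA", 19)), c("TTC", rep("AAA", 19))),
                        code13)
  expect_equal(many$dN, 0)
  expect_gt(many$dS, 0)
})

test_that("NG86 agrees with the ML fit at low divergence", {
  for (seed in 1:4) {
    sim <- simulate_codon_pair(1500, t = 0.05 + 0.05 * seed, omega = 0.2,
                               seed = 100 + seed)
    f <- fit_pairwise(sim$caln, code13)
    o <- ng86_estimate(sim$caln, code13)
    expect_equal(f$dN, o$dN, tolerance = 0.15)
  }
})

test_that("estimated dS increases with simulated divergence", {
  mean_ds <- vapply(c(0.05, 0.3, 1.0), function(tt) {
    mean(vapply(1:4, function(i) {
      sim <- simulate_codon_pair(800, t = tt, omega = 0.1, seed = 1000 * tt + i)
      fit_pairwise(sim$caln, code13)$dS
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ds) > 0))
})
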