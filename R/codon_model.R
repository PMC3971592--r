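#' F3x4 codon frequencies
#'
#' Codon frequencies as products of position-specific nucleotide frequencies,
#' pooled over both sequences of a codon alignment, restricted to the sense
#' codons of the genetic code, floored at 1e-10 and renormalized.
#'
#' @param x A `codon_alignment` (see [build_codon_alignment()]), or a
#'   character vector of codon strings, or a list of two such vectors.
#' @param code A [genetic_code()].
#' @return Named numeric vector over `code$sense_codons`, summing to 1.
#' @export
f3x4_frequencies <- function(x, code = genetic_code(13)) {
  cods <- if (inherits(x, "codon_alignment")) {
    c(x$codons_a[!x$mask], x$codons_b[!x$mask])
  } else if (is.list(x)) unlist(x) else x
  cods <- cods[!grepl("[^ACGT]", cods) & nchar(cods) == 3L]
  if (!length(cods)) stop("no unmasked codon columns")
  m <- do.call(rbind, strsplit(cods, ""))
  posfreq <- lapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / sum(tab)
  })
  sc <- code$sense_codons
  scm <- do.call(rbind, strsplit(sc, ""))
  idx <- function(b) match(b, c("A", "C", "G", "T"))
  fr <- posfreq[[1]][idx(scm[, 1])] * posfreq[[2]][idx(scm[, 2])] *
    posfreq[[3]][idx(scm[, 3])]
  fr <- pmax(fr, 1e-10)
  stats::setNames(fr / sum(fr), sc)
}

#' Goldman-Yang codon rate matrix
#'
#' Instantaneous rate matrix over sense codons: exchanges differing at more
#' than one position have rate zero; a single-nucleotide exchange i -> j has
#' rate proportional to `pi_j`, multiplied by `kappa` for transitions and by
#' `omega` for nonsynonymous changes.  The matrix is normalized so the mean
#' rate is one expected substitution per codon per unit time and satisfies
#' detailed balance by construction.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_freqs Named frequency vector over sense codons (see
#'   [f3x4_frequencies()]); uniform if NULL.
#' @param code A [genetic_code()].
#' @return List of class `gy94_matrix`: `q` (normalized rate matrix),
#'   `scale` (pre-normalization mean rate), `freqs`, `kappa`, `omega`,
#'   plus the synonymous flux proportion `rho_syn` of the normalized matrix.
#' @export
build_gy94_matrix <- function(kappa, omega, codon_freqs = NULL,
                              code = genetic_code(13)) {
  sc <- code$sense_codons
  n <- length(sc)
  if (is.null(codon_freqs)) codon_freqs <- stats::setNames(rep(1 / n, n), sc)
  pi <- pmax(as.numeric(codon_freqs[sc]), 1e-10)
  pi <- pi / sum(pi)
  pt <- codon_pair_table(code)
  mult <- ifelse(pt$ts, kappa, 1) * ifelse(pt$syn, 1, omega)
  q <- matrix(0, n, n, dimnames = list(sc, sc))
  q[cbind(pt$i, pt$j)] <- mult * pi[pt$j]
  q[cbind(pt$j, pt$i)] <- mult * pi[pt$i]
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  if (scale > 0) q <- q / scale
  flux <- pi[pt$i] * q[cbind(pt$i, pt$j)] + pi[pt$j] * q[cbind(pt$j, pt$i)]
  rho_syn <- sum(flux[pt$syn]) / sum(flux)
  structure(list(q = q, scale = scale, freqs = stats::setNames(pi, sc),
                 kappa = kappa, omega = omega, rho_syn = rho_syn),
            class = "gy94_matrix")
}

# Symmetrized eigendecomposition of a reversible Q (stable at large t).
gy94_eigen <- function(m) {
  pi <- m$freqs
  d <- sqrt(pi)
  s <- m$q * (d %o% (1 / d))
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, d = d)
}

#' Codon transition probability matrix P(t) = exp(Qt)
#'
#' @param m A [build_gy94_matrix()] object (or its cached eigendecomposition).
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @return Stochastic matrix over sense codons.
#' @export
gy94_probability <- function(m, t) {
  e <- if (is.list(m) && !is.null(m$values)) m else gy94_eigen(m)
  p <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * ((1 / e$d) %o% e$d)
  p[p < 0] <- 0
  p / rowSums(p)
}

# pattern-compressed pairwise codon data: indices into sense codons + counts
codon_patterns <- function(caln, code) {
  sc <- code$sense_codons
  keep <- !caln$mask
  ia <- match(caln$codons_a[keep], sc)
  ib <- match(caln$codons_b[keep], sc)
  ok <- !is.na(ia) & !is.na(ib)
  key <- paste(ia[ok], ib[ok])
  tab <- table(key)
  idx <- do.call(rbind, strsplit(names(tab), " "))
  list(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
       n = as.integer(tab), L = sum(ok))
}

pair_lnL <- function(pat, pi, pmat) {
  lik <- pi[pat$i] * pmat[cbind(pat$i, pat$j)]
  sum(pat$n * log(pmax(lik, 1e-300)))
}

# fast likelihood closure: rebuilds Q and its eigendecomposition only when
# (kappa, omega) change, so line searches and t-derivatives reuse them
make_pair_lnL <- function(pat, pi, code) {
  pt <- codon_pair_table(code)
  n <- length(pi)
  up <- cbind(pt$i, pt$j); dn <- cbind(pt$j, pt$i)
  pij <- pi[pt$j]; pji <- pi[pt$i]
  sq <- sqrt(pi); isq <- 1 / sq
  scl <- isq %o% sq
  pat_idx <- (pat$j - 1L) * n + pat$i
  log_pi_i <- log(pi[pat$i])
  cache <- new.env(parent = emptyenv()); cache$key <- c(NA_real_, NA_real_)
  function(t, kappa, omega) {
    key <- c(kappa, omega)
    if (!identical(key, cache$key)) {
      mult <- rep(1, nrow(pt))
      mult[pt$ts] <- kappa
      mult[!pt$syn] <- mult[!pt$syn] * omega
      q <- matrix(0, n, n)
      q[up] <- mult * pij
      q[dn] <- mult * pji
      diag(q) <- -rowSums(q)
      q <- q / (-sum(pi * diag(q)))
      s <- q * (sq %o% isq)
      e <- eigen((s + t(s)) / 2, symmetric = TRUE)
      cache$key <- key; cache$vec <- e$vectors; cache$val <- e$values
    }
    p <- (cache$vec %*% (exp(cache$val * t) * t(cache$vec))) * scl
    sum(pat$n * (log_pi_i + log(pmax(p[pat_idx], 1e-300))))
  }
}

#' Pairwise maximum-likelihood fit of the Goldman-Yang codon model
#'
#' Maximizes the pairwise likelihood over (t, kappa, omega) with F3x4 codon
#' frequencies estimated from the data, using a bounded quasi-Newton search
#' on log-transformed parameters with multiple starting points.  Synonymous
#' and nonsynonymous site counts follow the mutational-opportunity convention
#' (flux of the fitted matrix with omega forced to 1), so that
#' dN/dS = omega exactly.
#'
#' @param caln A [build_codon_alignment()] object.
#' @param code A [genetic_code()].
#' @param codon_freqs Optional frequency vector; F3x4 from the alignment if NULL.
#' @param starts Matrix of starting values, one row per start, columns
#'   (t, kappa, omega).
#' @param min_codons Minimum unmasked codon columns (default 50).
#' @return List of class `codon_fit`: `t`, `kappa`, `omega`, `dN`, `dS`,
#'   `S`, `N`, `rhoS`, `rhoN`, `lnL`, `lnL_starts`, `converged`,
#'   `n_codons_used`, `t12`, `t3` (expected substitutions per first-plus-second
#'   and per third codon-position site), `freqs`.
#' @export
fit_pairwise <- function(caln, code = genetic_code(13), codon_freqs = NULL,
                         starts = rbind(c(0.3, 2, 0.2), c(1, 2, 0.2), c(5, 2, 0.2)),
                         min_codons = 50L) {
  pat <- codon_patterns(caln, code)
  if (pat$L < min_codons)
    stop("fewer than ", min_codons, " unmasked codon columns")
  if (is.null(codon_freqs)) codon_freqs <- f3x4_frequencies(caln, code)
  pi <- as.numeric(codon_freqs[code$sense_codons])
  pi <- pmax(pi, 1e-10); pi <- pi / sum(pi)

  identical_seqs <- all(pat$i == pat$j)
  lower <- log(c(1e-6, 0.01, 1e-4))
  upper <- log(c(200, 100, 10))
  lnL_fun <- make_pair_lnL(pat, pi, code)
  nll <- function(par) {
    par <- exp(pmin(pmax(par, lower), upper))
    -lnL_fun(par[1], par[2], par[3])
  }
  lnL_starts <- apply(starts, 1, function(s) -nll(log(s)))

  if (identical_seqs) {
    best <- list(par = log(c(1e-6, starts[1, 2], starts[1, 3])), value = nll(log(c(1e-6, starts[1, 2], starts[1, 3]))))
    conv <- TRUE
  } else {
    ord <- order(-lnL_starts)
    best <- NULL; conv <- FALSE
    for (k in ord) {
      fit <- try(stats::optim(log(starts[k, ]), nll, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(factr = 1e7, maxit = 500)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        conv <- fit$convergence == 0
      }
      # accept the first start that converges and dominates all start points
      if (conv && -best$value >= max(lnL_starts) - 1e-9) break
    }
    if (is.null(best)) {  # all starts failed: report the best start point
      k <- ord[1]
      best <- list(par = log(starts[k, ]), value = -lnL_starts[k])
      conv <- FALSE
    }
  }
  par <- exp(best$par)
  t_hat <- par[1]; kappa <- par[2]; omega <- par[3]
  m_hat <- build_gy94_matrix(kappa, omega, codon_freqs, code)
  m_one <- build_gy94_matrix(kappa, 1, codon_freqs, code)
  rhoS <- m_hat$rho_syn; rhoN <- 1 - rhoS
  fS <- m_one$rho_syn                  # syn fraction of mutational opportunity
  S <- 3 * pat$L * fS; N <- 3 * pat$L - S
  dS <- t_hat * rhoS / (3 * fS)
  dN <- t_hat * rhoN / (3 * (1 - fS))
  # expected substitutions per site at P12 / P3 under the fitted matrix
  ptab <- codon_pair_table(code)
  flux <- m_hat$freqs[ptab$i] * m_hat$q[cbind(ptab$i, ptab$j)] +
    m_hat$freqs[ptab$j] * m_hat$q[cbind(ptab$j, ptab$i)]
  f12 <- sum(flux[ptab$pos != 3]) / sum(flux)
  structure(list(
    t = t_hat, kappa = kappa, omega = omega, dN = dN, dS = dS,
    S = S, N = N, rhoS = rhoS, rhoN = rhoN,
    lnL = -best$value, lnL_starts = lnL_starts, converged = conv,
    n_codons_used = pat$L,
    t12 = t_hat * f12 / 2, t3 = t_hat * (1 - f12),
    freqs = m_hat$freqs
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf(paste0("codon_fit: t=%.4g kappa=%.3g omega=%.4g  dN=%.4g dS=%.4g",
                     "  (S=%.1f N=%.1f, %d codons, lnL=%.2f%s)\n"),
              x$t, x$kappa, x$omega, x$dN, x$dS, x$S, x$N, x$n_codons_used,
              x$lnL, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Nei-Gojobori counting estimate of dN and dS
#'
#' Site and difference counting with equal-path averaging (paths passing
#' through stop codons are excluded when an alternative exists) and
#' Jukes-Cantor correction.  Returns NaN for a class whose corrected
#' proportion saturates (p >= 3/4).  Serves as an independent low-divergence
#' oracle for [fit_pairwise()].
#'
#' @param caln A [build_codon_alignment()] object.
#' @param code A [genetic_code()].
#' @return List: `dN`, `dS`, `pN`, `pS`, `S`, `N`, `Sd`, `Nd`.
#' @export
ng86_estimate <- function(caln, code = genetic_code(13)) {
  sc <- code$sense_codons
  aa <- code$codon_to_aa
  keep <- !caln$mask
  ca <- caln$codons_a[keep]; cb <- caln$codons_b[keep]
  ok <- ca %in% sc & cb %in% sc
  ca <- ca[ok]; cb <- cb[ok]
  bases <- c("A", "C", "G", "T")

  syn_sites <- function(cod) {  # synonymous site count of one codon
    s <- 0
    for (p in 1:3) {
      syn <- 0L; tot <- 0L
      for (b in setdiff(bases, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (aa[[alt]] == "*") next
        tot <- tot + 1L
        if (aa[[alt]] == aa[[cod]]) syn <- syn + 1L
      }
      if (tot > 0L) s <- s + syn / tot
    }
    s
  }
  site_cache <- vapply(sc, syn_sites, numeric(1))

  path_counts <- function(c1, c2) {  # average (syn, nonsyn) diffs over paths
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(pos)
    if (k == 0L) return(c(0, 0))
    perms <- if (k == 1L) list(pos) else
      if (k == 2L) list(pos, rev(pos)) else
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
               function(o) pos[o])
    res <- list()
    for (pp in perms) {
      cur <- c1; sy <- 0; ns <- 0; dead <- FALSE
      for (p in pp) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa[[nxt]] == "*") { dead <- TRUE; break }
        if (aa[[nxt]] == aa[[cur]]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      if (!dead) res[[length(res) + 1L]] <- c(sy, ns)
    }
    if (!length(res)) return(c(NA_real_, NA_real_))  # all paths hit a stop
    colMeans(do.call(rbind, res))
  }

  S <- sum(site_cache[ca] + site_cache[cb]) / 2
  N <- 3 * length(ca) - S
  diffs <- ca != cb
  Sd <- 0; Nd <- 0
  if (any(diffs)) {
    key <- paste(ca[diffs], cb[diffs])
    tab <- table(key)
    for (k in seq_along(tab)) {
      pr <- strsplit(names(tab)[k], " ")[[1]]
      cnt <- path_counts(pr[1], pr[2])
      if (anyNA(cnt)) next
      Sd <- Sd + tab[[k]] * cnt[1]; Nd <- Nd + tab[[k]] * cnt[2]
    }
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(pN), dS = jc(pS), pN = pN, pS = pS, S = S, N = N, Sd = Sd, Nd = Nd)
}
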