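# Seeded simulation of annotated mitogenome pairs and cohorts with the
# statistical structure the comparative pipeline assumes: ~13 PCGs evolving
# under the GY94 codon model, ~24 cloverleaf tRNAs with compensatory stem
# evolution, 2 rRNAs, and NCRs with homopolymer runs, slippage indels and
# start-codon boundary shifts.

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every tunable of the mitogenome simulator.  The divergence regime
#' presets place the expected number of codon substitutions per codon site
#' (`t`) at 0.02 (intraspecies), 0.3 (intermediate) and 3.0 (congeneric);
#' tRNA/rRNA/NCR rates scale from `t` through the `*_scale` factors, capped
#' so that highly diverged pairs do not degenerate into noise.
#'
#' @param seed Integer seed (used by the simulation entry points).
#' @param n_pcg_codons Codons in the concatenated protein-coding genes.
#' @param n_trnas Number of tRNA genes (2-24).
#' @param rrna_len Total rRNA length (split ~45/55 between rrnS and rrnL).
#' @param ncr_len Length of the largest noncoding region.
#' @param t,kappa,omega Codon-model parameters (expected substitutions per
#'   codon, transition/transversion ratio, dN/dS).
#' @param trna_scale,rrna_scale,ncr_scale Region rates as fractions of `t`.
#' @param stem_compensation_prob Probability that a stem substitution is
#'   accompanied by a partner-restoring substitution.
#' @param slippage Per-homopolymer, per-branch probability of a slippage
#'   length change in NCRs.
#' @param regime One of `intraspecies`, `intermediate`, `congeneric`
#'   (overrides `t` when `t` is NULL).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pcg_codons = 3500L, n_trnas = 24L,
                       rrna_len = 2000L, ncr_len = 500L, t = NULL,
                       kappa = 2, omega = 0.1, trna_scale = 0.12,
                       rrna_scale = 0.08, ncr_scale = 0.3,
                       stem_compensation_prob = 0.9, slippage = 0.05,
                       regime = c("intraspecies", "intermediate", "congeneric")) {
  regime <- match.arg(regime)
  if (is.null(t))
    t <- c(intraspecies = 0.02, intermediate = 0.3, congeneric = 3.0)[[regime]]
  stopifnot(t >= 0, kappa > 0, omega >= 0, n_trnas >= 2, n_trnas <= 24)
  structure(list(seed = seed, n_pcg_codons = as.integer(n_pcg_codons),
                 n_trnas = as.integer(n_trnas), rrna_len = as.integer(rrna_len),
                 ncr_len = as.integer(ncr_len), t = t, kappa = kappa,
                 omega = omega, trna_scale = trna_scale,
                 rrna_scale = rrna_scale, ncr_scale = ncr_scale,
                 stem_compensation_prob = stem_compensation_prob,
                 slippage = slippage, regime = regime),
            class = "sim_config")
}

# AT-rich position-specific nucleotide profile typical of these mitogenomes
default_nt_profile <- function() {
  m <- rbind(c(0.25, 0.15, 0.25, 0.35),
             c(0.20, 0.20, 0.15, 0.45),
             c(0.30, 0.10, 0.10, 0.50))
  dimnames(m) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
  m
}

codon_freqs_from_profile <- function(profile, code) {
  sc <- code$sense_codons
  m <- do.call(rbind, strsplit(sc, ""))
  fr <- profile[1, m[, 1]] * profile[2, m[, 2]] * profile[3, m[, 3]]
  stats::setNames(fr / sum(fr), sc)
}

# branch length (expected substitutions per codon) that yields a target dS
calibrate_branch_t <- function(dS, omega, kappa, codon_freqs, code) {
  fS1 <- build_gy94_matrix(kappa, 1, codon_freqs, code)$rho_syn
  rhoS <- build_gy94_matrix(kappa, omega, codon_freqs, code)$rho_syn
  3 * dS * fS1 / rhoS
}

evolve_codons <- function(idx, pmat, frozen = integer(0)) {
  new <- idx
  for (s in unique(idx)) {
    at <- which(idx == s)
    new[at] <- sample.int(ncol(pmat), length(at), replace = TRUE, prob = pmat[s, ])
  }
  if (length(frozen)) new[frozen] <- idx[frozen]
  new
}

# simple nucleotide substitution process with 2:1 transition bias
evolve_nt <- function(seq, p) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < p & v %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    for (i in hit) {
      v[i] <- if (stats::runif(1) < 0.5) ts[[v[i]]] else sample(tv[[v[i]]], 1)
    }
  }
  paste(v, collapse = "")
}

evolve_ncr <- function(seq, p, slip, min_len = 9L) {
  seq <- evolve_nt(seq, p)
  if (slip > 0) {
    runs <- find_homopolymers(seq, min_len)
    if (nrow(runs)) {
      for (r in rev(seq_len(nrow(runs)))) {  # right to left keeps coordinates valid
        if (stats::runif(1) < slip) {
          k <- sample(c(-2L, -1L, 1L, 2L), 1)
          s <- runs$start[r]; len <- runs$length[r]
          newrun <- strrep(runs$base[r], max(len + k, min_len - 2L))
          seq <- paste0(substr(seq, 1, s), newrun,
                        substr(seq, s + len + 1L, nchar(seq)))
        }
      }
    }
  }
  seq
}

# ---- cloverleaf construction and evolution -----------------------------------

# canonical 72-nt cloverleaf layout
cloverleaf_layout <- function() {
  paste0(strrep("A", 7), "ss", strrep("D", 4), strrep("b", 8), strrep("d", 4),
         "s", strrep("C", 5), "nn***nn", strrep("c", 5), strrep("v", 4),
         strrep("T", 5), strrep("u", 7), strrep("t", 5), strrep("a", 7), "@")
}

# random sequence consistent with a layout: stems get valid pairs, the
# position 5' of the anticodon is a pyrimidine (semi-invariant U33)
random_cloverleaf <- function(trna_id = "trna", layout = cloverleaf_layout()) {
  annv <- strsplit(layout, "")[[1]]
  n <- length(annv)
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.3, 0.15, 0.15, 0.4))
  ann <- parse_cloverleaf(paste(v, collapse = ""), layout, trna_id)
  valid <- c("AT", "TA", "GC", "CG", "GT", "TG")
  if (!is.null(ann$pairs)) {
    for (r in seq_len(nrow(ann$pairs))) {
      pr <- sample(valid, 1, prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05))
      v[ann$pairs[r, 1]] <- substr(pr, 1, 1)
      v[ann$pairs[r, 2]] <- substr(pr, 2, 2)
    }
  }
  if (length(ann$anticodon))
    v[min(ann$anticodon) - 1L] <- sample(c("T", "C"), 1, prob = c(0.8, 0.2))
  parse_cloverleaf(paste(v, collapse = ""), layout, trna_id)
}

# per-position (loops) and per-pair (stems) event weights, calibrated so the
# expected substitution shares reproduce the arm-level pattern seen in
# canonical mt tRNAs (T-arm ~40%, D-loop and AA-arm ~19% each)
trna_element_weights <- function() {
  list(loop = c("T-loop" = 3.086, "D-loop" = 1.71, "AC-loop" = 0.617,
                "variable-loop" = 0.72, "spacer" = 0.36, "discriminator" = 0.36),
       stem = c("T-stem" = 0.758, "AA-stem" = 1.029, "AC-stem" = 0.455,
                "D-stem" = 0.379))
}

# evolve one tRNA sequence given its structure; returns sequence + event log
evolve_trna <- function(seq, ann, rna_t, comp_prob,
                        weights = trna_element_weights()) {
  v <- strsplit(toupper(seq), "")[[1]]
  n_events <- n_comp <- 0L
  paired <- if (is.null(ann$pairs)) integer(0) else c(ann$pairs)
  for (i in seq_along(v)) {
    if (i %in% paired) next
    w <- weights$loop[[ann$element[i]]]
    if (is.null(w)) w <- 0.5
    if (stats::runif(1) < min(rna_t * w, 0.9))
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  valid <- c("AT", "TA", "GC", "CG", "GT", "TG")
  if (!is.null(ann$pairs)) {
    for (r in seq_len(nrow(ann$pairs))) {
      i <- ann$pairs[r, 1]; j <- ann$pairs[r, 2]
      w <- weights$stem[[ann$element[i]]]
      if (is.null(w)) w <- 0.5
      if (stats::runif(1) >= min(rna_t * w, 0.9)) next
      n_events <- n_events + 1L
      if (stats::runif(1) < comp_prob) {
        # compensatory: move to a valid pair differing at BOTH partners
        cur <- paste0(v[i], v[j])
        cand <- valid[substr(valid, 1, 1) != v[i] & substr(valid, 2, 2) != v[j]]
        if (!length(cand)) cand <- setdiff(valid, cur)
        pr <- sample(cand, 1)
        v[i] <- substr(pr, 1, 1); v[j] <- substr(pr, 2, 2)
        n_comp <- n_comp + 1L
      } else {
        side <- if (stats::runif(1) < 0.5) i else j
        v[side] <- sample(setdiff(c("A", "C", "G", "T"), v[side]), 1)
      }
    }
  }
  list(seq = paste(v, collapse = ""), n_events = n_events, n_comp = n_comp)
}

#' Simulate an aligned tRNA pair under structure-aware evolution
#'
#' Loop positions mutate independently; each stem pair experiences an event
#' with a structure-element-specific probability, and an event is paired with
#' a partner-restoring (compensatory) substitution with probability `c`.
#' Both sequences descend from the supplied structure's sequence (one branch
#' of `rna_t` each).
#'
#' @param structure A [parse_cloverleaf()] object (the ancestor).
#' @param rna_t Expected per-site substitution density per branch.
#' @param c Stem compensation probability.
#' @param seed Integer seed (optional).
#' @return List: `a`, `b` (sequences, equal length), `ann` (structure of
#'   `a`'s coordinates), `n_events`, `n_comp` (true stem event counts summed
#'   over both branches).
#' @export
simulate_trna_pair <- function(structure, rna_t, c = 0.9, seed = NULL) {
  with_seed(seed, {
    ea <- evolve_trna(structure$sequence, structure, rna_t, c)
    eb <- evolve_trna(structure$sequence, structure, rna_t, c)
    list(a = ea$seq, b = eb$seq, ann = structure,
         n_events = ea$n_events + eb$n_events,
         n_comp = ea$n_comp + eb$n_comp)
  })
}

#' Simulate a pair of in-frame coding sequences under the GY94 model
#'
#' The ancestor is drawn from the stationary (F3x4-style) codon distribution
#' and the two descendants evolve along branches of length `t/2` each by
#' exact transition-probability sampling, so the pair diverges by `t`
#' expected substitutions per codon.  Stop codons are never generated.
#'
#' @param n_codons Number of codons.
#' @param t,kappa,omega Codon-model parameters of the pair.
#' @param codon_freqs Stationary codon frequencies (default: AT-rich profile).
#' @param code A [genetic_code()].
#' @param seed Integer seed (optional).
#' @return List: `codons_a`, `codons_b` (codon-string vectors), `caln` (a
#'   ready [build_codon_alignment()]-style object), `truth` (t, kappa, omega).
#' @export
simulate_codon_pair <- function(n_codons, t, kappa = 2, omega = 0.1,
                                codon_freqs = NULL, code = genetic_code(13),
                                seed = NULL) {
  with_seed(seed, {
    if (is.null(codon_freqs))
      codon_freqs <- codon_freqs_from_profile(default_nt_profile(), code)
    m <- build_gy94_matrix(kappa, omega, codon_freqs, code)
    pmat <- gy94_probability(m, t / 2)
    anc <- sample.int(length(code$sense_codons), n_codons, replace = TRUE,
                      prob = m$freqs)
    ia <- evolve_codons(anc, pmat)
    ib <- evolve_codons(anc, pmat)
    ca <- code$sense_codons[ia]; cb <- code$sense_codons[ib]
    caln <- structure(list(codons_a = ca, codons_b = cb,
                           mask = rep(FALSE, n_codons)),
                      class = "codon_alignment")
    list(codons_a = ca, codons_b = cb, caln = caln,
         truth = list(t = t, kappa = kappa, omega = omega))
  })
}

# ---- whole-genome ancestors, branches, assembly ------------------------------

mito_gene_order <- function(n_trnas = 24L) {
  full <- c("cox1", "trnG(GGN)", "trnD", "cox2", "trnA", "trnR", "atp8",
            "trnQ", "atp6", "trnM(CAU)", "rrnS", "trnV", "rrnL", "trnL(UUR)",
            "nad1", "trnI", "nad2", "trnK", "cox3", "trnT", "nad3", "trnE",
            "trnS(AGY)", "nad4l", "trnH", "trnW", "trnL(CUN)", "nad5", "trnY",
            "trnF", "trnS(UCN)", "nad6", "trnC", "cob", "trnM(UAU)", "trnN",
            "trnP", "nad4", "trnG")
  trnas <- grep("^trn", full, value = TRUE)
  drop <- if (n_trnas < length(trnas)) utils::tail(trnas, length(trnas) - n_trnas) else character(0)
  setdiff(full, drop)
}

pcg_codon_counts <- function(n_total) {
  w <- c(atp6 = 227, atp8 = 70, cob = 380, cox1 = 512, cox2 = 230, cox3 = 260,
         nad1 = 300, nad2 = 330, nad3 = 117, nad4 = 459, nad4l = 98,
         nad5 = 560, nad6 = 160)
  n <- round(w / sum(w) * n_total)
  n[["cox1"]] <- n[["cox1"]] + (n_total - sum(n))
  n
}

default_ncr_slots <- function(ncr_len) {
  c("trnG~cox1" = ncr_len, "trnW~trnL(CUN)" = 25L, "trnG(GGN)~trnD" = 30L,
    "trnS(UCN)~nad6" = 20L, "trnP~nad4" = 15L, "cox2~trnA" = 12L,
    "trnK~cox3" = 9L, "nad3~trnE" = 14L, "trnY~trnF" = 10L,
    "cob~trnM(UAU)" = 18L)
}

# genes whose starts carry a conserved T-homopolymer pad (12 bp = 4 codons)
# allowing annotation-level start-codon shifts between genomes
pad_codons <- function(code) match(c("TTT", "TTT", "TTT", "TAT"), code$sense_codons)

make_ancestor <- function(cfg, code = genetic_code(13)) {
  profile <- default_nt_profile()
  freqs <- codon_freqs_from_profile(profile, code)
  counts <- pcg_codon_counts(cfg$n_pcg_codons)
  pads <- pad_codons(code)
  genes <- lapply(names(counts), function(g) {
    idx <- sample.int(length(code$sense_codons), counts[[g]], replace = TRUE,
                      prob = freqs)
    idx[1] <- match("ATG", code$sense_codons)
    if (g %in% c("nad6", "nad4")) idx <- c(pads, idx)
    idx
  })
  names(genes) <- names(counts)
  order_ <- mito_gene_order(cfg$n_trnas)
  trna_names <- grep("^trn", order_, value = TRUE)
  mults <- seq(0.3, 1.9, length.out = length(trna_names))
  trnas <- lapply(seq_along(trna_names), function(k)
    list(ann = random_cloverleaf(trna_names[k]), mult = mults[k]))
  names(trnas) <- trna_names
  rs <- floor(cfg$rrna_len * 0.45)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                       prob = c(0.3, 0.15, 0.15, 0.4)), collapse = "")
  ncr <- lapply(default_ncr_slots(cfg$ncr_len), rand_seq)
  # a large T homopolymer inside the major NCR
  big <- names(ncr)[1]
  mid <- nchar(ncr[[big]]) %/% 2
  ncr[[big]] <- paste0(substr(ncr[[big]], 1, mid), strrep("T", 10),
                       substr(ncr[[big]], mid + 11L, nchar(ncr[[big]])))
  list(code = code, freqs = freqs, genes = genes,
       frozen = list(nad6 = seq_along(pads), nad4 = seq_along(pads)),
       trna = lapply(trnas, function(x)
         list(seq = x$ann$sequence, ann = x$ann, mult = x$mult)),
       rrna = list(rrnS = rand_seq(rs), rrnL = rand_seq(cfg$rrna_len - rs)),
       ncr = ncr, order = order_)
}

branch_params <- function(cfg, t, omega = cfg$omega) {
  list(t = t, kappa = cfg$kappa, omega = omega,
       trna_t = min(cfg$trna_scale * t, 0.12),
       rrna_t = min(cfg$rrna_scale * t, 0.10),
       ncr_t = min(cfg$ncr_scale * t, 0.30),
       slip = cfg$slippage, comp = cfg$stem_compensation_prob)
}

evolve_state <- function(state, br) {
  if (br$t > 0) {
    m <- build_gy94_matrix(br$kappa, br$omega, state$freqs, state$code)
    pmat <- gy94_probability(m, br$t)
    state$genes <- lapply(stats::setNames(names(state$genes), names(state$genes)),
      function(g) evolve_codons(state$genes[[g]], pmat,
                                frozen = state$frozen[[g]] %||% integer(0)))
  }
  state$trna <- lapply(state$trna, function(x) {
    e <- evolve_trna(x$seq, x$ann, br$trna_t * x$mult, br$comp)
    x$seq <- e$seq
    x
  })
  state$rrna <- lapply(state$rrna, evolve_nt, p = br$rrna_t)
  state$ncr <- lapply(state$ncr, evolve_ncr, p = br$ncr_t, slip = br$slip)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# insert k bases (slippage-style duplication for small k, random block
# otherwise) into the middle of an NCR
ncr_insert <- function(seq, k) {
  mid <- max(nchar(seq) %/% 2, 1L)
  block <- if (k <= 2L) strrep(substr(seq, mid, mid), k)
           else paste(sample(c("A", "C", "G", "T"), k, replace = TRUE,
                             prob = c(0.3, 0.15, 0.15, 0.4)), collapse = "")
  paste0(substr(seq, 1, mid), block, substr(seq, mid + 1L, nchar(seq)))
}

assemble_genome <- function(state, accession, species, sample_name,
                            shifts = NULL, inserts = NULL) {
  code <- state$code
  ncr <- state$ncr
  if (!is.null(inserts))
    for (adj in names(inserts)) ncr[[adj]] <- ncr_insert(ncr[[adj]], inserts[[adj]])
  seqs <- character(0)
  feats <- list()
  pos <- 0L
  push <- function(name, category, s, reading_offset = 0L) {
    seqs <<- c(seqs, s)
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, category = category, start = pos, end = pos + nchar(s),
      strand = "+", reading_offset = reading_offset, incomplete_stop = "none",
      stringsAsFactors = FALSE)
    pos <<- pos + nchar(s)
  }
  ord <- state$order
  for (k in seq_along(ord)) {
    g <- ord[k]
    if (grepl("^trn", g)) {
      push(g, "tRNA", state$trna[[g]]$seq)
    } else if (grepl("^rrn", g)) {
      push(g, "rRNA", state$rrna[[g]])
    } else {
      s <- paste0(paste(code$sense_codons[state$genes[[g]]], collapse = ""), "TAA")
      shift <- shifts[[g]] %||% 0L
      if (shift > 0L) {
        # annotation-level start shift: the first `shift` bases act as NCR
        seqs <- c(seqs, substr(s, 1L, shift))
        pos <- pos + shift
        push(g, "PCG", substr(s, shift + 1L, nchar(s)),
             reading_offset = (3L - shift %% 3L) %% 3L)
      } else {
        push(g, "PCG", s)
      }
    }
    nxt <- ord[if (k < length(ord)) k + 1L else 1L]
    adj <- paste0(g, "~", nxt)
    if (!is.null(ncr[[adj]]) && nchar(ncr[[adj]])) {
      seqs <- c(seqs, ncr[[adj]])  # left unannotated: becomes an NCR feature
      pos <- pos + nchar(ncr[[adj]])
    }
  }
  g <- mito_genome(accession, paste(seqs, collapse = ""),
                   do.call(rbind, feats), species = species,
                   sample_name = sample_name)
  add_ncr_features(g)
}

# ---- tree-structured cohorts -------------------------------------------------

sim_node <- function(t, omega, children = NULL, sample = NULL, species = NULL,
                     genus = NULL, shifts = NULL, inserts = NULL) {
  list(t = t, omega = omega, children = children, sample = sample,
       species = species, genus = genus, shifts = shifts, inserts = inserts)
}

collect_leaves <- function(state, node, cfg) {
  st <- evolve_state(state, branch_params(cfg, node$t, node$omega))
  if (is.null(node$children)) {
    g <- assemble_genome(st, node$sample, node$species, node$sample,
                         shifts = node$shifts, inserts = node$inserts)
    return(stats::setNames(list(list(genome = g, state = st,
                                     species = node$species,
                                     genus = node$genus)), node$sample))
  }
  do.call(c, lapply(node$children, function(ch) {
    ch$genus <- ch$genus %||% node$genus
    collect_leaves(st, ch, cfg)
  }))
}

finish_cohort <- function(leaves, ancestor) {
  genomes <- lapply(leaves, `[[`, "genome")
  meta <- data.frame(
    sample = names(leaves),
    species = vapply(leaves, `[[`, "", "species"),
    genus = vapply(leaves, `[[`, "", "genus"),
    source = "simulated", row.names = NULL, stringsAsFactors = FALSE)
  structures <- lapply(ancestor$trna, `[[`, "ann")
  trna_sets <- lapply(leaves, function(l)
    vapply(l$state$trna, `[[`, "", "seq"))
  list(genomes = genomes, metadata = meta, structures = structures,
       trna_sets = trna_sets)
}

#' Simulate an annotated mitogenome pair
#'
#' Two genomes descend from a common ancestor along branches of `t/2` each;
#' every functional region evolves at its own rate (see [sim_config()]).
#' Optional NCR insertions and start-codon boundary shifts are applied to the
#' second genome.
#'
#' @param cfg A [sim_config()].
#' @param inserts Named integer vector of NCR insertions for genome B
#'   (names = adjacencies such as `"trnW~trnL(CUN)"`).
#' @param shifts Named integer vector of start-codon shifts for genome B
#'   (names = PCGs carrying a homopolymer pad: `nad6`, `nad4`).
#' @return List: `a`, `b` ([mito_genome()]s), `metadata`, `structures`
#'   (cloverleaf annotations), `trna_sets`, `truth`.
#' @export
simulate_genome_pair <- function(cfg = sim_config(), inserts = NULL,
                                 shifts = NULL) {
  with_seed(cfg$seed, {
    anc <- make_ancestor(cfg)
    root <- sim_node(0, cfg$omega, genus = "SimGenus", children = list(
      sim_node(cfg$t / 2, cfg$omega, sample = "simA", species = "Sim species"),
      sim_node(cfg$t / 2, cfg$omega, sample = "simB", species = "Sim species",
               shifts = as.list(shifts), inserts = inserts)))
    leaves <- collect_leaves(anc, root, cfg)
    out <- finish_cohort(leaves, anc)
    list(a = out$genomes[["simA"]], b = out$genomes[["simB"]],
         metadata = out$metadata, structures = out$structures,
         trna_sets = out$trna_sets,
         truth = list(t = cfg$t, kappa = cfg$kappa, omega = cfg$omega))
  })
}

#' Simulate a cohort of conspecific and congeneric mitogenomes
#'
#' One genus with `n_species` species (star phylogeny at divergence
#' `regime$congeneric`), `n_samples_per_species` samples per species at
#' `regime$intraspecies`, and optionally one extra "intermediate" sample
#' inside the first species whose pairwise divergence to its conspecifics is
#' `regime$intermediate` -- the ongoing-speciation scenario.
#'
#' @param n_species,n_samples_per_species Cohort dimensions.
#' @param regime Named list/vector with elements `intraspecies`,
#'   `intermediate`, `congeneric` (expected substitutions per codon).
#' @param intermediate_sample Add the intermediate sample? (default TRUE)
#' @param cfg A [sim_config()] (its `t` is ignored; `seed` is used).
#' @param seed Overrides `cfg$seed` when given.
#' @return List: `genomes` (named list), `metadata`, `structures`,
#'   `trna_sets`, `intermediate_pairs` (pair ids expected to be flagged).
#' @export
simulate_cohort <- function(n_species = 2L, n_samples_per_species = 2L,
                            regime = c(intraspecies = 0.02, intermediate = 0.3,
                                       congeneric = 3.0),
                            intermediate_sample = TRUE, cfg = sim_config(),
                            seed = NULL) {
  if (n_species < 2L) stop("need at least two species for congeneric pairs")
  regime <- as.list(regime)
  with_seed(seed %||% cfg$seed, {
    anc <- make_ancestor(cfg)
    t_sp <- (regime$congeneric - regime$intraspecies) / 2
    species_nodes <- lapply(seq_len(n_species), function(s) {
      spname <- sprintf("Sim species%d", s)
      samples <- lapply(seq_len(n_samples_per_species), function(i)
        sim_node(regime$intraspecies / 2, cfg$omega,
                 sample = sprintf("sp%d_s%d", s, i), species = spname))
      if (s == 1L && intermediate_sample)
        samples <- c(samples, list(
          sim_node(regime$intermediate - regime$intraspecies / 2, cfg$omega,
                   sample = "sp1_int", species = spname)))
      sim_node(t_sp, cfg$omega, children = samples)
    })
    root <- sim_node(0, cfg$omega, genus = "SimGenus", children = species_nodes)
    leaves <- collect_leaves(anc, root, cfg)
    out <- finish_cohort(leaves, anc)
    ip <- character(0)
    if (intermediate_sample) {
      sibs <- sprintf("sp1_s%d", seq_len(n_samples_per_species))
      ip <- paste(pmin(sibs, "sp1_int"), pmax(sibs, "sp1_int"), sep = "|")
    }
    c(out, list(intermediate_pairs = sort(ip)))
  })
}

#' Synthetic study cohort
#'
#' A cohort emulating the design of the comparative study the package is
#' built around: five genera with conspecific samples at low divergence, one
#' species (four samples) containing two deeply diverged specimens whose
#' pairwise dN sits between the intraspecies and congeneric ranges, cryptic
#' species pairs at the bottom of the congeneric range, and noncoding-region
#' differences (true indels of 11 and 13 bp, start-codon boundary shifts of
#' 11 and 7 bp, plus five small slippage-style length changes) in the
#' four-sample species.  Divergence times are calibrated analytically from
#' target dS values (intraspecies ~0.01-0.016; the divergent pairs 0.30; the
#' near-identical pair 0.06; congeneric 3.3-8) through the codon model
#' itself.
#'
#' @param seed Integer seed.
#' @param n_pcg_codons Codons in the protein-coding concatenate (default 3500).
#' @return As [simulate_cohort()], plus `bs_ita_pairs` (the five divergent
#'   intraspecies pair ids), `cryptic_pairs` (the congeneric pairs excluded
#'   in the reduced gap), `targets` (the calibration targets used).
#' @export
study_cohort <- function(seed = 1L, n_pcg_codons = 3500L) {
  cfg <- sim_config(seed = seed, n_pcg_codons = n_pcg_codons, slippage = 0)
  code <- genetic_code(13)
  freqs <- codon_freqs_from_profile(default_nt_profile(), code)
  calt <- function(ds, om) calibrate_branch_t(ds, om, cfg$kappa, freqs, code)
  with_seed(seed, {
    anc <- make_ancestor(cfg)
    om_i <- 0.03                      # intraspecies omega
    t_bs <- calt(0.30, 0.022)         # divergent conspecific pairs
    t_ea <- calt(0.06, 0.03)          # the near-identical pair
    bs <- sim_node(0, 0.022, children = list(
      sim_node(t_bs / 2, 0.022, sample = "Bs_VE", species = "Bot schlosseri",
               inserts = c("trnW~trnL(CUN)" = 11L, "trnG(GGN)~trnD" = 13L,
                           "cox2~trnA" = 1L, "trnK~cox3" = 1L)),
      sim_node(t_bs / 2, 0.022, sample = "Bs_TR", species = "Bot schlosseri",
               shifts = list(nad6 = 11L, nad4 = 7L),
               inserts = c("nad3~trnE" = 2L)),
      sim_node((t_bs - t_ea) / 2, 0.022, children = list(
        sim_node(t_ea / 2, 0.03, sample = "Bs_EA", species = "Bot schlosseri",
                 inserts = c("cob~trnM(UAU)" = 2L)),
        sim_node(t_ea / 2, 0.03, sample = "Bs_sc6ab", species = "Bot schlosseri",
                 inserts = c("trnY~trnF" = 1L))))),
      genus = "Botryllus")
    star2 <- function(prefix, species, t_intra, om = om_i)
      lapply(1:2, function(i) sim_node(t_intra / 2, om,
        sample = sprintf("%s_%d", prefix, i), species = species))
    t34 <- calt(3.4, 0.0153); t53 <- calt(5.3, 0.030)
    botrylloides <- sim_node(0, 0.03, genus = "Botrylloides", children = list(
      sim_node(t53 / 2, 0.030, children = star2("Bp", "Bot pizoni", calt(0.010, om_i))),
      sim_node((t53 - t34) / 2, 0.030, children = list(
        sim_node(t34 / 2, 0.0153, children = star2("Bl", "Bot leachii", calt(0.013, om_i))),
        sim_node(t34 / 2, 0.0153, sample = "Bn_1", species = "Bot nigrum")))))
    t33 <- calt(3.3, 0.0156); tA <- calt(0.012, om_i)
    ciona <- sim_node(0, 0.0156, genus = "Ciona", children = list(
      sim_node(t33 / 2, 0.0156, sample = "CiB_1", species = "Ciona spB"),
      sim_node((t33 - tA) / 2, 0.0156, children = star2("CiA", "Ciona spA", tA))))
    t60 <- calt(6.0, 0.027)
    clavelina <- sim_node(0, 0.027, genus = "Clavelina", children = list(
      sim_node(t60 / 2, 0.027, children = star2("Cl", "Cla lepadiformis", calt(0.017, om_i))),
      sim_node(t60 / 2, 0.027, sample = "Cp_1", species = "Cla phlegraea")))
    t80 <- calt(8.0, 0.024)
    halocynthia <- sim_node(0, 0.024, genus = "Halocynthia", children = list(
      sim_node(t80 / 2, 0.024, sample = "Hr_1", species = "Hal roretzi"),
      sim_node(t80 / 2, 0.024, sample = "Hp_1", species = "Hal papillosa")))
    leaves <- c(collect_leaves(anc, bs, cfg),
                collect_leaves(anc, botrylloides, cfg),
                collect_leaves(anc, ciona, cfg),
                collect_leaves(anc, clavelina, cfg),
                collect_leaves(anc, halocynthia, cfg))
    out <- finish_cohort(leaves, anc)
    ita <- c("Bs_VE", "Bs_TR")
    others <- c("Bs_EA", "Bs_sc6ab")
    bs_ita <- sort(c("Bs_TR|Bs_VE",
                     as.vector(outer(ita, others, function(x, y)
                       paste(pmin(x, y), pmax(x, y), sep = "|")))))
    c(out, list(
      bs_ita_pairs = bs_ita,
      ea_pair = "Bs_EA|Bs_sc6ab",
      cryptic_pairs = c("CiA_1|CiB_1", "CiA_2|CiB_1", "Bl_1|Bn_1", "Bl_2|Bn_1"),
      targets = list(ds_ita = 0.30, ds_ea = 0.06, ds_other = 0.013)))
  })
}
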