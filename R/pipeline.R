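#' Codon alignment of two genomes' protein-coding concatenates
#'
#' Pairs the per-gene in-frame CDSs of two [extract_regions()] partitions.
#' Genes with equal codon counts are paired column-by-column; when a
#' start-codon shift makes one copy longer, the longer head is trimmed by the
#' codon-count difference (the remaining codons correspond position-wise).
#'
#' @param pa,pb `region_partition` objects.
#' @param code A [genetic_code()].
#' @return A `codon_alignment` over the shared genes (alphabetical order).
#' @export
pcg_pair_alignment <- function(pa, pb, code = genetic_code(13)) {
  genes <- intersect(names(pa$pcg_by_gene), names(pb$pcg_by_gene))
  genes <- sort(genes)
  ca <- cb <- character(0)
  for (g in genes) {
    a <- codon_split(pa$pcg_by_gene[[g]])
    b <- codon_split(pb$pcg_by_gene[[g]])
    d <- length(a) - length(b)
    if (d > 0) a <- a[-seq_len(d)] else if (d < 0) b <- b[-seq_len(-d)]
    ca <- c(ca, a); cb <- c(cb, b)
  }
  mask <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb) |
    ca %in% code$stop_codons | cb %in% code$stop_codons
  structure(list(codons_a = ca, codons_b = cb, mask = mask),
            class = "codon_alignment")
}

align_ncr <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(NULL)
  if (nchar(a) == nchar(b)) return(c(a, b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 4, gapExtension = 1)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole comparative analysis over a set of annotated genomes
#'
#' For every conspecific and congeneric sample pair: region-wise uncorrected
#' distances (PCG/P12/P3/tRNA/rRNA and, for conspecific pairs, NCR), the
#' pairwise ML codon-model fit with its Nei-Gojobori cross-check, the
#' saturation table, the intraspecies-vs-congeneric dN gap (computed after
#' excluding flagged intermediate pairs), the intermediate-pair flags, the
#' structure-aware tRNA substitution profile over conspecific pairs, and the
#' per-species NCR architecture report.
#'
#' @param genomes Named list of [mito_genome()] objects (names = sample ids
#'   matching `metadata$sample`).
#' @param metadata `data.frame` with columns `sample`, `species`, `genus`.
#' @param outdir Output directory for the report bundle (created if needed);
#'   NULL (default) skips file output.
#' @param structures Optional named list of [parse_cloverleaf()] annotations
#'   (names = tRNA gene names) enabling the tRNA profile.
#' @param trna_sets Optional named list (per sample) of named tRNA sequences;
#'   derived from the genome features when NULL.
#' @param code A [genetic_code()].
#' @param ds_saturation dS saturation threshold (default 1).
#' @param flag_thresholds `c(low, high)` ratios for intermediate-pair
#'   flagging (default `c(5, 5)`).
#' @param sizeable_ncr_bp,min_homopolymer NCR report thresholds.
#' @param trna_identity_exclude Conspecific pairs whose tRNA concatenates
#'   differ by less than this fraction are excluded from the aggregate tRNA
#'   profile (default 0.002, the "almost identical" case).
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `mitorate_run`: `pairs`, `distances`, `dnds`,
#'   `fits`, `ng`, `saturation`, `flags`, `gap`, `trna_profile`,
#'   `trna_divergence`, `ncr`, `manifest`.
#' @export
run_pipeline <- function(genomes, metadata, outdir = NULL, structures = NULL,
                         trna_sets = NULL, code = genetic_code(13),
                         ds_saturation = 1, flag_thresholds = c(5, 5),
                         sizeable_ncr_bp = 5L, min_homopolymer = 9L,
                         trna_identity_exclude = 0.002, seed = NA_integer_) {
  stopifnot(length(genomes) >= 2)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "accession")
  missing <- setdiff(names(genomes), metadata$sample)
  if (length(missing)) stop("metadata does not cover: ", paste(missing, collapse = ", "))
  pairs <- pair_metadata(metadata[metadata$sample %in% names(genomes), ])
  pairs <- pairs[pairs$pair_level %in% c("intraspecies", "congeneric"), , drop = FALSE]
  if (!nrow(pairs)) stop("no intraspecies or congeneric pairs to analyze")

  parts <- lapply(genomes, extract_regions, code = code)
  if (is.null(trna_sets))
    trna_sets <- lapply(parts, function(p) unlist(p$trna_by_gene))

  fits <- list(); ng <- list(); dist_rows <- list(); failures <- character(0)
  for (r in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[r]
    a <- pairs$sample_a[r]; b <- pairs$sample_b[r]
    res <- try({
      caln <- pcg_pair_alignment(parts[[a]], parts[[b]], code)
      alns <- list(PCG = caln)
      pa <- parts[[a]]; pb <- parts[[b]]
      if (pairs$pair_level[r] == "intraspecies") {
        alns$NCR <- align_ncr(pa$ncr_concat, pb$ncr_concat)
      } else {
        # congeneric NCRs are not reliably alignable; skip the region quietly
        pa$ncr_concat <- pb$ncr_concat <- ""
      }
      dist_rows[[pid]] <- region_distance_table(pa, pb,
                                                alignments = alns, pair_id = pid)
      fits[[pid]] <- fit_pairwise(caln, code)
      ng[[pid]] <- ng86_estimate(caln, code)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("pair ", pid, " failed: ", attr(res, "condition")$message)
      failures <- c(failures, pid)
    }
  }
  distances <- do.call(rbind, c(dist_rows, list(make.row.names = FALSE)))
  dnds <- do.call(rbind, lapply(names(fits), function(pid) {
    f <- fits[[pid]]
    data.frame(pair = pid, pair_level = pairs$pair_level[pairs$pair_id == pid],
               t = f$t, kappa = f$kappa, omega = f$omega, dN = f$dN, dS = f$dS,
               S = f$S, N = f$N, lnL = f$lnL, converged = f$converged,
               ng_dN = ng[[pid]]$dN, ng_dS = ng[[pid]]$dS,
               stringsAsFactors = FALSE)
  }))
  sat <- saturation_table(fits, distances, ng, ds_saturation = ds_saturation)
  per_pair_dN <- stats::setNames(dnds$dN, dnds$pair)
  # gap and flags need both comparison levels; conspecific-only cohorts skip them
  flags <- tryCatch(
    flag_intermediate_pairs(per_pair_dN, pairs,
                            threshold_low = flag_thresholds[1],
                            threshold_high = flag_thresholds[2]),
    error = function(e) { message("flags skipped: ", e$message); NULL })
  gap <- tryCatch(
    dn_gap_report(per_pair_dN, pairs,
                  exclude = if (is.null(flags)) character(0)
                            else flags$pair_id[flags$flagged]),
    error = function(e) { message("gap report skipped: ", e$message); NULL })

  # --- tRNA profile over conspecific pairs (near-identical pairs excluded)
  trna_profile <- NULL; trna_div <- NULL
  if (!is.null(structures)) {
    intra <- pairs[pairs$pair_level == "intraspecies", , drop = FALSE]
    per_pair <- list()
    for (r in seq_len(nrow(intra))) {
      a <- intra$sample_a[r]; b <- intra$sample_b[r]
      conc <- p_distance(parts[[a]]$trna_concat, parts[[b]]$trna_concat)
      if (conc$p_distance < trna_identity_exclude) next
      per_pair[[intra$pair_id[r]]] <- lapply(names(structures), function(tr)
        classify_trna_substitutions(trna_sets[[a]][[tr]], trna_sets[[b]][[tr]],
                                    structures[[tr]]))
    }
    if (length(per_pair)) trna_profile <- aggregate_trna_profiles(per_pair)
    by_species <- split(metadata$sample[metadata$sample %in% names(genomes)],
                        metadata$species[metadata$sample %in% names(genomes)])
    multi <- by_species[vapply(by_species, length, 0L) >= 2]
    if (length(multi))
      trna_div <- do.call(rbind, lapply(names(multi), function(sp) {
        d <- per_trna_divergence(trna_sets[multi[[sp]]])
        d$species <- sp
        d
      }))
  }

  # --- NCR architecture per species with >= 2 genomes
  by_species <- split(names(genomes),
                      metadata$species[match(names(genomes), metadata$sample)])
  ncr_rows <- lapply(names(by_species)[vapply(by_species, length, 0L) >= 2],
    function(sp) {
      rep_ <- try(ncr_report(genomes[by_species[[sp]]],
                             sizeable_bp = sizeable_ncr_bp,
                             min_homopolymer = min_homopolymer), silent = TRUE)
      if (inherits(rep_, "try-error")) return(NULL)
      rep_$species <- sp
      rep_
    })
  ncr <- do.call(rbind, ncr_rows)

  manifest <- list(
    n_genomes = length(genomes), samples = names(genomes),
    n_pairs = nrow(pairs), failed_pairs = failures, seed = seed,
    thresholds = list(ds_saturation = ds_saturation,
                      flag_low = flag_thresholds[1],
                      flag_high = flag_thresholds[2],
                      sizeable_ncr_bp = sizeable_ncr_bp,
                      min_homopolymer = min_homopolymer),
    genetic_code = code$table_id)

  out <- structure(list(pairs = pairs, distances = distances, dnds = dnds,
                        fits = fits, ng = ng, saturation = sat, flags = flags,
                        gap = gap, trna_profile = trna_profile,
                        trna_divergence = trna_div, ncr = ncr,
                        manifest = manifest),
                   class = "mitorate_run")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(distances, file.path(outdir, "distances.tsv"))
    write_tsv(dnds, file.path(outdir, "dnds.tsv"))
    write_tsv(sat, file.path(outdir, "saturation.tsv"))
    if (!is.null(flags)) write_tsv(flags, file.path(outdir, "flags.tsv"))
    if (!is.null(gap)) {
      gap_json <- gap[c("max_intra_dN", "max_intra_pair", "min_congeneric_dN",
                        "min_congeneric_pair", "delta", "no_gap", "excluded_pairs")]
      jsonlite::write_json(gap_json, file.path(outdir, "gap_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(trna_profile)) {
      tp <- data.frame(arm = names(trna_profile$arm_pct),
                       pct = as.numeric(trna_profile$arm_pct),
                       pct_mean = as.numeric(trna_profile$arm_pct_mean),
                       pct_sd = as.numeric(trna_profile$arm_pct_sd))
      write_tsv(tp, file.path(outdir, "trna_profile.tsv"))
    }
    if (!is.null(ncr)) write_tsv(ncr, file.path(outdir, "ncr_report.tsv"))
    manifest$stage_hashes <- vapply(
      c("distances.tsv", "dnds.tsv", "saturation.tsv"),
      function(f) as.character(tools::md5sum(file.path(outdir, f))), "")
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.mitorate_run <- function(x, ...) {
  cat(sprintf("mitorate_run: %d genomes, %d pairs (%d intraspecies, %d congeneric)\n",
              x$manifest$n_genomes, nrow(x$pairs),
              sum(x$pairs$pair_level == "intraspecies"),
              sum(x$pairs$pair_level == "congeneric")))
  if (!is.null(x$gap))
    cat(sprintf("  dN gap delta: %.4g; flagged intermediate pairs: %d\n",
                x$gap$delta, sum(x$flags$flagged)))
  invisible(x)
}
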