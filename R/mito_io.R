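#' Annotated mitochondrial genome container
#'
#' A `mito_genome` holds one circular mitochondrial sequence together with its
#' typed gene features (protein-coding genes, tRNAs, rRNAs and noncoding
#' regions).  Coordinates are 0-based half-open internally; 1-based inclusive
#' coordinates appear only at I/O boundaries (GenBank).  A feature whose
#' `start > end` wraps across the origin of the circular molecule.
#'
#' @param accession Text identifier.
#' @param sequence DNA string (A/C/G/T/N plus IUPAC ambiguity codes).
#' @param features `data.frame` with columns `name`, `category` (one of
#'   `PCG`, `tRNA`, `rRNA`, `NCR`), `start`, `end` (0-based half-open),
#'   `strand` (`+`/`-`), `reading_offset` (0-2) and `incomplete_stop`
#'   (`none`, `T` or `TA`).
#' @param species,sample_name Organism and specimen labels.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(accession, sequence, features,
                        species = NA_character_, sample_name = NA_character_) {
  sequence <- toupper(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("name", "category", "start", "end", "strand",
              "reading_offset", "incomplete_stop")
  for (col in setdiff(needed, names(features))) {
    features[[col]] <- switch(col,
      strand = "+", reading_offset = 0L, incomplete_stop = "none",
      stop("missing feature column: ", col))
  }
  features <- features[needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$reading_offset <- as.integer(features$reading_offset)
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  g <- structure(
    list(accession = accession, species = species, sample_name = sample_name,
         sequence = sequence, length = nchar(sequence), features = features),
    class = "mito_genome")
  validate_mito_genome(g)
  g
}

validate_mito_genome <- function(g) {
  stopifnot(g$length == nchar(g$sequence))
  f <- g$features
  if (!all(f$category %in% c("PCG", "tRNA", "rRNA", "NCR")))
    stop("unknown feature category")
  wrap <- f$start > f$end
  if (sum(wrap) > 1L) stop("at most one origin-wrapping feature is allowed")
  if (any(f$start < 0L | f$start > g$length | f$end < 0L | f$end > g$length))
    stop("feature coordinates outside [0, length]")
  pcg <- f[f$category == "PCG", , drop = FALSE]
  if (nrow(pcg)) {
    len <- feature_lengths(g)[f$category == "PCG"]
    if (any(len - pcg$reading_offset < 3L))
      stop("PCG shorter than one codon after reading offset: ",
           paste(pcg$name[len - pcg$reading_offset < 3L], collapse = ", "))
  }
  if (any(f$incomplete_stop != "none" & f$category != "PCG"))
    stop("incomplete_stop is only meaningful for PCG features")
  invisible(g)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("mito_genome %s (%s%s): %d bp, %d features (%s)\n",
              x$accession,
              ifelse(is.na(x$species), "?", x$species),
              ifelse(is.na(x$sample_name), "", paste0(" ", x$sample_name)),
              x$length, nrow(x$features),
              paste(sprintf("%d %s", table(x$features$category)[unique(x$features$category)],
                            unique(x$features$category)), collapse = ", ")))
  invisible(x)
}

feature_lengths <- function(g) {
  f <- g$features
  ifelse(f$start <= f$end, f$end - f$start, g$length - f$start + f$end)
}

#' Extract the sequence of one feature
#'
#' Handles origin wrapping (start > end) and minus-strand features
#' (reverse-complemented on extraction).
#'
#' @param g A [mito_genome()].
#' @param i Feature row index.
#' @return Character scalar.
#' @export
feature_seq <- function(g, i) {
  f <- g$features[i, ]
  s <- if (f$start <= f$end) {
    substr(g$sequence, f$start + 1L, f$end)
  } else {  # wraps the origin
    paste0(substr(g$sequence, f$start + 1L, g$length),
           substr(g$sequence, 1L, f$end))
  }
  if (f$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Synthesize NCR features for every inter-gene gap
#'
#' Given a genome whose features are genes only, adds one `NCR` feature per
#' strictly positive gap between consecutive genes (including the gap that
#' wraps the circular origin).  Existing NCR features are left untouched.
#'
#' @param g A [mito_genome()].
#' @return The genome with NCR features added.
#' @export
add_ncr_features <- function(g) {
  genes <- g$features[g$features$category != "NCR", , drop = FALSE]
  if (!nrow(genes)) return(g)
  L <- g$length
  covered <- logical(L)
  # gaps are measured against ALL existing features, so re-running on a
  # genome that already carries NCR features never duplicates them
  f <- g$features
  for (k in seq_len(nrow(f))) {
    if (f$start[k] <= f$end[k]) {
      if (f$end[k] > f$start[k]) covered[(f$start[k] + 1L):f$end[k]] <- TRUE
    } else {
      covered[(f$start[k] + 1L):L] <- TRUE
      if (f$end[k] > 0L) covered[1:f$end[k]] <- TRUE
    }
  }
  if (all(covered)) return(g)
  # uncovered runs on the circle (positions are 0-based: covered[i] is base i-1)
  gap <- which(!covered) - 1L
  brk <- which(diff(gap) != 1L)
  runs <- Map(function(s, e) c(gap[s], gap[e]),
              c(1L, brk + 1L), c(brk, length(gap)))
  # merge a run ending at L-1 with one starting at 0 (circular wrap)
  if (length(runs) > 1L) {
    first <- runs[[1L]]; last <- runs[[length(runs)]]
    if (first[1] == 0L && last[2] == L - 1L && any(covered)) {
      runs[[1L]] <- c(last[1], first[2])
      runs[[length(runs)]] <- NULL
    }
  }
  gene_at_end <- function(pos) {   # gene whose end abuts pos (0-based start of run)
    hit <- which(genes$end %% L == pos %% L)
    if (length(hit)) genes$name[hit[1]] else "origin"
  }
  gene_at_start <- function(pos) { # gene starting right after the run
    hit <- which(genes$start == pos %% L)
    if (length(hit)) genes$name[hit[1]] else "origin"
  }
  ncr <- lapply(runs, function(r) {
    s <- r[1]; e <- (r[2] + 1L)
    data.frame(
      name = sprintf("NCR_%s_%s", gene_at_end(s), gene_at_start(e)),
      category = "NCR", start = s %% L,
      end = if (e >= L && s > r[2]) e %% L else e,
      strand = "+", reading_offset = 0L, incomplete_stop = "none",
      stringsAsFactors = FALSE)
  })
  g$features <- rbind(g$features, do.call(rbind, ncr))
  g$features <- g$features[order(g$features$start, g$features$end), , drop = FALSE]
  rownames(g$features) <- NULL
  g
}

# ---- GenBank flat-file I/O ---------------------------------------------------

parse_gb_location <- function(loc, line = NA) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    # origin-wrapping join(a..L, 1..b) -> start a-1, end b
    return(list(start = rng[[1]][1] - 1L, end = rng[[length(rng)]][2],
                strand = strand))
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc) && !grepl("^[0-9]+$", loc))
    stop("malformed GenBank location at line: ", line)
  xs <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(xs) == 1L) xs <- c(xs, xs)
  list(start = xs[1] - 1L, end = xs[2], strand = strand)
}

#' Read a GenBank flat file into a `mito_genome`
#'
#' Parses LOCUS, the feature table (CDS, tRNA, rRNA, D-loop and misc_feature
#' entries) and the ORIGIN sequence block.  Coordinates are converted to
#' 0-based half-open; `codon_start` becomes `reading_offset`; a
#' `/note="incomplete stop: T"` (or `TA`) qualifier is honoured.  NCR features
#' are synthesized for every inter-gene gap.
#'
#' @param path File path.
#' @param add_ncrs Synthesize NCR features for inter-gene gaps (default TRUE).
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path, add_ncrs = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("malformed record: expected LOCUS at line 1 of ", path)
  accession <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[1])
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) accession <- sub("^ACCESSION\\s+(\\S+).*", "\\1", acc_line[1])
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  species <- if (length(org_line)) sub("^\\s+ORGANISM\\s+", "", org_line[1]) else NA_character_
  samp_line <- grep("/isolate=|/specimen_voucher=", lines, value = TRUE)
  sample_name <- if (length(samp_line))
    sub('.*="?([^"]*)"?.*', "\\1", samp_line[1]) else NA_character_

  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (!length(orig_start)) stop("missing ORIGIN sequence in ", path)
  if (!length(feat_start)) stop("malformed record: missing FEATURES in ", path)

  seq_lines <- lines[(orig_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("missing ORIGIN sequence in ", path)

  flines <- lines[(feat_start[1] + 1L):(orig_start[1] - 1L)]
  keys <- grep("^\\s{5}\\S", flines)
  feats <- list()
  for (k in seq_along(keys)) {
    block <- flines[keys[k]:(if (k < length(keys)) keys[k + 1L] - 1L else length(flines))]
    key <- sub("^\\s+(\\S+).*", "\\1", block[1])
    category <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       "D-loop" = "NCR", misc_feature = "NCR", NULL)
    if (is.null(category)) next
    loc <- sub("^\\s+\\S+\\s+", "", block[1])
    # location may continue on following non-qualifier lines
    j <- 2L
    while (j <= length(block) && !grepl("^\\s+/", block[j])) {
      loc <- paste0(loc, trimws(block[j])); j <- j + 1L
    }
    pos <- parse_gb_location(loc, line = block[1])
    quals <- block[grepl("^\\s+/", block)]
    getq <- function(q) {
      hit <- grep(paste0("^\\s+/", q, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(paste0("^\\s+/", q, '="?([^"]*)"?.*'), "\\1", hit[1])
    }
    name <- getq("gene")
    if (is.na(name)) name <- getq("product")
    if (is.na(name)) name <- key
    offs <- getq("codon_start")
    offs <- if (is.na(offs)) 0L else as.integer(offs) - 1L
    note <- getq("note")
    inc <- "none"
    if (!is.na(note) && grepl("incomplete stop", note))
      inc <- toupper(sub(".*incomplete stop:\\s*(TA?|T).*", "\\1", note))
    feats[[length(feats) + 1L]] <- data.frame(
      name = name, category = category, start = pos$start,
      end = if (pos$end > nchar(sequence)) pos$end - nchar(sequence) else pos$end,
      strand = pos$strand,
      reading_offset = if (category == "PCG") offs else 0L,
      incomplete_stop = if (category == "PCG") inc else "none",
      stringsAsFactors = FALSE)
    # keep wrapped representation: start > end signals origin wrapping
    last <- length(feats)
    if (pos$end > nchar(sequence)) feats[[last]]$end <- pos$end - nchar(sequence)
  }
  if (!length(feats)) stop("malformed record: no usable features in ", path)
  g <- mito_genome(accession, sequence, do.call(rbind, feats),
                   species = species, sample_name = sample_name)
  if (add_ncrs) g <- add_ncr_features(g)
  g
}

#' Write a `mito_genome` as a GenBank flat file
#'
#' Inverse of [read_genbank()]: emits LOCUS/ACCESSION/FEATURES/ORIGIN with
#' 1-based inclusive coordinates, `join()` notation for the origin-wrapping
#' feature and `complement()` for minus-strand features.  NCR features are
#' written as `misc_feature` so the round trip preserves them.
#'
#' @param g A [mito_genome()].
#' @param path Output file path.
#' @export
write_genbank <- function(g, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular", g$accession, g$length),
           sprintf("ACCESSION   %s", g$accession))
  if (!is.na(g$species)) out <- c(out, sprintf("  ORGANISM  %s", g$species))
  out <- c(out, "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", NCR = "misc_feature")
    loc <- if (f$start <= f$end) sprintf("%d..%d", f$start + 1L, f$end)
           else sprintf("join(%d..%d,1..%d)", f$start + 1L, g$length, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf('                     /gene="%s"', f$name))
    if (f$category == "PCG") {
      out <- c(out, sprintf("                     /codon_start=%d", f$reading_offset + 1L))
      if (f$incomplete_stop != "none")
        out <- c(out, sprintf('                     /note="incomplete stop: %s"', f$incomplete_stop))
    }
  }
  if (!is.na(g$sample_name))
    out <- c(out, sprintf('                     /isolate="%s"', g$sample_name))
  out <- c(out, "ORIGIN")
  s <- g$sequence
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# ---- region partitioning -----------------------------------------------------

#' Partition a genome into functional-region concatenates
#'
#' Builds the per-genome concatenates compared across samples: in-frame
#' protein-coding codons (reading offsets applied, terminal complete and
#' incomplete stop codons removed, genes concatenated alphabetically by gene
#' name so partitions are comparable across genomes), tRNA, rRNA and NCR
#' concatenates, the total NCR length, and the P1/P2/P3 site-class labels of
#' the codon concatenate.  Internal stop codons trigger a warning only.
#'
#' @param g A [mito_genome()].
#' @param code A [genetic_code()].
#' @return An object of class `region_partition`: list with `genome_id`,
#'   `pcg_codons`, `trna_concat`, `rrna_concat`, `ncr_concat`,
#'   `ncr_total_len`, `site_class` and the per-gene lists `pcg_by_gene`,
#'   `trna_by_gene`, `rrna_by_gene`, `ncr_by_adjacency`.
#' @export
extract_regions <- function(g, code = genetic_code(13)) {
  f <- g$features
  take <- function(cat) {
    idx <- which(f$category == cat)
    idx <- idx[order(f$name[idx])]
    stats::setNames(lapply(idx, function(i) feature_seq(g, i)), f$name[idx])
  }
  pcg_raw <- take("PCG")
  pcg_idx <- which(f$category == "PCG")
  pcg_idx <- pcg_idx[order(f$name[pcg_idx])]
  pcg <- lapply(seq_along(pcg_raw), function(k) {
    i <- pcg_idx[k]
    s <- substr(pcg_raw[[k]], f$reading_offset[i] + 1L, nchar(pcg_raw[[k]]))
    inc <- f$incomplete_stop[i]
    if (inc != "none") {
      if (toupper(substr(s, nchar(s) - nchar(inc) + 1L, nchar(s))) != inc)
        stop("annotated incomplete stop not found at end of ", f$name[i])
      s <- substr(s, 1L, nchar(s) - nchar(inc))
    }
    if (nchar(s) %% 3L != 0L)
      stop("PCG length not a codon multiple after stop trimming: ", f$name[i])
    last <- toupper(substr(s, nchar(s) - 2L, nchar(s)))
    if (last %in% code$stop_codons) s <- substr(s, 1L, nchar(s) - 3L)
    aa <- translate_cds(s, code)
    if (grepl("\\*", aa))
      warning("internal stop codon(s) in ", f$name[i], " (kept)")
    s
  })
  names(pcg) <- names(pcg_raw)
  pcg_codons <- paste(unlist(pcg), collapse = "")
  trna <- take("tRNA"); rrna <- take("rRNA")
  # NCRs keep genomic order (adjacency identity), not alphabetical
  ncr_idx <- which(f$category == "NCR")
  ncr <- stats::setNames(lapply(ncr_idx, function(i) feature_seq(g, i)), f$name[ncr_idx])
  structure(list(
    genome_id = g$accession,
    pcg_codons = pcg_codons,
    trna_concat = paste(unlist(trna), collapse = ""),
    rrna_concat = paste(unlist(rrna), collapse = ""),
    ncr_concat = paste(unlist(ncr), collapse = ""),
    ncr_total_len = sum(nchar(unlist(ncr))),
    site_class = rep(c("P1", "P2", "P3"), length.out = nchar(pcg_codons)),
    pcg_by_gene = pcg, trna_by_gene = trna, rrna_by_gene = rrna,
    ncr_by_adjacency = ncr
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition %s: %d PCG codons, tRNA %d bp, rRNA %d bp, NCR %d bp\n",
              x$genome_id, nchar(x$pcg_codons) %/% 3L, nchar(x$trna_concat),
              nchar(x$rrna_concat), x$ncr_total_len))
  invisible(x)
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned amino-acid column expands to one codon column; a gap in the
#' protein alignment becomes a three-base gap.  Columns containing a gap or
#' an ambiguity code in either sequence are masked (pairwise deletion).  A
#' trailing incomplete stop codon (`T`/`TA`) on either CDS is dropped before
#' back-translation.
#'
#' @param cds_a,cds_b In-frame coding sequences (stops already removed).
#' @param protein_aln Character vector of two equal-length gapped amino-acid
#'   strings; ungapped, they must equal the translations of the CDSs.
#' @param code A [genetic_code()].
#' @return A list of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors of codon strings, `---` for gaps) and logical `mask`
#'   (TRUE = column excluded).
#' @export
build_codon_alignment <- function(cds_a, cds_b, protein_aln = NULL,
                                  code = genetic_code(13)) {
  trim_partial <- function(s) substr(s, 1L, 3L * (nchar(s) %/% 3L))
  cds_a <- trim_partial(toupper(cds_a)); cds_b <- trim_partial(toupper(cds_b))
  if (is.null(protein_aln)) {
    if (nchar(cds_a) != nchar(cds_b))
      stop("equal-length CDSs required when no protein alignment is given")
    protein_aln <- c(translate_cds(cds_a, code), translate_cds(cds_b, code))
  }
  pa <- strsplit(protein_aln[1], "")[[1]]
  pb <- strsplit(protein_aln[2], "")[[1]]
  if (length(pa) != length(pb)) stop("protein alignment rows differ in length")
  expand <- function(cds, p, who) {
    cods <- codon_split(cds)
    tr <- strsplit(translate_cds(cds, code), "")[[1]]
    res <- character(length(p)); k <- 0L
    for (i in seq_along(p)) {
      if (p[i] == "-") { res[i] <- "---"; next }
      k <- k + 1L
      if (k > length(cods)) stop("protein alignment longer than CDS ", who)
      if (tr[k] != p[i] && p[i] != "X")
        stop(sprintf("translation mismatch in %s at residue %d: %s vs %s",
                     who, k, tr[k], p[i]))
      res[i] <- cods[k]
    }
    if (k != length(cods)) stop("protein alignment shorter than CDS ", who)
    res
  }
  ca <- expand(cds_a, pa, "a"); cb <- expand(cds_b, pb, "b")
  amb <- function(x) grepl("[^ACGT]", x)
  mask <- ca == "---" | cb == "---" | amb(ca) | amb(cb) |
    ca %in% code$stop_codons | cb %in% code$stop_codons
  if (any((ca %in% code$stop_codons | cb %in% code$stop_codons) & ca != "---" & cb != "---"))
    warning("codon columns containing stop codons were masked")
  structure(list(codons_a = ca, codons_b = cb, mask = mask),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d columns (%d masked)\n",
              length(x$codons_a), sum(x$mask)))
  invisible(x)
}

# ---- FASTA and metadata ------------------------------------------------------

#' Read/write plain or aligned FASTA
#'
#' Thin wrappers over Biostrings with 60-column wrapping on output.
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample species genus source`.
#'
#' @param path File path.
#' @return `data.frame` with those columns.
#' @export
read_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "genus")
  if (!all(need %in% names(m)))
    stop("metadata must have columns: sample species genus [source]")
  m
}

#' Enumerate sample pairs with their comparison level
#'
#' @param meta Metadata `data.frame` (see [read_metadata()]).
#' @return `data.frame` with `sample_a`, `sample_b`, `species_a`, `species_b`,
#'   `genus_a`, `genus_b`, `pair_id` (`a|b`, samples sorted) and `pair_level`
#'   (`intraspecies` when the species match, `congeneric` when the species
#'   differ within one genus, otherwise `other`).
#' @export
pair_metadata <- function(meta) {
  if (nrow(meta) < 2) stop("need at least two samples")
  cmb <- utils::combn(seq_len(nrow(meta)), 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  out <- data.frame(
    sample_a = meta$sample[a], sample_b = meta$sample[b],
    species_a = meta$species[a], species_b = meta$species[b],
    genus_a = meta$genus[a], genus_b = meta$genus[b],
    stringsAsFactors = FALSE)
  out$pair_id <- paste(pmin(out$sample_a, out$sample_b),
                       pmax(out$sample_a, out$sample_b), sep = "|")
  out$pair_level <- ifelse(out$species_a == out$species_b, "intraspecies",
                    ifelse(out$genus_a == out$genus_b, "congeneric", "other"))
  out
}
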