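#' Per-adjacency noncoding-region table for a set of genomes sharing gene order
#'
#' One row per inter-gene adjacency per genome, including zero-length and
#' overlap cases (negative length = gene overlap).  Errors if the genomes do
#' not share gene order, naming the first discordant adjacency.
#'
#' @param genomes List of [mito_genome()] objects.
#' @return `data.frame`: `genome_id`, `upstream_gene`, `downstream_gene`,
#'   `length`, `sequence`.
#' @export
ncr_adjacency_table <- function(genomes) {
  orders <- lapply(genomes, function(g) {
    f <- g$features[g$features$category != "NCR", , drop = FALSE]
    f[order(f$start), , drop = FALSE]
  })
  ref <- orders[[1]]$name
  for (k in seq_along(orders)[-1]) {
    other <- orders[[k]]$name
    if (length(other) != length(ref) || any(other != ref)) {
      bad <- if (length(other) != length(ref)) min(length(other), length(ref)) + 1L
             else which(other != ref)[1]
      stop(sprintf("gene order mismatch between %s and %s at adjacency %s-%s",
                   genomes[[1]]$accession, genomes[[k]]$accession,
                   ref[max(bad - 1L, 1L)], ref[min(bad, length(ref))]))
    }
  }
  out <- list()
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]; f <- orders[[k]]
    n <- nrow(f)
    for (i in seq_len(n)) {
      up <- f[i, ]; dn <- f[(i %% n) + 1L, ]
      up_end <- if (up$start <= up$end) up$end else up$end  # wrapped end is post-origin
      dn_start <- dn$start
      len <- if (i < n) dn_start - up_end else (dn_start + g$length - up_end) %% g$length
      if (i == n && up$start > up$end) len <- dn_start - up$end  # upstream wraps origin
      seqs <- if (len > 0) {
        s <- (up_end %% g$length)
        if (s + len <= g$length) substr(g$sequence, s + 1L, s + len)
        else paste0(substr(g$sequence, s + 1L, g$length),
                    substr(g$sequence, 1L, len - (g$length - s)))
      } else ""
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g$accession, upstream_gene = up$name,
        downstream_gene = dn$name, length = len, sequence = seqs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Maximal homopolymer runs in a sequence
#'
#' @param seq DNA string.
#' @param min_len Minimum run length (default 9, the threshold used for the
#'   large T homopolymers at protein-gene starts; 6 catches the shorter runs
#'   seen in other species).
#' @return `data.frame`: `base`, `start` (0-based), `length`; maximal runs only.
#' @export
find_homopolymers <- function(seq, min_len = 9L) {
  stopifnot(min_len >= 2L)
  v <- strsplit(toupper(seq), "")[[1]]
  if (!length(v)) return(data.frame(base = character(0), start = integer(0),
                                    length = integer(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  data.frame(base = r$values[keep],
             start = (ends - r$lengths)[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Classify an NCR length difference across conspecific genomes
#'
#' Compares one adjacency's NCR across genomes and attributes the largest
#' length difference to one of: `identical` (equal lengths, equal sequences),
#' `boundary_shift` (the sequence around the adjacency is the same but the
#' annotated start/stop of a flanking gene moved, typically at a homopolymer
#' run), `true_indel` (a global alignment of the NCRs shows gapped blocks
#' accounting for the difference), or `unclassified` (ambiguous evidence is
#' never guessed at).
#'
#' @param rows Subset of an [ncr_adjacency_table()] for ONE adjacency (one
#'   row per genome).
#' @param genomes The corresponding list of [mito_genome()] objects (for the
#'   flanking-window comparison).
#' @param margin Bases of flanking gene sequence included in the
#'   boundary-shift window (default `max_delta + 15`).
#' @param min_homopolymer Run length that counts as homopolymer involvement.
#' @param min_window_identity Identity required between equal-length windows
#'   to call a pure annotation (boundary) shift.
#' @return One-row `data.frame`: `upstream_gene`, `downstream_gene`,
#'   `max_delta`, `cause`, `homopolymer_involved`, plus the per-genome
#'   lengths collapsed as `lengths`.
#' @export
classify_ncr_difference <- function(rows, genomes = NULL, margin = NULL,
                                    min_homopolymer = 9L,
                                    min_window_identity = 0.9) {
  lens <- rows$length
  res <- data.frame(
    upstream_gene = rows$upstream_gene[1],
    downstream_gene = rows$downstream_gene[1],
    max_delta = max(lens) - min(lens),
    cause = "unclassified", homopolymer_involved = FALSE,
    lengths = paste(lens, collapse = ","), stringsAsFactors = FALSE)
  if (res$max_delta == 0 && length(unique(rows$sequence)) == 1L) {
    res$cause <- "identical"
    return(res)
  }
  i_min <- which.min(lens); i_max <- which.max(lens)
  delta <- res$max_delta
  hp <- function(s) nrow(find_homopolymers(s, min_homopolymer)) > 0
  if (delta == 0) {  # same length, substitutions only
    res$cause <- "unclassified"
    res$homopolymer_involved <- hp(rows$sequence[i_max])
    return(res)
  }
  # boundary-shift check: the window [end of upstream gene - m, start of
  # downstream gene + m] is (nearly) identical although the annotation differs
  if (!is.null(genomes)) {
    m <- if (is.null(margin)) delta + 15L else margin
    win_len <- 2L * m + max(lens)  # sequence-anchored, annotation-independent
    win <- vapply(c(i_min, i_max), function(i) {
      g <- genomes[[match(rows$genome_id[i], vapply(genomes, `[[`, "", "accession"))]]
      f <- g$features
      up <- f[f$name == rows$upstream_gene[i] & f$category != "NCR", ][1, ]
      s <- up$end - m
      idx <- ((s:(s + win_len - 1L)) %% g$length) + 1L
      paste(strsplit(g$sequence, "")[[1]][idx], collapse = "")
    }, "")
    if (nchar(win[1]) == nchar(win[2])) {
      ident <- 1 - p_distance(win[1], win[2])$p_distance
      if (ident >= min_window_identity) {
        res$cause <- "boundary_shift"
        res$homopolymer_involved <- hp(win[2])
        return(res)
      }
    }
  }
  # true-indel check: affine global alignment of the two NCR sequences
  a <- rows$sequence[i_min]; b <- rows$sequence[i_max]
  if (nchar(a) == 0L) {  # insertion against an empty spacer
    res$cause <- "true_indel"
    res$homopolymer_involved <- hp(b)
    return(res)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 4, gapExtension = 1)
  nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
  matched_identity <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  if (matched_identity >= 0.85) {  # clean gapped blocks over a conserved NCR
    res$cause <- "true_indel"
    res$homopolymer_involved <- hp(b)
  }
  res
}

#' NCR architecture report for a conspecific genome set
#'
#' Runs [ncr_adjacency_table()] and [classify_ncr_difference()] over every
#' adjacency and marks "sizeable" differences.
#'
#' @param genomes List of [mito_genome()] objects sharing gene order.
#' @param sizeable_bp Differences above this many bp are sizeable (default 5).
#' @param min_homopolymer Passed to [classify_ncr_difference()].
#' @return `data.frame` with one row per adjacency: flanking genes, per-genome
#'   lengths, `max_delta`, `cause`, `homopolymer_involved`, `sizeable`,
#'   `is_box` (NCR > 20 bp in at least one genome).
#' @export
ncr_report <- function(genomes, sizeable_bp = 5L, min_homopolymer = 9L) {
  tab <- ncr_adjacency_table(genomes)
  key <- paste(tab$upstream_gene, tab$downstream_gene, sep = "~")
  out <- lapply(unique(key), function(k) {
    rows <- tab[key == k, , drop = FALSE]
    r <- classify_ncr_difference(rows, genomes, min_homopolymer = min_homopolymer)
    r$sizeable <- r$max_delta > sizeable_bp
    r$is_box <- any(rows$length > 20L)
    r
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
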