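#' Uncorrected p-distance between two aligned sequences
#'
#' Counts differing sites over comparable sites.  Sites with a gap (`-`) or a
#' non-ACGT ambiguity code in either sequence are excluded (pairwise
#' deletion); comparison is case-insensitive.
#'
#' @param a,b Equal-length (gapped) sequence strings.
#' @param mask Optional logical vector (TRUE = site excluded) or integer
#'   vector of site indices to keep.
#' @param pair_id,region Labels carried into the output record.
#' @return A one-row `data.frame`: `pair_id`, `region`, `p_distance`,
#'   `n_sites`, `n_diff`.
#' @export
p_distance <- function(a, b, mask = NULL, pair_id = NA_character_,
                       region = NA_character_) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) stop("sequences differ in aligned length")
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!is.null(mask)) {
    if (is.logical(mask)) keep <- keep & !mask
    else keep <- keep & seq_along(av) %in% mask
  }
  n <- sum(keep)
  if (n == 0L) stop("zero comparable sites")
  d <- sum(av[keep] != bv[keep])
  data.frame(pair_id = pair_id, region = region,
             p_distance = d / n, n_sites = n, n_diff = d,
             stringsAsFactors = FALSE)
}

#' Region-wise uncorrected distances for one genome pair
#'
#' Emits one record per functional region: all protein-coding positions
#' (`PCG`), first-plus-second (`P12`) and third (`P3`) codon positions,
#' `tRNA`, `rRNA` and (when an alignment is available) `NCR`.  P12/P3 use the
#' site-class labels carried through the codon alignment columns.
#'
#' @param pa,pb [extract_regions()] partitions of the two genomes.
#' @param alignments Optional list with elements `PCG` (a
#'   [build_codon_alignment()] object), `tRNA`, `rRNA`, `NCR` (each a
#'   character vector of two gapped sequences).  Regions whose concatenates
#'   are equal-length are compared directly when no alignment is supplied;
#'   otherwise the region is skipped with a warning.
#' @param pair_id Label for the output records.
#' @return `data.frame` of distance records.
#' @export
region_distance_table <- function(pa, pb, alignments = list(),
                                  pair_id = paste(pa$genome_id, pb$genome_id, sep = "|")) {
  out <- list()
  # --- PCG / P12 / P3 from the codon alignment
  caln <- alignments$PCG
  if (is.null(caln)) {
    if (nchar(pa$pcg_codons) == nchar(pb$pcg_codons)) {
      caln <- list(codons_a = codon_split(pa$pcg_codons),
                   codons_b = codon_split(pb$pcg_codons))
      caln$mask <- grepl("[^ACGT]", caln$codons_a) | grepl("[^ACGT]", caln$codons_b)
    } else {
      warning("PCG concatenates differ in length and no codon alignment supplied; skipped")
    }
  }
  if (!is.null(caln)) {
    keep <- !caln$mask
    sa <- paste(caln$codons_a[keep], collapse = "")
    sb <- paste(caln$codons_b[keep], collapse = "")
    cls <- rep(c("P1", "P2", "P3"), length.out = nchar(sa))
    out$PCG <- p_distance(sa, sb, pair_id = pair_id, region = "PCG")
    out$P12 <- p_distance(sa, sb, mask = cls == "P3", pair_id = pair_id, region = "P12")
    out$P3 <- p_distance(sa, sb, mask = cls != "P3", pair_id = pair_id, region = "P3")
  }
  # --- nucleotide regions
  for (reg in c("tRNA", "rRNA", "NCR")) {
    aln <- alignments[[reg]]
    if (is.null(aln)) {
      sa <- switch(reg, tRNA = pa$trna_concat, rRNA = pa$rrna_concat, NCR = pa$ncr_concat)
      sb <- switch(reg, tRNA = pb$trna_concat, rRNA = pb$rrna_concat, NCR = pb$ncr_concat)
      if (nchar(sa) != nchar(sb)) {
        warning(reg, " concatenates differ in length and no alignment supplied; skipped")
        next
      }
      aln <- c(sa, sb)
    }
    if (nchar(aln[1]) == 0L) next
    out[[reg]] <- p_distance(aln[1], aln[2], pair_id = pair_id, region = reg)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
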