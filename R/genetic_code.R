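#' Genetic code tables for mitochondrial codon analyses
#'
#' Wraps the NCBI translation tables shipped with Biostrings into the small
#' structure the rest of the package consumes: a 64-entry codon-to-amino-acid
#' map, the stop and alternative start codons, and the ordered vector of sense
#' codons.  The default is NCBI table 13, the ascidian mitochondrial code
#' (AGA/AGG -> Gly, ATA -> Met, TGA -> Trp; stops TAA and TAG), which leaves
#' 62 sense codons.
#'
#' @param table_id NCBI translation table number (integer or string).
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector of length 64, DNA
#'   codons), `stop_codons`, `start_codons` and `sense_codons`.
#' @examples
#' code <- genetic_code(13)
#' length(code$sense_codons)  # 62
#' code$codon_to_aa[["AGA"]]  # "G"
#' @export
genetic_code <- function(table_id = 13) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  starts <- attr(map, "alt_init_codons")
  map <- map[order(names(map))]
  stops <- names(map)[map == "*"]
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = map,
      stop_codons = stops,
      start_codons = unique(c("ATG", starts)),
      sense_codons = names(map)[map != "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, "-", length(x$sense_codons),
      "sense codons; stops:", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

#' Translate an in-frame DNA string
#'
#' @param dna Character scalar of A/C/G/T (length divisible by 3).
#' @param code A [genetic_code()] object.
#' @return Character scalar of amino acids (`*` for stops, `X` where the
#'   codon contains an ambiguity).
#' @export
translate_cds <- function(dna, code = genetic_code(13)) {
  stopifnot(nchar(dna) %% 3 == 0)
  if (nchar(dna) == 0L) return("")
  cods <- codon_split(dna)
  aa <- unname(code$codon_to_aa[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split an in-frame DNA string into uppercase codon strings
codon_split <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Classification of all single-nucleotide codon exchanges among sense codons.
# Cached per code table: data.frame with columns i, j (indices into
# sense_codons, i < j), pos (1-3), ts (transition?), syn (synonymous?).
.pair_cache <- new.env(parent = emptyenv())

codon_pair_table <- function(code) {
  key <- as.character(code$table_id)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  sc <- code$sense_codons
  aa <- code$codon_to_aa[sc]
  n <- length(sc)
  mat <- do.call(rbind, strsplit(sc, ""))
  ii <- jj <- pos <- integer(0); ts <- syn <- logical(0)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (p in 1:3) {
    other <- setdiff(1:3, p)
    grp <- paste(mat[, other[1]], mat[, other[2]])
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < 2) next
      cmb <- utils::combn(idx, 2)
      ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ]); pos <- c(pos, rep(p, ncol(cmb)))
      ts <- c(ts, is_ts(mat[cmb[1, ], p], mat[cmb[2, ], p]))
      syn <- c(syn, aa[cmb[1, ]] == aa[cmb[2, ]])
    }
  }
  out <- data.frame(i = ii, j = jj, pos = pos, ts = ts, syn = syn)
  .pair_cache[[key]] <- out
  out
}
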