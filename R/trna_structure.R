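#' Cloverleaf secondary-structure annotation of a tRNA (or tRNA-like) gene
#'
#' Structures are supplied as a per-position annotation string of the same
#' length as the sequence, using one character per position:
#'
#' * `A`/`a` amino-acid acceptor (AA) stem, 5'/3' side
#' * `D`/`d` D-stem, `b` D-loop
#' * `C`/`c` anticodon (AC) stem, `n` AC-loop, `*` anticodon (3 positions)
#' * `T`/`t` T-stem, `u` T-loop
#' * `v` variable loop, `s` spacer, `@` discriminator
#'
#' Stem partners are derived bracket-style: the k-th position of a stem's 5'
#' side pairs with the k-th position from the end of its 3' side.
#'
#' @param sequence DNA/RNA string (T and U are equivalent).
#' @param annotation Same-length annotation string.
#' @param trna_id Identifier carried through outputs.
#' @return Object of class `cloverleaf`: `trna_id`, `sequence`, `element`
#'   (per-position labels), `pairs` (two-column matrix of partner indices),
#'   `anticodon` (integer positions).
#' @export
parse_cloverleaf <- function(sequence, annotation, trna_id = "trna") {
  seqv <- strsplit(toupper(gsub("U", "T", sequence)), "")[[1]]
  annv <- strsplit(annotation, "")[[1]]
  if (length(seqv) != length(annv))
    stop("annotation length differs from sequence length for ", trna_id)
  lab <- c(A = "AA-stem", a = "AA-stem", D = "D-stem", d = "D-stem",
           b = "D-loop", C = "AC-stem", c = "AC-stem", n = "AC-loop",
           `*` = "AC-loop", T = "T-stem", t = "T-stem", u = "T-loop",
           v = "variable-loop", s = "spacer", `@` = "discriminator")
  if (any(!annv %in% names(lab)))
    stop("unknown annotation character(s): ",
         paste(unique(annv[!annv %in% names(lab)]), collapse = " "))
  element <- unname(lab[annv])
  pairs <- NULL
  for (st in c("A", "D", "C", "T")) {
    five <- which(annv == st)
    three <- which(annv == tolower(st))
    if (length(five) != length(three))
      stop("unbalanced ", lab[[st]], " in ", trna_id, ": ",
           length(five), " vs ", length(three), " positions")
    if (length(five) && max(five) > min(three))
      stop("interleaved stem sides (", lab[[st]], ") in ", trna_id)
    if (length(five))
      pairs <- rbind(pairs, cbind(five, rev(three)))
  }
  if (!is.null(pairs) && anyDuplicated(c(pairs)))
    stop("a position participates in more than one pair in ", trna_id)
  anticodon <- which(annv == "*")
  if (length(anticodon) && length(anticodon) != 3L)
    stop("anticodon must span exactly 3 positions in ", trna_id)
  if (length(anticodon)) {
    flank <- c(min(anticodon) - 1L, max(anticodon) + 1L)
    flank <- flank[flank >= 1L & flank <= length(annv)]
    if (!all(element[flank] == "AC-loop"))
      stop("anticodon must be flanked by AC-loop positions in ", trna_id)
  }
  structure(list(trna_id = trna_id, sequence = paste(seqv, collapse = ""),
                 element = element, annotation = annotation,
                 pairs = pairs, anticodon = anticodon),
            class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf("cloverleaf %s: %d nt, %d stem pairs%s\n", x$trna_id,
              nchar(x$sequence), if (is.null(x$pairs)) 0L else nrow(x$pairs),
              if (length(x$anticodon)) paste0(", anticodon at ",
                                              min(x$anticodon)) else ""))
  invisible(x)
}

#' Read a cloverleaf structure fixture file
#'
#' Three-line records: `>id`, sequence, annotation string (see
#' [parse_cloverleaf()] for the alphabet).
#'
#' @param path File path.
#' @return Named list of `cloverleaf` objects.
#' @export
read_cloverleaf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads) || any(diff(heads) != 3L) || length(lines) != max(heads) + 2L)
    stop("expected three-line records (>id / sequence / annotation) in ", path)
  out <- lapply(heads, function(h)
    parse_cloverleaf(lines[h + 1L], lines[h + 2L], trna_id = sub("^>", "", lines[h])))
  stats::setNames(out, vapply(out, `[[`, "", "trna_id"))
}

#' @rdname read_cloverleaf
#' @param structures Named list of `cloverleaf` objects.
#' @export
write_cloverleaf <- function(structures, path) {
  lines <- unlist(lapply(structures, function(s)
    c(paste0(">", s$trna_id), s$sequence, s$annotation)))
  writeLines(lines, path)
  invisible(path)
}

valid_rna_pair <- function(x, y) {
  paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Attribute substitutions between two aligned tRNAs to structural elements
#'
#' Each differing column is attributed to the element of its (gap-stripped)
#' reference position; insertions relative to the reference inherit the
#' element of the nearest preceding reference position.  Stem pairs are
#' classified per event: a pair with at least one differing partner is one
#' stem event; it is compensatory when BOTH partners differ and pairing
#' (Watson-Crick or G-U) holds in both sequences, noncompensatory otherwise.
#'
#' @param a,b Aligned sequences (equal gapped length); `a` is the reference
#'   the annotation describes (its gap-stripped length must equal the
#'   annotation length).
#' @param ann A [parse_cloverleaf()] object.
#' @return List of class `trna_profile`: `subs` and `indels` (named counts
#'   per element), `stem_total`, `compensatory`, `noncompensatory`,
#'   `n_sites` (comparable columns), `n_diff`, `pct_diff`.
#' @export
classify_trna_substitutions <- function(a, b, ann) {
  av <- strsplit(toupper(gsub("U", "T", a)), "")[[1]]
  bv <- strsplit(toupper(gsub("U", "T", b)), "")[[1]]
  if (length(av) != length(bv)) stop("aligned tRNAs differ in length")
  ref_pos <- cumsum(av != "-")
  if (max(ref_pos) != length(ann$element))
    stop("annotation length does not match gap-stripped reference")
  elements <- unique(c(ann$element))
  subs <- stats::setNames(numeric(length(elements)), elements)
  indels <- subs
  col_elem <- ann$element[pmax(ref_pos, 1L)]  # insertions before pos 1 -> first element
  comparable <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  diff_col <- comparable & av != bv
  for (e in elements) {
    sel <- col_elem == e
    subs[e] <- sum(diff_col & sel)
    indels[e] <- sum(sel & ((av == "-") != (bv == "-")))
  }
  # stem events on reference coordinates
  stem_total <- comp <- 0L
  if (!is.null(ann$pairs)) {
    col_of <- match(seq_len(max(ref_pos)), ref_pos)  # ref pos -> alignment column
    for (r in seq_len(nrow(ann$pairs))) {
      i <- col_of[ann$pairs[r, 1]]; j <- col_of[ann$pairs[r, 2]]
      if (is.na(i) || is.na(j) || !comparable[i] || !comparable[j]) next
      di <- av[i] != bv[i]; dj <- av[j] != bv[j]
      if (!di && !dj) next
      stem_total <- stem_total + 1L
      if (di && dj && valid_rna_pair(av[i], av[j]) && valid_rna_pair(bv[i], bv[j]))
        comp <- comp + 1L
    }
  }
  n_sites <- sum(comparable)
  structure(list(
    trna_id = ann$trna_id, subs = subs, indels = indels,
    stem_total = stem_total, compensatory = comp,
    noncompensatory = stem_total - comp,
    n_sites = n_sites, n_diff = sum(diff_col),
    pct_diff = if (n_sites > 0) 100 * sum(diff_col) / n_sites else NA_real_
  ), class = "trna_profile")
}

#' Aggregate tRNA substitution profiles across tRNAs and pairs
#'
#' Sums element-wise substitution counts and reports arm-level percentage
#' shares (T-arm = T-stem + T-loop, and so on), the mean and SD of per-pair
#' shares, and the pooled compensatory fraction of stem events.
#'
#' @param profiles List of [classify_trna_substitutions()] results, or a list
#'   of such lists (one inner list per pair, aggregated per pair first).
#' @return List: `element_counts`, `arm_pct` (named vector over arms,
#'   pooled), `arm_pct_mean`, `arm_pct_sd` (across pairs, when nested),
#'   `stem_total`, `compensatory`, `noncompensatory`,
#'   `compensatory_fraction`.
#' @export
aggregate_trna_profiles <- function(profiles) {
  nested <- length(profiles) > 0 && !inherits(profiles[[1]], "trna_profile")
  groups <- if (nested) profiles else list(profiles)
  arm_of <- c("AA-stem" = "AA-arm", "D-stem" = "D-arm", "D-loop" = "D-arm",
              "AC-stem" = "AC-arm", "AC-loop" = "AC-arm",
              "T-stem" = "T-arm", "T-loop" = "T-arm",
              "variable-loop" = "other", "spacer" = "other",
              "discriminator" = "other")
  arms <- unique(unname(arm_of))
  per_group <- lapply(groups, function(g) {
    counts <- stats::setNames(numeric(length(arms)), arms)
    elem <- numeric(0)
    st <- co <- 0L
    for (p in g) {
      for (e in names(p$subs)) {
        counts[arm_of[[e]]] <- counts[arm_of[[e]]] + p$subs[[e]]
        elem[e] <- (if (is.na(elem[e])) 0 else elem[e]) + p$subs[[e]]
      }
      st <- st + p$stem_total; co <- co + p$compensatory
    }
    list(counts = counts, elem = elem, stem_total = st, compensatory = co)
  })
  counts <- Reduce(`+`, lapply(per_group, `[[`, "counts"))
  pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else counts
  shares <- do.call(rbind, lapply(per_group, function(g)
    if (sum(g$counts) > 0) 100 * g$counts / sum(g$counts) else rep(NA_real_, length(arms))))
  colnames(shares) <- arms
  st <- sum(vapply(per_group, `[[`, 0L, "stem_total"))
  co <- sum(vapply(per_group, `[[`, 0L, "compensatory"))
  elem_all <- lapply(per_group, `[[`, "elem")
  elem_names <- unique(unlist(lapply(elem_all, names)))
  elem_counts <- stats::setNames(numeric(length(elem_names)), elem_names)
  for (e in elem_all) elem_counts[names(e)] <- elem_counts[names(e)] + e
  list(element_counts = elem_counts, arm_pct = pct,
       arm_pct_mean = colMeans(shares, na.rm = TRUE),
       arm_pct_sd = apply(shares, 2, stats::sd, na.rm = TRUE),
       stem_total = st, compensatory = co, noncompensatory = st - co,
       compensatory_fraction = if (st > 0) co / st else NA_real_)
}

#' Screen a tRNA-like structure for features uncommon in functional tRNAs
#'
#' Checks, in order: presence of the T-arm; the single-nucleotide spacer
#' between the D- and AC-arms; a pyrimidine at the semi-invariant position
#' just 5' of the anticodon; pairing at the base of the AA stem; and the
#' number of AA-stem mispairs against a threshold.
#'
#' @param ann A [parse_cloverleaf()] object.
#' @param max_aa_mispairs Mispairs tolerated in the AA stem (default 2).
#' @return `data.frame` with columns `structure_id`, `anomaly`, `detail`
#'   (zero rows when the structure looks canonical).
#' @export
trna_like_anomalies <- function(ann, max_aa_mispairs = 2L) {
  s <- strsplit(ann$sequence, "")[[1]]
  annv <- strsplit(ann$annotation, "")[[1]]
  out <- list()
  flag <- function(an, detail) out[[length(out) + 1L]] <<- data.frame(
    structure_id = ann$trna_id, anomaly = an, detail = detail,
    stringsAsFactors = FALSE)
  if (!any(annv %in% c("T", "t", "u")))
    flag("missing_T_arm", "no T-stem or T-loop positions")
  d3 <- which(annv == "d"); c5 <- which(annv == "C")
  if (length(d3) && length(c5) && min(c5) == max(d3) + 1L)
    flag("missing_D_AC_spacer", "AC stem starts immediately after the D stem")
  if (length(ann$anticodon)) {
    p <- min(ann$anticodon) - 1L
    if (p >= 1L && s[p] %in% c("A", "G"))
      flag("purine_before_anticodon",
           sprintf("%s at position %d, 5' of the anticodon", s[p], p))
  }
  aa <- which(annv == "A")
  if (length(aa) && !is.null(ann$pairs)) {
    aa_pairs <- ann$pairs[ann$pairs[, 1] %in% aa, , drop = FALSE]
    base <- aa_pairs[which.min(aa_pairs[, 1]), ]  # outermost pair = stem base
    if (!valid_rna_pair(s[base[1]], s[base[2]]))
      flag("AA_stem_base_mispair",
           sprintf("%s-%s at positions %d:%d", s[base[1]], s[base[2]],
                   base[1], base[2]))
    mis <- sum(!valid_rna_pair(s[aa_pairs[, 1]], s[aa_pairs[, 2]]))
    if (mis > max_aa_mispairs)
      flag("AA_stem_excess_mispairs",
           sprintf("%d mispairs in the AA stem", mis))
  }
  if (!length(out))
    return(data.frame(structure_id = character(0), anomaly = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-tRNA pairwise divergence across a cohort
#'
#' @param trna_sets Named list (one element per sample) of named character
#'   vectors of aligned tRNA sequences (same tRNA names in each sample).
#' @param pairs Optional two-column matrix/data.frame of sample-name pairs to
#'   compare; all pairs by default.
#' @return `data.frame`: `trna`, `min_pct`, `max_pct`, `mean_pct` over the
#'   compared pairs.
#' @export
per_trna_divergence <- function(trna_sets, pairs = NULL) {
  samples <- names(trna_sets)
  if (length(samples) < 2) stop("need at least two samples")
  if (is.null(pairs)) pairs <- t(utils::combn(samples, 2))
  trnas <- names(trna_sets[[1]])
  out <- lapply(trnas, function(tr) {
    pct <- apply(pairs, 1, function(pr) {
      rec <- p_distance(trna_sets[[pr[1]]][[tr]], trna_sets[[pr[2]]][[tr]])
      100 * rec$p_distance
    })
    data.frame(trna = tr, min_pct = min(pct), max_pct = max(pct),
               mean_pct = mean(pct), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
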