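#' Observed-versus-inferred saturation table
#'
#' One point per pair and region, pairing the uncorrected distance (observed)
#' with the model-inferred substitutions per site: for `P12` and `P3` the
#' expected substitutions per first-plus-second / third codon-position site
#' under the fitted codon model, for `PCG-syn` / `PCG-nonsyn` the dS / dN
#' estimates (observed then being the raw proportions of synonymous /
#' nonsynonymous differences per site).  Synonymous saturation is flagged at
#' dS greater than the threshold (1 substitution/site by default).
#'
#' @param fits Named list of [fit_pairwise()] results (names = pair ids).
#' @param distances `data.frame` of [p_distance()] records covering regions
#'   P12 and P3 for the same pair ids.
#' @param ng Optional named list of [ng86_estimate()] results supplying the
#'   observed synonymous/nonsynonymous proportions (`pS`, `pN`).
#' @param ds_saturation dS threshold for the saturated flag.
#' @return `data.frame`: `pair_id`, `region`, `observed`, `inferred`,
#'   `saturated`.
#' @export
saturation_table <- function(fits, distances, ng = NULL, ds_saturation = 1) {
  out <- list()
  for (pid in names(fits)) {
    fit <- fits[[pid]]
    drec <- distances[distances$pair_id == pid, , drop = FALSE]
    if (!nrow(drec)) { warning("no distance records for pair ", pid); next }
    sat <- !is.na(fit$dS) && fit$dS > ds_saturation
    row <- function(region, obs, inf, s) data.frame(
      pair_id = pid, region = region, observed = obs, inferred = inf,
      saturated = s, stringsAsFactors = FALSE)
    p12 <- drec$p_distance[drec$region == "P12"]
    p3 <- drec$p_distance[drec$region == "P3"]
    if (length(p12)) out[[length(out) + 1L]] <- row("P12", p12, fit$t12, FALSE)
    if (length(p3)) out[[length(out) + 1L]] <- row("P3", p3, fit$t3, sat)
    if (!is.null(ng[[pid]])) {
      out[[length(out) + 1L]] <- row("PCG-syn", ng[[pid]]$pS, fit$dS, sat)
      out[[length(out) + 1L]] <- row("PCG-nonsyn", ng[[pid]]$pN, fit$dN,
                                     !is.na(fit$dN) && fit$dN > ds_saturation)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gap between intraspecies and congeneric nonsynonymous rates
#'
#' Reports the highest intraspecies dN, the lowest congeneric dN, and their
#' difference (the dN gap).  A negative delta is reported as such ("no gap"),
#' never clamped.  Ties are broken by pair id.
#'
#' @param per_pair_dN Named numeric vector of dN values (names = pair ids) or
#'   a `data.frame` with columns `pair_id`, `dN`.
#' @param meta Pair metadata as from [pair_metadata()] (columns `pair_id`,
#'   `pair_level`).
#' @param exclude Character vector of pair ids excluded from the bookkeeping.
#' @return List of class `gap_report`: `max_intra_dN`, `max_intra_pair`,
#'   `min_congeneric_dN`, `min_congeneric_pair`, `delta`, `no_gap`,
#'   `excluded_pairs`, `per_pair_dN` (data.frame with levels).
#' @export
dn_gap_report <- function(per_pair_dN, meta, exclude = character(0)) {
  dn <- if (is.data.frame(per_pair_dN))
    stats::setNames(per_pair_dN$dN, per_pair_dN$pair_id) else per_pair_dN
  lvl <- stats::setNames(meta$pair_level, meta$pair_id)[names(dn)]
  keep <- !(names(dn) %in% exclude) & !is.na(dn) & lvl %in% c("intraspecies", "congeneric")
  dni <- dn[keep & lvl == "intraspecies"]
  dnc <- dn[keep & lvl == "congeneric"]
  if (!length(dni)) stop("no intraspecies pairs left after exclusion")
  if (!length(dnc)) stop("no congeneric pairs left after exclusion")
  ord_i <- order(-dni, names(dni)); ord_c <- order(dnc, names(dnc))
  hi <- dni[ord_i[1]]; lo <- dnc[ord_c[1]]
  structure(list(
    max_intra_dN = unname(hi), max_intra_pair = names(hi),
    min_congeneric_dN = unname(lo), min_congeneric_pair = names(lo),
    delta = unname(lo - hi), no_gap = unname(lo - hi) <= 0,
    excluded_pairs = exclude,
    per_pair_dN = data.frame(pair_id = names(dn), dN = unname(dn),
                             pair_level = unname(lvl),
                             excluded = names(dn) %in% exclude,
                             stringsAsFactors = FALSE)
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("dN gap: max intraspecies %.4g (%s), min congeneric %.4g (%s), delta %.4g%s\n",
              x$max_intra_dN, x$max_intra_pair, x$min_congeneric_dN,
              x$min_congeneric_pair, x$delta,
              if (x$no_gap) " [no gap]" else ""))
  invisible(x)
}

#' Flag intraspecies pairs with intermediate ("ongoing speciation") dN
#'
#' An intraspecies pair is flagged when its dN is at least `threshold_low`
#' times the highest intraspecies dN among pairs of *other* species, and at
#' the same time at least `threshold_high` times lower than the lowest
#' congeneric dN.  The baseline deliberately excludes same-species pairs: the
#' candidate signal of an ongoing split within one species contaminates every
#' pair of that species.
#'
#' @inheritParams dn_gap_report
#' @param threshold_low Minimum ratio over the intraspecies baseline (default 5).
#' @param threshold_high Minimum ratio of the congeneric minimum over the
#'   pair's dN (default 5).
#' @return `data.frame`: `pair_id`, `dN`, `ratio_to_intra`,
#'   `ratio_to_congeneric`, `flagged`; one row per intraspecies pair.
#' @export
flag_intermediate_pairs <- function(per_pair_dN, meta, threshold_low = 5,
                                    threshold_high = 5) {
  dn <- if (is.data.frame(per_pair_dN))
    stats::setNames(per_pair_dN$dN, per_pair_dN$pair_id) else per_pair_dN
  m <- meta[match(names(dn), meta$pair_id), ]
  lvl <- m$pair_level
  dnc <- dn[lvl == "congeneric" & !is.na(dn)]
  if (!length(dnc)) stop("no congeneric pairs")
  min_cong <- min(dnc)
  intra <- which(lvl == "intraspecies" & !is.na(dn))
  if (!length(intra)) stop("no intraspecies pairs")
  out <- lapply(intra, function(i) {
    other <- intra[m$species_a[intra] != m$species_a[i]]
    base <- if (length(other)) max(dn[other]) else NA_real_
    r_in <- if (!is.na(base) && base > 0) dn[i] / base else NA_real_
    r_cg <- if (dn[i] > 0) min_cong / dn[i] else Inf
    data.frame(pair_id = names(dn)[i], dN = unname(dn[i]),
               ratio_to_intra = unname(r_in), ratio_to_congeneric = unname(r_cg),
               flagged = !is.na(r_in) && r_in >= threshold_low && r_cg >= threshold_high,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$pair_id), , drop = FALSE]
}

#' Gap between within-group and between-group distances
#'
#' The barcode-gap statistic for grouped (clade-labelled) distance data:
#' `gap = min(between) - max(within)`, with the attaining pairs reported.
#' Single-member groups contribute no within-group distances.
#'
#' @param distance_matrix Symmetric numeric matrix with dimnames.
#' @param group_labels Vector of group labels, one per row/column.
#' @return List: `max_within`, `max_within_pair`, `min_between`,
#'   `min_between_pair`, `gap`.
#' @export
grouped_distance_gap <- function(distance_matrix, group_labels) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (length(group_labels) != nrow(d))
    stop("one group label per row is required")
  if (length(unique(group_labels)) < 2) stop("need at least 2 groups")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- seq_len(nrow(d))
  cmb <- utils::combn(nrow(d), 2)
  same <- group_labels[cmb[1, ]] == group_labels[cmb[2, ]]
  vals <- d[cbind(cmb[1, ], cmb[2, ])]
  pair_name <- paste(rownames(d)[cmb[1, ]], rownames(d)[cmb[2, ]], sep = "|")
  if (!any(same)) stop("no within-group distances (all groups are singletons)")
  wi <- which(same)[which.max(vals[same])]
  be <- which(!same)[which.min(vals[!same])]
  list(max_within = vals[wi], max_within_pair = pair_name[wi],
       min_between = vals[be], min_between_pair = pair_name[be],
       gap = vals[be] - vals[wi])
}
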