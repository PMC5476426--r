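#' Exclusion policy for homolog-proximity comparisons
#'
#' Bin-level filters applied to anchors and comparison partners. The
#' genome-wide analysis of pairing across conditions excludes the
#' rDNA-carrying chromosomes (whose nucleolar tether splits them) and
#' centromere-containing bins, for which arm length cannot be controlled;
#' the locus-level background additionally requires a minimum centromeric
#' distance and a telomere margin.
#'
#' @param exclude_rdna_chromosomes drop all bins of rDNA-carrying
#'   chromosomes.
#' @param exclude_centromere_bins drop centromere-containing bins.
#' @param min_dcen minimum centromeric distance in bins (locus presets use
#'   3 or 15).
#' @param telomere_margin bins from each chromosome end to drop (locus
#'   preset 1).
#' @param arm_ratio_min minimum shorter/longer arm-length ratio for the
#'   arm-controlled stringency ("within 25%" = 0.75).
#' @param min_comparables minimum nonhomologous comparison partners for an
#'   anchor to count (default 2).
#' @return an `exclusion_policy` list.
#' @export
exclusion_policy <- function(exclude_rdna_chromosomes = FALSE,
                             exclude_centromere_bins = FALSE,
                             min_dcen = 0, telomere_margin = 0,
                             arm_ratio_min = 0.75, min_comparables = 2) {
  stopifnot(min_dcen >= 0, telomere_margin >= 0, arm_ratio_min > 0,
            arm_ratio_min <= 1, min_comparables >= 0)
  structure(list(exclude_rdna_chromosomes = exclude_rdna_chromosomes,
                 exclude_centromere_bins = exclude_centromere_bins,
                 min_dcen = min_dcen, telomere_margin = telomere_margin,
                 arm_ratio_min = arm_ratio_min,
                 min_comparables = min_comparables),
            class = "exclusion_policy")
}

#' @rdname exclusion_policy
#' @export
policy_genomewide <- function() {
  exclusion_policy(exclude_rdna_chromosomes = TRUE,
                   exclude_centromere_bins = TRUE)
}

#' @param min_dcen minimum centromeric distance in bins (15 for the strict
#'   locus background, 3 for the permissive one).
#' @rdname exclusion_policy
#' @export
policy_locus <- function(min_dcen = 15) {
  exclusion_policy(exclude_rdna_chromosomes = TRUE, min_dcen = min_dcen,
                   telomere_margin = 1)
}

control_levels <- c("ALL", "DCEN", "DCEN_ARM")

# per-bin eligibility under a policy (logical over global bins)
eligible_bins <- function(index, policy) {
  nb_per_chrom <- stats::ave(index$chrom_bin, index$chrom, FUN = length)
  from_telomere <- pmin(index$chrom_bin, nb_per_chrom - 1L - index$chrom_bin)
  ok <- !index$masked &
    index$d_cen >= policy$min_dcen &
    from_telomere >= policy$telomere_margin
  if (policy$exclude_rdna_chromosomes) ok <- ok & !index$rdna_chromosome
  if (policy$exclude_centromere_bins) ok <- ok & !index$centromere_bin
  ok
}

arm_comparable <- function(a, b, ratio_min) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  ifelse(hi == 0, TRUE, lo / hi >= ratio_min)
}

#' Build the comparison set of one homologous bin pair
#'
#' The admissible nonhomologous background of an anchor homolog pair
#' (bin1, bin2) consists of intergenome bin pairs sharing exactly one bin
#' with the anchor: (bin1, j) for parent-2 bins j, and (i, bin2) for
#' parent-1 bins i. Pairs inside the homology exclusion zone and bins
#' failing the policy are removed. The `"DCEN"` stringency additionally
#' requires the candidate partner's centromeric distance to equal that of
#' the bin it replaces exactly; `"DCEN_ARM"` further requires the partner's
#' arm length to be within 25% (ratio `>= arm_ratio_min`) of the replaced
#' bin's arm.
#'
#' @param anchor length-2 integer vector: global bin ids (parent 1,
#'   parent 2) of the homolog pair.
#' @param level `"ALL"`, `"DCEN"`, or `"DCEN_ARM"` (nested stringencies).
#' @param policy an [exclusion_policy()].
#' @param index the `bin_index`.
#' @param hmap the [call_homologous_bins()] map.
#' @return data frame `bin1`, `bin2` of admissible comparison pairs.
#' @export
build_comparison_set <- function(anchor, level, policy, index, hmap) {
  level <- match.arg(level, control_levels)
  b1 <- anchor[1]; b2 <- anchor[2]
  elig <- eligible_bins(index, policy)
  d <- index$d_cen
  al <- index$arm_length

  cand_j <- index$bin[index$parent == 2L & elig & index$bin != b2]
  cand_i <- index$bin[index$parent == 1L & elig & index$bin != b1]
  if (level %in% c("DCEN", "DCEN_ARM")) {
    cand_j <- cand_j[d[cand_j + 1L] == d[b2 + 1L]]
    cand_i <- cand_i[d[cand_i + 1L] == d[b1 + 1L]]
  }
  if (level == "DCEN_ARM") {
    cand_j <- cand_j[arm_comparable(al[cand_j + 1L], al[b2 + 1L], policy$arm_ratio_min)]
    cand_i <- cand_i[arm_comparable(al[cand_i + 1L], al[b1 + 1L], policy$arm_ratio_min)]
  }
  out <- rbind(data.frame(bin1 = rep(b1, length(cand_j)), bin2 = cand_j),
               data.frame(bin1 = cand_i, bin2 = rep(b2, length(cand_i))))
  if (nrow(out))
    out <- out[!hmap$excluded[cbind(out$bin1 + 1L, out$bin2 + 1L)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# anchors with their comparable values; shared by profile and bootstrap
comparison_values <- function(cm, hmap, level, policy) {
  idx <- cm$index
  elig <- eligible_bins(idx, policy)
  v <- cm$values
  anchors <- hmap$pairs
  vals <- vector("list", nrow(anchors))
  hom <- rep(NA_real_, nrow(anchors))
  ok_anchor <- logical(nrow(anchors))
  for (a in seq_len(nrow(anchors))) {
    b1 <- anchors$bin1[a]; b2 <- anchors$bin2[a]
    ok_anchor[a] <- elig[b1 + 1L] && elig[b2 + 1L] &&
      cm$valid[b1 + 1L] && cm$valid[b2 + 1L]
    if (!ok_anchor[a]) next
    hom[a] <- v[b1 + 1L, b2 + 1L]
    if (is.na(hom[a])) { ok_anchor[a] <- FALSE; next }
    cs <- build_comparison_set(c(b1, b2), level, policy, idx, hmap)
    cv <- v[cbind(cs$bin1 + 1L, cs$bin2 + 1L)]
    vals[[a]] <- cv[!is.na(cv)]
  }
  list(anchors = anchors, homolog_value = hom, comparables = vals,
       anchor_ok = ok_anchor)
}

#' Per-bin homolog proximity profile
#'
#' For each homologous bin pair, the ratio of its normalized interaction
#' frequency to the median over its admissible nonhomologous comparison
#' pairs. Anchors with fewer than `min_comparables` partners (or filtered
#' bins, or a zero median) are flagged insufficient and excluded from
#' summaries.
#'
#' @param cm a normalized `contact_matrix`.
#' @param hmap a [call_homologous_bins()] map on the same bins.
#' @param level control stringency (see [build_comparison_set()]).
#' @param policy an [exclusion_policy()].
#' @return data frame: `bin1`, `bin2`, `homolog_value`,
#'   `median_comparable`, `n_comparables`, `sufficient`, `ratio`.
#' @export
proximity_profile <- function(cm, hmap, level = "DCEN_ARM",
                              policy = policy_genomewide()) {
  cvals <- comparison_values(cm, hmap, level, policy)
  n <- nrow(cvals$anchors)
  med <- vapply(cvals$comparables, function(x) {
    if (is.null(x) || !length(x)) NA_real_ else stats::median(x)
  }, numeric(1))
  ncomp <- vapply(cvals$comparables, function(x) if (is.null(x)) 0L else length(x),
                  integer(1))
  sufficient <- cvals$anchor_ok & ncomp >= policy$min_comparables &
    !is.na(med) & med > 0
  ratio <- ifelse(sufficient, cvals$homolog_value / med, NA_real_)
  data.frame(cvals$anchors, homolog_value = cvals$homolog_value,
             median_comparable = med, n_comparables = ncomp,
             sufficient = sufficient, ratio = ratio)
}

#' Bootstrap distribution of genome-wide homolog proximity
#'
#' Each replicate compares the sum of normalized interaction frequencies
#' over all sufficient homologous bin pairs to the sum over an equal
#' number of randomly chosen comparable nonhomologous pairs, one drawn
#' (with replacement) per homologous pair. Replicates with a zero
#' denominator are redrawn, keeping the replicate count fixed.
#'
#' @inheritParams proximity_profile
#' @param n_reps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return a `proximity_distribution`: list with `ratios` (length
#'   `n_reps`), `n_anchors`, `level`, `seed`, `n_redrawn`.
#' @export
bootstrap_genomic_proximity <- function(cm, hmap, level = "DCEN_ARM",
                                        policy = policy_genomewide(),
                                        n_reps = 10000, seed = 1) {
  cvals <- comparison_values(cm, hmap, level, policy)
  ncomp <- vapply(cvals$comparables, function(x) if (is.null(x)) 0L else length(x),
                  integer(1))
  use <- cvals$anchor_ok & ncomp >= max(1L, policy$min_comparables)
  if (!any(use)) stop("no sufficient homologous bin pairs to bootstrap")
  vals <- cvals$comparables[use]
  num <- sum(cvals$homolog_value[use])
  set.seed(seed)
  draws <- vapply(vals, function(x) x[sample.int(length(x), n_reps, replace = TRUE)],
                  numeric(n_reps))
  denom <- rowSums(draws)
  n_redrawn <- 0L
  while (any(denom == 0)) {
    bad <- which(denom == 0)
    n_redrawn <- n_redrawn + length(bad)
    redraw <- vapply(vals, function(x) x[sample.int(length(x), length(bad),
                                                    replace = TRUE)],
                     numeric(length(bad)))
    denom[bad] <- rowSums(matrix(redraw, nrow = length(bad)))
  }
  structure(list(ratios = num / denom, n_anchors = sum(use), level = level,
                 seed = seed, n_redrawn = n_redrawn),
            class = "proximity_distribution")
}

#' @export
print.proximity_distribution <- function(x, ...) {
  q <- stats::quantile(x$ratios, c(0.025, 0.5, 0.975))
  cat(sprintf("proximity_distribution (%s): median %.3f [2.5%%: %.3f, 97.5%%: %.3f], %d anchors, %d reps\n",
              x$level, q[2], q[1], q[3], x$n_anchors, length(x$ratios)))
  invisible(x)
}

#' Summary statistics of a proximity distribution
#' @param dist a `proximity_distribution`.
#' @return list with `median`, `q025`, `q975`, `n_anchors`, `n_reps`.
#' @export
summarize_proximity <- function(dist) {
  q <- stats::quantile(dist$ratios, c(0.025, 0.5, 0.975), names = FALSE)
  list(median = q[2], q025 = q[1], q975 = q[3],
       n_anchors = dist$n_anchors, n_reps = length(dist$ratios),
       level = dist$level)
}

#' Pairing strength of one locus against the intergenome background
#'
#' Compares the normalized interaction frequency of a designated homologous
#' bin pair to all intergenome bin pairs passing the policy filters (e.g.
#' both bins at least 15 bins from a centromere, at least 1 bin from a
#' telomere, and not on an rDNA-carrying chromosome). Rank 1 is the
#' strongest interaction; ties take the midrank.
#'
#' @param cm a normalized `contact_matrix`.
#' @param locus length-2 integer vector of global bin ids (parent-1 bin,
#'   parent-2 bin).
#' @param policy an [exclusion_policy()], typically [policy_locus()].
#' @return list with `value`, `rank`, `percentile`, `n_background`.
#' @export
locus_pairing_strength <- function(cm, locus, policy = policy_locus()) {
  idx <- cm$index
  elig <- eligible_bins(idx, policy) & cm$valid
  for (b in locus) {
    if (!elig[b + 1L]) {
      i <- idx[b + 1L, ]
      nb <- sum(idx$chrom == i$chrom)
      reasons <- c(
        if (i$masked || !cm$valid[b + 1L]) "bin masked or row-filtered",
        if (i$d_cen < policy$min_dcen)
          sprintf("d_cen %d < min_dcen %d", i$d_cen, policy$min_dcen),
        if (min(i$chrom_bin, nb - 1L - i$chrom_bin) < policy$telomere_margin)
          "within the telomere margin",
        if (policy$exclude_rdna_chromosomes && i$rdna_chromosome)
          "on an rDNA-carrying chromosome",
        if (policy$exclude_centromere_bins && i$centromere_bin) "centromere bin")
      stop("locus bin ", b, " fails policy filters: ",
           paste(reasons, collapse = "; "))
    }
  }
  v <- cm$values[locus[1] + 1L, locus[2] + 1L]
  if (is.na(v)) stop("locus value is undefined in the matrix")
  b1s <- idx$bin[idx$parent == 1L & elig]
  b2s <- idx$bin[idx$parent == 2L & elig]
  bg_all <- as.vector(cm$values[b1s + 1L, b2s + 1L, drop = FALSE])
  # drop the locus cell itself from its background
  keep <- !(rep(b1s, times = length(b2s)) == locus[1] &
              rep(b2s, each = length(b1s)) == locus[2])
  bg <- bg_all[keep]
  bg <- bg[!is.na(bg)]
  n_gt <- sum(bg > v)
  n_eq <- sum(bg == v)
  rank <- n_gt + n_eq / 2 + 1
  percentile <- 100 * (sum(bg < v) + n_eq / 2) / length(bg)
  list(value = v, rank = rank, percentile = percentile,
       n_background = length(bg))
}
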