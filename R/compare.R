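#' Differential contact map between two conditions
#'
#' Both normalized matrices are restricted to bins valid in both, rescaled
#' so their totals over the shared valid off-diagonal cells are equal (the
#' marginal normalization is not depth-preserving), and subtracted
#' (`a - b`). The result is antisymmetric under swapping the inputs.
#'
#' @param a,b normalized `contact_matrix` objects on the same `bin_index`.
#' @return a `differential_map`: list with `values` (symmetric matrix of
#'   differences, `NA` outside the shared valid set), `valid`, and the
#'   `scale_a`, `scale_b` factors used.
#' @export
differential_map <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"),
            a$normalized, b$normalized,
            n_bins(a$index) == n_bins(b$index))
  valid <- a$valid & b$valid
  if (!any(valid)) stop("validity masks of the two conditions are disjoint")
  va <- a$values; vb <- b$values
  cells <- !is.na(va) & !is.na(vb)
  cells[!valid, ] <- FALSE
  cells[, !valid] <- FALSE
  ta <- sum(va[cells]) / 2
  tb <- sum(vb[cells]) / 2
  target <- (ta + tb) / 2
  sa <- target / ta
  sb <- target / tb
  d <- matrix(NA_real_, nrow(va), ncol(va))
  d[cells] <- sa * va[cells] - sb * vb[cells]
  structure(list(values = d, valid = valid, scale_a = sa, scale_b = sb,
                 index = a$index),
            class = "differential_map")
}

#' @export
print.differential_map <- function(x, ...) {
  cat(sprintf("differential_map: %d/%d shared valid bins, range [%.3g, %.3g]\n",
              sum(x$valid), length(x$valid),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Centromere-distance-stratified interaction shift test for one anchor
#'
#' Tests whether the interaction frequencies of an anchor bin with trans
#' partners shift between two conditions, stratified by the partner bin's
#' centromeric distance: partner bins on other chromosomes (valid in both
#' matrices) are grouped into `n_strata` strata of `d_cen` (0, 1, ...,
#' with the last stratum open-ended), and within each stratum the anchor's
#' normalized interaction values in condition `a` are compared to those in
#' condition `b` by a two-sample Mann-Whitney (Wilcoxon rank-sum) test,
#' Bonferroni-corrected over the strata tested.
#'
#' The matrices are first rescaled to equal totals over shared valid
#' cells, as in [differential_map()], so a global depth difference does
#' not masquerade as a shift.
#'
#' @param a,b normalized `contact_matrix` objects on the same `bin_index`.
#' @param anchor_bin global bin id of the anchor locus.
#' @param n_strata number of centromeric-distance strata (default 9,
#'   matching the correction count of the reference analysis).
#' @param alpha significance level applied after correction (default 0.05).
#' @return a `stratified_test` data frame: per stratum `d_cen_min`,
#'   `d_cen_max` (`Inf` for the open-ended last stratum), `n_partners`,
#'   `statistic`, `p`, `p_adjusted`, `significant`, `tested`,
#'   `median_shift` (median of a-minus-b partner differences).
#' @export
anchor_shift_test <- function(a, b, anchor_bin, n_strata = 9, alpha = 0.05) {
  stopifnot(n_bins(a$index) == n_bins(b$index))
  idx <- a$index
  valid <- a$valid & b$valid
  if (!valid[anchor_bin + 1L]) stop("anchor bin is not valid in both matrices")
  cells <- !is.na(a$values) & !is.na(b$values)
  cells[!valid, ] <- FALSE; cells[, !valid] <- FALSE
  ta <- sum(a$values[cells]) / 2; tb <- sum(b$values[cells]) / 2
  target <- (ta + tb) / 2
  va <- a$values * (target / ta)
  vb <- b$values * (target / tb)

  anchor_chrom <- idx$chrom[anchor_bin + 1L]
  partners <- idx$bin[idx$chrom != anchor_chrom & valid]
  pv_a <- va[anchor_bin + 1L, partners + 1L]
  pv_b <- vb[anchor_bin + 1L, partners + 1L]
  ok <- !is.na(pv_a) & !is.na(pv_b)
  partners <- partners[ok]; pv_a <- pv_a[ok]; pv_b <- pv_b[ok]
  dcen <- idx$d_cen[partners + 1L]
  stratum <- pmin(dcen, n_strata - 1L)

  rows <- lapply(seq_len(n_strata) - 1L, function(s) {
    in_s <- stratum == s
    n <- sum(in_s)
    tested <- n >= 3
    if (tested) {
      wt <- suppressWarnings(stats::wilcox.test(pv_a[in_s], pv_b[in_s]))
      stat <- unname(wt$statistic); p <- wt$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    data.frame(d_cen_min = s, d_cen_max = if (s == n_strata - 1L) Inf else s,
               n_partners = n, statistic = stat, p = p, tested = tested,
               median_shift = if (n) stats::median(pv_a[in_s] - pv_b[in_s]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$tested)
  out$p_adjusted <- pmin(1, out$p * n_tested)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  attr(out, "n_tested") <- n_tested
  attr(out, "alpha") <- alpha
  class(out) <- c("stratified_test", "data.frame")
  out
}
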