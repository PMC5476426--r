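#' Restriction fragment map
#'
#' @param sites named list: per chromosome, the sorted restriction-site
#'   positions (bp, strictly increasing, excluding 0 and the chromosome
#'   end). Fragments are the half-open intervals between consecutive
#'   boundaries `0, sites..., length`.
#' @param genome a [hybrid_genome()] providing chromosome lengths.
#' @return a `fragment_map`: per chromosome, the vector of fragment
#'   boundaries.
#' @export
fragment_map <- function(sites, genome) {
  stopifnot(inherits(genome, "hybrid_genome"))
  missing <- setdiff(names(sites), genome$chrom)
  if (length(missing)) stop("unknown chromosomes in sites: ", paste(missing, collapse = ","))
  fm <- lapply(stats::setNames(genome$chrom, genome$chrom), function(cn) {
    len <- genome$length[genome$chrom == cn]
    s <- sort(unique(as.numeric(sites[[cn]])))
    if (any(s <= 0 | s >= len)) stop("restriction sites must lie strictly inside ", cn)
    c(0, s, len)
  })
  structure(fm, class = "fragment_map", genome = genome)
}

frag_id <- function(fm, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    findInterval(pos[i], fm[[chrom[i]]], rightmost.closed = TRUE)
  }, numeric(1))
}

#' Filter Hi-C ligation pairs
#'
#' Removes, in order: records with positions outside their chromosome, PCR
#' duplicates (identical order-normalized fragment-pair signature),
#' same-fragment pairs, and cis pairs closer than `min_cis_distance`
#' (unligated or invalid ligation products).
#'
#' @param pairs data frame with columns `chrom_1`, `pos_1`, `chrom_2`,
#'   `pos_2` and optional `strand_1`, `strand_2` (see [read_pairs_file()]).
#' @param fragments a [fragment_map()].
#' @param min_cis_distance minimum cis separation in bp (default 1000).
#' @return list with `pairs` (the surviving records) and `report` (named
#'   counts: `n_input`, `n_invalid_position`, `n_duplicate`,
#'   `n_same_fragment`, `n_short_cis`, `n_kept`).
#' @export
filter_pairs <- function(pairs, fragments, min_cis_distance = 1000) {
  genome <- attr(fragments, "genome")
  lim <- stats::setNames(genome$length, genome$chrom)
  report <- c(n_input = nrow(pairs), n_invalid_position = 0L, n_duplicate = 0L,
              n_same_fragment = 0L, n_short_cis = 0L, n_kept = 0L)

  in1 <- pairs$chrom_1 %in% genome$chrom & pairs$pos_1 >= 0 &
    pairs$pos_1 < ifelse(is.na(lim[pairs$chrom_1]), 0, lim[pairs$chrom_1])
  in2 <- pairs$chrom_2 %in% genome$chrom & pairs$pos_2 >= 0 &
    pairs$pos_2 < ifelse(is.na(lim[pairs$chrom_2]), 0, lim[pairs$chrom_2])
  ok <- in1 & in2
  report["n_invalid_position"] <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]

  f1 <- frag_id(fragments, pairs$chrom_1, pairs$pos_1)
  f2 <- frag_id(fragments, pairs$chrom_2, pairs$pos_2)
  k1 <- paste0(pairs$chrom_1, ":", f1)
  k2 <- paste0(pairs$chrom_2, ":", f2)
  sig <- ifelse(k1 <= k2, paste0(k1, "|", k2), paste0(k2, "|", k1))
  dup <- duplicated(sig)
  report["n_duplicate"] <- sum(dup)
  keep <- !dup

  same_frag <- keep & (k1 == k2)
  report["n_same_fragment"] <- sum(same_frag)
  keep <- keep & !same_frag

  short_cis <- keep & pairs$chrom_1 == pairs$chrom_2 &
    abs(pairs$pos_1 - pairs$pos_2) < min_cis_distance
  report["n_short_cis"] <- sum(short_cis)
  keep <- keep & !short_cis

  report["n_kept"] <- sum(keep)
  list(pairs = pairs[keep, , drop = FALSE], report = report)
}

#' Read a pairs-style ligation file
#'
#' Whitespace/tab-separated columns `read_id chrom1 pos1 chrom2 pos2
#' strand1 strand2` (strands optional); `#`-prefixed lines are ignored.
#'
#' @param path file path.
#' @return data frame with columns `read_id`, `chrom_1`, `pos_1`,
#'   `chrom_2`, `pos_2`, `strand_1`, `strand_2`.
#' @export
read_pairs_file <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(d) < 5) stop("pairs file needs at least 5 columns")
  names(d)[1:5] <- c("read_id", "chrom_1", "pos_1", "chrom_2", "pos_2")
  d$strand_1 <- if (ncol(d) >= 6) as.character(d[[6]]) else NA_character_
  d$strand_2 <- if (ncol(d) >= 7) as.character(d[[7]]) else NA_character_
  d[c("read_id", "chrom_1", "pos_1", "chrom_2", "pos_2", "strand_1", "strand_2")]
}

# restriction-site coordinate for one read end: the fragment boundary in the
# direction of the strand ('+' -> downstream boundary, '-' -> upstream), or
# the nearest boundary when no strand is given
assign_site <- function(fm, chrom, pos, strand) {
  vapply(seq_along(chrom), function(i) {
    b <- fm[[chrom[i]]]
    f <- findInterval(pos[i], b, rightmost.closed = TRUE)
    lo <- b[f]; hi <- b[f + 1L]
    s <- strand[i]
    if (is.na(s) || !s %in% c("+", "-")) {
      if (pos[i] - lo <= hi - pos[i]) lo else hi
    } else if (s == "+") hi else lo
  }, numeric(1))
}

#' Bin filtered ligation pairs into a raw contact matrix
#'
#' Each pair increments the symmetric cell of the two bins containing the
#' restriction-site coordinates assigned to its ends.
#'
#' @param pairs filtered pairs (see [filter_pairs()]).
#' @param fragments a [fragment_map()].
#' @param index a `bin_index`.
#' @return a raw `contact_matrix` whose `total_pairs` equals `nrow(pairs)`.
#' @export
bin_contacts <- function(pairs, fragments, index) {
  s1 <- assign_site(fragments, pairs$chrom_1, pairs$pos_1, pairs$strand_1)
  s2 <- assign_site(fragments, pairs$chrom_2, pairs$pos_2, pairs$strand_2)
  b1 <- bin_of_position(index, pairs$chrom_1, s1)
  b2 <- bin_of_position(index, pairs$chrom_2, s2)
  n <- n_bins(index)
  m <- matrix(0, n, n)
  for (i in seq_along(b1)) {
    m[b1[i] + 1L, b2[i] + 1L] <- m[b1[i] + 1L, b2[i] + 1L] + 1
    if (b1[i] != b2[i]) m[b2[i] + 1L, b1[i] + 1L] <- m[b2[i] + 1L, b1[i] + 1L] + 1
  }
  contact_matrix(m, index, normalized = FALSE)
}

#' Contact matrix container
#'
#' @param values symmetric numeric matrix over the global bins of `index`
#'   (for raw matrices, the diagonal counts within-bin pairs once).
#' @param index the `bin_index` the matrix is binned on.
#' @param normalized logical.
#' @param valid per-bin validity; defaults to `!index$masked`.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(values, index, normalized = FALSE, valid = NULL) {
  stopifnot(nrow(values) == n_bins(index), ncol(values) == n_bins(index))
  asym <- suppressWarnings(max(abs(values - t(values)), na.rm = TRUE))
  scale <- suppressWarnings(max(1, abs(values), na.rm = TRUE))
  if (is.finite(asym) && asym > 1e-8 * scale)
    stop("contact matrix must be symmetric")
  if (is.null(valid)) valid <- !index$masked
  total <- sum(values[upper.tri(values, diag = TRUE)], na.rm = TRUE)
  structure(list(values = values, index = index, valid = valid,
                 normalized = normalized, total_pairs = total),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins, %s, %d/%d valid bins, total %.4g\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw",
              sum(x$valid), length(x$valid), x$total_pairs))
  invisible(x)
}

#' Mask repetitive or artifact-prone regions
#'
#' Bins overlapping any mask interval are flagged; their rows and columns
#' are zeroed and the bins drop out of the validity set and total.
#'
#' @param cm a raw `contact_matrix`.
#' @param masks data frame with `chrom`, `start`, `end` (0-based half-open),
#'   or a BED file path.
#' @return the masked `contact_matrix`.
#' @export
apply_masks <- function(cm, masks) {
  if (is.character(masks)) masks <- read_bed(masks)
  if (nrow(masks) == 0) return(cm)
  idx <- cm$index
  hit <- rep(FALSE, n_bins(idx))
  for (i in seq_len(nrow(masks))) {
    ov <- idx$chrom == masks$chrom[i] & idx$start < masks$end[i] & idx$end > masks$start[i]
    hit <- hit | ov
  }
  v <- cm$values
  v[hit, ] <- 0
  v[, hit] <- 0
  idx$masked <- idx$masked | hit
  out <- contact_matrix(v, idx, normalized = cm$normalized)
  out$valid <- out$valid & !hit
  out
}

#' Read a BED file of intervals
#' @param path BED path (chrom, start, end; no header).
#' @return data frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  stats::setNames(d[1:3], c("chrom", "start", "end"))
}

#' Single-pass marginal normalization of a contact matrix
#'
#' Implements, in order: diagonal exclusion (within-bin interactions are
#' undefined), row filtering (bins whose off-diagonal mean over valid bins
#' is below `min_row_mean` are invalidated), then scaling of every entry by
#' the total number of read pairs divided by the row and column sums:
#' `N_ij = C_ij * T / (m_i * m_j)` with marginals `m` and total `T` computed
#' over valid off-diagonal cells (`T` counts each unordered pair once).
#' This is a single pass, not iterative matrix balancing.
#'
#' @param cm a raw `contact_matrix` (after masking, if any).
#' @param min_row_mean row-mean threshold in reads per bin (default 1.0).
#' @return a normalized `contact_matrix`; entries of invalid bins and the
#'   diagonal are `NA`.
#' @export
normalize_matrix <- function(cm, min_row_mean = 1.0) {
  stopifnot(inherits(cm, "contact_matrix"), !cm$normalized)
  v <- cm$values
  diag(v) <- 0
  valid <- cm$valid
  nv <- sum(valid)
  if (nv < 2) stop("insufficient coverage: fewer than two valid bins")
  denom <- pmax(nv - 1L, 1L)  # off-diagonal valid bins per row
  row_mean <- rowSums(v[, valid, drop = FALSE]) / denom
  valid <- valid & (row_mean >= min_row_mean)
  if (sum(valid) < 2)
    stop("insufficient coverage: all bins fall below the row-mean filter")
  vv <- v[valid, valid, drop = FALSE]
  m <- rowSums(vv)
  total <- sum(vv) / 2
  if (any(m == 0)) {
    # a valid bin with zero marginal cannot be scaled; invalidate it
    valid[valid] <- m > 0
    vv <- v[valid, valid, drop = FALSE]
    m <- rowSums(vv)
    total <- sum(vv) / 2
  }
  norm <- matrix(NA_real_, nrow(v), ncol(v))
  norm[valid, valid] <- vv * total / outer(m, m)
  diag(norm) <- NA_real_
  out <- contact_matrix(norm, cm$index, normalized = TRUE, valid = valid)
  out$total_pairs <- total
  out
}
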