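#' Read or write a one-to-one gene homology table
#'
#' TSV with columns `pair_id`, `chrom_1`, `start_1`, `end_1`, `chrom_2`,
#' `start_2`, `end_2`: one row per one-to-one homologous gene pair, with the
#' parent-1 copy in the `_1` columns and the parent-2 copy in `_2`.
#'
#' @param path file path.
#' @return a data frame of homologous gene pairs.
#' @export
read_homology_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("pair_id", "chrom_1", "start_1", "end_1", "chrom_2", "start_2", "end_2")
  if (!all(need %in% names(d)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  if (any(d$start_1 >= d$end_1) || any(d$start_2 >= d$end_2))
    stop("gene intervals must satisfy start < end")
  d
}

#' @param table a homology table data frame.
#' @rdname read_homology_table
#' @export
write_homology_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call homologous bins from gene homology
#'
#' For each parent-1 bin receiving at least one start or end of a homologous
#' gene, the partner is the parent-2 bin receiving the most votes, where each
#' gene casts one vote per endpoint (its start maps start-to-start, its end
#' end-to-end). Vote ties are resolved towards the lowest parent-2 bin
#' coordinate, which is deterministic and input-order independent.
#'
#' Isolated calls, which typically arise from repetitive sequence rather
#' than true synteny, are pruned: a homolog pair is kept only if another
#' pair on the same chromosome pair lies within Chebyshev distance 2 on the
#' (bin1, bin2) grid. An exclusion zone of all intergenome bin pairs within
#' `buffer` bins (Chebyshev, same chromosome pair) of any retained homolog
#' pair is recorded so near-homologous pairs never enter nonhomologous
#' background sets.
#'
#' @param table homology table (see [read_homology_table()]).
#' @param index a `bin_index` from [build_bin_index()].
#' @param prune_isolated drop pairs with no neighbouring pair within 2 bins
#'   (default `TRUE`).
#' @param buffer exclusion-zone radius in bins (default 2).
#' @return A `homology_map`: list with `pairs` (data frame `bin1`, `bin2`,
#'   global bin ids), `excluded` (symmetric logical matrix over all bins;
#'   `TRUE` marks pairs barred from nonhomologous background sets), `pruned`
#'   (pairs removed by isolation pruning) and `buffer`.
#' @export
call_homologous_bins <- function(table, index, prune_isolated = TRUE, buffer = 2) {
  chrom_parent <- tapply(index$parent, index$chrom, unique)
  bad1 <- chrom_parent[table$chrom_1] != 1L
  bad2 <- chrom_parent[table$chrom_2] != 2L
  if (any(is.na(bad1)) || any(is.na(bad2)))
    stop("homology table references chromosomes absent from the bin index")
  if (any(bad1) || any(bad2))
    stop("chrom_1 must be parent-1 and chrom_2 parent-2 chromosomes")
  glen <- attr(index, "genome")
  lim <- stats::setNames(glen$length, glen$chrom)
  if (any(table$end_1 > lim[table$chrom_1]) || any(table$end_2 > lim[table$chrom_2]))
    stop("gene coordinates exceed chromosome length")

  # one vote per gene endpoint: start_1 -> start_2, end_1 -> end_2
  v1 <- c(bin_of_position(index, table$chrom_1, table$start_1),
          bin_of_position(index, table$chrom_1, table$end_1 - 1))
  v2 <- c(bin_of_position(index, table$chrom_2, table$start_2),
          bin_of_position(index, table$chrom_2, table$end_2 - 1))
  votes <- stats::aggregate(n ~ bin1 + bin2,
                            data = data.frame(bin1 = v1, bin2 = v2, n = 1L), FUN = sum)
  # per parent-1 bin: max votes, ties to lowest parent-2 bin id
  votes <- votes[order(votes$bin1, -votes$n, votes$bin2), ]
  pairs <- votes[!duplicated(votes$bin1), c("bin1", "bin2")]
  rownames(pairs) <- NULL

  cb <- index$chrom_bin
  ch <- index$chrom
  pruned <- pairs[0, ]
  if (prune_isolated && nrow(pairs) > 1L) {
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
      same <- ch[pairs$bin1 + 1L] == ch[pairs$bin1[i] + 1L] &
        ch[pairs$bin2 + 1L] == ch[pairs$bin2[i] + 1L]
      d <- pmax(abs(cb[pairs$bin1 + 1L] - cb[pairs$bin1[i] + 1L]),
                abs(cb[pairs$bin2 + 1L] - cb[pairs$bin2[i] + 1L]))
      any(same & d <= 2 & seq_len(nrow(pairs)) != i)
    }, logical(1))
    pruned <- pairs[!keep, , drop = FALSE]
    pairs <- pairs[keep, , drop = FALSE]
  } else if (prune_isolated && nrow(pairs) == 1L) {
    pruned <- pairs
    pairs <- pairs[0, , drop = FALSE]
  }

  n <- nrow(index)
  excluded <- matrix(FALSE, n, n)
  off <- expand.grid(d1 = -buffer:buffer, d2 = -buffer:buffer)
  chrom_start <- tapply(index$bin, index$chrom, min)
  chrom_n <- tapply(index$bin, index$chrom, length)
  for (i in seq_len(nrow(pairs))) {
    b1 <- pairs$bin1[i]; b2 <- pairs$bin2[i]
    c1 <- ch[b1 + 1L]; c2 <- ch[b2 + 1L]
    n1 <- cb[b1 + 1L] + off$d1
    n2 <- cb[b2 + 1L] + off$d2
    ok <- n1 >= 0 & n1 < chrom_n[c1] & n2 >= 0 & n2 < chrom_n[c2]
    g1 <- chrom_start[c1] + n1[ok]
    g2 <- chrom_start[c2] + n2[ok]
    excluded[cbind(g1 + 1L, g2 + 1L)] <- TRUE
    excluded[cbind(g2 + 1L, g1 + 1L)] <- TRUE
  }
  structure(list(pairs = pairs, excluded = excluded, pruned = pruned,
                 buffer = buffer, index_bins = n),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("homology_map: %d homolog bin pairs (%d pruned as isolated), buffer %d bins\n",
              nrow(x$pairs), nrow(x$pruned), x$buffer))
  invisible(x)
}
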