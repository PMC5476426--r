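# brute-force comparison-set oracle: enumerate all intergenome pairs and
# apply the filter rules literally
brute_force_comparison_set <- function(anchor, level, policy, index, hmap) {
  elig <- hybridhic:::eligible_bins(index, policy)
  out <- list()
  for (i in index$bin[index$parent == 1]) {
    for (j in index$bin[index$parent == 2]) {
      shares1 <- i == anchor[1] && j != anchor[2]
      shares2 <- j == anchor[2] && i != anchor[1]
      if (!xor(shares1, shares2)) next
      cand <- if (shares1) j else i
      if (!elig[cand + 1]) next
      if (hmap$excluded[i + 1, j + 1]) next
      if (level %in% c("DCEN", "DCEN_ARM")) {
        if (shares1 && index$d_cen[j + 1] != index$d_cen[anchor[2] + 1]) next
        if (shares2 && index$d_cen[i + 1] != index$d_cen[anchor[1] + 1]) next
      }
      if (level == "DCEN_ARM") {
        ref <- if (shares1) anchor[2] else anchor[1]
        cand <- if (shares1) j else i
        a1 <- index$arm_length[ref + 1]; a2 <- index$arm_length[cand + 1]
        if (max(a1, a2) > 0 && min(a1, a2) / max(a1, a2) < policy$arm_ratio_min) next
      }
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(bin1 = integer(0), bin2 = integer(0)))
  d <- as.data.frame(do.call(rbind, out))
  names(d) <- c("bin1", "bin2")
  d
}

sort_pairs <- function(d) {
  d <- d[order(d$bin1, d$bin2), ]
  rownames(d) <- NULL
  d
}

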