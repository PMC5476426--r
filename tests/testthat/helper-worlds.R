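# small fixture builders shared across test files

# two-chromosome hybrid: one chromosome per parent
tiny_genome <- function(len1 = 96000, len2 = 96000, cen1 = 40000, cen2 = 40000) {
  hybrid_genome(chrom = c("a", "a2"), parent = c(1, 2),
                length = c(len1, len2), centromere = c(cen1, cen2))
}

# default toy hybrid world with its homolog map (memoised: several files use it)
toy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- make_toy_hybrid(synthetic_world_config())
      w$hmap <- call_homologous_bins(w$homology, w$index)
      cache <<- w
    }
    cache
  }
})

# small polymer configuration for fast structure tests
fast_polymer_config <- function(...) {
  polymer_config(n_structures = 10, seed = 4242, ...)
}

# brute-force contact counting oracle for one structure; distances are
# accumulated in the same left-to-right double order as the implementation so
# bonds clamped exactly to the contact threshold compare identically
brute_force_contacts <- function(coords, bead_bin, threshold, nbins) {
  m <- matrix(0, nbins, nbins)
  n <- nrow(coords)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- coords[i, 1] - coords[j, 1]
      dy <- coords[i, 2] - coords[j, 2]
      dz <- coords[i, 3] - coords[j, 3]
      if (sqrt(dx * dx + dy * dy + dz * dz) <= threshold) {
        b1 <- bead_bin[i] + 1L; b2 <- bead_bin[j] + 1L
        m[b1, b2] <- m[b1, b2] + 1
        if (b1 != b2) m[b2, b1] <- m[b2, b1] + 1
      }
    }
  }
  m
}
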