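test_that("bins tile chromosomes exactly and carry correct d_cen annotations", {
  g <- tiny_genome(len1 = 100000, len2 = 100000)
  bi <- build_bin_index(g, 32000)
  # 4 bins per chromosome, last one short
  expect_equal(nrow(bi), 8L)
  a <- bi[bi$chrom == "a", ]
  expect_equal(a$start, c(0, 32000, 64000, 96000))
  expect_equal(a$end, c(32000, 64000, 96000, 100000))
  # tiling conservation for assorted genomes
  for (len in c(64000, 100000, 123456, 320001)) {
    gg <- tiny_genome(len1 = len, len2 = 96000, cen1 = len %/% 2)
    ii <- build_bin_index(gg, 32000)
    sums <- tapply(ii$end - ii$start, ii$chrom, sum)
    expect_equal(as.numeric(sums[c("a", "a2")]), c(len, 96000))
  }
  # centromere at 40000 -> bin 1; d_cen 1,0,1,2
  expect_equal(a$d_cen, c(1L, 0L, 1L, 2L))
  expect_equal(a$centromere_bin, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(a$d_cen <= a$arm_length))
})

test_that("d_cen is invariant under mirroring the chromosome", {
  # centromere mid-bin, so the mirrored position lands mid-bin too
  len <- 320000
  g1 <- tiny_genome(len1 = len, len2 = len, cen1 = 112000, cen2 = 112000)
  g2 <- tiny_genome(len1 = len, len2 = len, cen1 = len - 112000, cen2 = 112000)
  d1 <- build_bin_index(g1, 32000)
  d2 <- build_bin_index(g2, 32000)
  a1 <- d1$d_cen[d1$chrom == "a"]
  a2 <- d2$d_cen[d2$chrom == "a"]
  expect_equal(a1, rev(a2))
})

test_that("genome validation rejects malformed specifications", {
  expect_error(hybrid_genome("a", 1, 1000, 500), "each parent")
  expect_error(hybrid_genome(c("a", "a"), c(1, 2), c(1000, 1000), c(500, 500)),
               "unique")
  expect_error(hybrid_genome(c("a", "b"), c(1, 2), c(1000, 1000), c(1000, 500)),
               "centromere")
  expect_error(
    hybrid_genome(c("a", "b"), c(1, 2), c(10000, 10000), c(5000, 5000),
                  rdna_start = c(4000, NA), rdna_end = c(6000, NA)),
    "centromere")
})

test_that("genome spec TSV round-trips including missing rDNA fields", {
  g <- hybrid_genome(c("a", "b", "a2", "b2"), c(1, 1, 2, 2),
                     length = c(200000, 150000, 200000, 150000),
                     centromere = c(70000, 60000, 70000, 60000),
                     rdna_start = c(100000, NA, 100000, NA),
                     rdna_end = c(132000, NA, 132000, NA))
  p <- tempfile(fileext = ".tsv")
  write_genome_spec(g, p)
  g2 <- read_genome_spec(p)
  expect_equal(as.data.frame(g), as.data.frame(g2))
  bi <- build_bin_index(g, 32000)
  expect_true(all(bi$rdna_chromosome[bi$chrom %in% c("a", "a2")]))
  expect_false(any(bi$rdna_chromosome[bi$chrom %in% c("b", "b2")]))
})

test_that("rDNA arm splitting is off by default and splits arm ids when enabled", {
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(320000, 320000), c(48000, 48000),
                     rdna_start = c(160000, 160000), rdna_end = c(192000, 192000))
  bi0 <- build_bin_index(g, 32000)
  expect_equal(length(unique(bi0$arm_id[bi0$chrom == "a"])), 3L) # L, C, R
  bi1 <- build_bin_index(g, 32000, split_rdna_arms = TRUE)
  a <- bi1[bi1$chrom == "a", ]
  expect_true("a:R2" %in% a$arm_id)
  # distal segment has its own arm length, d_cen unchanged
  expect_equal(a$d_cen, bi0$d_cen[bi0$chrom == "a"])
  distal <- a[a$arm_id == "a:R2", ]
  expect_equal(unique(distal$arm_length), nrow(a) - 1L - 5L)
})

test_that("homologous bins are called by endpoint votes with deterministic ties", {
  g <- tiny_genome()
  bi <- build_bin_index(g, 32000)
  # one gene pair: parent-1 gene [10k,12k) bin 0; parent-2 gene [40k,42k) bin 1
  tab <- data.frame(pair_id = "g1", chrom_1 = "a", start_1 = 10000, end_1 = 12000,
                    chrom_2 = "a2", start_2 = 40000, end_2 = 42000)
  hm <- call_homologous_bins(tab, bi, prune_isolated = FALSE)
  expect_equal(hm$pairs$bin1, 0L)
  expect_equal(hm$pairs$bin2, bi$bin[bi$chrom == "a2"][2])

  # vote tie between parent-2 bins: lowest coordinate wins, input order irrelevant
  tie <- data.frame(
    pair_id = c("t1", "t2"),
    chrom_1 = "a", start_1 = c(1000, 2000), end_1 = c(1500, 2500),
    chrom_2 = "a2", start_2 = c(70000, 40000), end_2 = c(70500, 40500))
  hm1 <- call_homologous_bins(tie, bi, prune_isolated = FALSE)
  hm2 <- call_homologous_bins(tie[2:1, ], bi, prune_isolated = FALSE)
  b2_first <- bi$bin[bi$chrom == "a2"][2] # bin at 32-64k, lower than 64-96k
  expect_equal(hm1$pairs$bin2, b2_first)
  expect_equal(hm1$pairs, hm2$pairs)
})

test_that("isolation pruning removes pairs with no neighbour within 2 bins", {
  w <- toy_world()
  # contiguous diagonal homology: pruning removes nothing
  expect_equal(nrow(w$hmap$pruned), 0L)
  # one pair per parent-1 bin outside the gene-free subtelomeres
  expect_equal(nrow(w$hmap$pairs), sum(w$index$parent == 1 &
                                         !w$index$telomere_margin))

  # a lone off-diagonal pair >2 bins from the diagonal must be pruned
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(352000, 352000), c(112000, 112000))
  bi <- build_bin_index(g, 32000)
  mk <- function(id, b1, b2) data.frame(
    pair_id = id, chrom_1 = "a", start_1 = b1 * 32000 + 100, end_1 = b1 * 32000 + 600,
    chrom_2 = "a2", start_2 = b2 * 32000 + 100, end_2 = b2 * 32000 + 600)
  tab <- rbind(mk("d1", 4, 4), mk("d2", 5, 5), mk("iso", 9, 2))
  hm <- call_homologous_bins(tab, bi, prune_isolated = TRUE)
  expect_equal(nrow(hm$pairs), 2L)
  expect_equal(nrow(hm$pruned), 1L)
  # Chebyshev distance 3 in one coordinate: also pruned
  tab2 <- rbind(mk("d1", 5, 5), mk("far", 8, 9))
  hm2 <- call_homologous_bins(tab2, bi, prune_isolated = TRUE)
  expect_equal(nrow(hm2$pairs), 0L)
})

test_that("exclusion zone contains all intergenome pairs within the buffer", {
  w <- toy_world()
  hm <- w$hmap
  idx <- w$index
  # homolog pairs themselves are excluded
  expect_true(all(hm$excluded[cbind(hm$pairs$bin1 + 1, hm$pairs$bin2 + 1)]))
  # brute-force check on a subsample of pairs
  ch <- idx$chrom; cb <- idx$chrom_bin
  set.seed(1)
  p1 <- sample(idx$bin[idx$parent == 1], 40)
  p2 <- sample(idx$bin[idx$parent == 2], 40)
  for (i in p1) for (j in p2) {
    within <- any(ch[hm$pairs$bin1 + 1] == ch[i + 1] &
                    ch[hm$pairs$bin2 + 1] == ch[j + 1] &
                    pmax(abs(cb[hm$pairs$bin1 + 1] - cb[i + 1]),
                         abs(cb[hm$pairs$bin2 + 1] - cb[j + 1])) <= 2)
    expect_identical(unname(hm$excluded[i + 1, j + 1]), within)
  }
})
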