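# comparison-set oracle helpers live in helper-oracles.R

test_that("comparison sets match brute-force enumeration at every level", {
  w <- toy_world()
  set.seed(3)
  anchors <- w$hmap$pairs[sample.int(nrow(w$hmap$pairs), 8), ]
  for (pol in list(exclusion_policy(), policy_genomewide(),
                   policy_locus(min_dcen = 3))) {
    for (a in seq_len(nrow(anchors))) {
      anchor <- c(anchors$bin1[a], anchors$bin2[a])
      for (lev in c("ALL", "DCEN", "DCEN_ARM")) {
        got <- sort_pairs(build_comparison_set(anchor, lev, pol, w$index, w$hmap))
        want <- sort_pairs(brute_force_comparison_set(anchor, lev, pol,
                                                      w$index, w$hmap))
        expect_equal(got, want,
                     info = sprintf("anchor (%d,%d) level %s", anchor[1],
                                    anchor[2], lev))
      }
    }
  }
})

test_that("comparison-set stringencies are nested", {
  w <- toy_world()
  pol <- exclusion_policy()
  for (a in seq_len(nrow(w$hmap$pairs))) {
    anchor <- c(w$hmap$pairs$bin1[a], w$hmap$pairs$bin2[a])
    n_all <- nrow(build_comparison_set(anchor, "ALL", pol, w$index, w$hmap))
    n_dc <- nrow(build_comparison_set(anchor, "DCEN", pol, w$index, w$hmap))
    n_da <- nrow(build_comparison_set(anchor, "DCEN_ARM", pol, w$index, w$hmap))
    expect_lte(n_da, n_dc)
    expect_lte(n_dc, n_all)
  }
})

test_that("arm-ratio rule admits and rejects per the 25% boundary", {
  expect_true(hybridhic:::arm_comparable(8, 10, 0.75))   # 0.8
  expect_false(hybridhic:::arm_comparable(7, 10, 0.75))  # 0.7
  expect_true(hybridhic:::arm_comparable(0, 0, 0.75))    # degenerate arms
})

# deterministic normalized matrix with a known homolog boost
profile_fixture <- function(beta = 2) {
  w <- toy_world()
  eff <- condition_effects(beta = beta)
  e <- expected_matrix(w, eff)
  n <- nrow(e)
  v <- e * 1e6
  diag(v) <- NA
  cm <- contact_matrix(v, w$index, normalized = TRUE, valid = rep(TRUE, n))
  list(w = w, cm = cm)
}

test_that("proximity profile computes per-anchor ratios and sufficiency", {
  fx <- profile_fixture(beta = 2)
  pr <- proximity_profile(fx$cm, fx$w$hmap, "DCEN", exclusion_policy())
  expect_true(any(pr$sufficient))
  expect_equal(pr$ratio[pr$sufficient],
               pr$homolog_value[pr$sufficient] /
                 pr$median_comparable[pr$sufficient])
  # anchors with fewer than two comparables are insufficient
  expect_true(all(pr$n_comparables[pr$sufficient] >= 2))

  # hand-checked arithmetic on a synthetic 3-comparable case
  v <- fx$cm$values
  a <- which(pr$sufficient)[1]
  cs <- build_comparison_set(c(pr$bin1[a], pr$bin2[a]), "DCEN",
                             exclusion_policy(), fx$w$index, fx$w$hmap)
  med <- median(v[cbind(cs$bin1 + 1, cs$bin2 + 1)], na.rm = TRUE)
  expect_equal(pr$median_comparable[a], med)
})

test_that("bootstrap is seed-stable, scale invariant, and degenerate-exact", {
  fx <- profile_fixture(beta = 2)
  b1 <- bootstrap_genomic_proximity(fx$cm, fx$w$hmap, "DCEN",
                                    n_reps = 200, seed = 5)
  b2 <- bootstrap_genomic_proximity(fx$cm, fx$w$hmap, "DCEN",
                                    n_reps = 200, seed = 5)
  expect_identical(b1$ratios, b2$ratios)
  expect_length(b1$ratios, 200)
  expect_true(all(b1$ratios > 0))

  # multiplying the matrix by k changes nothing
  cm_k <- fx$cm
  cm_k$values <- cm_k$values * 37.5
  bk <- bootstrap_genomic_proximity(cm_k, fx$w$hmap, "DCEN",
                                    n_reps = 200, seed = 5)
  expect_equal(bk$ratios, b1$ratios, tolerance = 1e-12)

  # degenerate case: homolog value 2c, all comparables c -> every rep exactly 2
  w <- toy_world()
  n <- nrow(w$index)
  v <- matrix(1, n, n)
  hp <- w$hmap$pairs
  v[cbind(hp$bin1 + 1, hp$bin2 + 1)] <- 2
  v[cbind(hp$bin2 + 1, hp$bin1 + 1)] <- 2
  diag(v) <- NA
  cm <- contact_matrix(v, w$index, normalized = TRUE, valid = rep(TRUE, n))
  bd <- bootstrap_genomic_proximity(cm, w$hmap, "DCEN_ARM", n_reps = 50, seed = 1)
  expect_equal(bd$ratios, rep(2, 50))
})

test_that("bootstrap mean matches exhaustive enumeration on a tiny anchor set", {
  # two chromosomes per parent, two homolog pairs, hand-set comparables
  g <- hybrid_genome(c("a", "b", "a2", "b2"), c(1, 1, 2, 2),
                     length = rep(160000, 4), centromere = rep(64000, 4))
  bi <- build_bin_index(g, 32000)
  mk <- function(chrom1, chrom2, b) data.frame(
    pair_id = paste0(chrom1, b), chrom_1 = chrom1, start_1 = b * 32000 + 10,
    end_1 = b * 32000 + 400, chrom_2 = chrom2, start_2 = b * 32000 + 10,
    end_2 = b * 32000 + 400)
  tab <- rbind(mk("a", "a2", 0), mk("a", "a2", 1), mk("b", "b2", 0),
               mk("b", "b2", 1))
  hm <- call_homologous_bins(tab, bi, prune_isolated = FALSE)
  n <- nrow(bi)
  set.seed(8)
  v <- matrix(runif(n * n, 0.5, 2), n, n)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- NA
  cm <- contact_matrix(v, bi, normalized = TRUE, valid = rep(TRUE, n))
  pol <- exclusion_policy()
  cv <- hybridhic:::comparison_values(cm, hm, "ALL", pol)
  use <- cv$anchor_ok & sapply(cv$comparables, length) >= 2
  vals <- cv$comparables[use]
  num <- sum(cv$homolog_value[use])
  # exhaustive mean of the rep ratio over all single-draw combinations
  grids <- do.call(expand.grid, vals)
  exact <- mean(num / rowSums(grids))
  b <- bootstrap_genomic_proximity(cm, hm, "ALL", policy = exclusion_policy(),
                                   n_reps = 60000, seed = 2)
  expect_equal(mean(b$ratios), exact, tolerance = 0.01)
})

test_that("locus pairing strength ranks a dominant locus first", {
  fx <- profile_fixture(beta = 1)
  w <- fx$w
  cm <- fx$cm
  spike <- w$registry$spike
  cm$values[spike[1] + 1, spike[2] + 1] <- max(cm$values, na.rm = TRUE) * 10
  cm$values[spike[2] + 1, spike[1] + 1] <- cm$values[spike[1] + 1, spike[2] + 1]
  res <- locus_pairing_strength(cm, spike, policy_locus(min_dcen = 3))
  expect_equal(res$rank, 1)
  expect_equal(res$percentile, 100)
  expect_gt(res$n_background, 100)

  # a locus failing its own filters errors with the violated filter named
  cen_bin <- w$index$bin[w$index$centromere_bin & w$index$parent == 1][1]
  partner <- w$hmap$pairs$bin2[w$hmap$pairs$bin1 == cen_bin]
  expect_error(locus_pairing_strength(cm, c(cen_bin, partner),
                                      policy_locus(min_dcen = 3)),
               "min_dcen")
})

test_that("tied locus values take the midrank", {
  w <- toy_world()
  n <- nrow(w$index)
  v <- matrix(1, n, n)
  diag(v) <- NA
  cm <- contact_matrix(v, w$index, normalized = TRUE, valid = rep(TRUE, n))
  res <- locus_pairing_strength(cm, w$registry$spike, policy_locus(min_dcen = 3))
  # all values tie: midrank = (n_bg)/2 + 1, percentile 50
  expect_equal(res$rank, res$n_background / 2 + 1)
  expect_equal(res$percentile, 50)
})
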