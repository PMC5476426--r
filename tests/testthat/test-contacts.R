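make_frag_genome <- function() {
  g <- hybrid_genome(c("a", "b2"), c(1, 2), c(96000, 96000), c(40000, 40000))
  sites <- list(a = seq(4000, 92000, by = 4000), b2 = seq(4000, 92000, by = 4000))
  list(genome = g, fm = fragment_map(sites, g),
       index = build_bin_index(g, 32000))
}

test_that("pair filtering removes duplicates, same-fragment and short-cis pairs", {
  fg <- make_frag_genome()
  pairs <- data.frame(
    read_id = paste0("r", 1:6),
    chrom_1 = c("a", "a", "a", "a", "a", "a"),
    pos_1 = c(1000, 1000, 5000, 7900, 7950, 50000),
    chrom_2 = c("b2", "b2", "a", "a", "a", "a"),
    pos_2 = c(70000, 70500, 5500, 8400, 8300, 80000),
    strand_1 = NA_character_, strand_2 = NA_character_)
  out <- filter_pairs(pairs, fg$fm)
  # r2 duplicates r1 (same fragment signature); r3 same-fragment; r4 spans a
  # fragment boundary but is under 1 kb (short cis); r5 duplicates r4's
  # signature (removed as a duplicate before the cis rule); r6 is valid
  expect_equal(unname(out$report["n_duplicate"]), 2L)
  expect_equal(unname(out$report["n_same_fragment"]), 1L)
  expect_equal(unname(out$report["n_short_cis"]), 1L)
  expect_equal(unname(out$report["n_kept"]), 2L)
  expect_setequal(out$pairs$read_id, c("r1", "r6"))

  # filter idempotence: refiltering the survivors removes nothing
  out2 <- filter_pairs(out$pairs, fg$fm)
  expect_equal(unname(out2$report["n_kept"]), nrow(out$pairs))
  expect_equal(out2$pairs$read_id, out$pairs$read_id)

  # cis pair 500 bp apart in different fragments is removed
  close_pair <- data.frame(read_id = "c", chrom_1 = "a", pos_1 = 3900,
                           chrom_2 = "a", pos_2 = 4400,
                           strand_1 = NA_character_, strand_2 = NA_character_)
  expect_equal(unname(filter_pairs(close_pair, fg$fm)$report["n_short_cis"]), 1L)

  # out-of-bounds positions get their own counter
  oob <- data.frame(read_id = "o", chrom_1 = "a", pos_1 = 1e6,
                    chrom_2 = "b2", pos_2 = 100,
                    strand_1 = NA_character_, strand_2 = NA_character_)
  expect_equal(unname(filter_pairs(oob, fg$fm)$report["n_invalid_position"]), 1L)
})

test_that("binning counts pairs symmetrically and conserves the total", {
  fg <- make_frag_genome()
  pairs <- data.frame(
    read_id = paste0("p", 1:3), chrom_1 = "a", pos_1 = c(2000, 2100, 2200),
    chrom_2 = "b2", pos_2 = c(70000, 70100, 70300),
    strand_1 = NA_character_, strand_2 = NA_character_)
  cm <- bin_contacts(pairs, fg$fm, fg$index)
  b2_bin <- fg$index$bin[fg$index$chrom == "b2"][3] # 64-96k bin of b2
  expect_equal(cm$values[1, b2_bin + 1], 3)
  expect_equal(cm$values[b2_bin + 1, 1], 3)
  expect_equal(cm$total_pairs, 3)

  # boundary arithmetic with strand-directed site assignment: a '-' end at
  # 31999 takes its fragment start (28000, bin 0), a '+' end at 32000 takes
  # its fragment end (36000, bin 1)
  bp <- data.frame(read_id = "b", chrom_1 = "a", pos_1 = 31999,
                   chrom_2 = "a", pos_2 = 32000,
                   strand_1 = "-", strand_2 = "+")
  cmb <- bin_contacts(bp, fg$fm, fg$index)
  expect_equal(cmb$values[1, 2], 1)
})

test_that("binning agrees with a brute-force per-pair loop on random input", {
  fg <- make_frag_genome()
  set.seed(7)
  n <- 2000
  chroms <- c("a", "b2")
  pairs <- data.frame(
    read_id = paste0("r", seq_len(n)),
    chrom_1 = sample(chroms, n, replace = TRUE),
    pos_1 = sample.int(96000, n) - 1,
    chrom_2 = sample(chroms, n, replace = TRUE),
    pos_2 = sample.int(96000, n) - 1,
    strand_1 = sample(c("+", "-", NA), n, replace = TRUE),
    strand_2 = sample(c("+", "-", NA), n, replace = TRUE))
  cm <- bin_contacts(pairs, fg$fm, fg$index)
  # oracle: assign each end to its site independently, accumulate
  nb <- nrow(fg$index)
  oracle <- matrix(0, nb, nb)
  for (i in seq_len(n)) {
    s1 <- hybridhic:::assign_site(fg$fm, pairs$chrom_1[i], pairs$pos_1[i],
                                  pairs$strand_1[i])
    s2 <- hybridhic:::assign_site(fg$fm, pairs$chrom_2[i], pairs$pos_2[i],
                                  pairs$strand_2[i])
    b1 <- hybridhic:::bin_of_position(fg$index, pairs$chrom_1[i], s1) + 1
    b2 <- hybridhic:::bin_of_position(fg$index, pairs$chrom_2[i], s2) + 1
    oracle[b1, b2] <- oracle[b1, b2] + 1
    if (b1 != b2) oracle[b2, b1] <- oracle[b2, b1] + 1
  }
  expect_equal(cm$values, oracle)
  expect_equal(cm$total_pairs, n)
})

test_that("masking zeroes overlapping bins including boundary-spanning intervals", {
  fg <- make_frag_genome()
  nb <- nrow(fg$index)
  m <- matrix(1, nb, nb); diag(m) <- 0
  cm <- contact_matrix(m, fg$index)
  expect_equal(apply_masks(cm, data.frame(chrom = character(0), start = numeric(0),
                                          end = numeric(0)))$values, cm$values)
  # interval spanning the bin-1/bin-2 boundary of chromosome a masks both bins
  masked <- apply_masks(cm, data.frame(chrom = "a", start = 30000, end = 34000))
  expect_true(all(masked$values[1:2, ] == 0))
  expect_true(all(masked$values[, 1:2] == 0))
  expect_false(any(masked$valid[1:2]))
  expect_true(all(masked$values[3:nb, 3:nb] == cm$values[3:nb, 3:nb]))
})

test_that("normalization reproduces the hand-computed three-bin case", {
  g <- hybrid_genome(c("a", "b2"), c(1, 2), c(96000, 32000), c(40000, 16000))
  bi <- build_bin_index(g, 32000)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2
  m[1, 3] <- m[3, 1] <- 4
  m[2, 3] <- m[3, 2] <- 6
  cm <- contact_matrix(m, bi)
  cm$valid[4] <- FALSE
  nm <- normalize_matrix(cm, min_row_mean = 0)
  # marginals (6,8,10), T = 12: N01 = 2*12/48, N02 = 4*12/60, N12 = 6*12/80
  expect_equal(nm$values[1, 2], 0.5)
  expect_equal(nm$values[1, 3], 0.8)
  expect_equal(nm$values[2, 3], 0.9)
  expect_true(all(is.na(diag(nm$values))))
  expect_equal(nm$values, t(nm$values))
})

test_that("normalization is scale invariant and filters thin rows", {
  w <- toy_world()
  set.seed(42)
  n <- nrow(w$index)
  m <- matrix(rpois(n * n, 8), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  cm <- contact_matrix(m, w$index)
  nm <- normalize_matrix(cm, min_row_mean = 0)
  for (k in c(0.1, 10, 1000)) {
    nk <- normalize_matrix(contact_matrix(m * k, w$index), min_row_mean = 0)
    expect_lt(max(abs(nk$values - nm$values) / pmax(abs(nm$values), 1e-300),
                  na.rm = TRUE), 1e-12)
  }
  # uniform off-diagonal counts: all normalized values equal
  mu <- matrix(5, n, n); diag(mu) <- 0
  mu_n <- normalize_matrix(contact_matrix(mu, w$index))
  expect_equal(max(mu_n$values, na.rm = TRUE), min(mu_n$values, na.rm = TRUE))
  # a starving row falls below the row-mean filter and is invalidated
  m2 <- m
  m2[5, ] <- 0; m2[, 5] <- 0; m2[5, 6] <- m2[6, 5] <- 1
  nm2 <- normalize_matrix(contact_matrix(m2, w$index), min_row_mean = 1)
  expect_false(nm2$valid[5])
  expect_true(all(is.na(nm2$values[5, ])))
  # all-invalid input errors
  expect_error(normalize_matrix(contact_matrix(matrix(0, n, n), w$index)),
               "insufficient coverage")
})

test_that("contact matrices round-trip through COO TSV", {
  w <- toy_world()
  set.seed(9)
  n <- nrow(w$index)
  m <- matrix(rpois(n * n, 3), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_matrix(m, w$index)
  p <- tempfile(fileext = ".tsv")
  write_contact_matrix(cm, p)
  back <- read_contact_matrix(p, w$index)
  expect_equal(back$values, cm$values)
  expect_equal(back$total_pairs, cm$total_pairs)
  expect_false(back$normalized)
  # normalized matrices keep NA structure and validity
  nm <- normalize_matrix(cm)
  p2 <- tempfile(fileext = ".tsv")
  write_contact_matrix(nm, p2)
  back2 <- read_contact_matrix(p2, w$index)
  expect_equal(back2$valid, nm$valid)
  expect_equal(back2$values, nm$values, tolerance = 1e-12)
  expect_true(back2$normalized)
})
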