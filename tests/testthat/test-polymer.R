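test_that("chain specs derive bead counts and special bead indices", {
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(320000, 320000), c(160000, 160000),
                     rdna_start = c(96000, 96000), rdna_end = c(128000, 128000))
  pc <- fast_polymer_config()
  ch <- build_chain_specs(g, pc)
  expect_equal(ch$n_beads, c(100L, 100L))
  expect_equal(ch$cen_bead, c(50L, 50L))
  expect_equal(ch$rdna_from, c(30L, 30L))
  expect_equal(ch$rdna_to, c(40L, 40L))
  # hybrid of the toy world: one chain per chromosome
  w <- toy_world()
  ch2 <- build_chain_specs(w$genome, pc)
  expect_equal(nrow(ch2), nrow(w$genome))
  # chromosome shorter than a bead: single-bead chain, flagged
  g3 <- hybrid_genome(c("s", "s2"), c(1, 2), c(2000, 2000), c(1000, 1000))
  ch3 <- build_chain_specs(g3, pc)
  expect_equal(ch3$n_beads, c(1L, 1L))
  expect_true(all(ch3$single_bead))
})

test_that("nuclear geometry scales with ploidy and size multiplier", {
  expect_equal(nuclear_radius(polymer_config()), 1250)
  expect_equal(nuclear_radius(polymer_config(size_multiplier = 0.8)), 1000)
  expect_equal(nuclear_radius(polymer_config(size_multiplier = 0.64)), 800)
  # ploidy scaling leaves fiber properties alone; the size multiplier
  # rescales every model length (contact threshold excepted)
  p1 <- hybridhic:::geometry_params(polymer_config(), FALSE)
  expect_equal(p1$bead_diameter, 30)
  expect_equal(p1$bond_max, 45)
  p <- hybridhic:::geometry_params(polymer_config(size_multiplier = 0.64), FALSE)
  expect_equal(p$bead_diameter, 30 * 0.64)
  expect_equal(p$bond_max, 45 * 0.64)
  expect_equal(p$shell_thickness, 100 * 1.25 * 0.64)
})

test_that("sampled structures satisfy every constraint and are seed-reproducible", {
  g <- hybrid_genome(c("a", "b", "a2", "b2"), c(1, 1, 2, 2),
                     length = c(256000, 160000, 256000, 160000),
                     centromere = c(96000, 64000, 96000, 64000))
  pc <- fast_polymer_config()
  ch <- build_chain_specs(g, pc)
  st <- sample_structure(ch, pc, seed = 99)
  v <- check_constraints(st, pc)
  expect_true(all(v == 0))
  st2 <- sample_structure(ch, pc, seed = 99)
  expect_identical(st$coords, st2$coords)
  st3 <- sample_structure(ch, pc, seed = 100)
  expect_false(identical(st$coords, st3$coords))
})

test_that("constraint checker counts hand-built violations", {
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(12800, 12800), c(6400, 6400))
  pc <- fast_polymer_config()
  ch <- build_chain_specs(g, pc) # two chains of 4 beads, cen bead 2
  # feasible hand-built toy near the SPB: cen bead (index 2) inside the capture
  # sphere at radius 1160; telomere beads at radii >= 1125 (shell); bonds 35 nm;
  # the two chains offset 40 nm in z so no bead pair overlaps
  mk_chain <- function(z0) {
    rbind(c(1160, -70, z0), c(1160, -35, z0), c(1160, 0, z0), c(1195, 0, z0))
  }
  good <- rbind(mk_chain(0), mk_chain(40))
  vg <- check_constraints(good, pc, chains = ch)
  expect_equal(sum(vg), 0)
  R <- hybridhic:::geometry_params(pc, FALSE)$nuclear_radius

  # overlap: two beads 10 nm apart (diameter 30)
  bad <- good
  bad[6, ] <- bad[2, ] + c(10, 0, 0)
  vb <- check_constraints(bad, pc, chains = ch)
  expect_gte(vb[["overlap"]], 1)

  # centromere bead at nuclear centre with the capture sphere at the envelope
  bad2 <- good
  bad2[3, ] <- c(0, 0, 0)
  vb2 <- check_constraints(bad2, pc, chains = ch)
  expect_gte(vb2[["centromere_tether"]], 1)

  # a bead far outside the nucleus
  bad3 <- good
  bad3[2, ] <- c(2 * R, 0, 0)
  vb3 <- check_constraints(bad3, pc, chains = ch)
  expect_gte(vb3[["outside_nucleus"]], 1)
})

test_that("rDNA beads are confined to the nucleolus and others excluded", {
  # rDNA far enough along the chain that the nucleolar cap (opposite the SPB)
  # is reachable within the bond budget
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(320000, 320000), c(32000, 32000),
                     rdna_start = c(192000, 192000), rdna_end = c(224000, 224000))
  pc <- fast_polymer_config(max_iterations = 20000)
  ch <- build_chain_specs(g, pc)
  expect_true(hybridhic:::chains_have_rdna(ch))
  st <- sample_structure(ch, pc, seed = 5)
  expect_true(all(check_constraints(st, pc) == 0))
  p <- hybridhic:::geometry_params(pc, TRUE)
  rdna_beads <- c(ch$rdna_from[1]:(ch$rdna_to[1] - 1) + 1,
                  sum(ch$n_beads[1]) + ch$rdna_from[2]:(ch$rdna_to[2] - 1) + 1)
  expect_true(all(st$coords[rdna_beads, 1] <= p$nucleolus_plane + 0.5))
  expect_true(all(st$coords[-rdna_beads, 1] >= p$nucleolus_plane - 0.5))
})

test_that("populations are reproducible and 100% constraint-clean", {
  w <- toy_world()
  pc <- fast_polymer_config()
  ch <- build_chain_specs(w$genome, pc)
  pop <- simulate_population(ch, pc)
  expect_length(pop$structures, 10)
  for (s in pop$structures) {
    expect_true(all(check_constraints(s, pc, chains = ch) == 0))
  }
  pop2 <- simulate_population(ch, pc)
  expect_identical(pop$structures, pop2$structures)
})

test_that("contact calling matches the brute-force distance oracle", {
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(64000, 64000), c(32000, 32000))
  pc <- fast_polymer_config(bead_size = 3200) # 20 beads per chain
  ch <- build_chain_specs(g, pc)
  idx <- build_bin_index(g, 32000)
  pop <- simulate_population(ch, pc)
  cm <- population_to_contact_matrix(pop, idx)
  bead_bin <- hybridhic:::bead_bin_assignment(ch, idx)
  oracle <- Reduce(`+`, lapply(pop$structures, brute_force_contacts,
                               bead_bin = bead_bin, threshold = 45, nbins = 4))
  expect_equal(cm$values, oracle)
  # threshold is inclusive at exactly 45 nm and additive over structures
  two <- rbind(c(0, 0, 0), c(45, 0, 0))
  got <- hybridhic:::cpp_population_contacts(list(two, two), c(0L, 1L), 45, 2)
  expect_equal(got[1, 2], 2)
  apart <- rbind(c(0, 0, 0), c(45.001, 0, 0))
  got2 <- hybridhic:::cpp_population_contacts(list(apart), c(0L, 1L), 45, 2)
  expect_equal(got2[1, 2], 0)
})

test_that("cis contact frequency decays with genomic separation", {
  # single long chromosome pair, modest population
  g <- hybrid_genome(c("a", "a2"), c(1, 2), c(640000, 640000), c(320000, 320000))
  pc <- polymer_config(n_structures = 60, seed = 77, base_nuclear_radius = 450)
  ch <- build_chain_specs(g, pc)
  idx <- build_bin_index(g, 32000)
  pop <- simulate_population(ch, pc)
  cm <- population_to_contact_matrix(pop, idx)
  a_bins <- idx$bin[idx$chrom == "a"] + 1
  m <- cm$values[a_bins, a_bins]
  sep <- abs(outer(seq_along(a_bins), seq_along(a_bins), "-"))
  ut <- upper.tri(m)
  expect_lt(cor(sep[ut], m[ut], method = "spearman"), 0)
})

test_that("infeasible configurations are rejected up front", {
  w <- toy_world()
  pc <- fast_polymer_config(base_nuclear_radius = 60)
  ch <- build_chain_specs(w$genome, pc)
  expect_error(sample_structure(ch, pc, seed = 1), "infeasible")
})
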