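#' Configuration of the synthetic hybrid Hi-C world
#'
#' Defines a toy hybrid diploid genome (parent 2 mirrors parent 1) and the
#' designated special loci used by condition experiments: a mid-arm
#' pairing-spike homolog pair (emulating a condition-specific locus pairing
#' phenomenon) and a pericentromeric relocalization anchor bin (emulating
#' an inducible gene moving away from the centromere cluster).
#'
#' The default karyotype (6 chromosomes per parent, 10-24 bins each, with
#' off-centre centromeres) is designed so that every chromosome arm has a
#' close length match (ratio >= 0.75) on a *different* chromosome, as in the
#' budding-yeast karyotype whose arms form a near-continuum of lengths.
#' Without that property the arm-length control has nothing comparable to
#' match against and retains arm-geometry signal even at full stringency.
#'
#' @param chrom_lengths parent-1 chromosome lengths in bp.
#' @param centromeres centromere positions in bp.
#' @param bin_size bin width in bp (default 32000).
#' @param rdna_chrom index of the rDNA-carrying chromosome in
#'   `chrom_lengths`, or `NA` for none; the rDNA interval is placed
#'   mid-way along the longer arm.
#' @param genes_per_bin homologous gene density per bin (default 1).
#' @param subtelomere_gene_free bins at each chromosome end left without
#'   homologous genes (default 1): one-to-one orthologs are rare in real
#'   subtelomeres, so telomere bins rarely become homolog anchors.
#' @param spike_dcen centromeric distance (bins) of the designated spike
#'   locus, placed on the longer arm of the median-length chromosome
#'   (default 6) -- the reference phenomenon sits on a mid-sized
#'   chromosome, and mid-sized chromosomes are also typical of the
#'   intergenome background their pairing is ranked against.
#' @param anchor_dcen centromeric distance of the relocalization anchor
#'   bin, placed on the parent-2 copy of the second chromosome (default 1).
#' @param seed integer seed recorded in the config.
#' @return a `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(chrom_lengths = c(320000, 384000, 512000,
                                                     576000, 704000, 768000),
                                   centromeres = c(112000, 144000, 208000,
                                                   240000, 304000, 336000),
                                   bin_size = 32000, rdna_chrom = NA_integer_,
                                   genes_per_bin = 1, subtelomere_gene_free = 1,
                                   spike_dcen = 6,
                                   anchor_dcen = 1, seed = 1) {
  stopifnot(length(chrom_lengths) == length(centromeres),
            all(chrom_lengths >= 2 * bin_size), genes_per_bin >= 1,
            subtelomere_gene_free >= 0)
  structure(list(chrom_lengths = chrom_lengths, centromeres = centromeres,
                 bin_size = bin_size, rdna_chrom = rdna_chrom,
                 genes_per_bin = genes_per_bin,
                 subtelomere_gene_free = subtelomere_gene_free,
                 spike_dcen = spike_dcen,
                 anchor_dcen = anchor_dcen, seed = seed),
            class = "synthetic_world_config")
}

#' Synthetic yeast-shaped hybrid world
#'
#' A [synthetic_world_config()] whose parent-1 karyotype approximates the
#' shape of the budding-yeast reference assembly (16 chromosomes, lengths
#' and centromere positions rounded to the nearest kb, the rDNA-carrying
#' twelfth chromosome flagged); parent 2 mirrors parent 1. This synthetic
#' stand-in reproduces the karyotype *shape* — the near-continuum of arm
#' lengths that gives the arm-length control its comparison partners — and
#' is the default genome of the polymer-null experiments. It is not a
#' reference-accurate coordinate set.
#'
#' @param seed integer seed stored in the config.
#' @return a `synthetic_world_config`.
#' @export
yeast_shaped_config <- function(seed = 1) {
  lens <- c(230000, 813000, 317000, 1532000, 577000, 270000, 1091000,
            563000, 440000, 746000, 667000, 1078000, 924000, 784000,
            1091000, 948000)
  cens <- c(151000, 238000, 114000, 450000, 152000, 149000, 497000, 106000,
            356000, 436000, 440000, 151000, 268000, 629000, 327000, 556000)
  synthetic_world_config(chrom_lengths = lens, centromeres = cens,
                         rdna_chrom = 12L, seed = seed)
}

#' Build the toy hybrid world
#'
#' @param config a [synthetic_world_config()].
#' @return a `synthetic_world` list: `genome` ([hybrid_genome()]), `index`
#'   (`bin_index`), `homology` (gene table with 1:1 diagonal homology),
#'   `registry` (global bin ids: `spike` = c(parent-1 bin, parent-2 bin),
#'   `anchor` = anchor bin), and `config`.
#' @export
make_toy_hybrid <- function(config) {
  nc <- length(config$chrom_lengths)
  chrom1 <- paste0("chr", seq_len(nc))
  chrom2 <- paste0("chr", seq_len(nc), "_p2")
  rs <- rep(NA_real_, nc); re <- rep(NA_real_, nc)
  if (!is.na(config$rdna_chrom)) {
    i <- config$rdna_chrom
    len <- config$chrom_lengths[i]; cen <- config$centromeres[i]
    # rDNA mid-way along the longer arm, one bin wide
    if (len - cen >= cen) {
      mid <- cen + (len - cen) %/% 2
    } else mid <- cen %/% 2
    rs[i] <- (mid %/% config$bin_size) * config$bin_size
    re[i] <- rs[i] + config$bin_size
  }
  genome <- hybrid_genome(
    chrom = c(chrom1, chrom2), parent = rep(c(1L, 2L), each = nc),
    length = rep(config$chrom_lengths, 2),
    centromere = rep(config$centromeres, 2),
    rdna_start = rep(rs, 2), rdna_end = rep(re, 2)
  )
  index <- build_bin_index(genome, config$bin_size)

  # one-to-one diagonal homology: genes_per_bin gene pairs per bin
  gene_rows <- list()
  margin <- config$subtelomere_gene_free %||% 1
  for (ci in seq_len(nc)) {
    nb <- as.integer(ceiling(config$chrom_lengths[ci] / config$bin_size))
    for (b in seq_len(nb) - 1L) {
      if (b < margin || b >= nb - margin) next # gene-free subtelomeres
      width <- min(config$bin_size, config$chrom_lengths[ci] - b * config$bin_size)
      for (g in seq_len(config$genes_per_bin)) {
        off <- (g - 0.5) / config$genes_per_bin * width
        s <- b * config$bin_size + floor(off)
        e <- min(s + 500, config$chrom_lengths[ci])
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(pair_id = sprintf("%s_b%d_g%d", chrom1[ci], b, g),
                     chrom_1 = chrom1[ci], start_1 = s, end_1 = e,
                     chrom_2 = chrom2[ci], start_2 = s, end_2 = e,
                     stringsAsFactors = FALSE)
      }
    }
  }
  homology <- do.call(rbind, gene_rows)

  mid <- order(config$chrom_lengths)[ceiling((nc + 1) / 2)]
  cen_bin_mid <- config$centromeres[mid] %/% config$bin_size
  nb_mid <- ceiling(config$chrom_lengths[mid] / config$bin_size)
  # spike on the longer arm of the median-length chromosome
  spike_cb <- if (nb_mid - 1 - cen_bin_mid >= cen_bin_mid)
    cen_bin_mid + config$spike_dcen else cen_bin_mid - config$spike_dcen
  s1 <- index$bin[index$chrom == chrom1[mid] & index$chrom_bin == spike_cb]
  s2 <- index$bin[index$chrom == chrom2[mid] & index$chrom_bin == spike_cb]
  a_chrom <- chrom2[min(2L, nc)]
  a_cb <- config$centromeres[min(2L, nc)] %/% config$bin_size + config$anchor_dcen
  anchor <- index$bin[index$chrom == a_chrom & index$chrom_bin == a_cb]

  structure(list(genome = genome, index = index, homology = homology,
                 registry = list(spike = c(s1, s2), anchor = anchor),
                 config = config),
            class = "synthetic_world")
}

#' Condition effect parameters of the generator
#'
#' @param beta genome-wide homolog pairing boost: multiplier on every
#'   homologous bin pair (1 = no pairing beyond nuclear architecture).
#' @param gamma locus-specific pairing spike multiplier applied to the
#'   designated spike pair (on top of `beta`).
#' @param rho pericentromeric retention factor for the relocalization
#'   anchor: its trans entries with partner `d_cen < kappa` are multiplied
#'   by `rho` (< 1 = depletion, i.e. movement away from the centromere
#'   cluster).
#' @param alpha intra-chromosomal distance-decay exponent (contact
#'   frequency ~ separation^-alpha; default 1).
#' @param kappa centromere-clustering decay scale in bins (default 1:
#'   enrichment confined to the immediate pericentromere at 32 kb resolution).
#' @param tau telomere-clustering bonus for bin pairs both in the telomere
#'   margin (default 0.3).
#' @param trans_base baseline trans contact weight (default 1).
#' @param cis_trans_ratio target ratio of total cis to total trans
#'   expected mass (default 1).
#' @param depth expected total read pairs (default 1e6).
#' @return a `condition_effects` list.
#' @export
condition_effects <- function(beta = 1, gamma = 1, rho = 1, alpha = 1,
                              kappa = 1, tau = 0.3, trans_base = 1,
                              cis_trans_ratio = 1, depth = 1e6) {
  stopifnot(beta >= 1, gamma >= 1,
            rho > 0, rho <= 1, alpha > 0, kappa > 0, tau >= 0,
            trans_base > 0, depth > 0)
  structure(list(beta = beta, gamma = gamma, rho = rho, alpha = alpha,
                 kappa = kappa, tau = tau, trans_base = trans_base,
                 cis_trans_ratio = cis_trans_ratio, depth = depth),
            class = "condition_effects")
}

#' Expected contact matrix of the generative model
#'
#' Cis cells follow a power-law distance decay `A * s^-alpha` (s = bin
#' separation >= 1); trans cells carry a baseline plus a
#' centromere-clustering term decaying with the summed centromeric
#' distances of the two bins and a telomere-clustering bonus when both
#' bins lie in the telomere margin (the Rabl signature). `A` is set so the
#' cis/trans mass ratio matches the configured target. The matrix is then
#' Sinkhorn-balanced to equal marginals (unless `balance = FALSE`), so the
#' injected effects below are defined on the normalized scale the analysis
#' operates on, and finally the homologous-pair boost `beta`, the spike
#' multiplier `gamma` and the anchor depletion `rho` are applied.
#'
#' @param world a [make_toy_hybrid()] world.
#' @param effects a [condition_effects()].
#' @param balance Sinkhorn-balance the structural matrix before applying
#'   effects (default `TRUE`).
#' @return numeric matrix of expected values (zero diagonal); the scale is
#'   arbitrary ([sample_matrix()] rescales to the requested depth).
#' @export
expected_matrix <- function(world, effects, balance = TRUE) {
  idx <- world$index
  n <- nrow(idx)
  same_chrom <- outer(idx$chrom, idx$chrom, "==")
  sep <- abs(outer(idx$chrom_bin, idx$chrom_bin, "-"))
  dsum <- outer(idx$d_cen, idx$d_cen, "+")
  telo <- outer(idx$telomere_margin, idx$telomere_margin, "&")

  cis <- ifelse(same_chrom & sep >= 1, sep^(-effects$alpha), 0)
  trans <- ifelse(!same_chrom,
                  effects$trans_base *
                    (1 + exp(-dsum / effects$kappa) + effects$tau * telo), 0)
  A <- effects$cis_trans_ratio * sum(trans) / sum(cis)
  e <- A * cis + trans
  diag(e) <- 0

  if (balance) e <- sinkhorn_balance(e)

  hp <- identity_homolog_pairs(idx)
  e[cbind(hp$bin1 + 1L, hp$bin2 + 1L)] <- e[cbind(hp$bin1 + 1L, hp$bin2 + 1L)] * effects$beta
  e[cbind(hp$bin2 + 1L, hp$bin1 + 1L)] <- e[cbind(hp$bin2 + 1L, hp$bin1 + 1L)] * effects$beta
  sp <- world$registry$spike
  e[sp[1] + 1L, sp[2] + 1L] <- e[sp[1] + 1L, sp[2] + 1L] * effects$gamma
  e[sp[2] + 1L, sp[1] + 1L] <- e[sp[2] + 1L, sp[1] + 1L] * effects$gamma
  an <- world$registry$anchor
  dep <- which(!same_chrom[an + 1L, ] & idx$d_cen < effects$kappa)
  e[an + 1L, dep] <- e[an + 1L, dep] * effects$rho
  e[dep, an + 1L] <- e[dep, an + 1L] * effects$rho
  e
}

# identity homolog pairing of a mirrored hybrid (parent-2 bin = parent-1
# bin shifted by the parent-1 bin count)
identity_homolog_pairs <- function(index) {
  b1 <- index$bin[index$parent == 1L]
  b2 <- index$bin[index$parent == 2L]
  stopifnot(length(b1) == length(b2))
  data.frame(bin1 = b1, bin2 = b2)
}

sinkhorn_balance <- function(e, max_iter = 500, tol = 1e-10) {
  for (i in seq_len(max_iter)) {
    r <- rowSums(e)
    if (max(r) == 0) stop("cannot balance an empty matrix")
    if (max(abs(r / mean(r) - 1)) < tol) break
    s <- sqrt(r / mean(r))
    e <- e / outer(s, s)
  }
  e
}

#' Sample a Poisson count matrix from an expected matrix
#'
#' Upper-triangle cells are drawn independently Poisson with means scaled
#' to the requested total depth, then symmetrized.
#'
#' @param expected expected-value matrix (see [expected_matrix()]).
#' @param depth expected total pair count.
#' @param seed integer seed.
#' @param index the `bin_index` of the world.
#' @return a raw `contact_matrix`.
#' @export
sample_matrix <- function(expected, depth, seed, index) {
  n <- nrow(expected)
  ut <- upper.tri(expected)
  mu <- expected[ut] / sum(expected[ut]) * depth
  set.seed(seed)
  counts <- stats::rpois(length(mu), mu)
  m <- matrix(0, n, n)
  m[ut] <- counts
  m <- m + t(m)
  contact_matrix(m, index, normalized = FALSE)
}

#' Ground truth record of a generated condition
#'
#' @param effects a [condition_effects()].
#' @param world a [make_toy_hybrid()] world.
#' @return list echoing the injected `beta`, `gamma`, `rho` and the
#'   special-locus identities, for parameter-recovery tests.
#' @export
ground_truth <- function(effects, world) {
  list(beta = effects$beta, gamma = effects$gamma, rho = effects$rho,
       spike = world$registry$spike, anchor = world$registry$anchor)
}

#' Generate one synthetic condition end to end
#'
#' @param world a [make_toy_hybrid()] world.
#' @param effects a [condition_effects()].
#' @param seed integer seed for the Poisson draw.
#' @param balance passed to [expected_matrix()].
#' @return list with `raw` (raw `contact_matrix`), `expected`, and
#'   `truth` ([ground_truth()]).
#' @export
synth_condition <- function(world, effects, seed, balance = TRUE) {
  e <- expected_matrix(world, effects, balance = balance)
  raw <- sample_matrix(e, effects$depth, seed, world$index)
  list(raw = raw, expected = e, truth = ground_truth(effects, world))
}
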