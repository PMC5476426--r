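#' Configuration of the Rabl volume-exclusion polymer model
#'
#' Chromosomes are represented as chains of impenetrable beads inside a
#' spherical nucleus. Centromere beads are confined to a capture sphere at
#' the spindle pole body (SPB, on the +x axis), telomere beads to a
#' peripheral shell at the nuclear envelope, and rDNA beads to a nucleolar
#' spherical cap opposite the SPB, from which all other beads are excluded.
#' Consecutive beads must be adjacent (bond length within
#' `bond_length`) and no two beads may overlap.
#'
#' Two scalings apply. The diploid `ploidy_scale` (1.25) multiplies the
#' nuclear-geometry parameters only (nuclear radius, capture sphere,
#' telomere shell, nucleolus): chromatin fiber properties do not change
#' with ploidy. The nuclear-size `size_multiplier` (0.8 / 0.64 for the
#' smaller nuclei of cells approaching stationary phase) rescales *all*
#' model lengths — geometry, bead diameter and bond lengths — leaving
#' only the contact-calling threshold (an analysis constant, 45 nm)
#' unscaled; a smaller model therefore has a relatively larger contact
#' radius, which blurs positional structure.
#'
#' The capture-sphere radius and telomere-shell thickness are assumptions
#' of this implementation (the tethering literature varies); they are
#' configurable, not reproductions of a published value.
#'
#' @param bead_size bp of genome per bead (default 3200, ten beads per
#'   32 kb bin).
#' @param bead_diameter bead diameter in nm (default 30).
#' @param bond_length length-2 numeric, allowed centre distance between
#'   consecutive beads in nm (default `c(30, 45)`).
#' @param base_nuclear_radius haploid nuclear radius in nm (default 1000).
#' @param ploidy_scale linear scale of nuclear geometry for the diploid
#'   (default 1.25).
#' @param size_multiplier additional linear scale for nuclear-size
#'   experiments (default 1; alternatives 0.8 and 0.64).
#' @param centromere_capture_radius radius in nm of the SPB capture sphere
#'   (default 250, scaled like the nucleus).
#' @param telomere_shell_thickness thickness in nm of the peripheral shell
#'   (default 100, scaled like the nucleus).
#' @param nucleolus_volume_fraction nuclear volume fraction of the
#'   nucleolar cap (default 0.1); only enforced for genomes with an rDNA
#'   interval.
#' @param telomere_anchor_spread scale factor on the random-walk
#'   end-to-end width (`sqrt(beads) * mean bond length`) used when drawing
#'   each arm's telomere anchor point on the peripheral shell. Controls how
#'   strongly short arms' telomeres concentrate near the SPB; a free
#'   parameter of the growth heuristic (see the methods vignette).
#' @param contact_threshold bead-centre distance in nm called as a contact
#'   (default 45, inclusive).
#' @param n_structures population size (paper-scale default 20000; use far
#'   fewer for interactive work).
#' @param max_iterations constraint-projection sweeps per structure before
#'   the attempt is abandoned and reseeded (default 5000).
#' @param overlap_tolerance overlap slack in nm when checking violations
#'   (default 0.5).
#' @param region_tolerance tether/bond slack in nm when checking violations
#'   (default 0.5).
#' @param seed integer seed; per-structure seeds are derived
#'   deterministically from it.
#' @return a `polymer_config` list.
#' @export
polymer_config <- function(bead_size = 3200, bead_diameter = 30,
                           bond_length = c(30, 45), base_nuclear_radius = 1000,
                           ploidy_scale = 1.25, size_multiplier = 1,
                           centromere_capture_radius = 250,
                           telomere_shell_thickness = 100,
                           nucleolus_volume_fraction = 0.1,
                           telomere_anchor_spread = 1.4,
                           contact_threshold = 45, n_structures = 20000,
                           max_iterations = 5000, overlap_tolerance = 0.5,
                           region_tolerance = 0.5, seed = 1) {
  stopifnot(contact_threshold > 0, bead_diameter > 0, bead_size > 0,
            length(bond_length) == 2, bond_length[1] <= bond_length[2],
            size_multiplier > 0, ploidy_scale > 0)
  structure(list(
    bead_size = bead_size, bead_diameter = bead_diameter,
    bond_length = bond_length, base_nuclear_radius = base_nuclear_radius,
    ploidy_scale = ploidy_scale, size_multiplier = size_multiplier,
    centromere_capture_radius = centromere_capture_radius,
    telomere_shell_thickness = telomere_shell_thickness,
    nucleolus_volume_fraction = nucleolus_volume_fraction,
    telomere_anchor_spread = telomere_anchor_spread,
    contact_threshold = contact_threshold, n_structures = n_structures,
    max_iterations = max_iterations, overlap_tolerance = overlap_tolerance,
    region_tolerance = region_tolerance, seed = seed
  ), class = "polymer_config")
}

#' Effective nuclear radius of a polymer configuration
#' @param config a [polymer_config()].
#' @return radius in nm after ploidy and size scaling.
#' @export
nuclear_radius <- function(config) {
  config$base_nuclear_radius * config$ploidy_scale * config$size_multiplier
}

#' Base nuclear radius matching the chromatin density of the study system
#'
#' A toy genome smaller than the real diploid yeast genome placed in a
#' full-size nucleus would be unrealistically dilute, weakening the
#' inter-chromosomal mixing that volume exclusion provides. This helper
#' shrinks the base (haploid) nuclear radius so that bp per unit nuclear
#' volume equals that of the reference system (diploid budding yeast,
#' roughly 24 Mb in a nucleus of 1250 nm radius, i.e. base radius 1000 nm
#' before the 1.25 ploidy scaling).
#'
#' @param genome a [hybrid_genome()] (both parental sets).
#' @param reference_bp genome size of the reference diploid (default 24e6).
#' @param reference_base_radius base haploid nuclear radius of the
#'   reference (default 1000 nm).
#' @return base nuclear radius in nm for [polymer_config()].
#' @export
density_matched_radius <- function(genome, reference_bp = 24e6,
                                   reference_base_radius = 1000) {
  reference_base_radius * (sum(genome$length) / reference_bp)^(1 / 3)
}

# model parameters handed to the C++ solver: nuclear geometry carries the
# ploidy scaling; the size multiplier rescales every model length
geometry_params <- function(config, has_rdna) {
  sm <- config$size_multiplier
  s <- config$ploidy_scale * sm
  R <- config$base_nuclear_radius * s
  cap_r <- config$centromere_capture_radius * s
  shell <- config$telomere_shell_thickness * s
  f <- config$nucleolus_volume_fraction
  # spherical cap of volume f * (4/3) pi R^3: solve h from pi h^2 (3R - h)/3
  h <- stats::uniroot(function(h) h^2 * (3 * R - h) - 4 * f * R^3,
                      c(0, 2 * R))$root
  list(nuclear_radius = R, cap_cx = R - cap_r, cap_radius = cap_r,
       shell_thickness = shell, nucleolus_plane = -(R - h),
       has_nucleolus = has_rdna, bead_diameter = config$bead_diameter * sm,
       bond_min = config$bond_length[1] * sm,
       bond_max = config$bond_length[2] * sm,
       # numerical slack scales with the model so a resized model is an
       # exact rescale of the baseline (same seed, same trajectory)
       overlap_tolerance = config$overlap_tolerance * sm,
       region_tolerance = config$region_tolerance * sm,
       anchor_sigma_scale = config$telomere_anchor_spread,
       max_iterations = as.integer(config$max_iterations))
}

#' Build bead-chain specifications for a hybrid genome
#'
#' One chain per chromosome with `ceiling(length / bead_size)` beads;
#' centromere, telomere and rDNA bead indices are derived from the
#' annotated positions.
#'
#' @param genome a [hybrid_genome()].
#' @param config a [polymer_config()].
#' @return a `chain_specs` data frame: `chrom`, `n_beads`, `cen_bead`,
#'   `rdna_from`, `rdna_to` (0-based bead indices; rDNA `-1` when absent),
#'   `single_bead` flag.
#' @export
build_chain_specs <- function(genome, config) {
  stopifnot(inherits(genome, "hybrid_genome"))
  n <- as.integer(ceiling(genome$length / config$bead_size))
  cen <- pmin(as.integer(genome$centromere %/% config$bead_size), n - 1L)
  rf <- ifelse(is.na(genome$rdna_start), -1L,
               as.integer(genome$rdna_start %/% config$bead_size))
  rt <- ifelse(is.na(genome$rdna_end), -1L,
               pmin(as.integer(ceiling(genome$rdna_end / config$bead_size)), n))
  cs <- data.frame(chrom = genome$chrom, n_beads = n, cen_bead = cen,
                   rdna_from = rf, rdna_to = rt, single_bead = n == 1L,
                   stringsAsFactors = FALSE)
  attr(cs, "genome") <- genome
  attr(cs, "bead_size") <- config$bead_size
  class(cs) <- c("chain_specs", "data.frame")
  cs
}

chains_have_rdna <- function(chains) any(chains$rdna_from >= 0)

#' Sample one constraint-satisfying structure
#'
#' Chains are grown from the centromere bead outward towards a telomere
#' anchor on the peripheral shell, then relaxed by iterative constraint
#' projection until every bond, tether, exclusion and confinement
#' constraint is met. Identical seeds yield bitwise-identical coordinates.
#'
#' @param chains a [build_chain_specs()] result.
#' @param config a [polymer_config()].
#' @param seed integer seed for this structure.
#' @param max_attempts reseeded attempts before giving up (default 20).
#' @return a `structure3d`: list with `coords` (total beads x 3 matrix,
#'   nm), `chains`, `seed`.
#' @export
sample_structure <- function(chains, config, seed, max_attempts = 20) {
  check_feasible(chains, config)
  p <- geometry_params(config, chains_have_rdna(chains))
  for (attempt in seq_len(max_attempts)) {
    s <- cpp_mix_seed(seed, attempt - 1)
    res <- cpp_sample_structure(chains$n_beads, chains$cen_bead,
                                chains$rdna_from, chains$rdna_to, p, s)
    if (res$converged) {
      return(structure(list(coords = res$coords, chains = chains, seed = seed,
                            iterations = res$iterations, attempt = attempt),
                       class = "structure3d"))
    }
  }
  stop(sprintf(paste0("polymer sampling failed to satisfy constraints after %d ",
                      "attempts of %d sweeps; the configuration is likely ",
                      "infeasible (nucleus too small or tethers unreachable)"),
               max_attempts, config$max_iterations))
}

check_feasible <- function(chains, config) {
  R <- nuclear_radius(config)
  d <- config$bead_diameter * config$size_multiplier
  bead_vol <- sum(chains$n_beads) * (4 / 3) * pi * (d / 2)^3
  if (bead_vol > 0.35 * (4 / 3) * pi * R^3)
    stop("infeasible polymer configuration: bead volume exceeds 35% of the nucleus")
  invisible(TRUE)
}

#' Check all constraints of a structure
#'
#' @param structure a `structure3d` (or a bead coordinate matrix).
#' @param config the [polymer_config()] to check against.
#' @param chains chain specs; defaults to those stored in `structure`.
#' @return named integer vector of violation counts: bond length, pairwise
#'   overlap, centromere/telomere tethers, rDNA in/out of nucleolus, beads
#'   outside the nucleus.
#' @export
check_constraints <- function(structure, config, chains = NULL) {
  if (inherits(structure, "structure3d")) {
    if (is.null(chains)) chains <- structure$chains
    coords <- structure$coords
  } else coords <- structure
  stopifnot(!is.null(chains))
  p <- geometry_params(config, chains_have_rdna(chains))
  cpp_check_constraints(coords, chains$n_beads, chains$cen_bead,
                        chains$rdna_from, chains$rdna_to, p)
}

#' Simulate a population of Rabl structures
#'
#' @param chains a [build_chain_specs()] result.
#' @param config a [polymer_config()]; `config$n_structures` and
#'   `config$seed` control the population.
#' @param progress print progress every 200 structures.
#' @return a `structure_population`: list with `structures` (list of
#'   coordinate matrices), `seeds`, `chains`, `config`.
#' @export
simulate_population <- function(chains, config, progress = FALSE) {
  n <- config$n_structures
  seeds <- vapply(seq_len(n), function(i) cpp_mix_seed(config$seed, i), numeric(1))
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    st <- sample_structure(chains, config, seeds[i])
    structures[[i]] <- st$coords
    if (progress && i %% 200 == 0) message("structure ", i, "/", n)
  }
  structure(list(structures = structures, seeds = seeds, chains = chains,
                 config = config),
            class = "structure_population")
}

#' @export
print.structure_population <- function(x, ...) {
  cat(sprintf("structure_population: %d structures, %d beads (%d chains), size_multiplier %.2f\n",
              length(x$structures), sum(x$chains$n_beads), nrow(x$chains),
              x$config$size_multiplier))
  invisible(x)
}

#' Convert a structure population into a simulated contact matrix
#'
#' Every unordered bead pair with centre distance at or below the contact
#' threshold (45 nm by default) is called a contact and accumulated into
#' the cell of the bin pair containing the two beads' midpoint coordinates.
#' The result feeds [normalize_matrix()] unchanged, exactly like an
#' experimental count matrix.
#'
#' @param pop a [simulate_population()] result.
#' @param index a `bin_index` on the same genome.
#' @return a raw `contact_matrix`.
#' @export
population_to_contact_matrix <- function(pop, index) {
  bead_bin <- bead_bin_assignment(pop$chains, index)
  m <- cpp_population_contacts(pop$structures, bead_bin,
                               pop$config$contact_threshold, n_bins(index))
  contact_matrix(m, index, normalized = FALSE)
}

# global 0-based bin id of each bead (by bead midpoint bp coordinate)
bead_bin_assignment <- function(chains, index) {
  bs <- attr(chains, "bead_size")
  out <- integer(0)
  for (i in seq_len(nrow(chains))) {
    mid <- (seq_len(chains$n_beads[i]) - 0.5) * bs
    out <- c(out, bin_of_position(index, rep(chains$chrom[i], chains$n_beads[i]), mid))
  }
  out
}

#' Write a structure population to a text file
#'
#' One row per bead (`structure`, `chain`, `bead`, `x`, `y`, `z` in nm)
#' plus a JSON sidecar of the configuration.
#'
#' @param pop a `structure_population`.
#' @param path output TSV path; the config is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  chain_id <- rep(pop$chains$chrom, pop$chains$n_beads)
  bead_id <- unlist(lapply(pop$chains$n_beads, seq_len)) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("structure\tchain\tbead\tx\ty\tz", con)
  for (s in seq_along(pop$structures)) {
    co <- pop$structures[[s]]
    writeLines(sprintf("%d\t%s\t%d\t%.3f\t%.3f\t%.3f", s, chain_id, bead_id,
                       co[, 1], co[, 2], co[, 3]), con)
  }
  cfg <- pop$config
  cfg$seeds <- pop$seeds
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
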