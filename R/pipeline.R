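#' Read and validate a pipeline configuration
#'
#' A flat YAML file of `key: value` pairs. Unknown keys are rejected.
#' Recognised keys (all optional unless a stage needs them):
#' paths `genome`, `homology`, `pairs`, `matrix`, `matrix_b`, `masks`,
#' `out_dir`; generator keys `chrom_lengths`, `centromeres`, `bin_size`,
#' `beta`, `gamma`, `rho`, `depth`; processing keys `min_cis_distance`,
#' `min_row_mean`; polymer keys `n_structures`, `size_multiplier`,
#' `bead_size`; proximity keys `level`, `min_dcen`, `telomere_margin`,
#' `exclude_rdna`, `exclude_centromere_bins`, `n_reps`; comparison keys
#' `anchor_bin`, `n_strata`, `alpha_level`; and `seed`, `log_level`.
#'
#' @param config a path to a YAML file or a named list.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("genome", "homology", "pairs", "matrix", "matrix_b", "masks",
             "out_dir", "chrom_lengths", "centromeres", "bin_size", "beta",
             "gamma", "rho", "depth", "min_cis_distance", "min_row_mean",
             "n_structures", "size_multiplier", "bead_size", "level",
             "min_dcen", "telomere_margin", "exclude_rdna",
             "exclude_centromere_bins", "n_reps", "anchor_bin", "n_strata",
             "alpha_level", "seed", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  toy <- synthetic_world_config()
  defaults <- list(chrom_lengths = toy$chrom_lengths,
                   centromeres = toy$centromeres,
                   out_dir = "hybridhic_out", bin_size = 32000, beta = 1,
                   gamma = 1, rho = 1, depth = 1e6, min_cis_distance = 1000,
                   min_row_mean = 1, n_structures = 100, size_multiplier = 1,
                   bead_size = 3200, level = "DCEN_ARM", min_dcen = 0,
                   telomere_margin = 0, exclude_rdna = TRUE,
                   exclude_centromere_bins = TRUE, n_reps = 10000,
                   n_strata = 9, alpha_level = 0.05, seed = 1,
                   log_level = "info")
  cfg <- utils::modifyList(defaults, config)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  # djb2 over the deparsed canonical (key-sorted) config; path-valued keys
  # are excluded so the hash identifies the analysis, not its location
  cfg <- unclass(cfg)
  paths <- c("out_dir", "genome", "homology", "pairs", "matrix", "matrix_b",
             "masks")
  cfg <- cfg[setdiff(names(cfg), paths)]
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

plog <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages
#'
#' Orchestrates the analysis as named stages writing artifacts under
#' `config$out_dir`: `synth` (toy world + sampled raw matrix), `polymer`
#' (Rabl null population + its raw matrix), `process` (filter/bin or load,
#' mask, normalize), `proximity` (profile + bootstrap + JSON summary),
#' `compare` (differential map + anchor shift test), `report`. Stages run
#' in dependency order; a stage whose upstream artifact is missing stops
#' with an error naming the stage to run. Every artifact carries a
#' provenance header (config hash, seed, package version). Reruns with an
#' identical config reproduce identical files for deterministic stages.
#'
#' @param config path to a YAML config or a named list (see
#'   [read_pipeline_config()]).
#' @param stages character subset of `c("synth", "polymer", "process",
#'   "proximity", "compare", "report")`.
#' @param seed overrides `config$seed` if non-NULL.
#' @return invisibly, the list of written artifact paths.
#' @export
run_pipeline <- function(config, stages = c("synth", "process", "proximity"),
                         seed = NULL) {
  cfg <- read_pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  if (!is.null(seed)) cfg$seed <- seed
  order_all <- c("synth", "polymer", "process", "proximity", "compare", "report")
  stages <- order_all[order_all %in% match.arg(stages, order_all, several.ok = TRUE)]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(config_hash = config_hash(cfg), seed = as.character(cfg$seed),
            version = as.character(utils::packageVersion("hybridhic")))
  paths <- list()
  pth <- function(f) file.path(cfg$out_dir, f)

  load_world <- function() {
    # an explicit genome file wins over the built-in toy karyotype
    if (!is.null(cfg$genome) || is.null(cfg$chrom_lengths)) {
      genome_path <- cfg$genome %||% pth("genome.tsv")
      if (!file.exists(genome_path))
        stop("missing genome spec; run stage 'synth' or set 'genome'")
      g <- read_genome_spec(genome_path)
      list(genome = g, index = build_bin_index(g, cfg$bin_size))
    } else {
      make_toy_hybrid(synthetic_world_config(
        chrom_lengths = cfg$chrom_lengths, centromeres = cfg$centromeres,
        bin_size = cfg$bin_size, seed = cfg$seed))
    }
  }

  if ("synth" %in% stages) {
    world <- make_toy_hybrid(synthetic_world_config(
      chrom_lengths = cfg$chrom_lengths %||% synthetic_world_config()$chrom_lengths,
      centromeres = cfg$centromeres %||% synthetic_world_config()$centromeres,
      bin_size = cfg$bin_size, seed = cfg$seed))
    eff <- condition_effects(beta = cfg$beta, gamma = cfg$gamma, rho = cfg$rho,
                             depth = cfg$depth)
    cond <- synth_condition(world, eff, seed = cfg$seed)
    write_genome_spec(world$genome, pth("genome.tsv"))
    write_homology_table(world$homology, pth("homology.tsv"))
    write_contact_matrix(cond$raw, pth("matrix_raw.tsv"), extra = prov)
    jsonlite::write_json(cond$truth, pth("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$synth <- pth(c("genome.tsv", "homology.tsv", "matrix_raw.tsv",
                         "ground_truth.json"))
    plog(cfg, "info", "synth: wrote toy world at depth ", cfg$depth)
  }

  if ("polymer" %in% stages) {
    world <- load_world()
    pc <- polymer_config(bead_size = cfg$bead_size,
                         size_multiplier = cfg$size_multiplier,
                         n_structures = cfg$n_structures, seed = cfg$seed)
    chains <- build_chain_specs(world$genome, pc)
    pop <- simulate_population(chains, pc)
    cm <- population_to_contact_matrix(pop, world$index)
    write_population(pop, pth("population.tsv"))
    write_contact_matrix(cm, pth("polymer_matrix_raw.tsv"), extra = prov)
    paths$polymer <- pth(c("population.tsv", "polymer_matrix_raw.tsv"))
    plog(cfg, "info", "polymer: ", cfg$n_structures, " structures")
  }

  if ("process" %in% stages) {
    world <- load_world()
    if (!is.null(cfg$pairs)) {
      pr <- read_pairs_file(cfg$pairs)
      sites <- lapply(stats::setNames(world$genome$length, world$genome$chrom),
                      function(l) seq(4000, l - 1, by = 4000))
      fm <- fragment_map(sites, world$genome)
      flt <- filter_pairs(pr, fm, cfg$min_cis_distance)
      raw <- bin_contacts(flt$pairs, fm, world$index)
    } else {
      raw_path <- cfg$matrix %||% pth("matrix_raw.tsv")
      if (!file.exists(raw_path))
        stop("missing raw matrix; run stage 'synth' (or 'polymer') or set 'matrix'")
      raw <- read_contact_matrix(raw_path, world$index)
    }
    if (!is.null(cfg$masks)) raw <- apply_masks(raw, cfg$masks)
    norm <- normalize_matrix(raw, cfg$min_row_mean)
    write_contact_matrix(norm, pth("matrix_norm.tsv"), extra = prov)
    paths$process <- pth("matrix_norm.tsv")
    plog(cfg, "info", "process: normalized matrix with ", sum(norm$valid),
         " valid bins")
  }

  if ("proximity" %in% stages) {
    world <- load_world()
    norm_path <- pth("matrix_norm.tsv")
    if (!file.exists(norm_path))
      stop("missing normalized matrix; run stage 'process' first")
    norm <- read_contact_matrix(norm_path, world$index)
    hom_path <- cfg$homology %||% pth("homology.tsv")
    if (!file.exists(hom_path))
      stop("missing homology table; run stage 'synth' or set 'homology'")
    hmap <- call_homologous_bins(read_homology_table(hom_path), world$index)
    pol <- exclusion_policy(exclude_rdna_chromosomes = cfg$exclude_rdna,
                            exclude_centromere_bins = cfg$exclude_centromere_bins,
                            min_dcen = cfg$min_dcen,
                            telomere_margin = cfg$telomere_margin)
    prof <- proximity_profile(norm, hmap, cfg$level, pol)
    boot <- bootstrap_genomic_proximity(norm, hmap, cfg$level, pol,
                                        n_reps = cfg$n_reps, seed = cfg$seed)
    write_tsv_with_header(prof, pth("proximity_profile.tsv"), prov)
    write_tsv_with_header(data.frame(rep = seq_along(boot$ratios),
                                     ratio = boot$ratios),
                          pth("proximity_boot.tsv"), prov)
    jsonlite::write_json(c(summarize_proximity(boot), as.list(prov)),
                         pth("proximity_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    paths$proximity <- pth(c("proximity_profile.tsv", "proximity_boot.tsv",
                             "proximity_summary.json"))
    plog(cfg, "info", "proximity: bootstrap median ",
         round(stats::median(boot$ratios), 3))
  }

  if ("compare" %in% stages) {
    world <- load_world()
    pa <- pth("matrix_norm.tsv")
    if (!file.exists(pa))
      stop("missing normalized matrix for condition a; run stage 'process' first")
    if (is.null(cfg$matrix_b))
      stop("stage 'compare' needs 'matrix_b' (normalized matrix of condition b)")
    a <- read_contact_matrix(pa, world$index)
    b <- read_contact_matrix(cfg$matrix_b, world$index)
    dm <- differential_map(a, b)
    dvals <- dm$values
    cmd <- contact_matrix(replace(dvals, is.na(dvals), 0), world$index,
                          normalized = FALSE, valid = dm$valid)
    write_contact_matrix(cmd, pth("differential.tsv"), extra = prov)
    if (!is.null(cfg$anchor_bin)) {
      st <- anchor_shift_test(a, b, cfg$anchor_bin, cfg$n_strata, cfg$alpha_level)
      write_tsv_with_header(as.data.frame(st), pth("anchor_test.tsv"), prov)
      jsonlite::write_json(as.data.frame(st), pth("anchor_test.json"),
                           digits = NA)
    }
    paths$compare <- pth(c("differential.tsv", "anchor_test.tsv"))
    plog(cfg, "info", "compare: differential map written")
  }

  if ("report" %in% stages) {
    paths$report <- pipeline_report(cfg$out_dir)
  }
  invisible(paths)
}

write_tsv_with_header <- function(d, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(prov), ": ", prov), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize pipeline outputs into a human-readable report
#'
#' Renders whatever stage outputs are present in `out_dir`: normalized
#' contact-map heat map, proximity bootstrap violin and per-bin profile,
#' and the stratified-test table. Missing sections are skipped with a
#' warning. Plots require ggplot2 and are skipped (with a warning) without
#' it.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return paths of the report files written, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  written <- character(0)
  lines <- c("hybridhic pipeline report", strrep("=", 25))
  sections <- 0L
  read_body <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                             comment.char = "#")
  has_gg <- requireNamespace("ggplot2", quietly = TRUE)

  f <- file.path(out_dir, "matrix_norm.tsv")
  if (file.exists(f)) {
    d <- read_body(f)
    sections <- sections + 1L
    lines <- c(lines, "", "[contact map]",
               sprintf("  %d non-zero normalized cells; value range %.3g-%.3g",
                       nrow(d), min(d$value), max(d$value)))
    if (has_gg) {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = bin1_id, y = bin2_id,
                                           fill = log10(value + 1e-9))) +
        ggplot2::geom_tile() + ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = "bin", y = "bin", fill = "log10 freq")
      ggplot2::ggsave(file.path(out_dir, "report_contact_map.png"), p,
                      width = 5, height = 4, dpi = 120)
      written <- c(written, file.path(out_dir, "report_contact_map.png"))
    }
  } else warning("report: no normalized matrix found; skipping contact map")

  f <- file.path(out_dir, "proximity_boot.tsv")
  if (file.exists(f)) {
    d <- read_body(f)
    sections <- sections + 1L
    q <- stats::quantile(d$ratio, c(0.025, 0.5, 0.975))
    lines <- c(lines, "", "[homolog proximity]",
               sprintf("  bootstrap median %.3f [%.3f, %.3f] over %d reps",
                       q[2], q[1], q[3], nrow(d)))
    if (has_gg) {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = "", y = ratio)) +
        ggplot2::geom_violin(fill = "grey80") +
        ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
        ggplot2::labs(x = NULL, y = "homologous / nonhomologous ratio")
      ggplot2::ggsave(file.path(out_dir, "report_proximity_violin.png"), p,
                      width = 3, height = 4, dpi = 120)
      written <- c(written, file.path(out_dir, "report_proximity_violin.png"))
    }
  } else warning("report: no bootstrap distribution found; skipping violin")

  f <- file.path(out_dir, "proximity_profile.tsv")
  if (file.exists(f)) {
    d <- read_body(f)
    sections <- sections + 1L
    lines <- c(lines, "", "[per-bin profile]",
               sprintf("  %d/%d homologous bins sufficient; median ratio %.3f",
                       sum(d$sufficient), nrow(d),
                       stats::median(d$ratio, na.rm = TRUE)))
    if (has_gg) {
      p <- ggplot2::ggplot(d[d$sufficient, ],
                           ggplot2::aes(x = bin1, y = ratio)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.7) +
        ggplot2::labs(x = "parent-1 genome position (bin)",
                      y = "homolog proximity ratio")
      ggplot2::ggsave(file.path(out_dir, "report_proximity_profile.png"), p,
                      width = 6, height = 3, dpi = 120)
      written <- c(written, file.path(out_dir, "report_proximity_profile.png"))
    }
  } else warning("report: no proximity profile found; skipping profile")

  f <- file.path(out_dir, "anchor_test.tsv")
  if (file.exists(f)) {
    d <- read_body(f)
    sections <- sections + 1L
    lines <- c(lines, "", "[anchor shift test]",
               utils::capture.output(print(d, row.names = FALSE)))
  } else warning("report: no anchor test found; skipping stratified table")

  lines <- c(lines, "", sprintf("%d section(s) rendered", sections))
  rp <- file.path(out_dir, "report.txt")
  writeLines(lines, rp)
  invisible(c(rp, written))
}
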