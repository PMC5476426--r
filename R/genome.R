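#' Hybrid diploid genome specification
#'
#' A hybrid genome is an ordered set of chromosomes contributed by two
#' parental genomes (all parent-1 chromosomes first, then all parent-2
#' chromosomes), each with a point centromere and an optional rDNA interval.
#'
#' @param chrom character vector of unique chromosome names.
#' @param parent integer vector (1 or 2): parental genome of origin.
#' @param length integer vector of chromosome lengths in bp.
#' @param centromere integer vector of centromere positions in bp
#'   (0 < centromere < length).
#' @param rdna_start,rdna_end optional rDNA interval (half-open, bp); `NA`
#'   where absent. The interval must lie within the chromosome and must not
#'   contain the centromere.
#'
#' @return A `hybrid_genome` data frame with one row per chromosome.
#' @examples
#' hybrid_genome(
#'   chrom = c("chrA", "chrA_p2"), parent = c(1, 2),
#'   length = c(200000, 200000), centromere = c(70000, 70000)
#' )
#' @export
hybrid_genome <- function(chrom, parent, length, centromere,
                          rdna_start = NA_real_, rdna_end = NA_real_) {
  g <- data.frame(
    chrom = as.character(chrom),
    parent = as.integer(parent),
    length = as.numeric(length),
    centromere = as.numeric(centromere),
    rdna_start = as.numeric(rep_len(rdna_start, length(chrom))),
    rdna_end = as.numeric(rep_len(rdna_end, length(chrom))),
    stringsAsFactors = FALSE
  )
  validate_hybrid_genome(g)
}

validate_hybrid_genome <- function(g) {
  if (nrow(g) == 0L) stop("empty genome: at least one chromosome per parent is required")
  if (anyDuplicated(g$chrom)) stop("chromosome names must be unique")
  if (!all(g$parent %in% c(1L, 2L))) stop("parent must be 1 or 2")
  if (!all(1L %in% g$parent) || !all(2L %in% g$parent))
    stop("each parent must contribute at least one chromosome")
  if (any(g$length <= 0)) stop("chromosome lengths must be positive")
  if (any(g$centromere <= 0 | g$centromere >= g$length))
    stop("centromere must satisfy 0 < centromere < length")
  has_rdna <- !is.na(g$rdna_start)
  if (any(has_rdna != !is.na(g$rdna_end)))
    stop("rdna_start and rdna_end must be both present or both absent")
  if (any(has_rdna)) {
    r <- g[has_rdna, ]
    if (any(r$rdna_start < 0 | r$rdna_end > r$length | r$rdna_start >= r$rdna_end))
      stop("rdna interval must lie within [0, length) with start < end")
    if (any(r$centromere >= r$rdna_start & r$centromere < r$rdna_end))
      stop("rdna interval must not contain the centromere")
  }
  # enforce parent-1-then-parent-2 ordering
  g <- g[order(g$parent, match(g$chrom, g$chrom)), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("hybrid_genome", "data.frame")
  g
}

#' Read or write a genome specification TSV
#'
#' Columns: `chrom`, `length`, `parent`, `centromere`, `rdna_start`,
#' `rdna_end`; the rDNA fields may be `"."` where absent. Lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return `read_genome_spec()` returns a [hybrid_genome()].
#' @export
read_genome_spec <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chrom", "length", "parent", "centromere")
  if (!all(need %in% names(d)))
    stop("genome spec must have columns: ", paste(need, collapse = ", "))
  dot_na <- function(x) as.numeric(ifelse(is.null(x) | x == ".", NA, x))
  hybrid_genome(
    chrom = d$chrom, parent = as.integer(d$parent),
    length = as.numeric(d$length), centromere = as.numeric(d$centromere),
    rdna_start = if ("rdna_start" %in% names(d)) dot_na(d$rdna_start) else NA,
    rdna_end = if ("rdna_end" %in% names(d)) dot_na(d$rdna_end) else NA
  )
}

#' @param genome a [hybrid_genome()].
#' @rdname read_genome_spec
#' @export
write_genome_spec <- function(genome, path) {
  d <- as.data.frame(genome)
  d$rdna_start <- ifelse(is.na(d$rdna_start), ".", format(d$rdna_start, scientific = FALSE))
  d$rdna_end <- ifelse(is.na(d$rdna_end), ".", format(d$rdna_end, scientific = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the binned coordinate system of a hybrid genome
#'
#' Tiles every chromosome with fixed-width half-open bins (the last bin of a
#' chromosome may be shorter) and annotates each bin with its centromeric
#' distance `d_cen` (bins between it and the centromere-containing bin), arm
#' identity and arm length, and flags used by downstream exclusion policies.
#'
#' Conventions: coordinates are 0-based half-open; a position `p` falls in
#' bin `floor(p / bin_size)`. The centromere bin has `d_cen = 0` and belongs
#' to both arms; its `arm_length` is the longer of the two. `arm_length` is
#' the maximal `d_cen` on the arm, so `d_cen <= arm_length` always holds.
#'
#' @param genome a [hybrid_genome()].
#' @param bin_size bin width in bp (default 32000, i.e. 32 kb resolution).
#' @param telomere_margin number of bins at each chromosome end flagged as
#'   telomeric margin (default 1).
#' @param split_rdna_arms if `TRUE`, bins distal to the rDNA interval (on the
#'   rDNA side of the centromere) form their own arm for `arm_length`
#'   purposes, reflecting the nucleolar tether splitting the chromosome into
#'   quasi-independent domains. Default `FALSE`.
#' @return A `bin_index` data frame with one row per bin: `bin` (0-based
#'   global id), `chrom`, `parent`, `start`, `end`, `chrom_bin`, `d_cen`,
#'   `arm_id`, `arm_length`, and logical flags `centromere_bin`,
#'   `telomere_margin`, `rdna_chromosome`, `masked`.
#' @examples
#' g <- hybrid_genome(c("a", "b"), c(1, 2), c(100000, 100000), c(40000, 40000))
#' bi <- build_bin_index(g, 32000)
#' bi$d_cen  # 1 0 1 2 per chromosome
#' @export
build_bin_index <- function(genome, bin_size = 32000, telomere_margin = 1,
                            split_rdna_arms = FALSE) {
  stopifnot(inherits(genome, "hybrid_genome"), bin_size > 0)
  rows <- lapply(seq_len(nrow(genome)), function(ci) {
    len <- genome$length[ci]
    n <- as.integer(ceiling(len / bin_size))
    start <- (seq_len(n) - 1L) * bin_size
    end <- pmin(start + bin_size, len)
    cen_bin <- as.integer(genome$centromere[ci] %/% bin_size)
    chrom_bin <- seq_len(n) - 1L
    d_cen <- abs(chrom_bin - cen_bin)
    arm <- ifelse(chrom_bin < cen_bin, "L", ifelse(chrom_bin > cen_bin, "R", "C"))
    arm_len_L <- cen_bin
    arm_len_R <- n - 1L - cen_bin
    arm_length <- ifelse(arm == "L", arm_len_L,
                         ifelse(arm == "R", arm_len_R, max(arm_len_L, arm_len_R)))
    arm_id <- paste0(genome$chrom[ci], ":", arm)
    has_rdna <- !is.na(genome$rdna_start[ci])
    if (split_rdna_arms && has_rdna) {
      r0 <- as.integer(genome$rdna_start[ci] %/% bin_size)
      r1 <- as.integer((genome$rdna_end[ci] - 1) %/% bin_size)
      if (r0 > cen_bin) { # rDNA on the right arm: bins beyond it are their own arm
        distal <- chrom_bin > r1
        arm_id[distal] <- paste0(genome$chrom[ci], ":R2")
        arm_length[distal] <- n - 1L - r1
      } else if (r1 < cen_bin) {
        distal <- chrom_bin < r0
        arm_id[distal] <- paste0(genome$chrom[ci], ":L2")
        arm_length[distal] <- r0
      }
    }
    data.frame(
      chrom = genome$chrom[ci], parent = genome$parent[ci],
      start = start, end = end, chrom_bin = chrom_bin,
      d_cen = as.integer(d_cen), arm_id = arm_id,
      arm_length = as.integer(arm_length),
      centromere_bin = chrom_bin == cen_bin,
      telomere_margin = chrom_bin < telomere_margin | chrom_bin >= n - telomere_margin,
      rdna_chromosome = has_rdna,
      masked = FALSE,
      stringsAsFactors = FALSE
    )
  })
  idx <- do.call(rbind, rows)
  idx <- cbind(bin = seq_len(nrow(idx)) - 1L, idx)
  rownames(idx) <- NULL
  attr(idx, "bin_size") <- bin_size
  attr(idx, "genome") <- genome
  class(idx) <- c("bin_index", "data.frame")
  idx
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("bin_index: %d bins of %d bp over %d chromosomes\n",
              nrow(x), attr(x, "bin_size"),
              length(unique(x$chrom))))
  NextMethod()
}

n_bins <- function(index) nrow(index)

bin_size_of <- function(index) attr(index, "bin_size")

# global 0-based bin id for (chrom, pos); pos clamped into the chromosome
bin_of_position <- function(index, chrom, pos) {
  bs <- bin_size_of(index)
  first <- tapply(index$bin, index$chrom, min)[chrom]
  nb <- tapply(index$bin, index$chrom, length)[chrom]
  cb <- pmin(pmax(floor(pos / bs), 0), nb - 1L)
  as.integer(first + cb)
}
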