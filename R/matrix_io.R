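#' Write or read a contact matrix as COO TSV
#'
#' Upper-triangle coordinate format: columns `bin1_id`, `bin2_id`, `value`
#' (0-based global bin ids, `bin1_id <= bin2_id`), preceded by `#`-prefixed
#' header lines recording the bin size, number of bins, whether the matrix
#' is raw or normalized, and the total.
#'
#' @param cm a `contact_matrix`.
#' @param path output path.
#' @param extra named character vector of extra provenance header fields.
#' @return the path, invisibly.
#' @export
write_contact_matrix <- function(cm, path, extra = NULL) {
  v <- cm$values
  ut <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0, arr.ind = TRUE)
  d <- data.frame(bin1_id = ut[, 1] - 1L, bin2_id = ut[, 2] - 1L,
                  value = v[ut])
  d <- d[order(d$bin1_id, d$bin2_id), ]
  hdr <- c(bin_size = as.character(bin_size_of(cm$index)),
           n_bins = as.character(n_bins(cm$index)),
           kind = if (cm$normalized) "normalized" else "raw",
           total = format(cm$total_pairs, digits = 15),
           valid_bins = paste(which(cm$valid) - 1L, collapse = ","),
           extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(hdr), ": ", hdr), con)
  writeLines("bin1_id\tbin2_id\tvalue", con)
  if (nrow(d))
    writeLines(sprintf("%d\t%d\t%s", d$bin1_id, d$bin2_id,
                       format(d$value, digits = 15, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' @param index the `bin_index` the matrix was binned on (checked against
#'   the header).
#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path, index) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  hdr <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", hdr_lines)
  kv <- do.call(rbind, strsplit(hdr, "\t"))
  h <- stats::setNames(kv[, 2], kv[, 1])
  if (as.integer(h[["n_bins"]]) != n_bins(index))
    stop("matrix header n_bins does not match the supplied bin index")
  if (as.numeric(h[["bin_size"]]) != bin_size_of(index))
    stop("matrix header bin_size does not match the supplied bin index")
  body <- lines[!grepl("^#", lines)]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t")
  n <- n_bins(index)
  normalized <- identical(h[["kind"]], "normalized")
  v <- matrix(if (normalized) NA_real_ else 0, n, n)
  valid <- rep(TRUE, n)
  if (!is.na(h["valid_bins"])) {
    ids <- as.integer(strsplit(h[["valid_bins"]], ",")[[1]])
    valid <- (seq_len(n) - 1L) %in% ids
  }
  if (normalized) v[valid, valid] <- 0
  if (nrow(d)) {
    v[cbind(d$bin1_id + 1L, d$bin2_id + 1L)] <- d$value
    v[cbind(d$bin2_id + 1L, d$bin1_id + 1L)] <- d$value
  }
  if (normalized) diag(v) <- NA_real_
  out <- contact_matrix(v, index, normalized = normalized, valid = valid)
  if (!is.na(h["total"])) out$total_pairs <- as.numeric(h[["total"]])
  out
}
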