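#' Read a probe-level intensity matrix
#'
#' Reads a tab-separated matrix whose first column holds probe identifiers
#' and whose header row names the samples. Every probe must be present in
#' the annotation and every sample column must be described in the sample
#' sheet; non-numeric cells are an error.
#'
#' @param path path to a tab-separated file.
#' @param annotation probe annotation (see [validate_annotation()]).
#' @param samples sample metadata (see [validate_samples()]).
#' @return numeric matrix (probes x samples), linear scale.
#' @export
read_probe_matrix <- function(path, annotation, samples) {
  validate_annotation(annotation)
  validate_samples(samples)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !grepl("\t", header)) {
    stop("malformed matrix file: missing tab-separated header row")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L) stop("matrix file must have a probe_id column plus sample columns")
  probe_ids <- as.character(d[[1L]])
  unknown_probe <- setdiff(probe_ids, annotation$probe_id)
  if (length(unknown_probe) > 0L) {
    stop("probe(s) not present in annotation: ",
         paste(utils::head(unknown_probe, 5L), collapse = ", "))
  }
  sample_ids <- colnames(d)[-1L]
  unknown_sample <- setdiff(sample_ids, samples$sample_id)
  if (length(unknown_sample) > 0L) {
    stop("sample(s) in header absent from sample sheet: ",
         paste(unknown_sample, collapse = ", "))
  }
  vals <- d[, -1L, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(not_num)) {
    stop("non-numeric values in column(s): ",
         paste(sample_ids[not_num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- probe_ids
  check_matrix(m, "probe matrix")
  if (any(m < 0)) stop("linear-scale probe intensities must be non-negative")
  set_scale(m, "linear")
}

# Deterministic TSV writer shared by the exported writers: rows sorted
# lexicographically (C collation via radix) and values printed at fixed
# precision so repeated writes are byte-identical.
write_intensity_matrix <- function(m, path, digits = 6L) {
  if (length(m) == 0L) stop("refusing to write an empty matrix")
  check_matrix(m)
  ord <- order(rownames(m), method = "radix")
  m <- m[ord, , drop = FALSE]
  fmt <- paste0("%.", digits, "f")
  lines <- c(
    paste(c("feature_id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf(fmt, m[i, ])), collapse = "\t")
    }, character(1L))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a summarized probe-set matrix to TSV
#'
#' Rows are written in lexicographic probe-set order and values at fixed
#' decimal precision, so two writes of the same matrix are byte-identical.
#'
#' @param m probe-set intensity matrix.
#' @param path output path.
#' @param digits decimal places retained (default 6).
#' @export
write_probeset_matrix <- function(m, path, digits = 6L) {
  write_intensity_matrix(m, path, digits = digits)
}

#' Write a probe-level matrix to TSV
#'
#' Same format as [write_probeset_matrix()] but with probe rows; the header
#' key column is the probe identifier.
#'
#' @inheritParams write_probeset_matrix
#' @export
write_probe_matrix <- function(m, path, digits = 6L) {
  write_intensity_matrix(m, path, digits = digits)
}

#' Read a summarized probe-set matrix written by [write_probeset_matrix()]
#'
#' @param path path to the TSV file.
#' @param scale intensity scale of the stored values.
#' @return numeric matrix with the requested scale attribute.
#' @export
read_probeset_matrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  check_matrix(m, "probe-set matrix")
  set_scale(m, scale)
}

write_annotation <- function(annotation, path) {
  a <- annotation
  a$probeset_id[is.na(a$probeset_id)] <- ""
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
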