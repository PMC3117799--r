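#' @keywords internal
"_PACKAGE"

# Fraction vocabulary: five plasma-derived fractions from sequential
# centrifugation plus the three cellular (hematopoietic) fractions.
PLASMA_FRACTIONS <- c("CS", "S1", "S2", "P1", "P2")
CELLULAR_FRACTIONS <- c("RBC", "WBC", "LEU")
ALL_FRACTIONS <- c(PLASMA_FRACTIONS, CELLULAR_FRACTIONS)

#' Validate a probe annotation table
#'
#' A probe annotation maps every array probe to its probe set and records
#' whether the probe is a `target` probe (interrogating a miRNA) or an
#' anti-genomic `background` probe used for GC-stratified background
#' estimation.
#'
#' @param annotation data.frame with columns `probe_id`, `probeset_id`,
#'   `probe_class` (`"target"` or `"background"`), `gc_count` (number of G+C
#'   bases in the probe sequence) and `is_human` (logical).
#' @param probe_length maximum probe length; `gc_count` may not exceed it.
#' @return the annotation, invisibly, after validation.
#' @export
validate_annotation <- function(annotation, probe_length = 25L) {
  required <- c("probe_id", "probeset_id", "probe_class", "gc_count", "is_human")
  missing <- setdiff(required, names(annotation))
  if (length(missing) > 0L) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(annotation$probe_id)) {
    stop("annotation probe_id values must be unique")
  }
  bad_class <- setdiff(unique(annotation$probe_class), c("target", "background"))
  if (length(bad_class) > 0L) {
    stop("unknown probe_class value(s): ", paste(bad_class, collapse = ", "))
  }
  is_target <- annotation$probe_class == "target"
  if (any(is_target & (is.na(annotation$probeset_id) | annotation$probeset_id == ""))) {
    stop("every target probe must map to a probeset_id")
  }
  if (any(annotation$gc_count < 0L) || any(annotation$gc_count > probe_length)) {
    stop("gc_count must lie in [0, ", probe_length, "]")
  }
  invisible(annotation)
}

#' Validate a sample metadata sheet
#'
#' @param samples data.frame with columns `sample_id`, `fraction` (one of
#'   CS, S1, S2, P1, P2, RBC, WBC, LEU), `subject_id` and `sex`
#'   (`"M"`, `"F"` or `"NA"`).
#' @return the sample sheet, invisibly, after validation.
#' @export
validate_samples <- function(samples) {
  required <- c("sample_id", "fraction", "subject_id", "sex")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique")
  }
  bad <- setdiff(unique(samples$fraction), ALL_FRACTIONS)
  if (length(bad) > 0L) {
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ALL_FRACTIONS, collapse = "/"), ")")
  }
  bad_sex <- setdiff(unique(as.character(samples$sex)), c("M", "F", "NA", NA))
  if (length(bad_sex) > 0L) {
    stop("sex must be one of M, F, NA; found: ", paste(bad_sex, collapse = ", "))
  }
  invisible(samples)
}

# Intensity matrices carry a "scale" attribute: "linear" (raw, >= 0) or
# "log2". Subsetting with `[` drops attributes, so functions that care pass
# or re-derive the scale explicitly and use these helpers at boundaries.
set_scale <- function(m, scale = c("linear", "log2")) {
  attr(m, "scale") <- match.arg(scale)
  m
}

get_scale <- function(m, default = "log2") {
  s <- attr(m, "scale")
  if (is.null(s)) default else s
}

# Convert a (possibly log2) matrix to linear intensities.
as_linear <- function(m, scale = get_scale(m)) {
  if (identical(scale, "log2")) 2^m else m
}

check_matrix <- function(m, what = "intensity matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must have row and column names")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop(what, " row/column names must be unique")
  }
  if (anyNA(m)) stop(what, " may not contain missing values")
  invisible(m)
}

# Downstream stages reject matrices whose columns lack sample metadata.
check_matrix_samples <- function(m, samples) {
  unknown <- setdiff(colnames(m), samples$sample_id)
  if (length(unknown) > 0L) {
    stop("sample(s) without metadata: ", paste(unknown, collapse = ", "))
  }
  invisible(m)
}

#' Read a probe annotation table from TSV
#'
#' Expects columns `probe_id`, `probeset_id`, `probe_class`, `gc_count`,
#' `is_human`.
#'
#' @param path path to a tab-separated file.
#' @return validated annotation data.frame.
#' @export
read_probe_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  a$gc_count <- as.integer(a$gc_count)
  a$is_human <- as.logical(a$is_human)
  a$probeset_id <- as.character(a$probeset_id)
  a$probeset_id[a$probeset_id == ""] <- NA_character_
  validate_annotation(a)
  a
}

#' Read a sample metadata sheet from TSV
#'
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `fraction`, `subject_id`, `sex`.
#' @return validated sample data.frame.
#' @export
read_sample_metadata <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  validate_samples(s)
  s
}
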