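#' Features detected in a given proportion of named samples
#'
#' @param d `detection_table` from [detection_call()].
#' @param sample_ids non-empty subset of the table's sample columns.
#' @param rate required detection proportion in (0, 1]; a feature is
#'   included when detected in at least `ceiling(rate * length(sample_ids))`
#'   of the named samples. `rate = 1` is the 100% (present-in-all)
#'   criterion; `rate = 0.5` over 18 samples requires 9 calls.
#' @return sorted character vector of probe-set identifiers.
#' @export
detected_set <- function(d, sample_ids, rate = 1) {
  stopifnot(inherits(d, "detection_table"))
  if (length(sample_ids) == 0L) stop("sample_ids must be non-empty")
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  unknown <- setdiff(sample_ids, colnames(d$calls))
  if (length(unknown) > 0L) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  need <- ceiling(rate * length(sample_ids))
  hits <- rowSums(d$calls[, sample_ids, drop = FALSE])
  sort(rownames(d$calls)[hits >= need])
}

#' Build the cellular contaminant catalogue
#'
#' Applies the 100% detection criterion within each cellular class (RBC,
#' WBC, LEU) separately — a feature qualifies for a class when detected in
#' every one of that class's samples — then takes the union of the three
#' per-class sets.
#'
#' @param d `detection_table` for the fractionation arm.
#' @param samples sample metadata; must include at least one sample of each
#'   cellular fraction.
#' @return object of class `contaminant_catalog`: list with `members`
#'   (sorted union) and `per_class` (named list of per-class sets).
#' @export
build_catalog <- function(d, samples) {
  stopifnot(inherits(d, "detection_table"))
  validate_samples(samples)
  per_class <- lapply(stats::setNames(nm = CELLULAR_FRACTIONS), function(cl) {
    ids <- samples$sample_id[samples$fraction == cl]
    if (length(ids) == 0L) {
      stop("no samples for cellular class ", cl)
    }
    detected_set(d, ids, rate = 1)
  })
  structure(list(members = sort(unique(unlist(per_class, use.names = FALSE))),
                 per_class = per_class),
            class = "contaminant_catalog")
}

#' @export
print.contaminant_catalog <- function(x, ...) {
  sizes <- vapply(x$per_class, length, integer(1L))
  cat("Contaminant catalogue:", length(x$members), "probe sets",
      sprintf("(RBC %d, WBC %d, LEU %d)\n",
              sizes[["RBC"]], sizes[["WBC"]], sizes[["LEU"]]))
  invisible(x)
}

#' Remove contaminant features
#'
#' Drops catalogue members from a feature set or from the rows of a
#' probe-set matrix. Idempotent; an empty catalogue is the identity.
#'
#' @param x character vector of probe-set ids, or a probe-set matrix.
#' @param catalog `contaminant_catalog` (or a character vector of members).
#' @return the same kind of object with contaminant features removed.
#' @export
filter_contaminants <- function(x, catalog) {
  members <- if (inherits(catalog, "contaminant_catalog")) catalog$members
             else as.character(catalog)
  if (is.matrix(x)) {
    keep <- !(rownames(x) %in% members)
    out <- x[keep, , drop = FALSE]
    attr(out, "scale") <- attr(x, "scale")
    out
  } else {
    x[!(x %in% members)]
  }
}

#' Write a contaminant catalogue as a plain-text member list
#'
#' One probe-set id per line, lexicographic order.
#'
#' @param catalog `contaminant_catalog`.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "contaminant_catalog"))
  writeLines(sort(catalog$members), path)
  invisible(path)
}
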