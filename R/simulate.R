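#' Simulation parameters for the fractionation/cohort generator
#'
#' Defaults emulate the study design the analysis stages assume: 847 human
#' miRNA probe sets of which 313 (37%) are of hematopoietic-cell origin,
#' anti-genomic background probes with GC-dependent baseline signal,
#' contaminant abundance carried over into plasma fractions according to
#' per-fraction multipliers (high in the cloudy supernatant CS and first
#' pellet P1, strongly depleted in the clarified supernatants S1/S2), a
#' circulating feature set stable across plasma fractions and absent from
#' cellular fractions, log-normal probe noise, inter-subject biological
#' variance, and a small set of female-up-regulated features at 1.8x fold
#' change in a cohort of 8 males and 10 females.
#'
#' @param n_features number of human miRNA probe sets.
#' @param n_background number of anti-genomic background probes.
#' @param probes_per_set target probes per probe set.
#' @param frac_contaminant proportion of features of cellular origin.
#' @param carryover named per-fraction multipliers on contaminant linear
#'   abundance.
#' @param circ_mu_log2,circ_sigma_log2 mean/sd of circulating feature log2
#'   abundance.
#' @param contam_mu_log2 mean log2 abundance of contaminant features in the
#'   cellular fractions (they are the high-intensity class).
#' @param noise_sigma_log2 probe-level log-normal noise sd (log2 units).
#' @param bio_sigma_log2 inter-subject sd (log2 units).
#' @param bio_sigma_contam_log2 inter-subject sd for contaminant features;
#'   defaults to `bio_sigma_log2`, may be inflated to emulate variable cell
#'   lysis/carryover between individuals.
#' @param gc_slope background log2 intensity increment per GC base.
#' @param bg_mu_log2 background baseline log2 intensity at GC = 0.
#' @param de_features number of planted female-up-regulated features.
#' @param de_fold linear fold change of planted features (female/male).
#' @param de_min_abundance_log2 abundance floor (log2 linear units) for
#'   features eligible to carry a planted effect; gender-specific markers
#'   are robustly expressed (log2 intensity around 6-7.5), so effects are
#'   planted on circulating features of at least this baseline abundance.
#' @param n_males,n_females cohort sizes.
#' @param n_subjects number of subjects (biological replicates) in the
#'   fractionation arm.
#' @param seed integer seed controlling all randomness.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_features = 847L,
                       n_background = 500L,
                       probes_per_set = 4L,
                       frac_contaminant = 0.37,
                       carryover = c(CS = 1.0, S1 = 0.05, S2 = 0.04,
                                     P1 = 1.0, P2 = 0.05,
                                     RBC = 1.0, WBC = 1.0, LEU = 1.0),
                       circ_mu_log2 = 5,
                       circ_sigma_log2 = 1.5,
                       contam_mu_log2 = 7,
                       noise_sigma_log2 = 0.25,
                       bio_sigma_log2 = 0.4,
                       bio_sigma_contam_log2 = NULL,
                       gc_slope = 0.1,
                       bg_mu_log2 = 2,
                       de_features = 4L,
                       de_fold = 1.8,
                       de_min_abundance_log2 = 6,
                       n_males = 8L,
                       n_females = 10L,
                       n_subjects = 3L,
                       seed = 20110617L) {
  p <- list(n_features = as.integer(n_features),
            n_background = as.integer(n_background),
            probes_per_set = as.integer(probes_per_set),
            frac_contaminant = frac_contaminant,
            carryover = carryover,
            circ_mu_log2 = circ_mu_log2,
            circ_sigma_log2 = circ_sigma_log2,
            contam_mu_log2 = contam_mu_log2,
            noise_sigma_log2 = noise_sigma_log2,
            bio_sigma_log2 = bio_sigma_log2,
            bio_sigma_contam_log2 = if (is.null(bio_sigma_contam_log2))
              bio_sigma_log2 else bio_sigma_contam_log2,
            gc_slope = gc_slope,
            bg_mu_log2 = bg_mu_log2,
            de_features = as.integer(de_features),
            de_fold = de_fold,
            de_min_abundance_log2 = de_min_abundance_log2,
            n_males = as.integer(n_males),
            n_females = as.integer(n_females),
            n_subjects = as.integer(n_subjects),
            seed = as.integer(seed))
  counts <- c(p$n_features, p$n_background, p$probes_per_set,
              p$n_males, p$n_females, p$n_subjects)
  if (any(counts < 1L)) stop("all counts must be positive integers")
  if (p$frac_contaminant < 0 || p$frac_contaminant > 1) {
    stop("frac_contaminant must lie in [0, 1]")
  }
  missing_fr <- setdiff(ALL_FRACTIONS, names(p$carryover))
  if (length(missing_fr) > 0L) {
    stop("carryover must name every fraction; missing: ",
         paste(missing_fr, collapse = ", "))
  }
  if (any(p$carryover < 0)) stop("carryover multipliers must be >= 0")
  sds <- c(p$circ_sigma_log2, p$noise_sigma_log2, p$bio_sigma_log2,
           p$bio_sigma_contam_log2)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (p$de_fold <= 0) stop("de_fold must be positive")
  structure(p, class = "sim_params")
}

# Run `expr` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic probe annotation
#'
#' Creates `n_features * probes_per_set` target probes (grouped into probe
#' sets) plus `n_background` anti-genomic background probes with GC counts
#' uniform on 6..20. Deterministic given the seed.
#'
#' @param p [sim_params()] object.
#' @return annotation data.frame (see [validate_annotation()]).
#' @export
make_annotation <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    probeset_ids <- sprintf("mir-%04d", seq_len(p$n_features))
    target <- data.frame(
      probe_id = sprintf("%s:p%d",
                         rep(probeset_ids, each = p$probes_per_set),
                         rep(seq_len(p$probes_per_set), p$n_features)),
      probeset_id = rep(probeset_ids, each = p$probes_per_set),
      probe_class = "target",
      gc_count = sample(6:20, p$n_features * p$probes_per_set, replace = TRUE),
      is_human = TRUE,
      stringsAsFactors = FALSE
    )
    background <- data.frame(
      probe_id = sprintf("bg-%04d", seq_len(p$n_background)),
      probeset_id = NA_character_,
      probe_class = "background",
      gc_count = sample(6:20, p$n_background, replace = TRUE),
      is_human = FALSE,
      stringsAsFactors = FALSE
    )
    validate_annotation(rbind(target, background))
  })
}

# Feature roles and baseline linear abundances, drawn once per simulation.
# Contaminant features are the high-abundance cellular class; circulating
# features are stable plasma residents.
draw_feature_model <- function(p, probeset_ids) {
  n_contam <- round(p$frac_contaminant * p$n_features)
  contaminant <- sort(sample(probeset_ids, n_contam))
  circulating <- setdiff(probeset_ids, contaminant)
  abundance <- stats::setNames(numeric(p$n_features), probeset_ids)
  abundance[contaminant] <-
    2^stats::rnorm(length(contaminant), p$contam_mu_log2, p$circ_sigma_log2)
  abundance[circulating] <-
    2^stats::rnorm(length(circulating), p$circ_mu_log2, p$circ_sigma_log2)
  list(contaminant = contaminant, circulating = circulating,
       abundance = abundance)
}

# Per-feature x per-subject multiplicative biological effects (2^N(0, sd)),
# with a separate sd for contaminant features.
draw_subject_effects <- function(p, model, subjects) {
  nf <- length(model$abundance)
  eff <- matrix(2^stats::rnorm(nf * length(subjects), 0, p$bio_sigma_log2),
                nrow = nf, dimnames = list(names(model$abundance), subjects))
  is_contam <- names(model$abundance) %in% model$contaminant
  if (any(is_contam) && p$bio_sigma_contam_log2 != p$bio_sigma_log2) {
    eff[is_contam, ] <- 2^stats::rnorm(sum(is_contam) * length(subjects), 0,
                                       p$bio_sigma_contam_log2)
  }
  eff
}

# Assemble the probe-level matrix for given per-feature, per-sample linear
# signals: target probe = signal * 2^noise + GC-dependent baseline * 2^noise;
# background probe = GC-dependent baseline * 2^noise.
build_probe_matrix <- function(p, annotation, signal, sample_ids) {
  is_target <- annotation$probe_class == "target"
  n_probe <- nrow(annotation)
  n_samp <- length(sample_ids)
  baseline <- 2^(p$bg_mu_log2 + p$gc_slope * annotation$gc_count)
  noise <- function(n) 2^stats::rnorm(n, 0, p$noise_sigma_log2)
  m <- matrix(0, nrow = n_probe, ncol = n_samp,
              dimnames = list(annotation$probe_id, sample_ids))
  sig_rows <- signal[annotation$probeset_id[is_target], , drop = FALSE]
  m[is_target, ] <- sig_rows * noise(sum(is_target) * n_samp) +
    baseline[is_target] * noise(sum(is_target) * n_samp)
  m[!is_target, ] <- baseline[!is_target] * noise(sum(!is_target) * n_samp)
  set_scale(m, "linear")
}

#' Simulate the blood fractionation arm
#'
#' One sample per fraction per subject across the eight fractions
#' (CS, S1, S2, P1, P2, RBC, WBC, LEU). Contaminant features' linear
#' abundance is scaled by the fraction's carryover multiplier; circulating
#' features are constant across plasma fractions and absent (background
#' level) in the cellular fractions.
#'
#' @param p [sim_params()] object.
#' @param annotation output of [make_annotation()] (defaults to generating
#'   one from `p`).
#' @return list with `matrix` (linear probe matrix), `samples` (metadata),
#'   `annotation`, and `truth` (planted contaminant/circulating sets,
#'   abundances and parameters).
#' @export
simulate_fractions <- function(p = sim_params(), annotation = make_annotation(p)) {
  stopifnot(inherits(p, "sim_params"))
  validate_annotation(annotation)
  probeset_ids <- unique(annotation$probeset_id[annotation$probe_class == "target"])
  with_seed(p$seed + 1L, {
    model <- draw_feature_model(p, probeset_ids)
    subjects <- sprintf("sub%02d", seq_len(p$n_subjects))
    effects <- draw_subject_effects(p, model, subjects)
    samples <- expand.grid(subject_id = subjects, fraction = ALL_FRACTIONS,
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$fraction, samples$subject_id, sep = "_")
    samples$sex <- "M"
    samples <- samples[, c("sample_id", "fraction", "subject_id", "sex")]
    is_contam <- probeset_ids %in% model$contaminant
    signal <- matrix(0, nrow = length(probeset_ids), ncol = nrow(samples),
                     dimnames = list(probeset_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      fr <- samples$fraction[j]
      subj <- samples$subject_id[j]
      s <- model$abundance * effects[, subj]
      s[is_contam] <- s[is_contam] * p$carryover[[fr]]
      if (fr %in% CELLULAR_FRACTIONS) s[!is_contam] <- 0
      signal[, j] <- s
    }
    m <- build_probe_matrix(p, annotation, signal, samples$sample_id)
    list(matrix = m, samples = validate_samples(samples),
         annotation = annotation,
         truth = list(contaminant = model$contaminant,
                      circulating = model$circulating,
                      abundance = model$abundance, params = p))
  })
}

#' Simulate the male/female cohort arm (S1 fraction)
#'
#' Generates one S1-fraction sample per subject for `n_males` males and
#' `n_females` females. `de_features` randomly chosen circulating features
#' are multiplied by `de_fold` in females; contaminant features appear at
#' their S1 carryover level. Subject effects are drawn once per subject.
#'
#' @inheritParams simulate_fractions
#' @return list with `matrix`, `samples`, `annotation` and `truth` (planted
#'   differential and contaminant sets).
#' @export
simulate_cohort <- function(p = sim_params(), annotation = make_annotation(p)) {
  stopifnot(inherits(p, "sim_params"))
  validate_annotation(annotation)
  probeset_ids <- unique(annotation$probeset_id[annotation$probe_class == "target"])
  with_seed(p$seed + 2L, {
    model <- draw_feature_model(p, probeset_ids)
    if (p$de_features > length(model$circulating)) {
      stop("de_features exceeds the number of circulating features")
    }
    # plant effects on robustly expressed circulating features; fall back to
    # the most abundant ones when too few clear the floor
    eligible <- model$circulating[
      model$abundance[model$circulating] >= 2^p$de_min_abundance_log2]
    if (length(eligible) < p$de_features) {
      ord <- order(model$abundance[model$circulating], decreasing = TRUE)
      eligible <- model$circulating[ord][seq_len(p$de_features)]
    }
    de <- sort(sample(eligible, p$de_features))
    subjects <- c(sprintf("M%d", seq_len(p$n_males)),
                  sprintf("F%d", seq_len(p$n_females)))
    sex <- rep(c("M", "F"), c(p$n_males, p$n_females))
    effects <- draw_subject_effects(p, model, subjects)
    samples <- data.frame(sample_id = paste0("S1_", subjects),
                          fraction = "S1", subject_id = subjects, sex = sex,
                          stringsAsFactors = FALSE)
    is_contam <- probeset_ids %in% model$contaminant
    base <- model$abundance
    base[is_contam] <- base[is_contam] * p$carryover[["S1"]]
    signal <- matrix(0, nrow = length(probeset_ids), ncol = nrow(samples),
                     dimnames = list(probeset_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      s <- base * effects[, samples$subject_id[j]]
      if (sex[j] == "F") s[de] <- s[de] * p$de_fold
      signal[, j] <- s
    }
    m <- build_probe_matrix(p, annotation, signal, samples$sample_id)
    list(matrix = m, samples = validate_samples(samples),
         annotation = annotation,
         truth = list(de = de, de_fold = p$de_fold,
                      contaminant = model$contaminant,
                      circulating = model$circulating,
                      abundance = model$abundance, params = p))
  })
}

#' Write a simulation to disk as the standard TSV/JSON bundle
#'
#' Emits `matrix.tsv`, `probes.tsv`, `samples.tsv` and `truth.json` into a
#' directory.
#'
#' @param sim output of [simulate_fractions()] or [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_probe_matrix(sim$matrix, file.path(dir, "matrix.tsv"))
  write_annotation(sim$annotation, file.path(dir, "probes.tsv"))
  write_samples(sim$samples, file.path(dir, "samples.tsv"))
  truth <- sim$truth
  truth$abundance <- NULL
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
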