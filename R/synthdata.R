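# Synthetic cohorts, count matrices and metabolite panels with planted
# biphasic / monotone / group-shift structure, so every downstream stage of
# the pipeline can be exercised against a known truth table.

#' Specify a synthetic cohort
#'
#' Defines the sampling frame for [generate_cohort()]: cohort size, the BMI
#' distribution (truncated normal) and the sequencing batch layout. Defaults
#' describe a mid-sized cardiac-surgery biopsy cohort: 53 samples with BMI
#' spread over roughly 18-45 and peaking near 28-29, processed in two
#' sequencing batches.
#'
#' @param n_samples Number of samples (>= 8).
#' @param bmi_mean,bmi_sd Mean and standard deviation of the underlying
#'   normal BMI distribution, in BMI units (kg/m^2).
#' @param bmi_range Length-2 numeric, truncation bounds; must bracket
#'   `bmi_mean`.
#' @param n_batches Number of processing batches, assigned round-robin.
#' @param batch_effect_sd Standard deviation (log2 units) of additive
#'   per-batch, per-feature offsets used by [generate_transcriptome()].
#' @param seed Integer seed; a fixed seed makes every generated object
#'   bit-identical across calls.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 53, bmi_mean = 29, bmi_sd = 4.5,
                        bmi_range = c(18, 45), n_batches = 2,
                        batch_effect_sd = 0.3, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 8)
    stop("configuration error: n_samples must be a single number >= 8")
  if (length(bmi_range) != 2 || !(bmi_range[1] < bmi_mean && bmi_mean < bmi_range[2]))
    stop("configuration error: bmi_range must satisfy min < mean < max")
  if (n_batches < 1) stop("configuration error: n_batches must be >= 1")
  structure(list(n_samples = as.integer(n_samples), bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, bmi_range = bmi_range,
                 n_batches = as.integer(n_batches),
                 batch_effect_sd = batch_effect_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws BMI from a truncated normal (inverse-CDF sampling, so the draw is
#' deterministic under the spec's seed) and assigns batches round-robin.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `sample_id`, `bmi`, `batch` (factor) and
#'   attribute `batch_effect_sd`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  lo <- stats::pnorm(spec$bmi_range[1], spec$bmi_mean, spec$bmi_sd)
  hi <- stats::pnorm(spec$bmi_range[2], spec$bmi_mean, spec$bmi_sd)
  u <- stats::runif(spec$n_samples, lo, hi)
  bmi <- stats::qnorm(u, spec$bmi_mean, spec$bmi_sd)
  cohort <- data.frame(
    sample_id = sprintf("S%03d", seq_len(spec$n_samples)),
    bmi = bmi,
    batch = factor(sprintf("batch%d", rep_len(seq_len(spec$n_batches),
                                              spec$n_samples))),
    stringsAsFactors = FALSE
  )
  attr(cohort, "batch_effect_sd") <- spec$batch_effect_sd
  attr(cohort, "bmi_range") <- spec$bmi_range
  cohort
}

#' Describe a planted feature effect
#'
#' A single row of the truth table consumed by [generate_transcriptome()] and
#' [generate_metabolome()]. Biphasic kinds use a continuous hinge mean
#' function: two linear segments in log2 space meeting at `breakpoint`, so the
#' planted extremum is well defined. `group_shift` multiplies intensities by
#' `2^group_log2fc` for samples whose BMI falls inside `stratum`.
#'
#' @param feature_id Feature identifier (must exist in the generated matrix).
#' @param kind One of `"biphasic_u"`, `"biphasic_n"`, `"monotone"`, `"null"`,
#'   `"group_shift"`.
#' @param breakpoint BMI value of the planted extremum (biphasic kinds only).
#' @param slope1,slope2 Segment slopes, log2 units per BMI unit. Biphasic
#'   kinds require opposite signs.
#' @param group_log2fc Log2 fold change applied inside `stratum`
#'   (`group_shift` only).
#' @param stratum Length-2 numeric BMI interval `(lo, hi]`-style bounds (use
#'   `-Inf`/`Inf` for open ends) where the shift applies.
#' @param noise_sd Extra per-observation log2-normal noise.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(feature_id, kind, breakpoint = NA_real_,
                           slope1 = NA_real_, slope2 = NA_real_,
                           group_log2fc = NA_real_, stratum = c(-Inf, Inf),
                           noise_sd = 0.1) {
  kind <- match.arg(kind, c("biphasic_u", "biphasic_n", "monotone", "null",
                            "group_shift"))
  if (kind %in% c("biphasic_u", "biphasic_n")) {
    if (!is.finite(breakpoint)) stop("configuration error: biphasic effect needs a breakpoint")
    if (sign(slope1) == sign(slope2))
      stop("configuration error: biphasic effect requires sign(slope1) != sign(slope2)")
    if (kind == "biphasic_u" && !(slope1 < 0 && slope2 > 0))
      stop("configuration error: biphasic_u requires slope1 < 0 < slope2")
    if (kind == "biphasic_n" && !(slope1 > 0 && slope2 < 0))
      stop("configuration error: biphasic_n requires slope1 > 0 > slope2")
  }
  structure(list(feature_id = feature_id, kind = kind, breakpoint = breakpoint,
                 slope1 = slope1, slope2 = slope2, group_log2fc = group_log2fc,
                 stratum = stratum, noise_sd = noise_sd),
            class = "planted_effect")
}

# Expected log2 signal contributed by one planted effect at given BMI values.
# Exported so tests can use the generator's own mean function as an oracle.

#' Expected log2 effect of a planted feature at given BMI values
#'
#' The generator's mean function: hinge (continuous two-segment) response for
#' biphasic kinds, a single slope for monotone, a stratum indicator times the
#' log2 fold change for group shifts, zero for null.
#'
#' @param effect A [planted_effect()].
#' @param bmi Numeric vector of BMI values.
#' @return Numeric vector of log2-scale expected deviations from baseline.
#' @export
effect_log2_mean <- function(effect, bmi) {
  stopifnot(inherits(effect, "planted_effect"))
  switch(effect$kind,
    biphasic_u = ,
    biphasic_n = ifelse(bmi < effect$breakpoint,
                        effect$slope1 * (bmi - effect$breakpoint),
                        effect$slope2 * (bmi - effect$breakpoint)),
    monotone = effect$slope1 * (bmi - mean(bmi)),
    group_shift = effect$group_log2fc *
      as.numeric(bmi > effect$stratum[1] & bmi <= effect$stratum[2]),
    null = rep(0, length(bmi))
  )
}

effects_to_truth <- function(effects) {
  if (length(effects) == 0)
    return(data.frame(feature_id = character(), kind = character(),
                      breakpoint = numeric(), slope1 = numeric(),
                      slope2 = numeric(), group_log2fc = numeric(),
                      stratum_lo = numeric(), stratum_hi = numeric(),
                      noise_sd = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(effects, function(e) data.frame(
    feature_id = e$feature_id, kind = e$kind, breakpoint = e$breakpoint,
    slope1 = e$slope1, slope2 = e$slope2, group_log2fc = e$group_log2fc,
    stratum_lo = e$stratum[1], stratum_hi = e$stratum[2],
    noise_sd = e$noise_sd, stringsAsFactors = FALSE)))
}

#' Generate a synthetic RNA-seq count matrix
#'
#' Counts are negative-binomial around a log2-scale mean built from a
#' per-feature baseline (uniform on 2-9 log2 CPM), the planted effect's mean
#' function, an additive per-batch log2 offset (sd `batch_effect_sd`, zero-sum
#' across batches in expectation) and per-sample library-size scaling.
#' Gene-wise dispersions are log-normal around 0.05, a realistic level of
#' bulk RNA-seq overdispersion. Features not named in `effects` are flat
#' (null).
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param n_features Number of features.
#' @param effects List of [planted_effect()]; feature ids must be unique and
#'   are matched against `gene0001 ...` style ids (any id not matching an
#'   existing feature id is an error).
#' @param lib_size_mean Mean library size (counts per sample); per-sample
#'   sizes are log-normal with 20% coefficient of variation.
#' @param batch_effect_sd Per-batch offset sd (log2); defaults to the value
#'   recorded on the cohort.
#' @param seed Integer seed.
#' @return Integer matrix features x samples with `truth` attribute (the
#'   planted-effect table).
#' @export
generate_transcriptome <- function(cohort, n_features, effects = list(),
                                   lib_size_mean = 5e6,
                                   batch_effect_sd = attr(cohort, "batch_effect_sd"),
                                   seed = 1L) {
  ids <- vapply(effects, function(e) e$feature_id, character(1))
  if (anyDuplicated(ids))
    stop("configuration error: duplicate feature ids in effects")
  if (length(effects) > n_features)
    stop("configuration error: more effects than features")
  if (is.null(batch_effect_sd)) batch_effect_sd <- 0
  set.seed(seed)
  n <- nrow(cohort)
  feature_id <- sprintf("gene%04d", seq_len(n_features))
  if (!all(ids %in% feature_id))
    stop("configuration error: effect feature ids not present in the matrix")
  base <- stats::runif(n_features, 2, 9)               # baseline log2 CPM
  disp <- stats::rlnorm(n_features, log(0.05), 0.3)    # gene-wise dispersion
  lib <- stats::rlnorm(n, log(lib_size_mean), 0.2)
  batches <- levels(cohort$batch)
  # per-feature, per-batch offsets; centered so the batch term is pure contrast
  boff <- matrix(stats::rnorm(n_features * length(batches), 0, batch_effect_sd),
                 n_features, length(batches))
  boff <- boff - rowMeans(boff)
  if (batch_effect_sd == 0) boff[] <- 0
  eta <- matrix(base, n_features, n) + boff[, as.integer(cohort$batch), drop = FALSE]
  for (e in effects) {
    i <- match(e$feature_id, feature_id)
    eta[i, ] <- eta[i, ] + effect_log2_mean(e, cohort$bmi)
    if (e$noise_sd > 0)
      eta[i, ] <- eta[i, ] + stats::rnorm(n, 0, e$noise_sd)
  }
  mu <- 2^eta * rep(lib / 1e6, each = n_features)
  counts <- matrix(stats::rnbinom(n_features * n, mu = mu,
                                  size = rep(1 / disp, n)),
                   n_features, n,
                   dimnames = list(feature_id, cohort$sample_id))
  storage.mode(counts) <- "integer"
  attr(counts, "truth") <- effects_to_truth(effects)
  counts
}

#' Generate a synthetic metabolite intensity panel
#'
#' Log-normal positive intensities; `group_shift` effects multiply a
#' metabolite's intensity by `2^group_log2fc` for samples whose BMI falls in
#' the effect's stratum; missing values are inserted completely at random.
#'
#' @param cohort Cohort table.
#' @param panel_size Number of metabolites in the panel.
#' @param effects List of [planted_effect()] (typically `group_shift`).
#' @param missing_rate MCAR missingness proportion in `[0, 1)`.
#' @param noise_sd Baseline log2 biological + technical noise sd.
#' @param seed Integer seed.
#' @return Numeric matrix metabolites x samples with `NA` for missing cells
#'   and a `truth` attribute.
#' @export
generate_metabolome <- function(cohort, panel_size = 144, effects = list(),
                                missing_rate = 0.05, noise_sd = 0.6,
                                seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("configuration error: missing_rate must be in [0, 1)")
  if (panel_size < length(effects))
    stop("configuration error: panel_size smaller than number of effects")
  ids <- vapply(effects, function(e) e$feature_id, character(1))
  if (anyDuplicated(ids))
    stop("configuration error: duplicate feature ids in effects")
  set.seed(seed)
  n <- nrow(cohort)
  metab_id <- sprintf("met%03d", seq_len(panel_size))
  # planted effects occupy the first slots under their own names
  if (length(effects)) metab_id[seq_along(effects)] <- ids
  base <- stats::runif(panel_size, 10, 20)   # log2 abundance
  eta <- matrix(base, panel_size, n) +
    matrix(stats::rnorm(panel_size * n, 0, noise_sd), panel_size, n)
  for (e in effects) {
    i <- match(e$feature_id, metab_id)
    eta[i, ] <- eta[i, ] + effect_log2_mean(e, cohort$bmi)
    if (!is.na(e$noise_sd) && e$noise_sd > 0)
      eta[i, ] <- eta[i, ] + stats::rnorm(n, 0, e$noise_sd)
  }
  intens <- 2^eta
  if (missing_rate > 0) {
    miss <- stats::runif(panel_size * n) < missing_rate
    intens[matrix(miss, panel_size, n)] <- NA_real_
  }
  dimnames(intens) <- list(metab_id, cohort$sample_id)
  attr(intens, "truth") <- effects_to_truth(effects)
  intens
}

#' Default synthetic study fixture
#'
#' One call generating the complete study-scale dataset used throughout the
#' package's tests and examples: 53 samples in 2 batches; 2,000 transcript
#' features of which 60 are biphasic (breakpoints drawn from Normal(28.5, 2)
#' truncated to 22-35, half u- and half n-shaped, segment slopes 0.08-0.15
#' log2/BMI unit) and 100 monotone, the rest null; a 144-metabolite panel
#' carrying 8 acylcarnitine-like upshifts in the high-BMI stratum (BMI > 32)
#' and one alpha-ketoglutarate-like metabolite elevated at low BMI
#' (BMI < 25).
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_features,n_biphasic,n_monotone Transcriptome dimensions.
#' @param panel_size Metabolite panel size.
#' @return A list of class `synthetic_dataset` with elements `cohort`,
#'   `counts`, `metabolites`, `truth` (transcript truth table) and
#'   `truth_metab`.
#' @export
default_fixture <- function(seed = 1L, n_features = 2000, n_biphasic = 60,
                            n_monotone = 100, panel_size = 144) {
  spec <- cohort_spec(seed = seed)
  cohort <- generate_cohort(spec)
  set.seed(seed + 1000L)
  bp <- stats::qnorm(stats::runif(n_biphasic,
                                  stats::pnorm(22, 28.5, 2),
                                  stats::pnorm(35, 28.5, 2)), 28.5, 2)
  sl <- function(k) stats::runif(k, 0.08, 0.15)
  s1 <- sl(n_biphasic); s2 <- sl(n_biphasic)
  kinds <- rep(c("biphasic_u", "biphasic_n"), length.out = n_biphasic)
  effects <- vector("list", n_biphasic + n_monotone)
  for (i in seq_len(n_biphasic)) {
    u <- kinds[i] == "biphasic_u"
    effects[[i]] <- planted_effect(sprintf("gene%04d", i), kinds[i],
                                   breakpoint = bp[i],
                                   slope1 = if (u) -s1[i] else s1[i],
                                   slope2 = if (u) s2[i] else -s2[i],
                                   noise_sd = 0.1)
  }
  mono_slope <- stats::runif(n_monotone, 0.05, 0.12) *
    sample(c(-1, 1), n_monotone, replace = TRUE)
  for (j in seq_len(n_monotone)) {
    effects[[n_biphasic + j]] <- planted_effect(
      sprintf("gene%04d", n_biphasic + j), "monotone",
      slope1 = mono_slope[j], noise_sd = 0.1)
  }
  counts <- generate_transcriptome(cohort, n_features, effects, seed = seed + 1L)

  set.seed(seed + 2000L)
  acyl_fc <- stats::runif(8, 0.7, 1.2)
  met_effects <- c(
    lapply(seq_len(8), function(i) planted_effect(
      sprintf("acylcarnitine_like_%02d", i), "group_shift",
      group_log2fc = acyl_fc[i], stratum = c(32, Inf), noise_sd = 0)),
    list(planted_effect("alpha_ketoglutarate_like", "group_shift",
                        group_log2fc = 0.541, stratum = c(-Inf, 25),
                        noise_sd = 0))
  )
  metab <- generate_metabolome(cohort, panel_size, met_effects,
                               missing_rate = 0.05, seed = seed + 2L)
  structure(list(cohort = cohort, counts = counts, metabolites = metab,
                 truth = attr(counts, "truth"),
                 truth_metab = attr(metab, "truth")),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the four files the pipeline readers consume: counts TSV (feature id
#' in the first column), metadata CSV (`sample_id,bmi,batch`), metabolite TSV
#' with empty cells for missing values, and the truth tables.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             truth = file.path(dir, "truth_transcripts.tsv"),
             truth_metab = file.path(dir, "truth_metabolites.tsv"))
  write_matrix_tsv(dataset$counts, paths["counts"], id_col = "feature_id")
  utils::write.csv(dataset$cohort, paths["metadata"], row.names = FALSE,
                   quote = FALSE)
  write_matrix_tsv(dataset$metabolites, paths["metabolites"],
                   id_col = "metabolite_id", na = "")
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$truth_metab, paths["truth_metab"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
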