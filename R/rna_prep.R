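# Expression preprocessing: low-expression filtering, log-CPM transform,
# quantile normalization and batch-effect removal. Downstream statistics
# (two-segment scans, moderated models, networks) all run on the matrix this
# stage produces.

#' Filter weakly expressed features
#'
#' A feature is kept iff its CPM exceeds `min_count` scaled by the median
#' library size (in millions) in at least `min(group_sizes)` samples, and its
#' total count across samples is at least `min_count + 5`. This is the
#' standard expression filter for count matrices ahead of linear modelling,
#' stated as an explicit rule so its behaviour is fully testable.
#'
#' @param counts Nonnegative integer matrix, features x samples.
#' @param group_sizes Integer vector of per-group sample counts; the smallest
#'   group sets the minimum number of samples in which a feature must pass
#'   the CPM cutoff.
#' @param min_count Minimum count per sample (at the median library size).
#' @return List with `counts` (kept features) and `record`, a
#'   `normalization_record` documenting the applied cutoffs.
#' @export
filter_low_expression <- function(counts, group_sizes, min_count = 10) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0)
    stop("input error: empty count matrix")
  if (any(counts < 0)) stop("input error: negative counts")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("input error: zero library size for sample(s) ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (!length(group_sizes) || all(group_sizes < 1))
    stop("input error: need at least one group of size >= 1")
  med_lib_millions <- stats::median(lib) / 1e6
  cpm_cutoff <- min_count / med_lib_millions
  cpm <- t(t(counts) / lib * 1e6)
  min_samples <- min(group_sizes[group_sizes >= 1])
  keep <- rowSums(cpm >= cpm_cutoff) >= min_samples &
    rowSums(counts) >= min_count + 5
  record <- structure(list(
    n_features_in = nrow(counts), n_features_kept = sum(keep),
    cpm_cutoff = cpm_cutoff, min_samples = min_samples,
    min_count = min_count), class = "normalization_record")
  list(counts = counts[keep, , drop = FALSE], record = record)
}

#' Log2 counts-per-million transform
#'
#' `log2((count + 0.5) / (library size + 1) * 1e6)`; the half-count offset
#' keeps zeros finite.
#'
#' @param counts Nonnegative count matrix.
#' @return Numeric matrix of log2-CPM values, same dimnames.
#' @export
cpm_log_transform <- function(counts) {
  if (any(counts < 0)) stop("input error: negative counts")
  lib <- colSums(counts)
  log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same distribution: the mean of
#' the per-sample sorted value vectors. Ties within a sample receive the mean
#' of the reference values at their tied ranks.
#'
#' @param m Numeric matrix without missing values.
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("input error: missing values not allowed")
  if (ncol(m) == 1) {
    warning("single sample: quantile normalization is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Remove batch effects from a normalized matrix
#'
#' Per-feature least-squares batch coefficients (estimated jointly with
#' optional group terms, so real group structure is not absorbed into the
#' batch term) are subtracted; a final re-centering keeps every feature's
#' grand mean exactly unchanged.
#'
#' @param m Numeric matrix, features x samples.
#' @param batch Per-sample batch labels (>= 2 levels, each with >= 2
#'   samples).
#' @param preserve Optional per-sample group labels to protect during
#'   removal.
#' @return Batch-corrected matrix.
#' @export
remove_batch <- function(m, batch, preserve = NULL) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("input error: need >= 2 batch levels")
  if (any(table(batch) < 2))
    stop("input error: every batch needs >= 2 samples")
  if (!is.null(preserve)) {
    preserve <- factor(preserve)
    design <- stats::model.matrix(~preserve)
    full <- cbind(design, stats::model.matrix(~batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full))
      stop("confounding error: batch is confounded with the preserved groups")
  } else {
    design <- matrix(1, ncol(m), 1)
  }
  out <- limma::removeBatchEffect(m, batch = batch, design = design)
  out + (rowMeans(m) - rowMeans(out))
}
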