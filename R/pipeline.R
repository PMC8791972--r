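# End-to-end orchestration: read the four inputs, run preparation, the
# biphasic scan, group definition, differential expression, gene-set tests,
# correlation networks, metabolite contrasts and transcript-metabolite
# integration, writing every output file plus a JSON run manifest with input
# hashes, the config echo, the seed and per-stage timings.

#' Build a validated pipeline configuration
#'
#' All tunables of the pipeline in one flat list. Unknown keys are rejected
#' so typos cannot silently disable an option.
#'
#' @param paths Named list with `counts`, `metadata`, `metabolites`,
#'   `gene_sets` (GMT) and `out_dir`.
#' @param ... Overrides for the defaults: `alpha` (0.05), `min_arm` (5),
#'   `halfwidth` (3), `min_count` (10), `p_cut` (0.05), `powers` (1:20),
#'   `r2_target` (0.8), `cut_height` (0.25), `min_size` (10),
#'   `missing_cutoff` (0.2), `rsd_cutoff` (3), `n_components` (2),
#'   `threshold` (0.7), `covariate` ("bmi"), `seed` (1).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, ...) {
  defaults <- list(alpha = 0.05, min_arm = 5, halfwidth = 3, min_count = 10,
                   p_cut = 0.05, powers = 1:20, r2_target = 0.8,
                   cut_height = 0.25, min_size = 10, missing_cutoff = 0.2,
                   rsd_cutoff = 3, n_components = 2, threshold = 0.7,
                   covariate = "bmi", seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown config keys: ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, dots)
  need <- c("counts", "metadata", "metabolites", "gene_sets", "out_dir")
  miss <- setdiff(need, names(paths))
  if (length(miss))
    stop("configuration error: paths missing: ", paste(miss, collapse = ", "))
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$min_arm >= 2,
            cfg$halfwidth > 0, cfg$threshold > 0, cfg$threshold <= 1,
            cfg$missing_cutoff >= 0, cfg$missing_cutoff < 1)
  cfg$paths <- paths
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a `paths:` block and any scalar overrides.
#' @return A `pipeline_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  paths <- y$paths
  y$paths <- NULL
  do.call(pipeline_config, c(list(paths = paths), y))
}

#' Read and cross-check the pipeline inputs
#'
#' Parses the counts TSV, metadata CSV, metabolite TSV (empty cells are
#' missing) and GMT gene sets, and aligns samples by id. Any id present in
#' one expression input but absent from the metadata is a hard consistency
#' error: samples are never silently dropped.
#'
#' @param paths Named list as in [pipeline_config()].
#' @return List `counts`, `metadata`, `metabolites`, `sets`; expression
#'   columns reordered to match the metadata rows present in each assay.
#' @export
read_inputs <- function(paths) {
  counts <- read_matrix_tsv(paths$counts)
  meta <- read_metadata_csv(paths$metadata)
  metab <- read_matrix_tsv(paths$metabolites)
  sets <- read_gmt(paths$gene_sets)
  off <- setdiff(colnames(counts), meta$sample_id)
  off2 <- setdiff(colnames(metab), meta$sample_id)
  if (length(off) || length(off2))
    stop("consistency error: samples missing from metadata: ",
         paste(unique(c(off, off2)), collapse = ", "))
  storage.mode(counts) <- "integer"
  list(counts = counts, metadata = meta, metabolites = metab, sets = sets)
}

.write_stage <- function(obj, path) {
  if (is.matrix(obj)) write_matrix_tsv(obj, path)
  else utils::write.table(obj, path, sep = "\t", row.names = FALSE,
                          quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: expression filtering + log-CPM + quantile
#' normalization + batch removal; the per-feature two-segment biphasic scan;
#' breakpoint aggregation and data-driven group definition; moderated
#' differential expression; competitive gene-set tests per contrast;
#' correlation-network modules, eigengenes and their BMI tests plus per-
#' module over-representation; metabolite preprocessing and pairwise
#' contrasts; and transcript-metabolite association network export. Rerunning
#' with an identical config and seed reproduces every output bit-identically.
#'
#' @param config A `pipeline_config`.
#' @return The run manifest (also written to `manifest.json` in the output
#'   directory): input hashes, config echo, seed, per-stage timings and the
#'   output file list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  outputs <- character(); timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr),
                  error = function(e) stop("stage '", name, "' failed: ",
                                           conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  inputs <- stage("read", read_inputs(config$paths))
  meta_rna <- inputs$metadata[match(colnames(inputs$counts),
                                    inputs$metadata$sample_id), ]
  bmi <- meta_rna[[config$covariate]]

  norm <- stage("prep", {
    filt <- filter_low_expression(inputs$counts,
                                  group_sizes = as.integer(table(meta_rna$batch)),
                                  min_count = config$min_count)
    lg <- cpm_log_transform(filt$counts)
    qn <- quantile_normalize(lg)
    corrected <- if (nlevels(meta_rna$batch) >= 2)
      remove_batch(qn, meta_rna$batch) else qn
    outputs <- c(outputs, .write_stage(corrected,
                                       file.path(out_dir, "normalized.tsv")))
    jsonlite::write_json(unclass(filt$record),
                         file.path(out_dir, "normalization_record.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, "normalization_record.json"),
                  file.path(out_dir, "normalized.tsv"))
    list(m = corrected, record = filt$record)
  })

  fits <- stage("twolines", {
    f <- scan_features(norm$m, bmi, alpha = config$alpha,
                       min_arm = config$min_arm)
    outputs <- c(outputs, .write_stage(f, file.path(out_dir, "fits.tsv")))
    f
  })

  scheme <- stage("groups", {
    summ <- summarize_breakpoints(fits)
    sc <- define_groups(summ, halfwidth = config$halfwidth)
    grp <- data.frame(sample_id = inputs$metadata$sample_id,
                      bmi = inputs$metadata[[config$covariate]],
                      group = assign_group(inputs$metadata[[config$covariate]],
                                           sc))
    outputs <- c(outputs, .write_stage(grp, file.path(out_dir, "groups.tsv")))
    jsonlite::write_json(list(lower = sc$lower, upper = sc$upper,
                              modal_bins = summ$modal_bins),
                         file.path(out_dir, "group_scheme.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, "group_scheme.json"))
    sc
  })
  groups_rna <- assign_group(bmi, scheme)

  defit <- stage("de", {
    fit <- fit_moderated_model(norm$m, groups_rna,
                               batch = if (nlevels(meta_rna$batch) >= 2)
                                 meta_rna$batch else NULL)
    de <- data.frame(feature_id = rownames(fit$coefficients),
                     fit$coefficients, check.names = FALSE,
                     F = fit$F, F_p = fit$F_p, F_q = fit$F_q)
    outputs <- c(outputs, .write_stage(de, file.path(out_dir, "de.tsv")))
    fit
  })

  stage("gsa", {
    for (ctr in colnames(defit$t)) {
      res <- suppressWarnings(
        camera_test(defit$t[, ctr], defit$residuals, inputs$sets,
                    df_stat = defit$df_resid))
      outputs <- c(outputs, .write_stage(
        res, file.path(out_dir, paste0("genesets_", gsub("[^a-zA-Z0-9]", "_",
                                                         ctr), ".tsv"))))
    }
    NULL
  })

  netres <- stage("network", {
    vars <- select_variable_features(defit, p_cut = config$p_cut)
    if (length(vars) < max(3, config$min_size)) {
      warning("too few variable features for network analysis")
      NULL
    } else {
      sub <- norm$m[vars, , drop = FALSE]
      st <- pick_soft_threshold(sub, powers = config$powers,
                                r2_target = config$r2_target)
      at <- adjacency_tom(sub, st$beta)
      part <- detect_modules(at$tom, min_size = config$min_size,
                             cut_height = config$cut_height)
      profs <- module_eigengene(sub, part)
      profs <- eigengene_bmi_tests(profs, bmi, groups_rna,
                                   alpha = config$alpha,
                                   min_arm = config$min_arm)
      outputs <- c(outputs, .write_stage(
        data.frame(feature_id = names(part), module = as.character(part)),
        file.path(out_dir, "modules.tsv")))
      if (length(profs)) {
        eg <- do.call(cbind, lapply(profs, `[[`, "eigengene"))
        colnames(eg) <- vapply(profs, `[[`, character(1), "module")
        outputs <- c(outputs, .write_stage(
          eg, file.path(out_dir, "eigengenes.tsv")))
        mt <- do.call(rbind, lapply(profs, function(p) data.frame(
          module = p$module, n_members = p$n_members,
          var_explained = p$var_explained, bmi_r = p$bmi_corr$r,
          bmi_q = p$bmi_corr$q, shape = p$twolines$shape,
          breakpoint = p$twolines$breakpoint, anova_p = p$anova_p)))
        outputs <- c(outputs, .write_stage(
          mt, file.path(out_dir, "module_tests.tsv")))
        enr <- do.call(rbind, lapply(profs, function(p) {
          members <- names(part)[part == p$module]
          e <- overrep_test(members, vars, inputs$sets)
          if (nrow(e)) cbind(module = p$module, e) else NULL
        }))
        if (!is.null(enr) && nrow(enr))
          outputs <- c(outputs, .write_stage(
            enr, file.path(out_dir, "module_enrichment.tsv")))
      }
      list(vars = vars, partition = part, profiles = profs)
    }
  })

  metabres <- stage("metab", {
    meta_met <- inputs$metadata[match(colnames(inputs$metabolites),
                                      inputs$metadata$sample_id), ]
    groups_met <- assign_group(meta_met[[config$covariate]], scheme)
    ml <- preprocess_metabolites(inputs$metabolites,
                                 missing_cutoff = config$missing_cutoff,
                                 rsd_cutoff = config$rsd_cutoff)
    pairs <- list(c("low", "mid"), c("mid", "high"), c("low", "high"))
    res <- list()
    for (pr in pairs) {
      if (sum(groups_met == pr[1]) >= 3 && sum(groups_met == pr[2]) >= 3)
        res[[paste(pr, collapse = "_")]] <-
          contrast_metabolites(ml, groups = groups_met, pair = pr,
                               seed = config$seed)
    }
    if (length(res)) {
      all_res <- do.call(rbind, res)
      rownames(all_res) <- NULL
      outputs <- c(outputs, .write_stage(
        all_res, file.path(out_dir, "metabolite_contrasts.tsv")))
    }
    list(log = ml, groups = groups_met, contrasts = res)
  })

  stage("integrate", {
    shared <- intersect(colnames(norm$m), colnames(metabres$log))
    vars <- if (!is.null(netres)) netres$vars else
      select_variable_features(defit, p_cut = config$p_cut)
    if (length(shared) < 5 || length(vars) < 2) {
      warning("integration skipped: insufficient shared samples or features")
      NULL
    } else {
      w <- latent_association_scores(norm$m[vars, shared, drop = FALSE],
                                     metabres$log[, shared, drop = FALSE],
                                     n_components = config$n_components)
      net <- build_network(w, threshold = config$threshold)
      outputs <- c(outputs, export_network(
        net, file.path(out_dir, "association_network.sif"), "sif"))
      outputs <- c(outputs, export_network(
        net, file.path(out_dir, "association_network.graphml"), "graphml"))
      net
    }
  })

  outputs <- unique(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bmiomics")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)), "paths")],
    inputs = lapply(config$paths[c("counts", "metadata", "metabolites",
                                   "gene_sets")],
                    function(p) unname(tools::md5sum(p))),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
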