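# Pipeline configuration: every analysis threshold, with its standard default.
# Kept flat so configs stay human-editable YAML.
pipeline_defaults <- function() {
  list(
    min_cpm = 1, min_cpm_samples = 5,
    mean_cut = 2, rep_cut = 1,
    rpkm_cut = 5, fdr_cut = 0.05, lfc_cut = 2,
    venn_expressed_cut = 2,
    min_direct = 50, min_propagated = 150,
    normalization = "rank_inverse_normal",
    folds = 5, recall_target = 0.10,
    c_grid = c(0.01, 0.1, 1, 10)
  )
}

check_config_value <- function(key, value) {
  ok <- switch(
    key,
    min_cpm = is.numeric(value) && value >= 0,
    min_cpm_samples = is_count(value) && value >= 1,
    mean_cut = , rep_cut = , rpkm_cut = , lfc_cut = ,
    venn_expressed_cut = is.numeric(value) && length(value) == 1,
    fdr_cut = is.numeric(value) && value > 0 && value <= 1,
    min_direct = , min_propagated = is_count(value) && value >= 0,
    normalization = value %in% c("rank_inverse_normal", "zscore"),
    folds = is_count(value) && value >= 2,
    recall_target = is.numeric(value) && value > 0 && value <= 1,
    c_grid = is.numeric(value) && length(value) >= 1 && all(value > 0),
    FALSE
  )
  isTRUE(ok)
}

#' Validate a pipeline configuration file
#'
#' Reads a flat YAML key-value file, rejects unknown keys and out-of-range
#' values (listing every offender), and fills unspecified keys with the
#' standard defaults. An empty file yields all defaults.
#'
#' @param path path to a YAML config file.
#' @return a `pipeline_config` list.
#' @export
validate_config <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop_input("no such config file: ", path)
  if (is.null(user)) user <- list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  bad <- names(user)[!vapply(names(user), function(k) {
    k %in% names(defaults) && check_config_value(k, user[[k]])
  }, logical(1))]
  bad <- setdiff(bad, unknown)
  if (length(unknown) || length(bad)) {
    stop_input(
      "invalid configuration: ",
      if (length(unknown)) paste0("unknown key(s): ",
                                  paste(unknown, collapse = ", "), "; ") else "",
      if (length(bad)) paste0("out-of-range value(s): ",
                              paste(bad, collapse = ", ")) else ""
    )
  }
  cfg <- defaults
  for (k in names(user)) cfg[[k]] <- if (is.list(user[[k]]))
    unlist(user[[k]]) else user[[k]]
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' Round-trips through [validate_config()].
#'
#' @param config a `pipeline_config` (or plain list of known keys).
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the full synthetic prediction study
#'
#' Generates the default synthetic prediction world (2,000 genes, 8 tissues
#' in 4 systems, 12 datasets of whole-animal mixture samples), the toy
#' anatomy ontology with partial noisy annotations, the propagated gold
#' standard and the normalized compendium. Used by [run_demo()], and directly
#' by analyses that only need the prediction stage.
#'
#' @param seed global seed; stage seeds are derived from it.
#' @param config pipeline configuration (demo gold-standard retention
#'   thresholds are scaled to the simulated annotation volume).
#' @return list: `signatures` (with truth sets), `compendium` (assembled),
#'   `sim` (raw simulated datasets + truth), `anatomy`, `gold_standard`,
#'   `tissue_terms` (term id -> signature tissue name map).
#' @export
build_prediction_study <- function(seed = 1L, config = pipeline_defaults()) {
  sigs <- tissue_signatures(seed = derive_seed(seed, "signatures"))
  sim <- simulate_compendium(
    sim_compendium_config(seed = derive_seed(seed, "compendium")),
    sigs$signatures
  )
  normalized <- lapply(sim$datasets, normalize_dataset,
                       method = config$normalization)
  compendium <- assemble_compendium(normalized, universe = rownames(sigs$signatures))

  anatomy <- simulate_anatomy(
    sim_anatomy_config(seed = derive_seed(seed, "anatomy")),
    memberships = sigs$memberships
  )
  ann <- filter_small_scale(anatomy$annotations)
  propagated <- propagate_annotations(ann, anatomy$ontology)
  slim <- define_slim(anatomy$ontology, slim = anatomy$ontology$slim_roots)
  # retention thresholds scaled to the simulated annotation volume
  retained <- select_tissues(propagated, min_direct = 20, min_propagated = 40)
  retained <- intersect(anatomy$truth$tissues, retained)
  gs <- build_gold_standard(propagated, slim, retained)

  tissue_terms <- setNames(colnames(sigs$memberships), anatomy$truth$tissues)
  list(signatures = sigs, sim = sim, compendium = compendium,
       anatomy = anatomy, gold_standard = gs, tissue_terms = tissue_terms)
}

#' Run the self-contained end-to-end demonstration
#'
#' Generates a synthetic 4-tissue replicate RNA-seq experiment and the full
#' synthetic prediction study, then runs the complete pipeline: detection
#' filter, expressed / enriched / unique calling, pathway-set Venn
#' partitioning, gold-standard construction, compendium assembly, per-tissue
#' SVM training with cross-validated cost selection, genome-wide prediction,
#' and evaluation (per-tissue precision at 10% recall, tissue-concordance of
#' truth-enriched gene-set scores, sample-contribution ranks). Writes every
#' stage's outputs plus a human-readable report and a manifest with per-file
#' checksums.
#'
#' @param seed global seed; one seed determines every stage.
#' @param out_dir output directory (created if needed).
#' @param config a `pipeline_config`; defaults to [pipeline_defaults()].
#' @return invisibly, a list with the `manifest`, the fitted `tissue_svm`
#'   object, the `gene_calls`, and the headline `metrics`.
#' @export
run_demo <- function(seed = 1L, out_dir = file.path(tempdir(), "tissueome-demo"),
                     config = pipeline_defaults()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    val
  }

  # stage 1: tissue-ome RNA-seq and gene calling
  rnaseq <- tick("simulate_rnaseq", simulate_tissue_rnaseq(
    sim_tissue_config(seed = derive_seed(seed, "rnaseq"))))
  detected <- cpm_filter(rnaseq$expr, config$min_cpm, config$min_cpm_samples)
  calls <- tick("gene_calls", gene_calls(
    rnaseq$expr, config$mean_cut, config$rep_cut, config$rpkm_cut,
    config$fdr_cut, config$lfc_cut))

  # pathway-style Venn partition: a planted "target" panel spanning classes
  panel <- c(rnaseq$truth$ubiquitous[1:40],
             unlist(lapply(rnaseq$truth$unique, head, 10), use.names = FALSE))
  venn <- venn_partition(panel, expressed_by_mean(rnaseq$expr,
                                                  config$venn_expressed_cut))

  # stage 2: prediction study (gold standard + compendium + SVMs)
  study <- tick("prediction_study", build_prediction_study(seed, config))
  fit <- tick("tissue_svm", tissue_svm(
    study$compendium, study$gold_standard, c_grid = config$c_grid,
    folds = config$folds, recall_target = config$recall_target,
    seed = derive_seed(seed, "svm")))

  # stage 3: evaluation
  enriched_truth <- lapply(study$signatures$specific, identity)
  names(enriched_truth) <- names(study$tissue_terms)[
    match(names(enriched_truth), study$tissue_terms)]
  profile <- gene_set_profile(fit, enriched_truth[colnames(fit$predictions)])
  concordant <- sum(vapply(rownames(profile$scores), function(t) {
    colnames(profile$scores)[which.max(profile$scores[t, ])] == t
  }, logical(1)))
  contrib <- sample_contributions(fit)
  perf <- summary(fit)
  metrics <- list(
    median_precision_at_target = median_precision(perf$precision_at_target),
    concordant_tissues = concordant,
    n_prediction_tissues = nrow(perf),
    detected_genes = length(detected),
    expressed = lengths(calls$expressed),
    enriched = lengths(calls$enriched),
    unique = lengths(calls$unique)
  )

  # stage 4: outputs, report, manifest
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  write_tissue_expr(rnaseq$expr, file.path(out_dir, "tissueome"))
  write.table(calls$table, file.path(out_dir, "gene_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(calls$expressed, file.path(out_dir, "expressed.gmt"))
  write_gmt(calls$enriched, file.path(out_dir, "enriched.gmt"))
  write_gmt(calls$unique, file.path(out_dir, "unique.gmt"))
  write_json_file(venn$blocks, file.path(out_dir, "venn_blocks.json"))
  write_obo(study$anatomy$ontology, file.path(out_dir, "anatomy.obo"))
  write_annotations(study$anatomy$annotations,
                    file.path(out_dir, "annotations.tsv"))
  write_gold_standard(study$gold_standard,
                      file.path(out_dir, "gold_standard.tsv"))
  write_compendium(study$compendium, file.path(out_dir, "compendium"))
  write_matrix_tsv(round(fit$predictions, 6),
                   file.path(out_dir, "predictions.tsv"))
  write_matrix_tsv(round(fit$raw, 6), file.path(out_dir, "raw_scores.tsv"))
  write_json_file(
    lapply(fit$models, function(m) list(w = unname(m$w), b = m$b, c = m$cost)),
    file.path(out_dir, "models.json"))
  write_matrix_tsv(contrib$ranks, file.path(out_dir, "sample_ranks.tsv"))
  report_path <- file.path(out_dir, "report.txt")
  writeLines(c(
    "tissueome demonstration run",
    sprintf("seed: %d", seed),
    sprintf("detected genes (CPM filter): %d", length(detected)),
    "",
    "tissue-ome calls (expressed / enriched / unique):",
    sprintf("  %-12s %5d %5d %5d", names(calls$expressed),
            lengths(calls$expressed), lengths(calls$enriched),
            lengths(calls$unique)),
    "",
    sprintf("prediction models: %d tissues", nrow(perf)),
    sprintf("  %-8s prior=%.3f best_c=%-5g precision@%d%%recall=%.3f",
            perf$tissue, perf$prior, perf$best_c,
            round(100 * config$recall_target), perf$precision_at_target),
    sprintf("median precision at %d%% recall: %.3f",
            round(100 * config$recall_target),
            metrics$median_precision_at_target),
    sprintf("tissue concordance of truth-enriched gene-set scores: %d/%d",
            concordant, nrow(perf))
  ), report_path)

  files <- setdiff(list.files(out_dir, full.names = TRUE), file.path(out_dir, "manifest.json"))
  manifest <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("tissueome")),
    files = data.frame(
      name = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    ),
    timings_seconds = as.list(timings)
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest, fit = fit, calls = calls, venn = venn,
                 profile = profile, contributions = contrib,
                 metrics = metrics, study = study, rnaseq = rnaseq))
}
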