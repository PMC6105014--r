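#' Configuration for the multi-tissue RNA-seq simulator
#'
#' Defaults emulate a 4-tissue adult bulk RNA-seq study with replicate
#' libraries, a negative-binomial count noise model (variance =
#' mu + dispersion * mu^2), and planted ubiquitous / tissue-enriched /
#' tissue-unique gene classes. Planted classes are disjoint across tissues and
#' unique genes are, by construction, a subset of the enriched genes of their
#' tissue.
#'
#' @param n_tissues number of tissues (>= 2).
#' @param replicates_per_tissue replicate libraries per tissue (>= 2).
#' @param n_genes total genes in the simulated genome.
#' @param n_ubiquitous genes expressed at baseline in every tissue.
#' @param n_enriched_per_tissue planted enriched genes per tissue.
#' @param n_unique_per_tissue planted unique genes per tissue; must not exceed
#'   `n_enriched_per_tissue` (unique genes are the first unique-sized block of
#'   each tissue's enriched genes).
#' @param enrichment_log2fc planted effect, log2 units, added in the target
#'   tissue on top of the gene's baseline.
#' @param baseline_log2_mean,baseline_log2_sd normal distribution of per-gene
#'   baseline expression (log2 RPKM) for expressed genes.
#' @param nb_dispersion negative-binomial dispersion (mean-dispersion form).
#' @param library_size_range min/max library size in reads.
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @return a `tissueome_sim_config` list.
#' @export
sim_tissue_config <- function(n_tissues = 4,
                              replicates_per_tissue = 6,
                              n_genes = 2000,
                              n_ubiquitous = 300,
                              n_enriched_per_tissue = 100,
                              n_unique_per_tissue = 50,
                              enrichment_log2fc = 4,
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 1,
                              nb_dispersion = 0.1,
                              library_size_range = c(2e6, 5e6),
                              seed = 1L) {
  cfg <- list(
    n_tissues = n_tissues, replicates_per_tissue = replicates_per_tissue,
    n_genes = n_genes, n_ubiquitous = n_ubiquitous,
    n_enriched_per_tissue = n_enriched_per_tissue,
    n_unique_per_tissue = n_unique_per_tissue,
    enrichment_log2fc = enrichment_log2fc,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range, seed = seed
  )
  validate_sim_tissue_config(cfg)
  structure(cfg, class = "tissueome_sim_config")
}

validate_sim_tissue_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop_input("invalid simulation config field '", field, "': ", why)
  }
  chk(is_count(cfg$n_tissues) && cfg$n_tissues >= 2, "n_tissues", ">= 2 required")
  chk(is_count(cfg$replicates_per_tissue) && cfg$replicates_per_tissue >= 2,
      "replicates_per_tissue", ">= 2 required")
  chk(is_count(cfg$n_genes) && cfg$n_genes >= 1, "n_genes", "positive integer")
  chk(is_count(cfg$n_ubiquitous) && cfg$n_ubiquitous >= 0, "n_ubiquitous",
      "nonnegative integer")
  chk(is_count(cfg$n_enriched_per_tissue) && cfg$n_enriched_per_tissue >= 0,
      "n_enriched_per_tissue", "nonnegative integer")
  chk(is_count(cfg$n_unique_per_tissue) &&
        cfg$n_unique_per_tissue >= 0 &&
        cfg$n_unique_per_tissue <= cfg$n_enriched_per_tissue,
      "n_unique_per_tissue", "must lie in [0, n_enriched_per_tissue]")
  chk(cfg$n_ubiquitous + cfg$n_tissues * cfg$n_enriched_per_tissue <= cfg$n_genes,
      "n_genes", "planted classes exceed the gene total")
  chk(is.numeric(cfg$enrichment_log2fc) && cfg$enrichment_log2fc > 0,
      "enrichment_log2fc", "positive real")
  chk(is.numeric(cfg$nb_dispersion) && cfg$nb_dispersion > 0,
      "nb_dispersion", "positive real")
  chk(is.numeric(cfg$library_size_range) &&
        length(cfg$library_size_range) == 2 &&
        all(cfg$library_size_range > 0) &&
        diff(cfg$library_size_range) >= 0,
      "library_size_range", "increasing pair of positive sizes")
  chk(is_count(cfg$seed), "seed", "integer")
  invisible(cfg)
}

#' Simulate a multi-tissue replicate RNA-seq experiment with planted classes
#'
#' Counts are drawn negative-binomial around tissue-specific means. Per-gene
#' baselines are normal in log2-RPKM space; planted enriched genes gain
#' `enrichment_log2fc` in their target tissue, and enriched-but-not-unique
#' genes additionally gain half the effect in one other tissue so that the
#' rest-average rule still fires while the every-other-tissue rule does not.
#' Gene lengths are log-normal (median 1 kb) so the RPKM layer genuinely
#' differs from CPM. RPKM is computed from counts, lengths and realized
#' library size.
#'
#' @param config a [sim_tissue_config()] object.
#' @return list with elements `expr` (a [tissue_expr()]) and `truth` (planted
#'   ubiquitous genes plus per-tissue enriched/unique sets and the per-gene
#'   expected log2-RPKM matrix).
#' @export
simulate_tissue_rnaseq <- function(config = sim_tissue_config()) {
  validate_sim_tissue_config(config)
  set.seed(config$seed)
  nt <- config$n_tissues
  nr <- config$replicates_per_tissue
  ng <- config$n_genes
  tissue_names <- default_tissue_names(nt)
  gene_ids <- sprintf("g%05d", seq_len(ng))

  # planted class bookkeeping: [ubiquitous | enriched t1 | ... | background]
  ubiq <- gene_ids[seq_len(config$n_ubiquitous)]
  enriched <- list(); unique_sets <- list()
  offset <- config$n_ubiquitous
  for (t in tissue_names) {
    idx <- offset + seq_len(config$n_enriched_per_tissue)
    enriched[[t]] <- gene_ids[idx]
    unique_sets[[t]] <- gene_ids[idx[seq_len(config$n_unique_per_tissue)]]
    offset <- offset + config$n_enriched_per_tissue
  }

  baseline <- rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  level <- matrix(rep(baseline, nt), nrow = ng, ncol = nt,
                  dimnames = list(gene_ids, tissue_names))
  level[gene_ids[offset < seq_len(ng)], ] <- 0 # background: ~1 RPKM everywhere
  for (t in tissue_names) {
    level[enriched[[t]], t] <- level[enriched[[t]], t] + config$enrichment_log2fc
    shared <- setdiff(enriched[[t]], unique_sets[[t]])
    if (length(shared)) {
      other <- sample(setdiff(tissue_names, t), length(shared), replace = TRUE)
      for (o in unique(other)) {
        g <- shared[other == o]
        level[g, o] <- level[g, o] + config$enrichment_log2fc / 2
      }
    }
  }

  lengths_bp <- rlnorm(ng, meanlog = log(1000), sdlog = 0.5)
  names(lengths_bp) <- gene_ids
  sample_tissue <- rep(tissue_names, each = nr)
  sample_ids <- paste0(sample_tissue, "_r", rep(seq_len(nr), times = nt))
  lib <- runif(nt * nr, config$library_size_range[1], config$library_size_range[2])

  # expected counts from expected RPKM: mu = rpkm * (len/1e3) * (lib/1e6)
  counts <- matrix(0L, ng, nt * nr, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(nt * nr)) {
    mu <- 2^level[, sample_tissue[j]] * (lengths_bp / 1e3) * (lib[j] / 1e6)
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
  }
  total <- colSums(counts)
  rpkm <- sweep(counts / (lengths_bp / 1e3), 2, total / 1e6, "/")

  samples <- data.frame(
    sample_id = sample_ids, tissue = sample_tissue,
    replicate = rep(seq_len(nr), times = nt), dataset = "tissueome",
    stringsAsFactors = FALSE
  )
  truth <- list(
    ubiquitous = ubiq, enriched = enriched, unique = unique_sets,
    background = gene_ids[seq_len(ng) > offset],
    expected_log2_rpkm = level
  )
  list(expr = tissue_expr(counts, rpkm, samples, lengths_bp), truth = truth)
}

default_tissue_names <- function(n) {
  base <- c("neuron", "muscle", "hypodermis", "intestine")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("tissue%02d", seq_len(n - length(base))))
}
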