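#' Gene x tissue expression signatures with planted structure
#'
#' Builds the latent signatures that whole-animal samples mix: ubiquitous
#' genes carry a per-gene level in every tissue, tissue-specific genes carry
#' their level only in their own tissue, background genes are flat at zero.
#' Levels are on a log-like abundance scale (arbitrary units).
#'
#' @param n_genes total gene universe.
#' @param n_tissues number of tissues.
#' @param n_ubiquitous genes expressed in all tissues.
#' @param n_specific_per_tissue tissue-specific genes per tissue.
#' @param level_mean,level_sd normal distribution of per-gene expressed levels.
#' @param seed integer seed.
#' @return list with `signatures` (gene x tissue matrix), `memberships`
#'   (logical gene x tissue), and per-tissue `specific` / `ubiquitous` /
#'   `background` gene sets.
#' @export
tissue_signatures <- function(n_genes = 2000, n_tissues = 8,
                              n_ubiquitous = 200, n_specific_per_tissue = 100,
                              level_mean = 3, level_sd = 0.5, seed = 1L) {
  stopifnot(n_ubiquitous + n_tissues * n_specific_per_tissue <= n_genes)
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  tissue_names <- sprintf("tissue%02d", seq_len(n_tissues))
  level <- rnorm(n_genes, level_mean, level_sd)
  sig <- matrix(0, n_genes, n_tissues, dimnames = list(gene_ids, tissue_names))
  memb <- matrix(FALSE, n_genes, n_tissues, dimnames = list(gene_ids, tissue_names))
  ubiq <- gene_ids[seq_len(n_ubiquitous)]
  sig[ubiq, ] <- level[seq_len(n_ubiquitous)]
  memb[ubiq, ] <- TRUE
  specific <- list()
  offset <- n_ubiquitous
  for (t in tissue_names) {
    idx <- offset + seq_len(n_specific_per_tissue)
    sig[idx, t] <- level[idx]
    memb[idx, t] <- TRUE
    specific[[t]] <- gene_ids[idx]
    offset <- offset + n_specific_per_tissue
  }
  list(signatures = sig, memberships = memb, specific = specific,
       ubiquitous = ubiq, background = gene_ids[seq_len(n_genes) > offset])
}

#' Configuration for the whole-animal compendium simulator
#'
#' Each simulated sample is a noisy convex mixture of tissue signatures:
#' tissue proportions are Dirichlet, every dataset applies a multiplicative
#' scalar effect, Gaussian noise is added per cell, and each dataset measures
#' only a random subset of the gene universe (the rest are missing, to be
#' zero-filled at assembly). The simulation lives on a log-like abundance
#' scale rather than counts, mirroring a mixed microarray/RNA-seq compendium
#' that is normalized per dataset downstream anyway.
#'
#' @param n_datasets number of datasets.
#' @param samples_per_dataset min/max samples per dataset (inclusive range).
#' @param mixture_concentration Dirichlet concentration over tissue
#'   proportions; small values give near-pure samples.
#' @param dataset_scale_sd sd of the per-dataset log-scale factor.
#' @param sample_noise_sd sd of the additive Gaussian cell noise.
#' @param gene_coverage_fraction fraction of the gene universe measured per
#'   dataset, in (0, 1].
#' @param seed integer seed.
#' @return a `compendium_sim_config` list.
#' @export
sim_compendium_config <- function(n_datasets = 12,
                                  samples_per_dataset = c(20, 30),
                                  mixture_concentration = 0.15,
                                  dataset_scale_sd = 0.3,
                                  sample_noise_sd = 0.4,
                                  gene_coverage_fraction = 0.85,
                                  seed = 1L) {
  cfg <- list(n_datasets = n_datasets,
              samples_per_dataset = samples_per_dataset,
              mixture_concentration = mixture_concentration,
              dataset_scale_sd = dataset_scale_sd,
              sample_noise_sd = sample_noise_sd,
              gene_coverage_fraction = gene_coverage_fraction, seed = seed)
  stopifnot(is_count(cfg$n_datasets), cfg$n_datasets >= 1,
            length(cfg$samples_per_dataset) == 2,
            all(cfg$samples_per_dataset >= 1),
            cfg$mixture_concentration > 0,
            cfg$dataset_scale_sd >= 0, cfg$sample_noise_sd >= 0,
            cfg$gene_coverage_fraction > 0, cfg$gene_coverage_fraction <= 1,
            is_count(cfg$seed))
  structure(cfg, class = "compendium_sim_config")
}

# Dirichlet draws via normalized gammas; rows sum to 1 exactly after division
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0 # possible at tiny concentration: fall back to one-hot
  if (any(zero)) {
    for (i in which(zero)) x[i, sample.int(length(alpha), 1L)] <- 1
  }
  x / rowSums(x)
}

#' Simulate a multi-dataset whole-animal expression compendium
#'
#' @param config a [sim_compendium_config()].
#' @param signatures gene x tissue matrix, e.g. from [tissue_signatures()];
#'   must have at least one tissue column and a nonempty gene universe.
#' @return list with `datasets` (list of `expr_dataset` objects with missing
#'   values for unmeasured genes) and `truth` (per-sample mixture proportions
#'   and per-dataset measured gene sets).
#' @export
simulate_compendium <- function(config = sim_compendium_config(), signatures) {
  if (is.null(dim(signatures)) || ncol(signatures) < 1 || nrow(signatures) < 1) {
    stop_input("signatures must be a nonempty gene x tissue matrix")
  }
  set.seed(config$seed)
  universe <- rownames(signatures)
  n_t <- ncol(signatures)
  datasets <- list(); proportions <- list(); measured <- list()
  for (d in seq_len(config$n_datasets)) {
    id <- sprintf("ds%02d", d)
    n_s <- if (config$samples_per_dataset[1] == config$samples_per_dataset[2])
      config$samples_per_dataset[1] else
        sample(seq(config$samples_per_dataset[1],
                   config$samples_per_dataset[2]), 1L)
    pi_mat <- rdirichlet(n_s, rep(config$mixture_concentration, n_t))
    colnames(pi_mat) <- colnames(signatures)
    rownames(pi_mat) <- sprintf("%s_s%02d", id, seq_len(n_s))
    scale_d <- exp(rnorm(1, 0, config$dataset_scale_sd))
    n_meas <- max(1L, round(config$gene_coverage_fraction * length(universe)))
    genes_d <- sort(sample(universe, n_meas))
    base <- signatures[genes_d, , drop = FALSE] %*% t(pi_mat)
    noise <- matrix(rnorm(length(base), 0, config$sample_noise_sd),
                    nrow = nrow(base))
    mat <- scale_d * base + noise
    colnames(mat) <- rownames(pi_mat)
    datasets[[id]] <- expr_dataset(id, mat, platform = "synthetic")
    proportions[[id]] <- pi_mat
    measured[[id]] <- genes_d
  }
  list(datasets = datasets,
       truth = list(proportions = proportions, measured = measured,
                    universe = universe))
}
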