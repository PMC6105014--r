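# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, enumeration, closed forms) and never call the implementation paths
# they check.

# --- tiny expression fixture built from explicit log2-RPKM values ----------
# 'levels' is a gene x tissue matrix of log2(rpkm) values; each tissue gets
# n_rep identical replicates unless jitter is supplied.
expr_from_levels <- function(levels, n_rep = 3, jitter = 0) {
  tissues <- colnames(levels)
  rpkm <- do.call(cbind, lapply(tissues, function(t) {
    base <- matrix(rep(2^levels[, t] - 1, n_rep), ncol = n_rep)
    if (jitter > 0) base <- base * 2^matrix(rnorm(length(base), 0, jitter),
                                            nrow(base))
    base
  }))
  rownames(rpkm) <- rownames(levels)
  colnames(rpkm) <- paste0(rep(tissues, each = n_rep), "_r",
                           rep(seq_len(n_rep), length(tissues)))
  counts <- round(rpkm * 10) # arbitrary positive library
  samples <- data.frame(
    sample_id = colnames(rpkm),
    tissue = rep(tissues, each = n_rep),
    replicate = rep(seq_len(n_rep), length(tissues)),
    stringsAsFactors = FALSE
  )
  tissue_expr(counts, rpkm, samples)
}

# --- brute-force oracles ----------------------------------------------------

# per-gene loop over samples for the CPM detection rule
oracle_cpm_filter <- function(counts, min_cpm, min_samples) {
  lib <- colSums(counts)
  keep <- character(0)
  for (g in rownames(counts)) {
    n_ok <- 0
    for (s in colnames(counts)) {
      if (counts[g, s] * 1e6 / lib[s] >= min_cpm) n_ok <- n_ok + 1
    }
    if (n_ok >= min_samples) keep <- c(keep, g)
  }
  keep
}

# textbook step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exhaustive enumeration of Venn blocks over all nonempty tissue combinations
oracle_venn <- function(gene_set, expressed_sets) {
  tissues <- names(expressed_sets)
  combos <- unlist(lapply(seq_along(tissues), function(k) {
    asplit(utils::combn(tissues, k), 2)
  }), recursive = FALSE)
  blocks <- list()
  for (cmb in combos) {
    hit <- Filter(function(g) {
      all(vapply(tissues, function(t) {
        (g %in% expressed_sets[[t]]) == (t %in% cmb)
      }, logical(1)))
    }, gene_set)
    if (length(hit)) blocks[[paste(cmb, collapse = "+")]] <- hit
  }
  blocks
}

# hypergeometric upper tail by direct pmf summation with choose()
oracle_hyper_tail <- function(k, K, N, n) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  sum(vapply(k:kmax, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 1))
}

# prefix enumeration of the PR curve, tied scores entering together
oracle_pr <- function(scores, labels) {
  pos <- labels > 0
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  th <- unique(s)
  t(vapply(th, function(v) {
    sel <- s >= v
    c(precision = sum(p[sel]) / sum(sel), recall = sum(p[sel]) / sum(pos))
  }, c(precision = 0, recall = 0)))
}

# smallest prefix reaching the target recall, by scanning prefixes
oracle_precision_at_recall <- function(scores, labels, target) {
  curve <- oracle_pr(scores, labels)
  curve[which(curve[, "recall"] >= target)[1], "precision"]
}

# --- random DAG generator for ontology oracle tests -------------------------
# indices only ever point from higher to lower ids, so the result is acyclic
random_dag <- function(n_terms, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("T:%03d", seq_len(n_terms))
  child <- sample(2:n_terms, n_edges, replace = TRUE)
  parent <- vapply(child, function(cc) sample.int(cc - 1, 1), 1L)
  edges <- unique(data.frame(
    child = ids[child], parent = ids[parent],
    relation = sample(c("is_a", "part_of"), length(child), replace = TRUE),
    stringsAsFactors = FALSE
  ))
  anatomy_ontology(data.frame(id = ids, name = ids), edges)
}

# ancestor closure through igraph (independent reachability implementation)
igraph_ancestors <- function(ont, term) {
  g <- igraph::graph_from_data_frame(ont$edges[, c("child", "parent")],
                                     vertices = ont$terms$id)
  reach <- igraph::subcomponent(g, term, mode = "out")
  setdiff(names(reach), term)
}

# --- miniature end-to-end prediction study (fast) ---------------------------
make_mini_study <- function(seed = 1, n_genes = 400, n_tissues = 4) {
  sigs <- tissue_signatures(n_genes = n_genes, n_tissues = n_tissues,
                            n_ubiquitous = 60, n_specific_per_tissue = 40,
                            seed = derive_seed(seed, "signatures"))
  sim <- simulate_compendium(
    sim_compendium_config(n_datasets = 5, samples_per_dataset = c(12, 16),
                          seed = derive_seed(seed, "compendium")),
    sigs$signatures
  )
  comp <- assemble_compendium(
    lapply(sim$datasets, normalize_dataset),
    universe = rownames(sigs$signatures)
  )
  anatomy <- simulate_anatomy(
    sim_anatomy_config(n_systems = n_tissues / 2, tissues_per_system = 2,
                       genes_annotated_fraction = 0.5,
                       seed = derive_seed(seed, "anatomy")),
    memberships = sigs$memberships
  )
  propagated <- propagate_annotations(filter_small_scale(anatomy$annotations),
                                      anatomy$ontology)
  slim <- define_slim(anatomy$ontology, slim = anatomy$ontology$slim_roots)
  retained <- intersect(anatomy$truth$tissues,
                        select_tissues(propagated, 10, 20))
  gs <- build_gold_standard(propagated, slim, retained)
  list(signatures = sigs, sim = sim, compendium = comp, anatomy = anatomy,
       gold_standard = gs,
       tissue_terms = setNames(colnames(sigs$memberships),
                               anatomy$truth$tissues))
}
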