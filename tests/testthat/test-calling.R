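# gene-calling rules: detection filter, expressed/enriched/unique thresholds,
# Welch statistic, BH adjustment, Venn partitioning, Spearman profiles

test_that("CPM detection filter applies the per-sample rule and matches a loop oracle", {
  counts <- matrix(0L, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  counts[1, 1:5] <- 10L          # CPM 10 in 5 samples -> retained
  counts[3, ] <- 1000L           # keeps library sizes positive
  rpkm <- counts / 10
  samples <- data.frame(sample_id = colnames(counts),
                        tissue = rep(c("a", "b"), each = 3),
                        replicate = rep(1:3, 2))
  em <- tissue_expr(counts, rpkm, samples)
  kept <- cpm_filter(em, min_cpm = 1, min_samples = 5)
  expect_true("g1" %in% kept)
  expect_false("g2" %in% kept)   # all-zero gene dropped

  set.seed(21)
  for (i in 1:5) {
    counts <- matrix(rpois(200 * 20, 4), 200, 20,
                     dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:20)))
    em <- tissue_expr(counts, counts / 7,
                      data.frame(sample_id = colnames(counts),
                                 tissue = rep(c("a", "b"), each = 10),
                                 replicate = rep(1:10, 2)))
    expect_identical(cpm_filter(em, 1, 5), oracle_cpm_filter(counts, 1, 5))
  }
})

test_that("zero library sizes are reported by sample name", {
  counts <- matrix(c(0L, 0L, 5L, 5L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("bad", "ok")))
  em <- tissue_expr(counts, counts, data.frame(
    sample_id = c("bad", "ok"), tissue = "a", replicate = 1:2))
  expect_error(cpm(em), "bad")
})

test_that("expressed rule requires both the mean and every-replicate clause", {
  levels <- rbind(g1 = c(a = 3, b = 0), g2 = c(a = 3, b = 0))
  em <- expr_from_levels(levels, n_rep = 3)
  # break one replicate of g2 in tissue a: mean stays above 2 (4,4,0.5)
  em$rpkm["g2", 1:3] <- 2^c(4, 4, 0.5) - 1
  ex <- call_expressed(em)
  expect_true("g1" %in% ex$a)
  expect_false("g2" %in% ex$a)  # second clause binds despite mean 2.83 > 2
  expect_length(ex$b, 0)
})

test_that("near-noiseless planted effects are recovered almost perfectly", {
  cfg <- sim_tissue_config(n_genes = 500, n_ubiquitous = 60,
                           n_enriched_per_tissue = 40, n_unique_per_tissue = 20,
                           enrichment_log2fc = 8, nb_dispersion = 0.01,
                           baseline_log2_mean = 5, baseline_log2_sd = 0.4,
                           replicates_per_tissue = 5, seed = 17)
  r <- simulate_tissue_rnaseq(cfg)
  ex <- call_expressed(r$expr)
  for (t in names(ex)) {
    planted <- c(r$truth$ubiquitous, r$truth$enriched[[t]])
    expect_gte(mean(planted %in% ex[[t]]), 0.99)
  }
  calls <- gene_calls(r$expr)
  for (t in names(calls$enriched)) {
    expect_gte(mean(r$truth$enriched[[t]] %in% calls$enriched[[t]]), 0.95)
    expect_lte(mean(!(calls$enriched[[t]] %in% r$truth$enriched[[t]])), 0.05)
  }
})

test_that("differential statistic: fold-changes, conventions, and t.test oracle", {
  levels <- rbind(g1 = c(a = 3, b = 3, c = 3), g2 = c(a = 3, b = 3, c = 3))
  em <- expr_from_levels(levels, n_rep = 3)
  de <- differential_stat(em, "a", "rest_average")
  expect_equal(de$logFC, c(0, 0))
  expect_equal(de$p, c(1, 1)) # zero-variance equal-means convention

  # logFC ~ 6 for (8,8,8) vs (2,2,2) with tiny jitter
  set.seed(5)
  em2 <- expr_from_levels(rbind(g1 = c(a = 8, b = 2)), n_rep = 3, jitter = 0.02)
  de2 <- differential_stat(em2, "a", "rest_average")
  expect_equal(de2$logFC, 6, tolerance = 0.1)

  # Welch p-values match stats::t.test gene by gene
  set.seed(6)
  lr <- matrix(rnorm(40 * 10, 5), 40, 10,
               dimnames = list(sprintf("g%02d", 1:40), NULL))
  rpkm <- 2^lr - 1
  colnames(rpkm) <- paste0(rep(c("a", "b"), each = 5), "_r", rep(1:5, 2))
  em3 <- tissue_expr(round(rpkm * 3), rpkm, data.frame(
    sample_id = colnames(rpkm), tissue = rep(c("a", "b"), each = 5),
    replicate = rep(1:5, 2)))
  de3 <- differential_stat(em3, "a", "rest_average")
  for (i in c(1, 7, 23, 40)) {
    ref <- t.test(lr[i, 1:5], lr[i, 6:10])
    expect_equal(de3$p[i], ref$p.value, tolerance = 1e-12)
  }

  # each-other contrast returns one comparison per other tissue
  em4 <- expr_from_levels(rbind(g1 = c(a = 5, b = 1, c = 1, d = 1)), n_rep = 3)
  de4 <- differential_stat(em4, "a", "each_other")
  expect_named(de4, c("b", "c", "d"))
})

test_that("Welch test is calibrated on null data", {
  set.seed(99)
  p <- replicate(4, {
    lr <- matrix(rnorm(500 * 10, 6), 500, 10,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
    rpkm <- 2^lr - 1
    colnames(rpkm) <- paste0(rep(c("a", "b"), each = 5), "_r", rep(1:5, 2))
    em <- tissue_expr(round(rpkm), rpkm, data.frame(
      sample_id = colnames(rpkm), tissue = rep(c("a", "b"), each = 5),
      replicate = rep(1:5, 2)))
    differential_stat(em, "a", "rest_average")$p
  })
  alpha <- mean(p < 0.05)
  expect_gte(alpha, 0.03); expect_lte(alpha, 0.07)
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  }
  # permutation equivariance
  p <- runif(25); perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("enriched and unique rules apply their clauses and stay nested", {
  # g1: high + strong FC everywhere -> unique; g2: fails the expression cut;
  # g3: beats the rest-average but not every single tissue
  levels <- rbind(g1 = c(a = 8, b = 1, c = 1, d = 1),
                  g2 = c(a = 4.5, b = 1, c = 1, d = 1),
                  g3 = c(a = 8, b = 6.5, c = 1, d = 1),
                  g4 = c(a = 3, b = 3, c = 3, d = 3))
  set.seed(8)
  em <- expr_from_levels(levels, n_rep = 4, jitter = 0.05)
  calls <- gene_calls(em)
  expect_true("g1" %in% calls$enriched$a)
  expect_true("g1" %in% calls$unique$a)
  expect_false("g2" %in% calls$enriched$a) # mean log-RPKM below 5
  expect_true("g3" %in% calls$enriched$a)  # rest-average still > 2
  expect_false("g3" %in% calls$unique$a)   # fails against tissue b alone
  for (t in names(calls$expressed)) {
    expect_true(all(calls$unique[[t]] %in% calls$enriched[[t]]))
    expect_true(all(calls$enriched[[t]] %in% calls$expressed[[t]]))
  }
  # q >= p throughout the call table
  expect_true(all(calls$table$q >= calls$table$p - 1e-15))
})

test_that("Venn partition matches exhaustive enumeration and handles remainders", {
  ex <- list(neuron = c("g1", "g2"), muscle = c("g1"), hyp = c("g1"),
             intestine = c("g1", "g3"))
  vp <- venn_partition(c("g1", "g2", "g3", "g4"), ex)
  expect_setequal(vp$blocks[["neuron+muscle+hyp+intestine"]], "g1")
  expect_setequal(vp$blocks[["neuron"]], "g2")
  expect_identical(vp$not_detected, "g4")
  expect_error(venn_partition(character(0), ex), "nonempty")

  set.seed(12)
  for (i in 1:10) {
    tissues <- c("t1", "t2", "t3", "t4")
    genes <- sprintf("g%03d", 1:100)
    member <- matrix(runif(400) < 0.4, 100, 4,
                     dimnames = list(genes, tissues))
    sets <- lapply(tissues, function(t) genes[member[, t]])
    names(sets) <- tissues
    vp <- venn_partition(genes, sets)
    oracle <- oracle_venn(genes, sets)
    expect_identical(lapply(vp$blocks[sort(names(vp$blocks))], sort),
                     lapply(oracle[sort(names(oracle))], sort))
    # disjoint and exhaustive over detected genes
    all_blocks <- unlist(vp$blocks, use.names = FALSE)
    expect_identical(anyDuplicated(all_blocks), 0L)
    expect_setequal(c(all_blocks, vp$not_detected), genes)
  }
})

test_that("Spearman profile is rank-invariant and matches rank-then-Pearson", {
  set.seed(14)
  rpkm <- matrix(rexp(50 * 8, 0.1), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 paste0(rep(c("a", "b"), each = 4), "_r", rep(1:4, 2))))
  rpkm[, 2] <- rpkm[, 1]              # duplicated sample
  rpkm[, 3] <- rpkm[, 1]^2 * 3        # strictly monotone transform
  em <- tissue_expr(round(rpkm * 5), rpkm, data.frame(
    sample_id = colnames(rpkm), tissue = rep(c("a", "b"), each = 4),
    replicate = rep(1:4, 2)))
  enr <- list(a = rownames(rpkm)[1:30], b = rownames(rpkm)[20:50])
  sc <- enriched_correlation(em, enr)
  expect_equal(unname(sc[1, 2]), 1)
  expect_equal(unname(sc[1, 3]), 1)
  expect_equal(sc, t(sc))
  expect_equal(unname(diag(sc)), rep(1, 8))
  # definitional oracle: Pearson on column ranks of log2(rpkm+1)
  u <- unique(unlist(enr))
  ranked <- apply(log2(rpkm[u, ] + 1), 2, rank)
  expect_equal(unname(sc), unname(cor(ranked)), tolerance = 1e-12)
  expect_error(enriched_correlation(em, list(a = rownames(rpkm)[1:2])), "3")
})
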