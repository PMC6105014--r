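# anatomy ontology: OBO parsing, propagation, tissue retention, slim
# assignment, gold-standard label algebra

test_that("minimal OBO files parse, obsolete terms drop, unknown relations warn", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A:1", "name: child", "is_a: A:2 ! parent",
    "relationship: part_of A:3", "relationship: develops_from A:2", "",
    "[Term]", "id: A:2", "name: parent", "",
    "[Term]", "id: A:3", "name: organ", "",
    "[Term]", "id: A:9", "name: gone", "is_obsolete: true", ""
  ), path)
  expect_warning(ont <- parse_obo(path), "develops_from")
  expect_setequal(ont$terms$id, c("A:1", "A:2", "A:3"))
  expect_identical(nrow(ont$edges), 2L)
  expect_setequal(ont$edges$relation, c("is_a", "part_of"))
})

test_that("cyclic ontologies are rejected with a concrete cycle", {
  terms <- data.frame(id = c("X", "Y"), name = c("x", "y"))
  edges <- data.frame(child = c("X", "Y"), parent = c("Y", "X"),
                      relation = "is_a")
  expect_error(anatomy_ontology(terms, edges), "cycle")
})

test_that("ontology round-trips through OBO write and parse", {
  for (seed in 1:5) {
    ont <- random_dag(30, 45, seed)
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(ont, path)
    back <- parse_obo(path)
    expect_setequal(back$terms$id, ont$terms$id)
    key <- function(o) sort(paste(o$edges$child, o$edges$relation, o$edges$parent))
    expect_identical(key(back), key(ont))
  }
})

test_that("propagation equals an independent transitive-closure oracle", {
  ann <- data.frame(gene = "g1", term = "T:003")
  chain <- anatomy_ontology(
    data.frame(id = c("T:001", "T:002", "T:003"), name = letters[1:3]),
    data.frame(child = c("T:003", "T:002"), parent = c("T:002", "T:001"),
               relation = "is_a")
  )
  prop <- propagate_annotations(ann, chain)
  expect_setequal(prop$term, c("T:001", "T:002", "T:003"))
  expect_identical(prop$direct[prop$term == "T:003"], TRUE)

  # annotation to a root adds nothing
  prop_root <- propagate_annotations(data.frame(gene = "g1", term = "T:001"),
                                     chain)
  expect_identical(nrow(prop_root), 1L)

  expect_error(propagate_annotations(data.frame(gene = "g", term = "NO:PE"),
                                     chain), "NO:PE")

  set.seed(77)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    ont <- random_dag(n, round(1.5 * n), seed = 1000 + i)
    ann <- data.frame(
      gene = sample(sprintf("g%02d", 1:15), 30, replace = TRUE),
      term = sample(ont$terms$id, 30, replace = TRUE)
    )
    prop <- propagate_annotations(ann, ont)
    for (g in unique(ann$gene)) {
      direct_terms <- unique(ann$term[ann$gene == g])
      closure <- unique(c(direct_terms, unlist(
        lapply(direct_terms, function(tm) igraph_ancestors(ont, tm)))))
      expect_setequal(prop$term[prop$gene == g], closure)
    }
    # propagated annotations never fewer than direct ones, per gene
    n_dir <- table(ann$gene)
    n_prop <- table(prop$gene)
    expect_true(all(n_prop[names(n_dir)] >= tapply(ann$term, ann$gene,
                                                   function(x) length(unique(x)))))
  }
})

test_that("tissue retention thresholds are strict at the printed boundary", {
  mk <- function(n_direct, n_extra) {
    # n_direct genes annotated straight to P; n_extra genes reach P only by
    # propagation from the child L, so P has direct = n_direct and
    # propagated = n_direct + n_extra
    ont <- anatomy_ontology(
      data.frame(id = c("P", "L"), name = c("p", "l")),
      data.frame(child = "L", parent = "P", relation = "is_a")
    )
    ann <- rbind(
      data.frame(gene = sprintf("d%03d", seq_len(n_direct)), term = "P"),
      data.frame(gene = sprintf("e%03d", seq_len(n_extra)), term = "L")
    )
    propagate_annotations(ann, ont)
  }
  # direct=51, propagated=151 at P -> retained at the (50, 150) defaults
  prop <- mk(51, 100)
  expect_true("P" %in% select_tissues(prop, 50, 150))
  expect_true("L" %in% select_tissues(prop, 50, 50))
  # boundary: exactly 50 direct or exactly 150 propagated fails the strict rule
  prop2 <- mk(50, 500)
  expect_false("P" %in% select_tissues(prop2, 50, 150))
  prop3 <- mk(51, 99)  # propagated at P = 150 exactly
  expect_false("P" %in% select_tissues(prop3, 50, 150))
  expect_true("P" %in% select_tissues(prop3, 50, 149))
  # raising thresholds never adds tissues
  set.seed(3)
  propr <- propagate_annotations(
    data.frame(gene = sample(sprintf("g%03d", 1:80), 300, replace = TRUE),
               term = sample(sprintf("T:%03d", 1:10), 300, replace = TRUE)),
    random_dag(10, 12, 5))
  lo <- select_tissues(propr, 5, 10)
  hi <- select_tissues(propr, 10, 20)
  expect_true(all(hi %in% lo))
})

test_that("slim assignment is reflexive and matches an ancestor-set oracle", {
  # root with two systems, tissues below
  ont <- anatomy_ontology(
    data.frame(id = c("root", "S1", "S2", "t1", "t2"),
               name = c("organ system", "nervous", "muscular", "neuron", "body wall")),
    data.frame(child = c("S1", "S2", "t1", "t2"),
               parent = c("root", "root", "S1", "S2"),
               relation = c("is_a", "is_a", "is_a", "part_of"))
  )
  slim <- define_slim(ont, roots = "root")
  expect_setequal(slim$t1, "S1")
  expect_setequal(slim$S1, "S1") # a slim term maps to itself
  expect_length(slim$root, 0)

  set.seed(9)
  for (i in 1:10) {
    ont <- random_dag(40, 60, 200 + i)
    slim_terms <- sample(ont$terms$id, 5)
    asg <- suppressWarnings(define_slim(ont, slim = slim_terms))
    for (tm in sample(ont$terms$id, 10)) {
      expect_setequal(asg[[tm]],
                      intersect(c(tm, igraph_ancestors(ont, tm)), slim_terms))
    }
  }
})

test_that("gold-standard labels follow the same-system exclusion rule", {
  ont <- anatomy_ontology(
    data.frame(id = c("S1", "S2", "t1", "t2", "t3"), name = c("nervous",
               "muscular", "dopaminergic", "interneuron", "body wall")),
    data.frame(child = c("t1", "t2", "t3"), parent = c("S1", "S1", "S2"),
               relation = "is_a")
  )
  slim <- define_slim(ont, slim = c("S1", "S2"))
  ann <- data.frame(
    gene = c("gpos", "gsys", "gneg", "gboth"),
    term = c("t1", "t2", "t3", "t1")
  )
  ann <- rbind(ann, data.frame(gene = "gboth", term = "t3"))
  prop <- propagate_annotations(ann, ont)
  gs <- build_gold_standard(prop, slim, c("t1", "t3"))
  # muscle-system-only gene is negative for a nervous-system tissue
  expect_true("gneg" %in% gs$tissues$t1$negatives)
  # same-system, different-tissue gene is excluded outright
  expect_false("gsys" %in% gs$tissues$t1$positives)
  expect_false("gsys" %in% gs$tissues$t1$negatives)
  # annotated to the tissue itself: positive, never negative
  expect_true("gboth" %in% gs$tissues$t1$positives)
  expect_false("gboth" %in% gs$tissues$t1$negatives)
  expect_equal(gs$tissues$t1$prior,
               length(gs$tissues$t1$positives) /
                 (length(gs$tissues$t1$positives) + length(gs$tissues$t1$negatives)))
})

test_that("gold-standard construction matches a set-algebra oracle on random instances", {
  set.seed(55)
  for (i in 1:25) {
    ns <- sample(2:4, 1); tps <- sample(1:3, 1)
    sim <- simulate_anatomy(sim_anatomy_config(
      n_systems = ns, tissues_per_system = tps, depth = sample(1:2, 1),
      genes_annotated_fraction = 0.6, annotation_noise = 0.05,
      seed = 300 + i))
    prop <- propagate_annotations(filter_small_scale(sim$annotations),
                                  sim$ontology)
    slim <- define_slim(sim$ontology, slim = sim$ontology$slim_roots)
    gs <- suppressWarnings(
      build_gold_standard(prop, slim, sim$truth$tissues))
    terms_by_gene <- split(prop$term, prop$gene)
    for (t in names(gs$tissues)) {
      sys_t <- slim[[t]]
      pos_o <- names(Filter(function(ts) t %in% ts, terms_by_gene))
      neg_o <- names(Filter(function(ts) {
        !(t %in% ts) &&
          !any(sys_t %in% unlist(slim[ts], use.names = FALSE))
      }, terms_by_gene))
      expect_setequal(gs$tissues[[t]]$positives, pos_o)
      expect_setequal(gs$tissues[[t]]$negatives, neg_o)
      expect_length(intersect(gs$tissues[[t]]$positives,
                              gs$tissues[[t]]$negatives), 0)
      # hierarchy consistency: a positive for t is never negative for an
      # ancestor of t that is also modeled
      anc_t <- intersect(igraph_ancestors(sim$ontology, t), names(gs$tissues))
      for (a in anc_t) {
        expect_length(intersect(gs$tissues[[t]]$positives,
                                gs$tissues[[a]]$negatives), 0)
      }
    }
  }
})

test_that("evidence filter keeps only small-scale annotations", {
  ann <- data.frame(gene = c("g1", "g2"), term = c("A", "B"),
                    evidence = c("small_scale", "high_throughput"))
  expect_identical(filter_small_scale(ann)$gene, "g1")
})
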