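#' Configuration for the toy anatomy ontology simulator
#'
#' Generates a small anatomy DAG shaped like a cell-and-anatomy ontology:
#' system-level slim roots, tissue terms under each system, and (for
#' `depth > 1`) finer cell-type terms under each tissue, with a mixture of
#' `is_a` and `part_of` edges. Gene annotations are direct (unpropagated),
#' cover a configurable fraction of the truly expressed genes per tissue,
#' and carry a configurable rate of spurious (false-positive) annotations;
#' true memberships are never removed, matching the assumption that curated
#' annotations are incomplete but mostly correct.
#'
#' @param n_systems number of system-level slim terms.
#' @param tissues_per_system tissue terms per system.
#' @param depth levels below the systems (1 = tissues are leaves; 2 adds two
#'   cell-type children per tissue, and so on).
#' @param genes_annotated_fraction fraction of true (gene, tissue) memberships
#'   that receive an annotation.
#' @param annotation_noise fraction of spurious annotations added, relative
#'   to the number of true annotations.
#' @param seed integer seed.
#' @return an `anatomy_sim_config` list.
#' @export
sim_anatomy_config <- function(n_systems = 4, tissues_per_system = 2,
                               depth = 2, genes_annotated_fraction = 0.4,
                               annotation_noise = 0.03, seed = 1L) {
  cfg <- list(n_systems = n_systems, tissues_per_system = tissues_per_system,
              depth = depth,
              genes_annotated_fraction = genes_annotated_fraction,
              annotation_noise = annotation_noise, seed = seed)
  stopifnot(is_count(cfg$n_systems), cfg$n_systems >= 1,
            is_count(cfg$tissues_per_system), cfg$tissues_per_system >= 1,
            is_count(cfg$depth), cfg$depth >= 1,
            cfg$genes_annotated_fraction >= 0, cfg$genes_annotated_fraction <= 1,
            cfg$annotation_noise >= 0, cfg$annotation_noise <= 1,
            is_count(cfg$seed))
  structure(cfg, class = "anatomy_sim_config")
}

#' Simulate a toy anatomy ontology with partial, noisy annotations
#'
#' Builds the DAG described by `config`, then annotates genes to terms within
#' the subtree of each tissue they truly belong to (split between the tissue
#' term itself and its cell-type descendants, so propagation is genuinely
#' exercised). Spurious annotations are added as false positives only. A small
#' share of extra annotations is tagged `high_throughput` to exercise the
#' evidence filter; all true small-scale annotations are tagged `small_scale`.
#'
#' @param config a [sim_anatomy_config()].
#' @param memberships logical gene x tissue matrix of true memberships; its
#'   column count must equal `n_systems * tissues_per_system`. When `NULL`, a
#'   default membership structure is generated (120 genes per tissue plus 80
#'   shared across all tissues).
#' @return list with `ontology` (an [anatomy_ontology()]), `annotations`
#'   (data.frame gene, term, evidence) and `truth` (tissue term ids, per-gene
#'   memberships).
#' @export
simulate_anatomy <- function(config = sim_anatomy_config(), memberships = NULL) {
  set.seed(config$seed)
  ns <- config$n_systems; tps <- config$tissues_per_system
  systems <- sprintf("SYS:%02d", seq_len(ns))
  tissues <- sprintf("TIS:%02d", seq_len(ns * tps))
  terms <- data.frame(
    id = c(systems, tissues),
    name = c(sprintf("system %d", seq_len(ns)),
             sprintf("tissue %d", seq_len(ns * tps))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = tissues,
    parent = rep(systems, each = tps),
    relation = rep_len(c("is_a", "part_of"), ns * tps),
    stringsAsFactors = FALSE
  )
  # finer levels: two children per term at each extra depth level
  frontier <- tissues
  subtree <- setNames(as.list(tissues), tissues) # tissue -> all descendants+self
  level_tag <- "CEL"
  for (d in seq_len(config$depth - 1)) {
    kids <- data.frame(
      child = sprintf("%s:%02d-%d%s", level_tag, rep(seq_along(frontier), each = 2),
                      d, rep(c("a", "b"), length(frontier))),
      parent = rep(frontier, each = 2),
      relation = rep_len(c("part_of", "is_a"), 2 * length(frontier)),
      stringsAsFactors = FALSE
    )
    terms <- rbind(terms, data.frame(id = kids$child,
                                     name = paste("cell", kids$child),
                                     stringsAsFactors = FALSE))
    edges <- rbind(edges, kids)
    for (t in tissues) {
      inside <- kids$child[kids$parent %in% subtree[[t]]]
      subtree[[t]] <- c(subtree[[t]], inside)
    }
    frontier <- kids$child
  }
  ont <- anatomy_ontology(terms, edges, slim_roots = systems)

  if (is.null(memberships)) {
    n_t <- ns * tps
    gene_ids <- sprintf("g%05d", seq_len(120 * n_t + 80))
    memberships <- matrix(FALSE, length(gene_ids), n_t,
                          dimnames = list(gene_ids, tissues))
    memberships[seq_len(80), ] <- TRUE
    for (j in seq_len(n_t)) {
      memberships[80 + (j - 1) * 120 + seq_len(120), j] <- TRUE
    }
  } else {
    memberships <- as.matrix(memberships)
    if (ncol(memberships) != length(tissues)) {
      stop_input("memberships must have one column per tissue term (",
                 length(tissues), ")")
    }
    colnames(memberships) <- tissues
  }

  pairs <- which(memberships, arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < config$genes_annotated_fraction
  pairs <- pairs[keep, , drop = FALSE]
  ann_term <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tr <- subtree[[tissues[pairs[i, 2]]]]
    ann_term[i] <- tr[sample.int(length(tr), 1L)]
  }
  annotations <- data.frame(
    gene = rownames(memberships)[pairs[, 1]],
    term = ann_term, evidence = rep("small_scale", nrow(pairs)),
    stringsAsFactors = FALSE
  )
  n_noise <- round(config$annotation_noise * nrow(annotations))
  if (n_noise > 0) {
    noise <- data.frame(
      gene = sample(rownames(memberships), n_noise, replace = TRUE),
      term = sample(c(tissues, unlist(subtree, use.names = FALSE)),
                    n_noise, replace = TRUE),
      evidence = "small_scale", stringsAsFactors = FALSE
    )
    annotations <- rbind(annotations, noise)
  }
  # a slice of high-throughput annotations, to be excluded by the evidence filter
  n_ht <- max(1L, round(0.05 * nrow(annotations)))
  ht <- data.frame(
    gene = sample(rownames(memberships), n_ht, replace = TRUE),
    term = sample(tissues, n_ht, replace = TRUE),
    evidence = "high_throughput", stringsAsFactors = FALSE
  )
  annotations <- unique(rbind(annotations, ht))
  rownames(annotations) <- NULL

  list(ontology = ont,
       annotations = annotations,
       truth = list(systems = systems, tissues = tissues,
                    memberships = memberships, subtree = subtree))
}
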