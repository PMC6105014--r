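#' Anatomy ontology container
#'
#' A typed DAG of anatomy terms. Edges point child -> parent and carry a
#' relation (`is_a` or `part_of`). Slim roots mark the system-level terms used
#' to decide which genes may serve as negative examples.
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param slim_roots character vector of system-level term ids (may be empty).
#' @return object of class `anatomy_ontology`.
#' @export
anatomy_ontology <- function(terms, edges, slim_roots = character()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(terms))) stop_input("terms need id, name")
  if (nrow(edges) && !all(c("child", "parent", "relation") %in% names(edges))) {
    stop_input("edges need child, parent, relation")
  }
  if (anyDuplicated(terms$id)) stop_input("duplicate term ids")
  known <- terms$id
  if (nrow(edges)) {
    bad <- setdiff(c(edges$child, edges$parent), known)
    if (length(bad)) stop_input("edges reference unknown terms: ",
                                paste(bad, collapse = ", "))
  }
  if (length(slim_roots) && !all(slim_roots %in% known)) {
    stop_input("slim roots must be ontology terms")
  }
  ont <- structure(list(terms = terms, edges = edges, slim_roots = slim_roots),
                   class = "anatomy_ontology")
  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    stop_input("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  ont
}

#' @export
print.anatomy_ontology <- function(x, ...) {
  cat("Anatomy ontology:", nrow(x$terms), "terms,", nrow(x$edges), "edges",
      sprintf("(%d is_a, %d part_of)\n",
              sum(x$edges$relation == "is_a"), sum(x$edges$relation == "part_of")))
  if (length(x$slim_roots)) {
    cat("  slim roots:", paste(x$slim_roots, collapse = ", "), "\n")
  }
  invisible(x)
}

# Kahn topological order over child->parent edges (parents last); returns the
# order, or NULL when a cycle exists.
topo_order <- function(ont) {
  ids <- ont$terms$id
  if (!nrow(ont$edges)) return(ids)
  out_deg <- table(factor(ont$edges$child, levels = ids)) # edges leaving child
  parents_of <- split(ont$edges$parent, factor(ont$edges$child, levels = ids))
  children_of <- split(ont$edges$child, factor(ont$edges$parent, levels = ids))
  # process parents first: in-degree = number of outgoing child->parent edges
  # reversed; easier to peel roots (terms with no parents) is wrong direction,
  # so peel leaves-of-the-reverse: terms all of whose parents are emitted.
  remaining <- setNames(as.integer(out_deg), ids) # unresolved parent count
  queue <- ids[remaining == 0] # roots (no parents)
  order <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children_of[[v]] %||% character()) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) NULL else order
}

# locate one concrete cycle by iterative DFS over child->parent edges
find_cycle <- function(ont) {
  if (!is.null(topo_order(ont))) return(NULL)
  ids <- ont$terms$id
  parents_of <- split(ont$edges$parent, factor(ont$edges$child, levels = ids))
  state <- setNames(integer(length(ids)), ids) # 0 new, 1 on stack, 2 done
  path <- character(0)
  dfs <- function(v) {
    state[v] <<- 1L
    path <<- c(path, v)
    for (p in parents_of[[v]] %||% character()) {
      if (state[p] == 1L) {
        i <- match(p, path)
        return(c(path[i:length(path)], p))
      }
      if (state[p] == 0L) {
        res <- dfs(p)
        if (!is.null(res)) return(res)
      }
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
    NULL
  }
  for (v in ids) {
    if (state[v] == 0L) {
      res <- dfs(v)
      if (!is.null(res)) return(res)
    }
  }
  NULL # unreachable: topo_order said there is a cycle
}

#' Ancestor sets of every term
#'
#' Ancestors reachable through the whitelisted relations, excluding the term
#' itself. Computed in one topological pass.
#'
#' @param ont an [anatomy_ontology()].
#' @param relations relations to traverse.
#' @return named list: term id -> character vector of ancestor ids.
#' @export
term_ancestors <- function(ont, relations = c("is_a", "part_of")) {
  edges <- ont$edges[ont$edges$relation %in% relations, , drop = FALSE]
  ids <- ont$terms$id
  parents_of <- split(edges$parent, factor(edges$child, levels = ids))
  anc <- setNames(vector("list", length(ids)), ids)
  ord <- topo_order(ont) # parents appear before children
  for (v in ord) {
    ps <- parents_of[[v]] %||% character()
    anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Parse an OBO ontology file
#'
#' Minimal OBO support: `[Term]` stanzas with `id`, `name`, `is_a`,
#' `relationship: <type> <id>` and `is_obsolete` lines. Obsolete terms (and
#' edges touching them) are dropped; unknown relationship types are ignored
#' with one warning; a cycle raises an error listing one cycle.
#'
#' @param path path to an OBO file.
#' @param slim_roots optional character vector of system term ids to record.
#' @return an [anatomy_ontology()].
#' @export
parse_obo <- function(path, slim_roots = character()) {
  if (!file.exists(path)) stop_input("no such OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list(); unknown_rel <- character(0)
  cur <- NULL; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, name = cur$name %||% cur$id, stringsAsFactors = FALSE)
      for (e in cur$edges) {
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = e[2], relation = e[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln)) # strip trailing comments
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush(); cur <- list(edges = list()); in_term <- identical(ln, "[Term]")
      if (!in_term) cur <- NULL
      next
    }
    if (!in_term || is.null(cur)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_obsolete:", ln)) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    } else if (grepl("^is_a:", ln)) {
      cur$edges <- c(cur$edges, list(c("is_a", trimws(sub("^is_a:", "", ln)))))
    } else if (grepl("^relationship:", ln)) {
      parts <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% c("is_a", "part_of")) {
        cur$edges <- c(cur$edges, list(c(parts[1], parts[2])))
      } else if (length(parts) >= 1) {
        unknown_rel <- c(unknown_rel, parts[1])
      }
    }
  }
  flush()
  if (length(unknown_rel)) {
    warning("ignored unknown relation type(s): ",
            paste(unique(unknown_rel), collapse = ", "), call. = FALSE)
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(id = character(), name = character())
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(), relation = character())
  # drop edges that point at obsolete (absent) terms
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, ,
                 drop = FALSE]
  anatomy_ontology(terms, edges, intersect(slim_roots, terms$id))
}

#' Write an ontology as OBO
#'
#' Emits one `[Term]` stanza per term with `is_a` and
#' `relationship: part_of` lines; round-trips through [parse_obo()].
#'
#' @param ont an [anatomy_ontology()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    writeLines(c("[Term]", paste0("id: ", id),
                 paste0("name: ", ont$terms$name[i])), con)
    e <- ont$edges[ont$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[j]), con)
      } else {
        writeLines(paste0("relationship: ", e$relation[j], " ", e$parent[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Propagate gene annotations up the ontology
#'
#' Expands each (gene, term) annotation to (gene, ancestor) for every ancestor
#' reachable through the whitelisted relations. Direct annotations are
#' retained and flagged; the output is deduplicated, with `direct = TRUE`
#' winning when a pair arises both ways.
#'
#' @param annotations data.frame with columns `gene`, `term` and optionally
#'   `evidence` (`small_scale` / `high_throughput`).
#' @param ont an [anatomy_ontology()].
#' @param relations relations to traverse.
#' @return data.frame (gene, term, direct) of propagated annotations.
#' @export
propagate_annotations <- function(annotations, ont,
                                  relations = c("is_a", "part_of")) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(annotations))) {
    stop_input("annotations need columns gene, term")
  }
  dangling <- setdiff(unique(annotations$term), ont$terms$id)
  if (length(dangling)) {
    stop_input("annotation references unknown term id(s): ",
               paste(dangling, collapse = ", "))
  }
  anc <- term_ancestors(ont, relations)
  direct <- unique(annotations[, c("gene", "term")])
  a_list <- anc[direct$term]
  up <- data.frame(gene = rep(direct$gene, lengths(a_list)),
                   term = unlist(a_list, use.names = FALSE),
                   stringsAsFactors = FALSE)
  direct$direct <- TRUE
  if (nrow(up)) {
    up <- unique(up)
    up$direct <- FALSE
    all <- rbind(direct, up)
  } else {
    all <- direct
  }
  # dedupe with direct winning
  all <- all[order(all$gene, all$term, !all$direct), ]
  all <- all[!duplicated(all[, c("gene", "term")]), ]
  rownames(all) <- NULL
  all
}

#' Keep annotations from small-scale experiments only
#'
#' @param annotations data.frame with an `evidence` column; rows without one
#'   are kept.
#' @return filtered data.frame.
#' @export
filter_small_scale <- function(annotations) {
  if (is.null(annotations$evidence)) return(annotations)
  annotations[annotations$evidence == "small_scale", , drop = FALSE]
}

#' Select tissue terms with enough annotation support
#'
#' A term is retained iff it has strictly more than `min_direct` distinct
#' directly annotated genes AND strictly more than `min_propagated` distinct
#' genes after propagation.
#'
#' @param propagated output of [propagate_annotations()].
#' @param min_direct,min_propagated strict lower bounds (defaults 50 / 150).
#' @return character vector of retained term ids (possibly empty).
#' @export
select_tissues <- function(propagated, min_direct = 50, min_propagated = 150) {
  prop_n <- tapply(propagated$gene, propagated$term,
                   function(g) length(unique(g)))
  d <- propagated[propagated$direct, , drop = FALSE]
  direct_n <- tapply(d$gene, d$term, function(g) length(unique(g)))
  dn <- direct_n[names(prop_n)]
  dn[is.na(dn)] <- 0
  unname(names(prop_n)[prop_n > min_propagated & dn > min_direct])
}

#' Assign tissue terms to system-level slim terms
#'
#' The slim is either given directly or defined as the immediate children of
#' `roots`. Every term is assigned the slim terms among its ancestors, with
#' the term counting as its own ancestor (so slim terms map to themselves). A
#' term reaching no slim term gets an empty assignment with a warning.
#'
#' @param ont an [anatomy_ontology()].
#' @param roots term ids whose immediate children define the slim.
#' @param slim alternatively, the slim term ids themselves.
#' @param relations relations to traverse.
#' @return named list: term id -> character vector of slim term ids.
#' @export
define_slim <- function(ont, roots = NULL, slim = NULL,
                        relations = c("is_a", "part_of")) {
  if (is.null(slim)) {
    if (is.null(roots)) stop_input("give either roots or slim terms")
    if (!all(roots %in% ont$terms$id)) {
      stop_input("unknown root term(s): ",
                 paste(setdiff(roots, ont$terms$id), collapse = ", "))
    }
    slim <- unique(ont$edges$child[ont$edges$parent %in% roots &
                                     ont$edges$relation %in% relations])
  }
  anc <- term_ancestors(ont, relations)
  out <- lapply(ont$terms$id, function(v) intersect(c(v, anc[[v]]), slim))
  names(out) <- ont$terms$id
  orphans <- names(out)[lengths(out) == 0]
  orphans <- setdiff(orphans, c(roots %||% character()))
  if (length(orphans)) {
    warning(length(orphans), " term(s) reach no slim term", call. = FALSE)
  }
  out
}

#' Build per-tissue positive/negative gold standards
#'
#' For each retained tissue term t: positives are the genes annotated
#' (directly or through propagation) to t; negatives are genes annotated
#' somewhere, not to t, and to no term sharing any system-level slim term
#' with t. Genes annotated only within t's system(s) but not to t are
#' excluded (neither label), as are unannotated genes. Tissues with zero
#' positives are dropped with a warning. The prior of a tissue is
#' |positives| / (|positives| + |negatives|).
#'
#' @param propagated output of [propagate_annotations()] (small-scale
#'   evidence only, if the evidence filter is in use).
#' @param slim_assignment output of [define_slim()].
#' @param tissues character vector of tissue term ids to model.
#' @return object of class `gold_standard`: per tissue, `positives`,
#'   `negatives` and `prior`, plus a long `table` (tissue, gene, label).
#' @export
build_gold_standard <- function(propagated, slim_assignment, tissues) {
  terms_by_gene <- split(propagated$term, propagated$gene)
  genes <- names(terms_by_gene)
  systems_by_gene <- lapply(terms_by_gene, function(ts) {
    unique(unlist(slim_assignment[ts], use.names = FALSE))
  })
  out <- list()
  for (t in tissues) {
    sys_t <- slim_assignment[[t]] %||% character()
    has_t <- vapply(terms_by_gene, function(ts) t %in% ts, logical(1))
    pos <- genes[has_t]
    shares <- vapply(systems_by_gene,
                     function(s) length(intersect(s, sys_t)) > 0, logical(1))
    neg <- genes[!has_t & !shares]
    if (length(pos) == 0L) {
      warning("tissue with no positive examples dropped: ", t, call. = FALSE)
      next
    }
    stopifnot(length(intersect(pos, neg)) == 0)
    out[[t]] <- list(positives = pos, negatives = neg,
                     prior = length(pos) / (length(pos) + length(neg)))
  }
  table <- do.call(rbind, lapply(names(out), function(t) {
    data.frame(tissue = t,
               gene = c(out[[t]]$positives, out[[t]]$negatives),
               label = rep(c(1L, -1L), c(length(out[[t]]$positives),
                                         length(out[[t]]$negatives))),
               stringsAsFactors = FALSE)
  }))
  structure(list(tissues = out, table = table), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Tissue expression gold standard (", length(x$tissues), " tissues)\n",
      sep = "")
  df <- data.frame(
    tissue = names(x$tissues),
    positives = vapply(x$tissues, function(t) length(t$positives), 1L),
    negatives = vapply(x$tissues, function(t) length(t$negatives), 1L),
    prior = round(vapply(x$tissues, function(t) t$prior, 1), 3),
    row.names = NULL
  )
  print(df)
  invisible(x)
}

#' Write / read a gold standard as TSV (tissue, gene, label in {+1, -1})
#'
#' @param gs a [build_gold_standard()] object.
#' @param path output path.
#' @export
write_gold_standard <- function(gs, path) {
  write.table(gs$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tissues <- lapply(split(tab, tab$tissue), function(d) {
    list(positives = d$gene[d$label == 1L],
         negatives = d$gene[d$label == -1L],
         prior = mean(d$label == 1L))
  })
  structure(list(tissues = tissues, table = tab), class = "gold_standard")
}
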