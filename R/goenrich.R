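# GO term statistics for entity sets: per-node counts, the parent-child-union
# hypergeometric p-value, the replicated/pruned display tree, and
# paths-to-root.

#' Parent-child-union hypergeometric p-value for one GO term
#'
#' Instead of testing a term against the whole annotated genome, the
#' parent-child-union approach conditions on the term's parents: the
#' population for term `t` is `U_t`, the union of the propagated annotation
#' sets of `t`'s parents (for a root term, all annotated proteins). With
#' `N_t = |U_t|`, `m_t = |propagated(t)|` (contained in `U_t` by the
#' true-path rule), `n_t = |study ∩ U_t|` draws and `k_t = |study ∩
#' propagated(t)|` hits, the p-value is the upper hypergeometric tail
#' `P(X >= k_t)`. This asks whether the term is enriched *beyond what its
#' parents already explain*, damping the cascade of trivially significant
#' ancestors that the term-for-term test produces.
#'
#' @param term Term id.
#' @param study Character vector of study protein ids.
#' @param propagated Named list term -> propagated protein set, from
#'   [propagate_annotations()].
#' @param dag The `go_dag`.
#' @param relations Parent relations that define the conditioning union.
#' @return A list with `p_value` in (0, 1] and the internals `population`
#'   (`N_t`), `term_total` (`m_t`), `draws` (`n_t`), `hits` (`k_t`).
#' @export
#' @examples
#' # diamond DAG: R <- A, R <- B, A <- C, B <- C
#' dag <- snapsets:::toy_dag(c("C\tA", "C\tB", "A\tR", "B\tR"))
#' direct <- tibble::tibble(
#'   protein_id = c(paste0("u", 1:3), paste0("u", 4:6), paste0("u", 7:9)),
#'   term_id = rep(c("A", "C", "B"), each = 3))
#' prop <- propagate_annotations(dag, direct)
#' pcu_pvalue("C", c("u1", "u4", "u5", "u6", "u10"), prop, dag)$p_value
pcu_pvalue <- function(term, study, propagated, dag,
                       relations = c("is_a", "part_of")) {
  pars <- pcu_term_params(term, propagated, dag, relations)
  study <- unique(study)
  N <- length(pars$universe)
  m <- length(pars$term_set)
  n <- length(intersect(study, pars$universe))
  k <- length(intersect(study, pars$term_set))
  p <- if (N == 0L) 1 else min(1, phyper(k - 1L, m, N - m, n, lower.tail = FALSE))
  list(p_value = p, population = N, term_total = m, draws = n, hits = k)
}

# the conditioning population and success set of one term: the universe is
# the union of the parents' propagated sets (for a root, all annotated
# proteins), the success set the term's own propagated set within it
pcu_term_params <- function(term, propagated, dag,
                            relations = c("is_a", "part_of")) {
  if (!term %in% dag$terms$term_id) stop_lookup("unknown term '%s'", term)
  parents <- dag_parents(dag, term, relations)
  universe <- if (length(parents) == 0L) {
    sort_ids(unlist(propagated[dag$roots], use.names = FALSE))
  } else {
    sort_ids(unlist(propagated[parents], use.names = FALSE))
  }
  list(universe = universe,
       term_set = intersect(propagated[[term]] %||% character(), universe))
}

#' Null calibration of the parent-child-union test
#'
#' Draws study sets uniformly at random from a species' proteins and
#' measures, for every annotated term, how often the parent-child-union
#' p-value falls at or below each significance level. Because the
#' hypergeometric test is discrete the rejection rate is conservative:
#' it should not exceed the nominal level (up to Monte-Carlo noise).
#'
#' @param bundle A `ref_bundle` with ontology and annotations.
#' @param species Species to calibrate on.
#' @param n_draws Number of random study sets.
#' @param study_size Proteins per study set (default: a quarter of the
#'   species' proteins, at least 5).
#' @param alphas Significance levels to evaluate.
#' @param seed RNG seed.
#' @param relations GO relations traversed.
#' @return Tibble with one row per (term, alpha): `term_id`, `alpha`,
#'   `rejection_rate`, `n_draws`.
#' @export
pcu_calibration <- function(bundle, species, n_draws = 10000L,
                            study_size = NULL, alphas = c(0.01, 0.05),
                            seed = 1L, relations = c("is_a", "part_of")) {
  sd <- species_data(bundle, species)
  if (is.null(bundle$godag)) stop_lookup("no ontology loaded in this bundle")
  if (is.null(sd$annotations)) {
    stop_lookup("no GO annotations loaded for species '%s'", species)
  }
  dag <- bundle$godag
  prop <- propagate_annotations(dag, sd$annotations, relations)
  proteins <- sort_ids(names(sd$genome$proteins))
  np <- length(proteins)
  if (is.null(study_size)) study_size <- max(5L, np %/% 4L)

  annotated <- dag$terms$term_id[vapply(dag$terms$term_id, function(t)
    length(prop[[t]] %||% character()) > 0L, NA)]
  pars <- lapply(annotated, pcu_term_params, propagated = prop, dag = dag,
                 relations = relations)
  U <- do.call(rbind, lapply(pars, function(x) proteins %in% x$universe))
  Tm <- do.call(rbind, lapply(pars, function(x) proteins %in% x$term_set))
  N <- rowSums(U)
  m <- rowSums(Tm)

  set.seed(seed)
  S <- matrix(FALSE, nrow = np, ncol = n_draws)
  for (j in seq_len(n_draws)) {
    S[sample.int(np, study_size), j] <- TRUE
  }
  n_mat <- (U * 1L) %*% S    # terms x draws: |study ∩ U_t|
  k_mat <- (Tm * 1L) %*% S   # terms x draws: |study ∩ propagated(t)|
  p_mat <- matrix(phyper(as.vector(k_mat) - 1L, rep(m, n_draws),
                         rep(N - m, n_draws), as.vector(n_mat),
                         lower.tail = FALSE),
                  nrow = length(annotated))
  p_mat[N == 0L, ] <- 1
  p_mat <- pmin(p_mat, 1)

  out <- lapply(alphas, function(a) {
    tibble(term_id = annotated, alpha = a,
           rejection_rate = rowMeans(p_mat <= a),
           n_draws = n_draws)
  })
  bind_rows(out)
}

#' GO term enrichment of an entity set
#'
#' Computes, for every term whose subtree contains at least one study
#' protein, the classic per-node report: (i) the term description, (ii)
#' direct study hits on the node, (iii) direct genome annotations of the
#' node, (iv) study proteins in the subtree rooted at the node, (v) the
#' study total at the analysis level, and (vi) the parent-child-union
#' hypergeometric p-value (see [pcu_pvalue()]). Counts (ii) and (iii) use
#' direct annotations; (iv) and the p-value use true-path-propagated sets.
#'
#' At `level = "protein"` the study set is the set's protein projection; at
#' `level = "gene"` each member gene contributes all its proteins, so
#' annotation is interpreted through the gene. Study proteins without any
#' annotation still count toward the study total but can never contribute
#' hits.
#'
#' @param set An `entity_set` (or the result of [snapshot_content()]).
#' @param bundle A `ref_bundle` with ontology and annotations loaded.
#' @param level `"protein"` (default) or `"gene"`.
#' @param namespace Optional ontology namespace filter (e.g.
#'   `"biological_process"`).
#' @param bh Add a Benjamini-Hochberg adjusted column `p_bh` (off by
#'   default; the per-node report is conventionally raw).
#' @param relations GO relations traversed for propagation and conditioning.
#' @return A `go_enrichment` tibble, one row per term with a study hit in
#'   its subtree, sorted by ascending `p_value` with ties broken by term id.
#'   Carries columns `term_id`, `name`, `direct_in_set`, `direct_in_genome`,
#'   `subtree_in_set`, `set_total`, `p_value` and the test internals
#'   `population`, `term_total`, `draws`, `hits`.
#' @export
go_enrich <- function(set, bundle, level = c("protein", "gene"),
                      namespace = NULL, bh = FALSE,
                      relations = c("is_a", "part_of")) {
  check_entity_set(set)
  level <- match.arg(level)
  if (is.null(bundle$godag)) stop_lookup("no ontology loaded in this bundle")
  sd <- species_data(bundle, set$species)
  if (is.null(sd$annotations)) {
    stop_lookup("no GO annotations loaded for species '%s'", set$species)
  }
  dag <- bundle$godag
  prop <- propagate_annotations(dag, sd$annotations, relations)

  study <- if (level == "protein") {
    set$proteins
  } else {
    full <- es_extend(set, sd$genome)  # every protein of every member gene
    full$proteins
  }
  set_total <- length(es_project(set, level))

  terms <- dag$terms
  if (!is.null(namespace)) {
    terms <- terms[terms$namespace == namespace, , drop = FALSE]
  }
  direct_by_term <- split(sd$annotations$protein_id, sd$annotations$term_id)

  rows <- lapply(seq_len(nrow(terms)), function(i) {
    t <- terms$term_id[i]
    subtree_hits <- intersect(prop[[t]] %||% character(), study)
    if (length(subtree_hits) == 0L) return(NULL)
    direct <- unique(direct_by_term[[t]] %||% character())
    stat <- pcu_pvalue(t, study, prop, dag, relations)
    tibble(term_id = t, name = terms$name[i],
           direct_in_set = length(intersect(direct, study)),
           direct_in_genome = length(direct),
           subtree_in_set = length(subtree_hits),
           set_total = set_total,
           p_value = stat$p_value,
           population = stat$population, term_total = stat$term_total,
           draws = stat$draws, hits = stat$hits)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(term_id = character(), name = character(),
                  direct_in_set = integer(), direct_in_genome = integer(),
                  subtree_in_set = integer(), set_total = integer(),
                  p_value = double(), population = integer(),
                  term_total = integer(), draws = integer(), hits = integer())
  }
  out <- out[order(out$p_value, out$term_id, method = "radix"), ]
  if (isTRUE(bh)) out$p_bh <- p.adjust(out$p_value, method = "BH")
  structure(out, class = c("go_enrichment", class(tibble())),
            species = set$species, level = level, study_size = length(study))
}

#' @export
tidy.go_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.go_enrichment <- function(x, ...) {
  tibble(species = attr(x, "species"), level = attr(x, "level"),
         n_terms = nrow(x), study_size = attr(x, "study_size"),
         min_p = if (nrow(x) > 0L) min(x$p_value) else NA_real_)
}

# ---- display tree -----------------------------------------------------------

#' Display tree of an enrichment result
#'
#' Renders the GO DAG as a tree the way term browsers do: expansion starts
#' from each ontology root, a term with multiple retained parents is
#' replicated once under each of them, and subtrees without a single study
#' match are pruned entirely. Because propagated sets grow toward the root,
#' the retained terms are exactly the result's terms and every displayed
#' subtree contains a match.
#'
#' @param results A `go_enrichment`.
#' @param dag The `go_dag` the results were computed on.
#' @param relations Edge types defining the tree.
#' @return A `go_display_tree`: list of rooted nodes, each
#'   `list(term_id, children)`; print shows the indented tree.
#' @export
go_display_tree <- function(results, dag, relations = c("is_a", "part_of")) {
  retained <- results$term_id
  kids_of <- function(t) {
    ch <- dag$children[[t]] %||% character()
    rel_edges <- dag$edges[dag$edges$parent == t &
                             dag$edges$relation %in% relations, , drop = FALSE]
    sort_ids(intersect(rel_edges$child, retained))
  }
  build <- function(t) {
    list(term_id = t, children = lapply(kids_of(t), build))
  }
  roots <- sort_ids(intersect(dag$roots, retained))
  structure(list(roots = lapply(roots, build), results = results),
            class = "go_display_tree")
}

#' @export
print.go_display_tree <- function(x, ...) {
  stats <- x$results
  emit <- function(node, depth) {
    row <- stats[stats$term_id == node$term_id, ]
    cat(strrep("  ", depth), node$term_id,
        sprintf(" [%d/%d, p=%.3g]", row$subtree_in_set[1L], row$set_total[1L],
                row$p_value[1L]), "\n", sep = "")
    for (ch in node$children) emit(ch, depth + 1L)
  }
  for (r in x$roots) emit(r, 0L)
  invisible(x)
}

# number of displayed copies of every retained term
tree_copy_counts <- function(tree) {
  counts <- new.env(parent = emptyenv())
  walk <- function(node) {
    counts[[node$term_id]] <- (counts[[node$term_id]] %||% 0L) + 1L
    for (ch in node$children) walk(ch)
  }
  for (r in tree$roots) walk(r)
  ids <- sort_ids(ls(counts))
  setNames(vapply(ids, function(i) counts[[i]], 0L), ids)
}

#' All parent chains from a term to the ontology roots
#'
#' A term below a multi-parent region of the DAG reaches a root along
#' several chains; each corresponds to one copy of the term in the display
#' tree. Paths are returned in lexicographic order of their id sequence.
#'
#' @param term Term id.
#' @param dag The `go_dag`.
#' @param relations Edge types to traverse.
#' @return List of character vectors, each a chain `term, parent, ..., root`.
#' @export
go_paths_to_root <- function(term, dag, relations = c("is_a", "part_of")) {
  if (!term %in% dag$terms$term_id) stop_lookup("unknown term '%s'", term)
  recurse <- function(t) {
    parents <- dag_parents(dag, t, relations)
    if (length(parents) == 0L) return(list(t))
    out <- list()
    for (p in parents) {  # parents sorted: paths come out lexicographically
      for (tail in recurse(p)) {
        out[[length(out) + 1L]] <- c(t, tail)
      }
    }
    out
  }
  recurse(term)
}

#' Proteins annotated to a term (node) or its subtree
#'
#' `mode = "node"` returns the directly annotated proteins; `mode =
#' "subtree"` the true-path-propagated set. When `scope` is an entity set,
#' the result is intersected with its protein projection, e.g. to pull the
#' matching members out of a snapshot. The result feeds [snap_add()] /
#' [es_add()] directly (transitive closure then brings in transcripts and
#' genes).
#'
#' @param term Term id.
#' @param bundle A `ref_bundle`.
#' @param species Species whose annotations to use.
#' @param mode `"subtree"` (default) or `"node"`.
#' @param scope Optional `entity_set` restricting the result.
#' @param relations GO relations traversed for propagation.
#' @return Sorted character vector of protein ids.
#' @export
go_term_entities <- function(term, bundle, species,
                             mode = c("subtree", "node"), scope = NULL,
                             relations = c("is_a", "part_of")) {
  mode <- match.arg(mode)
  if (is.null(bundle$godag) || !term %in% bundle$godag$terms$term_id) {
    stop_lookup("unknown term '%s'", term)
  }
  sd <- species_data(bundle, species)
  if (is.null(sd$annotations)) {
    stop_lookup("no GO annotations loaded for species '%s'", species)
  }
  out <- if (mode == "node") {
    sort_ids(sd$annotations$protein_id[sd$annotations$term_id == term])
  } else {
    prop <- propagate_annotations(bundle$godag, sd$annotations, relations)
    prop[[term]] %||% character()
  }
  if (!is.null(scope)) out <- intersect(out, es_project(scope, "protein"))
  sort_ids(out)
}

# test helper: build a go_dag from "child\tparent[\trelation]" strings
toy_dag <- function(edge_lines, extra_terms = character()) {
  parts <- strsplit(edge_lines, "\t", fixed = TRUE)
  edges <- tibble(
    child = vapply(parts, `[[`, "", 1L),
    parent = vapply(parts, `[[`, "", 2L),
    relation = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "is_a", "")
  )
  ids <- sort_ids(c(edges$child, edges$parent, extra_terms))
  terms <- tibble(term_id = ids, name = paste("term", ids),
                  namespace = "biological_process")
  new_go_dag(terms, edges, source = "toy")
}
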