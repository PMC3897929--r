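# Independent oracles: brute force / enumeration implementations kept free
# of the code paths they check.

# ancestor closure by boolean matrix products on the child->parent adjacency
reachability_oracle <- function(dag) {
  ids <- dag$terms$term_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(dag$edges))) {
    A[dag$edges$child[i], dag$edges$parent[i]] <- TRUE
  }
  R <- diag(n) > 0
  dimnames(R) <- dimnames(A)
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R  # R[c, t] TRUE iff t is an ancestor-or-self of c
}

# propagated(t) oracle: proteins directly annotated to any term whose
# ancestor-or-self set contains t
propagation_oracle <- function(dag, direct) {
  R <- reachability_oracle(dag)
  ids <- dag$terms$term_id
  out <- lapply(ids, function(t) {
    sources <- ids[R[, t]]
    sort(unique(direct$protein_id[direct$term_id %in% sources]))
  })
  names(out) <- ids
  out
}

# exhaustive hypergeometric upper tail: draw n from a universe holding m
# marked elements; P(X >= k) by enumerating all C(N, n) draws
hyper_tail_oracle <- function(N, m, n, k) {
  if (N == 0L || n == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)  # elements 1..m are the marked ones
  mean(hits >= k)
}

# number of root-to-term paths restricted to a retained, ancestor-closed
# term set (memoized recursion on parents)
path_count_oracle <- function(dag, retained) {
  memo <- new.env(parent = emptyenv())
  count <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    parents <- intersect(snapsets:::dag_parents(dag, t), retained)
    v <- if (length(parents) == 0L) 1L else sum(vapply(parents, count, 0L))
    memo[[t]] <- v
    v
  }
  setNames(vapply(retained, count, 0L), retained)
}

# shortest-path hop distances through an edge list (igraph as third party)
bfs_oracle <- function(edges, seeds, hops) {
  if (nrow(edges) == 0L || length(seeds) == 0L) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0L) return(character())
  d <- igraph::distances(g, v = present)
  dd <- apply(d, 2L, min)
  sort(names(dd)[is.finite(dd) & dd <= hops])
}

# O(n) interval scan
region_oracle <- function(genes, chromosome, qs, qe) {
  hits <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$chromosome[i] == chromosome &&
        genes$start[i] <= qe && genes$end[i] >= qs) {
      hits <- c(hits, genes$gene_id[i])
    }
  }
  sort(hits)
}

expect_consistent <- function(set, gm) {
  expect_silent(snapsets:::es_validate(set, gm))
  # level hierarchy: genes of the transcript projection are members, etc.
  expect_true(all(unname(gm$transcripts[set$transcripts]) %in% set$genes))
  expect_true(all(unname(gm$proteins[set$proteins]) %in% set$transcripts))
}
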