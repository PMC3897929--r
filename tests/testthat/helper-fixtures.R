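# Shared fixtures, built once per test session.

fig1_dir <- function() {
  d <- file.path(tempdir(), "snapsets-fig1")
  if (!file.exists(file.path(d, "genome.tsv"))) figure1_bundle(d)
  d
}

.fixture_cache <- new.env(parent = emptyenv())

fig1_bundle_loaded <- function() {
  if (is.null(.fixture_cache$fig1)) {
    .fixture_cache$fig1 <- load_bundle(fig1_dir())
  }
  .fixture_cache$fig1
}

synth_bundle <- function(seed = 42L, ...) {
  key <- paste0("synth", seed, paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    d <- generate_bundle(bundle_spec(seed = seed, ...),
                         file.path(tempdir(), paste0("snapsets-", key)))
    .fixture_cache[[key]] <- load_bundle(d)
  }
  .fixture_cache[[key]]
}

# deterministic, strictly increasing clock for reproducible workspaces
fixed_clock <- function(start = "2026-01-01 00:00:00") {
  t <- as.POSIXct(start, tz = "UTC")
  function() {
    t <<- t + 1
    t
  }
}

fig1_workspace <- function() {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  aliases <- replay_script(ws, file.path(fig1_dir(), "figure1.replay"))
  list(ws = ws, al = aliases)
}

# diamond ontology R <- A, R <- B, A <- C, B <- C with the worked annotation
# layout: propagated A = u1..u6, B = u4..u9, C = u4..u6
diamond_fixture <- function() {
  dag <- snapsets:::toy_dag(c("C\tA", "C\tB", "A\tR", "B\tR"))
  direct <- tibble::tibble(
    protein_id = c(paste0("u", 1:3), paste0("u", 7:9), paste0("u", 4:6)),
    term_id = c(rep("A", 3), rep("B", 3), rep("C", 3))
  )
  list(dag = dag, direct = direct,
       prop = propagate_annotations(dag, direct))
}

# per-term statistics for a bare dag/annotation fixture (no bundle needed)
go_enrich_from <- function(fx, study) {
  retained <- fx$dag$terms$term_id[vapply(fx$dag$terms$term_id, function(t)
    length(intersect(fx$prop[[t]], study)) > 0L, NA)]
  rows <- lapply(retained, function(t) {
    st <- pcu_pvalue(t, study, fx$prop, fx$dag)
    tibble::tibble(term_id = t, p_value = st$p_value,
                   subtree_in_set = st$hits)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(tibble::tibble(term_id = character(),
                                             p_value = double(),
                                             subtree_in_set = integer()))
  out[order(out$p_value, out$term_id), ]
}

# a random acyclic ontology: term i draws parents among terms 1..i-1
random_dag <- function(n_terms, seed, max_parents = 3L, n_roots = 1L) {
  set.seed(seed)
  ids <- sprintf("D%02d", seq_len(n_terms))
  edges <- character()
  for (i in seq_len(n_terms)) {
    if (i <= n_roots) next
    np <- sample(seq_len(min(max_parents, i - 1L)), 1L)
    for (p in sample(i - 1L, np)) {
      edges <- c(edges, paste(ids[i], ids[p], sep = "\t"))
    }
  }
  snapsets:::toy_dag(edges, extra_terms = ids)
}

# random direct annotations of `proteins` onto a DAG
random_annotations <- function(dag, n_proteins, seed, density = 0.7) {
  set.seed(seed)
  prots <- sprintf("u%02d", seq_len(n_proteins))
  rows <- list()
  for (p in prots) {
    if (runif(1) < density) {
      for (t in sample(dag$terms$term_id, sample(1:2, 1L))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(protein_id = p, term_id = t)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(protein_id = character(), term_id = character()))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

# run one random action sequence (add/extend/union/intersect/minus/branch/
# clear) on a fresh workspace over the worked-example bundle; returns the
# workspace for invariant and replay checking
fuzz_workspace <- function(seed, n_actions = 6L) {
  b <- fig1_bundle_loaded()
  gm <- b$species$A$genome
  pool <- c(gm$genes$gene_id, names(gm$transcripts), names(gm$proteins))
  ws <- workspace(b, clock = fixed_clock())
  cid <- container_create(ws, "A")
  snapshot_create(ws, cid)
  set.seed(seed)
  for (i in seq_len(n_actions)) {
    snaps <- names(ws$snapshots)
    s <- sample(snaps, 1L)
    verb <- sample(c("add", "add", "extend", "branch", "union", "intersect",
                     "minus", "clear"), 1L)
    o <- sample(snaps, 1L)
    switch(verb,
      add = snap_add(ws, s, sample(pool, sample(1:3, 1L))),
      extend = snap_extend(ws, s),
      branch = snapshot_create(ws, cid, parent = s),
      union = snap_union(ws, s, o),
      intersect = snap_intersect(ws, s, o),
      minus = snap_minus(ws, s, o,
                         minus_level = sample(c("gene", "transcript",
                                                "protein"), 1L)),
      clear = snapshot_clear(ws, s))
  }
  ws
}

# random transitively consistent entity set over a genome model
random_entity_set <- function(gm, seed, n = 4L) {
  set.seed(seed)
  pool <- c(gm$genes$gene_id, names(gm$transcripts), names(gm$proteins))
  es_add(entity_set(gm$species), gm, sample(pool, min(n, length(pool))))
}
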