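test_that("the parent-child-union p-value reproduces the worked diamond case", {
  fx <- diamond_fixture()
  res <- pcu_pvalue("C", c("u1", "u4", "u5", "u6", "u10"), fx$prop, fx$dag)
  expect_equal(res$population, 9L)   # union of A and B propagated sets
  expect_equal(res$term_total, 3L)
  expect_equal(res$draws, 4L)        # u10 is outside the parents' union
  expect_equal(res$hits, 3L)
  expect_equal(res$p_value, 6 / 126, tolerance = 1e-12)
})

test_that("degenerate inputs give p = 1", {
  fx <- diamond_fixture()
  expect_equal(pcu_pvalue("C", character(), fx$prop, fx$dag)$p_value, 1)
  expect_equal(pcu_pvalue("C", "uZZ", fx$prop, fx$dag)$p_value, 1)  # k = 0
  expect_error(pcu_pvalue("nope", "u1", fx$prop, fx$dag),
               class = "snapsets_lookup_error")
})

test_that("a single-parent term is tested against that parent's propagated set", {
  dag <- snapsets:::toy_dag(c("B\tA", "A\tR"))
  direct <- tibble::tibble(protein_id = paste0("u", 1:8),
                           term_id = c(rep("A", 5), rep("B", 3)))
  prop <- propagate_annotations(dag, direct)
  study <- c("u6", "u7", "u1")
  got <- pcu_pvalue("B", study, prop, dag)
  expect_equal(got$population, length(prop$A))
  expect_equal(got$p_value,
               hyper_tail_oracle(length(prop$A), length(prop$B),
                                 length(intersect(study, prop$A)),
                                 length(intersect(study, prop$B))),
               tolerance = 1e-12)
})

test_that("enrichment reports the six per-node statistics with deterministic order", {
  b <- synth_bundle()
  gm <- b$species$spA$genome
  set.seed(3)
  es <- es_add(entity_set("spA"), gm, sample(names(gm$proteins), 12L),
               level = "protein")
  r1 <- go_enrich(es, b)
  r2 <- go_enrich(es, b)
  expect_identical(r1, r2)                        # bit-identical reruns
  expect_true(all(diff(r1$p_value) >= 0))
  expect_true(all(r1$subtree_in_set >= 1L))
  expect_true(all(r1$direct_in_set <= r1$subtree_in_set))
  expect_true(all(r1$subtree_in_set <= r1$set_total))
  expect_true(all(r1$direct_in_set <= r1$direct_in_genome))
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  expect_true(all(r1$hits <= pmin(r1$term_total, r1$draws)))
  expect_equal(unique(r1$set_total), length(es$proteins))

  # subtree counts respect the true-path rule parent >= child
  prop_counts <- setNames(r1$subtree_in_set, r1$term_id)
  for (i in seq_len(nrow(b$godag$edges))) {
    ch <- b$godag$edges$child[i]; pa <- b$godag$edges$parent[i]
    if (ch %in% names(prop_counts) && pa %in% names(prop_counts)) {
      expect_gte(prop_counts[[pa]], prop_counts[[ch]])
    }
  }

  # optional BH column appears only on request and is monotone on sorted p
  expect_false("p_bh" %in% names(r1))
  r3 <- go_enrich(es, b, bh = TRUE)
  expect_identical(r3$p_bh, p.adjust(r3$p_value, "BH"))
})

test_that("enrichment handles empty and saturated study sets as forced", {
  b <- synth_bundle()
  expect_equal(nrow(go_enrich(entity_set("spA"), b)), 0L)

  gm <- b$species$spA$genome
  annotated <- sort(unique(b$species$spA$annotations$protein_id))
  all_set <- es_add(entity_set("spA"), gm, annotated, level = "protein")
  r <- go_enrich(all_set, b)
  # every annotated protein drawn: k = m and n = N for every term, so p = 1
  expect_true(all(r$p_value == 1))
  prop <- propagate_annotations(b$godag, b$species$spA$annotations)
  expect_equal(setNames(r$subtree_in_set, r$term_id)[r$term_id],
               vapply(r$term_id, function(t) length(prop[[t]]), 0L))
})

test_that("a snapshot made of one term's subtree ranks that term first (or tied)", {
  b <- synth_bundle()
  gm <- b$species$spA$genome
  prop <- propagate_annotations(b$godag, b$species$spA$annotations)
  sizes <- vapply(prop, length, 0L)
  # a mid-size term: informative but not the root
  t_star <- names(sizes)[sizes > 2 & sizes < max(sizes)][2L]
  es <- es_add(entity_set("spA"), gm, prop[[t_star]], level = "protein")
  r <- go_enrich(es, b)
  best <- r$term_id[r$p_value <= r$p_value[1L]]
  expect_true(t_star %in% best)
})

test_that("gene-level enrichment interprets annotation through each gene's proteins", {
  b <- synth_bundle()
  gm <- b$species$spA$genome
  es <- es_add(entity_set("spA"), gm, gm$genes$gene_id[1:10], level = "gene")
  r <- go_enrich(es, b, level = "gene")
  expect_equal(unique(r$set_total), 10L)
  full <- es_extend(es, gm)
  r_protein_view <- go_enrich(full, b, level = "protein")
  expect_identical(r$term_id, r_protein_view$term_id)
  expect_identical(r$p_value, r_protein_view$p_value)
})

test_that("the display tree replicates multi-parent terms and prunes empty subtrees", {
  fx <- diamond_fixture()
  study <- "u4"  # hits only C's subtree (and so A, B, R by true-path)
  retained_stats <- go_enrich_from(fx, study)
  tree <- go_display_tree(retained_stats, fx$dag)
  counts <- snapsets:::tree_copy_counts(tree)
  expect_equal(counts[["C"]], 2L)    # once under A, once under B
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["R"]], 1L)

  none <- retained_stats[0, ]
  expect_length(go_display_tree(none, fx$dag)$roots, 0L)
})

test_that("display-tree copy counts equal the root-path-count oracle on random DAGs", {
  for (seed in 21:40) {
    dag <- random_dag(sample(8:25, 1L), seed = seed, max_parents = 3L)
    direct <- random_annotations(dag, 12L, seed + 500L)
    if (nrow(direct) == 0L) next
    prop <- propagate_annotations(dag, direct)
    set.seed(seed + 900L)
    study <- sample(unique(direct$protein_id),
                    min(4L, length(unique(direct$protein_id))))
    retained <- dag$terms$term_id[vapply(dag$terms$term_id, function(t)
      length(intersect(prop[[t]], study)) > 0L, NA)]
    if (length(retained) == 0L) next
    tree <- go_display_tree(tibble::tibble(term_id = retained), dag)
    counts <- snapsets:::tree_copy_counts(tree)
    oracle <- path_count_oracle(dag, retained)
    expect_identical(counts[sort(names(counts))], oracle[sort(names(oracle))])
  }
})

test_that("paths to root enumerate every parent chain in lexicographic order", {
  fx <- diamond_fixture()
  expect_equal(go_paths_to_root("C", fx$dag),
               list(c("C", "A", "R"), c("C", "B", "R")))
  expect_equal(go_paths_to_root("R", fx$dag), list("R"))
  expect_error(go_paths_to_root("nope", fx$dag), class = "snapsets_lookup_error")

  for (seed in 41:48) {
    dag <- random_dag(sample(6:15, 1L), seed = seed, max_parents = 3L)
    t <- dag$terms$term_id[nrow(dag$terms)]
    paths <- go_paths_to_root(t, dag)
    expect_equal(length(paths),
                 unname(path_count_oracle(dag, dag$terms$term_id)[t]))
    expect_false(anyDuplicated(vapply(paths, paste, "", collapse = ">")) > 0)
  }
})

test_that("term entity lookups distinguish node from subtree and honor scope", {
  b <- synth_bundle()
  gm <- b$species$spA$genome
  ann <- b$species$spA$annotations
  prop <- propagate_annotations(b$godag, ann)
  t_mid <- names(which(vapply(prop, length, 0L) > 2))[2L]

  node <- go_term_entities(t_mid, b, "spA", mode = "node")
  subtree <- go_term_entities(t_mid, b, "spA", mode = "subtree")
  expect_identical(node, sort(unique(ann$protein_id[ann$term_id == t_mid])))
  expect_identical(subtree, prop[[t_mid]])
  expect_true(all(node %in% subtree))

  scope <- es_add(entity_set("spA"), gm, subtree[1L], level = "protein")
  expect_identical(go_term_entities(t_mid, b, "spA", scope = scope), subtree[1L])
  expect_error(go_term_entities("nope", b, "spA"), class = "snapsets_lookup_error")

  # composition: the subtree proteins can be added straight to a set
  grown <- es_add(entity_set("spA"), gm, subtree, level = "protein")
  expect_consistent(grown, gm)
})

test_that("the diamond worked example also holds inside a full bundle universe", {
  fx <- diamond_fixture()
  # u10 exists in the study but is annotated nowhere
  res <- go_enrich_from(fx, c("u1", "u4", "u5", "u6", "u10"))
  expect_equal(res$p_value[res$term_id == "C"], 6 / 126, tolerance = 1e-12)
})
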