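test_that("direct-neighbor expansion of the worked example yields the six captioned proteins", {
  b <- fig1_bundle_loaded()
  gm <- b$species$A$genome
  c_snap <- es_extend(es_add(entity_set("A"), gm, c("g1", "g2", "g3")), gm)
  net <- interaction_network(c_snap, b, hops = 1, mode = "any")
  expect_setequal(net$nodes$protein_id,
                  c("p1_1", "p1_2", "p3_1", "p4_1", "p5_1", "p5_2"))
  # the edgeless seed is not displayed
  expect_false("p2_1" %in% net$nodes$protein_id)
  expect_setequal(net$nodes$role[net$nodes$protein_id %in% c("p4_1", "p5_1", "p5_2")],
                  "added")
  # every edge lies inside the node set
  expect_true(all(net$edges$protein_a %in% net$nodes$protein_id))
  expect_true(all(net$edges$protein_b %in% net$nodes$protein_id))
})

test_that("empty inputs and multi-hop walks behave as documented", {
  b <- fig1_bundle_loaded()
  empty <- interaction_network(entity_set("A"), b)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  # path graph a-b-c-d, seed {a}, hops 2 -> {a, b, c}
  edges <- tibble::tibble(protein_a = c("p1_1", "p1_2", "p2_1"),
                          protein_b = c("p1_2", "p2_1", "p3_1"),
                          score = NA_real_)
  gm <- b$species$A$genome
  seed <- es_add(entity_set("A"), gm, "p1_1")
  net <- interaction_network(seed, edges, hops = 2)
  expect_setequal(net$nodes$protein_id, c("p1_1", "p1_2", "p2_1"))
  expect_equal(net$nodes$hops[net$nodes$protein_id == "p2_1"], 2L)
})

test_that("any-mode expansion matches the shortest-path oracle on random graphs", {
  b <- synth_bundle()
  gm <- b$species$spA$genome
  prots <- names(gm$proteins)
  for (seed in 1:50) {
    set.seed(seed + 2000L)
    n <- sample(10:40, 1L)
    pool <- sample(prots, n)
    pairs <- t(utils::combn(pool, 2L))
    keep <- runif(nrow(pairs)) < 0.1
    edges <- tibble::tibble(protein_a = pairs[keep, 1L],
                            protein_b = pairs[keep, 2L],
                            score = runif(sum(keep), 0, 1000))
    seeds <- sample(pool, sample(1:3, 1L))
    hops <- sample(1:3, 1L)
    es <- es_add(entity_set("spA"), gm, seeds, level = "protein")
    net <- interaction_network(es, edges, hops = hops)
    expect_identical(sort(net$nodes$protein_id),
                     bfs_oracle(edges, seeds, hops))
    # monotone in the hop count
    net_more <- interaction_network(es, edges, hops = hops + 1L)
    expect_true(all(net$nodes$protein_id %in% net_more$nodes$protein_id))
  }
})

test_that("re-expanding after adding the network nodes is idempotent on the node set", {
  b <- fig1_bundle_loaded()
  gm <- b$species$A$genome
  s <- es_extend(es_add(entity_set("A"), gm, c("g1", "g2", "g3")), gm)
  net1 <- interaction_network(s, b, hops = 1)
  s2 <- es_add(s, gm, net1$nodes$protein_id, level = "protein")
  net2 <- interaction_network(s2, b, hops = 1)
  expect_setequal(net2$nodes$protein_id, net1$nodes$protein_id)
})

test_that("all-mode keeps only common neighbors and rejects hops > 1", {
  edges <- tibble::tibble(protein_a = c("p1_1", "p2_1", "p1_1"),
                          protein_b = c("p5_1", "p5_1", "p4_1"),
                          score = NA_real_)
  gm <- fig1_bundle_loaded()$species$A$genome
  seeds <- es_add(entity_set("A"), gm, c("p1_1", "p2_1"), level = "protein")
  net <- interaction_network(seeds, edges, mode = "all")
  expect_true("p5_1" %in% net$nodes$protein_id)   # adjacent to both seeds
  expect_false("p4_1" %in% net$nodes$protein_id)  # adjacent to one only
  expect_error(interaction_network(seeds, edges, mode = "all", hops = 2),
               class = "snapsets_validation_error")
})

test_that("score thresholds filter edges before expansion", {
  b <- fig1_bundle_loaded()
  gm <- b$species$A$genome
  s <- es_extend(es_add(entity_set("A"), gm, c("g1", "g2", "g3")), gm)
  net <- interaction_network(s, b, min_score = 750)
  # only p1_1-p4_1 (900) and p1_2-p5_1 (800) survive
  expect_setequal(net$nodes$protein_id, c("p1_1", "p1_2", "p4_1", "p5_1"))
})

test_that("pathway ECs are classified into the exhaustive three-way partition", {
  d <- tempfile(); dir.create(d)
  file.copy(file.path(fig1_dir(), "genome.tsv"), file.path(d, "genome.tsv"))
  writeLines(c("protein_id\tec_number",
               "p1_1\t2.7.1.1", "p4_1\t1.1.1.1"), file.path(d, "ec.tsv"))
  writeLines(c("pathway_id\tpathway_name\tec_number",
               "pw1\tglycolysis-like\t2.7.1.1",
               "pw1\tglycolysis-like\t1.1.1.1",
               "pw1\tglycolysis-like\t9.9.9.9"), file.path(d, "pathways.tsv"))
  b <- load_bundle(d)
  gm <- b$species$A$genome
  s <- es_add(entity_set("A"), gm, "p1_1")
  hl <- classify_pathway("pw1", s, b)
  st <- setNames(hl$status, hl$ec_number)
  expect_equal(st[["2.7.1.1"]], "IN_SET")
  expect_equal(st[["1.1.1.1"]], "IN_GENOME_ONLY")
  expect_equal(st[["9.9.9.9"]], "ABSENT")
  expect_error(classify_pathway("nope", s, b), class = "snapsets_lookup_error")

  # statuses always partition the pathway's EC set
  b2 <- synth_bundle()
  gm2 <- b2$species$spA$genome
  set.seed(9)
  s2 <- es_add(entity_set("spA"), gm2, sample(names(gm2$proteins), 10),
               level = "protein")
  for (pw in unique(b2$pathways$pathway_id)) {
    hl2 <- classify_pathway(pw, s2, b2)
    expect_setequal(hl2$ec_number,
                    unique(b2$pathways$ec_number[b2$pathways$pathway_id == pw]))
    expect_true(all(hl2$status %in% c("IN_SET", "IN_GENOME_ONLY", "ABSENT")))
  }
})

test_that("EC wildcards match on the specified components only", {
  expect_true(snapsets:::ec_matches("2.7.-.-", "2.7.1.1"))
  expect_true(snapsets:::ec_matches("2.7.1.1", "2.7.1.1"))
  expect_false(snapsets:::ec_matches("2.7.-.-", "2.8.1.1"))
  expect_false(snapsets:::ec_matches("2.7.1.2", "2.7.1.1"))
})

test_that("genes behind an EC or a whole pathway come from the protein hierarchy", {
  d <- tempfile(); dir.create(d)
  file.copy(file.path(fig1_dir(), "genome.tsv"), file.path(d, "genome.tsv"))
  writeLines(c("protein_id\tec_number",
               "p1_1\t2.7.1.1", "p4_1\t1.1.1.1"), file.path(d, "ec.tsv"))
  writeLines(c("pathway_id\tpathway_name\tec_number",
               "pw1\tx\t2.7.1.1", "pw1\tx\t1.1.1.1"),
             file.path(d, "pathways.tsv"))
  b <- load_bundle(d)
  expect_equal(pathway_genes(b, "A", ec = "2.7.1.1"), "g1")
  expect_equal(pathway_genes(b, "A", pathway = "pw1"), c("g1", "g4"))
  expect_equal(pathway_genes(b, "A", ec = "5.5.5.5"), character())
  expect_error(pathway_genes(b, "A"), class = "snapsets_validation_error")
})
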