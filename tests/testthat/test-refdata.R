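test_that("the packaged worked-example bundle loads with the documented shape", {
  b <- fig1_bundle_loaded()
  expect_s3_class(b, "ref_bundle")
  expect_setequal(names(b$species), c("A", "B"))
  gm <- b$species$A$genome
  expect_equal(nrow(gm$genes), 5L)
  expect_length(gm$transcripts, 7L)
  expect_length(gm$proteins, 7L)
  expect_equal(unname(gm$proteins[["p1_2"]]), "t1_2")
  expect_equal(unname(gm$transcripts[["t5_2"]]), "g5")
  expect_equal(nrow(b$orthology), 2L)
  expect_null(b$godag)
})

test_that("loading is idempotent: the same directory yields an identical bundle", {
  b1 <- load_bundle(fig1_dir())
  b2 <- load_bundle(fig1_dir())
  expect_identical(b1, b2)
  s <- synth_bundle()
  s2 <- load_bundle(s$dir)
  expect_identical(s, s2)
})

test_that("dangling references, duplicates and malformed ECs are load errors naming the spot", {
  d <- tempfile(); dir.create(d)
  hdr <- "species\tgene_id\tgene_name\tchromosome\tstart\tend\tstrand\ttranscript_id\tprotein_id"
  # protein cell without a transcript reference
  writeLines(c(hdr,
               "A\tg1\tn\tchr1\t1\t10\t1\tt1\tp1",
               "A\tg2\tn\tchr1\t1\t10\t1\t\tp2"),
             file.path(d, "genome.tsv"))
  err <- expect_error(load_bundle(d), class = "snapsets_validation_error")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "p2")

  # duplicate identifier across levels
  writeLines(c(hdr, "A\tg1\tn\tchr1\t1\t10\t1\tg1\tp1"),
             file.path(d, "genome.tsv"))
  expect_error(load_bundle(d), "not unique", class = "snapsets_validation_error")

  # transcript under two genes
  writeLines(c(hdr,
               "A\tg1\tn\tchr1\t1\t10\t1\tt1\t",
               "A\tg2\tn\tchr1\t1\t10\t1\tt1\t"),
             file.path(d, "genome.tsv"))
  expect_error(load_bundle(d), "more than one gene",
               class = "snapsets_validation_error")

  # two proteins on one transcript
  writeLines(c(hdr,
               "A\tg1\tn\tchr1\t1\t10\t1\tt1\tp1",
               "A\tg1\tn\tchr1\t1\t10\t1\tt1\tp2"),
             file.path(d, "genome.tsv"))
  expect_error(load_bundle(d), "more than one protein",
               class = "snapsets_validation_error")

  # start > end
  writeLines(c(hdr, "A\tg1\tn\tchr1\t50\t10\t1\tt1\tp1"),
             file.path(d, "genome.tsv"))
  expect_error(load_bundle(d), "start > end", class = "snapsets_validation_error")

  # malformed EC
  writeLines(c(hdr, "A\tg1\tn\tchr1\t1\t10\t1\tt1\tp1"),
             file.path(d, "genome.tsv"))
  writeLines(c("protein_id\tec_number", "p1\t1.2.3"), file.path(d, "ec.tsv"))
  expect_error(load_bundle(d), "malformed EC", class = "snapsets_validation_error")
  unlink(file.path(d, "ec.tsv"))

  # interaction endpoint missing from the genome
  writeLines(c("protein_a\tprotein_b\tscore", "p1\tpX\t500"),
             file.path(d, "interactions.tsv"))
  expect_error(load_bundle(d), "pX", class = "snapsets_validation_error")
})

test_that("bundles without optional layers load, and modules error lazily", {
  d <- tempfile(); dir.create(d)
  writeLines(c("species\tgene_id\tgene_name\tchromosome\tstart\tend\tstrand\ttranscript_id\tprotein_id",
               "A\tg1\tn\tchr1\t1\t10\t1\tt1\tp1"),
             file.path(d, "genome.tsv"))
  writeLines("protein_a\tprotein_b\tscore", file.path(d, "interactions.tsv"))
  b <- load_bundle(d)
  expect_s3_class(b, "ref_bundle")
  es <- es_add(entity_set("A"), b$species$A$genome, "g1")
  expect_error(go_enrich(es, b), "no ontology loaded",
               class = "snapsets_lookup_error")
  expect_error(classify_pathway("pw1", es, b), "no pathways",
               class = "snapsets_lookup_error")
})

test_that("annotation propagation follows the true-path rule on chains and diamonds", {
  # chain R <- A <- B, protein u annotated at the leaf only
  dag <- snapsets:::toy_dag(c("B\tA", "A\tR"))
  direct <- tibble::tibble(protein_id = "u", term_id = "B")
  prop <- propagate_annotations(dag, direct)
  expect_equal(prop, list(A = "u", B = "u", R = "u"))

  # diamond: one protein at the bottom counts once at the root
  dag2 <- snapsets:::toy_dag(c("C\tA", "C\tB", "A\tR", "B\tR"))
  prop2 <- propagate_annotations(dag2, tibble::tibble(protein_id = "u",
                                                      term_id = "C"))
  expect_equal(prop2$A, "u")
  expect_equal(prop2$B, "u")
  expect_equal(prop2$R, "u")
})

test_that("propagation agrees with the boolean-reachability oracle on random DAGs", {
  for (seed in c(7L, 8L, 9L, 10L)) {
    dag <- random_dag(n_terms = sample(10:30, 1L), seed = seed)
    direct <- random_annotations(dag, n_proteins = 15L, seed = seed + 100L)
    expect_identical(propagate_annotations(dag, direct),
                     propagation_oracle(dag, direct))
  }
})

test_that("propagation is monotone in the direct annotations", {
  dag <- random_dag(20L, seed = 5L)
  direct <- random_annotations(dag, 10L, seed = 6L)
  prop <- propagate_annotations(dag, direct)
  more <- dplyr::bind_rows(direct,
                           tibble::tibble(protein_id = "uZZ",
                                          term_id = dag$terms$term_id[17L]))
  prop2 <- propagate_annotations(dag, more)
  for (t in dag$terms$term_id) {
    expect_true(all(prop[[t]] %in% prop2[[t]]))
  }
})

test_that("cyclic ontologies are rejected with a cycle listed", {
  terms <- tibble::tibble(term_id = c("X", "Y"), name = "", namespace = "")
  edges <- tibble::tibble(child = c("X", "Y"), parent = c("Y", "X"),
                          relation = "is_a")
  err <- expect_error(snapsets:::new_go_dag(terms, edges),
                      class = "snapsets_validation_error")
  expect_match(conditionMessage(err), "cyclic")
  expect_match(conditionMessage(err), "->")
})

test_that("OBO and GAF readers honor the documented conventions", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: T:1", "name: root", "namespace: biological_process",
               "",
               "[Term]", "id: T:2", "name: mid", "namespace: biological_process",
               "is_a: T:1 ! root",
               "relationship: part_of T:1",
               "relationship: regulates T:1",
               "",
               "[Term]", "id: T:3", "name: gone", "is_obsolete: true",
               "",
               "[Typedef]", "id: part_of"), obo)
  expect_warning(dag <- snapsets:::parse_obo(obo), "regulates")
  expect_setequal(dag$terms$term_id, c("T:1", "T:2"))
  expect_setequal(dag$edges$relation, c("is_a", "part_of"))
  expect_equal(dag$roots, "T:1")

  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "p1", "sym", "", "T:1", "ref", "IEA", "", "P",
                     "", "", "protein", "taxon:1", "20240101", "DB", "", "",
                     sep = "\t"),
               paste("DB", "p2", "sym", "NOT", "T:1", "ref", "IEA", "", "P",
                     "", "", "protein", "taxon:1", "20240101", "DB", "", "",
                     sep = "\t"),
               paste("DB", "p3", "sym", "NOT|contributes_to", "T:2", "ref",
                     "IEA", "", "P", "", "", "protein", "taxon:1", "20240101",
                     "DB", "", "", sep = "\t")), gaf)
  tab <- snapsets:::parse_gaf(gaf)
  expect_equal(tab$protein_id, "p1")  # NOT-qualified rows skipped
  expect_equal(tab$term_id, "T:1")
})

test_that("region queries use 1-based closed intervals and agree with a scan oracle", {
  gm <- fig1_bundle_loaded()$species$A$genome
  expect_equal(genes_in_region(gm, "chr1", 150, 160), "g1")   # containment
  expect_equal(genes_in_region(gm, "chr1", 200, 299), "g1")   # single-base overlap
  expect_equal(genes_in_region(gm, "chr1", 201, 299), character())
  expect_equal(genes_in_region(gm, "chrUnknown", 1, 10), character())
  expect_error(genes_in_region(gm, "chr1", 10, 1),
               class = "snapsets_validation_error")

  sgm <- synth_bundle()$species$spA$genome
  set.seed(11)
  for (i in seq_len(1000L)) {
    chrom <- sample(c(unique(sgm$genes$chromosome), "chrX"), 1L)
    qs <- sample(1:1000000L, 1L)
    qe <- qs + sample(0:50000L, 1L)
    expect_identical(genes_in_region(sgm, chrom, qs, qe),
                     region_oracle(sgm$genes, chrom, qs, qe))
  }
})
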