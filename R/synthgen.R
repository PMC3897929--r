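# Deterministic generators for complete reference bundles, plus the constant
# two-species worked-example bundle used throughout the documentation and
# tests. Only relational structure matters here; coordinates and sequences
# are placeholders.

#' Describe a synthetic reference bundle
#'
#' Collects the knobs of the synthetic-bundle generator. The defaults
#' describe a small but fully featured study system: two species of 60 genes
#' each, a geometric number of transcripts per gene (mean 1.5) with 90% of
#' transcripts coding, a single-rooted GO DAG of 40 terms with up to two
#' parents per term, 60% of proteins carrying 1–3 direct annotations, a
#' sparse interaction graph (3% edge probability), and orthology covering
#' 60% of genes with occasional two-gene fan-out. The same spec and seed
#' always produce byte-identical bundle files.
#'
#' @param seed Integer seed; the generator derives one independent stream per
#'   file type from it, so adding a file type never perturbs existing files.
#' @param n_species,genes_per_species Bundle dimensions.
#' @param tx_mean Mean transcripts per gene (geometric, support >= 1).
#' @param protein_prob Probability a transcript codes for a protein.
#' @param go_terms,go_roots,max_parents,part_of_prob GO DAG shape; parents
#'   are drawn only from earlier-indexed terms, so the DAG is acyclic by
#'   construction.
#' @param annotation_density Fraction of proteins with direct annotations.
#' @param interaction_edge_prob Per-pair interaction probability.
#' @param ortholog_fraction Fraction of genes with at least one ortholog in
#'   the next species.
#' @param ortholog_fanout_prob Probability a mapped gene maps to two target
#'   genes (ignored when `ortholog_one_to_one`).
#' @param ortholog_one_to_one If `TRUE`, orthology is a strict one-to-one
#'   injection (used by round-trip checks).
#' @param n_mirna,n_disease,n_drug Association keys per kind.
#' @param n_ec,n_pathways Enzyme and pathway counts.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(seed = 1L,
                        n_species = 2L,
                        genes_per_species = 60L,
                        tx_mean = 1.5,
                        protein_prob = 0.9,
                        go_terms = 40L,
                        go_roots = 1L,
                        max_parents = 2L,
                        part_of_prob = 0.2,
                        annotation_density = 0.6,
                        interaction_edge_prob = 0.03,
                        ortholog_fraction = 0.6,
                        ortholog_fanout_prob = 0.1,
                        ortholog_one_to_one = FALSE,
                        n_mirna = 6L,
                        n_disease = 6L,
                        n_drug = 6L,
                        n_ec = 12L,
                        n_pathways = 4L) {
  spec <- list(seed = as.integer(seed), n_species = as.integer(n_species),
               genes_per_species = as.integer(genes_per_species),
               tx_mean = tx_mean, protein_prob = protein_prob,
               go_terms = as.integer(go_terms), go_roots = as.integer(go_roots),
               max_parents = as.integer(max_parents), part_of_prob = part_of_prob,
               annotation_density = annotation_density,
               interaction_edge_prob = interaction_edge_prob,
               ortholog_fraction = ortholog_fraction,
               ortholog_fanout_prob = ortholog_fanout_prob,
               ortholog_one_to_one = isTRUE(ortholog_one_to_one),
               n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
               n_drug = as.integer(n_drug), n_ec = as.integer(n_ec),
               n_pathways = as.integer(n_pathways))
  probs <- c(spec$protein_prob, spec$part_of_prob, spec$annotation_density,
             spec$interaction_edge_prob, spec$ortholog_fraction,
             spec$ortholog_fanout_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("all probabilities must lie in [0, 1]")
  }
  if (spec$tx_mean < 1) stop_validation("tx_mean must be >= 1")
  if (spec$go_roots > spec$go_terms) {
    stop_validation("more ontology roots (%d) than terms (%d)",
                    spec$go_roots, spec$go_terms)
  }
  if (spec$n_species < 1L || spec$genes_per_species < 1L) {
    stop_validation("need at least one species and one gene")
  }
  structure(spec, class = "bundle_spec")
}

# independent stream per file type: re-seed from the spec seed plus a fixed
# per-file offset, so adding a file type never perturbs existing files
with_stream <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed * 101L + offset)
  force(code)
}

#' Generate a synthetic reference bundle on disk
#'
#' Writes every bundle file described in [load_bundle()] according to a
#' [bundle_spec()]. Generation is deterministic: the same spec (including
#' seed) yields byte-identical files. The output always passes
#' `load_bundle()` validation.
#'
#' @param spec A [bundle_spec()].
#' @param dir Output directory (created if needed).
#' @return The bundle directory path, invisibly usable with [load_bundle()].
#' @export
#' @examples
#' dir <- generate_bundle(bundle_spec(seed = 42), tempfile())
#' bundle <- load_bundle(dir)
generate_bundle <- function(spec, dir) {
  if (!inherits(spec, "bundle_spec")) spec <- do.call(bundle_spec, as.list(spec))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp_names <- paste0("sp", LETTERS[seq_len(spec$n_species)])

  # ---- genome.tsv
  genome_rows <- with_stream(spec, 1L, {
    rows <- character()
    for (s in sp_names) {
      for (i in seq_len(spec$genes_per_species)) {
        gid <- sprintf("%s_g%03d", s, i)
        chrom <- paste0("chr", sample(1:3, 1L))
        start <- sample(1:900000L, 1L)
        end <- start + sample(500:20000L, 1L)
        strand <- sample(c("1", "-1"), 1L)
        ntx <- 1L + rgeom(1L, prob = 1 / spec$tx_mean)
        for (k in seq_len(ntx)) {
          tid <- sprintf("%s_t%d", gid, k)
          pid <- if (runif(1L) < spec$protein_prob) sprintf("%s_p%d", gid, k) else ""
          rows <- c(rows, paste(s, gid, paste0("name_", gid), chrom, start, end,
                                strand, tid, pid, sep = "\t"))
        }
      }
    }
    rows
  })
  write_atomic(c(paste(c("species", "gene_id", "gene_name", "chromosome",
                         "start", "end", "strand", "transcript_id",
                         "protein_id"), collapse = "\t"), genome_rows),
               file.path(dir, "genome.tsv"))

  gm <- load_genomes(file.path(dir, "genome.tsv"))
  proteins_by_sp <- lapply(gm, function(g) sort_ids(names(g$proteins)))
  genes_by_sp <- lapply(gm, function(g) sort_ids(g$genes$gene_id))

  # ---- go.obo
  terms <- sprintf("T:%07d", seq_len(spec$go_terms))
  obo <- with_stream(spec, 2L, {
    out <- c("format-version: 1.2", "ontology: synthetic-go")
    for (i in seq_along(terms)) {
      out <- c(out, "", "[Term]", paste0("id: ", terms[i]),
               paste0("name: synthetic process ", i),
               "namespace: biological_process")
      if (i > spec$go_roots) {
        npar <- sample(seq_len(min(spec$max_parents, i - 1L)), 1L)
        pars <- sample(seq_len(i - 1L), npar)
        for (p in pars) {
          if (runif(1L) < spec$part_of_prob) {
            out <- c(out, paste0("relationship: part_of ", terms[p]))
          } else {
            out <- c(out, paste0("is_a: ", terms[p]))
          }
        }
      }
      out
    }
    out
  })
  write_atomic(obo, file.path(dir, "go.obo"))

  # ---- annotations.gaf
  gaf <- with_stream(spec, 3L, {
    out <- c("!gaf-version: 2.1")
    for (s in sp_names) {
      for (p in proteins_by_sp[[s]]) {
        if (runif(1L) < spec$annotation_density) {
          k <- sample(1:3, 1L)
          for (t in sample(terms, k)) {
            out <- c(out, paste("SYN", p, p, "", t, "SYN:0001", "IEA", "",
                                "P", "", "", "protein", "taxon:0", "20240101",
                                "SYN", "", "", sep = "\t"))
          }
        }
      }
    }
    out
  })
  write_atomic(gaf, file.path(dir, "annotations.gaf"))

  # ---- interactions.tsv
  inter <- with_stream(spec, 4L, {
    rows <- character()
    for (s in sp_names) {
      pr <- proteins_by_sp[[s]]
      if (length(pr) < 2L) next
      pairs <- combn(pr, 2L)
      keep <- runif(ncol(pairs)) < spec$interaction_edge_prob
      if (any(keep)) {
        sc <- round(runif(sum(keep), 100, 1000))
        rows <- c(rows, paste(pairs[1L, keep], pairs[2L, keep], sc, sep = "\t"))
      }
    }
    rows
  })
  write_atomic(c("protein_a\tprotein_b\tscore", inter),
               file.path(dir, "interactions.tsv"))

  # ---- orthology.tsv (consecutive species pairs)
  orth <- with_stream(spec, 5L, {
    rows <- character()
    if (spec$n_species >= 2L) {
      for (i in seq_len(spec$n_species - 1L)) {
        sa <- sp_names[i]; sb <- sp_names[i + 1L]
        ga <- genes_by_sp[[sa]]; gb <- genes_by_sp[[sb]]
        n_map <- round(spec$ortholog_fraction * length(ga))
        src <- sample(ga, n_map)
        if (spec$ortholog_one_to_one) {
          tgt <- sample(gb, n_map)
          rows <- c(rows, paste(sa, src, sb, tgt, sep = "\t"))
        } else {
          for (g in src) {
            k <- if (runif(1L) < spec$ortholog_fanout_prob) 2L else 1L
            for (t in sample(gb, k)) {
              rows <- c(rows, paste(sa, g, sb, t, sep = "\t"))
            }
          }
        }
      }
    }
    rows
  })
  write_atomic(c("species_a\tgene_a\tspecies_b\tgene_b", orth),
               file.path(dir, "orthology.tsv"))

  # ---- association tables
  assoc_counts <- c(mirna = spec$n_mirna, disease = spec$n_disease,
                    drug = spec$n_drug)
  prefixes <- c(mirna = "miR-", disease = "OMIM:", drug = "DB")
  for (j in seq_along(assoc_counts)) {
    kind <- names(assoc_counts)[j]
    rows <- with_stream(spec, 5L + j, {
      out <- character()
      for (i in seq_len(assoc_counts[[kind]])) {
        key <- sprintf("%s%03d", prefixes[[kind]], i)
        s <- sample(sp_names, 1L)
        gpool <- genes_by_sp[[s]]
        genes <- sample(gpool, min(sample(1:8, 1L), length(gpool)))
        out <- c(out, paste(key, paste0(kind, " entry ", i), genes, sep = "\t"))
      }
      out
    })
    write_atomic(c("key_id\tkey_name\tgene_id", rows),
                 file.path(dir, paste0(kind, ".tsv")))
  }

  # ---- ec.tsv + pathways.tsv
  ec_state <- with_stream(spec, 9L, {
    ecs <- unique(sprintf("%d.%d.%d.%d", sample(1:6, spec$n_ec, TRUE),
                          sample(1:20, spec$n_ec, TRUE),
                          sample(1:20, spec$n_ec, TRUE),
                          sample(1:99, spec$n_ec, TRUE)))
    rows <- character()
    for (e in ecs) {
      s <- sample(sp_names, 1L)
      pr <- proteins_by_sp[[s]]
      if (length(pr) == 0L) next
      for (p in sample(pr, min(sample(1:4, 1L), length(pr)))) {
        rows <- c(rows, paste(p, e, sep = "\t"))
      }
    }
    pw_rows <- character()
    for (i in seq_len(spec$n_pathways)) {
      pid <- sprintf("pw%03d", i)
      nm <- paste0("synthetic pathway ", i)
      chosen <- sample(ecs, min(length(ecs), sample(2:5, 1L)))
      # one EC per pathway may be absent from every genome (tests status ABSENT)
      if (runif(1L) < 0.5) {
        chosen <- c(chosen, sprintf("7.%d.%d.%d", sample(1:9, 1L),
                                    sample(1:9, 1L), sample(1:99, 1L)))
      }
      pw_rows <- c(pw_rows, paste(pid, nm, chosen, sep = "\t"))
    }
    list(ec = rows, pw = pw_rows)
  })
  write_atomic(c("protein_id\tec_number", ec_state$ec), file.path(dir, "ec.tsv"))
  write_atomic(c("pathway_id\tpathway_name\tec_number", ec_state$pw),
               file.path(dir, "pathways.tsv"))

  invisible(dir)
}

# ---- the constant worked-example bundle ------------------------------------

FIG1_GENOME <- c(
  "species\tgene_id\tgene_name\tchromosome\tstart\tend\tstrand\ttranscript_id\tprotein_id",
  "A\tg1\tgene one\tchr1\t100\t200\t1\tt1_1\tp1_1",
  "A\tg1\tgene one\tchr1\t100\t200\t1\tt1_2\tp1_2",
  "A\tg2\tgene two\tchr1\t300\t400\t-1\tt2_1\tp2_1",
  "A\tg3\tgene three\tchr1\t500\t600\t1\tt3_1\tp3_1",
  "A\tg4\tgene four\tchr1\t700\t800\t1\tt4_1\tp4_1",
  "A\tg5\tgene five\tchr1\t900\t1000\t-1\tt5_1\tp5_1",
  "A\tg5\tgene five\tchr1\t900\t1000\t-1\tt5_2\tp5_2",
  "B\tg6\tgene six\tchr1\t100\t200\t1\tt6_1\tp6_1",
  "B\tg7\tgene seven\tchr1\t300\t400\t1\tt7_1\tp7_1",
  "B\tg8\tgene eight\tchr1\t500\t600\t-1\tt8_1\tp8_1",
  "B\tg9\tgene nine\tchr1\t700\t800\t1\tt9_1\tp9_1"
)

FIG1_INTERACTIONS <- c(
  "protein_a\tprotein_b\tscore",
  "p1_1\tp4_1\t900",
  "p1_2\tp5_1\t800",
  "p3_1\tp5_2\t700"
)

FIG1_ORTHOLOGY <- c(
  "species_a\tgene_a\tspecies_b\tgene_b",
  "A\tg1\tB\tg6",
  "A\tg2\tB\tg7"
)

FIG1_REPLAY <- c(
  "# worked-example replay script: one action per line, tab-separated",
  "container\tI\tA",
  "snapshot\ta\tI\t-",
  "add\ta\tgene\tg1,g2,g3",
  "snapshot\tb\tI\ta",
  "add\tb\tprotein\tp1_1,p4_1",
  "add\tb\ttranscript\tt1_2,t2_1",
  "minus\tb\tgene\tg3",
  "snapshot\tc\tI\ta",
  "extend\tc",
  "snapshot\td\tI\tc",
  "network_add\td\tc\t1",
  "container\tII\tB",
  "snapshot\te\tII\t-",
  "translate_add\te\td",
  "snapshot\tf\tII\te",
  "add\tf\tgene\tg8,g9",
  "minus\tf\tgene\tg7",
  "snapshot\tg\tI\t-",
  "translate_add\tg\tf"
)

#' Write the constant two-species worked-example bundle
#'
#' Species A has five genes (`g1`..`g5`) with seven transcripts and seven
#' proteins (`g1` and `g5` have two isoforms each); species B has four
#' single-isoform genes (`g6`..`g9`). Three interaction edges connect
#' `p1_1–p4_1`, `p1_2–p5_1` and `p3_1–p5_2` (so `p2_1` is deliberately
#' edgeless), and the orthology maps `g1<->g6` and `g2<->g7`. A replay
#' script (`figure1.replay`) encoding the full worked analysis — upload,
#' branch, transitive additions, extension, network expansion, cross-species
#' translation and back-translation — is written alongside the data files.
#'
#' @param dir Output directory (created if needed).
#' @return The bundle directory path.
#' @export
#' @examples
#' dir <- figure1_bundle(tempfile())
#' list.files(dir)
figure1_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(FIG1_GENOME, file.path(dir, "genome.tsv"))
  write_atomic(FIG1_INTERACTIONS, file.path(dir, "interactions.tsv"))
  write_atomic(FIG1_ORTHOLOGY, file.path(dir, "orthology.tsv"))
  write_atomic(FIG1_REPLAY, file.path(dir, "figure1.replay"))
  invisible(dir)
}
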