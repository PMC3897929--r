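# Reference bundle: genome models, GO DAG + annotations, interactions,
# orthology, association tables, pathway/EC maps — all from plain-text files.

EC_PATTERN <- "^([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Load a reference bundle from a directory of text files
#'
#' A bundle directory holds, for one or more species, the genome model and
#' the optional annotation layers every analysis module draws on:
#'
#' * `genome.tsv` (required) — columns `species`, `gene_id`, `gene_name`,
#'   `chromosome`, `start`, `end`, `strand`, `transcript_id`, `protein_id`;
#'   one row per gene–transcript pair, transcript/protein cells may be empty.
#' * `go.obo` (OBO 1.2) and `annotations.gaf` (GAF 2.x).
#' * `interactions.tsv` — `protein_a`, `protein_b`, `score` (score optional,
#'   0–1000).
#' * `orthology.tsv` — `species_a`, `gene_a`, `species_b`, `gene_b`.
#' * `mirna.tsv` / `disease.tsv` / `drug.tsv` — `key_id`, `key_name`,
#'   `gene_id`.
#' * `ec.tsv` — `protein_id`, `ec_number`; `pathways.tsv` — `pathway_id`,
#'   `pathway_name`, `ec_number`.
#'
#' All files are tab-separated UTF-8 with one header row; lines starting with
#' `#` are ignored. Every cross-reference is validated at load time: a
#' dangling transcript/protein/gene reference, a duplicate identifier or a
#' malformed EC number is a load error naming the file, line and identifier.
#' Entity identifiers must be unique across the whole bundle (Ensembl-style
#' identifiers are), which lets files without a species column resolve their
#' identifiers through the genome models. Loading is a pure function of the
#' files: re-loading the same directory yields an identical bundle.
#'
#' @param dir Path to the bundle directory.
#' @param min_score Optional interaction score threshold; edges with a score
#'   below it (or with no score) are dropped at load time. Default `NULL`
#'   keeps every edge.
#' @return A `ref_bundle`: per-species genome models, direct GO annotations,
#'   interaction edges, association tables and EC assignments, plus the
#'   bundle-wide GO DAG, orthology pairs and pathway map.
#' @export
#' @examples
#' dir <- figure1_bundle(tempfile())
#' bundle <- load_bundle(dir)
#' names(bundle$species)
load_bundle <- function(dir, min_score = NULL) {
  if (!dir.exists(dir)) {
    stop_lookup("bundle directory not found: %s", dir)
  }
  genome_path <- file.path(dir, "genome.tsv")
  if (!file.exists(genome_path)) {
    stop_validation("genome.tsv: required file missing from %s", dir)
  }
  genomes <- load_genomes(genome_path)

  index <- build_entity_index(genomes)

  godag <- NULL
  obo_path <- file.path(dir, "go.obo")
  if (file.exists(obo_path)) {
    godag <- parse_obo(obo_path)
  }

  bundle <- structure(
    list(
      dir = normalizePath(dir),
      species = lapply(genomes, function(g) {
        list(genome = g, annotations = NULL, interactions = NULL,
             assoc = list(), ec = NULL)
      }),
      godag = godag,
      orthology = NULL,
      pathways = NULL,
      index = index
    ),
    class = "ref_bundle"
  )

  gaf <- parse_gaf(file.path(dir, "annotations.gaf"))
  if (nrow(gaf) > 0L) {
    if (is.null(godag)) {
      stop_validation("annotations.gaf: annotations present but no go.obo in bundle")
    }
    unknown_terms <- setdiff(unique(gaf$term_id), godag$terms$term_id)
    if (length(unknown_terms) > 0L) {
      warn(sprintf("annotations.gaf: dropping %d annotation(s) to unknown term(s): %s",
                   sum(gaf$term_id %in% unknown_terms),
                   paste(head(unknown_terms, 3L), collapse = ", ")))
      gaf <- gaf[!gaf$term_id %in% unknown_terms, ]
    }
    sp <- resolve_species(index, gaf$protein_id, "protein", "annotations.gaf", gaf$.line)
    for (s in unique(sp)) {
      bundle$species[[s]]$annotations <-
        distinct(gaf[sp == s, c("protein_id", "term_id")])
    }
  }

  inter <- read_tsv_table(file.path(dir, "interactions.tsv"),
                          c("protein_a", "protein_b", "score"))
  if (nrow(inter) > 0L) {
    sp_a <- resolve_species(index, inter$protein_a, "protein", "interactions.tsv", inter$.line)
    sp_b <- resolve_species(index, inter$protein_b, "protein", "interactions.tsv", inter$.line)
    bad <- which(sp_a != sp_b)
    if (length(bad) > 0L) {
      stop_validation("interactions.tsv line %d: endpoints %s and %s belong to different species",
                      inter$.line[bad[1L]], inter$protein_a[bad[1L]], inter$protein_b[bad[1L]])
    }
    loops <- which(inter$protein_a == inter$protein_b)
    if (length(loops) > 0L) {
      stop_validation("interactions.tsv line %d: self-interaction of %s",
                      inter$.line[loops[1L]], inter$protein_a[loops[1L]])
    }
    score <- suppressWarnings(as.numeric(inter$score))
    bad_score <- which(!is.na(score) & (score < 0 | score > 1000))
    if (length(bad_score) > 0L) {
      stop_validation("interactions.tsv line %d: score %s outside [0, 1000]",
                      inter$.line[bad_score[1L]], inter$score[bad_score[1L]])
    }
    edges <- tibble(protein_a = pmin(inter$protein_a, inter$protein_b),
                    protein_b = pmax(inter$protein_a, inter$protein_b),
                    score = score, species = sp_a)
    edges <- distinct(edges, .data$protein_a, .data$protein_b, .keep_all = TRUE)
    if (!is.null(min_score)) {
      edges <- edges[!is.na(edges$score) & edges$score >= min_score, ]
    }
    for (s in unique(edges$species)) {
      bundle$species[[s]]$interactions <-
        edges[edges$species == s, c("protein_a", "protein_b", "score")]
    }
  }

  orth <- read_tsv_table(file.path(dir, "orthology.tsv"),
                         c("species_a", "gene_a", "species_b", "gene_b"))
  if (nrow(orth) > 0L) {
    for (side in c("a", "b")) {
      sp <- orth[[paste0("species_", side)]]
      gn <- orth[[paste0("gene_", side)]]
      unknown_sp <- which(!sp %in% names(genomes))
      if (length(unknown_sp) > 0L) {
        stop_validation("orthology.tsv line %d: unknown species %s",
                        orth$.line[unknown_sp[1L]], sp[unknown_sp[1L]])
      }
      for (i in seq_along(gn)) {
        if (!gn[i] %in% genomes[[sp[i]]]$genes$gene_id) {
          stop_validation("orthology.tsv line %d: gene %s not in genome of %s",
                          orth$.line[i], gn[i], sp[i])
        }
      }
    }
    bundle$orthology <- distinct(orth[, c("species_a", "gene_a", "species_b", "gene_b")])
  }

  for (kind in c("mirna", "disease", "drug")) {
    tab <- read_tsv_table(file.path(dir, paste0(kind, ".tsv")),
                          c("key_id", "key_name", "gene_id"))
    if (nrow(tab) == 0L) next
    sp <- resolve_species(index, tab$gene_id, "gene", paste0(kind, ".tsv"), tab$.line)
    nm <- tapply(tab$key_name, tab$key_id, function(x) unique(x))
    multi_name <- names(nm)[lengths(nm) > 1L]
    if (length(multi_name) > 0L) {
      stop_validation("%s.tsv: key %s has conflicting names", kind, multi_name[1L])
    }
    for (s in unique(sp)) {
      bundle$species[[s]]$assoc[[kind]] <-
        distinct(tab[sp == s, c("key_id", "key_name", "gene_id")])
    }
  }

  ec <- read_tsv_table(file.path(dir, "ec.tsv"), c("protein_id", "ec_number"))
  if (nrow(ec) > 0L) {
    bad <- which(!grepl(EC_PATTERN, ec$ec_number))
    if (length(bad) > 0L) {
      stop_validation("ec.tsv line %d: malformed EC number '%s'",
                      ec$.line[bad[1L]], ec$ec_number[bad[1L]])
    }
    sp <- resolve_species(index, ec$protein_id, "protein", "ec.tsv", ec$.line)
    for (s in unique(sp)) {
      bundle$species[[s]]$ec <- distinct(ec[sp == s, c("protein_id", "ec_number")])
    }
  }

  pw <- read_tsv_table(file.path(dir, "pathways.tsv"),
                       c("pathway_id", "pathway_name", "ec_number"))
  if (nrow(pw) > 0L) {
    bad <- which(!grepl(EC_PATTERN, pw$ec_number))
    if (length(bad) > 0L) {
      stop_validation("pathways.tsv line %d: malformed EC number '%s'",
                      pw$.line[bad[1L]], pw$ec_number[bad[1L]])
    }
    bundle$pathways <- distinct(pw[, c("pathway_id", "pathway_name", "ec_number")])
  }

  bundle
}

load_genomes <- function(path) {
  cols <- c("species", "gene_id", "gene_name", "chromosome", "start", "end",
            "strand", "transcript_id", "protein_id")
  tab <- read_tsv_table(path, cols)
  if (nrow(tab) == 0L) {
    stop_validation("genome.tsv: no records")
  }
  fname <- basename(path)

  # a protein cell requires a transcript cell on the same row
  orphan <- which(nzchar(tab$protein_id) & !nzchar(tab$transcript_id))
  if (length(orphan) > 0L) {
    stop_validation("%s line %d: protein %s has no transcript reference",
                    fname, tab$.line[orphan[1L]], tab$protein_id[orphan[1L]])
  }

  genomes <- list()
  for (s in unique(tab$species)) {
    rows <- tab[tab$species == s, ]
    gtab <- distinct(rows[, c("gene_id", "gene_name", "chromosome",
                              "start", "end", "strand", ".line")],
                     .data$gene_id, .keep_all = TRUE)
    # a gene_id must describe one gene: conflicting coordinate rows are an error
    full <- distinct(rows[, c("gene_id", "gene_name", "chromosome", "start", "end", "strand")])
    dup_gene <- full$gene_id[duplicated(full$gene_id)]
    if (length(dup_gene) > 0L) {
      stop_validation("%s: gene %s defined twice with different attributes",
                      fname, dup_gene[1L])
    }
    start <- suppressWarnings(as.integer(gtab$start))
    end <- suppressWarnings(as.integer(gtab$end))
    if (anyNA(start) || anyNA(end)) {
      bad <- which(is.na(start) | is.na(end))[1L]
      stop_validation("%s line %d: non-integer coordinates for gene %s",
                      fname, gtab$.line[bad], gtab$gene_id[bad])
    }
    rev <- which(start > end)
    if (length(rev) > 0L) {
      stop_validation("%s line %d: gene %s has start > end",
                      fname, gtab$.line[rev[1L]], gtab$gene_id[rev[1L]])
    }
    strand <- ifelse(gtab$strand %in% c("1", "+1", "+"), 1L,
                     ifelse(gtab$strand %in% c("-1", "-"), -1L, NA_integer_))
    if (anyNA(strand)) {
      bad <- which(is.na(strand))[1L]
      stop_validation("%s line %d: strand must be +1 or -1, got '%s'",
                      fname, gtab$.line[bad], gtab$strand[bad])
    }

    trows <- rows[nzchar(rows$transcript_id), ]
    tmap <- distinct(trows[, c("transcript_id", "gene_id", ".line")],
                     .data$transcript_id, .keep_all = TRUE)
    tfull <- distinct(trows[, c("transcript_id", "gene_id")])
    dup_tx <- tfull$transcript_id[duplicated(tfull$transcript_id)]
    if (length(dup_tx) > 0L) {
      stop_validation("%s: transcript %s assigned to more than one gene",
                      fname, dup_tx[1L])
    }

    prows <- rows[nzchar(rows$protein_id), ]
    pmap <- distinct(prows[, c("protein_id", "transcript_id", ".line")],
                     .data$protein_id, .keep_all = TRUE)
    pfull <- distinct(prows[, c("protein_id", "transcript_id")])
    dup_p <- pfull$protein_id[duplicated(pfull$protein_id)]
    if (length(dup_p) > 0L) {
      stop_validation("%s: protein %s assigned to more than one transcript",
                      fname, dup_p[1L])
    }
    # at most one protein per transcript
    dup_ptx <- pmap$transcript_id[duplicated(pmap$transcript_id)]
    if (length(dup_ptx) > 0L) {
      stop_validation("%s: transcript %s has more than one protein",
                      fname, dup_ptx[1L])
    }

    genomes[[s]] <- new_genome_model(
      species = s,
      genes = tibble(gene_id = gtab$gene_id, gene_name = gtab$gene_name,
                     chromosome = gtab$chromosome, start = start, end = end,
                     strand = strand),
      transcripts = setNames(tmap$gene_id, tmap$transcript_id),
      proteins = setNames(pmap$transcript_id, pmap$protein_id)
    )
  }
  genomes
}

new_genome_model <- function(species, genes, transcripts, proteins) {
  structure(
    list(
      species = species,
      genes = genes,
      transcripts = transcripts,  # transcript_id -> gene_id
      proteins = proteins,        # protein_id -> transcript_id
      tx_by_gene = split(names(transcripts), unname(transcripts)),
      prot_by_tx = setNames(names(proteins), unname(proteins))
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> species %s: %d genes, %d transcripts, %d proteins\n",
              x$species, nrow(x$genes), length(x$transcripts), length(x$proteins)))
  invisible(x)
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat(sprintf("<ref_bundle> %d species (%s); ontology: %s; orthology pairs: %d\n",
              length(x$species), paste(names(x$species), collapse = ", "),
              if (is.null(x$godag)) "none" else
                sprintf("%d terms", nrow(x$godag$terms)),
              if (is.null(x$orthology)) 0L else nrow(x$orthology)))
  invisible(x)
}

# id -> (species, level) lookup over all genome models; duplicate ids across
# species or levels are rejected so species-less files stay resolvable
build_entity_index <- function(genomes) {
  parts <- lapply(genomes, function(g) {
    tibble(
      id = c(g$genes$gene_id, names(g$transcripts), names(g$proteins)),
      species = g$species,
      level = c(rep("gene", nrow(g$genes)),
                rep("transcript", length(g$transcripts)),
                rep("protein", length(g$proteins)))
    )
  })
  index <- bind_rows(parts)
  dup <- index$id[duplicated(index$id)]
  if (length(dup) > 0L) {
    stop_validation("genome.tsv: identifier %s is not unique across the bundle", dup[1L])
  }
  index
}

resolve_species <- function(index, ids, level, fname, lines) {
  pos <- match(ids, index$id)
  bad <- which(is.na(pos) | index$level[pos] != level)
  if (length(bad) > 0L) {
    stop_validation("%s line %d: unknown %s identifier '%s'",
                    fname, lines[bad[1L]], level, ids[bad[1L]])
  }
  index$species[pos]
}

species_data <- function(bundle, species) {
  if (!species %in% names(bundle$species)) {
    stop_lookup("unknown species '%s' (bundle has: %s)", species,
                paste(names(bundle$species), collapse = ", "))
  }
  bundle$species[[species]]
}

# ---- OBO / GAF parsing ------------------------------------------------------

# Minimal OBO 1.2 reader: [Term] stanzas, id/name/namespace/is_a/
# relationship part_of; obsolete terms and other relations are skipped
# (other relations with a one-time warning).
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) {
    stop_validation("%s: no [Term] stanzas found", basename(path))
  }
  stanza_bounds <- c(which(startsWith(lines, "[")), length(lines) + 1L)

  terms <- list()
  edges <- list()
  skipped_rel <- character()
  for (st in term_starts) {
    nxt <- min(stanza_bounds[stanza_bounds > st])
    block <- lines[(st + 1L):(nxt - 1L)]
    fields <- block[grepl(":", block, fixed = TRUE)]
    key <- sub(":.*$", "", fields)
    val <- trimws(sub("^[^:]+:", "", fields))
    val <- sub("!.*$", "", val)  # trailing comments
    val <- trimws(val)
    if (any(key == "is_obsolete" & val == "true")) next
    id <- val[key == "id"][1L]
    if (is.na(id)) next
    nm <- val[key == "name"][1L]
    ns <- val[key == "namespace"][1L]
    terms[[id]] <- c(name = if (is.na(nm)) "" else nm,
                     namespace = if (is.na(ns)) "" else ns)
    for (p in val[key == "is_a"]) {
      edges[[length(edges) + 1L]] <- c(id, p, "is_a")
    }
    for (r in val[key == "relationship"]) {
      bits <- strsplit(r, "[ \t]+")[[1L]]
      if (length(bits) >= 2L && bits[1L] == "part_of") {
        edges[[length(edges) + 1L]] <- c(id, bits[2L], "part_of")
      } else if (length(bits) >= 1L) {
        skipped_rel <- c(skipped_rel, bits[1L])
      }
    }
  }
  if (length(skipped_rel) > 0L) {
    warn(sprintf("%s: ignored relationship type(s): %s", basename(path),
                 paste(unique(skipped_rel), collapse = ", ")))
  }
  term_tbl <- tibble(
    term_id = names(terms),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace")
  )
  edge_tbl <- if (length(edges) > 0L) {
    m <- do.call(rbind, edges)
    tibble(child = m[, 1L], parent = m[, 2L], relation = m[, 3L])
  } else {
    tibble(child = character(), parent = character(), relation = character())
  }
  new_go_dag(term_tbl, edge_tbl, source = basename(path))
}

new_go_dag <- function(terms, edges, source = "go.obo") {
  dangling <- setdiff(edges$parent, terms$term_id)
  if (length(dangling) > 0L) {
    stop_validation("%s: parent term %s referenced but not defined",
                    source, dangling[1L])
  }
  edges <- distinct(edges)
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms$term_id)
    if (!igraph::is_dag(g)) {
      cyc <- find_dag_cycle(edges)
      stop_validation("%s: ontology graph is cyclic: %s", source,
                      paste(cyc, collapse = " -> "))
    }
  }
  parents <- split(edges$parent, edges$child)
  relations <- split(edges$relation, edges$child)
  children <- split(edges$child, edges$parent)
  roots <- sort_ids(setdiff(terms$term_id, edges$child))
  structure(
    list(terms = terms, edges = edges, parents = parents,
         parent_relations = relations, children = children, roots = roots),
    class = "go_dag"
  )
}

# report one directed cycle (simple DFS with a stack)
find_dag_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- state[[v]] %||% 0L
    if (st == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == 2L) return()
    state[[v]] <- 1L
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    state[[v]] <- 2L
  }
  for (v in names(adj)) visit(v)
  found %||% character()
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges, %d root(s)\n",
              nrow(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

dag_parents <- function(dag, term, relations = c("is_a", "part_of")) {
  p <- dag$parents[[term]] %||% character()
  r <- dag$parent_relations[[term]] %||% character()
  sort_ids(p[r %in% relations])
}

# GAF 2.x: tab-separated, '!' comment lines; column 2 = DB object ID
# (read as protein id), column 4 = qualifier, column 5 = GO id.
# Rows whose qualifier contains NOT are skipped.
parse_gaf <- function(path) {
  if (!file.exists(path)) {
    return(tibble(protein_id = character(), term_id = character(), .line = integer()))
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  kept <- which(!startsWith(raw, "!") & nzchar(raw))
  if (length(kept) == 0L) {
    return(tibble(protein_id = character(), term_id = character(), .line = integer()))
  }
  parts <- strsplit(raw[kept], "\t", fixed = TRUE)
  short <- which(lengths(parts) < 5L)
  if (length(short) > 0L) {
    stop_validation("%s line %d: fewer than 5 columns", basename(path), kept[short[1L]])
  }
  protein <- vapply(parts, `[[`, "", 2L)
  qualifier <- vapply(parts, `[[`, "", 4L)
  term <- vapply(parts, `[[`, "", 5L)
  keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
  tibble(protein_id = protein[keep], term_id = term[keep], .line = kept[keep])
}

# ---- annotation propagation -------------------------------------------------

#' Propagate direct GO annotations up the ontology (true-path rule)
#'
#' An annotation to a term implies annotation to all of the term's ancestors.
#' This computes, for every term, the set of proteins annotated to the term
#' or to any descendant: `propagated(t) = direct(t) U union over children c of
#' propagated(c)`, traversing `is_a` and `part_of` edges by default.
#'
#' @param dag A `go_dag`.
#' @param direct Tibble of direct annotations with columns `protein_id`,
#'   `term_id` (as held in `bundle$species[[s]]$annotations`).
#' @param relations Edge types to traverse (default both `is_a` and
#'   `part_of`).
#' @return Named list mapping each term id to the sorted character vector of
#'   proteins in its subtree.
#' @export
propagate_annotations <- function(dag, direct,
                                  relations = c("is_a", "part_of")) {
  if (!inherits(dag, "go_dag")) stop_validation("`dag` must be a go_dag")
  edges <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  terms <- dag$terms$term_id
  prop <- setNames(vector("list", length(terms)), terms)
  if (!is.null(direct) && nrow(direct) > 0L) {
    d <- split(direct$protein_id, direct$term_id)
    prop[names(d)] <- lapply(d, unique)
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      cyc <- find_dag_cycle(edges)
      stop_validation("ontology graph is cyclic: %s", paste(cyc, collapse = " -> "))
    }
    order <- names(igraph::topo_sort(g, mode = "out"))
    parents_of <- split(edges$parent, edges$child)
    for (v in order) {  # children come before parents along child->parent edges
      for (p in parents_of[[v]] %||% character()) {
        # keep empty results as character(0): assigning NULL would drop the term
        prop[[p]] <- union(prop[[p]] %||% character(), prop[[v]] %||% character())
      }
    }
  }
  lapply(prop, function(x) sort_ids(x %||% character()))
}

# cached propagated table for a species in a bundle
bundle_propagated <- function(bundle, species, relations = c("is_a", "part_of")) {
  sd <- species_data(bundle, species)
  if (is.null(bundle$godag)) {
    stop_lookup("no ontology loaded in this bundle")
  }
  if (is.null(sd$annotations) || nrow(sd$annotations) == 0L) {
    stop_lookup("no GO annotations loaded for species '%s'", species)
  }
  propagate_annotations(bundle$godag, sd$annotations, relations)
}

# ---- genome region queries --------------------------------------------------

#' Genes overlapping a genomic region
#'
#' Coordinates are 1-based, fully closed intervals (Ensembl convention); a
#' gene is returned when its interval overlaps the query by at least one
#' base, on either strand. An unknown chromosome yields an empty set rather
#' than an error, so bundles without coordinates still support the
#' non-genomic modules.
#'
#' @param genome A `genome_model`.
#' @param chromosome Chromosome name.
#' @param start,end Query interval, `start <= end`.
#' @return Sorted character vector of gene ids.
#' @export
genes_in_region <- function(genome, chromosome, start, end) {
  if (!inherits(genome, "genome_model")) stop_validation("`genome` must be a genome_model")
  if (start > end) stop_validation("region start (%s) exceeds end (%s)", start, end)
  g <- genome$genes
  hit <- g$chromosome == chromosome & g$start <= end & g$end >= start
  sort_ids(g$gene_id[hit])
}
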