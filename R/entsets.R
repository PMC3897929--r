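# Species-bound entity sets with the transitive-consistency rule:
# a member protein forces its transcript into the set, a member transcript
# forces its gene. The reverse never happens implicitly.

LEVELS <- c("gene", "transcript", "protein")

check_level <- function(level) {
  if (length(level) != 1L || !level %in% LEVELS) {
    stop_validation("level must be one of %s", paste(LEVELS, collapse = ", "))
  }
  level
}

#' Create an (empty) species-bound entity set
#'
#' An entity set holds gene, transcript and protein identifiers of a single
#' species and is kept transitively consistent at all times: if a protein is
#' a member, so is its coding transcript, and if a transcript is a member, so
#' is its gene. Membership of a gene does not imply membership of anything
#' below it. All mutating operations preserve this invariant.
#'
#' @param species Species identifier the set is bound to.
#' @param genes,transcripts,proteins Optional initial members. They are taken
#'   as-is, so the combination must already be transitively consistent
#'   (checked when a genome model is supplied via `genome`).
#' @param genome Optional `genome_model` used to validate the initial members.
#' @return An `entity_set`.
#' @export
#' @examples
#' es <- entity_set("A")
#' es
entity_set <- function(species, genes = character(), transcripts = character(),
                       proteins = character(), genome = NULL) {
  set <- structure(
    list(species = species,
         genes = sort_ids(genes),
         transcripts = sort_ids(transcripts),
         proteins = sort_ids(proteins)),
    class = "entity_set"
  )
  if (!is.null(genome)) es_validate(set, genome)
  set
}

#' @export
print.entity_set <- function(x, ...) {
  cat(sprintf("<entity_set> species %s: %d genes, %d transcripts, %d proteins\n",
              x$species, length(x$genes), length(x$transcripts), length(x$proteins)))
  invisible(x)
}

#' @export
format.entity_set <- function(x, ...) {
  sprintf("entity_set(%s: g=%d t=%d p=%d)", x$species,
          length(x$genes), length(x$transcripts), length(x$proteins))
}

check_entity_set <- function(set) {
  if (!inherits(set, "entity_set")) stop_validation("expected an entity_set")
  set
}

check_same_species <- function(a, b) {
  if (a$species != b$species) {
    stop_validation(paste0(
      "sets belong to different species (%s vs %s); ",
      "translate one of them first (see translate_set())"), a$species, b$species)
  }
}

check_genome_species <- function(set, genome) {
  if (!inherits(genome, "genome_model")) stop_validation("expected a genome_model")
  if (set$species != genome$species) {
    stop_validation("set species %s does not match genome species %s",
                    set$species, genome$species)
  }
}

# full invariant check (used by tests and at construction with a genome)
es_validate <- function(set, genome) {
  check_genome_species(set, genome)
  unknown <- c(
    setdiff(set$genes, genome$genes$gene_id),
    setdiff(set$transcripts, names(genome$transcripts)),
    setdiff(set$proteins, names(genome$proteins))
  )
  if (length(unknown) > 0L) {
    stop_validation("identifier(s) not in genome model of %s: %s",
                    genome$species, paste(unknown, collapse = ", "))
  }
  tx_of_p <- unname(genome$proteins[set$proteins])
  if (!all(tx_of_p %in% set$transcripts)) {
    bad <- set$proteins[!tx_of_p %in% set$transcripts][1L]
    stop_validation("transitivity violated: protein %s without its transcript", bad)
  }
  g_of_t <- unname(genome$transcripts[set$transcripts])
  if (!all(g_of_t %in% set$genes)) {
    bad <- set$transcripts[!g_of_t %in% set$genes][1L]
    stop_validation("transitivity violated: transcript %s without its gene", bad)
  }
  invisible(set)
}

# resolve ids to (id, level); level NULL -> inferred per id from the genome
resolve_refs <- function(genome, ids, level = NULL) {
  ids <- as.character(ids)
  if (!is.null(level)) {
    level <- check_level(level)
    pool <- switch(level,
                   gene = genome$genes$gene_id,
                   transcript = names(genome$transcripts),
                   protein = names(genome$proteins))
    unknown <- setdiff(ids, pool)
    if (length(unknown) > 0L) {
      stop_lookup("unknown %s identifier(s) in species %s: %s", level,
                  genome$species, paste(unknown, collapse = ", "))
    }
    return(tibble(id = ids, level = level))
  }
  lv <- character(length(ids))
  lv[ids %in% genome$genes$gene_id] <- "gene"
  is_tx <- ids %in% names(genome$transcripts)
  is_p <- ids %in% names(genome$proteins)
  amb <- (nzchar(lv) & (is_tx | is_p)) | (is_tx & is_p)
  if (any(amb)) {
    stop_validation("ambiguous identifier(s) in species %s: %s (state the level explicitly)",
                    genome$species, paste(ids[amb], collapse = ", "))
  }
  lv[is_tx] <- "transcript"
  lv[is_p] <- "protein"
  if (any(!nzchar(lv))) {
    stop_lookup("unknown identifier(s) in species %s: %s", genome$species,
                paste(ids[!nzchar(lv)], collapse = ", "))
  }
  tibble(id = ids, level = lv)
}

#' Add entities to a set (with upward transitive closure)
#'
#' Inserts the given identifiers together with their upward closure: an added
#' protein brings its coding transcript, an added transcript brings its gene.
#' Adding a gene adds nothing below it.
#'
#' @param set An `entity_set`.
#' @param genome The matching `genome_model`; identifiers are validated
#'   against it at mutation time.
#' @param ids Character vector of identifiers to add.
#' @param level Optional level (`"gene"`, `"transcript"`, `"protein"`) of all
#'   `ids`; if `NULL` each id's level is inferred from the genome model and
#'   ambiguous identifiers are an error.
#' @return The enlarged `entity_set`.
#' @export
#' @examples
#' dir <- figure1_bundle(tempfile())
#' bundle <- load_bundle(dir)
#' gm <- bundle$species$A$genome
#' es <- entity_set("A") |> es_add(gm, c("g1", "g2", "g3"))
#' es_add(es, gm, c("p1_1", "p4_1"))  # pulls in t1_1, t4_1 and g4
es_add <- function(set, genome, ids, level = NULL) {
  check_entity_set(set)
  check_genome_species(set, genome)
  refs <- resolve_refs(genome, ids, level)
  proteins <- refs$id[refs$level == "protein"]
  transcripts <- union(refs$id[refs$level == "transcript"],
                       unname(genome$proteins[proteins]))
  genes <- union(refs$id[refs$level == "gene"],
                 unname(genome$transcripts[transcripts]))
  entity_set(set$species,
             genes = c(set$genes, genes),
             transcripts = c(set$transcripts, transcripts),
             proteins = c(set$proteins, proteins))
}

#' Extend a set downward: add every transcript and protein of member genes
#'
#' The downward closure of the set's gene projection: for every member gene
#' all its transcripts are added, and for every transcript its protein (if
#' any). The result is transitively consistent and idempotent under repeated
#' extension.
#'
#' @inheritParams es_add
#' @return The extended `entity_set`.
#' @export
es_extend <- function(set, genome) {
  check_entity_set(set)
  check_genome_species(set, genome)
  tx <- unlist(genome$tx_by_gene[set$genes], use.names = FALSE) %||% character()
  all_tx <- union(set$transcripts, tx)
  prots <- unname(genome$prot_by_tx[all_tx])
  prots <- prots[!is.na(prots)]
  entity_set(set$species,
             genes = set$genes,
             transcripts = all_tx,
             proteins = union(set$proteins, prots))
}

#' Set algebra on entity sets
#'
#' `es_union()` and `es_intersect()` act element-wise at all three levels;
#' both preserve transitive consistency automatically. `es_minus()` operates
#' at a chosen level: every element of `b`'s projection at that level is
#' removed from `a`, cascading downward (removing a gene removes its member
#' transcripts and their proteins; removing a transcript removes its member
#' proteins; removing a protein removes only itself). Elements above the
#' level are never removed. Cross-species operands are an error — translate
#' first.
#'
#' @param a,b `entity_set`s of the same species.
#' @param genome The matching `genome_model` (needed by `es_minus` for the
#'   downward cascade).
#' @param level Level at which the removal is computed.
#' @return An `entity_set`.
#' @export
es_union <- function(a, b) {
  check_entity_set(a); check_entity_set(b); check_same_species(a, b)
  entity_set(a$species,
             genes = c(a$genes, b$genes),
             transcripts = c(a$transcripts, b$transcripts),
             proteins = c(a$proteins, b$proteins))
}

#' @rdname es_union
#' @export
es_intersect <- function(a, b) {
  check_entity_set(a); check_entity_set(b); check_same_species(a, b)
  entity_set(a$species,
             genes = intersect(a$genes, b$genes),
             transcripts = intersect(a$transcripts, b$transcripts),
             proteins = intersect(a$proteins, b$proteins))
}

#' @rdname es_union
#' @export
es_minus <- function(a, b, genome, level = "gene") {
  check_entity_set(a); check_entity_set(b); check_same_species(a, b)
  check_genome_species(a, genome)
  level <- check_level(level)
  drop <- es_project(b, level)
  es_remove_at(a, genome, drop, level)
}

# remove the given ids at `level` from a set, cascading downward
es_remove_at <- function(a, genome, drop, level) {
  genes <- a$genes
  transcripts <- a$transcripts
  proteins <- a$proteins
  if (level == "gene") {
    genes <- setdiff(genes, drop)
    transcripts <- transcripts[unname(genome$transcripts[transcripts]) %in% genes]
  } else if (level == "transcript") {
    transcripts <- setdiff(transcripts, drop)
  }
  if (level %in% c("gene", "transcript")) {
    proteins <- proteins[unname(genome$proteins[proteins]) %in% transcripts]
  } else {
    proteins <- setdiff(proteins, drop)
  }
  entity_set(a$species, genes = genes, transcripts = transcripts,
             proteins = proteins)
}

#' Compare two entity sets at a level
#'
#' Equality, subset and proper-subset are computed on the projections of the
#' two sets at the chosen level; members at other levels are invisible to the
#' comparison.
#'
#' @inheritParams es_minus
#' @return A one-row tibble with logical columns `equal`, `subset`,
#'   `proper_subset` (relations of `a` with respect to `b`).
#' @export
es_compare <- function(a, b, level = "gene") {
  check_entity_set(a); check_entity_set(b); check_same_species(a, b)
  pa <- es_project(a, level)
  pb <- es_project(b, level)
  subset <- all(pa %in% pb)
  equal <- subset && length(pa) == length(pb)
  tibble(equal = equal, subset = subset, proper_subset = subset && !equal)
}

#' Project an entity set to one level
#'
#' @param set An `entity_set`.
#' @param level `"gene"`, `"transcript"` or `"protein"`.
#' @return Sorted character vector of the identifiers at that level.
#' @export
es_project <- function(set, level) {
  check_entity_set(set)
  level <- check_level(level)
  switch(level, gene = set$genes, transcript = set$transcripts,
         protein = set$proteins)
}

es_equal <- function(a, b) {
  identical(a$species, b$species) &&
    identical(a$genes, b$genes) &&
    identical(a$transcripts, b$transcripts) &&
    identical(a$proteins, b$proteins)
}

#' @export
tidy.entity_set <- function(x, ...) {
  tibble(
    species = x$species,
    level = factor(c(rep("gene", length(x$genes)),
                     rep("transcript", length(x$transcripts)),
                     rep("protein", length(x$proteins))), levels = LEVELS),
    id = c(x$genes, x$transcripts, x$proteins)
  )
}

#' @export
glance.entity_set <- function(x, ...) {
  tibble(species = x$species, n_genes = length(x$genes),
         n_transcripts = length(x$transcripts),
         n_proteins = length(x$proteins))
}

# ---- list files -------------------------------------------------------------

# one ID per line; optional "# level: gene|transcript|protein" directive
read_id_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  level <- NULL
  m <- grepl("^#\\s*level\\s*:", lines)
  if (any(m)) {
    level <- trimws(sub("^#\\s*level\\s*:", "", lines[which(m)[1L]]))
    level <- check_level(level)
  }
  ids <- trimws(lines[!startsWith(lines, "#")])
  list(ids = ids[nzchar(ids)], level = level)
}
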