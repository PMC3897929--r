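# Orthology-based set translation and the miRNA/disease/drug association
# lookups.

#' Translate an entity set to another species through orthology
#'
#' Operates on the gene projection: every source gene is replaced by all of
#' its orthologs in the target species (many-to-many relations expand; the
#' report makes the fan-out visible). Transcripts and proteins are not
#' translated — orthology is a gene-level relation here. Source genes
#' without an ortholog are dropped from the result but listed in the
#' report: a translation is lossy, never an error. The source set is never
#' modified.
#'
#' @param set An `entity_set`.
#' @param target_species Target species id (must exist in the bundle).
#' @param bundle A `ref_bundle` with orthology loaded (pairs are indexed in
#'   both directions).
#' @return A `translation` object: `source_species`, `target_species`,
#'   `mapped` (named list source gene -> target genes), `unmapped`
#'   (character), and `result`, an `entity_set` of the target species
#'   containing the union of all mapped genes.
#' @export
#' @examples
#' bundle <- load_bundle(figure1_bundle(tempfile()))
#' gm <- bundle$species$A$genome
#' s <- entity_set("A") |> es_add(gm, c("g1", "g2", "g3"))
#' tr <- translate_set(s, "B", bundle)
#' tr$result$genes   # g6, g7
#' tr$unmapped       # g3
translate_set <- function(set, target_species, bundle) {
  check_entity_set(set)
  species_data(bundle, target_species)  # errors if unknown
  src_genes <- es_project(set, "gene")
  orth <- bundle$orthology
  pairs <- if (is.null(orth)) {
    tibble(src = character(), tgt = character())
  } else {
    fwd <- orth[orth$species_a == set$species & orth$species_b == target_species, ]
    rev <- orth[orth$species_b == set$species & orth$species_a == target_species, ]
    distinct(tibble(src = c(fwd$gene_a, rev$gene_b),
                    tgt = c(fwd$gene_b, rev$gene_a)))
  }
  if (nrow(pairs) == 0L && length(src_genes) > 0L) {
    warn(sprintf("no orthology pairs between %s and %s: every gene is unmapped",
                 set$species, target_species))
  }
  hits <- pairs[pairs$src %in% src_genes, , drop = FALSE]
  mapped <- lapply(split(hits$tgt, hits$src), sort_ids)
  unmapped <- sort_ids(setdiff(src_genes, names(mapped)))
  result <- entity_set(target_species,
                       genes = unlist(mapped, use.names = FALSE) %||% character())
  structure(list(source_species = set$species,
                 target_species = target_species,
                 mapped = mapped, unmapped = unmapped, result = result),
            class = "translation")
}

#' @export
print.translation <- function(x, ...) {
  cat(sprintf("<translation> %s -> %s: %d gene(s) mapped to %d, %d unmapped\n",
              x$source_species, x$target_species, length(x$mapped),
              length(x$result$genes), length(x$unmapped)))
  invisible(x)
}

#' @export
tidy.translation <- function(x, ...) {
  mapped <- if (length(x$mapped) > 0L) {
    tibble(source_gene = rep(names(x$mapped), lengths(x$mapped)),
           target_gene = unlist(x$mapped, use.names = FALSE))
  } else {
    tibble(source_gene = character(), target_gene = character())
  }
  bind_rows(mapped,
            tibble(source_gene = x$unmapped,
                   target_gene = NA_character_))
}

#' @export
glance.translation <- function(x, ...) {
  tibble(source_species = x$source_species, target_species = x$target_species,
         n_source = length(x$mapped) + length(x$unmapped),
         n_mapped = length(x$mapped), n_unmapped = length(x$unmapped),
         n_result = length(x$result$genes))
}

# ---- associations -----------------------------------------------------------

assoc_table <- function(bundle, species, kind) {
  kind <- match.arg(kind, c("mirna", "disease", "drug"))
  sd <- species_data(bundle, species)
  sd$assoc[[kind]] %||%
    tibble(key_id = character(), key_name = character(), gene_id = character())
}

#' Association keys (miRNAs, diseases, drugs) hitting an entity set
#'
#' Lists every key of the chosen kind whose gene set intersects the set's
#' gene projection — "which microRNAs regulate genes in this snapshot",
#' "which drugs target them", "which diseases are they associated with" —
#' with the intersecting genes spelled out.
#'
#' @param set An `entity_set`.
#' @param bundle A `ref_bundle` with the association table loaded for the
#'   set's species.
#' @param kind `"mirna"`, `"disease"` or `"drug"`.
#' @return Tibble `key_id`, `key_name`, `n_hits`, `hit_genes` (list-column),
#'   sorted by descending hit count, ties by key id.
#' @export
set_associations <- function(set, bundle, kind) {
  check_entity_set(set)
  tab <- assoc_table(bundle, set$species, kind)
  genes <- es_project(set, "gene")
  hits <- tab[tab$gene_id %in% genes, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(key_id = character(), key_name = character(),
                  n_hits = integer(), hit_genes = list()))
  }
  out <- hits |>
    group_by(.data$key_id, .data$key_name) |>
    summarise(n_hits = dplyr::n_distinct(.data$gene_id),
              hit_genes = list(sort_ids(.data$gene_id)), .groups = "drop")
  out[order(-out$n_hits, out$key_id, method = "radix"), ]
}

#' Genes behind one association key
#'
#' The full gene set of a miRNA, disease or drug entry, ready for
#' [snap_add()]. An unknown key is an error; keys whose display name
#' contains the query are suggested.
#'
#' @param bundle A `ref_bundle`.
#' @param species Species whose association table to use.
#' @param kind `"mirna"`, `"disease"` or `"drug"`.
#' @param key Key id.
#' @return Sorted character vector of gene ids.
#' @export
association_genes <- function(bundle, species, kind, key) {
  tab <- assoc_table(bundle, species, kind)
  rows <- tab[tab$key_id == key, , drop = FALSE]
  if (nrow(rows) == 0L) {
    near <- unique(tab$key_id[grepl(key, tab$key_name, fixed = TRUE) |
                                grepl(key, tab$key_id, fixed = TRUE)])
    stop_lookup("unknown %s key '%s'%s", kind, key,
                if (length(near) > 0L)
                  paste0(" (did you mean: ", paste(head(near, 5L), collapse = ", "), "?)")
                else "")
  }
  sort_ids(rows$gene_id)
}
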