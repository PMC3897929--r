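# Interaction-network expansion of entity sets and three-way pathway/EC
# classification.

#' Expand an entity set through the protein interaction graph
#'
#' Starting from the set's proteins (the seeds), `mode = "any"` collects
#' every protein reachable within `hops` edges from any seed — the union of
#' neighborhoods, matching how interaction viewers grow a network. `mode =
#' "all"` is the stricter common-neighbor query: non-seed proteins adjacent
#' to *every* seed (direct neighbors only, so `hops` must be 1). In both
#' modes, seeds without a single interaction are excluded from the network
#' display (they remain members of the set, of course), and the edge list is
#' the subgraph induced on the returned nodes.
#'
#' @param set An `entity_set`.
#' @param bundle A `ref_bundle` with interactions loaded for the set's
#'   species (an `interactions` tibble may be passed directly).
#' @param hops Maximum edge distance from a seed (>= 1).
#' @param mode `"any"` (default) or `"all"`.
#' @param min_score Optional score threshold; edges below it (or unscored
#'   edges) are ignored.
#' @return An `interaction_network`: `nodes` tibble (`protein_id`, `role` =
#'   seed/added, `hops`) and `edges` tibble (`protein_a`, `protein_b`,
#'   `score`).
#' @export
#' @examples
#' bundle <- load_bundle(figure1_bundle(tempfile()))
#' gm <- bundle$species$A$genome
#' s <- entity_set("A") |> es_add(gm, c("g1", "g2", "g3")) |> es_extend(gm)
#' interaction_network(s, bundle)$nodes
interaction_network <- function(set, bundle, hops = 1L,
                                mode = c("any", "all"), min_score = NULL) {
  check_entity_set(set)
  mode <- match.arg(mode)
  hops <- as.integer(hops)
  if (hops < 1L) stop_validation("hops must be >= 1")
  if (mode == "all" && hops > 1L) {
    stop_validation("mode = \"all\" supports direct neighbors only (hops = 1)")
  }
  edges <- if (inherits(bundle, "ref_bundle")) {
    species_data(bundle, set$species)$interactions
  } else {
    bundle
  }
  if (is.null(edges)) {
    edges <- tibble(protein_a = character(), protein_b = character(),
                    score = double())
  }
  if (!is.null(min_score)) {
    edges <- edges[!is.na(edges$score) & edges$score >= min_score, , drop = FALSE]
  }
  seeds <- set$proteins
  if (nrow(edges) > 0L) {
    adj <- split(c(edges$protein_b, edges$protein_a),
                 c(edges$protein_a, edges$protein_b))
    adj <- lapply(adj, unique)
  } else {
    adj <- list()
  }

  connected_seeds <- seeds[seeds %in% names(adj)]
  if (mode == "any") {
    dist <- setNames(rep(0L, length(connected_seeds)), connected_seeds)
    frontier <- connected_seeds
    for (d in seq_len(hops)) {
      if (length(frontier) == 0L) break
      nbrs <- sort_ids(unlist(adj[frontier], use.names = FALSE))
      new <- setdiff(nbrs, names(dist))
      dist[new] <- d
      frontier <- new
    }
    nodes <- tibble(protein_id = names(dist),
                    role = ifelse(names(dist) %in% seeds, "seed", "added"),
                    hops = unname(dist))
  } else {
    common <- NULL
    for (s in seeds) {
      nb <- adj[[s]] %||% character()
      common <- if (is.null(common)) nb else intersect(common, nb)
    }
    common <- setdiff(common %||% character(), seeds)
    keep <- sort_ids(c(connected_seeds, common))
    nodes <- tibble(protein_id = keep,
                    role = ifelse(keep %in% seeds, "seed", "added"),
                    hops = ifelse(keep %in% seeds, 0L, 1L))
  }
  nodes <- nodes[order(nodes$protein_id, method = "radix"), ]
  sub <- edges[edges$protein_a %in% nodes$protein_id &
                 edges$protein_b %in% nodes$protein_id, , drop = FALSE]
  structure(list(nodes = nodes, edges = sub, species = set$species,
                 hops = hops, mode = mode),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %s, %d node(s) (%d seed), %d edge(s), hops=%d, mode=%s\n",
              x$species, nrow(x$nodes), sum(x$nodes$role == "seed"),
              nrow(x$edges), x$hops, x$mode))
  invisible(x)
}

#' @export
tidy.interaction_network <- function(x, ...) {
  x$nodes
}

#' @export
glance.interaction_network <- function(x, ...) {
  tibble(species = x$species, n_nodes = nrow(x$nodes),
         n_seeds = sum(x$nodes$role == "seed"),
         n_added = sum(x$nodes$role == "added"),
         n_edges = nrow(x$edges), hops = x$hops, mode = x$mode)
}

# ---- pathway / EC -----------------------------------------------------------

# componentwise EC match; '-' components of the pathway pattern match
# anything
ec_matches <- function(pattern, ec) {
  pp <- strsplit(pattern, ".", fixed = TRUE)[[1L]]
  ee <- strsplit(ec, ".", fixed = TRUE)[[1L]]
  length(pp) == 4L && length(ee) == 4L && all(pp == "-" | pp == ee)
}

proteins_for_ec <- function(bundle, species, pattern) {
  ec <- species_data(bundle, species)$ec
  if (is.null(ec) || nrow(ec) == 0L) return(character())
  hit <- vapply(ec$ec_number, ec_matches, NA, pattern = pattern)
  sort_ids(ec$protein_id[hit])
}

pathway_ecs <- function(bundle, pathway) {
  if (is.null(bundle$pathways)) stop_lookup("no pathways loaded in this bundle")
  rows <- bundle$pathways[bundle$pathways$pathway_id == pathway, , drop = FALSE]
  if (nrow(rows) == 0L) stop_lookup("unknown pathway '%s'", pathway)
  rows
}

#' Three-way EC classification of a pathway against an entity set
#'
#' Every EC number of the pathway falls into exactly one of three classes:
#' `IN_SET` when a protein of the set carries the activity, `IN_GENOME_ONLY`
#' when the species encodes such an enzyme but the set does not contain it,
#' and `ABSENT` when no protein of the species is annotated with the EC
#' number. Pathway EC numbers may use `-` wildcards for unspecified
#' components.
#'
#' @param pathway Pathway id.
#' @param set An `entity_set`.
#' @param bundle A `ref_bundle` with pathway and EC tables loaded.
#' @return A `pathway_highlight` tibble: `ec_number`, `status`, `n_in_set`,
#'   `n_in_genome`.
#' @export
classify_pathway <- function(pathway, set, bundle) {
  check_entity_set(set)
  rows <- pathway_ecs(bundle, pathway)
  set_proteins <- set$proteins
  out <- lapply(unique(rows$ec_number), function(e) {
    genome_hits <- proteins_for_ec(bundle, set$species, e)
    set_hits <- intersect(genome_hits, set_proteins)
    status <- if (length(set_hits) > 0L) "IN_SET"
      else if (length(genome_hits) > 0L) "IN_GENOME_ONLY" else "ABSENT"
    tibble(ec_number = e, status = status,
           n_in_set = length(set_hits), n_in_genome = length(genome_hits))
  })
  structure(bind_rows(out), class = c("pathway_highlight", class(tibble())),
            pathway = pathway, species = set$species)
}

#' Genes behind an enzymatic function or a whole pathway
#'
#' Resolves an EC number (or every EC of a pathway) to the proteins carrying
#' it in the given species and returns their coding genes — ready to be
#' added to a snapshot.
#'
#' @param bundle A `ref_bundle`.
#' @param species Species to resolve in.
#' @param pathway Pathway id (mutually exclusive with `ec`).
#' @param ec A single EC number (wildcards allowed).
#' @return Sorted character vector of gene ids.
#' @export
pathway_genes <- function(bundle, species, pathway = NULL, ec = NULL) {
  if (is.null(pathway) == is.null(ec)) {
    stop_validation("give exactly one of `pathway` or `ec`")
  }
  ecs <- if (!is.null(pathway)) unique(pathway_ecs(bundle, pathway)$ec_number)
         else ec
  gm <- species_data(bundle, species)$genome
  prots <- sort_ids(unlist(lapply(ecs, function(e)
    proteins_for_ec(bundle, species, e)), use.names = FALSE))
  tx <- unname(gm$proteins[prots])
  sort_ids(unname(gm$transcripts[tx]))
}
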