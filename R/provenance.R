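# Containers, snapshot version trees and the append-only action history.
# A workspace is an environment (handle semantics): mutating verbs update it
# in place and log one history entry per action, so the history replay of a
# snapshot's lineage is the correctness oracle for its content.

#' Create a workspace over a reference bundle
#'
#' The workspace holds containers (species-bound collections of snapshots),
#' the snapshot version trees, the append-only history, and the
#' collaboration state (users, groups, pools). It has handle semantics: the
#' mutating verbs (`container_create()`, `snapshot_create()`, `snap_add()`,
#' ...) modify it in place.
#'
#' @param bundle A `ref_bundle` from [load_bundle()].
#' @param clock A zero-argument function returning the current time; tests
#'   inject a fixed clock so persisted state is reproducible.
#' @return A `workspace` handle.
#' @export
#' @examples
#' bundle <- load_bundle(figure1_bundle(tempfile()))
#' ws <- workspace(bundle)
#' cid <- container_create(ws, "A", name = "I")
#' sid <- snapshot_create(ws, cid, label = "a")
#' snap_add(ws, sid, c("g1", "g2", "g3"))
#' es_project(snapshot_content(ws, sid), "gene")
workspace <- function(bundle, clock = Sys.time) {
  if (!inherits(bundle, "ref_bundle")) stop_validation("expected a ref_bundle")
  ws <- new.env(parent = emptyenv())
  ws$bundle <- bundle
  ws$containers <- list()
  ws$snapshots <- list()
  ws$history <- list()
  ws$seq <- 0L
  ws$next_container <- 1L
  ws$next_snapshot <- 1L
  ws$users <- list()
  ws$groups <- list()
  ws$pools <- list()
  ws$next_group <- 1L
  ws$next_entry <- 1L
  ws$next_process <- 1L
  ws$clock <- clock
  class(ws) <- "workspace"
  ws
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("<workspace> %d container(s), %d snapshot(s), %d history entr%s\n",
              length(x$containers), length(x$snapshots), length(x$history),
              if (length(x$history) == 1L) "y" else "ies"))
  invisible(x)
}

check_workspace <- function(ws) {
  if (!inherits(ws, "workspace")) stop_validation("expected a workspace")
  ws
}

ws_genome <- function(ws, species) {
  species_data(ws$bundle, species)$genome
}

get_container <- function(ws, id) {
  ws$containers[[id]] %||% stop_lookup("unknown container '%s'", id)
}

get_snapshot <- function(ws, id) {
  ws$snapshots[[id]] %||% stop_lookup("unknown snapshot '%s'", id)
}

# resolve a snapshot by id or unique label
find_snapshot <- function(ws, key) {
  if (key %in% names(ws$snapshots)) return(key)
  labels <- vapply(ws$snapshots, `[[`, "", "label")
  hit <- names(labels)[labels == key]
  if (length(hit) == 1L) return(hit)
  stop_lookup("unknown snapshot '%s'", key)
}

log_action <- function(ws, actor, snapshot, action, params, effect,
                       before = NULL, after = NULL) {
  ws$seq <- ws$seq + 1L
  delta <- if (!is.null(before) && !is.null(after)) {
    lapply(setNames(LEVELS, LEVELS), function(lv) {
      b <- es_project(before, lv); a <- es_project(after, lv)
      c(added = length(setdiff(a, b)), removed = length(setdiff(b, a)))
    })
  }
  ws$history[[ws$seq]] <- list(
    seq = ws$seq,
    timestamp = ws$clock(),
    actor = actor,
    snapshot = snapshot,
    action = action,
    params = params,
    effect = effect,
    delta = delta
  )
  invisible(ws$seq)
}

# ---- containers -------------------------------------------------------------

#' Create a container
#'
#' A container is a species-bound collection of snapshots with optional
#' description, color and comments. Its species is fixed at creation; every
#' snapshot it holds inherits it. Names are labels, not keys — ids are
#' system-assigned.
#'
#' @param ws A `workspace`.
#' @param species Species identifier; must be known to the loaded bundle.
#' @param name,description,color Container properties.
#' @param actor User id recorded in the history.
#' @return The new container id.
#' @export
container_create <- function(ws, species, name = "", description = "",
                             color = "#888888", actor = "user") {
  check_workspace(ws)
  species_data(ws$bundle, species)  # errors on unknown species
  id <- sprintf("C%d", ws$next_container)
  ws$next_container <- ws$next_container + 1L
  ws$containers[[id]] <- list(id = id, species = species, name = name,
                              description = description, color = color,
                              comments = list(), owner = actor)
  log_action(ws, actor, NA_character_, "container_create",
             list(container = id, species = species, name = name),
             list(kind = "none"))
  id
}

#' Comment on a container
#' @param ws A `workspace`.
#' @param container Container id.
#' @param text Comment text.
#' @param actor Comment author.
#' @return The workspace, invisibly.
#' @export
container_comment <- function(ws, container, text, actor = "user") {
  check_workspace(ws)
  co <- get_container(ws, container)
  co$comments[[length(co$comments) + 1L]] <-
    list(timestamp = ws$clock(), author = actor, text = text)
  ws$containers[[container]] <- co
  log_action(ws, actor, NA_character_, "container_comment",
             list(container = container, text = text), list(kind = "none"))
  invisible(ws)
}

#' List containers as a tibble
#' @param ws A `workspace`.
#' @return A tibble with one row per container.
#' @export
containers <- function(ws) {
  check_workspace(ws)
  if (length(ws$containers) == 0L) {
    return(tibble(id = character(), species = character(), name = character(),
                  description = character(), color = character(),
                  n_snapshots = integer()))
  }
  owners <- vapply(ws$snapshots, `[[`, "", "container")
  tibble(
    id = unname(vapply(ws$containers, `[[`, "", "id")),
    species = unname(vapply(ws$containers, `[[`, "", "species")),
    name = unname(vapply(ws$containers, `[[`, "", "name")),
    description = unname(vapply(ws$containers, `[[`, "", "description")),
    color = unname(vapply(ws$containers, `[[`, "", "color")),
    n_snapshots = unname(vapply(ws$containers, function(co)
      sum(owners == co$id), 0L))
  )
}

# ---- snapshots --------------------------------------------------------------

#' Create a snapshot, optionally branching from a parent
#'
#' With a parent, the new snapshot starts as a deep copy of the parent's
#' content — later edits never touch the parent. Without one it starts
#' empty. Any snapshot, however old, may serve as parent, so analyses form
#' trees inside a container; parent and child must share the container.
#'
#' @param ws A `workspace`.
#' @param container Container id.
#' @param parent Optional parent snapshot id.
#' @param label Optional human label (used by replay scripts).
#' @param actor User id recorded in the history.
#' @return The new snapshot id.
#' @export
snapshot_create <- function(ws, container, parent = NULL, label = "",
                            actor = "user") {
  check_workspace(ws)
  co <- get_container(ws, container)
  content <- entity_set(co$species)
  if (!is.null(parent)) {
    pa <- get_snapshot(ws, parent)
    if (pa$container != container) {
      stop_validation("parent snapshot %s belongs to container %s, not %s",
                      parent, pa$container, container)
    }
    content <- pa$content
  }
  id <- sprintf("S%d", ws$next_snapshot)
  ws$next_snapshot <- ws$next_snapshot + 1L
  ws$snapshots[[id]] <- list(id = id, container = container,
                             parent = parent, label = label,
                             created_at = ws$clock(), content = content)
  log_action(ws, actor, id, "snapshot_create",
             list(container = container, parent = parent, label = label),
             list(kind = "create", parent = parent))
  id
}

#' Read a snapshot's entity set
#' @param ws A `workspace`.
#' @param snapshot Snapshot id or label.
#' @return The snapshot's `entity_set`.
#' @export
snapshot_content <- function(ws, snapshot) {
  check_workspace(ws)
  get_snapshot(ws, find_snapshot(ws, snapshot))$content
}

snapshot_children <- function(ws, id) {
  kids <- vapply(ws$snapshots, function(s) identical(s$parent, id), NA)
  names(ws$snapshots)[kids]
}

#' Copy, clear or remove a snapshot
#'
#' `snapshot_copy()` creates a sibling with identical content;
#' `snapshot_clear()` empties a snapshot's content (a normal, logged action —
#' recover by branching from an ancestor); `snapshot_remove()` deletes a
#' snapshot, refused unless it is a leaf so the version tree and its history
#' stay replayable.
#'
#' @param ws A `workspace`.
#' @param snapshot Snapshot id.
#' @param actor User id recorded in the history.
#' @return `snapshot_copy()` the new id; the others the workspace, invisibly.
#' @export
snapshot_copy <- function(ws, snapshot, actor = "user") {
  check_workspace(ws)
  src <- get_snapshot(ws, snapshot)
  id <- sprintf("S%d", ws$next_snapshot)
  ws$next_snapshot <- ws$next_snapshot + 1L
  ws$snapshots[[id]] <- list(id = id, container = src$container,
                             parent = src$parent,
                             label = paste0(src$label, "_copy"),
                             created_at = ws$clock(), content = src$content)
  log_action(ws, actor, id, "snapshot_copy", list(source = snapshot),
             list(kind = "set", content = es_triple(src$content)))
  id
}

#' @rdname snapshot_copy
#' @export
snapshot_clear <- function(ws, snapshot, actor = "user") {
  check_workspace(ws)
  sn <- get_snapshot(ws, snapshot)
  before <- sn$content
  sn$content <- entity_set(before$species)
  ws$snapshots[[snapshot]] <- sn
  log_action(ws, actor, snapshot, "snapshot_clear", list(),
             list(kind = "clear"), before, sn$content)
  invisible(ws)
}

#' @rdname snapshot_copy
#' @export
snapshot_remove <- function(ws, snapshot, actor = "user") {
  check_workspace(ws)
  get_snapshot(ws, snapshot)
  kids <- snapshot_children(ws, snapshot)
  if (length(kids) > 0L) {
    stop_validation("snapshot %s has child snapshot(s) (%s); only leaves can be removed",
                    snapshot, paste(kids, collapse = ", "))
  }
  ws$snapshots[[snapshot]] <- NULL
  log_action(ws, actor, snapshot, "snapshot_remove", list(), list(kind = "none"))
  invisible(ws)
}

#' Snapshot version trees of a container
#' @param ws A `workspace`.
#' @param container Container id.
#' @return Tibble with columns `id`, `parent`, `label`, `n_genes`,
#'   `n_transcripts`, `n_proteins`.
#' @export
snapshot_tree <- function(ws, container) {
  check_workspace(ws)
  get_container(ws, container)
  snaps <- Filter(function(s) s$container == container, ws$snapshots)
  tibble(
    id = vapply(snaps, `[[`, "", "id"),
    parent = vapply(snaps, function(s) s$parent %||% NA_character_, ""),
    label = vapply(snaps, `[[`, "", "label"),
    n_genes = vapply(snaps, function(s) length(s$content$genes), 0L),
    n_transcripts = vapply(snaps, function(s) length(s$content$transcripts), 0L),
    n_proteins = vapply(snaps, function(s) length(s$content$proteins), 0L)
  )
}

es_triple <- function(set) {
  list(genes = set$genes, transcripts = set$transcripts,
       proteins = set$proteins, species = set$species)
}

triple_to_set <- function(tr) {
  entity_set(tr$species, genes = tr$genes, transcripts = tr$transcripts,
             proteins = tr$proteins)
}

# ---- snapshot content mutation ---------------------------------------------

apply_content <- function(ws, snapshot, actor, action, params, effect, fn) {
  sn <- get_snapshot(ws, snapshot)
  before <- sn$content
  after <- fn(before)
  sn$content <- after
  ws$snapshots[[snapshot]] <- sn
  log_action(ws, actor, snapshot, action, params, effect, before, after)
  invisible(snapshot)
}

#' Mutate a snapshot's entity set
#'
#' Thin, history-logged wrappers over the entity-set operations: `snap_add()`
#' adds identifiers with upward closure, `snap_extend()` adds all transcripts
#' and proteins of member genes, and `snap_union()`, `snap_intersect()`,
#' `snap_minus()` combine the snapshot with another snapshot (or a bare
#' `entity_set`). Every call appends exactly one history entry carrying the
#' operand's membership at call time, which is what makes lineage replay
#' exact.
#'
#' @param ws A `workspace`.
#' @param snapshot Snapshot id (or label).
#' @param ids Identifiers to add.
#' @param level Optional level of `ids` (else inferred per id).
#' @param other Snapshot id/label or an `entity_set`.
#' @param actor User id recorded in the history.
#' @return The snapshot id, invisibly.
#' @export
snap_add <- function(ws, snapshot, ids, level = NULL, actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  sn <- get_snapshot(ws, snapshot)
  gm <- ws_genome(ws, sn$content$species)
  refs <- resolve_refs(gm, ids, level)  # resolve first: atomic on error
  apply_content(ws, snapshot, actor, "add",
                list(ids = refs$id, levels = refs$level),
                list(kind = "add", ids = refs$id, levels = refs$level),
                function(es) es_add(es, gm, refs$id))
}

#' @rdname snap_add
#' @export
snap_extend <- function(ws, snapshot, actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  sn <- get_snapshot(ws, snapshot)
  gm <- ws_genome(ws, sn$content$species)
  apply_content(ws, snapshot, actor, "extend", list(), list(kind = "extend"),
                function(es) es_extend(es, gm))
}

other_set <- function(ws, other) {
  if (inherits(other, "entity_set")) other
  else snapshot_content(ws, other)
}

#' @rdname snap_add
#' @export
snap_union <- function(ws, snapshot, other, actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  ob <- other_set(ws, other)
  apply_content(ws, snapshot, actor, "union", list(operand = es_triple(ob)),
                list(kind = "union", operand = es_triple(ob)),
                function(es) es_union(es, ob))
}

#' @rdname snap_add
#' @export
snap_intersect <- function(ws, snapshot, other, actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  ob <- other_set(ws, other)
  apply_content(ws, snapshot, actor, "intersect", list(operand = es_triple(ob)),
                list(kind = "intersect", operand = es_triple(ob)),
                function(es) es_intersect(es, ob))
}

#' @rdname snap_add
#' @param minus_level Level at which `snap_minus` removes (cascade below).
#' @export
snap_minus <- function(ws, snapshot, other, minus_level = "gene",
                       actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  sn <- get_snapshot(ws, snapshot)
  gm <- ws_genome(ws, sn$content$species)
  ob <- other_set(ws, other)
  apply_content(ws, snapshot, actor, "minus",
                list(operand = es_triple(ob), level = minus_level),
                list(kind = "minus", operand = es_triple(ob), level = minus_level),
                function(es) es_minus(es, ob, gm, minus_level))
}

# ---- import / export --------------------------------------------------------

#' Import an identifier list file into a snapshot / export a projection
#'
#' List files carry one identifier per line with an optional
#' `# level: gene|transcript|protein` directive; without it each
#' identifier's level is inferred from the genome model. Import is atomic:
#' if any identifier fails to resolve, all offenders are listed and the
#' snapshot is left unchanged. Export writes the level projection sorted,
#' one id per line; an export/import round trip is the identity at that
#' level.
#'
#' @param ws A `workspace`.
#' @param snapshot Snapshot id or label.
#' @param file List file path (import) / output path (export).
#' @param level Level for export.
#' @param actor User id recorded in the history.
#' @return `import_set()` the snapshot id invisibly; `export_set()` the file
#'   path invisibly.
#' @export
import_set <- function(ws, snapshot, file, actor = "user") {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  lst <- read_id_list(file)
  sn <- get_snapshot(ws, snapshot)
  gm <- ws_genome(ws, sn$content$species)
  if (is.null(lst$level)) {
    bad <- Filter(function(id) {
      !id %in% gm$genes$gene_id && !id %in% names(gm$transcripts) &&
        !id %in% names(gm$proteins)
    }, lst$ids)
    if (length(bad) > 0L) {
      stop_lookup("unresolvable identifier(s) in %s: %s", basename(file),
                  paste(bad, collapse = ", "))
    }
  }
  snap_add(ws, snapshot, lst$ids, level = lst$level, actor = actor)
}

#' @rdname import_set
#' @export
export_set <- function(ws, snapshot, level, file) {
  check_workspace(ws)
  ids <- es_project(snapshot_content(ws, snapshot), level)
  writeLines(c(paste0("# level: ", level), ids), file, useBytes = TRUE)
  invisible(file)
}

# ---- history ----------------------------------------------------------------

#' The workspace action history
#'
#' Every mutating operation appends exactly one entry: sequence number,
#' timestamp, actor, target snapshot, action name, parameter record and a
#' per-level delta summary.
#'
#' @param ws A `workspace`.
#' @param snapshot,container,actor Optional filters.
#' @return Tibble in sequence order with list-columns `params` and `delta`.
#' @export
ws_history <- function(ws, snapshot = NULL, container = NULL, actor = NULL) {
  check_workspace(ws)
  entries <- ws$history
  entries <- Filter(Negate(is.null), entries)
  if (!is.null(snapshot)) {
    entries <- Filter(function(e) identical(e$snapshot, snapshot), entries)
  }
  if (!is.null(container)) {
    member <- names(Filter(function(s) s$container == container, ws$snapshots))
    entries <- Filter(function(e) {
      (!is.na(e$snapshot) && e$snapshot %in% member) ||
        identical(e$params$container, container)
    }, entries)
  }
  if (!is.null(actor)) {
    entries <- Filter(function(e) identical(e$actor, actor), entries)
  }
  tibble(
    seq = vapply(entries, `[[`, 0L, "seq"),
    timestamp = vapply(entries, function(e) format_time(e$timestamp), ""),
    actor = vapply(entries, `[[`, "", "actor"),
    snapshot = vapply(entries, function(e) e$snapshot %||% NA_character_, ""),
    action = vapply(entries, `[[`, "", "action"),
    params = lapply(entries, `[[`, "params"),
    delta = lapply(entries, `[[`, "delta")
  )
}

format_time <- function(t) {
  if (inherits(t, "POSIXt")) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  else as.character(t)
}

# apply one logged effect to an entity set (replay primitive)
apply_effect <- function(es, effect, gm) {
  switch(effect$kind,
    none = es,
    create = es,
    set = triple_to_set(effect$content),
    add = es_add(es, gm, effect$ids),
    extend = es_extend(es, gm),
    clear = entity_set(es$species),
    union = es_union(es, triple_to_set(effect$operand)),
    intersect = es_intersect(es, triple_to_set(effect$operand)),
    minus = es_minus(es, triple_to_set(effect$operand), gm, effect$level),
    stop_validation("unknown history effect kind '%s'", effect$kind)
  )
}

#' Rebuild a snapshot's content by replaying its lineage history
#'
#' Walks from the root of the snapshot's version tree down to the snapshot,
#' applying each ancestor's logged actions up to the point where the next
#' child branched off, then the snapshot's own actions. The result must
#' equal the stored content — this is the package's provenance-correctness
#' oracle.
#'
#' @param ws A `workspace`.
#' @param snapshot Snapshot id.
#' @return The reconstructed `entity_set`.
#' @export
replay_history <- function(ws, snapshot) {
  check_workspace(ws)
  snapshot <- find_snapshot(ws, snapshot)
  # lineage root -> snapshot
  path <- character()
  cur <- snapshot
  while (!is.null(cur)) {
    path <- c(cur, path)
    cur <- get_snapshot(ws, cur)$parent
  }
  create_seq <- vapply(path, function(id) {
    for (e in ws$history) {
      if (!is.null(e) && identical(e$snapshot, id) &&
          e$action %in% c("snapshot_create", "snapshot_copy")) return(e$seq)
    }
    stop_validation("no creation record for snapshot %s", id)
  }, 0L)
  species <- get_snapshot(ws, snapshot)$content$species
  gm <- ws_genome(ws, species)
  es <- entity_set(species)
  for (i in seq_along(path)) {
    id <- path[i]
    cutoff <- if (i < length(path)) create_seq[i + 1L] else .Machine$integer.max
    for (e in ws$history) {
      if (is.null(e) || !identical(e$snapshot, id)) next
      if (e$seq >= cutoff) next
      if (e$action == "snapshot_create") next
      es <- apply_effect(es, e$effect, gm)
    }
  }
  es
}

# ---- replay scripts ---------------------------------------------------------

#' Run a plain-text action script against a workspace
#'
#' One action per line, tab-separated: `container NAME SPECIES`,
#' `snapshot NAME CONTAINER PARENT|-`, `add SNAP LEVEL ID,ID,...`,
#' `extend SNAP`, `minus SNAP LEVEL ID,...`, `union SNAP OTHER`,
#' `intersect SNAP OTHER`, `network_add SNAP SOURCE HOPS`,
#' `translate_add SNAP SOURCE`. Names are script-local aliases; the returned
#' map links them to workspace ids. The worked-example scenario ships as
#' `figure1.replay` next to the bundle written by [figure1_bundle()].
#'
#' @param ws A `workspace`.
#' @param path Script file path.
#' @param actor User id recorded in the history.
#' @return Named character vector mapping script aliases to workspace ids.
#' @export
#' @examples
#' dir <- figure1_bundle(tempfile())
#' ws <- workspace(load_bundle(dir))
#' aliases <- replay_script(ws, file.path(dir, "figure1.replay"))
#' es_project(snapshot_content(ws, aliases[["b"]]), "gene")
replay_script <- function(ws, path, actor = "user") {
  check_workspace(ws)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  containers <- character()
  snaps <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    verb <- f[1L]
    if (verb == "container") {
      containers[[f[2L]]] <- container_create(ws, f[3L], name = f[2L],
                                              actor = actor)
    } else if (verb == "snapshot") {
      parent <- if (f[4L] == "-") NULL else snaps[[f[4L]]]
      snaps[[f[2L]]] <- snapshot_create(ws, containers[[f[3L]]],
                                        parent = parent, label = f[2L],
                                        actor = actor)
    } else if (verb == "add") {
      snap_add(ws, snaps[[f[2L]]], strsplit(f[4L], ",", fixed = TRUE)[[1L]],
               level = f[3L], actor = actor)
    } else if (verb == "extend") {
      snap_extend(ws, snaps[[f[2L]]], actor = actor)
    } else if (verb == "minus") {
      sn <- get_snapshot(ws, snaps[[f[2L]]])
      ids <- strsplit(f[4L], ",", fixed = TRUE)[[1L]]
      op <- entity_set(sn$content$species)
      op[[paste0(f[3L], "s")]] <- sort_ids(ids)
      snap_minus(ws, snaps[[f[2L]]], op, minus_level = f[3L], actor = actor)
    } else if (verb == "union") {
      snap_union(ws, snaps[[f[2L]]], snaps[[f[3L]]], actor = actor)
    } else if (verb == "intersect") {
      snap_intersect(ws, snaps[[f[2L]]], snaps[[f[3L]]], actor = actor)
    } else if (verb == "network_add") {
      src <- snapshot_content(ws, snaps[[f[3L]]])
      net <- interaction_network(src, ws$bundle,
                                 hops = as.integer(f[4L] %||% "1"))
      if (nrow(net$nodes) > 0L) {
        snap_add(ws, snaps[[f[2L]]], net$nodes$protein_id, level = "protein",
                 actor = actor)
      }
    } else if (verb == "translate_add") {
      dst <- get_snapshot(ws, snaps[[f[2L]]])
      src <- snapshot_content(ws, snaps[[f[3L]]])
      tr <- translate_set(src, dst$content$species, ws$bundle)
      if (length(tr$result$genes) > 0L) {
        snap_add(ws, snaps[[f[2L]]], tr$result$genes, level = "gene",
                 actor = actor)
      }
    } else {
      stop_validation("unknown replay verb '%s'", verb)
    }
  }
  c(containers, snaps)
}

# ---- persistence ------------------------------------------------------------

#' Save / load a workspace as a directory of plain-text state files
#'
#' Containers and snapshot metadata are TSV tables, each snapshot's content
#' a level-sorted id list, the history an append-only TSV with JSON-encoded
#' parameters, and the collaboration state a JSON document. The layout is
#' human-diffable and byte-stable: save, load, save yields identical files.
#' Writes are atomic (temp file + rename).
#'
#' @param ws A `workspace`.
#' @param dir State directory.
#' @param bundle The `ref_bundle` the workspace was built over (bundles are
#'   loaded separately from their own directory).
#' @param clock Clock injected into the restored workspace.
#' @return `ws_save()` the directory, invisibly; `ws_load()` a `workspace`.
#' @export
ws_save <- function(ws, dir) {
  check_workspace(ws)
  dir.create(file.path(dir, "snapshots"), recursive = TRUE, showWarnings = FALSE)

  cons <- ws$containers[sort_ids(names(ws$containers))]
  write_atomic(c(
    "id\tspecies\tname\tdescription\tcolor\towner",
    vapply(cons, function(co) paste(co$id, co$species, co$name, co$description,
                                    co$color, co$owner, sep = "\t"), "")
  ), file.path(dir, "containers.tsv"))

  write_atomic(c(
    "container\ttimestamp\tauthor\ttext",
    unlist(lapply(cons, function(co) {
      vapply(co$comments, function(cm) paste(co$id, format_time(cm$timestamp),
                                             cm$author, cm$text, sep = "\t"), "")
    }))
  ), file.path(dir, "comments.tsv"))

  snaps <- ws$snapshots[sort_ids(names(ws$snapshots))]
  write_atomic(c(
    "id\tcontainer\tparent\tlabel\tcreated_at",
    vapply(snaps, function(s) paste(s$id, s$container, s$parent %||% "-",
                                    s$label, format_time(s$created_at),
                                    sep = "\t"), "")
  ), file.path(dir, "snapshots.tsv"))

  existing <- list.files(file.path(dir, "snapshots"), full.names = TRUE)
  unlink(setdiff(existing, file.path(dir, "snapshots",
                                     paste0(names(snaps), ".tsv"))))
  for (s in snaps) {
    td <- tidy(s$content)
    write_atomic(c("level\tid",
                   paste(as.character(td$level), td$id, sep = "\t")),
                 file.path(dir, "snapshots", paste0(s$id, ".tsv")))
  }

  entries <- Filter(Negate(is.null), ws$history)
  write_atomic(c(
    "seq\ttimestamp\tactor\tsnapshot\taction\tparams\teffect\tdelta",
    vapply(entries, function(e) {
      paste(e$seq, format_time(e$timestamp), e$actor,
            e$snapshot %||% "-", e$action,
            jsonlite::toJSON(e$params, auto_unbox = TRUE, null = "null"),
            jsonlite::toJSON(e$effect, auto_unbox = TRUE, null = "null"),
            jsonlite::toJSON(e$delta, auto_unbox = TRUE, null = "null"),
            sep = "\t")
    }, "")
  ), file.path(dir, "history.tsv"))

  counters <- list(seq = ws$seq, next_container = ws$next_container,
                   next_snapshot = ws$next_snapshot, next_group = ws$next_group,
                   next_entry = ws$next_entry, next_process = ws$next_process)
  collab <- list(users = ws$users, groups = ws$groups, pools = ws$pools,
                 counters = counters)
  write_atomic(jsonlite::toJSON(collab, auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = TRUE),
               file.path(dir, "collab.json"))
  invisible(dir)
}

#' @rdname ws_save
#' @export
ws_load <- function(dir, bundle, clock = Sys.time) {
  ws <- workspace(bundle, clock = clock)
  cons <- read_tsv_table(file.path(dir, "containers.tsv"),
                         c("id", "species", "name", "description", "color", "owner"))
  cmts <- read_tsv_table(file.path(dir, "comments.tsv"),
                         c("container", "timestamp", "author", "text"))
  for (i in seq_len(nrow(cons))) {
    id <- cons$id[i]
    rows <- which(cmts$container == id)
    ws$containers[[id]] <- list(
      id = id, species = cons$species[i], name = cons$name[i],
      description = cons$description[i], color = cons$color[i],
      comments = lapply(rows, function(j) list(timestamp = cmts$timestamp[j],
                                               author = cmts$author[j],
                                               text = cmts$text[j])),
      owner = cons$owner[i])
  }
  snaps <- read_tsv_table(file.path(dir, "snapshots.tsv"),
                          c("id", "container", "parent", "label", "created_at"))
  for (i in seq_len(nrow(snaps))) {
    id <- snaps$id[i]
    content_tab <- read_tsv_table(file.path(dir, "snapshots", paste0(id, ".tsv")),
                                  c("level", "id"))
    species <- ws$containers[[snaps$container[i]]]$species
    ws$snapshots[[id]] <- list(
      id = id, container = snaps$container[i],
      parent = if (snaps$parent[i] == "-") NULL else snaps$parent[i],
      label = snaps$label[i], created_at = snaps$created_at[i],
      content = entity_set(species,
                           genes = content_tab$id[content_tab$level == "gene"],
                           transcripts = content_tab$id[content_tab$level == "transcript"],
                           proteins = content_tab$id[content_tab$level == "protein"]))
  }
  hist <- read_tsv_table(file.path(dir, "history.tsv"),
                         c("seq", "timestamp", "actor", "snapshot", "action",
                           "params", "effect", "delta"))
  ws$history <- lapply(seq_len(nrow(hist)), function(i) {
    list(seq = as.integer(hist$seq[i]), timestamp = hist$timestamp[i],
         actor = hist$actor[i],
         snapshot = if (hist$snapshot[i] == "-") NA_character_ else hist$snapshot[i],
         action = hist$action[i],
         params = parse_json_chr(hist$params[i]),
         effect = parse_json_chr(hist$effect[i]),
         delta = parse_json_chr(hist$delta[i]))
  })
  if (file.exists(file.path(dir, "collab.json"))) {
    collab <- jsonlite::fromJSON(file.path(dir, "collab.json"),
                                 simplifyVector = FALSE)
    ws$users <- collab$users
    ws$groups <- collab$groups
    ws$pools <- restore_pools(collab$pools)
    cn <- collab$counters
    ws$seq <- cn$seq; ws$next_container <- cn$next_container
    ws$next_snapshot <- cn$next_snapshot; ws$next_group <- cn$next_group
    ws$next_entry <- cn$next_entry; ws$next_process <- cn$next_process
  } else {
    ws$seq <- length(ws$history)
    nums <- function(ids, prefix) {
      n <- suppressWarnings(as.integer(sub(prefix, "", ids)))
      if (length(n) == 0L) 1L else max(n, na.rm = TRUE) + 1L
    }
    ws$next_container <- nums(names(ws$containers), "C")
    ws$next_snapshot <- nums(names(ws$snapshots), "S")
  }
  ws
}

parse_json_chr <- function(x) {
  v <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  v
}

# JSON round-trips character vectors to lists of scalars; normalize pool
# entry id vectors back to character vectors
restore_pools <- function(pools) {
  normalize_chr(pools)
}

normalize_chr <- function(x) {
  if (is.list(x)) {
    if (length(x) > 0L && all(vapply(x, function(e)
      is.character(e) && length(e) == 1L, NA))) {
      # keep named lists as lists; only flatten unnamed id vectors
      if (is.null(names(x))) return(unlist(x))
    }
    return(lapply(x, normalize_chr))
  }
  x
}
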