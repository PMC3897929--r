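# Multi-user pools: private and group pools of containers and analysis
# results, with two authorization levels (NORMAL reads, COORDINATOR updates
# and manages membership) and public groups readable by anyone. Users are
# workspace identities; authentication is a deployment concern outside the
# library.

AUTH_LEVELS <- c("NORMAL", "COORDINATOR")

#' Register a user in the workspace
#' @param ws A `workspace`.
#' @param user_id Unique user id.
#' @param name Display name.
#' @return The user id.
#' @export
user_create <- function(ws, user_id, name = user_id) {
  check_workspace(ws)
  if (user_id %in% names(ws$users)) {
    stop_validation("user '%s' already exists", user_id)
  }
  ws$users[[user_id]] <- list(user_id = user_id, name = name)
  ws$pools[[pool_key_user(user_id)]] <- list(containers = list(), processes = list())
  user_id
}

check_user <- function(ws, user_id) {
  if (!user_id %in% names(ws$users)) stop_lookup("unknown user '%s'", user_id)
  user_id
}

pool_key_user <- function(user_id) paste0("user:", user_id)
pool_key_group <- function(group_id) paste0("group:", group_id)

get_group <- function(ws, group_id) {
  ws$groups[[group_id]] %||% stop_lookup("unknown group '%s'", group_id)
}

member_level <- function(group, user_id) {
  lvl <- group$members[[user_id]]
  if (is.null(lvl)) NA_character_ else lvl
}

is_coordinator <- function(group, user_id) {
  identical(member_level(group, user_id), "COORDINATOR")
}

#' Create a user group
#'
#' Any user may create a group and becomes its first coordinator. A public
#' group's pool is readable by every user, member or not.
#'
#' @param ws A `workspace`.
#' @param actor Creating user.
#' @param name Group name.
#' @param public Mark the group's pool world-readable.
#' @return The new group id.
#' @export
group_create <- function(ws, actor, name, public = FALSE) {
  check_workspace(ws); check_user(ws, actor)
  id <- sprintf("G%d", ws$next_group)
  ws$next_group <- ws$next_group + 1L
  ws$groups[[id]] <- list(id = id, name = name, public = isTRUE(public),
                          members = setNames(list("COORDINATOR"), actor))
  ws$pools[[pool_key_group(id)]] <- list(containers = list(), processes = list())
  log_action(ws, actor, NA_character_, "group_create",
             list(group = id, name = name, public = isTRUE(public)),
             list(kind = "none"))
  id
}

#' Manage group membership
#'
#' Membership changes require the acting user to be a COORDINATOR of the
#' group. The last coordinator can never be removed or demoted — a group
#' always has at least one.
#'
#' @param ws A `workspace`.
#' @param actor Acting user (must be a coordinator).
#' @param group Group id.
#' @param user Target user.
#' @param level `"NORMAL"` or `"COORDINATOR"`.
#' @return The group id, invisibly.
#' @export
group_add_member <- function(ws, actor, group, user, level = "NORMAL") {
  check_workspace(ws); check_user(ws, actor); check_user(ws, user)
  g <- get_group(ws, group)
  if (!is_coordinator(g, actor)) {
    stop_auth("user '%s' is not a coordinator of group '%s'", actor, group)
  }
  if (!level %in% AUTH_LEVELS) stop_validation("level must be NORMAL or COORDINATOR")
  g$members[[user]] <- level
  ws$groups[[group]] <- g
  log_action(ws, actor, NA_character_, "group_add_member",
             list(group = group, user = user, level = level), list(kind = "none"))
  invisible(group)
}

#' @rdname group_add_member
#' @export
group_set_level <- function(ws, actor, group, user, level) {
  check_workspace(ws); check_user(ws, actor); check_user(ws, user)
  g <- get_group(ws, group)
  if (!is_coordinator(g, actor)) {
    stop_auth("user '%s' is not a coordinator of group '%s'", actor, group)
  }
  if (!level %in% AUTH_LEVELS) stop_validation("level must be NORMAL or COORDINATOR")
  if (is.null(g$members[[user]])) stop_lookup("'%s' is not a member of '%s'", user, group)
  if (level == "NORMAL" && is_coordinator(g, user) && n_coordinators(g) == 1L) {
    stop_validation("cannot demote the last coordinator of group '%s'", group)
  }
  g$members[[user]] <- level
  ws$groups[[group]] <- g
  log_action(ws, actor, NA_character_, "group_set_level",
             list(group = group, user = user, level = level), list(kind = "none"))
  invisible(group)
}

#' @rdname group_add_member
#' @export
group_remove_member <- function(ws, actor, group, user) {
  check_workspace(ws); check_user(ws, actor); check_user(ws, user)
  g <- get_group(ws, group)
  if (!is_coordinator(g, actor)) {
    stop_auth("user '%s' is not a coordinator of group '%s'", actor, group)
  }
  if (is.null(g$members[[user]])) stop_lookup("'%s' is not a member of '%s'", user, group)
  if (is_coordinator(g, user) && n_coordinators(g) == 1L) {
    stop_validation("cannot remove the last coordinator of group '%s'", group)
  }
  g$members[[user]] <- NULL
  ws$groups[[group]] <- g
  log_action(ws, actor, NA_character_, "group_remove_member",
             list(group = group, user = user), list(kind = "none"))
  invisible(group)
}

n_coordinators <- function(group) {
  sum(vapply(group$members, identical, NA, "COORDINATOR"))
}

#' Pure access check for a pool
#'
#' `intent = "read"` is granted to the pool's owner, to any member of the
#' owning group, or to anyone when the group is public. `intent = "update"`
#' is granted to the owner and to group coordinators only. Update permission
#' always implies read permission.
#'
#' @param ws A `workspace`.
#' @param actor User id.
#' @param pool Pool key: `"user:<id>"` or `"group:<id>"`.
#' @param intent `"read"` or `"update"`.
#' @return `TRUE` or `FALSE`; never errors on unknown combinations.
#' @export
check_access <- function(ws, actor, pool, intent = c("read", "update")) {
  check_workspace(ws)
  intent <- match.arg(intent)
  if (startsWith(pool, "user:")) {
    return(identical(pool, pool_key_user(actor)))
  }
  if (startsWith(pool, "group:")) {
    gid <- sub("^group:", "", pool)
    g <- ws$groups[[gid]]
    if (is.null(g)) return(FALSE)
    lvl <- member_level(g, actor)
    if (intent == "update") return(identical(lvl, "COORDINATOR"))
    return(!is.na(lvl) || isTRUE(g$public))
  }
  FALSE
}

# deep, self-contained copy of a container and its snapshots
freeze_container <- function(ws, container_id) {
  co <- get_container(ws, container_id)
  snaps <- Filter(function(s) s$container == container_id, ws$snapshots)
  list(
    id = co$id, species = co$species, name = co$name,
    description = co$description, color = co$color,
    snapshots = lapply(unname(snaps), function(s) {
      list(id = s$id, parent = s$parent, label = s$label,
           content = es_triple(s$content))
    })
  )
}

#' Store an analysis result in a user's private pool
#'
#' Module results (an interaction network, an enrichment table, a
#' translation, ...) are kept as process entries: the module name, the input
#' descriptor that reproduces the payload given the same bundle, and the
#' payload itself.
#'
#' @param ws A `workspace`.
#' @param actor Owning user.
#' @param module Module name, e.g. `"network"`, `"enrichment"`,
#'   `"translation"`.
#' @param descriptor List describing the inputs (snapshot id, parameters).
#' @param payload The result object.
#' @return The process entry id.
#' @export
pool_store_process <- function(ws, actor, module, descriptor, payload) {
  check_workspace(ws); check_user(ws, actor)
  id <- sprintf("P%d", ws$next_process)
  ws$next_process <- ws$next_process + 1L
  key <- pool_key_user(actor)
  ws$pools[[key]]$processes[[id]] <-
    list(id = id, module = module, descriptor = descriptor, payload = payload,
         owner = actor, created_at = format_time(ws$clock()))
  log_action(ws, actor, NA_character_, "pool_store_process",
             list(process = id, module = module), list(kind = "none"))
  id
}

#' Publish an item from a private pool to a group pool
#'
#' Only group coordinators may publish (pool update is a coordinator right).
#' The published entry is an immutable copy frozen at publish time: later
#' edits to the source container or process never alter it. Containers are
#' resolved from the actor's private holdings (containers the actor owns or
#' previously copied in); processes by their entry id.
#'
#' @param ws A `workspace`.
#' @param actor Publishing user (must be COORDINATOR of `group`).
#' @param item A container id (`"C.."`), a process id (`"P.."`) or a pool
#'   entry id from the actor's private pool.
#' @param group Group id.
#' @return The new group-pool entry id.
#' @export
pool_publish <- function(ws, actor, item, group) {
  check_workspace(ws); check_user(ws, actor)
  g <- get_group(ws, group)
  if (!is_coordinator(g, actor)) {
    stop_auth("user '%s' may not publish to group '%s': coordinator level required",
              actor, group)
  }
  frozen <- freeze_item(ws, actor, item)
  id <- sprintf("E%d", ws$next_entry)
  ws$next_entry <- ws$next_entry + 1L
  key <- pool_key_group(group)
  entry <- list(id = id, item = frozen$value, type = frozen$type,
                published_by = actor, published_at = format_time(ws$clock()))
  if (frozen$type == "container") {
    ws$pools[[key]]$containers[[id]] <- entry
  } else {
    ws$pools[[key]]$processes[[id]] <- entry
  }
  log_action(ws, actor, NA_character_, "pool_publish",
             list(group = group, item = item, entry = id), list(kind = "none"))
  id
}

freeze_item <- function(ws, actor, item) {
  priv <- ws$pools[[pool_key_user(actor)]]
  if (item %in% names(priv$processes)) {
    v <- priv$processes[[item]]
    return(list(type = "process", value = v$item %||% v))
  }
  if (item %in% names(priv$containers)) {
    return(list(type = "container", value = priv$containers[[item]]$item))
  }
  if (item %in% names(ws$containers)) {
    co <- get_container(ws, item)
    if (!identical(co$owner, actor)) {
      stop_auth("container '%s' is not in the private pool of '%s'", item, actor)
    }
    return(list(type = "container", value = freeze_container(ws, item)))
  }
  stop_lookup("item '%s' not found in the private pool of '%s'", item, actor)
}

#' Copy a group-pool entry into a private pool
#'
#' Reading a group pool requires membership at any level, or a public
#' group. The copy is deep and independent: curating it never touches the
#' published entry.
#'
#' @param ws A `workspace`.
#' @param actor Copying user.
#' @param group Group id.
#' @param entry Entry id in the group pool.
#' @return The id of the new private-pool entry.
#' @export
pool_copy <- function(ws, actor, group, entry) {
  check_workspace(ws); check_user(ws, actor)
  g <- get_group(ws, group)
  if (!check_access(ws, actor, pool_key_group(group), "read")) {
    stop_auth("user '%s' may not read the pool of group '%s'", actor, group)
  }
  pool <- ws$pools[[pool_key_group(group)]]
  src <- pool$containers[[entry]] %||% pool$processes[[entry]]
  if (is.null(src)) stop_lookup("no entry '%s' in the pool of group '%s'", entry, group)
  id <- sprintf("E%d", ws$next_entry)
  ws$next_entry <- ws$next_entry + 1L
  key <- pool_key_user(actor)
  copy <- list(id = id, item = src$item, type = src$type,
               copied_from = paste0(group, "/", entry),
               copied_at = format_time(ws$clock()))
  if (src$type == "container") {
    ws$pools[[key]]$containers[[id]] <- copy
  } else {
    ws$pools[[key]]$processes[[id]] <- copy
  }
  log_action(ws, actor, NA_character_, "pool_copy",
             list(group = group, entry = entry, copy = id), list(kind = "none"))
  id
}

#' List the entries of a pool
#' @param ws A `workspace`.
#' @param pool Pool key (`"user:<id>"` or `"group:<id>"`).
#' @return Tibble of entry ids, types and provenance.
#' @export
pool_entries <- function(ws, pool) {
  check_workspace(ws)
  p <- ws$pools[[pool]] %||% stop_lookup("unknown pool '%s'", pool)
  entries <- c(p$containers, p$processes)
  tibble(
    entry = names(entries) %||% character(),
    type = vapply(entries, function(e) e$type %||% "process", ""),
    published_by = vapply(entries, function(e)
      e$published_by %||% e$owner %||% NA_character_, "")
  )
}
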