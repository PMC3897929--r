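test_that("containers are species-bound and snapshot trees live inside them", {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  cid <- container_create(ws, "A", name = "container I")
  expect_equal(containers(ws)$n_snapshots, 0L)
  expect_error(container_create(ws, "X"), class = "snapsets_lookup_error")
  # duplicate names allowed: ids are system-assigned
  cid2 <- container_create(ws, "A", name = "container I")
  expect_false(identical(cid, cid2))

  root <- snapshot_create(ws, cid)
  expect_length(snapshot_content(ws, root)$genes, 0L)
  expect_error(snapshot_create(ws, cid2, parent = root),
               class = "snapsets_validation_error")
})

test_that("branching copies content; children never write back to parents", {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  cid <- container_create(ws, "A")
  a <- snapshot_create(ws, cid, label = "a")
  snap_add(ws, a, c("g1", "g2", "g3"))
  b <- snapshot_create(ws, cid, parent = a, label = "b")
  expect_equal(snapshot_content(ws, b)$genes, c("g1", "g2", "g3"))

  snap_add(ws, b, "p4_1")
  expect_equal(snapshot_content(ws, a)$genes, c("g1", "g2", "g3"))
  expect_length(snapshot_content(ws, a)$proteins, 0L)

  snapshot_clear(ws, b)
  expect_equal(snapshot_content(ws, a)$genes, c("g1", "g2", "g3"))
  expect_length(snapshot_content(ws, b)$genes, 0L)
})

test_that("copy clears and removes respect tree integrity", {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  cid <- container_create(ws, "A")
  a <- snapshot_create(ws, cid, label = "a")
  snap_add(ws, a, "g1")
  b <- snapshot_create(ws, cid, parent = a)

  cp <- snapshot_copy(ws, b)
  for (lv in c("gene", "transcript", "protein")) {
    expect_identical(es_project(snapshot_content(ws, cp), lv),
                     es_project(snapshot_content(ws, b), lv))
  }
  snapshot_clear(ws, cp)
  expect_equal(es_project(snapshot_content(ws, cp), "gene"), character())

  expect_error(snapshot_remove(ws, a), "child",
               class = "snapsets_validation_error")
  snapshot_remove(ws, cp)
  expect_error(snapshot_content(ws, cp), class = "snapsets_lookup_error")
})

test_that("import is atomic and export/import round-trips per level", {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  cid <- container_create(ws, "A")
  a <- snapshot_create(ws, cid, label = "a")

  f <- tempfile()
  writeLines(c("g1", "g2", "g3"), f)
  import_set(ws, a, f)
  expect_equal(snapshot_content(ws, a)$genes, c("g1", "g2", "g3"))

  bad <- tempfile()
  writeLines(c("g4", "bogus1", "bogus2"), bad)
  err <- expect_error(import_set(ws, a, bad), class = "snapsets_lookup_error")
  expect_match(conditionMessage(err), "bogus1")
  expect_match(conditionMessage(err), "bogus2")
  expect_equal(snapshot_content(ws, a)$genes, c("g1", "g2", "g3"))  # unchanged

  out <- tempfile()
  export_set(ws, a, "gene", out)
  b <- snapshot_create(ws, cid, label = "fresh")
  import_set(ws, b, out)
  expect_true(es_compare(snapshot_content(ws, a),
                         snapshot_content(ws, b), "gene")$equal)
})

test_that("history is append-only, filterable, and lineage replay is exact", {
  fx <- fig1_workspace()
  ws <- fx$ws; al <- fx$al
  h <- ws_history(ws)
  expect_true(all(diff(h$seq) > 0))
  expect_gt(nrow(h), 10L)

  only_b <- ws_history(ws, snapshot = al[["b"]])
  expect_true(all(only_b$snapshot == al[["b"]]))

  ws2 <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  expect_equal(nrow(ws_history(ws2)), 0L)
  cid <- container_create(ws2, "A", actor = "user1")
  s <- snapshot_create(ws2, cid, actor = "user2")
  by_actor <- ws_history(ws2, actor = "user1")
  expect_equal(by_actor$action, "container_create")

  for (snap in al[c("a", "b", "c", "d", "e", "f", "g")]) {
    expect_true(snapsets:::es_equal(replay_history(ws, snap),
                                    snapshot_content(ws, snap)))
  }
})

test_that("replay stays exact even when an ancestor mutates after branching", {
  ws <- workspace(fig1_bundle_loaded(), clock = fixed_clock())
  cid <- container_create(ws, "A")
  a <- snapshot_create(ws, cid, label = "a")
  snap_add(ws, a, "g1")
  b <- snapshot_create(ws, cid, parent = a, label = "b")
  snap_add(ws, a, "g5")             # parent moves on after the branch
  snap_add(ws, b, "g2")
  c <- snapshot_create(ws, cid, parent = a, label = "c")
  snap_union(ws, b, c)              # operand recorded at call time
  snap_add(ws, c, "g3")             # operand changes later
  for (s in c(a, b, c)) {
    expect_true(snapsets:::es_equal(replay_history(ws, s),
                                    snapshot_content(ws, s)))
  }
  expect_equal(snapshot_content(ws, b)$genes, c("g1", "g2", "g5"))
})

test_that("no snapshot is its own ancestor and each reaches exactly one root", {
  fx <- fig1_workspace()
  ws <- fx$ws
  for (id in names(ws$snapshots)) {
    seen <- character()
    cur <- id
    while (!is.null(cur)) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- ws$snapshots[[cur]]$parent
    }
    expect_null(ws$snapshots[[seen[length(seen)]]]$parent)
  }
})

test_that("workspace state survives save/load byte-identically", {
  fx <- fig1_workspace()
  ws <- fx$ws
  container_comment(ws, "C1", "first pass done", actor = "user1")
  for (u in c("user1", "user2")) user_create(ws, u)
  g <- group_create(ws, "user1", "team", public = TRUE)
  pid <- pool_store_process(ws, "user1", "network",
                            list(snapshot = fx$al[["c"]], hops = 1),
                            list(nodes = c("p1_1", "p4_1")))
  pool_publish(ws, "user1", pid, g)

  d1 <- tempfile(); d2 <- tempfile()
  ws_save(ws, d1)
  ws2 <- ws_load(d1, fig1_bundle_loaded())
  ws_save(ws2, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  # semantic equality of the reloaded state
  for (s in names(ws$snapshots)) {
    expect_true(snapsets:::es_equal(snapshot_content(ws, s),
                                    snapshot_content(ws2, s)))
    expect_true(snapsets:::es_equal(replay_history(ws2, s),
                                    snapshot_content(ws2, s)))
  }
  expect_equal(ws_history(ws2)$action, ws_history(ws)$action)
})
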