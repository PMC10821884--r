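test_that("YAML parsing enforces mandatory fields and the operation vocabulary", {
  minimal <- "author: ada\ndate: 2024-01-01T00:00:00Z\nroot_model: toy3\nmodifications:\n  - target: R1\n    operation: knockout\n"
  mf <- parse_modification_file(minimal, file_name = "m1")
  expect_null(mf$parent)
  expect_length(mf$entries, 1)
  expect_equal(mf$entries[[1]]$operation, "knockout")

  with_parent <- paste0(minimal, "parent: modA\n")
  expect_equal(parse_modification_file(with_parent)$parent, "modA")

  no_root <- "author: ada\ndate: 2024-01-01T00:00:00Z\nmodifications: []\n"
  expect_error(parse_modification_file(no_root), class = "fluxtrace_format_error")

  bad_op <- "author: a\ndate: d\nroot_model: m\nmodifications:\n  - target: R1\n    operation: teleport\n"
  expect_error(parse_modification_file(bad_op), class = "fluxtrace_format_error")

  bad_payload <- "author: a\ndate: d\nroot_model: m\nmodifications:\n  - target: R1\n    operation: set_bounds\n    lower: 5\n    upper: 0\n"
  expect_error(parse_modification_file(bad_payload), class = "fluxtrace_format_error")
})

test_that("serialisation is canonical: parse-serialize round trips are byte-stable", {
  for (seed in 1:5) {
    fx <- generate_lineage_fixture(depth = 2, entries_per_file = 3, seed = seed)
    for (f in fx$files) {
      y1 <- serialize_modification_file(f)
      f2 <- parse_modification_file(y1, file_name = f$file_name)
      expect_identical(serialize_modification_file(f2), y1)
      expect_equal(f2$entries, f$entries)
      expect_identical(f2$parent, f$parent)
    }
  }
})

test_that("lineage expansion appends ancestors first and detects broken chains", {
  store <- local_toy_store()
  p <- store_mod(store, "P", "toy3", list(ko("R1")))
  c1 <- store_mod(store, "C", "toy3", list(sb("EX_out", 0, 5)), parent = "P")

  expanded <- resolve_lineage(c1, store)
  expect_equal(vapply(expanded, function(e) e$target, ""), c("R1", "EX_out"))

  # grandparent chain unrolls ancestors-first
  g <- store_mod(store, "G2", "toy3", list(ko("EX_up")))
  p2 <- store_mod(store, "P2", "toy3", list(ko("R1")), parent = "G2")
  c2 <- store_mod(store, "C2", "toy3", list(sb("EX_out", 0, 5)), parent = "P2")
  expect_equal(vapply(resolve_lineage(c2, store), function(e) e$target, ""),
               c("EX_up", "R1", "EX_out"))

  orphan <- modification_file("orphan", "t", "toy3", list(ko("R1")),
                              parent = "missing")
  expect_error(resolve_lineage(orphan, store),
               class = "fluxtrace_reference_error")

  expect_error(put_modification_file(store, modification_file(
    "selfie", "t", "toy3", list(ko("R1")), parent = "selfie")),
    class = "fluxtrace_reference_error")
})

test_that("a self- or mutually-parented chain raises a lineage error", {
  store <- local_toy_store()
  # write files that reference each other by hand (bypassing put's checks)
  for (nm in c("cycA", "cycB")) {
    other <- setdiff(c("cycA", "cycB"), nm)
    writeLines(serialize_modification_file(modification_file(
      nm, "t", "toy3", list(ko("R1")), parent = other)),
      file.path(store$dir, "mods", paste0(nm, ".yaml")))
  }
  expect_error(resolve_lineage("cycA", store), class = "fluxtrace_lineage_error")
})

test_that("lineage expansion equals brute-force concatenation on random trees", {
  for (seed in 1:20) {
    depth <- 1 + (seed %% 5)
    store <- local_store()
    fx <- generate_lineage_fixture(depth = depth, entries_per_file = 2, seed = seed)
    register_model(store, write_sbml_model(fx$model), fx$model$model_id)
    for (f in fx$files) put_modification_file(store, f)

    # oracle: materialise the ancestor list explicitly, concatenate in order
    oracle <- unlist(lapply(fx$files, function(f)
      lapply(f$entries, entry_sig)))
    got <- vapply(resolve_lineage(fx$files[[depth]], store), entry_sig, "")
    expect_identical(got, as.character(oracle))
    expect_length(got, depth * 2)
  }
})

test_that("the last file loaded wins, per target, and order reversal flips conflicts", {
  store <- local_toy_store()
  f1 <- store_mod(store, "F1", "toy3", list(sb("R1", 0, 5)))
  f2 <- store_mod(store, "F2", "toy3", list(ko("R1")))

  s12 <- resolve_effective_state(list(f1, f2), store)
  expect_equal(nrow(s12), 1)
  expect_equal(s12$operation, "knockout")
  expect_equal(s12$provenance, "F2")
  expect_equal(s12$load_index, 2L)

  s21 <- resolve_effective_state(list(f2, f1), store)
  expect_equal(s21$operation, "set_bounds")
  expect_equal(s21$lower, 0)
  expect_equal(s21$upper, 5)
  expect_equal(s21$provenance, "F1")

  # disjoint targets: one winner each
  f3 <- store_mod(store, "F3", "toy3", list(ko("EX_out")))
  s <- resolve_effective_state(list(f2, f3), store)
  expect_equal(nrow(s), 2)
  expect_setequal(s$target, c("R1", "EX_out"))

  # within one file, the later entry wins
  f4 <- store_mod(store, "F4", "toy3", list(sb("R1", 0, 1), sb("R1", 0, 2)))
  s4 <- resolve_effective_state(list(f4), store)
  expect_equal(s4$upper, 2)

  other <- generate_toy_model("parallel", 2)
  register_model(store, other$sbml, "par2")
  f5 <- store_mod(store, "F5", "par2", list(ko("R1")))
  expect_error(resolve_effective_state(list(f1, f5), store),
               class = "fluxtrace_consistency_error")
})

test_that("diffs partition lineage-expanded entry lists", {
  store <- local_toy_store()
  a <- store_mod(store, "A", "toy3", list(ko("R1"), ko("EX_out")))
  b <- store_mod(store, "B", "toy3", list(ko("EX_out"), sb("EX_up", -5, 0)))

  d <- diff_modification_files(a, b, store)
  expect_equal(vapply(d$only_in_a, entry_sig, ""), entry_sig(ko("R1")))
  expect_equal(vapply(d$common, entry_sig, ""), entry_sig(ko("EX_out")))
  expect_equal(vapply(d$only_in_b, entry_sig, ""), entry_sig(sb("EX_up", -5, 0)))

  dd <- diff_modification_files(a, a, store)
  expect_length(dd$only_in_a, 0)
  expect_length(dd$only_in_b, 0)
  expect_length(dd$common, 2)

  # child vs parent: own entries vs inherited entries
  child <- store_mod(store, "childA", "toy3", list(sb("R1", 0, 7)), parent = "A")
  dc <- diff_modification_files(child, a, store)
  expect_equal(vapply(dc$only_in_a, entry_sig, ""), entry_sig(sb("R1", 0, 7)))
  expect_length(dc$common, 2)
  expect_length(dc$only_in_b, 0)

  # partitions are exhaustive when entries are unique
  ea <- resolve_lineage(child, store)
  expect_equal(length(dc$only_in_a) + length(dc$common), length(ea))
})

test_that("saving records the parent, the unshared earlier entries, then the session", {
  store <- local_toy_store()
  f1 <- store_mod(store, "S1", "toy3", list(ko("R1")))
  f2 <- store_mod(store, "S2", "toy3", list(ko("EX_out")))

  saved <- save_modification_file(store, loaded = list(f1, f2),
                                  session_entries = list(sb("EX_up", -3, 0)),
                                  author = "ada", file_name = "S3")
  expect_equal(saved$parent, "S2")
  expect_equal(vapply(saved$entries, entry_sig, ""),
               c(entry_sig(ko("R1")), entry_sig(sb("EX_up", -3, 0))))

  # no loads: no parent, session only
  s0 <- save_modification_file(store, loaded = list(),
                               session_entries = list(ko("R1")),
                               author = "ada", file_name = "S0",
                               root_model = "toy3")
  expect_null(s0$parent)
  expect_length(s0$entries, 1)

  # pure checkpoint: parent only, no entries
  chk <- save_modification_file(store, loaded = list("S2"),
                                session_entries = list(),
                                author = "ada", file_name = "CHK")
  expect_equal(chk$parent, "S2")
  expect_length(chk$entries, 0)

  expect_error(save_modification_file(store, list(), list(ko("R1")),
                                      "ada", "S0", root_model = "toy3"),
               class = "fluxtrace_conflict_error")
  expect_error(save_modification_file(store, list(), list(ko("GHOST")),
                                      "ada", "SX", root_model = "toy3"),
               class = "fluxtrace_consistency_error")
})

test_that("loading only the saved file reproduces the session's effective state", {
  # includes the adversarial case: an earlier file overridden by the parent
  cases <- list(
    list(files = list(list("R1", "ko"), list("EX_out", "ko")),
         session = list(sb("EX_up", -3, 0))),
    list(files = list(list("R1", "sb"), list("R1", "ko")),
         session = list()),
    list(files = list(list("R1", "ko"), list("R1", "sb"), list("EX_out", "sb")),
         session = list(ko("R1"))))
  for (ci in seq_along(cases)) {
    store <- local_toy_store()
    case <- cases[[ci]]
    loaded <- list()
    for (i in seq_along(case$files)) {
      spec <- case$files[[i]]
      e <- if (spec[[2]] == "ko") ko(spec[[1]]) else sb(spec[[1]], 0, i)
      loaded[[i]] <- store_mod(store, sprintf("L%d", i), "toy3", list(e))
    }
    want <- resolve_effective_state(c(loaded, list(modification_file(
      "session", "s", "toy3", case$session))), store)

    saved <- save_modification_file(store, loaded = loaded,
                                    session_entries = case$session,
                                    author = "s", file_name = "SAVED")
    got <- resolve_effective_state(list(saved), store)
    expect_equal(got[, c("target", "operation", "lower", "upper")],
                 want[, c("target", "operation", "lower", "upper")],
                 info = sprintf("case %d", ci))
  }
})
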