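test_that("dump parsing handles headers, line numbers and field trimming", {
  p <- write_dump(c(dump_line("A", ichi(1)), dump_line("B", ichi(2)),
                    dump_line(" C ", ichi(3))))
  out <- parse_source_dump(p)
  expect_identical(out$line_no, 1:3)
  expect_identical(out$src_compound_id, c("A", "B", "C"))

  ph <- write_dump(c("SRC_COMPOUND_ID\tstandardinchi\tstandardinchikey",
                     dump_line("A", ichi(1))))
  outh <- parse_source_dump(ph)
  expect_identical(outh$line_no, 2L)
  expect_identical(nrow(outh), 1L)
})

test_that("a wrong column count is a parse error naming the line", {
  p <- write_dump(c(dump_line("A", ichi(1)), paste("B", ichi(2), sep = "\t")))
  expect_error(parse_source_dump(p), "line 2", class = "chemxref_parse_error")
})

test_that("exact duplicate lines collapse to one record with a comment", {
  l <- dump_line("A", ichi(1))
  p <- write_dump(c(l, dump_line("B", ichi(2)), l))
  out <- parse_source_dump(p)
  expect_identical(nrow(out), 2L)
  cmt <- dump_comments(out)
  expect_identical(cmt$line_no, 3L)
  expect_match(cmt$comment, "duplicate of line 1")
})

test_that("a fresh release creates only current assignments", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  rep <- load_release(st, s, recs(c("A", "B", "C"), ichi(1:3)), "v1")
  expect_identical(rep$n_accepted, 3L)
  expect_identical(rep$n_new_structures, 3L)
  expect_identical(rep$n_new_assignments, 3L)
  expect_identical(rep$n_to_obsolete, 0L)
  df <- tidy(st)
  expect_true(all(df$status == "current"))
  expect_true(all(is.na(df$last_release_u_current)))
})

test_that("dropped assignments obsolesce with the source's previous release recorded", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  r1 <- load_release(st, s, recs(c("A", "B"), ichi(1:2)), "v1")
  r2 <- load_release(st, s, recs("A", ichi(1)), "v2")
  expect_identical(r2$n_to_obsolete, 1L)
  df <- tidy(st)
  b <- df[df$src_compound_id == "B", ]
  expect_identical(b$status, "obsolete")
  expect_identical(b$last_release_u_current, r1$release_u)
  expect_identical(df[df$src_compound_id == "A", ]$status, "current")
})

test_that("a re-appearing assignment flips back to current, and only the most
           recent obsolescence is tracked", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  with_b <- recs(c("A", "B"), ichi(1:2))
  without_b <- recs("A", ichi(1))
  load_release(st, s, with_b, "v1")       # release 1: B current
  load_release(st, s, without_b, "v2")    # release 2: B obsolete (last cur 1)
  r3 <- load_release(st, s, with_b, "v3") # release 3: B current again
  expect_identical(r3$n_to_current, 1L)
  b <- tidy(st)[tidy(st)$src_compound_id == "B", ]
  expect_identical(b$status, "current")
  expect_true(is.na(b$last_release_u_current))

  load_release(st, s, without_b, "v4")    # release 4: B obsolete again
  b <- tidy(st)[tidy(st)$src_compound_id == "B", ]
  expect_identical(b$status, "obsolete")
  # the first obsolescence (after release 1) is overwritten by the second
  expect_identical(b$last_release_u_current, r3$release_u)
})

test_that("reloading the same dump is a state no-op", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  r <- recs(c("A", "B"), ichi(1:2))
  load_release(st, s, r, "v1")
  before <- store_assignment_state(st)
  rep2 <- load_release(st, s, r, "v1-again")
  expect_identical(rep2$n_new_assignments, 0L)
  expect_identical(rep2$n_new_structures, 0L)
  expect_identical(rep2$n_to_obsolete, 0L)
  expect_identical(rep2$n_to_current, 0L)
  expect_identical(as.data.frame(store_assignment_state(st)), as.data.frame(before))
})

test_that("conflicting rows in one release load as parallel current assignments", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  rep <- load_release(st, s, recs(c("A", "A"), ichi(1:2)), "v1")
  expect_identical(rep$n_new_assignments, 2L)
  df <- tidy(st)
  expect_identical(nrow(df), 2L)
  expect_true(all(df$status == "current"))
  expect_identical(unique(df$src_compound_id), "A")
})

test_that("an empty accepted set is refused without explicit confirmation", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  load_release(st, s, recs("A", ichi(1)), "v1")
  empty <- recs(character(0), character(0), character(0))
  expect_error(load_release(st, s, empty, "v2"), class = "chemxref_guard")
  # state untouched by the refused load
  expect_identical(glance(st)$n_releases, 1L)
  rep <- load_release(st, s, empty, "v2", allow_empty = TRUE)
  expect_identical(rep$n_to_obsolete, 1L)
})

test_that("loading into an unregistered source is a not-found error", {
  st <- new_mock_store()
  on.exit(store_close(st))
  expect_error(load_release(st, 5L, recs("A", ichi(1)), "v1"),
               class = "chemxref_not_found")
})

test_that("per-rule rejection counts and comments are retained in the release table", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  long_inchi <- paste0("InChI=1S/", strrep("C", 2001 - 9))
  rows <- tibble::tibble(
    src_compound_id = c("OK1", "NOKEY", "A1", "A2", "A3", "", "A5"),
    std_inchi = c(ichi(1), ichi(2), ichi(3), "", "not-an-inchi", ichi(4), long_inchi),
    std_inchikey = c(mock_key(ichi(1)), "", "AAAAAAAAAAAAAA-AAAAAAAASA-N", "", "", "", ""))
  rep <- load_release(st, s, rows, "v1")
  expect_identical(rep$n_parsed, 7L)
  expect_identical(rep$n_accepted, 2L)
  expect_identical(unname(rep$n_rejected_by_rule), rep(1L, 5))
  expect_identical(rep$n_parsed, rep$n_accepted + sum(rep$n_rejected_by_rule))
  expect_match(rep$comments$comment, "absent", all = FALSE)

  persisted <- DBI::dbGetQuery(st$con, "SELECT * FROM UC_RELEASE WHERE RELEASE_U = 1")
  expect_identical(as.integer(persisted[paste0("N_REJ_R", 1:5)]), rep(1L, 5))
  n_comments <- DBI::dbGetQuery(st$con, "SELECT COUNT(*) AS N FROM UC_COMMENTS")$N
  expect_true(n_comments >= 1)
})

test_that("assignments are append-only and the triple set only grows across loads", {
  spec <- universe_spec(n_structures = 50L, seed = 11L)
  man <- make_history(spec)
  st <- new_mock_store()
  on.exit(store_close(st))
  for (s in unique(man$src_index)) add_source(st, man$source_name[man$src_index == s][1])
  prev <- triples(st)
  for (i in seq_len(nrow(man))) {
    load_dump(st, man$source_name[i], man$path[i], man$version_label[i],
              allow_empty = TRUE)
    cur <- triples(st)
    expect_true(all(prev %in% cur))  # superset, never shrinking
    prev <- cur
  }
})

test_that("rollback restores the exact pre-load assignment snapshot", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  load_release(st, s, recs(c("A", "B"), ichi(1:2)), "v1")
  pre <- store_assignment_state(st)
  pre_triples <- triples(st)

  rep <- load_release(st, s, recs(c("A", "C"), ichi(c(1, 5))), "v2")
  expect_false(identical(as.data.frame(store_assignment_state(st)), as.data.frame(pre)))
  rb <- rollback_release(st, rep$release_u)
  expect_identical(rb$action, "rollback")
  expect_identical(as.data.frame(store_assignment_state(st)), as.data.frame(pre))
  expect_identical(triples(st), pre_triples)

  # structures registered by the rolled-back release survive (immutability)
  expect_identical(nrow(search_structure(st, ichi(5), "inchi")), 0L)
  uci <- DBI::dbGetQuery(st$con, "SELECT UCI FROM UC_STRUCTURES WHERE STANDARDINCHI = ?",
                         params = list(ichi(5)))$UCI
  expect_identical(length(uci), 1L)
})

test_that("only the most recent load of a source can be rolled back", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  r1 <- load_release(st, s, recs("A", ichi(1)), "v1")
  r2 <- load_release(st, s, recs("B", ichi(2)), "v2")
  expect_error(rollback_release(st, r1$release_u),
               class = "chemxref_unsupported_rollback")
  rollback_release(st, r2$release_u)
  expect_error(rollback_release(st, r2$release_u),
               class = "chemxref_unsupported_rollback")
  # after undoing r2, r1 is the latest effective load again
  rb <- rollback_release(st, r1$release_u)
  expect_identical(rb$n_assignments_removed, 1L)
  expect_identical(nrow(tidy(st)), 0L)
  expect_error(rollback_release(st, 99L), class = "chemxref_not_found")
})

test_that("current assignments always equal the latest release's accepted pairs", {
  spec <- universe_spec(n_structures = 40L, seed = 3L,
                        churn_rates = c(p_drop = 0.3, p_add = 0.2, p_reappear = 0.4))
  man <- make_history(spec)
  st <- new_mock_store()
  on.exit(store_close(st))
  load_history(st, man)
  for (s in unique(man$src_index)) {
    sub <- man[man$src_index == s, ]
    last <- sub[nrow(sub), ]
    out <- validate_records(parse_source_dump(last$path), mock_be)
    expected <- unique(paste(out$src_compound_id[out$accepted],
                             out$std_inchi[out$accepted], sep = "\r"))
    df <- tidy(st)
    got <- df[df$source_name == last$source_name & df$status == "current", ]
    expect_setequal(paste(got$src_compound_id, got$std_inchi, sep = "\r"), expected)
  }
})

test_that("load reports tidy, glance and serialize to JSON", {
  st <- new_mock_store()
  on.exit(store_close(st))
  s <- add_source(st, "src")
  rep <- load_release(st, s, recs(c("A", "B"), ichi(1:2)), "v1")
  td <- tidy(rep)
  expect_identical(td$rule, paste0("R", 1:5))
  expect_identical(sum(td$n_rejected), 0L)
  g <- glance(rep)
  expect_identical(g$n_parsed, 2L)
  parsed <- jsonlite::fromJSON(load_report_json(rep))
  expect_identical(parsed$release_u, 1L)
  expect_identical(parsed$n_rejected_by_rule$R1, 0L)
})
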