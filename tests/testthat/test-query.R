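# shared fixture store: the benzodiazepine scenario under the mock backend
local_diazepam_store <- function(env = parent.frame()) {
  st <- new_mock_store()
  withr::defer(store_close(st), envir = env)
  man <- diazepam_fixture(backend = "mock")
  load_history(st, man)
  st
}

test_that("identifier lookup returns all structurally equivalent identifiers", {
  st <- local_diazepam_store()
  rows <- lookup(st, "CHEMBL12", 1)
  expect_identical(nrow(rows), 3L)
  expect_identical(rows$src_compound_id, c("CHEMBL12", "DB00829", "DB07699"))
  expect_identical(rows$status, c("current", "current", "obsolete"))
  expect_identical(length(unique(rows$uci)), 1L)    # one shared structure
  expect_true("CHEMBL12" %in% rows$src_compound_id) # the query row itself
})

test_that("current-only lookup drops exactly the obsolete assignments", {
  st <- local_diazepam_store()
  all_rows <- lookup(st, "CHEMBL12", 1, mode = "all")
  cur_rows <- lookup(st, "CHEMBL12", 1, mode = "current")
  dropped <- dplyr::anti_join(all_rows, cur_rows,
                              by = c("src_compound_id", "src_id", "uci"))
  expect_identical(dropped$src_compound_id, "DB07699")
  expect_true(all(cur_rows$status == "current"))
})

test_that("source-restricted current lookup retrieves the single DrugBank record", {
  st <- local_diazepam_store()
  rows <- lookup(st, "CHEMBL12", 1, mode = "current", target_src_id = 2)
  expect_identical(nrow(rows), 1L)
  expect_identical(rows$src_compound_id, "DB00829")
})

test_that("unknown identifiers give empty results; unknown sources give errors", {
  st <- local_diazepam_store()
  expect_identical(nrow(lookup(st, "NOPE", 1)), 0L)
  expect_error(lookup(st, "CHEMBL12", 42), class = "chemxref_not_found")
  expect_error(lookup(st, "CHEMBL12", 1, target_src_id = 42),
               class = "chemxref_not_found")
})

test_that("a fully obsolete identifier anchors historically in mode=all, empty in current", {
  st <- local_diazepam_store()
  rows_all <- lookup(st, "DB07699", 2, mode = "all")
  expect_identical(rows_all$src_compound_id, c("CHEMBL12", "DB00829", "DB07699"))
  expect_identical(nrow(lookup(st, "DB07699", 2, mode = "current")), 0L)
})

test_that("URL lookup prepends the target source's base URL", {
  st <- local_diazepam_store()
  urls <- lookup_as_urls(st, "CHEMBL661", 1, 3)
  expect_identical(
    urls, "http://www.ebi.ac.uk/pdbe-srv/pdbechem/chemicalCompound/show/DIZ")
  expect_identical(lookup_as_urls(st, "CHEMBL12", 1, 3), character(0))  # no match
  expect_error(lookup_as_urls(st, "CHEMBL661", 1, 2),                   # no base URL
               class = "chemxref_unsupported_urls")
})

test_that("structure search by InChIKey equals the identifier lookup route", {
  st <- local_diazepam_store()
  by_id <- lookup(st, "CHEMBL12", 1, mode = "all")
  by_key <- search_structure(st, by_id$std_inchikey[[1]], "inchikey", mode = "all")
  by_inchi <- search_structure(st, by_id$std_inchi[[1]], "inchi", mode = "all")
  expect_identical(as.data.frame(by_key), as.data.frame(by_id))
  expect_identical(as.data.frame(by_inchi), as.data.frame(by_id))
})

test_that("structure search validates key shape and handles absent keys", {
  st <- local_diazepam_store()
  expect_error(search_structure(st, strrep("A", 26), "inchikey"),
               class = "chemxref_validation")
  expect_error(search_structure(st, paste0(strrep("A", 25), "-", "B"), "inchikey"),
               class = "chemxref_validation")
  absent <- "ZZZZZZZZZZZZZZ-ZZZZZZZZSA-N"
  expect_identical(nrow(search_structure(st, absent, "inchikey")), 0L)
  expect_identical(nrow(search_structure(st, ichi(99), "inchi")), 0L)
})

test_that("whole-source mapping joins on shared structures, both modes", {
  st <- local_diazepam_store()
  cur <- whole_source_mapping(st, 1, 2, mode = "current")
  expect_identical(as.data.frame(cur),
                   data.frame(from_id = "CHEMBL12", to_id = "DB00829"))
  all_pairs <- whole_source_mapping(st, 1, 2, mode = "all")
  expect_identical(all_pairs$to_id, c("DB00829", "DB07699"))
  expect_error(whole_source_mapping(st, 1, 99), class = "chemxref_not_found")
})

test_that("mapping a source to itself includes identity pairs", {
  st <- local_diazepam_store()
  self_map <- whole_source_mapping(st, 2, 2, mode = "all")
  expect_true(all(c("DB00829", "DB07699") %in% self_map$from_id))
  expect_true(nrow(self_map) == 4L)  # 2 ids x 2 ids on one structure
})

test_that("mapping is symmetric and matches a brute-force join on a random universe", {
  spec <- universe_spec(n_structures = 50L, seed = 19L, p_shared_structure = 0.6)
  man <- make_history(spec)
  st <- new_mock_store()
  withr::defer(store_close(st))
  load_history(st, man)

  ab <- whole_source_mapping(st, 1, 2, mode = "current")
  ba <- whole_source_mapping(st, 2, 1, mode = "current")
  expect_identical(sort(paste(ab$from_id, ab$to_id)), sort(paste(ba$to_id, ba$from_id)))

  # brute-force oracle: nested loop over current assignments joined on InChI
  df <- tidy(st)
  a <- df[df$src_id == 1 & df$status == "current", ]
  b <- df[df$src_id == 2 & df$status == "current", ]
  expected <- unique(unlist(lapply(seq_len(nrow(a)), function(i) {
    hits <- b$src_compound_id[b$std_inchi == a$std_inchi[i]]
    if (length(hits)) paste(a$src_compound_id[i], hits, sep = "\t")
  })))
  expect_setequal(paste(ab$from_id, ab$to_id, sep = "\t"), expected %||% character(0))
})

test_that("lookup unions rows over all current structures of a multi-mapped id", {
  st <- new_mock_store()
  withr::defer(store_close(st))
  s1 <- add_source(st, "one"); s2 <- add_source(st, "two")
  load_release(st, s1, recs(c("X", "X"), ichi(1:2)), "v1")  # X maps to 2 structures
  load_release(st, s2, recs(c("P", "Q"), ichi(1:2)), "v1")
  rows <- lookup(st, "X", s1)
  expect_identical(sort(unique(rows$src_compound_id)), c("P", "Q", "X"))
  expect_identical(length(unique(rows$uci)), 2L)

  # equals the union of InChIKey searches over X's current structures
  keys <- unique(rows$std_inchikey[rows$src_compound_id == "X"])
  unioned <- dplyr::bind_rows(lapply(keys, search_structure, store = st,
                                     key_type = "inchikey", mode = "all"))
  unioned <- dplyr::arrange(dplyr::distinct(unioned), uci, src_id, src_compound_id)
  expect_identical(as.data.frame(unioned), as.data.frame(rows))
})

test_that("source summary surfaces latest release metadata and rejections", {
  st <- local_diazepam_store()
  sm <- source_summary(st)
  expect_identical(sm$src_id, 1:3)
  expect_identical(sm$n_releases, c(2L, 2L, 1L))
  expect_identical(sm$last_version_label, c("r2", "v2", "2013.1"))
  expect_identical(sm$last_n_rej_r1, rep(0L, 3))
  expect_true(all(!is.na(sm$last_load_date)))
})

test_that("audit view lists obsolete assignments with their last-current release", {
  st <- local_diazepam_store()
  aud <- audit_obsolete(st)
  expect_identical(nrow(aud), 1L)
  expect_identical(aud$src_compound_id, "DB07699")
  expect_identical(aud$last_release_u_current, 2L)
  expect_identical(aud$last_current_version, "v1")
})

test_that("store tidiers and autoplot produce well-formed output", {
  st <- local_diazepam_store()
  g <- glance(st)
  expect_identical(g$n_structures, 2L)
  expect_identical(g$n_current + g$n_obsolete, g$n_assignments)
  df <- tidy(st)
  expect_identical(nrow(df), g$n_assignments)
  p <- ggplot2::autoplot(st)
  expect_s3_class(p, "ggplot")
})
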