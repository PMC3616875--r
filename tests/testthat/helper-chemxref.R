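`%||%` <- function(x, y) if (is.null(x)) y else x

mock_be <- inchikey_backend("mock")
rdkit_be <- inchikey_backend("rdkit")

mock_key <- function(inchi) generate_inchikey(inchi, mock_be)

new_mock_store <- function() store_create(":memory:", backend = "mock")

# small record tibbles for direct load_release() calls (mock-backend keys)
recs <- function(ids, inchis, keys = mock_key(inchis)) {
  tibble::tibble(src_compound_id = ids, std_inchi = inchis, std_inchikey = keys)
}

# a handful of distinct valid pseudo Standard InChIs for logic tests
ichi <- function(i) sprintf("InChI=1S/C%dH%d/c1-%d/h1H", i + 1L, 2L * i + 2L, i)

write_dump <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

dump_line <- function(id, inchi, key = mock_key(inchi)) {
  paste(id, inchi, key, sep = "\t")
}

read_diaz_inchi <- function() {
  fx <- utils::read.delim(
    system.file("extdata", "inchi_fixture.tsv", package = "chemxref"),
    sep = "\t", stringsAsFactors = FALSE)
  fx$std_inchi[fx$name == "diazepam"]
}

# set of assignment triples for append-only checks
triples <- function(store) {
  df <- tidy(store)
  sort(paste(df$src_compound_id, df$src_id, df$uci, sep = "\r"))
}

expect_oracle_equal <- function(store, manifest) {
  expect_identical(
    as.data.frame(store_assignment_state(store)),
    as.data.frame(oracle_state(manifest)))
}
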