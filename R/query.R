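match_rows <- function(store, ucis, mode, target_src_id = NULL) {
  if (length(ucis) == 0) return(empty_match_rows())
  sql <- sprintf(
    "SELECT x.SRC_COMPOUND_ID AS src_compound_id, x.SRC_ID AS src_id,
            s.NAME AS source_name, x.ASSIGNMENT AS status, x.UCI AS uci,
            u.STANDARDINCHI AS std_inchi, u.STANDARDINCHIKEY AS std_inchikey
       FROM UC_XREF x
       JOIN UC_SOURCES s ON s.SRC_ID = x.SRC_ID
       JOIN UC_STRUCTURES u ON u.UCI = x.UCI
      WHERE x.UCI IN (%s)%s%s
      ORDER BY x.UCI, x.SRC_ID, x.SRC_COMPOUND_ID",
    paste(as.integer(ucis), collapse = ","),
    if (identical(mode, "current")) " AND x.ASSIGNMENT = 'current'" else "",
    if (!is.null(target_src_id)) sprintf(" AND x.SRC_ID = %d", as.integer(target_src_id)) else "")
  df <- DBI::dbGetQuery(store$con, sql)
  df$src_id <- as.integer(df$src_id)
  df$uci <- as.integer(df$uci)
  as_tibble(df)
}

empty_match_rows <- function() {
  tibble(src_compound_id = character(), src_id = integer(),
         source_name = character(), status = character(), uci = integer(),
         std_inchi = character(), std_inchikey = character())
}

query_ucis <- function(store, src_compound_id, src_id, status = NULL) {
  sql <- paste0(
    "SELECT DISTINCT UCI FROM UC_XREF WHERE SRC_COMPOUND_ID = ? AND SRC_ID = ?",
    if (!is.null(status)) " AND ASSIGNMENT = ?" else "")
  params <- c(list(src_compound_id, as.integer(src_id)), if (!is.null(status)) list(status))
  as.integer(DBI::dbGetQuery(store$con, sql, params = params)$UCI)
}

#' Find all identifiers structurally equivalent to a query identifier
#'
#' Answers "which other sources contain the same structure as
#' `src_compound_id` x from source y?". The query identifier is resolved to
#' the structures (UCIs) it is *currently* assigned to, and every assignment
#' of those structures -- across all sources, the query row included -- is
#' returned. With `mode = "all"` both current and obsolete assignments are
#' listed (status is reported per row); `mode = "current"` drops obsolete
#' rows. A query identifier with several current structures returns the
#' union of rows over all of them; the structural columns let the caller
#' cluster such output by sorting on them.
#'
#' A query identifier whose assignments are all obsolete anchors, in
#' `mode = "all"`, on the structures it was last assigned to; in
#' `mode = "current"` it is no longer assigned to anything and returns an
#' empty result. An identifier never seen at all also returns an empty
#' result (distinct from the error raised for an unregistered `src_id`).
#'
#' @param store an `xref_store`.
#' @param src_compound_id the query identifier.
#' @param src_id source of the query identifier (required: identical
#'   identifier strings may exist under different sources).
#' @param mode `"all"` (default) or `"current"`.
#' @param target_src_id optionally restrict the output rows to one source.
#' @return Tibble of match rows (`src_compound_id`, `src_id`, `source_name`,
#'   `status`, `uci`, `std_inchi`, `std_inchikey`), sorted by
#'   (`uci`, `src_id`, `src_compound_id`).
#' @export
lookup <- function(store, src_compound_id, src_id, mode = c("all", "current"),
                   target_src_id = NULL) {
  mode <- match.arg(mode)
  get_source(store, src_id)
  if (!is.null(target_src_id)) get_source(store, target_src_id)

  anchor <- query_ucis(store, src_compound_id, src_id, status = "current")
  if (length(anchor) == 0 && identical(mode, "all")) {
    anchor <- query_ucis(store, src_compound_id, src_id)
  }
  match_rows(store, anchor, mode, target_src_id)
}

#' Resolve a query identifier to compound-page URLs in a target source
#'
#' For sources that publish compound-specific pages, the full URL is the
#' source's base URL with the `src_compound_id` appended. This returns such
#' URLs for every current assignment in the target source that shares a
#' structure with the query identifier -- the building block for on-the-fly
#' link construction between resources.
#'
#' @inheritParams lookup
#' @param target_src_id the source whose URLs are wanted; it must have a
#'   registered `base_url`.
#' @return Character vector of URLs (empty when there is no structural
#'   match).
#' @export
lookup_as_urls <- function(store, src_compound_id, src_id, target_src_id) {
  target <- get_source(store, target_src_id)
  if (!isTRUE(target$supports_urls)) {
    stop_chemxref("chemxref_unsupported_urls",
      sprintf("source '%s' does not support compound-specific URLs (no base URL registered)",
              target$name))
  }
  rows <- lookup(store, src_compound_id, src_id, mode = "current",
                 target_src_id = target_src_id)
  if (nrow(rows) == 0) return(character(0))
  paste0(target$base_url, rows$src_compound_id)
}

#' Search the registry by Standard InChI or InChIKey
#'
#' Resolves an exact Standard InChI or 27-character Standard InChIKey to its
#' registered structure and returns that structure's assignment rows in the
#' same tabulated form as [lookup()]. A syntactically valid but unregistered
#' key yields an empty result; a malformed key (wrong length or hyphenation)
#' is an error.
#'
#' @param store an `xref_store`.
#' @param key the query string.
#' @param key_type `"inchi"` or `"inchikey"`.
#' @param mode `"all"` (default) or `"current"`.
#' @return Tibble of match rows as in [lookup()].
#' @export
search_structure <- function(store, key, key_type = c("inchi", "inchikey"),
                             mode = c("all", "current")) {
  key_type <- match.arg(key_type)
  mode <- match.arg(mode)
  key <- trimws(key)
  if (key_type == "inchikey") {
    key <- toupper(key)
    if (!is_inchikey_shaped(key)) {
      validation_error(
        "malformed InChIKey: expected 27 characters as XXXXXXXXXXXXXX-XXXXXXXXXX-X")
    }
    ucis <- DBI::dbGetQuery(store$con,
      "SELECT UCI FROM UC_STRUCTURES WHERE STANDARDINCHIKEY = ?", params = list(key))$UCI
  } else {
    ucis <- DBI::dbGetQuery(store$con,
      "SELECT UCI FROM UC_STRUCTURES WHERE STANDARDINCHI = ?", params = list(key))$UCI
  }
  match_rows(store, as.integer(ucis), mode)
}

#' Whole source-to-source identifier mapping
#'
#' The complete table of identifier pairs between two sources joined on
#' shared structure: every (`from_id`, `to_id`) such that the two
#' identifiers have at least one UCI in common. In `"current"` mode only
#' current assignments on both sides contribute. Pairs are deduplicated and
#' sorted. Mapping a source to itself yields the identity-by-structure
#' pairs, self-pairs included.
#'
#' @param store an `xref_store`.
#' @param from_src_id,to_src_id registered source ids.
#' @param mode `"all"` or `"current"` (default `"current"`, the usual
#'   link-building mode).
#' @return Tibble with columns `from_id`, `to_id`.
#' @export
whole_source_mapping <- function(store, from_src_id, to_src_id,
                                 mode = c("current", "all")) {
  mode <- match.arg(mode)
  get_source(store, from_src_id)
  get_source(store, to_src_id)
  cur <- if (identical(mode, "current")) {
    " AND a.ASSIGNMENT = 'current' AND b.ASSIGNMENT = 'current'"
  } else ""
  df <- DBI::dbGetQuery(store$con, paste0(
    "SELECT DISTINCT a.SRC_COMPOUND_ID AS from_id, b.SRC_COMPOUND_ID AS to_id
       FROM UC_XREF a JOIN UC_XREF b ON a.UCI = b.UCI
      WHERE a.SRC_ID = ? AND b.SRC_ID = ?", cur,
    " ORDER BY from_id, to_id"),
    params = list(as.integer(from_src_id), as.integer(to_src_id)))
  as_tibble(df)
}

#' Write a whole-source mapping as two-column TSV
#'
#' @param mapping tibble from [whole_source_mapping()].
#' @param path output path; a `.gz` suffix (or `gzip = TRUE`) writes a
#'   gzip-compressed file, the usual form for bulk mapping downloads.
#' @param gzip force gzip compression regardless of suffix.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(mapping, path, gzip = grepl("\\.gz$", path)) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c("from_id\tto_id", paste(mapping$from_id, mapping$to_id, sep = "\t")), con)
  invisible(path)
}

#' List obsolete assignments with their last-current release
#'
#' The audit view over identifier churn: every obsolete assignment together
#' with the release of its source in which it was last current (and that
#' release's version label and date).
#'
#' @param store an `xref_store`.
#' @return Tibble sorted by (`src_id`, `src_compound_id`, `uci`).
#' @export
audit_obsolete <- function(store) {
  df <- DBI::dbGetQuery(store$con,
    "SELECT s.NAME AS source_name, x.SRC_ID AS src_id,
            x.SRC_COMPOUND_ID AS src_compound_id, x.UCI AS uci,
            u.STANDARDINCHIKEY AS std_inchikey,
            x.LAST_REL_U_CUR AS last_release_u_current,
            r.VERSION_LABEL AS last_current_version,
            r.LOAD_DATE AS last_current_date
       FROM UC_XREF x
       JOIN UC_SOURCES s ON s.SRC_ID = x.SRC_ID
       JOIN UC_STRUCTURES u ON u.UCI = x.UCI
       LEFT JOIN UC_RELEASE r ON r.RELEASE_U = x.LAST_REL_U_CUR AND r.SRC_ID = x.SRC_ID
      WHERE x.ASSIGNMENT = 'obsolete'
      ORDER BY x.SRC_ID, x.SRC_COMPOUND_ID, x.UCI")
  df$src_id <- as.integer(df$src_id)
  df$uci <- as.integer(df$uci)
  df$last_release_u_current <- as.integer(df$last_release_u_current)
  as_tibble(df)
}
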