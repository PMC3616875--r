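#' Parse a three-column source dump
#'
#' Source feeds are UTF-8 tab-delimited files with three columns:
#' `src_compound_id`, Standard InChI, Standard InChIKey (the key column may
#' be empty when a source provides InChIs only). An optional single header
#' line is detected by a first field equal to `src_compound_id`
#' (case-insensitive). Fields are stripped of surrounding whitespace.
#' Byte-identical duplicate data lines are collapsed to one record, with a
#' comment noting the removal.
#'
#' @param path path to the dump file.
#' @return Tibble with columns `line_no`, `src_compound_id`, `std_inchi`,
#'   `std_inchikey`, one row per (deduplicated) data line in file order.
#'   Parser comments (duplicate removals) are attached as attribute
#'   `"dump_comments"`, a tibble of (`line_no`, `comment`).
#' @export
parse_source_dump <- function(path) {
  if (!file.exists(path)) not_found(sprintf("dump file '%s' does not exist", path))
  con <- file(path, encoding = "UTF-8")
  lines <- readLines(con, warn = FALSE)
  close(con)

  first_data <- 1L
  if (length(lines) >= 1L) {
    lead <- tolower(trimws(strsplit(paste0(lines[[1]], "\t\x01"), "\t", fixed = TRUE)[[1]][1]))
    if (identical(lead, "src_compound_id")) first_data <- 2L
  }
  data_idx <- seq.int(first_data, length.out = max(0L, length(lines) - first_data + 1L))
  if (length(data_idx) == 0L) {
    out <- tibble(line_no = integer(), src_compound_id = character(),
                  std_inchi = character(), std_inchikey = character())
    attr(out, "dump_comments") <- tibble(line_no = integer(), comment = character())
    return(out)
  }

  # sentinel keeps strsplit from dropping a trailing empty key column
  fields <- strsplit(paste0(lines[data_idx], "\t\x01"), "\t", fixed = TRUE)
  nf <- lengths(fields) - 1L
  bad <- which(nf != 3L)
  if (length(bad)) {
    parse_error(sprintf("line %d: expected 3 tab-separated columns, found %d",
                        data_idx[bad[[1]]], nf[bad[[1]]]))
  }

  raw <- lines[data_idx]
  dup <- duplicated(raw)
  comments <- tibble(line_no = integer(), comment = character())
  if (any(dup)) {
    firsts <- data_idx[match(raw[dup], raw)]
    comments <- tibble(
      line_no = data_idx[dup],
      comment = sprintf("exact duplicate of line %d removed during parsing", firsts))
  }

  keep <- which(!dup)
  m <- do.call(rbind, fields[keep])
  out <- tibble(
    line_no = data_idx[keep],
    src_compound_id = trimws(m[, 1]),
    std_inchi = trimws(m[, 2]),
    std_inchikey = trimws(m[, 3])
  )
  attr(out, "dump_comments") <- comments
  out
}

#' @rdname parse_source_dump
#' @param records a tibble returned by `parse_source_dump()`.
#' @export
dump_comments <- function(records) {
  attr(records, "dump_comments") %||% tibble(line_no = integer(), comment = character())
}

release_next_u <- function(store) {
  as.integer(q1(store, "SELECT COALESCE(MAX(RELEASE_U), 0) + 1 AS U FROM UC_RELEASE")$U[[1]])
}

#' Load one release of a source into the registry
#'
#' The single registration algorithm applied to every source: records are
#' filtered through the five loading rules ([validate_records()]), each
#' accepted record's structure is registered (new Standard InChIs get fresh
#' UCIs), and the source's assignments are reconciled against the accepted
#' set:
#' \itemize{
#'   \item an accepted `(src_compound_id, UCI)` pair not seen before is
#'     inserted as `current`;
#'   \item a pair that exists as `obsolete` and re-appears flips back to
#'     `current` (its last-release-current marker is cleared);
#'   \item a `current` assignment of this source that is absent from the
#'     accepted set flips to `obsolete`, and `LAST_REL_U_CUR` records the
#'     source's previous release -- the last occasion the assignment was
#'     current. Only the most recent such occasion is kept: an assignment
#'     that cycles obsolete/current/obsolete retains only the latest one.
#' }
#' Assignment rows are never deleted, so many-to-many mappings (several
#' identifiers on one structure, one identifier on several structures) and
#' their full history are retained. The load is transactional: either the
#' whole release applies or nothing does.
#'
#' A release whose accepted set is empty is refused unless
#' `allow_empty = TRUE`: such a load would obsolete every assignment of the
#' source, which more often signals a truncated download than a real
#' deletion of the source's content.
#'
#' @param store an `xref_store`.
#' @param src_id registered source id.
#' @param records parsed dump tibble (see [parse_source_dump()]).
#' @param version_label the source's own version string for this release.
#' @param allow_empty permit a release with zero accepted records.
#' @param source_provides_inchikey passed to [validate_records()].
#' @param backend InChIKey backend; defaults to the one recorded in the
#'   store metadata.
#' @return A `load_report` object: release/source ids, acceptance and
#'   per-rule rejection counts, new-structure/assignment and
#'   obsolete/current transition counts, and the recorded comments.
#' @export
load_release <- function(store, src_id, records, version_label,
                         allow_empty = FALSE, source_provides_inchikey = TRUE,
                         backend = store_backend(store)) {
  src <- get_source(store, src_id)

  outcome <- validate_records(records, backend = backend,
                              source_provides_inchikey = source_provides_inchikey)
  acc <- dplyr::filter(outcome, .data$accepted)
  if (nrow(acc) == 0 && !isTRUE(allow_empty)) {
    stop_chemxref("chemxref_guard", paste0(
      "release has no accepted records and would obsolete every assignment of source '",
      src$name, "'; pass allow_empty = TRUE to confirm"))
  }

  rej <- vapply(paste0("R", 1:5), function(r) sum(outcome$rule_violated == r, na.rm = TRUE),
                integer(1))
  comments <- bind_rows(
    dump_comments(records),
    tibble(line_no = outcome$line_no, comment = outcome$comment)
  )
  comments <- dplyr::filter(comments, !is.na(.data$comment))

  con <- store$con
  report <- DBI::dbWithTransaction(con, {
    release_u <- release_next_u(store)
    prev_ru <- q1(store,
      "SELECT MAX(RELEASE_U) AS U FROM UC_RELEASE WHERE SRC_ID = ? AND ROLLED_BACK = 0",
      as.integer(src_id))$U[[1]]
    prev_ru <- if (is.na(prev_ru)) NA_integer_ else as.integer(prev_ru)

    structs <- distinct(
      tibble(std_inchi = acc$std_inchi, std_inchikey = acc$computed_inchikey),
      .data$std_inchi, .keep_all = TRUE)
    structs <- register_structures_bulk(store, structs, release_u)

    pairs <- distinct(
      tibble(src_compound_id = acc$src_compound_id,
             uci = structs$uci[match(acc$std_inchi, structs$std_inchi)]))

    existing <- q1(store,
      "SELECT SRC_COMPOUND_ID AS src_compound_id, UCI AS uci,
              ASSIGNMENT AS status, LAST_REL_U_CUR AS last_rel_u_cur
         FROM UC_XREF WHERE SRC_ID = ?", as.integer(src_id))
    existing$uci <- as.integer(existing$uci)

    key <- function(df) paste(df$src_compound_id, df$uci, sep = "\r")
    in_release <- key(pairs)
    known <- key(existing)

    new_pairs <- pairs[!(in_release %in% known), , drop = FALSE]
    revive <- existing[existing$status == "obsolete" & known %in% in_release, , drop = FALSE]
    to_obs <- existing[existing$status == "current" & !(known %in% in_release), , drop = FALSE]

    journal <- bind_rows(
      if (nrow(new_pairs)) tibble(src_compound_id = new_pairs$src_compound_id,
                                  uci = new_pairs$uci, old_present = 0L,
                                  old_assignment = NA_character_,
                                  old_last = NA_integer_),
      if (nrow(revive)) tibble(src_compound_id = revive$src_compound_id,
                               uci = revive$uci, old_present = 1L,
                               old_assignment = revive$status,
                               old_last = as.integer(revive$last_rel_u_cur)),
      if (nrow(to_obs)) tibble(src_compound_id = to_obs$src_compound_id,
                               uci = to_obs$uci, old_present = 1L,
                               old_assignment = to_obs$status,
                               old_last = as.integer(to_obs$last_rel_u_cur))
    )

    if (nrow(new_pairs)) {
      DBI::dbAppendTable(con, "UC_XREF", data.frame(
        SRC_COMPOUND_ID = new_pairs$src_compound_id,
        SRC_ID = as.integer(src_id), UCI = new_pairs$uci,
        ASSIGNMENT = "current", LAST_REL_U_CUR = NA_integer_,
        stringsAsFactors = FALSE))
    }
    if (nrow(revive)) {
      DBI::dbExecute(con,
        "UPDATE UC_XREF SET ASSIGNMENT = 'current', LAST_REL_U_CUR = NULL
          WHERE SRC_COMPOUND_ID = ? AND SRC_ID = ? AND UCI = ?",
        params = list(revive$src_compound_id,
                      rep(as.integer(src_id), nrow(revive)), revive$uci))
    }
    if (nrow(to_obs)) {
      DBI::dbExecute(con,
        "UPDATE UC_XREF SET ASSIGNMENT = 'obsolete', LAST_REL_U_CUR = ?
          WHERE SRC_COMPOUND_ID = ? AND SRC_ID = ? AND UCI = ?",
        params = list(rep(prev_ru, nrow(to_obs)), to_obs$src_compound_id,
                      rep(as.integer(src_id), nrow(to_obs)), to_obs$uci))
    }

    DBI::dbExecute(con,
      "INSERT INTO UC_RELEASE (RELEASE_U, SRC_ID, VERSION_LABEL, LOAD_DATE,
         N_PARSED, N_ACCEPTED, N_REJ_R1, N_REJ_R2, N_REJ_R3, N_REJ_R4, N_REJ_R5,
         N_NEW_STRUCTURES, N_NEW_ASSIGNMENTS, N_TO_OBSOLETE, N_TO_CURRENT, ROLLED_BACK)
       VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, ?, 0)",
      params = list(release_u, as.integer(src_id), version_label,
                    format(Sys.Date()), nrow(outcome), nrow(acc),
                    rej[["R1"]], rej[["R2"]], rej[["R3"]], rej[["R4"]], rej[["R5"]],
                    attr(structs, "n_new"), nrow(new_pairs), nrow(to_obs), nrow(revive)))
    if (nrow(comments)) {
      DBI::dbAppendTable(con, "UC_COMMENTS", data.frame(
        RELEASE_U = release_u, SRC_ID = as.integer(src_id),
        LINE_NO = comments$line_no, COMMENT = comments$comment,
        stringsAsFactors = FALSE))
    }
    if (nrow(journal)) {
      DBI::dbAppendTable(con, "UC_JOURNAL", data.frame(
        RELEASE_U = release_u,
        SRC_COMPOUND_ID = journal$src_compound_id, SRC_ID = as.integer(src_id),
        UCI = journal$uci, OLD_PRESENT = journal$old_present,
        OLD_ASSIGNMENT = journal$old_assignment,
        OLD_LAST_REL_U_CUR = journal$old_last,
        stringsAsFactors = FALSE))
    }

    new_load_report(
      action = "load", release_u = release_u, src_id = as.integer(src_id),
      version_label = version_label,
      n_parsed = nrow(outcome), n_accepted = nrow(acc),
      n_rejected_by_rule = rej,
      n_new_structures = attr(structs, "n_new"),
      n_new_assignments = nrow(new_pairs),
      n_to_obsolete = nrow(to_obs), n_to_current = nrow(revive),
      comments = comments)
  })
  report
}

#' @rdname load_release
#' @param source_name source name (registered with [add_source()]).
#' @param path dump file path.
#' @param ... passed on to `load_release()`.
#' @export
load_dump <- function(store, source_name, path, version_label, ...) {
  src <- get_source_by_name(store, source_name)
  load_release(store, src$src_id, parse_source_dump(path), version_label, ...)
}

new_load_report <- function(...) {
  structure(list(...), class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("<load_report:%s> release_u %d, src_id %d (%s)\n",
              x$action, x$release_u, x$src_id, x$version_label %||% ""))
  if (identical(x$action, "load")) {
    cat(sprintf("  parsed %d | accepted %d | rejected %s\n",
                x$n_parsed, x$n_accepted,
                paste(sprintf("%s=%d", names(x$n_rejected_by_rule), x$n_rejected_by_rule),
                      collapse = " ")))
    cat(sprintf("  new structures %d | new assignments %d | -> obsolete %d | -> current %d\n",
                x$n_new_structures, x$n_new_assignments, x$n_to_obsolete, x$n_to_current))
  } else {
    cat(sprintf("  assignments removed %d | restored current %d | restored obsolete %d\n",
                x$n_assignments_removed, x$n_restored_current, x$n_restored_obsolete))
  }
  invisible(x)
}

#' Tidy a load report
#'
#' @param x a `load_report`.
#' @param ... unused.
#' @return Tibble with one row per filtering rule and its rejection count
#'   (for a load), or one row per reverted quantity (for a rollback).
#' @method tidy load_report
#' @export
tidy.load_report <- function(x, ...) {
  if (identical(x$action, "load")) {
    tibble(rule = names(x$n_rejected_by_rule),
           n_rejected = as.integer(x$n_rejected_by_rule))
  } else {
    tibble(quantity = c("assignments_removed", "restored_current", "restored_obsolete"),
           n = c(x$n_assignments_removed, x$n_restored_current, x$n_restored_obsolete))
  }
}

#' One-row summary of a load report
#'
#' @param x a `load_report`.
#' @param ... unused.
#' @return One-row tibble of the report's counters.
#' @method glance load_report
#' @export
glance.load_report <- function(x, ...) {
  if (identical(x$action, "load")) {
    tibble(action = x$action, release_u = x$release_u, src_id = x$src_id,
           version_label = x$version_label,
           n_parsed = x$n_parsed, n_accepted = x$n_accepted,
           n_rejected = sum(x$n_rejected_by_rule),
           n_new_structures = x$n_new_structures,
           n_new_assignments = x$n_new_assignments,
           n_to_obsolete = x$n_to_obsolete, n_to_current = x$n_to_current,
           n_comments = nrow(x$comments))
  } else {
    tibble(action = x$action, release_u = x$release_u, src_id = x$src_id,
           n_assignments_removed = x$n_assignments_removed,
           n_restored_current = x$n_restored_current,
           n_restored_obsolete = x$n_restored_obsolete)
  }
}

#' Serialize a load report as JSON
#'
#' @param report a `load_report`.
#' @return A JSON string (pretty-printed).
#' @export
load_report_json <- function(report) {
  x <- unclass(report)
  x$n_rejected_by_rule <- as.list(x$n_rejected_by_rule)
  x$comments <- if (nrow(report$comments)) report$comments else NULL
  jsonlite::toJSON(x[!vapply(x, is.null, logical(1))], auto_unbox = TRUE,
                   dataframe = "rows", pretty = TRUE, na = "null")
}

#' Roll back the most recent load of a source
#'
#' Restores the assignment table to its exact pre-load snapshot: assignments
#' inserted by the release are removed, and status plus last-release-current
#' markers changed by it are restored from the release journal. Structures
#' registered by the release are NOT removed -- the UCI-to-InChI binding is
#' immutable for the life of the store, so such structures simply remain,
#' possibly without any assignment. Only the most recent non-rolled-back
#' release of a source can be reversed.
#'
#' @param store an `xref_store`.
#' @param release_u the release to revert.
#' @return A `load_report` (action `"rollback"`) summarising the reversal.
#' @export
rollback_release <- function(store, release_u) {
  release_u <- as.integer(release_u)
  rel <- q1(store, "SELECT * FROM UC_RELEASE WHERE RELEASE_U = ?", release_u)
  if (nrow(rel) == 0) not_found(sprintf("no release with release_u %d", release_u))
  if (rel$ROLLED_BACK[[1]] == 1) {
    stop_chemxref("chemxref_unsupported_rollback",
                  sprintf("release %d has already been rolled back", release_u))
  }
  src_id <- as.integer(rel$SRC_ID[[1]])
  latest <- as.integer(q1(store,
    "SELECT MAX(RELEASE_U) AS U FROM UC_RELEASE WHERE SRC_ID = ? AND ROLLED_BACK = 0",
    src_id)$U[[1]])
  if (!identical(latest, release_u)) {
    stop_chemxref("chemxref_unsupported_rollback", sprintf(
      "only the most recent load of a source can be rolled back (release %d is superseded by %d)",
      release_u, latest))
  }

  con <- store$con
  DBI::dbWithTransaction(con, {
    j <- q1(store, "SELECT * FROM UC_JOURNAL WHERE RELEASE_U = ?", release_u)
    added <- j[j$OLD_PRESENT == 0L, , drop = FALSE]
    changed <- j[j$OLD_PRESENT == 1L, , drop = FALSE]
    if (nrow(added)) {
      DBI::dbExecute(con,
        "DELETE FROM UC_XREF WHERE SRC_COMPOUND_ID = ? AND SRC_ID = ? AND UCI = ?",
        params = list(added$SRC_COMPOUND_ID, added$SRC_ID, added$UCI))
    }
    if (nrow(changed)) {
      DBI::dbExecute(con,
        "UPDATE UC_XREF SET ASSIGNMENT = ?, LAST_REL_U_CUR = ?
          WHERE SRC_COMPOUND_ID = ? AND SRC_ID = ? AND UCI = ?",
        params = list(changed$OLD_ASSIGNMENT, changed$OLD_LAST_REL_U_CUR,
                      changed$SRC_COMPOUND_ID, changed$SRC_ID, changed$UCI))
    }
    DBI::dbExecute(con, "UPDATE UC_RELEASE SET ROLLED_BACK = 1 WHERE RELEASE_U = ?",
                   params = list(release_u))

    new_load_report(
      action = "rollback", release_u = release_u, src_id = src_id,
      version_label = rel$VERSION_LABEL[[1]],
      n_assignments_removed = nrow(added),
      n_restored_current = sum(changed$OLD_ASSIGNMENT == "current"),
      n_restored_obsolete = sum(changed$OLD_ASSIGNMENT == "obsolete"),
      comments = tibble(line_no = integer(), comment = character()))
  })
}
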