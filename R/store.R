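#' Create or open a cross-reference registry store
#'
#' The registry is a single-file embedded SQLite database with four main
#' tables: `UC_STRUCTURES` (one immutable row per distinct Standard InChI,
#' keyed by the integer UCI), `UC_SOURCES` (registered identifier
#' namespaces), `UC_XREF` (append-only identifier-to-structure assignments,
#' flagged current or obsolete), and `UC_RELEASE` (one row per load event,
#' with per-rule rejection counts retained permanently). Auxiliary tables
#' hold load comments and the per-release journal that makes the latest load
#' of a source reversible.
#'
#' Two hard invariants are enforced for the store's whole lifetime: a
#' `(UCI, Standard InChI)` pair, once written, is never updated or deleted;
#' and assignment rows are never deleted -- the only mutable assignment
#' fields are the current/obsolete flag and the last-release-current marker.
#'
#' @param path file path for the database (created), or `":memory:"` for an
#'   in-memory store (useful in tests).
#' @param backend InChIKey backend name recorded in the store metadata and
#'   used by subsequent loads: `"rdkit"` (production) or `"mock"` (logic
#'   tests). See [inchikey_backend()].
#' @param force overwrite an existing store file.
#' @return An object of class `xref_store` (keep it and pass it to every
#'   registry function; call [store_close()] when done).
#' @examples
#' st <- store_create(":memory:", backend = "mock")
#' add_source(st, "ChEMBL")
#' store_close(st)
#' @export
store_create <- function(path, backend = c("rdkit", "mock"), force = FALSE) {
  backend <- match.arg(backend)
  if (!identical(path, ":memory:") && file.exists(path)) {
    if (!force) conflict(sprintf("store already exists at '%s' (use force = TRUE)", path))
    unlink(path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ddl <- c(
    "CREATE TABLE UC_STRUCTURES (
       UCI INTEGER PRIMARY KEY,
       STANDARDINCHI TEXT NOT NULL UNIQUE,
       STANDARDINCHIKEY TEXT NOT NULL,
       FIRST_RELEASE_U INTEGER NOT NULL)",
    "CREATE INDEX IDX_STRUCT_KEY ON UC_STRUCTURES(STANDARDINCHIKEY)",
    "CREATE TABLE UC_SOURCES (
       SRC_ID INTEGER PRIMARY KEY,
       NAME TEXT NOT NULL UNIQUE,
       DESCRIPTION TEXT,
       BASE_URL TEXT)",
    "CREATE TABLE UC_XREF (
       SRC_COMPOUND_ID TEXT NOT NULL,
       SRC_ID INTEGER NOT NULL REFERENCES UC_SOURCES(SRC_ID),
       UCI INTEGER NOT NULL REFERENCES UC_STRUCTURES(UCI),
       ASSIGNMENT TEXT NOT NULL CHECK (ASSIGNMENT IN ('current','obsolete')),
       LAST_REL_U_CUR INTEGER,
       PRIMARY KEY (SRC_COMPOUND_ID, SRC_ID, UCI))",
    "CREATE INDEX IDX_XREF_UCI ON UC_XREF(UCI)",
    "CREATE INDEX IDX_XREF_SRC ON UC_XREF(SRC_ID, ASSIGNMENT)",
    "CREATE TABLE UC_RELEASE (
       RELEASE_U INTEGER NOT NULL,
       SRC_ID INTEGER NOT NULL REFERENCES UC_SOURCES(SRC_ID),
       VERSION_LABEL TEXT,
       LOAD_DATE TEXT,
       N_PARSED INTEGER, N_ACCEPTED INTEGER,
       N_REJ_R1 INTEGER, N_REJ_R2 INTEGER, N_REJ_R3 INTEGER,
       N_REJ_R4 INTEGER, N_REJ_R5 INTEGER,
       N_NEW_STRUCTURES INTEGER, N_NEW_ASSIGNMENTS INTEGER,
       N_TO_OBSOLETE INTEGER, N_TO_CURRENT INTEGER,
       ROLLED_BACK INTEGER NOT NULL DEFAULT 0,
       PRIMARY KEY (RELEASE_U, SRC_ID))",
    "CREATE TABLE UC_COMMENTS (
       RELEASE_U INTEGER, SRC_ID INTEGER, LINE_NO INTEGER, COMMENT TEXT)",
    "CREATE TABLE UC_JOURNAL (
       RELEASE_U INTEGER NOT NULL,
       SRC_COMPOUND_ID TEXT NOT NULL, SRC_ID INTEGER NOT NULL, UCI INTEGER NOT NULL,
       OLD_PRESENT INTEGER NOT NULL,
       OLD_ASSIGNMENT TEXT, OLD_LAST_REL_U_CUR INTEGER)",
    "CREATE TABLE UC_META (KEY TEXT PRIMARY KEY, VALUE TEXT)"
  )
  for (stmt in ddl) DBI::dbExecute(con, stmt)
  DBI::dbExecute(con, "INSERT INTO UC_META VALUES ('inchi_backend', ?), ('schema_version', '1')",
                 params = list(backend))
  new_store(con, path)
}

new_store <- function(con, path) {
  structure(list(con = con, path = path), class = "xref_store")
}

#' @rdname store_create
#' @export
store_open <- function(path) {
  if (!file.exists(path)) not_found(sprintf("no store at '%s'", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  if (!"UC_META" %in% DBI::dbListTables(con)) {
    DBI::dbDisconnect(con)
    integrity_error(sprintf("'%s' is not a chemxref store", path))
  }
  new_store(con, path)
}

#' @rdname store_create
#' @param store an `xref_store`.
#' @export
store_close <- function(store) {
  stopifnot(inherits(store, "xref_store"))
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

store_meta <- function(store, key) {
  v <- DBI::dbGetQuery(store$con, "SELECT VALUE FROM UC_META WHERE KEY = ?",
                       params = list(key))
  if (nrow(v) == 0) NULL else v$VALUE[[1]]
}

#' @export
print.xref_store <- function(x, ...) {
  g <- glance(x)
  cat("<xref_store> ", x$path, "\n", sep = "")
  cat(sprintf("  backend: %s | structures: %d | sources: %d | releases: %d\n",
              store_meta(x, "inchi_backend"), g$n_structures, g$n_sources, g$n_releases))
  cat(sprintf("  assignments: %d (%d current, %d obsolete)\n",
              g$n_assignments, g$n_current, g$n_obsolete))
  invisible(x)
}

#' InChIKey backend configured for a store
#'
#' @param store an `xref_store`.
#' @return The [inchikey_backend()] recorded at store creation.
#' @export
store_backend <- function(store) {
  inchikey_backend(store_meta(store, "inchi_backend") %||% "rdkit")
}

q1 <- function(store, sql, ...) {
  args <- list(...)
  if (length(args) == 0) DBI::dbGetQuery(store$con, sql)
  else DBI::dbGetQuery(store$con, sql, params = args)
}

# --- structures -------------------------------------------------------------

#' Register a structure and obtain its UCI
#'
#' Each distinct Standard InChI is stored exactly once; re-registering an
#' already-known InChI returns the existing UCI unchanged (idempotent).
#' Fresh structures are allocated consecutive integer UCIs in registration
#' order. UCIs are local to a store instance: independently built stores
#' will number the same structures differently.
#'
#' @param store an `xref_store`.
#' @param std_inchi Standard InChI string (must have passed validation).
#' @param std_inchikey its 27-character Standard InChIKey.
#' @param release_u the release that introduces the structure (recorded in
#'   `FIRST_RELEASE_U` for new structures only).
#' @return Integer UCI.
#' @export
register_structure <- function(store, std_inchi, std_inchikey, release_u = 0L) {
  std_inchi <- trimws(std_inchi)
  std_inchikey <- toupper(trimws(std_inchikey))
  if (!has_standard_prefix(std_inchi)) {
    validation_error("std_inchi must be a Standard InChI ('InChI=1S/...')")
  }
  if (!is_inchikey_shaped(std_inchikey)) {
    validation_error("std_inchikey is not a well-formed 27-character InChIKey")
  }
  hit <- q1(store, "SELECT UCI, STANDARDINCHIKEY FROM UC_STRUCTURES WHERE STANDARDINCHI = ?",
            std_inchi)
  if (nrow(hit)) {
    if (!identical(hit$STANDARDINCHIKEY[[1]], std_inchikey)) {
      integrity_error("std_inchikey disagrees with the key already registered for this InChI")
    }
    return(as.integer(hit$UCI[[1]]))
  }
  uci <- as.integer(q1(store, "SELECT COALESCE(MAX(UCI), 0) + 1 AS U FROM UC_STRUCTURES")$U[[1]])
  DBI::dbExecute(store$con,
    "INSERT INTO UC_STRUCTURES (UCI, STANDARDINCHI, STANDARDINCHIKEY, FIRST_RELEASE_U)
     VALUES (?, ?, ?, ?)",
    params = list(uci, std_inchi, std_inchikey, as.integer(release_u)))
  uci
}

# Bulk structure registration used by the loader. `structs` has columns
# std_inchi, std_inchikey (already trimmed/upper-cased, distinct by inchi).
# Returns structs with a `uci` column and attr "n_new".
register_structures_bulk <- function(store, structs, release_u) {
  if (nrow(structs) == 0) {
    structs$uci <- integer(0)
    attr(structs, "n_new") <- 0L
    return(structs)
  }
  DBI::dbWriteTable(store$con, "STAGE_STRUCT",
    data.frame(ORD = seq_len(nrow(structs)),
               STANDARDINCHI = structs$std_inchi,
               STANDARDINCHIKEY = structs$std_inchikey,
               stringsAsFactors = FALSE),
    temporary = TRUE, overwrite = TRUE)
  on.exit(DBI::dbExecute(store$con, "DROP TABLE IF EXISTS STAGE_STRUCT"), add = TRUE)
  hits <- DBI::dbGetQuery(store$con,
    "SELECT s.ORD AS ord, u.UCI AS uci, u.STANDARDINCHIKEY AS known_key,
            s.STANDARDINCHIKEY AS new_key
       FROM STAGE_STRUCT s JOIN UC_STRUCTURES u ON u.STANDARDINCHI = s.STANDARDINCHI")
  if (nrow(hits) && any(hits$known_key != hits$new_key)) {
    integrity_error("computed InChIKey disagrees with a registered structure's key")
  }
  uci <- rep(NA_integer_, nrow(structs))
  uci[hits$ord] <- as.integer(hits$uci)
  new_idx <- which(is.na(uci))
  if (length(new_idx)) {
    base <- as.integer(q1(store, "SELECT COALESCE(MAX(UCI), 0) AS U FROM UC_STRUCTURES")$U[[1]])
    uci[new_idx] <- base + seq_along(new_idx)
    DBI::dbAppendTable(store$con, "UC_STRUCTURES", data.frame(
      UCI = uci[new_idx],
      STANDARDINCHI = structs$std_inchi[new_idx],
      STANDARDINCHIKEY = structs$std_inchikey[new_idx],
      FIRST_RELEASE_U = as.integer(release_u),
      stringsAsFactors = FALSE))
  }
  structs$uci <- uci
  attr(structs, "n_new") <- length(new_idx)
  structs
}

# --- sources ----------------------------------------------------------------

#' Register an identifier source
#'
#' A source is a namespace of compound identifiers (e.g. a database that
#' deposits identifier-to-InChI dumps). `src_id` values are consecutive
#' integers in registration order. Identical `src_compound_id` strings may
#' exist under different sources, which is why every identifier query also
#' takes a `src_id`.
#'
#' @param store an `xref_store`.
#' @param name unique source name.
#' @param base_url optional base URL such that `base_url + src_compound_id`
#'   is the source's compound page; sources with a `base_url` support URL
#'   queries ([lookup_as_urls()]).
#' @param description free-text description of the source and how its feed
#'   is processed.
#' @return Integer `src_id`.
#' @export
add_source <- function(store, name, base_url = NULL, description = "") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (nrow(q1(store, "SELECT 1 FROM UC_SOURCES WHERE NAME = ?", name))) {
    conflict(sprintf("source name '%s' is already registered", name))
  }
  src_id <- as.integer(q1(store, "SELECT COALESCE(MAX(SRC_ID), 0) + 1 AS S FROM UC_SOURCES")$S[[1]])
  DBI::dbExecute(store$con,
    "INSERT INTO UC_SOURCES (SRC_ID, NAME, DESCRIPTION, BASE_URL) VALUES (?, ?, ?, ?)",
    params = list(src_id, name, description, base_url %||% NA_character_))
  src_id
}

source_row_to_tibble <- function(df) {
  tibble(
    src_id = as.integer(df$SRC_ID),
    name = df$NAME,
    description = df$DESCRIPTION,
    base_url = df$BASE_URL,
    supports_urls = !is.na(df$BASE_URL)
  )
}

#' Look up a registered source
#'
#' @param store an `xref_store`.
#' @param src_id integer source identifier.
#' @return One-row tibble with `src_id`, `name`, `description`, `base_url`,
#'   `supports_urls`.
#' @export
get_source <- function(store, src_id) {
  df <- q1(store, "SELECT * FROM UC_SOURCES WHERE SRC_ID = ?", as.integer(src_id))
  if (nrow(df) == 0) not_found(sprintf("no source with src_id %s", src_id))
  source_row_to_tibble(df)
}

get_source_by_name <- function(store, name) {
  df <- q1(store, "SELECT * FROM UC_SOURCES WHERE NAME = ?", name)
  if (nrow(df) == 0) not_found(sprintf("no source named '%s'", name))
  source_row_to_tibble(df)
}

#' List registered sources
#'
#' @param store an `xref_store`.
#' @return Tibble of all sources ordered by `src_id` (empty for a fresh
#'   store).
#' @export
list_sources <- function(store) {
  df <- DBI::dbGetQuery(store$con, "SELECT * FROM UC_SOURCES ORDER BY SRC_ID")
  source_row_to_tibble(df)
}

#' Per-source summary with latest-release information
#'
#' One row per source: release count, the version label and date of the last
#' (non-rolled-back) load, and that load's per-rule rejection counts -- the
#' numbers excluded by each filtering rule for the most recent release of a
#' source are retained and reported.
#'
#' @param store an `xref_store`.
#' @return Tibble ordered by `src_id`.
#' @export
source_summary <- function(store) {
  src <- list_sources(store)
  rel <- DBI::dbGetQuery(store$con,
    "SELECT r.* FROM UC_RELEASE r
      WHERE r.ROLLED_BACK = 0
        AND r.RELEASE_U = (SELECT MAX(r2.RELEASE_U) FROM UC_RELEASE r2
                            WHERE r2.SRC_ID = r.SRC_ID AND r2.ROLLED_BACK = 0)")
  nrel <- DBI::dbGetQuery(store$con,
    "SELECT SRC_ID, COUNT(*) AS N FROM UC_RELEASE WHERE ROLLED_BACK = 0 GROUP BY SRC_ID")
  out <- src
  idx <- match(out$src_id, rel$SRC_ID)
  out$n_releases <- ifelse(is.na(match(out$src_id, nrel$SRC_ID)), 0L,
                           as.integer(nrel$N[match(out$src_id, nrel$SRC_ID)]))
  out$last_release_u <- as.integer(rel$RELEASE_U[idx])
  out$last_version_label <- rel$VERSION_LABEL[idx]
  out$last_load_date <- rel$LOAD_DATE[idx]
  for (r in 1:5) {
    out[[paste0("last_n_rej_r", r)]] <- as.integer(rel[[paste0("N_REJ_R", r)]][idx])
  }
  as_tibble(out)
}

# --- whole-store views ------------------------------------------------------

#' Assignment table of a store as a tibble
#'
#' One row per assignment (the append-only cross-reference table joined to
#' its structures and sources); the canonical flat view used by the replay
#' oracle comparison and by [autoplot.xref_store()].
#'
#' @param x an `xref_store`.
#' @param ... unused.
#' @return Tibble with `source_name`, `src_id`, `src_compound_id`, `uci`,
#'   `std_inchi`, `std_inchikey`, `status`, `last_release_u_current`,
#'   sorted by (`src_id`, `src_compound_id`, `uci`).
#' @method tidy xref_store
#' @export
tidy.xref_store <- function(x, ...) {
  df <- DBI::dbGetQuery(x$con,
    "SELECT s.NAME AS source_name, x.SRC_ID AS src_id,
            x.SRC_COMPOUND_ID AS src_compound_id, x.UCI AS uci,
            u.STANDARDINCHI AS std_inchi, u.STANDARDINCHIKEY AS std_inchikey,
            x.ASSIGNMENT AS status, x.LAST_REL_U_CUR AS last_release_u_current
       FROM UC_XREF x
       JOIN UC_SOURCES s ON s.SRC_ID = x.SRC_ID
       JOIN UC_STRUCTURES u ON u.UCI = x.UCI
      ORDER BY x.SRC_ID, x.SRC_COMPOUND_ID, x.UCI")
  df$src_id <- as.integer(df$src_id)
  df$uci <- as.integer(df$uci)
  df$last_release_u_current <- as.integer(df$last_release_u_current)
  as_tibble(df)
}

#' One-row summary of a store
#'
#' @param x an `xref_store`.
#' @param ... unused.
#' @return Tibble with structure, source, release and assignment counts.
#' @method glance xref_store
#' @export
glance.xref_store <- function(x, ...) {
  n1 <- function(sql) as.integer(DBI::dbGetQuery(x$con, sql)[[1]])
  tibble(
    n_structures = n1("SELECT COUNT(*) FROM UC_STRUCTURES"),
    n_sources = n1("SELECT COUNT(*) FROM UC_SOURCES"),
    n_releases = n1("SELECT COUNT(*) FROM UC_RELEASE WHERE ROLLED_BACK = 0"),
    n_assignments = n1("SELECT COUNT(*) FROM UC_XREF"),
    n_current = n1("SELECT COUNT(*) FROM UC_XREF WHERE ASSIGNMENT = 'current'"),
    n_obsolete = n1("SELECT COUNT(*) FROM UC_XREF WHERE ASSIGNMENT = 'obsolete'")
  )
}

#' Plot assignment status per source
#'
#' Bar chart of current and obsolete assignment counts for every registered
#' source -- a quick visual check of identifier churn after a load history.
#'
#' @param object an `xref_store`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot xref_store
#' @export
autoplot.xref_store <- function(object, ...) {
  df <- tidy(object)
  counts <- df |>
    dplyr::count(.data$source_name, .data$status, name = "n_assignments")
  ggplot2::ggplot(counts,
      ggplot2::aes(x = .data$source_name, y = .data$n_assignments, fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "source", y = "assignments", fill = "status",
                  title = "Identifier assignments by source") +
    ggplot2::theme_minimal()
}
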