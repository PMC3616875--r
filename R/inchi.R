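#' InChIKey generation backends
#'
#' The registry never trusts a source-supplied InChIKey: keys are recomputed
#' from the Standard InChI and compared. Key generation is delegated to an
#' injectable backend so that the loading and querying logic can be exercised
#' without chemistry software.
#'
#' Two backends ship with the package:
#' \describe{
#'   \item{`"rdkit"`}{Calls the InChI library bundled with RDKit through a
#'     batched `python` subprocess. This is the production backend: keys are
#'     the true Standard InChIKeys.}
#'   \item{`"mock"`}{A pure-R deterministic hash shaped like an InChIKey
#'     (27 characters, hyphens after the 14- and 10-character blocks, `SA-N`
#'     suffix). Collision-free in practice for test universes and fully
#'     reproducible, but chemically meaningless. Intended for logic tests.}
#' }
#'
#' @param name `"rdkit"` or `"mock"`, or a function taking a character vector
#'   of Standard InChIs and returning a character vector of keys (with `NA`
#'   for failures) for a custom backend.
#' @return An object of class `inchikey_backend`.
#' @examples
#' be <- inchikey_backend("mock")
#' generate_inchikey("InChI=1S/H2O/h1H2", be)
#' @export
inchikey_backend <- function(name = c("rdkit", "mock")) {
  if (is.function(name)) {
    be <- list(name = "custom", keys = function(x) normalize_backend_keys(name(x)))
  } else {
    name <- match.arg(name)
    be <- switch(name,
      mock = list(name = "mock", keys = mock_inchikey_batch),
      rdkit = list(name = "rdkit", keys = rdkit_inchikey_batch)
    )
  }
  structure(be, class = "inchikey_backend")
}

#' @export
print.inchikey_backend <- function(x, ...) {
  cat("<inchikey_backend:", x$name, ">\n")
  invisible(x)
}

normalize_backend_keys <- function(keys) {
  keys <- as.character(keys)
  ifelse(!is.na(keys) & is_inchikey_shaped(keys), toupper(keys), NA_character_)
}

# Standard-InChI prefix check. The registry stores Standard InChIs only;
# non-standard "InChI=1/" strings fail key generation with a distinct message.
has_standard_prefix <- function(x) {
  !is.na(x) & startsWith(x, "InChI=1S/") & nchar(x) > nchar("InChI=1S/")
}

#' Check InChIKey shape
#'
#' A Standard InChIKey is 27 characters: a 14-character connectivity block,
#' a hyphen, a 10-character block (hash remainder, standard flag, version),
#' a hyphen, and one protonation character -- hyphens fall at positions 15
#' and 26 (1-based). All other characters are uppercase letters.
#'
#' @param key character vector.
#' @return logical vector.
#' @export
is_inchikey_shaped <- function(key) {
  !is.na(key) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
}

# --- mock backend -----------------------------------------------------------

hash_to_letters <- function(x, salt, n) {
  vapply(x, function(s) {
    h <- rlang::hash(paste0(salt, s))
    bytes <- strtoi(substring(h, seq(1L, 2L * n, 2L), seq(2L, 2L * n, 2L)), 16L)
    paste(LETTERS[bytes %% 26L + 1L], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

mock_inchikey_batch <- function(inchis) {
  ok <- has_standard_prefix(inchis)
  out <- rep(NA_character_, length(inchis))
  if (any(ok)) {
    b1 <- hash_to_letters(inchis[ok], "block1:", 14L)
    b2 <- hash_to_letters(inchis[ok], "block2:", 8L)
    out[ok] <- paste0(b1, "-", b2, "SA-N")
  }
  out
}

# --- rdkit backend ----------------------------------------------------------

# session cache: key generation is pure, so repeated loads of the same
# structures need not re-spawn the python subprocess
.rdkit_key_cache <- new.env(parent = emptyenv())

rdkit_inchikey_batch <- function(inchis) {
  if (length(inchis) == 0) return(character(0))
  cached <- vapply(inchis, function(i) {
    get0(i, envir = .rdkit_key_cache, ifnotfound = NA_character_)
  }, character(1), USE.NAMES = FALSE)
  todo <- which(is.na(cached) & !duplicated(inchis))
  if (length(todo)) {
    fresh <- rdkit_inchikey_subprocess(inchis[todo])
    for (j in seq_along(todo)) {
      if (!is.na(fresh[[j]])) assign(inchis[[todo[j]]], fresh[[j]], envir = .rdkit_key_cache)
    }
    cached <- vapply(inchis, function(i) {
      get0(i, envir = .rdkit_key_cache, ifnotfound = NA_character_)
    }, character(1), USE.NAMES = FALSE)
  }
  cached
}

rdkit_inchikey_subprocess <- function(inchis) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") {
    stop_chemxref("chemxref_backend", "no `python` executable found for the rdkit backend")
  }
  script <- system.file("python", "inchikey_batch.py", package = "chemxref", mustWork = TRUE)
  infile <- tempfile("inchi_", fileext = ".txt")
  outfile <- tempfile("inchikey_", fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  # InChIs are single-line by construction; NAs become empty lines (failures)
  writeLines(ifelse(is.na(inchis), "", inchis), infile, useBytes = TRUE)
  status <- system2(python, c(script, shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop_chemxref("chemxref_backend", "rdkit InChIKey backend subprocess failed")
  }
  keys <- readLines(outfile)
  if (length(keys) != length(inchis)) {
    stop_chemxref("chemxref_backend", "rdkit backend returned a truncated batch")
  }
  normalize_backend_keys(ifelse(keys == "", NA_character_, keys))
}

#' Generate Standard InChIKeys from Standard InChIs
#'
#' Deterministically computes the 27-character hashed form of each Standard
#' InChI via the configured backend. Inputs must carry the Standard-InChI
#' prefix `InChI=1S/`; anything else (including non-standard `InChI=1/`
#' strings) is a generation failure.
#'
#' @param std_inchi character vector of Standard InChI strings.
#' @param backend an [inchikey_backend()]; defaults to the rdkit backend.
#' @return character vector of InChIKeys, same length as `std_inchi`.
#' @examples
#' generate_inchikey("InChI=1S/H2O/h1H2", inchikey_backend("mock"))
#' @export
generate_inchikey <- function(std_inchi, backend = inchikey_backend("rdkit")) {
  stopifnot(inherits(backend, "inchikey_backend"))
  std_inchi <- trimws(as.character(std_inchi))
  keys <- rep(NA_character_, length(std_inchi))
  ok <- has_standard_prefix(std_inchi)
  if (any(ok)) keys[ok] <- backend$keys(std_inchi[ok])
  if (anyNA(keys)) {
    bad <- std_inchi[is.na(keys)][1]
    stop_chemxref("chemxref_keygen",
      sprintf("InChIKey generation failed for %s", encodeString(substr(bad, 1, 60), quote = "'")))
  }
  keys
}

# Batch key generation that reports failures as NA instead of erroring;
# used by the loading filter, where a failure is rule R3, not an error.
try_generate_inchikey <- function(std_inchi, backend) {
  keys <- rep(NA_character_, length(std_inchi))
  ok <- has_standard_prefix(std_inchi)
  if (any(ok)) keys[ok] <- backend$keys(std_inchi[ok])
  keys
}

#' Filter source records through the loading rules
#'
#' Every record of a source dump passes through five integrity rules before
#' registration; a record violating any of them is not loaded. Exactly one
#' rule is reported per rejected record, evaluated in a fixed order (cheapest
#' first, so each rejection has a single unambiguous cause):
#'
#' \describe{
#'   \item{R4}{The source does not provide an identifier for the structure.}
#'   \item{R2}{The source does not provide a Standard InChI for the record.}
#'   \item{R5}{The Standard InChI is longer than 2000 characters (strictly
#'     greater; a 2000-character InChI is accepted). The cut-off is what
#'     operationally defines "small molecule" for the registry.}
#'   \item{R3}{An InChIKey cannot be generated from the supplied InChI
#'     (malformed or non-standard input, or backend failure).}
#'   \item{R1}{The supplied InChIKey does not match the recomputed one.}
#' }
#'
#' A record whose InChI is valid but whose key column is empty is accepted:
#' the key is computed here and the absence is noted in a comment.
#'
#' @param records tibble of parsed dump rows with columns `line_no`,
#'   `src_compound_id`, `std_inchi`, `std_inchikey` (see
#'   [parse_source_dump()]).
#' @param backend an [inchikey_backend()].
#' @param source_provides_inchikey logical; set `FALSE` for sources whose
#'   feed never includes keys (the computed-key comment is then phrased as
#'   expected rather than as an anomaly).
#' @return The input tibble with columns `accepted` (logical),
#'   `rule_violated` (`"R1"`..`"R5"` or `NA`), `computed_inchikey`, and
#'   `comment` appended.
#' @export
validate_records <- function(records, backend = inchikey_backend("rdkit"),
                             source_provides_inchikey = TRUE) {
  stopifnot(is.data.frame(records))
  rec <- as_tibble(records)
  if (!"line_no" %in% names(rec)) rec$line_no <- seq_len(nrow(rec))
  for (col in c("src_compound_id", "std_inchi", "std_inchikey")) {
    rec[[col]] <- trimws(as.character(rec[[col]]))
    rec[[col]][is.na(rec[[col]])] <- ""
  }

  n <- nrow(rec)
  rule <- rep(NA_character_, n)
  comment <- rep(NA_character_, n)
  computed <- rep(NA_character_, n)

  rule[rec$src_compound_id == ""] <- "R4"
  rule[is.na(rule) & rec$std_inchi == ""] <- "R2"
  rule[is.na(rule) & nchar(rec$std_inchi) > 2000L] <- "R5"

  todo <- which(is.na(rule))
  if (length(todo)) {
    keys <- try_generate_inchikey(rec$std_inchi[todo], backend)
    computed[todo] <- keys
    failed <- todo[is.na(keys)]
    rule[failed] <- "R3"
    nonstd <- failed[startsWith(rec$std_inchi[failed], "InChI=1/")]
    comment[nonstd] <- "non-standard InChI (InChI=1/): only Standard InChI is accepted"
    comment[setdiff(failed, nonstd)] <- "InChIKey generation failed for the supplied InChI"
  }

  provided <- toupper(rec$std_inchikey)
  mism <- which(is.na(rule) & provided != "" & provided != computed)
  rule[mism] <- "R1"

  absent <- which(is.na(rule) & provided == "")
  comment[absent] <- if (isTRUE(source_provides_inchikey)) {
    "InChIKey absent from source record; computed during load"
  } else {
    "InChIKey computed during load (source provides InChIs only)"
  }

  rec$accepted <- is.na(rule)
  rec$rule_violated <- rule
  rec$computed_inchikey <- ifelse(rec$accepted, computed, NA_character_)
  rec$comment <- comment
  rec
}
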