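# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

read_inchi_fixture <- function() {
  path <- system.file("extdata", "inchi_fixture.tsv", package = "chemxref", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  as_tibble(df)
}

# Syntactically valid pseudo Standard InChIs, distinct by index; chemically
# meaningless, used only to grow test universes past the packaged fixture.
pseudo_inchis <- function(idx) {
  sprintf("InChI=1S/C%dH%dN%dO%d/c1-%d/h%dH", idx + 4L, 2L * idx + 6L,
          idx %% 3L + 1L, idx %% 4L + 1L, idx + 1L, idx %% 7L + 1L)
}

#' Build a pool of structure (InChI, InChIKey) pairs
#'
#' The pool backing synthetic dump histories. By default pairs are drawn
#' (in seeded random order) from a packaged list of 133 real small-molecule
#' Standard InChIs whose keys were computed once with the reference InChI
#' implementation; requests beyond the fixture size are padded with
#' syntactically valid pseudo-InChIs. Because pseudo-InChIs have no
#' reference key, and because the mock backend's keys differ from real ones
#' by construction, the pool's keys must be generated by the same backend
#' the consuming store will validate with: `keys = "fixture"` keeps the real
#' reference keys (fixture molecules only), `keys = "mock"` recomputes every
#' key with the mock backend, and the default `"auto"` picks `"fixture"`
#' when `n` fits inside the fixture and `"mock"` otherwise.
#'
#' @param n number of pairs (>= 1).
#' @param seed RNG seed; identical seeds give identical pools.
#' @param keys `"auto"`, `"fixture"` or `"mock"` (see above).
#' @return Tibble with `std_inchi`, `std_inchikey`, `n` rows, all distinct.
#' @export
make_structure_pool <- function(n, seed = 1L, keys = c("auto", "fixture", "mock")) {
  stopifnot(n >= 1)
  keys <- match.arg(keys)
  fix <- read_inchi_fixture()
  if (keys == "auto") keys <- if (n <= nrow(fix)) "fixture" else "mock"
  if (keys == "fixture" && n > nrow(fix)) {
    validation_error(sprintf(
      "keys = \"fixture\" supports at most %d structures (the packaged fixture size)",
      nrow(fix)))
  }
  pool <- with_local_seed(seed, {
    take <- min(n, nrow(fix))
    sampled <- fix[sample.int(nrow(fix), take), c("std_inchi", "std_inchikey")]
    if (n > take) {
      extra <- tibble(std_inchi = pseudo_inchis(seq_len(n - take)),
                      std_inchikey = NA_character_)
      sampled <- bind_rows(sampled, extra)
    }
    sampled
  })
  if (keys == "mock") {
    pool$std_inchikey <- generate_inchikey(pool$std_inchi, inchikey_backend("mock"))
  } else if (anyNA(pool$std_inchikey)) {
    pool$std_inchikey[is.na(pool$std_inchikey)] <-
      generate_inchikey(pool$std_inchi[is.na(pool$std_inchikey)], inchikey_backend("rdkit"))
  }
  as_tibble(pool)
}

#' Specify a synthetic multi-source dump universe
#'
#' Describes the conditions under which a synthetic load history is
#' generated: how many sources and structures, how many releases per source,
#' and the per-release churn model. Churn is per-record independent
#' Bernoulli: at each release after the first, an active record drops with
#' probability `p_drop`, a dropped record reappears with probability
#' `p_reappear`, and each not-yet-introduced record enters with probability
#' `p_add`. Structure sharing across sources (`p_shared_structure`) and
#' identifiers mapping to more than one structure (`p_multimap`) produce the
#' many-to-many mappings the registry must track.
#'
#' @param n_sources number of sources (>= 1).
#' @param n_structures size of the structure pool.
#' @param n_releases_per_source releases generated for every source.
#' @param churn_rates named numeric `c(p_drop=, p_add=, p_reappear=)`, each
#'   in \[0, 1\].
#' @param p_shared_structure probability that a structure is covered by each
#'   additional source beyond its first.
#' @param p_multimap probability that an identifier maps to a second
#'   structure.
#' @param seed RNG seed; identical seeds give byte-identical histories.
#' @param backend InChIKey backend the history is generated for (`"mock"` or
#'   `"rdkit"`); dumps carry keys from this backend so that a store created
#'   with the same backend accepts every record.
#' @return A `universe_spec` list.
#' @export
universe_spec <- function(n_sources = 3L, n_structures = 200L,
                          n_releases_per_source = 5L,
                          churn_rates = c(p_drop = 0.15, p_add = 0.15, p_reappear = 0.3),
                          p_shared_structure = 0.3, p_multimap = 0.1,
                          seed = 1L, backend = c("mock", "rdkit")) {
  backend <- match.arg(backend)
  stopifnot(n_sources >= 1, n_structures >= 1, n_releases_per_source >= 1,
            all(c("p_drop", "p_add", "p_reappear") %in% names(churn_rates)),
            all(churn_rates >= 0 & churn_rates <= 1),
            p_shared_structure >= 0, p_shared_structure <= 1,
            p_multimap >= 0, p_multimap <= 1)
  structure(list(
    n_sources = as.integer(n_sources), n_structures = as.integer(n_structures),
    n_releases_per_source = as.integer(n_releases_per_source),
    churn_rates = churn_rates, p_shared_structure = p_shared_structure,
    p_multimap = p_multimap, seed = as.integer(seed), backend = backend
  ), class = "universe_spec")
}

#' Generate a multi-source, multi-release dump history
#'
#' Writes one TSV dump per (source, release) in the loader's dialect, plus a
#' `manifest.json`, into `dir`. Releases are ordered round-robin across
#' sources (release 1 of every source, then release 2, ...), which is the
#' load order [load_history()] and [oracle_state()] assume when assigning
#' global release numbers. Identical specs (same seed) produce
#' byte-identical files.
#'
#' With `corrupt = TRUE`, five extra records -- exactly one violating each
#' loading rule -- are appended to the final release of the first source,
#' for exercising the filter.
#'
#' @param spec a [universe_spec()].
#' @param dir output directory (created).
#' @param corrupt inject one violation of each of the five rules.
#' @return The manifest: a tibble with `source_name`, `src_index`,
#'   `release_index`, `version_label`, `base_url`, `path`, in load order.
#' @export
make_history <- function(spec, dir = tempfile("history_"), corrupt = FALSE) {
  stopifnot(inherits(spec, "universe_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pool <- make_structure_pool(spec$n_structures, seed = spec$seed,
                              keys = if (spec$backend == "mock") "mock" else "auto")
  p <- spec$churn_rates

  releases <- with_local_seed(spec$seed + 1L, {
    # which sources cover each structure
    n_extra <- stats::rbinom(spec$n_structures, spec$n_sources - 1L, spec$p_shared_structure)
    coverage <- lapply(seq_len(spec$n_structures), function(i) {
      if (spec$n_sources == 1L) return(1L)
      sort(sample.int(spec$n_sources, 1L + n_extra[[i]]))
    })

    lapply(seq_len(spec$n_sources), function(s) {
      structs <- which(vapply(coverage, function(cv) s %in% cv, logical(1)))
      if (length(structs) == 0) structs <- s %% spec$n_structures + 1L  # never an empty source
      recs <- tibble(
        src_compound_id = sprintf("S%02dC%04d", s, seq_along(structs)),
        struct = structs)
      multi <- which(stats::runif(nrow(recs)) < spec$p_multimap)
      if (length(multi) && length(structs) > 1L) {
        second <- vapply(recs$struct[multi], function(st) {
          candidates <- setdiff(structs, st)
          candidates[[sample.int(length(candidates), 1L)]]
        }, integer(1))
        recs <- bind_rows(recs, tibble(
          src_compound_id = recs$src_compound_id[multi], struct = second))
      }
      # records start active except a held-back reserve that enters via p_add
      state <- rep("active", nrow(recs))
      if (p[["p_add"]] > 0) {
        state[stats::runif(nrow(recs)) < 0.3] <- "reserve"
      }
      per_release <- vector("list", spec$n_releases_per_source)
      for (r in seq_len(spec$n_releases_per_source)) {
        if (r > 1L) {
          u <- stats::runif(length(state))
          state <- ifelse(state == "active" & u < p[["p_drop"]], "dropped",
                   ifelse(state == "dropped" & u < p[["p_reappear"]], "active",
                   ifelse(state == "reserve" & u < p[["p_add"]], "active", state)))
        }
        per_release[[r]] <- recs[state == "active", , drop = FALSE]
      }
      per_release
    })
  })

  manifest <- tibble(
    source_name = character(), src_index = integer(), release_index = integer(),
    version_label = character(), base_url = character(), path = character())
  for (r in seq_len(spec$n_releases_per_source)) {
    for (s in seq_len(spec$n_sources)) {
      recs <- releases[[s]][[r]]
      rows <- tibble(
        src_compound_id = recs$src_compound_id,
        std_inchi = pool$std_inchi[recs$struct],
        std_inchikey = pool$std_inchikey[recs$struct])
      rows <- arrange(rows, .data$src_compound_id, .data$std_inchi)
      if (corrupt && s == 1L && r == spec$n_releases_per_source) {
        rows <- bind_rows(rows, corruption_rows(pool))
      }
      path <- file.path(dir, sprintf("source_%02d_r%02d.tsv", s, r))
      writeLines(c("src_compound_id\tstandardinchi\tstandardinchikey",
                   paste(rows$src_compound_id, rows$std_inchi, rows$std_inchikey,
                         sep = "\t")),
                 path, useBytes = TRUE)
      manifest <- bind_rows(manifest, tibble(
        source_name = sprintf("source_%02d", s), src_index = s, release_index = r,
        version_label = sprintf("v%d", r), base_url = NA_character_, path = path))
    }
  }
  attr(manifest, "backend") <- spec$backend
  jsonlite::write_json(
    list(backend = spec$backend, seed = spec$seed,
         dumps = manifest[c("source_name", "src_index", "release_index",
                            "version_label", "path")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, dataframe = "rows")
  manifest
}

# one record violating each loading rule, appended to a dump when corruption
# is requested; ids are labelled by the rule they trip
corruption_rows <- function(pool) {
  long_inchi <- paste0("InChI=1S/", strrep("C", 2001L - nchar("InChI=1S/")))  # length 2001
  tibble(
    src_compound_id = c("BAD_R1", "BAD_R2", "BAD_R3", "", "BAD_R5"),
    std_inchi = c(pool$std_inchi[[1]], "", "not-an-inchi", pool$std_inchi[[2]], long_inchi),
    std_inchikey = c("AAAAAAAAAAAAAA-AAAAAAAASA-N", "", "", "", ""))
}

#' Load a generated history into a store
#'
#' Registers every source in the manifest (in `src_index` order, so source
#' numbering matches the generator's) and loads the dumps in manifest order,
#' which is the round-robin order [make_history()] wrote and the order
#' [oracle_state()] replays.
#'
#' @param store an `xref_store` (its backend should match the manifest's).
#' @param manifest tibble from [make_history()] or [diazepam_fixture()].
#' @param allow_empty passed to [load_release()]; random churn can empty a
#'   release, which is legitimate in a synthetic history.
#' @return Tibble with one row per load (the [glance()] of each report).
#' @export
load_history <- function(store, manifest, allow_empty = TRUE) {
  for (s in unique(manifest$src_index)) {
    row <- manifest[manifest$src_index == s, ][1, ]
    bu <- row$base_url
    add_source(store, row$source_name,
               base_url = if (is.na(bu)) NULL else bu,
               description = "synthetic history source")
  }
  reports <- purrr::pmap(manifest, function(source_name, version_label, path, ...) {
    load_dump(store, source_name, path, version_label, allow_empty = allow_empty)
  })
  purrr::map_dfr(reports, glance)
}

#' Brute-force replay oracle for a dump history
#'
#' Recomputes the expected final assignment state of a history with plain
#' set operations, independently of the incremental loader: for each source,
#' the current assignments are exactly the accepted (identifier, InChI)
#' pairs of its latest release; every pair ever accepted but not current is
#' obsolete; and an obsolete pair's last-current release is the latest
#' (global) release number of a dump that contained it. Dumps are filtered
#' through the same five loading rules before replay.
#'
#' @param manifest tibble from [make_history()] (load order = row order).
#' @param backend an [inchikey_backend()]; defaults to the manifest's.
#' @return Tibble with `source_name`, `src_compound_id`, `std_inchi`,
#'   `status`, `last_release_u_current` (`NA` for current rows), sorted for
#'   direct comparison with the matching columns of [tidy.xref_store()].
#' @export
oracle_state <- function(manifest, backend = NULL) {
  if (is.null(backend)) {
    backend <- inchikey_backend(attr(manifest, "backend") %||% "mock")
  }
  st <- tibble(source_name = character(), src_compound_id = character(),
               std_inchi = character(), status = character(),
               last_seen = integer())
  for (i in seq_len(nrow(manifest))) {
    src <- manifest$source_name[[i]]
    recs <- parse_source_dump(manifest$path[[i]])
    out <- validate_records(recs, backend = backend)
    acc <- distinct(dplyr::filter(out, .data$accepted),
                    .data$src_compound_id, .data$std_inchi)
    present <- paste(src, acc$src_compound_id, acc$std_inchi, sep = "\r")
    keys <- paste(st$source_name, st$src_compound_id, st$std_inchi, sep = "\r")

    hit <- keys %in% present
    st$status[hit] <- "current"
    st$last_seen[hit] <- i
    st$status[st$source_name == src & !hit] <- "obsolete"

    fresh <- !(present %in% keys)
    if (any(fresh)) {
      st <- bind_rows(st, tibble(
        source_name = src,
        src_compound_id = acc$src_compound_id[fresh],
        std_inchi = acc$std_inchi[fresh],
        status = "current", last_seen = i))
    }
  }
  st$last_release_u_current <- ifelse(st$status == "obsolete", st$last_seen, NA_integer_)
  st$last_seen <- NULL
  arrange(st, .data$source_name, .data$src_compound_id, .data$std_inchi)
}

#' Assignment state of a store in oracle form
#'
#' Projects the store's assignment table onto the columns [oracle_state()]
#' reports, for direct equality comparison.
#'
#' @param store an `xref_store`.
#' @return Tibble with `source_name`, `src_compound_id`, `std_inchi`,
#'   `status`, `last_release_u_current`, sorted as the oracle sorts.
#' @export
store_assignment_state <- function(store) {
  df <- tidy(store)[c("source_name", "src_compound_id", "std_inchi",
                      "status", "last_release_u_current")]
  arrange(df, .data$source_name, .data$src_compound_id, .data$std_inchi)
}

#' The worked three-source benzodiazepine fixture
#'
#' A small hand-built history reproducing the canonical cross-referencing
#' scenario: a ChEMBL-like source whose identifier CHEMBL12 denotes
#' diazepam in both its releases; a DrugBank-like source whose first release
#' assigns both DB00829 and DB07699 to the same diazepam structure and whose
#' second release drops DB07699 (making that assignment obsolete, last
#' current in the source's first release); and a PDBe-like source with a
#' compound-page base URL whose identifier DIZ shares a second structure
#' with ChEMBL's CHEMBL661, exercising URL construction. Releases are
#' ordered round-robin, so DB07699's last-current release is global release
#' number 2.
#'
#' @param dir output directory for the dump files.
#' @param backend `"rdkit"` writes the real reference InChIKeys into the
#'   dumps; `"mock"` writes mock-backend keys so the fixture can be loaded
#'   into a mock-backend store without chemistry software.
#' @return Manifest tibble as from [make_history()].
#' @export
diazepam_fixture <- function(dir = tempfile("diazepam_"),
                             backend = c("rdkit", "mock")) {
  backend <- match.arg(backend)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fix <- read_inchi_fixture()
  diaz <- fix[fix$name == "diazepam", ]
  alpr <- fix[fix$name == "alprazolam", ]
  stopifnot(nrow(diaz) == 1, nrow(alpr) == 1)
  if (backend == "mock") {
    diaz$std_inchikey <- generate_inchikey(diaz$std_inchi, inchikey_backend("mock"))
    alpr$std_inchikey <- generate_inchikey(alpr$std_inchi, inchikey_backend("mock"))
  }

  dump <- function(file, ids, structs) {
    path <- file.path(dir, file)
    writeLines(c("src_compound_id\tstandardinchi\tstandardinchikey",
                 paste(ids,
                       vapply(structs, function(s) s$std_inchi, character(1)),
                       vapply(structs, function(s) s$std_inchikey, character(1)),
                       sep = "\t")),
               path, useBytes = TRUE)
    path
  }

  pdbe_base <- "http://www.ebi.ac.uk/pdbe-srv/pdbechem/chemicalCompound/show/"
  manifest <- tibble(
    source_name = c("ChEMBL", "DrugBank", "PDBe", "ChEMBL", "DrugBank"),
    src_index = c(1L, 2L, 3L, 1L, 2L),
    release_index = c(1L, 1L, 1L, 2L, 2L),
    version_label = c("r1", "v1", "2013.1", "r2", "v2"),
    base_url = c(NA, NA, pdbe_base, NA, NA),
    path = c(
      dump("chembl_r1.tsv", c("CHEMBL12", "CHEMBL661"), list(diaz, alpr)),
      dump("drugbank_r1.tsv", c("DB00829", "DB07699"), list(diaz, diaz)),
      dump("pdbe_r1.tsv", "DIZ", list(alpr)),
      dump("chembl_r2.tsv", c("CHEMBL12", "CHEMBL661"), list(diaz, alpr)),
      dump("drugbank_r2.tsv", "DB00829", list(diaz))
    ))
  attr(manifest, "backend") <- backend
  manifest
}
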