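# chemxref

Cross-referencing small-molecule identifiers across chemical databases is a
maintenance problem: every resource (a bioactivity database, a structural
archive, a metabolite dictionary) names its compounds its own way, updates
on its own schedule, and occasionally retires identifiers. `chemxref` is an
embeddable R registry that solves this the way large-scale sequence archives
solve it for proteins: by normalizing everything onto a canonical key — the
**Standard InChI** — and keeping an append-only history of every
identifier-to-structure assignment.

It is intended for data managers and cheminformaticians who need to build
and refresh structure-based links between resources (or audit identifier
churn within one resource) without hand-maintaining pairwise mappings.

## The model

The registry is four relational tables in a single SQLite file:

- `UC_STRUCTURES` — one row per distinct Standard InChI, keyed by an integer
  **UCI** allocated at first sight. The (UCI, InChI) binding is immutable:
  rows are never updated or deleted, even if a structure disappears from
  every source.
- `UC_SOURCES` — registered identifier namespaces (`src_id`, name, optional
  compound-page base URL). Identical identifier strings may exist under
  different sources, so every query names its source.
- `UC_XREF` — assignments `(src_compound_id, src_id, UCI)`, the composite
  primary key. Rows are never deleted; the only mutable fields are the
  `current`/`obsolete` flag and `LAST_REL_U_CUR`, the release in which an
  obsolete assignment was last current. Many-to-many mappings are ordinary
  data here.
- `UC_RELEASE` — one row per load event, with the per-rule rejection counts
  retained permanently.

Sources deposit three-column TSV dumps (`src_compound_id`, Standard InChI,
Standard InChIKey). A single loading algorithm filters each record through
five integrity rules (key/InChI mismatch; missing InChI; key generation
failure; missing identifier; InChI longer than 2000 characters — the
operational definition of "small molecule"), registers new structures, and
reconciles the source's assignments: absent pairs flip to obsolete,
re-appearing pairs flip back to current. Because equivalence is "same
Standard InChI", every cross-source link is implied by the data and needs no
curation; tautomers that a source distinguishes with non-standard keys
collapse onto one structure, a deliberate precision trade-off.

InChIKeys are always recomputed from the InChI, never trusted. Key
generation is an injectable backend: the production backend calls the InChI
implementation bundled with RDKit through a batched `python` subprocess;
a pure-R deterministic mock backend lets all registry logic run without
chemistry software.

## Worked example

The classic scenario: the ChEMBL identifier for diazepam, two DrugBank
identifiers on the same structure (one later retired), and a PDBe-like
source with compound-page URLs.

```r
library(chemxref)

st  <- store_create(":memory:", backend = "rdkit")
man <- diazepam_fixture()          # writes 5 TSV dumps for 3 sources
load_history(st, man)              # registers sources, loads in order

lookup(st, "CHEMBL12", 1)
#> # A tibble: 3 × 7
#>   src_compound_id src_id source_name status     uci std_inchi       std_inchikey
#>   <chr>            <int> <chr>       <chr>    <int> <chr>           <chr>
#> 1 CHEMBL12             1 ChEMBL      current      1 InChI=1S/C16H1… AAOVKJBEBID…
#> 2 DB00829              2 DrugBank    current      1 InChI=1S/C16H1… AAOVKJBEBID…
#> 3 DB07699              2 DrugBank    obsolete     1 InChI=1S/C16H1… AAOVKJBEBID…
```

All three identifiers share UCI 1 (the diazepam Standard InChI); DB07699 is
flagged obsolete because DrugBank's second release dropped it. Restricting
to current assignments in source 2 retrieves exactly the live DrugBank
record, and URL mode builds compound-page links:

```r
lookup(st, "CHEMBL12", 1, mode = "current", target_src_id = 2)$src_compound_id
#> [1] "DB00829"

lookup_as_urls(st, "CHEMBL661", 1, 3)
#> [1] "http://www.ebi.ac.uk/pdbe-srv/pdbechem/chemicalCompound/show/DIZ"

whole_source_mapping(st, 1, 2)      # bulk link table, joined on structure
#> # A tibble: 1 × 2
#>   from_id  to_id
#>   <chr>    <chr>
#> 1 CHEMBL12 DB00829

audit_obsolete(st)$last_release_u_current
#> [1] 2                              # DB07699 was last current in release 2
```

`search_structure()` answers the same queries from an InChI or InChIKey;
`tidy()`/`glance()` give flat views of a store or load report, and
`autoplot()` charts current/obsolete counts per source. A `chemxref` shell
command (in `exec/`) wraps the same functions: `init`, `add-source`,
`load`, `rollback`, `query`, `search`, `map`, `sources`, `audit`.

Synthetic multi-release histories with tunable identifier churn
(`universe_spec()`, `make_history()`) and a brute-force replay oracle
(`oracle_state()`) make the whole lifecycle testable offline; see the
methods vignette.

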