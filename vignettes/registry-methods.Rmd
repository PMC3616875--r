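---
title: "Structure-keyed identifier registration: model, rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-keyed identifier registration: model, rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemxref)
```

## The problem and the model

Chemistry resources each maintain their own compound identifiers, release
on their own schedules, and retire identifiers over time. Maintaining
pairwise links between $n$ resources scales as $n^2$ curation efforts;
`chemxref` instead normalizes every deposited record onto the Standard
InChI, so that all links between all sources follow from a single shared
table. The design borrows the archival discipline of large protein-sequence
archives: the binding between a structure and its registry identifier is
permanent, and assignment history is append-only.

Formally, the registry state is:

- a bijection $\mathrm{UCI} \leftrightarrow \mathrm{StdInChI}$ over all
  structures ever accepted, grown monotonically (UCIs are consecutive
  integers in first-registration order);
- a set of assignments $(i, s, u)$ — identifier $i$ of source $s$ bound to
  structure $u$ — each flagged *current* or *obsolete*. The set only grows.
  After loading release $r$ of source $s$, the current assignments of $s$
  are exactly the accepted (identifier, structure) pairs of $r$; every pair
  of $s$ ever seen but absent from $r$ is obsolete.
- for each obsolete assignment, `LAST_REL_U_CUR`: the source's release in
  which the pair last appeared. Deliberately, only the *most recent*
  obsolescence is tracked; an assignment that cycles
  current→obsolete→current→obsolete keeps only the latest marker. A full
  event history would need a different data model and has no driving use
  case here.

Structural equivalence is byte-exact Standard InChI equality (after
whitespace trimming; InChIKeys are upper-cased before comparison). This is
deliberately coarser than some sources' own normalization: a source that
distinguishes tautomers or ionization states with non-standard keys will
see several of its identifiers collapse onto one registry structure, and
mappings through that structure fan out accordingly. That precision loss is
accepted in exchange for an equivalence definition every depositor can
compute independently. No connection tables, Molfiles or SMILES are stored;
conversion of other representations into Standard InChI is upstream
preprocessing, outside the registry.

Provenance is likewise out of scope by design: all structures of a source
are loaded whether or not the source is their primary origin, so "circular"
links between mirroring resources are the querying user's filtering
problem. Sub-sets of a source can simply be registered as additional
sources.

## The loading rules

Each dump record passes five checks; a record failing any is not loaded,
and per-rule rejection counts are stored permanently with the release. The
rules, in their evaluation order:

| order | rule | condition |
|-------|------|-----------|
| 1 | R4 | no `src_compound_id` supplied |
| 2 | R2 | no Standard InChI supplied |
| 3 | R5 | InChI longer than 2000 characters (strictly; 2000 is accepted) |
| 4 | R3 | InChIKey cannot be generated from the InChI |
| 5 | R1 | supplied InChIKey differs from the recomputed one |

The 2000-character cut-off (counted over the full string including the
`InChI=1S/` prefix — an interpretation this package fixes explicitly) is
what operationally defines "small molecule" for the registry. No evaluation
order is inherent in the rules themselves; this package fixes
cheapest-first order so that exactly one rule is blamed per rejected record
and reports are unambiguous. R1/R3 are the integrity core: keys are always
recomputed, never trusted. A record with a valid InChI but no key is
accepted with the computed key and a comment noting the absence, since
several real feeds provide InChIs only. Strings with the non-standard
`InChI=1/` prefix are rejected under R3 with a distinguishing comment:
only Standard InChI is a valid normalization key here, and silently
treating the two as equivalent would corrupt the equivalence relation.

Validation is syntactic (prefix, emptiness, length, key agreement). The
reference key generator itself hashes any well-prefixed string, so a
chemically absurd but well-formed InChI will register; full chemical
validation of InChI layers is a non-goal, matching how such registries
treat depositor data in practice.

## Loading, transitions and rollback

`load_release()` allocates the next global release number, filters,
registers structures, then reconciles assignments by three set operations
(new → insert current; re-appearing obsolete → flip current; missing
current → flip obsolete with the source's previous release recorded). The
whole release is one SQLite transaction. Two deliberate choices:

- **Global release counter.** Release numbers increase across all sources
  (the composite `(RELEASE_U, SRC_ID)` key is still recorded). A
  per-source counter would be equally defensible; the global counter keeps
  the obsolescence marker an unambiguous foreign key.
- **Empty-release guard.** A release whose accepted set is empty would
  obsolete every assignment of the source. Far more often that is a
  truncated download than a real deletion, so it requires
  `allow_empty = TRUE`.

`rollback_release()` undoes the most recent load of a source from a
per-release journal of pre-images: inserted assignment rows are removed and
flipped rows restored, giving back the byte-exact pre-load snapshot. This
is the single exception to assignment-set monotonicity, and it never
touches `UC_STRUCTURES` — structures registered by a rolled-back release
simply remain, assignment-less, because the UCI binding is immutable.
Only the latest load is reversible; anything older has been built upon.

Within one release, the same identifier may legitimately appear with
several InChIs (and several identifiers with one InChI); all load as
parallel current assignments. Exact duplicate lines are collapsed at parse
time with a comment.

## Querying semantics

`lookup()` anchors on the structures the query identifier is *currently*
assigned to, then returns all assignments of those structures (the query
row included), with obsolete rows either labelled (`mode = "all"`) or
dropped (`mode = "current"`). Two boundary decisions are worth stating:

- A fully obsolete query identifier has no current anchor: in current mode
  it returns nothing (it is not assigned to anything anymore), while in
  all mode it anchors on its historical structures so its last known
  equivalences remain inspectable.
- A multi-mapped identifier anchors on *all* its current structures and
  returns the union of their rows; the structural columns in the output
  let callers cluster rows per structure by sorting. Consequently
  identifier-lookup equals the InChIKey search for single-structure
  identifiers, and equals the union of key searches in general — the form
  in which the route-equivalence property is tested.

`whole_source_mapping()` is the bulk form — all identifier pairs between
two sources joined on shared UCI — and equals the union of per-identifier
lookups; `lookup_as_urls()` prepends a target source's registered base URL
to matched identifiers. Row order `(uci, src_id, src_compound_id)` and
pair order `(from_id, to_id)` are fixed so that output is reproducible;
no ordering is semantically meaningful.

## InChIKey backends

Key generation is injectable. The `rdkit` backend shells out to the InChI
library bundled with RDKit (batched, one subprocess per novel batch, with a
session cache keyed on the InChI string — generation is pure). The `mock`
backend is a deterministic pure-R hash laid out like a real key
(`14 letters - 8 letters + "SA" - "N"`, hyphens at positions 15 and 26).
It exists so every piece of loader/query logic is testable without
chemistry software; its keys are not real InChIKeys, so a store must be
validated end-to-end with one backend throughout (the store records its
backend at creation). Mixed use is the one way to make every record fail
the R1 mismatch rule, which is also a useful property: it means key
provenance errors cannot pass silently.

## The synthetic-history generator and its oracle

`universe_spec()` fixes the generation conditions; its defaults — 3
sources, 200 structures, 5 releases per source, churn
`p_drop = 0.15, p_add = 0.15, p_reappear = 0.3`, `p_shared_structure = 0.3`,
`p_multimap = 0.1` — are the standing conditions under which the loader's
properties are exercised (and the sizes used by the acceptance checks:
20 such histories for the oracle comparison, single histories of 80–200
structures for the query-route and idempotency properties; a full run
stays within a couple of minutes on one CPU). Churn is per-record
independent Bernoulli per release: the simplest model that produces every
transition the loader must handle (new, dropped, re-appearing, never-seen).
Structure sharing and multi-mapping rates generate the many-to-many cases.
Records are drawn from a packaged fixture of 133 real small molecules with
reference-computed keys, padded with syntactically valid pseudo-InChIs
(mock-keyed) beyond that size. Generation is seed-deterministic to the
byte; a corruption switch appends exactly one violation of each loading
rule for filter tests.

What the generator does *not* emulate: chemically realistic structure
distributions, real sources' identifier formats and dump sizes (millions of
rows), wall-clock release schedules, or encoding pathologies in real feeds.
Passing tests therefore demonstrate the correctness of the registration
logic and query algebra under controlled churn, not the operational
robustness of downloading and parsing arbitrary third-party feeds — the
per-source downloaders that would face those are explicitly outside this
package.

`oracle_state()` is the independent check: it replays a history with plain
set operations (current = accepted pairs of the latest release; obsolete =
ever-seen minus current; last-current = the latest global release
containing the pair) and is compared for exact equality with the
incremental loader's full assignment state, including obsolescence
markers. The two computations share only the record filter, which is
deliberate: filtering is not what the oracle is checking.

## Numerical and degenerate-input choices

- UCIs and `src_id`s are instance-local consecutive integers; two
  independently built stores will number the same content differently.
  Nothing about the registry's answers depends on the numbering.
- Equality on InChIs is byte-exact after trimming; keys upper-cased. No
  Unicode normalization is applied — depositors supplying the same
  structure in different InChI *bytes* are different structures, as they
  are for any byte-keyed archive.
- Blank-line and wrong-column dumps fail parsing loudly with the line
  number; headers are detected only by the literal first field
  `src_compound_id` (case-insensitive), never guessed.
- An InChIKey query of the wrong shape is an error, not an empty result,
  to distinguish "not registered" from "not a key".
- Empty query results are successes everywhere (exit code 0 in the CLI);
  unknown *sources* are errors — source registration is explicit, so a
  typo'd `src_id` is a caller bug, not missing data.

## Known limitations

Single-writer embedded store (no concurrent loading); no REST layer, no
pagination; no similarity, substructure, or stereo-insensitive
connectivity-block search (the InChIKey's 14-character connectivity prefix
is stored and indexed, so the latter would be a natural extension); no
storage of multiple structure representations per UCI; rollback depth of
one release per source. Identifier history is archived only to the depth
of one obsolescence marker, as described above.
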