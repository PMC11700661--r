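---
title: "Protein-graphs: exact exploration of the annotated peptide search space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-graphs: exact exploration of the annotated peptide search space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgraph)
```

## The problem

Bottom-up proteomics identifies spectra against a database of candidate
peptide sequences, almost always the tryptic digest of canonical protein
sequences. UniProtKB, however, annotates far more sequence knowledge than
the canonical string: single amino acid polymorphisms (VARIANT), reported
sequence discrepancies (CONFLICT), experimentally induced substitutions
(MUTAGEN), isoforms (VAR_SEQ), and maturation events that remove the
initiator methionine, signal- and pro-peptides or excise internal products
(INIT_MET, SIGNAL, PROPEP, PEPTIDE, CHAIN). Exporting all combinations of
these annotations to FASTA is combinatorially hopeless: $k$ independent
substitutions alone multiply the number of sequence forms by $2^k$, and
well-annotated human proteins carry over a thousand variants.

`pepgraph` represents each protein entry as a labelled directed acyclic
graph instead. Every residue is a vertex on a chain between a dedicated
start vertex $s$ and end vertex $e$; every annotation adds alternative
routes; in-silico digestion opens peptide boundaries. After digestion,
**every complete $s \to e$ path spells exactly one peptide**, and the
whole search space can be counted exactly, characterized by attributes,
or queried by precursor mass — without ever materializing it.

## The graph model

`build_protein_graph()` applies a fixed pipeline:

1. **Initial graph** — one single-residue vertex per canonical residue,
   one extra chain per isoform (isoform sequences are materialized from
   VAR_SEQ edits beforehand by `derive_isoforms()`), all chains connected
   from $s$ and to $e$.
2. **Maturation features** — INIT_MET adds $s \to 2$; an N-terminal
   SIGNAL/PROPEP ($1..k$) adds $s \to k{+}1$; a C-terminal one ($k..L$)
   adds $k{-}1 \to e$; PEPTIDE and CHAIN ($a..b$) add both $s \to a$ and
   $b \to e$, so the matured product is itself a complete path.
3. **Substitution features** — an alternative chain spelling the
   replacement bridges every predecessor of the first replaced vertex to
   every successor of the last one (deletions bridge directly). The
   original chain is untouched, so paths with and without the feature
   coexist, and two features overlapping the same residues can never be
   combined on one path.
4. **Digestion** — for every residue edge $u \to v$ matching the enzyme
   rule (trypsin default: cut after K or R unless followed by P), the
   edge is marked *cleaved* and boundary edges $s \to v$ and $u \to e$
   are added. The missed-cleavage count of a peptide is the number of
   cleaved edges its path traverses. An unspecific rule marks every
   internal edge and opens boundaries at every residue.
5. **PTM annotation** — fixed modification deltas are folded into
   per-vertex masses; variable deltas are stored per residue occurrence
   and expanded during queries only.
6. **Compaction** — maximal chains whose interior vertices have in- and
   out-degree one, joined by uncleaved, feature-free edges, merge into
   single multi-residue vertices. The multiset of (spelled sequence,
   cleaved-edge count, feature-id set) over complete paths is provably
   unchanged; on the synthetic corpus this removes about 70–75% of
   vertices and about 60% of edges (the reduction grows with chain
   length, since a feature-free chain collapses to a single vertex).

Edges are a *set*: adding an edge that already exists merges its labels.
Two design consequences are worth spelling out, because they define what
"this peptide uses feature X" means everywhere in the package:

* **Feature identity is path identity.** A peptide is a path, not a
  string; two paths spelling the same sequence are distinct peptides and
  are merged only at FASTA export (optionally, with concatenated
  headers).
* **Bridges inherit the ids of the edges they bypass.** If a bridge for
  feature B starts at a vertex that is only adjacent to B's region
  because of feature A (a maturation start, an adjacent deletion), the
  bridge carries both ids. Without this, a peptide skipping two adjacent
  deleted regions would silently lose one of its annotations. A feature
  id is still counted once per path: alternative-chain vertices own their
  id, and the counting increment of an edge is the set of ids it
  introduces *newly*.

## Exact counting

`count_paths()` is a single topological-order pass accumulating the
number of paths into each vertex. Counts are arbitrary-precision
integers (`bigint`, base-$10^9$ limbs, addition and comparison only):
annotated search spaces exceed $10^{200}$ and must never overflow or
round. `count_by_attribute()` carries one bin-indexed vector per vertex
instead, for peptide length, missed cleavages, variant count or feature
count; with a `cap`, states beyond the cap collapse into an absorbing
overflow bin so capped runs stay cheap. One subtlety: a maturation
product traversed end to end sees its feature id on both its entry and
its exit edge; for the `feature_count` attribute the DP state therefore
also carries the (tiny) set of entry-edge ids that could reappear at the
end, and the final transition subtracts the overlap. The `variant_count`
attribute needs no such correction, because substitution ids are owned
by vertices and cannot recur.

## Mass queries

`to_csr()` freezes a compacted graph into a compressed sparse row form in
a deterministic topological order (Kahn's algorithm, smallest vertex id
first), so $s$ is vertex 0, $e$ is last, and every edge points forward;
`write_csr()`/`read_csr()` serialize it to a little-endian binary format
that round-trips bit for bit. All mass arithmetic is fixed-point at
$10^{-9}$ Da held in doubles (a 5000 Da peptide is $5 \times 10^{12}$,
far inside the $2^{53}$ exact-integer range), so pruning comparisons are
exact and platform-independent.

`query_csr()` enumerates every complete path whose monoisotopic mass
(residue masses + water + applied variable deltas) lies in a query
window. It is a depth-first traversal with interval pruning: after a
reverse-topological pass (`precompute_bounds()`) every vertex knows the
minimum and maximum mass still ahead of it, and a partial path is
abandoned as soon as its accumulated mass plus those bounds cannot meet
the window. Variable-modification deltas contribute their negative part
to the minimum and positive part to the maximum, which keeps the bounds
sound for mass losses as well. The number of complete paths is
exponential in the worst case ($O(2^{n-1})$ on a fully branched graph),
which is exactly why per-peptide limits (`query_limits()`: variants,
features, missed cleavages, hit cap) and a cooperative timeout exist;
truncation is signalled via the `completed` flag, never raised.

`precursor_to_interval()` converts an observed precursor ($m/z$, charge
$z$, tolerance in ppm) to a neutral-mass window
$[M(1-\epsilon), M(1+\epsilon)]$ with $M = z \cdot m/z - z \cdot m_p$,
rounded outward to the fixed-point grid. `estimate_feature_limit()`
answers "how many features per peptide can I afford to export for this
window": a saturating-count DP over (feature count, coarse mass bin)
states. Its mass binning accumulates bin lower edges and is deliberately
approximate — it is a budgeting heuristic, and its counts are only ever
compared against the budget.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| enzyme rule | trypsin (cut after K/R, blocked by P) | — | `enzyme_rule()`, `enzyme_unspecific()` |
| water mass | 18.010565 | Da | added once per peptide |
| proton mass | 1.007276466 | Da | precursor conversion |
| residue masses | standard monoisotopic table | Da | `default_residue_masses()`; U and O included, B/Z/X are mass-less and excluded from queries |
| `max_variable_per_peptide` | 3 | count | variable-PTM branching cap |
| global export mass cap | 5000 | Da | typical search-engine ceiling |
| `estimate_feature_limit` bin width | 25 | Da | coarse by design |
| timeout check interval | 4096 | expansions | cooperative timeout granularity |

All masses are overridable per call; none are read from global state.

## The synthetic corpus and what the tests show

`generate_fixtures()` writes deterministic UniProt-flavoured flat files:
random sequences of 8–30 residues over the 20-letter alphabet with
sampled, pairwise non-overlapping features (substitutions with
replacement lengths 0–3, maturation features, VAR_SEQ isoform edits),
keyed by a single private RNG stream so the same seed yields identical
bytes. It emulates the *structure* of real entries — feature types,
coordinate conventions, note dialects — and makes no attempt at
biological sequence statistics, homology or realistic feature densities.

`oracle_enumerate()` is the independent reference: it expands every
pairwise non-overlapping subset of substitution features by direct string
editing, derives entry/exit points from the annotations alone (a small
closure handles deletions that begin at an entry point, mirroring the
edge-set semantics above), scans each edited string for cleavage sites,
and enumerates every window with direct mass summation. It shares no
code with the graph pipeline and is exponential on purpose.

The equivalence tests compare graph-derived counts, every attribute bin,
and mass-window hit sets (sequence, missed cleavages, feature-id set and
exact fixed-point mass) against this oracle over hundreds of seeded
entries and thousands of random windows; compaction invariance and
pruning soundness are checked the same way, and CSR round-trips are
compared byte for byte. Problem sizes (200 corpus entries, 50 windows
per entry, entries capped at 30 residues and 4 features) keep the oracle
exact and the whole suite fast while exercising every feature
combination the generator can produce. Passing them demonstrates that
the implementation realizes this model exactly on structurally diverse
inputs; it says nothing about annotation densities or sequence
compositions the generator does not produce (a fully annotated human
protein is orders of magnitude denser than any fixture).

## Numerical and degenerate-input choices

* Fixed-point masses make interval membership exact; floating Daltons
  appear only at I/O boundaries, and windows round outward.
* Vertex ids are assigned in creation order; CSR order and query result
  order are therefore bit-reproducible across runs and platforms.
* Degenerate annotations are skipped with a warning rather than
  distorting the graph: a whole-chain deletion (it would spell an empty
  peptide), INIT_MET on a single-residue chain, a SIGNAL covering the
  whole chain, features with uncertain coordinates (`?..12`, `<1`), and
  any substitution whose stated original disagrees with the sequence.
* Unknown feature keys (HELIX, MOD_RES, ...) are ignored with a message,
  never an error.
* Peptides containing B, Z or X have no defined mass: they are flagged
  in the CSR form and pruned from mass queries, but still count in the
  DP characterization.

## Known limitations

* Counts are over paths; a unique-*sequence* count is not computable on
  the compact graph without expansion and is out of scope.
* Substitution features apply to the canonical chain only; isoform
  chains carry no features (matching how UniProt anchors coordinates).
* The feature-limit estimator is approximate by construction; use the
  DP counters for exact budgeting at fixed limits.
* No decoys, no spectra, no scoring: the package ends at FASTA, count
  tables and CSR files.

## A worked example

```{r example}
entry <- protein_entry("X0001", "X0001_TEST", "MKAR", features = list(
  feature_record("VARIANT", 3, 3, "A", "G", "VAR_000001")))
g <- build_protein_graph(entry)
count_paths(g)
count_by_attribute(g, "miscleavages")

csr <- to_csr(g)
query_csr(csr, mass_interval(245, 246))$hits[[1]]
```
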