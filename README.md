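# pepgraph

Protein-graphs for exact, exhaustive exploration of the annotated peptide
search space.

## The problem

Bottom-up proteomics matches MS2 spectra against a peptide database,
usually the tryptic digest of canonical protein sequences. UniProtKB
additionally annotates single amino acid polymorphisms (VARIANT),
sequence conflicts, mutagenesis sites, isoforms, and maturation events
(initiator-methionine removal, signal/pro-peptide cleavage, chain and
peptide products) — but exporting all their combinations to FASTA is
combinatorially impossible: *k* independent substitutions alone multiply
the number of sequence forms by 2^k, and the induced peptide counts of
well-annotated proteins exceed 10^200.

`pepgraph` encodes each UniProt entry as a labelled directed acyclic
graph *G = (V, E)* with dedicated start and end vertices *s* and *e*:
residues are vertices on chains, annotations add alternative routes, and
in-silico digestion opens peptide boundaries so that **every complete
s→e path spells exactly one peptide** — defined by its path (position
and features), not just its sequence. On that structure the package
provides:

* **uniprot_io** — a UniProt flat-file (`*.txt`) parser with isoform
  materialization from VAR_SEQ edits, plus FASTA output;
* **graph_build** — the feature rulesets, enzymatic digestion (trypsin
  default, unspecific supported), PTM annotation and chain compaction;
* **graph_stats** — exact arbitrary-precision path counts, total and
  binned by length, missed cleavages, variants or features, via a
  dynamic program in topological order;
* **mass_query** — a binary compressed-sparse-row serialization in
  topological order and a bound-pruned depth-first traversal (an
  interval extension of target-value search) that enumerates all
  peptides in a precursor-derived monoisotopic mass window, with
  variable modifications expanded during traversal;
* **export_cli** — global and precursor-specific FASTA exporters with a
  lossless header grammar, and an `Rscript` command-line interface;
* **fixtures** — a deterministic synthetic flat-file generator and a
  brute-force enumeration oracle, used by every equivalence test.

## A worked example

```r
library(pepgraph)

entry <- protein_entry("X0001", "X0001_TEST", "MKAR", features = list(
  feature_record("VARIANT", 3, 3, "A", "G", "VAR_000001")))
g <- build_protein_graph(entry)   # trypsin digestion + compaction
g
#> <protein_graph X0001: 6 vertices, 9 edges, digested (trypsin), compacted>

count_paths(g)
#> 5
count_by_attribute(g, "miscleavages")
#> <count_table by miscleavages: total 5>
#>     attribute bin count
#>  miscleavages   0     3
#>  miscleavages   1     2
```

The five peptides are MK, AR, GR, MKAR and MKGR: the A→G variant doubles
every peptide covering position 3, and MKAR/MKGR each contain one missed
cleavage (the internal K). Querying by precursor mass and exporting:

```r
csr <- to_csr(g)                       # topologically sorted CSR form
query_csr(csr, mass_interval(245, 246))$hits[[1]]
#> <peptide AR  245.14879 Da  mssclvg:0  canonical>

export_global(g, export_config(), "x0001.fasta")
#> [1] 5
```

FASTA headers are lossless and grep-able
(`>pg|<accession>|<chain>|<start>-<end>|mssclvg:<n>|<feature ids or
"canonical">`):

```
>pg|X0001|canonical|1-4|mssclvg:1|VAR_000001
MKGR
```

The same operations are available from the shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pepgraph.R", package = "pepgraph"))')
Rscript "$CLI" fixtures --out-dir corpus --seed 5 --n-entries 10
Rscript "$CLI" build --input corpus/fixtures.txt --out-dir corpus/csr
Rscript "$CLI" stats --input corpus/fixtures.txt --attribute variant_count
Rscript "$CLI" query --csr-dir corpus/csr --precursors precursors.csv --out hits.fasta
```

`precursors.csv` needs the header columns `mz,charge,tol_ppm`.

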