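---
title: "Methods: comparative MAG characterization with magchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MAG characterization with magchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magchar)
```

magchar implements the comparative-genomics workflow used to characterize
uncultivated bacterial lineages from draft genomes (MAGs/SAGs): orthology
and average amino acid identity (AAI), marker-based quality estimation with
MIMAG tiering, rule-based pathway presence inference, operon architecture
detection, and pathway energetics. This vignette documents the underlying
models, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## Alignment model and statistics

Pairwise protein comparison uses exact Smith–Waterman local alignment with
affine gaps rather than a heuristic seeded search. The choice is deliberate:
at the scale this package targets (hundreds of proteins per genome) the
exact algorithm is affordable in compiled code, is deterministic, and can be
verified against a brute-force dynamic-programming oracle — which the test
suite does, exhaustively on short random sequences. A hook for importing
external tabular alignment results exists for users who need heuristic
aligners at larger scale.

Scoring defaults follow the de facto protein-BLAST configuration:

| parameter | default | unit / meaning |
|---|---|---|
| substitution matrix | BLOSUM62 | half-bit matrix units |
| gap open / extend | 11 / 1 | a gap of length L costs 11 + L |
| λ, K | 0.267, 0.041 | gapped Karlin–Altschul constants |
| E-value threshold | 1e-5 | hits at or above are discarded |

Bit scores and E-values use `bit = (λ·S − ln K)/ln 2` and `E = m·n·2^(−bit)`
with `m`, `n` the sequence lengths. The ambiguity residue `X` scores 0
against every residue, so it neither rewards nor penalizes matches. Percent
identity is computed over aligned columns including gap columns. When two
database sequences reach the same optimal score, the hit with the
lexicographically smaller subject id is reported; this makes top-hit
selection deterministic under permutations of the database.

## Orthology and AAI

Two proteins are orthologs iff they are bidirectional top-scoring hits
(reciprocal best hits) with qualifying E-values. AAI is the *unweighted*
arithmetic mean of the ortholog pairs' percent identities; no length
weighting and, by default, no alignment-coverage filter is applied — the
published AAI methodology this follows filters on E-value only. A coverage
filter can matter for genomes rich in fragmented gene calls; users can
approximate one by pre-filtering their gene tables.

Below `min_orthologs` pairs (default 20) the AAI estimate is flagged
unreliable rather than suppressed: tiny shared-gene sets produce AAI values
dominated by a few anchor genes. With zero pairs the value is `NA`.

Rank delineation uses the published AAI bands for uncultivated taxa —
species 95–100%, genus 65–95%, family 45–65% — made half-open at the upper
bound so the printed band overlaps at 65 and 95 resolve upward (AAI of
exactly 95 is a species-level relationship). Genus-level grouping is
single-linkage: connected components of the graph joining pairs with AAI ≥ 65.
Single linkage matches how such groupings are read off a heatmap, but it can
chain through intermediate genomes; the threshold is configurable.

## Genome quality

Completeness and contamination use a single flat set of single-copy markers
(the shipped file has 107 generic ids usable with the simulator):
completeness is the percentage of distinct markers present, contamination
the percentage of surplus copies. Lineage-specific collocated marker sets, as
used by dedicated quality tools, are out of scope — the flat-set
simplification is tested only against synthetic ground truth, where dropout
f and duplication c are recovered within ±1 point of 100(1−f) and 100c.

Tiers: High requires completeness > 90 and contamination < 5; Medium
requires completeness ≥ 50 and contamination < 10; everything else is Low.
The boundaries are strict/inclusive exactly as written — a genome at 64.41%
completeness and 0% contamination is Medium. The published High tier also
requires rRNA/tRNA presence; since rRNA/tRNA calling is outside this
package, these enter `assign_tier()` as optional booleans defaulting to
satisfied.

N50 is the length of the shortest contig in the smallest set of longest
contigs covering half the assembly; GC excludes ambiguous `N` bases from the
denominator.

## Pathway presence rules

Pathway definitions are ordered steps, each a set of interchangeable gene
symbols (e.g. ATP- vs diphosphate-dependent phosphofructokinase, or the two
alternative benzoyl-CoA β-oxidation gene sets). The dual standard for
uncultivated lineages is: pathways previously described in the lineage are
present when the detected fraction of steps is ≥ 0.75 (inclusive); pathways
novel for the lineage require every step. Two reading choices are
documented rather than silent: the 75% rule counts *steps* (alternatives
collapse within a step), and the boundary is inclusive. The novel rule is
strictly stricter, and both rules are monotone in the gene complement —
both properties are enforced by tests.

Lineage-level gene status is quality-conditioned: *present* iff the gene is
detected in every medium-or-high-quality genome of the lineage; *absent*
iff it is detected in no genome at all **and** the lineage has at least one
high-quality genome; otherwise *uncertain*. The absence clause is
deliberately stricter than requiring absence only from high-quality
genomes: a detection in a medium- or even low-quality genome is still a
detection, and letting it coexist with an "absent" call would be
contradictory. A lineage without any medium-or-high genome yields
*uncertain* with a warning.

CAZyme domain-hit filtering keeps hits with E-value ≤ 1e-18 and model
coverage ≥ 0.35. Coverage is measured over the HMM model (the dbCAN
convention); a different coverage column can be selected where tools report
query-side coverage.

## Operon detection and synteny

A cluster is a maximal run of genes carrying model symbols in which
consecutive members are separated by at most `max_intervening_genes` other
genes (default 3) and at most `max_gap_bp` (default 5000 bp), on one contig,
broken at strand switches when `require_co_strand` (default on). These
thresholds are declared defaults, not values inferred from data — published
descriptions of the operons say "clustered" without quantifying it — and are
configurable per model. Clusters on the reverse strand are canonicalized
(gene order and strands flipped) before the architecture string is emitted,
so forward and reverse encodings of the same operon compare as identical.
When a model's symbols span several contigs of one genome, each hit is
flagged `split_across_contigs` rather than merged: merging would assert an
adjacency the assembly does not support.

The shipped `faeDCAB` model encodes the fumarate addition enzyme operon —
activase (D), gamma (C), alpha (A), beta (B) — with `dctP/dctQ/dctM`
TRAP-transporter genes and the unknown-function `faeE/F/G` tail as tolerated
insertions; `bssDCAB` and `assDCAB` models cover the canonical
benzylsuccinate- and alkylsuccinate-synthase arrangements. Motif scanning
supports patterns over amino-acid letters plus `x` (any residue); the
ferredoxin pattern `CxxCxxCxxxC`, diagnostic of the activating enzyme's
[4Fe-4S] binding, is the shipped example. No glycyl-radical-domain pattern
is shipped: there is no published single-string consensus to transcribe, so
that check is left to user-supplied patterns.

Synteny similarity between two hits is `Jaccard(shared symbols) ×
LCS(order of shared symbols)/|shared symbols|` — 1 exactly for identical
canonicalized architectures, 0 with no shared genes, and symmetric.

## Energetics

The reaction ledger is bookkeeping, not inference: each step carries an
integer count of ATP equivalents chosen when the ledger is written, and the
module sums them. The shipped propane-fermentation ledger makes its choices
explicit: the AMP-forming CoA ligation is counted as −1 ATP equivalent (as
the acetyl-CoA-ligation-like reaction it is modeled on is depicted), the
ion-gradient-coupled decarboxylation as +1, and the acyl-phosphate route to
the free fatty acid as +1, netting +1 ATP per alkane. Every step is
element-balanced (C, H, O, N, S, P), with CoA thioesters carried at full
elemental formulas, and the balance checker verifies this.

ΔG° uses formation energies at standard state (1 M solutes, 1 atm gases,
25 °C) with no pH or ionic-strength transformation. The shipped formation
energy table is approximate and editable — the original analysis cites an
external thermodynamic database — and deliberately omits authoritative
values for the CoA intermediates; per-step ΔG° for those steps is reported
as `NA` unless the user supplies estimates, while the net reaction (CoA and
ATP cancel) is computable from the shipped small-molecule values.

## Synthetic data: what it does and does not establish

The simulator draws proteins i.i.d. from a fixed amino-acid background,
lays them on contigs with fixed 100 bp intergenic spacers, plants markers,
operons and pathway complements, and derives descendants by substituting
each site independently with probability p to a uniformly chosen *different*
residue. Uniform substitution is a deliberate departure from realism
(BLOSUM-conditioned exchange would be more natural): it makes expected
identity analytically exactly 100(1−p), giving the estimators a closed-form
recovery target. The fixed spacer makes cluster-gap thresholds exact in
tests. The simulator does not model indels, nucleotide-level evolution,
recombination, gene gain/loss beyond marker dropout, or sequencing error —
so passing tests demonstrate correctness of the estimators under the model's
assumptions, not robustness to fragmented gene calls, chimeric bins, or
alignment-length heterogeneity in real MAGs.

The packaged 17-genome fixture transcribes the published study roster:
the seven operon-carrying genomes carry planted complete operons and their
printed completeness/contamination values; the other ten carry quality
values that are synthetic stand-ins consistent with their published tier
descriptions. Its protein sequences are simulated, so only label-based
analyses (tiering, pathway calls, operon architecture) — not AAI values —
are meaningful on it. Completeness figures in the fixture are attached
metadata, not re-derived from planted markers: the published values come
from lineage-specific marker sets that are out of scope here.

## Problem sizes and tolerances used by the tests

The suite validates AAI divergence recovery at 200 proteins of 80–150
residues per genome, within ±2 AAI points of 100(1−p) for p up to 0.3 —
the residual bias (well under a point at these lengths) comes from local
alignments trimming mismatch-dense ends, which inflates identity slightly
and grows with divergence. Alignment correctness is checked against the
brute-force oracle on sequences up to 30 residues (1,000 random pairs),
where the full-matrix oracle is fast in plain R. Substitution-rate recovery
uses 60,000 sites (±0.01 binomial tolerance). These sizes were chosen so the
whole suite exercises every estimator at statistically meaningful scale
while remaining a desk-scale computation.

## Degenerate inputs and edge behaviour

Empty genomes are rejected by assembly statistics; empty marker sets,
catalogs, ledgers and pathway steps are construction errors. Zero ortholog
pairs yield an `NA` AAI flagged unreliable, not an error. A missing
compound in the energy table names itself in the error. An empty reaction
is vacuously balanced. A single-genome pipeline run yields a 1×1 AAI matrix
of 100 by definition. Columns with exactly 95% gaps are retained by the
alignment trimmer (the rule is strictly greater). All external coordinates
are 1-based inclusive.

## Known limitations

- Exact Smith–Waterman is quadratic per pair; all-vs-all orthology beyond a
  few thousand proteins per genome calls for the external-aligner import
  hook instead.
- The flat marker model cannot separate contamination from ancient
  paralogy, and recovers the dropout/duplication parameters only under the
  single-copy assumption.
- Pathway calls are label-based: they trust the gene-family annotations in
  the input. The optional per-gene `verified` flag records
  database-confirmation status but the confirmation itself (remote BLAST
  checks) is outside the package.
- Genus grouping by single linkage can chain distinct groups through
  intermediate genomes at borderline AAI.
- The contig-to-reference assignment rule interprets "covered >80% of the
  length" against the contig (not the ORF); genomes with long intergenic
  stretches will under-cover, which is the conservative direction.
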