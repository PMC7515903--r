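---
title: "Reconstructing and analysing repetitive spider silk genes"
author: "silkforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and analysing repetitive spider silk genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkforge)
```

## The problem

Spidroin (spider silk protein) genes share one architecture: a
non-repetitive N-terminal domain (NTD) and C-terminal domain (CTD)
flanking a repetitive domain (RTD) that is a tandem array of a repeat
unit, often several hundred to over a thousand nucleotides long and
iterated ten times or more. The genes of interest here are intronless.
Because the array is far longer than a short sequencing read and its
copies are nearly identical, de novo assemblers collapse or truncate it:
contigs typically carry a terminal domain plus at most a copy or two of
the unit. silkforge implements a hybrid-read curation strategy for such
genes — seed extension over short reads anchored by exact matches of a
very large k-mer, with repeat copy number resolved by long reads — plus
the downstream analyses that turn curated sequences into a silk-gene
catalogue: domain/motif annotation, amino-acid-composition clustering of
the repetitive domains, terminal-domain phylogenies with monophyly
checks, and label-free protein quantification (emPAI) of web-region
proteomes.

Everything is exercisable offline: the package ships a generator that
produces genes with known ground truth, reads with controlled error
models, assembler-style contig fixtures, and peptide observations.

## Curation by seeded PWM extension

The curation stage (`curate_gene()`) runs in five steps.

1. **Seed discovery** (`find_seeds()`). Contigs are translated in all
   six frames and searched by local alignment (BLOSUM62) against
   amino-acid profiles of known terminal domains. A hit needs at least
   30 aligned residues at 75% identity; random 2 kb contigs essentially
   never qualify (the test suite measures an empirical false-positive
   rate below 1%).
2. **Large-k-mer screening** (`build_kmer_screen()`). Every k-mer of
   every short read, on both strands, goes into a keyed table. The
   default k is 72 for 150 nt reads: large enough that an anchor is
   effectively unique genome-wide, small enough that at 30x coverage
   the expected number of reads containing a given anchor *plus one
   further base* is about `30 * (150 - 73 + 1) / 150 ≈ 15.6` — roughly
   three times the acceptance depth, so a multi-kilobase walk does not
   stall on Poisson fluctuations. (At k = 100 that expectation is ~10
   and walks fail regularly; k is a tuning parameter, not a constant of
   the method.)
3. **PWM extension** (`extend_consensus()`). The 3'-terminal k-mer of
   the growing consensus recruits reads containing it exactly; their 3'
   overhangs are stacked gap-free into a position weight matrix.
   Columns are accepted while support is at least `min_depth = 5` reads
   and the dominant base reaches `min_purity = 0.8`. One refinement
   matters inside tandem arrays: recruited reads then come from *all*
   copies at once, so a position where a minority of copies diverged
   shows a genuinely mixed column. Such a column is still accepted when
   support is at least three times `min_depth`, purity is at least 0.5
   and the majority is strict — the accepted base is the across-copy
   majority, which is exactly the unit consensus being sought. Ties at
   the maximum with no purity pass stop the walk.
4. **Repeat detection** (`detect_repeat_unit()`). After each couple of
   steps the consensus tail is scanned for the smallest period p whose
   trailing window self-aligns at lag p with identity at least 0.9. The
   window is 3p when that much periodic sequence exists, and the
   minimal two-copy window 2p otherwise — two complete trailing copies
   are the stop condition, and requiring three would force the walk
   deeper into the array than necessary. Extension then stops rather
   than walking every copy: copy number is the long reads' job. The
   unit is re-phased to start at the NTD/array boundary (located by
   walking the lag-p agreement leftwards) and **polished**
   (`polish_unit()`): every unit position is re-called as the majority
   of a k-mer-anchored pileup taken in cyclic (tandem) space, in both
   orientations, followed by a recruitment-count repair — for each
   position and each base, count the reads recruited by the anchor
   ending there with that base substituted, and flip only on a clear
   (1.5x) majority, iterating to a fixed point. The repair matters when
   by chance only one copy besides the variant-carrying one is clean
   over an anchor window, which deadlocks a plain vote. Polishing
   removes the private variants of the single copy that anchored the
   first ~k bases of the walk; without it unit identity to truth sits
   near 0.98-0.99, with it at 0.995-1.0. A fallback anchor at k = 44 is
   used both for the repair and to rescue extension steps where no read
   carries the full 72-mer majority anchor (a real possibility in
   low-complexity units once per-copy divergence is taken into
   account).
5. **Copy-number estimation** (`estimate_iterations()`). Long reads are
   searched (both strands) for the NTD 3' anchor and the CTD 5' anchor
   by local alignment at identity ≥ 0.75 — the right scale for ~10%
   read error. Between the anchors, unit copies are counted by tiling a
   150 nt unit anchor at expected offsets, re-anchoring on every match
   so indel drift cannot accumulate; interior misses still count as
   tiles, trailing misses do not. The estimate is the mode over
   spanning reads (ties towards the larger value); continuity is
   validated when at least one read carries NTD, one or more copies and
   CTD in that order. With no spanning read the longest partial tiling
   is reported and flagged low-confidence.

When both terminal seeds exist, the NTD-side and CTD-side walks produce
two independent unit consensuses; they are compared under rotation
(units are defined only up to cyclic phase) and curation aborts if the
best rotational identity falls below 0.9 — a chimeric locus signal.

`recovery_experiment()` packages the whole validation loop: genes drawn
with unit lengths 200–1200 nt and 5–15 copies, 30x short reads at 0.1%
substitution error, 20x long reads at 10% indel-biased error, curated
end to end and scored against truth. The acceptance suite requires at
least 18 of 20 replicates to reach unit identity ≥ 99% and copy error
within ±1; in practice runs score 18–20 of 20 with copy number exact in
every successful replicate.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not tuning knobs.

* **Architectures.** Per-family defaults follow the catalogued
  spidroins: the cribellar spidroin CrSp gets a 2100 nt NTD (its NTD is
  over 2 kb, against ~500 nt for other families), a 1009 nt unit at 11
  copies, and a 962 nt CTD; AcSp a 1124 nt unit; Pflag a ~200 nt unit;
  the glycine-motif vocabulary (GGX, GPGGX, GPSS, QQ) goes to the
  flagelliform-like families and poly-A/TT/SS to CrSp, mirroring the
  motif inventories of the respective repetitive domains.
* **Open reading frames at any unit length.** A 1009 nt unit is not a
  codon multiple, so successive copies are read in shifted frames. The
  generator therefore builds coding sequence from "stop-safe" codons —
  no TA or TG dinucleotide anywhere and no codon ending in T — which
  guarantees no stop triplet in *any* frame, across junctions and
  truncations. The cost is that C, M, W and Y cannot be encoded; motifs
  containing them are rejected (silk repetitive domains essentially
  lack them), and mutation operators only apply substitutions that
  preserve the property. Codon choice is otherwise uniform over the
  allowed synonymous set.
* **Reads.** Short reads: 150 nt pairs, FR orientation, normal insert
  (default 350–400 nt), substitution-only errors (default 0.1%). Long
  reads: i.i.d. edit process at 10% with indel:substitution 4:1 and
  insertions/deletions balanced, a configurable fraction spanning the
  full reference. Every introduced edit is logged, so error-model
  audits in the tests are exact rather than statistical. Identical seed
  and configuration give byte-identical FASTQ. Curation-bound
  simulations embed the gene in 400 nt random flanks because a bare-CDS
  reference under-covers the gene termini.
* **Divergence.** Repeat copies diverge from the unit at 1% per copy by
  default — real arrays are homogenized but not identical — and
  orthologs across the six simulated species diverge at 5% per domain.
  Both are realistic mid-range values chosen once.
* **Peptides.** Per-region protein abundances with saturating detection
  probability `a / (a + k)`; only peptides that the proteomics module
  itself deems observable can ever be emitted.

What the generator does *not* emulate: flow-cell-specific error
profiles (no homopolymer bias, no quality-score realism), introns (the
target genes are intronless), paralog interference between families in
one read pool, and transcript-level artifacts. Passing recovery tests
therefore demonstrates the algorithmic contract — anchoring, consensus,
periodicity, copy counting under the stated error models — not
performance on any particular instrument's data.

## Annotation

`select_start_codon()` scores every ATG opening an ORF of at least 50
codons by Kozak context — purine at −3 (weight 2) and G at +4 (weight
1) — plus a bounded signal-peptide heuristic of the encoded N-terminus:
maximum 9-residue sliding-window Kyte–Doolittle hydropathy over
residues 1–30 rescaled to [0, 1] (weight 0.8), plus 0.2 for a K/R in
the first five residues. The heuristic replaces an external
signal-peptide predictor to keep annotation dependency-free and
deterministic; it is a coarse ranking device, adequate for choosing
among candidate starts, and all candidates are reported for audit.

`segment_domains()` aligns terminal profiles to the translated
sequence, takes the interval between them as the RTD and decomposes it
with `detect_repeat_unit()`; terminals covering under 80% of their
profile are flagged partial. `scan_motifs()` counts silk motifs with a
greedy left-to-right scan and longer-motif precedence
(GPGGX > GPSS > GGX); dipeptide classes QQ/TT/SS count `floor(run/2)`
over maximal runs outside consumed glycine motifs, and poly-A counts
maximal runs of at least 4 (the run threshold is configurable since
"poly-A" has no canonical minimum). `catalog_table()` emits the
per-gene architecture table plus per-family means.

## Composition clustering

Repetitive-domain amino-acid frequencies (20 canonical residues,
non-standard characters excluded from the denominator) are compared by
Pearson correlation; hierarchical clustering uses distance `1 − r` with
average linkage. Neither the distance nor the linkage is canonical for
this analysis, so both are arguments; outputs are stamped with the
choice. Flat groups are reported at a default cut height of 0.5
alongside the full dendrogram, deliberately avoiding over-claiming any
particular two-group split. `dendrogram_groups_intact()` asks the
qualitative question that matters for a family catalogue: do orthologs
join their family before any cross-family merge?

## Terminal-domain phylogenies

Terminal domains are trimmed to the first 90 (N) or last 80 (C)
residues by exact slicing, aligned with MAFFT, and compared under a
Poisson-corrected distance `d = −ln(1 − p)` with pairwise gap deletion
and a saturation cap (default 5). Trees are neighbor-joining; bootstrap
support resamples alignment columns (default 100 replicates for speed;
1000 mirrors common practice) and counts bipartition recovery. A family
is monophyletic when some edge bipartition separates exactly its
members. Distance/NJ stands in for full maximum-likelihood inference
deliberately: the claims read off these trees are topological (family
monophyly under strong between-family divergence), which is robust to
the inference method, and NJ on additive distances is provably exact —
a property the test suite checks against randomly generated trees.

## Proteomics

Digestion applies the trypsin rule (cleave after K/R, never before P)
with up to two missed cleavages. A Lys-C pre-digestion step adds no
sites under this convention — its K sites are a subset — which matches
treating "trypsin" as the identification search rule. Peptide masses
are monoisotopic with fixed carbamidomethyl-Cys (+57.02146 Da); a
peptide is observable if charge 2 or 3 puts its m/z inside 400–1500
(singly charged ions are excluded by default, as survey selection
prefers multiply charged ions; the charge set is configurable). emPAI
is `10^(n_observed / n_observable) − 1` with the observable count taken
over distinct fully cleaved peptides. Distinct-sequence counting makes
emPAI invariant to a protein's repeat copy number — asserted as a
property in the tests, and a real caveat: highly repetitive spidroins
expose few distinct peptides, so their emPAI saturates quickly.
Region comparison ranks emPAI per region and forms pairwise ratios;
Wilcoxon tests run only when replicate observations are present.

## Numerical and degenerate-input choices

* Coordinates in truth-table TSVs are 0-based half-open; R-level
  intervals are 1-based inclusive (each documented where returned).
* PWM column ties break lexicographically (A<C<G<T) only when purity
  passes; otherwise the walk stops.
* `detect_repeat_unit()` returns the *smallest* qualifying period, so a
  2-copy array of a unit that is itself internally periodic reports the
  inner period; the extension guards against trivial low-complexity
  hits with `min_period = 50` nt.
* Distance saturation (`p ≥ 1 − e^{−max}`) caps at `max_dist` rather
  than returning infinity; NJ tie-breaks are ape's deterministic ones.
* Empty inputs error early with the offending field named
  (`validate_run_config()`, `digest("")`, `aa_frequencies("")`,
  `trim_terminals()` on empty sequences).

## Problem sizes used by the tests

The default validation runs 20 curation replicates over the full
unit/copy ranges (~90 s), 200 period-detection oracle cases up to 5 kb,
50 digestion oracle proteins up to 500 residues, 100 random additive
NJ trees of 6–10 taxa, one 54-taxon bootstrap with 100 replicates, and
20 composition-clustering replicates of 9 families x 6 species. These
sizes make the full suite complete in a few minutes on one CPU while
still covering the stated parameter ranges.

## Known limitations

* Exact k-mer anchoring assumes substitution-dominated short-read
  error; indel-rich short reads would break recruitment (indels are
  delegated to the long-read stage).
* One gene is curated per read set; pooling many paralogs with
  near-identical terminal domains in one pool could cross-recruit at
  the anchoring stage. The unit-conflict check catches the resulting
  chimeras but does not resolve them.
* The signal-peptide heuristic is a ranking device, not a predictor
  with calibrated error rates.
* emPAI on short repetitive proteins rests on few observable peptides;
  ranks are more trustworthy than magnitudes.
* The pipeline claims topology-level reproduction for phylogenies, not
  branch lengths or model-based support values.
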