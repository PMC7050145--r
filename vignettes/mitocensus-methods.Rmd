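---
title: "Inferring a nucleus-encoded mitochondrial proteome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a nucleus-encoded mitochondrial proteome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocensus)
```

## The problem

Most mitochondrial proteins are encoded in the nucleus, synthesized in the
cytosol and imported into the organelle, usually by virtue of a cleavable
N-terminal mitochondrial targeting sequence (MTS). For an organism with no
proteomics data, the mitochondrial proteome must be inferred in silico:
run several MTS predictors over every annotated protein, combine their
outputs into a consensus, and curate the result against functional
knowledge. mitocensus implements that consensus-and-curation pipeline for
compact protist nuclear genomes — the setting where gene models are simple
enough (few, short introns; tight intergenic spacing) that assembled
RNA-Seq contigs can verify or correct each candidate's gene model
directly.

The package deliberately does **not** implement any MTS predictor itself,
nor homology search or tree inference. External predictor output is
consumed as tables; everything downstream of those tables is in scope.

## The consensus targeting model

Six predictors are recognized: TargetP, MitoProt, Predotar and PSORT II
(primary), plus PredSL and MitoFates (tertiary). All scores are normalized
to a 0–100 scale **at ingest** — PSORT II reports percentages while the
others report probabilities on 0–1, and a single internal unit avoids
silent mixed-scale means. The consensus metric is

$$P = \tfrac{1}{4}\,(\mathrm{TargetP} + \mathrm{MitoProt} +
      \mathrm{Predotar} + \mathrm{PSORT}),$$

the arithmetic mean of the four primary scores; the tertiary predictors
vote but never enter \(P\). If any primary score is missing, \(P\) is
undefined (`NA`) — never imputed as zero — and the protein can become a
candidate only through a curation inclusion.

Binning by targeting strength: **strong** \(P \ge 75\), **moderate**
\(50 \le P < 75\), **weak** \(30 \le P < 50\), else **not predicted**.
The moderate and weak bins are read as "probable" and "possible"
candidates. The upper edge of the strong bin is uncapped: the published
75–95 range records an observed maximum, not a rule. Bin comparisons use
unrounded \(P\); reports print one decimal (half-up).

The candidate decision rule is \(P \ge 30\) **and** at least three of the
six predictors calling "mitochondrial". What constitutes a per-program
call is not standardized by the predictors themselves, so the default is
score \(\ge 50\), overridable globally (`positivity_threshold`) or
per-protein via `<predictor>_call` columns mapped from class labels at
ingest. This was an open design point: the original analysis does not
state its per-program criterion, and 50 is the natural midpoint for
probability-like outputs.

### Curation overrides

Four flags override the baseline rule, applied in a fixed precedence in
which exclusions beat inclusions and exclusive-mitochondrial beats the
no-MTS class:

1. *functions elsewhere* — excluded even when robustly predicted;
2. *RNA-binding false positive* — cytosolic ribosomal proteins, histones
   and spliceosomal proteins whose amino-acid composition spuriously
   scores as an MTS (historically 10–15% of a TargetP screen);
3. *known exclusive mitochondrial* — included regardless of \(P\);
4. *known no-MTS class* — mitochondrial carrier (SLC25) and membrane
   proteins that genuinely lack an N-terminal MTS.

Exactly one override (or `none`) is recorded per protein, so every
decision is auditable. The precedence mirrors manual-culling practice:
positive functional knowledge that a protein lives elsewhere trumps any
prediction score.

## Gene-model reconciliation

Each gene model is compared against its assembled transcript contig.
The aligner is intentionally *not* a general spliced aligner: transcript
evidence from the same strain is expected to be near-identical to the
genome, so exact-anchor chaining suffices and is transparent. Unique
21-mers shared by transcript and genomic window are chained colinearly;
maximal same-diagonal runs become blocks; genomic gaps of at least 30 nt
between blocks become introns (smaller gaps are reported as indel
evidence, not splicing — the smallest credible spliceosomal intron here
is 55 nt, and 30 leaves headroom without manufacturing micro-introns).
Isolated substitutions (SNPs) stay inside blocks as recorded mismatches.

All splice-signal work happens on the coding strand (minus-strand windows
are reverse-complemented). When an intron can slide without changing the
spliced product, the junction is placed at the **leftmost position
consistent with GT..AG**; among several GT..AG placements the leftmost
wins, giving a deterministic canonical form. Non-GT..AG introns are
returned flagged `canonical = FALSE`, never silently dropped.

Mismatches inside the CDS are classified `silent_third_position`,
`silent_other` or `nonsynonymous` under the standard genetic code, and
`UTR` outside it — the expectation for a near-clonal haploid (or nearly
homozygous diploid) sample is a small number of mostly silent
third-position changes.

### N-terminus assignment

When the reading frame remains open upstream of the annotated start and
the transcript does not extend far enough 5′ to cover the putative
extension, the start is moved to the nearest upstream in-frame ATG whose
*extended* protein is scored MTS-positive by a caller-supplied `rescore`
callback; otherwise the annotated start is kept. The operation never
shortens the protein, cannot cross an in-frame stop, and always yields a
protein beginning with Met. When the transcript's aligned span does not
reach the in-frame upstream stop, the stop is inferred from genomic
sequence and that provenance is recorded. `assign_start` is
predictor-agnostic by design — rescoring an extended protein requires
re-running external predictors, which the default pipeline cannot do, so
the pipeline runs with start reassignment disabled and the tests exercise
the rule through the synthetic predictor simulator.

Conflicting isoforms are out of scope: one transcript contig per gene is
assumed, matching the compact-genome setting.

## Genome context and summaries

Genes packed closely enough that untranslated transcript ends overlap
co-assemble into a single RNA-Seq contig. Such pairs are detected from
the transcript-to-gene map (any contig mapping to two genome-adjacent
genes), and the intergenic spacer is measured **CDS-to-CDS** — transcript
spans may overlap while the coding spacer is positive, and "intergenic
spacer" refers to the distance between coding regions. Orientation is
`same` iff strands agree.

`summarize_candidates()` reports candidate counts, functional-category
composition (ten categories, A–J), the targeting-strength distribution,
intron statistics with per-category enrichment (descriptive fractions
only — no p-values), and spacer statistics. Category percentages default
to the nucleus-encoded candidate base; a flag switches to the total
mitoproteome base (candidates + mtDNA-encoded proteins, default 66),
since published category figures are ambiguous about their denominator.
Percentages are rounded half-up to one decimal and each table states its
base.

Alignment-column trimming (used before phylogenetics, retained here as a
utility) removes columns with **strictly more than 50%** missing
characters; a column at exactly half is kept, and the operation is
idempotent.

## The synthetic world

The generator emits a genome, annotation, transcripts, predictor tables
and a truth ledger with the statistical structure the analysis assumes —
it is the package's test bed, not a biological simulator. Its defaults
are the stated world:

| Parameter | Default | Why |
|---|---|---|
| intron-bearing genes | 12% | observed fraction in the target genome |
| single-intron fraction | 82% | observed; remainder get two introns |
| intron size | trunc. log-normal, mean 151 nt on [55, 756] | observed mean and range; meanlog 4.8999 / sdlog 0.45 fitted numerically so the truncated mean is 151 |
| intergenic spacer | Beta(2, 5.48) scaled to [44, 691], mean 217 nt | observed range and mean for co-assembled pairs |
| co-assembled pairs | 47 | size of the published pair survey |
| pair orientation | opposite with prob. 38/47 | observed 38 opposite : 9 same |
| mitochondrial genes | 30% | plausible enrichment for a candidate-oriented input set (not stated anywhere; chosen once) |
| no-MTS class among mitochondrial | 16% | 138/864 candidates lack a predicted MTS |
| RNA-binding contaminants | 3.6% of genes | yields ~12% of TargetP positives, inside the published 10–15% |
| predictor scores | Beta(8,2)×100 high / Beta(2,8)×100 low | high law for MTS-bearing and contaminant proteins, low law for the rest including the no-MTS class; independent per predictor |
| SNPs | 1% of genes, 80% silent third-position | "very small number, mostly silent" |
| CDS length | 100–500 codons; UTRs 20–80 nt | typical compact-genome scale |

Design choices worth recording:

* **Entity-keyed randomness.** Every gene draws from a stream derived
  from `(seed, entity id)`, so enlarging a simulation never perturbs
  existing genes and identical configs are byte-identical.
* **Canonical-by-construction introns.** Insertion sites are restricted
  so the exonic base 5′ of each donor is not G, making the planted
  junction the unique leftmost GT..AG placement. The ledger therefore
  contains exactly the coordinates a correct caller must report, and the
  tests need no shared canonicalizer.
* **Intronless pairs.** Co-assembled pairs are built from intronless
  genes so the merged contig literally mirrors the genomic span, as
  observed for real co-assembled contigs. This makes the expected
  intron-gene fraction over *all* genes slightly below the nominal 12%
  (pairs are 4.7% of the default world); recovery tests therefore measure
  the rate over intron-eligible genes and additionally check the
  published ±2-point envelope over all genes.
* **SNP placement.** Planted SNPs keep ≥30 nt clear of junctions and CDS
  ends so anchor seeding always brackets them; real data offer no such
  courtesy, which is one reason a green test here does not certify the
  aligner for divergent transcripts.

What the generator does **not** emulate: read-level errors and assembly
artifacts, alternative isoforms, heterozygosity beyond isolated SNPs,
codon-usage and GC realism, non-canonical splice sites, and predictor
score correlation across programs. A green suite establishes that the
pipeline's logic is correct under its stated assumptions, not that those
assumptions hold for any particular organism.

## Numerical and interface choices

* Coordinates are 0-based half-open internally, 1-based inclusive in GFF3.
* The interchange format is UTF-8 TSV with `.` for missing; XLSX
  supplementary workbooks are supported read-only through a converter
  that shells out to the system `python`/openpyxl (no R XLSX reader is
  assumed).
* The run configuration is a single JSON file (the environment provides
  no YAML reader; the keys are exactly the documented defaults), and the
  pipeline writes a manifest with MD5 checksums of config, inputs and
  outputs — identical config and inputs give identical checksums.
* Ties and degenerate inputs: an empty batch yields an undefined
  false-positive fraction (`NA`, not 0); a CDS whose length is not a
  multiple of 3 warns and is flagged rather than rejected, so damaged
  annotations can still be inspected; overlapping CDSs in a gene pair
  report spacer 0 with an overlap flag.

## Known limitations

The aligner assumes near-identity and will refuse rearranged or
anchor-free evidence rather than attempt a divergent alignment. Start
reassignment trusts the rescoring callback entirely. Pair detection
relies on transcript-to-gene mapping by exact probes and so inherits its
assumptions (no paralogous near-duplicates of a transcript elsewhere in
the genome). None of the biological interpretation downstream of the
candidate table — complex composition, phylogenetics, evolutionary
inference — is attempted here.
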