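---
title: "Methods: suppressor-screen analysis with modscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suppressor-screen analysis with modscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

## Scope and model

`modscreen` analyses whole-genome-sequenced strains from a chemical
mutagenesis suppressor screen. The biological setting it models: a
strain carrying a homozygous primary lesion (a single-nucleotide
missense allele in a target gene) is mutagenized with EMS and/or ENU;
surviving lineages carry a suppressing variant plus a genome-wide load
of random background substitutions; all strains are sequenced without
backcrossing, variants are called against the wildtype-like reference,
and each strain's call set is filtered, annotated and interpreted.

The package deliberately starts **downstream of variant calling**:
read trimming, alignment and calling are upstream tools' jobs, and the
unit of input here is a per-strain VCF plus a reference FASTA, gene
models in GFF3, and a strain manifest. Only single-nucleotide
substitutions are modelled — every event class the analysis targets is
one — and indels are explicitly skipped and counted by the VCF reader.

## Filtering

A call passes the homozygous-variant filter iff all four predicates
hold, evaluated in a fixed order (depth → allele fraction → region →
de novo) so that rejection tallies are deterministic:

1. `read_depth > 5` — *strict* inequality; depth 5 fails.
2. `allele_fraction > 0.9` — strict; selects homozygotes in a
   self-fertilizing hermaphrodite population.
3. region ∈ {coding, within ±10 nt of a splice junction} ∪ {UTRs when
   `include_utr = TRUE`}.
4. de novo: no parental call matches on the full
   (chromosome, position, ref, alt) tuple — a different alternate
   allele at a parental site still counts as de novo.

Two genuinely open readings are resolved as explicit options:

* **UTR admission.** A strict coding/splice-window reading of the
  filter would reject 5′UTR variants, yet upstream suppressors (e.g.
  positions 4 and 18 nt upstream of the start codon) are real and
  recurrent findings in this kind of screen. The default is therefore
  `include_utr = TRUE`; the strict behaviour is one flag away.
* **Threshold strictness.** Both thresholds are implemented exactly as
  printed, as strict inequalities. Whether the original in-house
  scripts were inclusive cannot be determined; strictness is the
  conservative reading and is config-exposed.

**Primary-allele retention.** Because calls are made against the
wildtype-like reference, the mutant parent's lesion appears as a
variant call. The adopted convention: a strain is `RETAINED` when the
exact primary substitution is among its raw calls; absence of *any*
call at the primary site means the strain carries the wildtype base,
i.e. `REVERTED`; a third allele at the site is `NOT_OBSERVED`. VCF
input cannot distinguish "reference base" from "no coverage" — a
limitation noted below.

## Coordinate mapping and effect annotation

Genomic positions map to cDNA coordinates through cumulative spliced
offsets from the CDS start, strand-aware; 5′UTR positions take
negative numbering counting back from −1 (no position 0, HGVS
convention); intronic positions return the nearest exonic anchor with
a signed offset (`c.938+3`), ties going to the donor side. The inverse
map is exact on exonic positions and round-trip identity is enforced
by property tests.

Coding position *c* lies in codon `ceil(c / 3)` at within-codon offset
`c − 3(ceil(c / 3) − 1)`. The annotator edits that single codon under
the standard genetic code (complementing call alleles for minus-strand
transcripts) and compares amino acids; the test suite checks this
codon-local computation against an independent oracle that rebuilds
and retranslates the *entire* mutated CDS and diffs the protein.

Rendering follows the compact one-letter style of worm-genetics
reports rather than full HGVS: `c.1154C>T`, `c.-4T>A`, `p.A385V`,
`p.H409=` for synonymous, `p.K533*` for nonsense. Start-loss and
stop-loss classes exist for completeness. 3′UTR positions are
classified but `c.*N` numbering is out of scope. When a variant hits
several overlapping transcripts all annotations are emitted.

Burden summaries report nonsense and splice-proximal fractions as
percentages rounded **half-up** to two decimals; this rounding rule is
what reproduces conventional printed percentages (e.g. 5/188 → 2.66)
from their fractions, where banker's rounding would not.

## Revertants, spectra, saturation

The six strand-collapsed substitution classes (a C>T call and a G>A
call are one class, because alkylating-mutagen chemistry is
strand-symmetric) summarise each strain's background. Defaults encode
the chemistries qualitatively — EMS: G:C>A:T at weight 0.85, remainder
uniform; ENU: A:T>T:A 0.30, A:T>G:C 0.25, G:C>A:T 0.25, remainder
uniform; the cocktail is their equal mixture. No quantitative spectrum
is authoritative here, so all weights are configuration, and every
test that depends on them reads them from the configuration.

A reverted strain is a **true revertant** when its filtered background
load (excluding the primary site) reaches `min_load` (default 20) and
the fraction of calls in positive-weight classes reaches
`min_fraction` (default 0.9); a reverted strain with almost no
background is **suspected contamination**; ample but
spectrum-inconsistent background is **ambiguous**. The two thresholds
are package conventions (the underlying biological evidence is
qualitative: a revertant still carries its mutagen scars) and both are
config keys. The verdict is monotone in load and fraction by
construction.

Saturation is reported as qualitative signals — a validated reversion
event, any position hit by ≥ 2 strains, any codon hit by ≥ 2 strains,
and overlap with prior-screen sites — not as a probability; no
defensible estimator exists at these sample sizes, and an
unseen-allele estimate would suggest more precision than the data
carry.

## Phenotype assays and survival curves

The hatching rate of a plate is total hatched embryos over total eggs
laid across the 4 assay days, as a percentage to two decimals; progeny
of mothers that died or were lost remain included, and a plate with
zero eggs yields an undefined marker rather than an error so batch
summaries keep going.

Population metrics are first-crossing times of daily count snapshots:
"reaches 50" is the first day the count is ≥ 50 (counts are daily, so
"equals" and "reaches" coincide at the first crossing). A plate dying
before reaching a count metric is **censored for that metric at its
death day** — the three outcomes are reported as separate curves, and
with no stated competing-risk treatment, censoring is the transparent
choice (the resulting curves estimate the metric-specific cumulative
incidence under independent censoring; a Fine–Gray style treatment is
a documented non-goal). Plates with no event by day 30 are censored at
the 30-day assay termination.

Product-limit estimation is delegated to `survival::survfit` behind
the `km_curve()` surface, with events preceding censorings at tied
days (the standard convention); tests verify the estimates against an
explicit risk-set product and, in the uncensored case, against the
empirical event fraction exactly. Curves are additionally reported as
`1 − S(t)`, the "fraction of plates that reached the metric"
orientation used in screen figures.

## The synthetic screen generator

The generator is first-class, tested code; its defaults *are* the
emulated study conditions, chosen once:

| Parameter | Default | Rationale |
|---|---|---|
| `mutation_load_mean` | 110 | filtered per-strain loads observed in such screens span ~47–188; the mean sits mid-range |
| background placement | coding/splice/UTR sites only | emulates the *post-filter* load directly; genome-wide placement would only add calls the filter removes |
| `depth_mean` | 30× | moderate-coverage WGS; negative binomial, size 10 |
| allele fraction | Beta(60, 1) | homozygous calls concentrate near 1; P(AF ≤ 0.9) ≈ 0.002 |
| `fraction_intragenic` | 0.12 | intragenic suppressors are ~12% of suppressor strains in this design |
| `fraction_revertant`, `fraction_contamination` | 0.01 each | rare events, one-ish per screen |
| decoy territory | 300 genes on 2 Mb | keeps the target gene a small fraction (<1%) of mutable sites, so background rarely lands in-gene, as in a real genome |
| brood | 200 eggs over 4 days | wildtype-scale brood |
| hatching | Binomial(eggs, strength) | suppression strength *is* the hatch probability |
| population | daily branching process | adults lay for 4 days from maturity (2 days), worms die at 12 days, eggs hatch next day; hatched worms are fertile with the same probability, so weak suppression is subcritical and plates die out |

Reproducibility: every simulator takes or derives an explicit seed;
per-strain seeds are a deterministic function of the plan seed and the
strain label, so a fixed plan yields byte-identical VCF bundles, which
the test suite asserts literally. A run's reports carry the seed and a
hash of the scientific configuration (output paths excluded) in their
headers.

The deterministic **fixture transcript** encodes a plus-strand,
four-exon target gene whose genomic↔cDNA offsets reproduce a published
intragenic suppressor coordinate set exactly (intron lengths 136, 83
and 2,022 nt; CDS of 707 codons; pinned reference codons force each
documented substitution's amino-acid change). One constraint is worth
recording: the third intron must fall between coding positions 1262
and 1325 — not merely before 1597 — for the primary lesion's genomic
position to map to codon 442; it is placed between c.1290 and c.1291.
The chromosome is padded with `N` outside the gene neighbourhood so
1-based coordinates hold without carrying megabases of sequence.

What the generator does **not** emulate: read-level data (no FASTQ,
so no mapping artefacts or coverage troughs), linkage and
recombination, heterozygous segregants, indels and structural
variants, or realistic worm demography. Passing tests therefore
demonstrate correctness of the analysis logic under the stated noise
model, not robustness to upstream calling artefacts.

## Numerical and interface choices

* Coordinates are 1-based inclusive at every interface; any internal
  half-open arithmetic is invisible.
* Chromosome names are taken verbatim; no `chr` normalisation.
* The VCF dialect reads DP/AF from INFO or the first sample's FORMAT,
  FORMAT winning — the writer emits both, and records lacking either
  field are rejected with a count, never fatally.
* Money is held as integer cents, so component sums are exact; the
  hands-on-time figures are totals at the reference screen size and
  scale linearly, an explicit simplification.
* Degenerate inputs have defined behaviour throughout: zero-egg plates
  give `NA` rates, empty call sets give empty passing sets with zero
  tallies, an empty manifest produces an empty report with a warning
  rather than an error.

## Problem sizes used by the shipped tests

The suite favours a few deep, parameterised checks per operation:
filter-vs-brute-force equivalence on 1,000 random call sets; annotator
vs whole-CDS retranslation on 10,000 random coding SNVs over 15 random
multi-exon genes (both strands); 100,000 spectrum draws for the
goodness-of-fit check; a 50-strain all-intragenic screen for planted
recovery; 200 plates for hatching-rate recovery. These sizes were
chosen to make the statistical assertions sharp at conventional
α = 0.01 while keeping a full run in the low minutes on one core.

## Known limitations

* Reversion cannot be distinguished from a coverage dropout at the
  primary site from VCF input alone; depth-aware confirmation would
  need the alignments.
* The annotator assumes intact reading frames and ignores
  splice-consequence prediction beyond window classification.
* Saturation signals are descriptive, not inferential.
* Phenotype simulation is a plate-level branching process, not a
  demographic model; its purpose is ground truth for the statistics,
  not biological realism.
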