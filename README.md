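# modscreen

Identification and interpretation of **intragenic suppressor variants**
from whole-genome-sequenced forward-genetics screens.

## The problem

A classic way to dissect gene function in *C. elegans* is a suppressor
screen: worms carrying a deleterious allele — e.g. a temperature-sensitive
missense mutation in an essential gene such as *zyg-1*, the polo-kinase
driving centriole duplication — are mutagenized with EMS and/or ENU and
survivors at the restrictive temperature are kept. Each surviving strain
carries a suppressing variant somewhere in a genome littered with dozens
to hundreds of random background mutations. Sequencing every strain's
whole genome (instead of Sanger-sequencing the target locus) identifies
intragenic (second-site, in-gene) suppressors, distinguishes true
revertants from wildtype contamination, reveals each strain's genomic
burden, and measures how close the screen is to saturation.

`modscreen` implements that analysis as a tested, reusable pipeline:

* **Filtering** — per-strain VCF calls are kept iff read depth > 5,
  allele fraction > 0.9 (homozygotes), position in a coding region,
  within ±10 nt of a splice junction, or (optionally) in a UTR, and the
  call is de novo relative to the parental strain. Rejections are
  tallied per criterion in a fixed order.
* **Effect annotation** — a from-scratch coding-effect annotator. A
  substitution at coding position *c* falls in codon
  `ceil(c / 3)`; editing that codon under the standard genetic code and
  diffing amino acids yields missense / synonymous / nonsense / splice /
  UTR classes rendered in the compact HGVS style used in worm genetics
  reports: `c.1154C>T; p.A385V`, `c.-4T>A`, `p.H409=`.
* **Interpretation** — strand-collapsed substitution spectra
  (G:C>A:T, A:T>T:A, ...) classify each call as transition or
  transversion; a strain whose primary lesion has reverted is a *true
  revertant* only if it retains a genome-wide, spectrum-consistent
  mutagen background, otherwise it is suspected contamination.
  Recurrently hit positions and codons across strains are the screen's
  saturation signals.
* **Phenotype assays** — 4-day hatching rates (total hatched / total
  laid), population metrics (first day ≥ 50 viable worms, first day
  ≥ 50 L4-or-older worms, population death) censored at 30 days, and
  Kaplan–Meier product-limit curves
  `S(t) = ∏_{u ≤ t} (1 − d_u / n_u)` reported in the
  "fraction of plates reaching the metric" orientation `1 − S(t)`.
* **Cost model** — exact decimal Sanger-vs-WGS screen cost comparison.
* **Synthetic screens** — a generator that emulates the study design
  end to end (mutagen spectra, homozygous call profiles, planted
  intragenic suppressors, revertants, contamination, plate assays), so
  every stage is tested against ground truth without any downloads.

## Worked example

Annotate one suppressor call against the packaged target-gene fixture
(a deterministic transcript whose coordinates reproduce a published
intragenic suppressor set exactly):

```r
library(modscreen)
fx <- build_fixture_transcript()
v <- variant_calls("MTG57", "II", 5651146, "C", "T",
                   read_depth = 30, allele_fraction = 1.0)
annotate_variant(fx$transcript, fx$genome, v)
#>   strain_id position region coding_position codon_index effect_class
#> 1     MTG57  5651146 CODING            1154         385     MISSENSE
#>      c_hgvs  p_hgvs
#>   c.1154C>T p.A385V
```

The call sits at coding position 1154, i.e. codon 385, and substitutes
valine for alanine — a candidate intragenic suppressor. Burden and cost
summaries print equally directly:

```r
burden_percentages(188, 5, 4)
#> 5/188 nonsense (2.66%), 4/188 splice-affecting (2.13%)
compare_costs(sanger_profile(100), wgs_profile(100))
#> <CostComparison> n = 100 strains
#>   SANGER   total    8140.00 CAD (81.40/strain), hands-on 60.0 h
#>   WGS      total   21400.00 CAD (214.00/strain), hands-on 7.0 h
```

A full synthetic screen runs through three commands:

```r
cfg <- run_config(list(outdir = "screen_out", seed = 1))
cmd_simulate(cfg)   # genome, GFF3, per-strain VCFs, truth table, plates
cmd_analyze(cfg)    # filter -> annotate -> interpret; candidates.tsv,
                    # recurrence.tsv, summary.json
cmd_phenotype(cfg)  # per-strain summaries + product-limit curve TSVs
```

A thin command-line front end with the same subcommands is installed at
`inst/cli/modscreen.R`.

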