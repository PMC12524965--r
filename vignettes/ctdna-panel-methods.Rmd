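---
title: "Methods: targeted-panel ctDNA analysis with liquidpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted-panel ctDNA analysis with liquidpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidpanel)
```

## The analysis problem

Neuroblastoma risk stratification and targeted-therapy selection depend on
the tumour's genetic profile — activating ALK kinase-domain mutations,
RAS-MAPK pathway mutations (PTPN11, KRAS, NRAS), TP53 status, and oncogene
amplifications, above all MYCN. Circulating tumour DNA (ctDNA) from plasma
lets these markers be read without an invasive biopsy, but the tumour
fraction of cell-free DNA is often a few percent or less, so the analysis
must separate low-VAF somatic signal from germline polymorphism, sequencing
artifact and sampling noise.

`liquidpanel` implements the computational half of a targeted UMI-panel
ctDNA workflow, starting from called, annotated variants and per-target
coverage (alignment, UMI consensus building and raw calling are upstream,
vendor-side steps). Its stages are:

1. **Sample QC** — a plasma sample whose cfDNA fraction is below 20% of
   total DNA is excluded outright.
2. **Variant filtering** — a cascade of row-wise predicates: UMI depth
   ≥ 100×, VAF ≥ 0.5%, removal of flagged recurrent artifacts and PCR
   duplicates, removal of population-common variants (dbSNP-common maximum
   super-population MAF ≥ 1%, or gnomAD exomes frequency > 1%), and
   subtraction of matched germline WGS calls where available.
3. **Pathogenicity classification** — a deterministic tier function of
   SIFT, PolyPhen-2, REVEL and COSMIC evidence.
4. **Reporting** — driver-tier variants with VAF strictly above 1%.
5. **CNV detection** — per-target coverage z-scores against a trimmed
   within-sample baseline.
6. **Concordance and trajectories** — cross-compartment (ctDNA vs tumour)
   and longitudinal comparison of driver calls, plus tumour purity from
   VAF under explicit mixing models.
7. **ddPCR quantification** — Poisson partition statistics for droplet
   counts.

The package functions, the bundled fixture and this vignette are the
primary interface; `inst/cli/liquidpanel.R` wraps the same functions for
shell use (`simulate`, `run`, `cnv`, `ddpcr`).

## Filtering semantics

Two decisions shape the cascade's behaviour on edge cases.

**Threshold edges.** "Coverage below 100× and frequencies below 0.5% are
filtered out" is implemented as *inclusive keep*: depth ≥ 100 and VAF
≥ 0.5% are retained. The reporting rule, by contrast, is a *strict*
bound — VAF > 1% — because it describes what crosses the line into a
clinical report rather than what survives QC.

**Missing values retain.** Every filter removes a row only on positive
evidence of a violation. A variant with no recorded population frequency
is kept (absence of evidence of commonness is not evidence of
commonness); a record with no depth — as in transcriptions of published
tables, which print VAF but not coverage — is not discarded by the depth
rule. This makes the cascade applicable both to full VCF exports and to
literature-derived tables without special-casing either.

The five super-populations behind the dbSNP-common rule are fixed as AFR,
AMR, EAS, EUR and SAS (the gnomAD/1000 Genomes convention). Recurrent
artifacts are an input flag rather than recomputed: panel-of-normals
artifact lists are produced upstream by the caller, and re-deriving them
requires raw data this pipeline deliberately does not consume.

Because every stage is a row-wise predicate, the cascade is idempotent,
order-invariant, and monotone in its thresholds; the test suite asserts
all three properties on generated data.

## Pathogenicity tiers

The tier function is evaluated in order:

| tier | rule |
|---|---|
| pathogenic | REVEL > 0.7 **and** COSMIC presence |
| likely_pathogenic | COSMIC presence + deleterious SIFT + damaging PolyPhen-2, **or** truncating consequence in a driver gene |
| VUS | any single piece of in-silico damage evidence |
| benign | otherwise |

"Damaging" PolyPhen-2 means a PRD or POD call (score ≥ 0.447, the tool's
own possibly-damaging boundary, when only a score is given); "deleterious"
SIFT means the vendor call, falling back to score ≤ 0.05. A *driver* is
anything in the top two tiers. The driver-gene set for the truncating rule
defaults to the panel's genes and is configurable.

The rule order was chosen so that classification is decidable from the
columns a published driver table actually prints, including its two hard
cases: a hotspot variant whose REVEL score is missing (N/A) but which is
COSMIC-catalogued with concordant SIFT/PolyPhen calls lands in
likely_pathogenic rather than being dropped, and a frameshift/splice-donor
indel with no scores at all is rescued by the truncating-in-driver-gene
rule. The tier is monotone in evidence — adding a fired rule can never
demote a variant — which the suite verifies exhaustively over all 32
evidence combinations.

## Coverage z-scores for amplification

For one sample, the copy-neutral baseline is estimated from per-target UMI
depths after three exclusions: targets of known-amplified genes, targets
of X-chromosomal genes (whose dosage depends on sex, not tumour state),
and a symmetric trim of the top and bottom 5% of the remaining depths.
The trim is what makes the baseline robust when an amplification is *not*
known in advance: a high-level amplification occupies the extreme upper
tail and is trimmed out of its own reference. With μ and σ from the
surviving targets,

$$ z = \frac{x - \mu}{\sigma} $$

is computed for *every* target, including excluded ones, against that one
baseline. The baseline is within-sample by construction — no reference
cohort of normal samples is assumed — so z is interpretable as "how far
this target sits outside this sample's own neutral spread". A sign-flipped
`inv_z` column is also emitted, matching the presentation convention in
which amplified regions are drawn as long positive bins.

Gene-level calls use the **median** of the gene's per-target z (robust to
a single dropped-out or noisy target), thresholded at `z_amp = 5` for
amplification and `z_gain = 2` for gain. No z threshold is canonical in
the field; these defaults exploit the fact that clinically meaningful
amplification in this disease is massive. At purity *p* and tumour copy
number *C* the expected relative coverage is

$$ \frac{2(1-p) + Cp}{2}, $$

so even a low-purity (30%) sample of a 50-copy MYCN amplification sits at
8.2× the neutral level — roughly 70 baseline standard deviations at 10%
coverage noise — while copy-neutral noise keeps gene medians within ±1.
Calls are therefore insensitive to the exact threshold in the regime that
matters; the suite confirms ≥ 95/100 detection at that operating point and
zero false amplification calls on 100 copy-neutral simulations.

Two blind spots are inherent and deliberately reproduced: a gene amplified
only outside the panel footprint produces no coverage signal and is never
called, and deletions/LOH are out of scope (panel coverage is too sparse
to call losses reliably; LOH is read from SNP arrays upstream).

## Concordance, trajectories and purity

Variant matching across compartments and assays is by genomic key
(`chrom:pos:ref:alt`; `gene:base_change` for coordinate-free tables).
Concordance classification (`shared` / `ctDNA_only` / `tumour_only`)
requires all samples to belong to one patient and is restricted by the
caller to driver-tier calls.

Longitudinal trajectories code a variant *absent* at a timepoint when it
is below the reporting threshold — mirroring "not detected" language in
clinical assays — while retaining the raw sub-threshold VAF in the output
series for inspection. Presence patterns map to event labels: `lost`,
`emergent`, `lost_then_emergent` (the pattern of a clone cleared at
remission and fixed at relapse), `emergent_then_lost`, and for
always-present variants `rising` / `falling` / `stable` under a 20%
relative-change tolerance.

Tumour purity from a somatic VAF uses two explicit mixing models:

- `het_diploid` — tumour cells diploid and heterozygous:
  $\mathrm{VAF} = p/2$, so $p = 2\,\mathrm{VAF}$;
- `hom_loh` — tumour cells hemizygous-mutant after loss of the wild-type
  allele (copy number 1, e.g. TP53 after 17p loss), mixed with diploid
  normal: $\mathrm{VAF} = p/(2-p)$, so $p = 2\,\mathrm{VAF}/(1+\mathrm{VAF})$.

```{r purity}
# a homozygous TP53 variant read at VAF 10.5% implies ~19% tumour content
purity_from_vaf(0.105, "hom_loh")
```

The inversion is exact (round-trip to 1e-9 across both states, asserted in
the suite). VAFs that invert above 1 are clipped and flagged rather than
silently truncated. The hom_loh model fixes tumour copy number 1 with 100%
mutant allele; other copy states would need allele-specific copy number
the panel cannot provide and are rejected explicitly.

## ddPCR Poisson statistics

With droplets as independent partitions, the per-droplet copy count is
Poisson and a channel with positive fraction $\hat p$ has

$$ \hat\lambda = -\ln(1 - \hat p), \qquad
   \text{concentration} = \hat\lambda / V_d, \qquad
   \mathrm{FA} = \frac{\lambda_\text{mut}}{\lambda_\text{mut} + \lambda_\text{wt}} $$

with droplet volume $V_d$ = 0.85 nL by default. Confidence intervals come
from the exact (Clopper–Pearson) binomial interval on $\hat p$ mapped
through $-\ln(1-\cdot)$, which is monotone, so no delta-method
approximation is needed. A saturated channel (every droplet positive)
leaves λ undefined and raises an error telling the operator to dilute. A
target is *detected* at ≥ 3 mutant-positive droplets — common field
practice; vendors report only detected/not-detected — and the threshold is
configurable.

## What the synthetic generator emulates — and what it does not

The generator exists so every downstream stage has ground truth. Its
defaults describe a realistic high-depth panel run:

- **Panel**: 42 genes — the 15 canonical neuroblastoma/driver genes plus
  filler genes of interest to the configured size, two of them
  X-chromosomal; 8 schematic non-overlapping targets per gene. Counts in
  panel analyses matter only relative to panel size, not to real
  coordinates.
- **Depth**: lognormal per-target UMI depth centred on 2228× (sdlog 0.5),
  the mean yield of this panel chemistry on a mid-output flow cell.
- **Somatic VAF**: expected VAF = purity × clonal fraction pushed through
  the copy-state mixing model above; alt UMI counts drawn binomially at
  the simulated depth. A variant drawing zero alt reads is *not called*,
  so a purity-0 sample yields an empty somatic table, as a real caller
  would report.
- **Germline SNPs**: scattered uniformly over the panel at population MAFs
  drawn from \[0.01, 0.45\], homozygous with probability equal to the MAF,
  with the MAF recorded in both population-frequency fields.
- **Artifacts**: Poisson-distributed low-VAF (< 0.5%) substitutions at a
  configurable per-target rate, never COSMIC-flagged, carrying the
  upstream artifact flag.
- **Scores**: pathogenic variants draw REVEL from \[0.72, 0.99\], benign
  from \[0, 0.5\] — deliberately disjoint so label-recovery tests can
  demand exactness; a configurable fraction of pathogenic variants gets a
  missing REVEL to exercise that classification path.

`scenario_clonal_evolution()` composes these into the two-clone ALK case:
minor R1275Q (expected VAF 2.85%) and major F1174L (28.5%) in diagnosis
plasma; single-site tumour biopsy carrying only R1275Q (32%); no somatic
signal at remission; F1174L alone at relapse (~98% in plasma under wild-
type-allele loss, 46.1% heterozygous in the metastatic tumour).

The generator does **not** simulate reads, UMI families, base-context
error profiles, GC/mappability coverage bias, subclonal copy-number
mixtures, or contamination. Passing tests therefore demonstrate that the
*statistics* behave as designed under their stated models — not that the
pipeline is robust to every artefact of real sequencing. The raw-variant
load per sample is controlled by the germline and artifact rates rather
than calibrated to any particular published per-sample count.

## Numerical and degenerate-input choices

- A constant coverage vector has σ = 0; z-scores are then undefined and
  `z_scores()` raises an error rather than returning infinities.
- A baseline with fewer than 5 surviving targets is refused.
- `compute_baseline()` trims `floor(n × trim_fraction)` targets per tail,
  so small panels with trim 0.05 may trim nothing — intended, as trimming
  exists to shed extreme tails of large panels.
- VAF = 1 under `het_diploid` is impossible at any purity and is an
  error; under `hom_loh` it inverts to purity 1.
- All simulators consume an explicit integer seed through an isolated RNG
  scope, so identical seeds give byte-identical outputs and the global RNG
  state of the session is untouched.
- Determinism of the whole pipeline: rerunning `run_pipeline()` on the
  same config writes byte-identical report files (no timestamps in
  outputs; provenance carries a config hash and the seed).

## Test problem sizes

The suite exercises the statistical claims at the scales the analyses were
designed for: 100 seeds for amplification detection and for the
copy-neutral false-positive rate, 50 seeds for the filtering cascade's
driver-retention property (drivers at expected VAFs 2.85–28.5% and mean
depth 2000×), 1000 replicates per λ ∈ {0.01, 0.1, 1} for ddPCR estimator
consistency, 10 end-to-end seeds for scenario label recovery, and
Monte-Carlo agreement bands of three standard errors throughout.

## Known limitations

- CNV calling is within-sample only; no reference-cohort normalisation,
  no segmentation, no gains smaller than the gene-median statistic can
  resolve, no deletions.
- Concordance is by genomic key only; assay sensitivity differences
  between platforms are metadata, not modelled.
- The VAF is taken as alt UMI families over total UMI families at the
  locus; upstream callers that define it otherwise should be harmonised
  before input.
- Purity estimation assumes one of two pure copy states; mixed or
  higher-ploidy states are out of scope.
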