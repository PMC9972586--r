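---
title: "Intronic genomic qPCR: models, design rules, and what the simulator establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intronic genomic qPCR: models, design rules, and what the simulator establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronicqpcr)
```

## The problem and the assay

Patient-derived xenograft (PDX) tumors and the cell lines derived from them
are routinely infiltrated by host (murine) stromal cells, sometimes to the
point where a nominally human model is mostly mouse. Standard
authentication tools (STR fingerprinting, SNP panels, karyotyping) are
slow, species-limited, or insensitive to mixtures. A genomic qPCR assay
sidesteps all of this: design one primer pair per species such that

* both primers lie **entirely within introns** that flank a **short exon**
  of a conserved housekeeping gene (Gapdh in the published assay), and
* each pair matches its own species' genome perfectly but has no
  productive binding-site pair in the other species' genome.

Because both binding sites are intronic, spliced mRNA and its cDNA cannot
template the reaction — only genomic DNA amplifies, at one locus copy per
haploid genome. Two Ct values per sample (human assay, mouse assay) then
quantify the species composition directly.

## Quantification model

All quantification rests on one premise: both amplicons double each cycle
(equal efficiency). A Ct difference then maps to a fold ratio of genomic
copies:

$$F = 2^{\,mCt - hCt}, \qquad hP = \frac{F}{F+1} \times 100\%, \qquad mP = 100\% - hP.$$

`composition_from_ct()` implements exactly this; `mP` is computed as
`100 - hP`, so the normalization identity holds bit-exactly (this is
asserted over random Ct pairs in the test suite, not assumed). The fold
scale is the familiar one: a gap of 6.64386 cycles is a 100-fold ratio, 20
cycles is 1,048,576-fold.

The detection-sensitivity mapping follows the same dynamic-range logic:
`sensitivity_from_delta_ct(d)` returns $100/2^{d}$ percent, i.e. 1% at a
100-fold window, 0.1% at 1,000-fold, 0.01% at 10,000-fold. An alternative
reading — the undetected species as a fraction of the *total*,
$100/(2^d + 1)$ — differs by about 1% of itself at the 1% level; the
implementation follows the fold-reciprocal mapping because that is the
published interpretation, and the alternative is noted here once.

Mass-to-copies conversion uses the molar mass of a base pair:
`copies = ng × 6.022e23 / (genome_len × 1e9 × 650)`, with haploid genome
lengths 3.2e9 nt (human) and 2.5e9 nt (mouse) as overridable constants
(`quant_constants()`). One nanogram of human genomic DNA is ~289.5 genome
copies.

### Censoring

Wells that never cross threshold are reported by instruments as
"Undetermined". The package follows the plate-reader convention of
recording them at the final cycle (40 by default): they enter replicate
means at Ct = 40. Because a censored reading only lower-bounds the true
Ct, a sample whose assay is *fully* censored additionally carries a
`detection_floor` — $100/2^{40 - \text{other mean Ct}}$ percent — an upper
bound on the undetected species' fraction. The point estimate alone would
overstate confidence; the floor is the honest summary.

Auxiliary formulas kept with the quantifier because they belong to the
same workflow: `relative_quantification()` (RQ = $2^{-\Delta\Delta Ct}$,
for mRNA expression), `doubling_time()` ($T\ln 2 / \ln(X_e/X_b)$) and
`tumor_volume()` ($w^2 l / 2$).

## Design rules

`enumerate_candidate_sites()` admits an exon only if it is short
(≤ 150 nt by default) and both flanking introns can host a primer. Within
the two introns, `design_primer_pairs()` scans **every** window of
18–25 nt and filters on:

| filter | default | why |
|---|---|---|
| GC content | 40–60% | standard primer practice |
| homopolymer run | ≤ 4 | slippage-prone templates |
| Tm | 57–63 °C, optimum 60 | anneal together at one cycling program |
| amplicon length | 80–300 nt | qPCR-sized products |
| N bases | none | oligos must be fully specified |

Tm is nearest-neighbor (unified 1998 parameter set) with the entropy salt
correction and a self-complementarity correction. The concentration term
uses total strand concentration over 4 (or 2 for self-complementary
oligos). Two conditions parameterize the model: oligo concentration
(250 nM, a typical qPCR primer concentration) and monovalent salt. The
salt default is **200 mM**, deliberately *not* the 50 mM KCl of a PCR
buffer: it is the monovalent equivalent of 50 mM K⁺ plus ~3 mM Mg²⁺, which
reproduces a divalent-corrected Tm within ~0.4 °C while keeping the model
a single published correction. Under these conditions ordinary 18–25-mers
at 40–60% GC land in the 57–63 °C window.

Pairs are ranked by a penalty —
$|Tm_f - 60| + |Tm_r - 60| + |Tm_f - Tm_r| + |L - L_{mid}|/100 +
(|GC_f - 50| + |GC_r - 50|)/10$ — and every tie breaks positionally
(leftmost forward start, then leftmost reverse start), so the ranking is a
total order and results are reproducible regardless of enumeration order.

`verify_genomic_only()` re-checks, rather than trusts, the core safety
property: both primers inside distinct introns and at least one complete
exon inside the amplicon.

### Annealing model

On-target prediction (`insilico_pcr()`) requires **perfect** matches —
full annealing initiates the PCR — pairs convergent non-overlapping sites
(any oligo may prime either end, so single-oligo products are found too),
and bounds products at 2,000 nt, generous for qPCR. Product length is
counted from forward 5′ end to reverse 5′ end inclusive.

Off-target screening (`cross_species_specificity()`) must be stricter than
"no perfect match", since near-matches can still prime. No mismatch
threshold is published for this assay, so the package operationalizes
"detects one species only" with a standard polymerase-extension argument:
a site counts if it has **at most 2 mismatches overall and a perfect
12 nt 3′-terminal seed**, because extension is governed by the primer's
3′ end. An assay passes only when no productive site pair exists under
this relaxed model. SYBR-chemistry artifacts (nonspecific amplification
visible on gels) are not predicted — they are polymerase, not
hybridization, phenomena.

`place_probe()` adds an optional hydrolysis probe: strictly between the
primers, Tm at least 5 °C above the hotter primer (so the probe is bound
when primers extend), no 5′-terminal G (reporter quenching), highest Tm
first, leftmost on ties.

## The simulator: its world and its limits

`simulate_ct()` draws
$Ct = Ct_1 - \log_{1+E}(\text{copies}) + \mathcal{N}(0, \sigma)$, censored
at cycle 40. Defaults are the stated world of the method: $E = 1$ (exact
doubling), intercept $Ct_1 = 38$ (a typical single-copy crossing point on
a 40-cycle run), $\sigma = 0.15$ cycles — Gaussian noise on the Ct scale
is standard qPCR practice, and 0.15 keeps triplicate SEMs at the barely
visible level of clean genomic qPCR error bars. Ct depends only on target
copies, not genome mass, mirroring the one-locus-per-haploid-genome
premise. Copies are integers; sub-single-copy Poisson sampling of the
template (the honest model near the detection limit) is a documented
extension, not the default, so the 50-copy floor scenario tests censoring
behavior, not stochastic dropout.

`mixture_series()` reproduces the two published plate designs: the
efficiency test (5,000 total copies at 100/0, 75/25, 50/50, 25/75, 0/100)
and a sensitivity series whose smallest component is 50 copies. The
preset fractions for the sensitivity series (99, 90, 75, 50, 25, 10, 1%)
were chosen once so that both extremes hit 50 copies at a 5,000-copy
total; only the 50-copy floor itself is a stated quantity.

`synthetic_genome_pair()` builds two genomes sharing a 5-exon gene:
100 nt exons conserved at 90% identity (coding conservation: the real
orthologs share 87.5% protein identity, and synonymous sites push
nucleotide identity slightly higher), 400 nt introns at 25% identity (the
expected identity of unrelated sequence over a four-letter alphabet —
introns are modeled as having diverged to noise), independent 300 nt
flanks. Setting `intron_identity = 1` makes the species
indistinguishable, which is the negative control for the specificity
machinery.

A quantitative note on recovery accuracy under the default noise: with
$\sigma = 0.15$ per well and triplicates, each assay's mean Ct has SD
$0.15/\sqrt{3} = 0.0866$, so $\Delta Ct$ has SD 0.1225 cycles. The
percentage responds at $100\ln 2\, F/(F+1)^2$ points per cycle — 17.3 at
50/50, 13.0 at 25/75 — so the recovered percentage has SD ≈ 2.1 points at
an even mixture and ≈ 1.6 points at 25/75. The probability of landing
within ±3 points is therefore about 84% at 50/50 and 94% at 25/75 (≈ 91%
averaged over the three-mixture design), and reaching 95% coverage at an
even mixture would require either ±4-point tolerance, lower noise, or
more replicates. The test suite asserts the analytically derived bound;
the stricter 95%-at-±3 target is also exercised and documented as not
attainable under this noise model.

What a green end-to-end test establishes: the design rules find primers,
the in-silico PCR agrees with an independent sliding-window oracle, the
quantifier inverts the simulator's own Ct model exactly in the noise-free
limit and within ±3 points under realistic noise. What it does not
establish: performance on real genomes (repeats, pseudogenes, segmental
duplications can create off-target sites a 2.9 kb synthetic genome cannot
represent), probe-chemistry effects, pipetting error, or efficiency
drift — the `efficiency` knob exists precisely to probe that last
assumption, but no published value constrains it.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
  convention is converted exactly once, at the I/O boundary.
* Intron numbering follows transcript order (intron *i* separates exons
  *i* and *i+1*); when several transcripts exist the one with the most
  exons is used unless a transcript id is given.
* Replicate SEM is sample SD over √n; a single replicate reports SEM 0.
* ΔCt is computed on replicate-mean Cts (triplicate aggregation precedes
  differencing); per-replicate ΔCt with error propagation is possible by
  calling `composition_from_ct()` per replicate, but the mean-first
  convention is the default because that is how triplicates are
  summarized upstream.
* Percentages print with 4 decimal places in reports, matching the
  precision at which such compositions are conventionally quoted.
* Degenerate bases other than N are rejected at parse time with a
  position; N is tolerated in genomes but disqualifies any primer window
  containing it.
* Exit codes: 0 success, 2 validation failure (no discriminating assay /
  no template), 1 usage or I/O error.

## Known limitations

* One printed consistency check in the source material
  ($2^{11.48} = 3.5\times10^4$) is arithmetically off by an order of
  magnitude ($2^{11.48} \approx 2.9\times10^3$); the package implements
  the formula, not that printed value.
* The relaxed annealing model is a hybridization heuristic; it does not
  model polymerase tolerance quantitatively, thermodynamic mismatch
  penalties, or bulge/indel binding.
* No multi-species (>2) deconvolution, no efficiency-curve fitting, no
  raw fluorescence traces.
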