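---
title: "Calling and explaining mitochondrial heteroplasmy from Sanger trace peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and explaining mitochondrial heteroplasmy from Sanger trace peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangerhet)
```

## The problem

Animal mitochondrial DNA is usually assumed to be homoplasmic and strictly
maternally inherited. When direct Sanger sequencing of an mtDNA amplicon
shows a clean double peak — two overlapping base signals at one position in
both the forward and the reverse read — that assumption is in question. A
double peak can mean true heteroplasmy (two mitochondrial sequence variants
in one individual), but it can equally be an artifact of a co-amplified
nuclear pseudogene (NUMT), a duplicated mitochondrial gene region, a
sex-specific genome under doubly uniparental inheritance (DUI), or a fresh
somatic mutation. Deciding between these explanations requires structured
data: broods of known mothers, multiple tissues of single individuals,
single-molecule clones, and adults of both sexes.

`sangerhet` implements that whole chain: quantifying the double peak,
confirming it across replicate extractions, enumerating haplotypes and
clone combinations, applying the elimination logic over pedigree / tissue /
sex structure, and modelling mother-to-egg transmission through a germline
bottleneck. It ships transcriptions of published peak-proportion tables for
the Atlantic spider crab *Maja brachydactyla* (a species where brood data
allowed the full elimination argument), and a simulator that generates
labelled data under each candidate scenario.

## Quantifying a double peak

The frequency of each nucleotide at a site is estimated per read as the
height of its peak divided by the sum of the two candidate peaks, and then
averaged over the forward and reverse reads:

\[ \hat p = \tfrac12\left(\frac{h^F_1}{h^F_1+h^F_2} + \frac{h^R_1}{h^R_1+h^R_2}\right). \]

The two reads are *not* expected to agree exactly: PCR yield differs
between primers, so the two amplitudes differ while the ratios agree in
expectation. With a single usable read the estimate is that read's ratio,
flagged `single_read`.

A site is called heteroplasmic when the minor proportion reaches
`min_minor_fraction` **and** the minor peak clears the baseline. Choices
made here, and why:

* `min_minor_fraction = 0.05`. The smallest minor proportions reported as
  real heteroplasmy in the curated tables are 6.5% (16S) and 6.7% (COI);
  5% sits below every reported positive while still excluding baseline
  wobble. Configurable everywhere.
* Baseline criterion for simulated/parsed traces: the minor peak must
  exceed 3x the read's baseline level in every available read. The source
  material demands only a "clear difference from the baseline"; the factor
  3 is this package's operationalization.
* Exact 50/50 sites are heteroplasmic by definition; the major base is then
  assigned by the fixed order A < C < G < T so output is deterministic.
* Percentage fixtures carry no raw heights, so the per-read averaging is
  bypassed and printed percentages are used as given (renormalized, since
  printed pairs occasionally sum to 99.6–100.3 after rounding).
* Replicate confirmation marks a site `confirmed` only when both
  independent extractions are heteroplasmic at the same position with the
  same base pair; discordant sites are kept and flagged `unconfirmed`,
  never dropped silently.

## Haplotypes and variable sites

Sequences with *any* double peak are excluded whole from haplotype and
variable-site analysis (the published tables do the same; their own
haplotype-membership lists partially contradict that footnote, and this
package follows the footnote). A variable column is any column with two or
more bases among the unambiguous sequences; it is parsimony-informative
when at least two bases each occur in at least two sequences, singleton
otherwise (the standard column rule — the source names the classes without
defining them).

Protein-coding analysis uses the invertebrate mitochondrial genetic code
(translation table 5: TGA=Trp, AGA/AGG=Ser, ATA=Met). Because the reading
frame of an arbitrary amplicon is not printed anywhere, `infer_reading_frame()`
picks the frame minimizing stop codons, breaking ties toward the smallest
offset — reproducible, though unverifiable against the source. Synonymous /
non-synonymous differences are counted per differing site with the whole
codon classified by direct codon-pair translation; no Nei–Gojobori pathway
averaging. This is the simplest rule consistent with small integer counts,
and it is symmetric in its arguments.

## The elimination logic

`classify_dataset()` runs deterministic, evidence-producing rules; each
hypothesis ends `rejected`, `not_rejected`, or `insufficient_data`, and a
rejection always carries the specimens and positions that drove it.

* **Homozygous NUMT** — a nuclear insert on both chromosomes reaches every
  egg, so a brood of a double-peak mother in which eggs are homoplasmic at
  all her double-peak sites is a counterexample. **Clone rule**: three or
  more distinct site combinations among single-molecule clones of one
  tissue imply (if one combination is mitochondrial and the rest nuclear)
  at least two combinations in every egg; broods showing one contradict it.
* **Any NUMT** — nuclear copies are in every cell, so heteroplasmy in one
  tissue with homoplasmy in another tissue of the same individual at the
  same site rejects both NUMT forms.
* **Duplication** — a duplicated region rides on every mtDNA molecule, so
  every egg of a double-peak mother must show the peak; homoplasmic eggs
  reject it. Individuals double-peaked at one locus only are recorded in
  the verdict note (two independent duplications would otherwise be
  needed).
* **DUI** — predicts the divergent genome in males; heteroplasmic somatic
  calls in both sexes reject it. A two-sided Fisher exact test of incidence
  by sex is attached as descriptive evidence only (the qualitative rule
  decides; the test is this package's addition).
* **De novo mutation** — with per-site rate \(\mu\) (default 1.63e-7 per
  site per generation, the *Daphnia pulex* estimate), the per-individual
  probability of a heteroplasmic site among \(s\) scored positions is
  \(1-(1-\mu)^s\); the observed incidence is compared with the
  Binomial(n, p) 99.9% quantile and the exact tail attached.
* **Recombination** — flagged non-primary, never the sole explanation: it
  cannot create novel site states and presupposes existing heteroplasmy.
  No recombination-detection algorithm is implemented.

**Dropout guard.** Conventional PCR can miss a variant in low proportion,
so every rule of the form "this specimen is homoplasmic, therefore ..." is
armed only when the *predicted* minor fraction exceeds
`detection_floor + dropout_margin` (defaults 0.05 + 0.02). This
operationalizes the caveat that low-proportion combinations may escape
detection, makes the rejection count monotone non-increasing in the floor,
and is why an egg heteroplasmic under an apparently homoplasmic mother is
recorded as `maternal_undetected` rather than used against any hypothesis.

The final call is `paternal_leakage` when heteroplasmy is present and every
alternative is rejected — by counterexample, as the data permit; a single
family typically leaves several hypotheses standing, which is reported as
`unresolved` with the surviving list.

## The germline bottleneck

Transmission is modelled as a single binomial draw: an egg receives
\(N\) segregating units from a maternal pool at minor fraction \(p\), so
its fraction is \(\mathrm{Bin}(N,p)/N\) with variance \(p(1-p)/N\). The
moment estimator inverts this:
\(\hat N = \bar p (1-\bar p) / (s^2 - \sigma^2_m)\), with measurement
variance subtracted and a bootstrap over offspring for the standard error.
When the corrected variance is not positive the estimate is reported
*unresolved* instead of a number. Known simplifications: one generation of
drift (no multi-round oogenesis model, no Kimura diffusion), and plain
variance subtraction for measurement noise. Published bottleneck sizes
(1–349 in humans, ~200 in mice, 370–740 in fruit fly) motivate the
simulator default `bottleneck_N = 200`; the source material applies no
estimator to its own families, so this module has no printed value to
match and is validated purely by parameter recovery.

## What the simulator emulates — and what it does not

`simulate_trace_set()` produces per-position, four-channel peak heights for
a forward and a reverse read:

\[ h = A_{\text{read}} \cdot \textstyle\sum_k f_k\,[{\rm seq}_k(i)=b]
      \cdot e^{\varepsilon},\quad \varepsilon\sim N(0,\sigma^2), \]

plus half-normal baseline noise on all channels. Parameter defaults and
their rationale (none of these is quantified in the source material; they
are conventions fixed once):

| parameter | default | why |
|---|---|---|
| `amplitude_f`, `amplitude_r` | 1000, 700 | unequal PCR yield between reads, qualitatively reported |
| `noise_sd` | 0.15 | multiplicative lognormal; ~15% peak-height jitter typical of capillary traces |
| `baseline_sd` | 0.025 of amplitude | gives mean baseline ~2% of amplitude |
| `numt_signal_ratio` | 1/3 | nuclear signal half the mitochondrial one; unknowable from trace data, exposed as a free parameter |
| `leakage_rate` | 0.2 | puts brood minor fractions in the reported 6–45% range |
| `bottleneck_N` | 200 | mouse-range germline bottleneck |
| `tissue_drift_N` | 200 | same order as the germline bottleneck; somatic drift magnitude is not separately reported |
| `duplication_ratio` | 0.5 | one diverged extra copy per genome |
| `n_eggs` | 10 | within the 2–17 egg broods sampled |

Scenario semantics: `maternal_strict` transmits the maternal mixture
through the bottleneck only; `paternal_leakage` mixes a fraction
\(\lambda\) of the paternal haplotype into the zygote before the
bottleneck; NUMT scenarios overlay a constant, cell-universal nuclear
signal (all eggs if homozygous, half in expectation if heterozygous);
`mito_duplication` overlays a constant duplicated-copy signal on every
specimen; `dui` keeps the brood and the female soma homoplasmic and adds a
male whose gonad trace is dominated by the divergent genome. All
randomness descends from one integer seed through a counter-based
substream map, so any specimen can be regenerated independently.

Not emulated: chromatogram waveforms (Gaussian peak shapes, mobility
shifts), basecalling from AB1/SCF files, PCR-cycle stochasticity beyond
the lognormal jitter, contamination, and alignment errors (inputs are
pre-aligned, coordinates as printed). A green simulation test therefore
establishes the *logic* of the pipeline under the stated generative model,
not robustness to raw-trace pathologies.

## Numerical and edge-case choices

* Proportions must sum to 1 within 1e-9; the percent reader renormalizes.
* All-zero heights raise a no-signal error rather than returning NaN.
* `estimate_bottleneck_N()` needs ≥3 offspring and a mean fraction strictly
  inside (0,1); degenerate inputs error, zero excess variance returns
  `unresolved` with `N_hat = Inf`.
* Reading-frame ties break toward frame 0; if every frame has stops a
  warning is raised and the minimizing frame still returned.
* Seeds are kept below 2^31 − 1 throughout.

## Known limitations

* The elimination argument is by counterexample: it can reject
  alternatives, not positively prove paternal leakage; the final call
  should be read accordingly.
* Quantities that depend on the deposited GenBank accessions (25 COI
  variable sites, 26 haplotypes, syn/non-syn maxima 5/4) can be recomputed
  with `run_cli(c("haplotypes", "--fasta", ...))` on a user-supplied FASTA
  but are not reproducible offline; the packaged synthetic 16S-like
  alignment (`synthetic_16s_alignment()`) reproduces only the *structure*
  of the 16S variation (site classes and haplotype counts) and is labelled
  synthetic.
* The published tissue table for one female prints 11 tissue rows while
  the text says ten tissues; the package reports counts from the rows as
  printed.
* No likelihood or Bayesian treatment anywhere: rules are deterministic
  predicates with a dropout guard, and the bottleneck estimator is a
  moment estimator by design.
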