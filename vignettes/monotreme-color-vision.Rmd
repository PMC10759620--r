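---
title: "Methods: pigment spectra, tuning sites, branch selection tests and activity budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pigment spectra, tuning sites, branch selection tests and activity budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monovis)
```

This vignette is the package's own account of its science: the models and
procedures, the tunable parameters that matter, what the synthetic-data
generators emulate (and do not), numerical choices, and known
limitations. No empirical claim is made here that the test suite or the
acceptance script does not itself compute.

## 1. The problem

Monotremes are dichromats with an unusual cone-opsin pair: LWS
(long-wavelength sensitive, λmax ≈ 510–560 nm) and SWS2
(short-wavelength sensitive, λmax ≈ 440–460 nm), instead of the LWS/SWS1
pair of marsupials and placentals. Characterizing their color vision
involves four desk-side analyses, each implemented as a module here:
estimating λmax of reconstructed pigments from spectrophotometer scans;
predicting λmax from the opsin sequence via known spectral-tuning sites;
testing each branch of the opsin gene tree for purifying selection
(dN/dS, ω < 1); and quantifying whether the animal's 24-h activity is
cathemeral (active in both light and dark).

## 2. Pigment spectra and λmax

### Generative model (synthetic data)

`simulate_measurement()` draws replicated dark and post-bleach ("light")
scans:

* dark scan = baseline + protein peak + α·T(λ; λmax) + ε
* light scan = baseline + protein peak +
  α·[(1−f)·T(λ; λmax) + f·T(λ; 380)] + ε

where T is the standard A1 visual-pigment absorbance template
(`govardovskii_template()`): the α band as a function of x = λmax/λ, plus
a Gaussian β band (position and width linear in λmax) that is included by
default below 500 nm, where it is spectrally distinct. The template is
normalized to peak at exactly 1 within one grid step of λmax; it is both
the simulation truth and the independent oracle for the spline estimator,
which never sees the closed form.

Defaults (all overridable in `pigment_template_params()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha_amplitude` | 0.015 | AU | low-expression cone pigment |
| `protein_peak_amplitude` | 10 × α | AU | the 10:1 protein:pigment ratio of poorly expressing cone pigments (Gaussian at 280 nm, sd 20 nm) |
| `baseline_offset` / `baseline_slope` | 0.02 / 0 | AU, AU/nm | flat baseline; a nonzero drift displaces the spline peak by ≈ slope/curvature and is deliberately *not* part of the default world |
| `bleach_product_lambda_max` | 380 | nm | free-retinal-like photoproduct |
| `bleach_fraction` | 1 | – | full bleach |
| `noise_sd` | 0.0015 | AU | calibrated once so that 8-replicate λmax SDs land in the 1–15 nm range reported for real cone-pigment measurements (measured ≈ 3–6 nm at 443 nm, ≈ 2–9 nm at 560 nm) |
| `n_replicates` | 8 | – | eight dark then eight light scans |
| `wavelength_grid` | 250–700 / 250–750 by 1 | nm | SWS2-like vs LWS-like scan ranges |

Noise is independent per wavelength point per scan — the simplest model
that exercises replicate averaging. Real spectrometer noise is
autocorrelated and heteroscedastic; a green recovery test therefore
establishes estimator correctness under idealized noise, not instrument
realism.

### Estimator

`estimate_lambda_max()` fits, per replicate, a cubic smoothing spline
with a knot at every observation (`stats::smooth.spline`,
`all.knots = TRUE`) to the replicate's dark spectrum or to the
positionally paired difference spectrum dark[i] − light[i], evaluates the
fit on a fixed 0.1-nm grid restricted to the search window, and takes the
argmax (ties to the lowest wavelength). Positional pairing was chosen
because the measurement protocol produces eight dark scans then eight
light scans and reports an 8-fold SD for the difference method; whether
the original pairing was positional is unverifiable from the published
record. Reported λmax is the mean of per-replicate peaks with sample
(n−1) SD — the dispersion of an estimate across replicates.

The `smoothness` control in [0, 1] maps monotonically to the roughness
penalty through an equivalent-degrees-of-freedom target
df = max(4, (1−s)·n). The default s = 0.9 (df = 10 % of the point count)
reproduces *heavy* smoothing comparable to the reference
implementation's `spar = 1`; that parameterization's internal scaling is
implementation-specific, so equivalence is claimed at the level of λmax
recovery, not coefficients. Default search windows exclude the 280-nm
protein peak: LWS 450–650, SWS2 380–520, RH1 420–570 nm. A fitted curve
that is monotone on the window (no interior peak — the situation real
low-amplitude LWS dark spectra are in) is flagged `boundary_peak` with a
warning rather than silently reported.

One numerical subtlety is worth recording: a cubic smoothing spline's
roughness penalty ∫f″² has a *linear* null space. Linear data are
reproduced at every smoothness; a cubic polynomial is reproduced only at
light smoothing and is shrunk toward linearity as the penalty grows. The
test suite asserts the correct version of this property.

### Why difference spectra overshoot for short-wave pigments

With a 380-nm photoproduct and full bleach, the difference spectrum of a
443-nm pigment is T(λ; 443) − T(λ; 380): the subtraction removes more
absorbance from the short-wave flank than the long-wave flank, pushing
the difference peak a few nm *above* the dark peak. The suite asserts
this direction (≥ 2 nm noise-free at defaults). This reproduces the known
method discrepancy for SWS-class pigments — a difference-spectrum λmax is
not directly comparable to a dark-spectrum λmax.

### Species comparison

`welch_t_test()` implements the two-sided Welch unequal-variance test
with Welch–Satterthwaite df, accepting raw per-replicate peaks, summary
triples (mean, sd, n), or `lambda_max_estimate` objects; the raw and
summary routes agree to machine precision, and the raw route is checked
against `stats::t.test` in the tests. Note that p-values recomputed from
1-decimal published summaries differ in the third significant digit from
those computed on raw data; the tests assert band agreement, not digit
agreement.

## 3. Tuning sites and the five-site rule

`extract_tuning_sites()` aligns the query protein globally to a
numbering reference (BLOSUM62, affine gaps, gap open 10 / extend 0.5 via
Biostrings) and reads residues at reference-numbered positions, so
insertions and deletions in the query do not shift site numbers. Sites
falling in gaps are reported `NA` with a warning; sequences under 25 %
identity to the reference are rejected. Alignment ties are resolved by
the dynamic-programming implementation's deterministic tie-break (a
stated deviation from the "gaps later" preference, accepted as part of
the build-vs-buy decision).

The packaged references are **synthetic stand-ins**: deterministic
pseudo-random proteins of realistic length (LWS 364 aa, SWS2 350 aa)
carrying the canonical residues at the tuning sites. They define the
numbering operationally for the synthetic pipeline; to number real
sequences, pass a real community reference FASTA via the `reference`
argument. This also resolves, operationally, the question of whether LWS
numbering counts from the initiation codon: numbering is whatever the
supplied reference makes it.

`predict_lws_lambda_max()` applies the additive five-site rule: base
genotype S180/H197/Y277/T285/A308 at 560 nm, plus one additive shift per
deviating site. Only the base value (560 nm) and the S180A shift (−5 nm)
are anchored by measurements this package models; the remaining
magnitudes (H197Y −28, Y277F −8, T285A −15, A308S −27 nm) are transcribed
from the five-site-rule literature and ship as a validated data file
(`inst/extdata/lws_five_site_shifts.csv`) — they are data, not code, and
a genotype whose deviation has no table entry is an error naming the
site, never an extrapolation. SWS2 gets key-site *comparison* only
(`compare_key_sites()`); no additive rule is applied to SWS2 because none
is established. The additive model itself is known to be incomplete —
measured λmax can sit ~10 nm from the five-site prediction, implying
further tuning residues; this package deliberately does not infer them.

Heterozygous sequences carry IUPAC ambiguity codes;
`enumerate_haplotype_genotypes()` expands up to 8 ambiguous positions
(2⁸ = 256 sequences), drops expansions that gain internal stop codons,
and deduplicates the resulting genotypes — synonymous ambiguities
collapse to a single genotype.

## 4. Branch dN/dS test

`pipeline_branch_test()` composes three stages over a fixed rooted
topology (tree inference is out of scope; the topology is user input):

1. **Ancestral reconstruction** (`infer_ancestral_codons()`): Fitch
   parsimony per nucleotide column, a deliberate simplification of
   likelihood methods — with one closely related ingroup pair plus an
   outgroup and strongly conserved genes, parsimony and ML ancestors
   coincide except at saturated sites (the suite checks ≥ 99 % codon
   recovery against simulation truth at short branches). Ambiguities are
   resolved deterministically: prefer the parent's state, then the
   outgroup's, then alphabetical. Reconstructed internal stop codons are
   replaced by the nearest non-stop combination from the columns' Fitch
   sets.
2. **Counting** (`count_branch_substitutions()`): classic unweighted
   Nei–Gojobori (1986). Site counts are fractional per codon position
   (synonymous fraction of the changes that do not create a stop, so
   N + S = 3 × codons exactly) and averaged over the two sequences.
   Differences for codons differing at 2–3 positions are averaged over
   all orderings of single steps, excluding pathways through stop codons
   (if every pathway is blocked, all are used, classifying steps
   involving stops as nonsynonymous). Counting is symmetric under
   parent/child exchange. No transition/transversion weighting is
   applied, as none is specified for the modelled analysis.
3. **Test** (`branch_omega_test()`): one-sided Fisher's exact test on
   `[[round(Nd), round(N−Nd)], [round(Sd), round(S−Sd)]]` with half-up
   rounding — Fisher needs integers, while the raw fractional counts are
   preserved in the output. The orientation of this table, and the
   one-sided default, are stated interpretations: the modelled analysis
   reports ω < 1 claims, so `side = "purifying"` (pN < pS) is the
   default, with `side = "positive"` available. ω is reported as the
   proportion ratio pN/pS without multiple-hit correction: at the tiny
   divergences this test targets, a Jukes–Cantor-style correction changes
   ω in the third decimal while complicating the identical-sequence edge
   cases. ω is `NA` (flagged) when a branch has no substitutions
   (`identical`, p = 1 — e.g. a taxon whose sequence equals the inferred
   ancestor) or when pS = 0.

### Simulator and its calibration

`simulate_codon_evolution()` runs an accept/reject scheme: Poisson
(branch length × sites) attempted point mutations, transitions proposed
κ times as often as each transversion, stop-creating changes rejected,
nonsynonymous changes accepted with probability min(1, ω) and synonymous
with min(1, 1/ω). The default κ = 1 matches the unweighted NG86 counting
downstream: with κ > 1 transitions are enriched, and since transitions
are disproportionately synonymous the unweighted estimator's pN/pS is
biased downward — the recovery properties (mean ω̂ within 10 % of 1 at
ω = 1; ≤ ~10 % false rejections) are statements about the matched κ = 1
world. κ is exposed for users who want to study exactly that bias.

One counting subtlety: under ω → 0 every *accepted event* is synonymous
and the protein never changes, but NG pathway averaging between endpoint
codons hit at two or more positions can still register fractional Nd
(the enumerated pathway need not be the temporal path). The invariant
that is actually true — and tested — is protein identity plus Nd = 0 for
every single-position codon difference.

## 5. Behavior

`annotate_activity()` assigns each per-minute record a light condition
(closed-open [on, off) interval, wrapping midnight; the default 22:47 →
09:47 schedule gives exactly 660 light and 780 dark minutes per day) and
a day type from a weekday calendar (default: Monday closed, Tue–Fri
weekday, Sat–Sun weekend). The minute grid is closed-open [00:00, 24:00);
a schedule boundary belongs to the interval it opens.

`activity_budget()` counts active minutes per category with multi-label
scoring: a minute carrying k categories increments all k counts, so
category totals can exceed active-minute totals — by design, matching
ethogram scoring where several behaviors occur within one minute.

`lightdark_test()` compares per-day activity *frequencies* (active
minutes ÷ observed minutes in that condition-day, so the 660/780
asymmetry cancels), paired by calendar day, with the Wilcoxon signed-rank
test (zero-difference exclusion; exact null for small n without ties,
normal approximation with continuity correction otherwise — the
`stats::wilcox.test` conventions) and Bonferroni correction over all
individuals tested in the run. Days with fewer than 6 pairs are flagged
underpowered but computed. The "frequency" reading of the per-day unit
(proportion rather than raw minutes) is a documented interpretation.

`daytype_chisq()` cross-tabulates active minutes by day type × time-of-day
bin and applies Pearson's χ² (checked against direct Σ(O−E)²/E in the
tests). The default 3-h bin is an *inference*: it is the unique uniform
binning for which three day types give (3−1)(8−1) = 14 df, the value
reported for this style of analysis; the row/column construction behind
that df is not otherwise stated, so the binning is flagged as an
interpretation. Note the χ² independence assumption is violated by persistent
activity bouts (adjacent minutes are correlated), so on bout-structured
data — including the package's own simulations with persistence > 0 —
the statistic is inflated; it is reported as the modelled analysis
reports it, not as a calibrated test.

The activity simulator is a persistent two-state chain (retain the
previous state with probability `persistence`, else redraw from the
condition's activity probability; defaults: 27 days, p ≈ 0.13 in both
conditions, persistence 0.8, halting over-weighted in the dark). It
emulates post-annotation tables, not video; scoring from imagery is
upstream of this package.

## 6. What a green suite does and does not establish

The generators' defaults are the stated world of the modelled study
(8 replicates, 27 days, 660/780 minutes, ~1,095-codon opsins), with free
parameters chosen once at field-realistic values and documented above.
Green recovery tests establish that the estimators recover the truth of
*that* world at the stated tolerances (λmax bias < 1 nm; ω type-I ≤
~10 %; Wilcoxon familywise type-I ≤ 5 % after Bonferroni). They do not
establish instrument-level realism (noise autocorrelation, baseline
drift, phase-known haplotypes, ML-vs-parsimony differences at saturated
sites), and the measured λmax values of real monotreme pigments are not
reproducible without the undeposited raw scans — the suite covers them by
recovery properties instead.
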