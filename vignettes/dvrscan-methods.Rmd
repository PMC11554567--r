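---
title: "Methods: models, parameters and design choices in dvrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dvrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical models, numerical
choices and their rationale. The companion README shows a worked example;
the test suite and `scripts/acceptance.R` compute every empirical claim made
here.

## The problem

Inducing an RNA editing enzyme and sequencing replicated RNA before and
after induction yields, per candidate site, replicate-level counts of the
alternative allele. Two distinct failure modes must be handled before a
site can be called a differential variant in RNA (DVR): transcribed genomic
SNVs masquerading as editing (removed by exact subtraction against WGS
calls), and between-replicate variability larger than binomial sampling
(absorbed by an overdispersed count model). The downstream biology —
sequence motifs, RNA secondary structure, activity concentration,
protein-binding profiles — is characterised from the called sites.

## The site model and test

For replicate $r$ of group $g$ the alternative count is
$k_{gr} \sim \mathrm{BetaBin}(n_{gr}, \pi_g, \rho)$ parameterised by mean
allele fraction $\pi_g$ and intra-site correlation $\rho$, with
$\alpha = \pi(1-\rho)/\rho$, $\beta = (1-\pi)(1-\rho)/\rho$; $\rho \to 0$
recovers the binomial, and the implementation switches to the exact
binomial likelihood below $\rho = 10^{-9}$. Assumptions: replicates are
exchangeable within a group, sites are independent (FDR is controlled
jointly across sites, not within classes), and a single $\rho$ is shared by
both groups at a site.

The null model fits one common $\pi$; the alternative one $\pi$ per group.
$\rho$ is re-estimated under each hypothesis, making the statistic a
profile LRT; `lrt_stat = max(0, 2(\ell_1 - \ell_0))` (clipping absorbs
optimiser noise in the nested comparison) is referred to $\chi^2_1$.
A beta-binomial with moderate $\rho$ is deliberately close in spirit to the
replicate-aware hierarchical tests used for differential splicing/variants,
while keeping the likelihood closed-form and the MLE checkable by grid
search — the test suite verifies the optimiser against a dense
$200\times200\times50$ grid with local refinement.

Numerical choices:

* $\pi$ is estimated on $[10^{-6}, 1-10^{-6}]$, $\rho$ on
  $[10^{-9}, 0.5]$ (L-BFGS-B box bounds). The $\rho$ ceiling keeps the
  null model from fitting arbitrarily bimodal data; it also bounds how much
  of a clean group separation the profile null can absorb, which is why a
  maximally separated toy site (4×0/100 vs 4×50/100) yields an LRT around
  33 rather than the larger value a fixed-$\rho$ test would give.
* Deterministic multi-start from three fixed initial means (pooled AF, 0.1,
  0.9); no randomness anywhere in fitting.
* Sites where every replicate is all-reference (or all-alternative) are
  resolved analytically: both hypotheses coincide, the statistic is 0.
* Non-convergence (never observed in the suite) flags the site and reports
  the conservative $p = 1$.

AF is pooled over replicates — `sum(alt)/sum(total)` — and
$\Delta AF = AF_{induced} - AF_{control}$; pooling follows the definition
of AF as a ratio of read depths. Averaging per-replicate AFs instead would
weight shallow replicates up; the pooled form is the one the package
reports. DVRs are sites with Benjamini–Hochberg $q \le 0.05$; no $|\Delta
AF|$ floor is applied by default (a `min_delta_af` argument exists).

**Calibration regime.** The type-I error study in the acceptance suite
simulates nulls at $\pi = 0.5$ (a heterozygous-SNV-like fraction), depth
$\sim$ Poisson(50), $\rho = 0.01$, 4+4 replicates, where the $\chi^2_1$
approximation is appropriate; measured rejection at $p \le 0.05$ falls
within [0.03, 0.07]. At very low $\pi$ (the background error rate of
0.005) with depth 50, most replicates carry zero alternative reads and the
LRT is strongly conservative — a boundary effect of discrete likelihoods,
not a defect; power against planted edits at such backgrounds remains high
because the induced group leaves the boundary.

## Genomic subtraction and filters

Subtraction is exact on `(contig, position, alternative allele)`: a genomic
C>G SNV does not veto an RNA C>U call at the same base. This is
deliberately conservative for sensitivity and is what makes the synthetic
truth property exact (100% of planted SNVs removed, 0% of planted edits).
Depth filtering retains sites where every replicate in both groups has
total depth ≥ 10 (borrowed from the control-site depth convention) and the
higher-AF group pools ≥ 2 alternative reads. Sites outside any annotated
gene, or inside overlapping genes of conflicting strand, keep strand `NA`
and are reported as `unstranded` rather than guessed.

## The folding engine

Structure context uses 100-nt windows centred on the site (50 up / 49 down
on the transcript strand, edited base at offset 51; windows truncated at
contig edges are kept but flagged and excluded from MFE distribution
comparisons, since loop penalties scale with length). The built-in engine
is a Zuker-style dynamic program over non-crossing structures with
canonical pairs (AU, GC, GU), minimum hairpin loop 3, and a simplified,
fully documented energy table (`fold_energy_params()`): per-pair strengths
GC/CG −3.3, AU/UA −2.1, GU/UG −1.4 kcal/mol with a stack scoring the mean
of its two pairs; linear hairpin/bulge/internal penalties; affine multiloop
cost; free exterior bases; internal loops capped at 30 nt. The mean-of-two
stack rule makes the table symmetric under reverse complementation of
Watson–Crick helices, giving the mirrored-structure property the tests
exercise. Ties are broken deterministically toward unpaired bases (hence
fewer pairs and lexicographically smaller dot-brackets).

These constants are not Turner parameters; MFE values are model-relative
and only comparisons within one backend are meaningful. Users wanting
RNAfold parity can pass `fold_backend_rnafold()` or any function returning
`(dotbracket, mfe)`. The DP is validated against exhaustive enumeration of
all non-crossing structures (every length-6 sequence and random sequences
up to 16 nt) with an independent energy evaluator in the test helpers.

"Within a loop" means unpaired at the edited base; the loop type (hairpin,
internal/bulge, multiloop, exterior) is derived from the innermost
enclosing pair, with hairpin membership reported separately since
single-stranded hairpin loops are the context of interest. Loop enrichment
against controls uses the pooled two-proportion Z test; MFE distributions
are compared by Mann–Whitney (the distributions are displayed, no test is
canonical, and rank-sum is robust to the non-normal MFE shape). A
bootstrap over control resamples is available for error bars but not
asserted in tests.

## Motifs

IUPAC matching is exact (V = A/C/G, K = G/U, W = A/U, N = any; T ≡ U,
case-insensitive) and anchored at the edited base. Position frequency
matrices use ±5-nt flanks by default (config-exposed; the flank used for
logo displays is not standardised) with no pseudocounts and no small-sample
IC correction, so information content is exactly
$2 + \sum_b f_b \log_2 f_b$ bits and the oracle tests are exact.
Enrichment of a motif in test sites over controls uses the control match
fraction as a fixed binomial null rather than Fisher's exact test: controls
number 10,000 by default, so their sampling error is negligible relative to
the test set's. A zero control fraction is floored at $1/(n_{control}+1)$
and flagged.

## Selectivity

Activity of a DVR is its alternative-read depth per million mapped reads
(CPM), averaged across induced replicates — the per-sample `mapped_reads`
column exists exactly so this normalisation needs no BAMs. Averaging
(rather than summing) across replicates is the scale on which the printed
formula reads most naturally; both differ only by the replicate count.
Un-induced background is not subtracted by default; a
`background_subtract` flag computes induced-minus-control CPM floored at
0. The Lorenz curve ranks DVRs by activity; the Gini coefficient is
computed by the trapezoid rule and verified to equal the pairwise
mean-absolute-difference form to $10^{-9}$. Gene concentration reports the
smallest number of genes whose summed shares reach a target (0.40 by
default).

## eCLIP profiles

Per-base fold enrichment is mass-normalised,
$(ip[x]/M_{ip}) / ((input[x]+\varepsilon)/M_{input})$ with
$\varepsilon = 0.5$ guarding empty input bases, so scaling either library
cancels. Profiles are taken at offsets −100..+100 in transcript
orientation (+1 = immediately 3′ of the edited base; minus-strand sites
read the genome right-to-left), matching the generator's convention, so
"signal immediately after the edited base" means the same thing in
simulation and analysis. Peak calling on the metaprofile is a simple
argmax of per-offset means with a site-level bootstrap CI; a profile whose
maximum mean is below 1.2× the median mean is flagged as having no peak.
Note that $E[X/(Y+\varepsilon)]$ exceeds $E[X]/E[Y+\varepsilon]$ for noisy
$Y$ (Jensen), so per-base ratios at low input coverage are inflated and
noisy — the generator's default input depth (below) is chosen deep enough
that this is immaterial.

## What the generator emulates — and what it does not

`simulate_study()` produces a complete miniature study: one gene per contig
(sidestepping overlapping-annotation ambiguity in the truth), random
strand, 60 genes of 3–5 kb by default; 100 C>U edits placed with Zipf
gene weights (exponent 1.0 — moderate concentration; 0 gives uniform
targeting), 90% in a UUCV context and 90% inside a constructive hairpin
cassette (8-bp GC-rich stem, 6-nt loop holding the edited C) written in
place so coordinates are stable and `in_loop` truth is constructive rather
than searched for; 60 A>G(I) edits; 50 genomic SNVs at allele fraction 0.5
or 1.0 in *both* groups; 300 null background sites at the base error
fraction 0.005. Counts are Poisson(50)-depth beta-binomial draws with
$\rho = 0.01$; planted edit effects are uniform on ΔAF ∈ [0.05, 0.4]
(spanning small to large visible effects; no quantitative editing-level
distribution is available to copy, so the range is config-exposed).
Library sizes span 10–20 million reads so per-million normalisation is
actually exercised. eCLIP input tracks are Poisson noise around 40
reads/base; IP tracks carry 5× that inside offsets +1..+10 downstream of
each C>U edit and baseline elsewhere, so IP and input have equal expected
mass when the fold is 1.

Two geometry choices matter for the negative controls. Planted sites are
separated by ≥ 250 bp by default — more than twice the profile half-width —
emulating the genome-scale sparsity of real variant sites; without it, hot
windows of nearby C>U edits leak into the ±100-nt profiles of A>G and SNV
sites and the "no enrichment at control classes" property fails for purely
geometric reasons. (Dense designs, e.g. 2000 sites for the power study,
override `min_site_separation` explicitly.) And the 40 reads/base input
depth keeps the per-offset mean fold enrichment over ~50 control sites
within ±0.1 of 1: at 10 reads/base the ratio's coefficient of variation
(~0.45) plus Jensen inflation makes a [0.8, 1.2] band unattainable at this
number of sites regardless of implementation.

Everything is deterministic under the master seed, which fans out to fixed
per-stage child seeds so reference, planting, counts and tracks are
independently reproducible.

What it does **not** emulate: read-level artefacts (alignment error,
strand bias, PCR duplicates), sequencing error spectra beyond a flat base
error fraction, splicing and isoform structure, overlapping genes,
expression-dependent coverage, or crosslink-specific eCLIP read geometry
(the IP signal is a coverage plateau, not a truncation pileup). Passing
tests therefore demonstrate the statistics and bookkeeping are right under
the declared generative model, not that upstream read processing is solved.

## Problem sizes

The shipped tests and the acceptance script use: 2000 null sites for
type-I calibration; 100 planted edits among 1900 nulls (depth 100) for
sensitivity/FDR; 10,000 sampled control sites for structure and motif
enrichment; all 4096 length-6 sequences plus 200 random ≤10-nt sequences
for the folding oracle; 20 random sites for the grid-search MLE check; and
a 10-gene study for end-to-end byte-identity. These sizes give stable
Monte-Carlo margins for every asserted band while keeping a full run in a
few minutes on one CPU.

## Known limitations

* The beta-binomial with shared $\rho$ is a modelling substitution for
  logit-normal random-effect tests; with 4+4 replicates the profile LRT is
  mildly anticonservative (measured ~0.06 at nominal 0.05), and $q$-values
  near the threshold should be read accordingly.
* The built-in energy model ranks structures sensibly but its MFEs are not
  comparable to Turner-parameter folders; only within-backend contrasts
  (DVRs vs controls) are meaningful.
* Multi-condition (>2) designs, paired samples, and peak-called eCLIP
  (rather than profiled coverage) are out of scope.
* `unstranded` sites are excluded from class-specific statistics rather
  than rescued by expression-based strand inference.
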