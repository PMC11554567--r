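# dvrscan

Detection and characterisation of **differential variants in RNA (DVRs)** —
RNA positions whose alternative-allele fraction changes between two
conditions — from replicated per-site allele counts, as arise when an RNA
editing enzyme (e.g. an APOBEC3 cytidine deaminase creating C>U edits, or
ADAR creating A>G(I) edits) is induced in one of the two conditions.

The package is aimed at transcriptomics analysts who already have per-site
allele counts from RNA-seq (two conditions, replicated), matched
whole-genome SNV calls, and optionally strand-specific eCLIP coverage, and
who want a tested, deterministic pipeline from counts to biology:
which sites are condition-dependent edits, what sequence and RNA-structure
context they sit in, how unevenly the editing activity is distributed, and
whether protein binding (eCLIP) coincides with the edited positions.

## The statistical core

For one site with replicate counts, the alternative-allele count of
replicate *r* in group *g* is modelled as beta-binomial,

k_gr ~ BetaBin(n_gr, pi_g, rho),  with  alpha = pi (1 − rho) / rho,
beta = (1 − pi)(1 − rho) / rho,

where pi_g is the group's mean allele fraction (AF) and rho the
between-replicate overdispersion. The null model constrains
pi_control = pi_induced; rho is re-estimated under each hypothesis (profile
likelihood). The test statistic

LRT = 2 (log L_alt − log L_null)  ~  chi-square(1)

is converted to p-values, and Benjamini–Hochberg FDR control across all
tested sites defines DVRs at q ≤ 0.05. Effect sizes are reported as
ΔAF = AF_induced − AF_control with AF = (alt read depth)/(total read depth),
pooled over replicates. Upstream, candidate sites matching a genomic SNV
(same position *and* same alternative allele) in the WGS call set or a
population-SNP blacklist are subtracted, so transcribed DNA variants are not
mistaken for editing.

Downstream characterisation:

* **structure** — 100-nt windows around each site are folded by a built-in
  Zuker-style minimum-free-energy dynamic program (simplified,
  documented nearest-neighbour energies; pluggable external backend), loop
  membership of the edited base is tested against 10,000 random control
  sites with a two-proportion Z test, and MFE distributions are compared by
  Mann–Whitney;
* **motifs** — position frequency matrices / information content around the
  edited base and exact-binomial enrichment of IUPAC motifs such as UUCV
  (V = A/C/G);
* **selectivity** — per-DVR editing activity (alt reads per million mapped,
  averaged over induced replicates), Lorenz curves and the Gini coefficient
  of activity concentration, and the smallest set of genes holding a target
  share of total activity;
* **eCLIP** — strand-aware per-site fold enrichment of IP over size-matched
  input at offsets −W..+W in transcript orientation, metaprofile peak
  location with a bootstrap CI.

A fully deterministic synthetic-study generator (`sim_config()`,
`simulate_study()`) plants C>U edits (with controllable UUCV-motif and
hairpin-loop placement), A>G(I) edits, genomic SNVs and null sites, then
simulates replicated beta-binomial counts and eCLIP tracks with truth
tables, which is how the whole pipeline is validated.

## Worked example

```r
library(dvrscan)
library(dplyr)

cfg <- sim_config(seed = 7, n_genes = 12, n_cu_edits = 20, n_ag_edits = 8,
                  n_dna_snvs = 10, n_null_sites = 40, depth_mean = 80)
sim <- simulate_study(cfg, tempdir())

counts <- apply_depth_filters(read_counts_table(sim$paths$counts))
wgs    <- read_vcf_sites(sim$paths$vcf)
keep   <- subtract_genomic_variants(distinct(counts, contig, pos, ref, alt), wgs)
filter_report(keep)
#>   n_input n_removed_genomic n_removed_blacklist n_removed_depth n_retained
#> 1      64                10                   0               0         54

res <- call_dvrs(semi_join(counts, keep, by = c("contig","pos","ref","alt")),
                 genes = sim$genes)
dvr_breakdown(res)
#>   class      direction     n
#> 1 C>U        up           18
#> 2 C>U        down          0
#> 3 A>G(I)     up            8
#> ...
```

All 10 planted genomic SNVs are removed by the subtraction step; 18 of the
20 planted C>U edits and all 8 A>G(I) edits reach q ≤ 0.05 (the two misses
were planted at ΔAF ≈ 0.05, the bottom of the configured range, and one
null site is falsely called — the `other up 1` row). Each call carries its
fitted AFs and FDR:

```r
filter(res, is_dvr, class == "C>U") |> head(3)
#>   contig     pos ref   alt   af_ctrl af_induced delta_af       fdr
#> 1 gene_001  1383 C     T     0.00318     0.218    0.215  0.0000130
#> 2 gene_001  1989 C     T     0.00623     0.0581   0.0518 0.00512
#> 3 gene_001  3326 C     T     0.00322     0.104    0.101  0.0000602
```

Characterisation recovers the planted biology — 94% of called C>U DVRs sit
in a predicted loop, and editing activity is unevenly spread (Gini 0.29
under near-uniform gene targeting):

```r
dvrs <- filter(res, is_dvr, class == "C>U")
mean(fold_sites(dvrs, sim$reference)$in_loop)
#> [1] 0.9444444
act <- activity_per_dvr(counts, induced = "induced", sites = dvrs)
lorenz_gini(act$activity)
#> <lorenz_result> n = 18 | Gini = 0.2884
```

`autoplot()` methods exist for DVR results (volcano), Lorenz curves, eCLIP
metaprofiles and PFMs; `tidy()`/`glance()` methods for fitted site models
and result objects. `run_dvr_pipeline(dvr_config(...))` chains every stage
and writes tables plus a JSON report.

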