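---
title: "Modelling dominant maternal effects in homing gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dominant maternal effects in homing gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matdrive)
```

## The problem

A CRISPR/Cas9 homing drive copies itself into the wild-type homolog in
the germline, biasing inheritance above the Mendelian 50%. Homing is
imperfect: when homology-directed repair (HDR) fails, non-homologous
end joining (NHEJ) destroys the gRNA target site and leaves a
drive-resistant allele. A second, less obvious resistance channel runs
through the egg: a drive-carrying mother deposits Cas9 protein and
gRNAs into her oocytes, and this maternal load mutates wild-type
alleles in the zygote — including zygotes whose own genome carries no
editing components. Because the mutation is caused by *gained* maternal
product rather than a missing one, this is a *dominant* maternal
effect. It matters for drive forecasting because it can mint
homozygous-resistant individuals in a single generation, a class that
otherwise requires two resistant parents to meet.

`matdrive` implements this two-channel model as an exact enumeration
engine plus the simulation and estimation machinery needed to study it.

## The model

One autosomal locus, four allele states: `WT`, `GD` (the drive), `R`
(NHEJ resistance) and `RSTAR` (maternally induced resistance, displayed
`R*`). `R` and `R*` behave identically in every genetic operation —
both are cut-proof, cargo-free target sites — and the star is a
provenance label only, reset to `R` at meiosis. Three operators
compose, in order, into `crossGenotypes()`:

1. **Germline homing** (`germlineConvert`): in a parent carrying at
   least one `GD`, each germline `WT` allele becomes `GD` with
   probability $x$ and `R` with probability $1-x$. Alleles without a
   target site are immune.
2. **Mendelian segregation** (`gameteDistribution`): each allele
   transmitted with probability 1/2; `R*` transmits as `R`.
3. **Zygotic maternal effect** (`maternalZygoticEffect`): iff the
   mother's own genome carries `GD`, each `WT` allele of the zygote
   independently becomes `R*` with probability $y$.

### Parameters

| parameter | meaning | default in examples | units |
|---|---|---|---|
| $x$ | germline HDR homing success per heterozygous germline | 0.95 | probability |
| $y$ | zygotic maternal-effect mutation per WT allele | 0.87 | probability |

Both defaults are the worked-example values: reported homing
efficiencies for comparable drives span roughly 0.91–0.99, and 0.87 is
the empirical disruption frequency measured in progeny of mothers
carrying both components when the progeny themselves carried neither.

### Modelling choices at points the experiments do not constrain

- **Conversion timing.** Homing is resolved per individual germline
  (GD/WT → GD/GD w.p. $x$, else GD/R) before Mendelian segregation. A
  per-gamete formulation yields the identical gamete marginal
  ($\tfrac{1+x}{2}$ drive, $\tfrac{1-x}{2}$ resistant) for
  heterozygotes; the per-individual form matches the "successful drive
  conversion" framing and keeps enumeration simple.
- **Maternal deposition condition.** A mother deposits editing activity
  iff her own genome carries `GD`. Grand-maternal carry-over (a
  drive-free mother who was herself maternally loaded) is real but
  unquantified, and is not modelled.
- **Per-allele independence.** The zygotic operator acts independently
  on every `WT` allele, including a maternally inherited one and both
  alleles of a WT/WT zygote ($(1-y)^2$, $2y(1-y)$, $y^2$). The
  two-allele case never arises in the canonical pedigree; this is a
  closure choice.
- **Strict repair dichotomy.** Failed HDR always yields a resistant
  allele, never a still-cleavable one. If some NHEJ repairs restored
  the target site, $1-x$ would overstate resistance creation.
- **No fitness costs, 1:1 sex ratio.** All genotypes are equally viable
  and fertile and sex is independent of genotype. A fitness hook is
  deliberately absent rather than defaulted, to keep the parameter
  surface honest.

## The two-generation pedigree

`pedigreeG2()` enumerates: G0 drive-heterozygous male × wild-type
female; G1 pooled at a 1:1 sex ratio, each G1 individual backcrossed to
wild type with equal brood sizes; the maternal effect acts only in
broods of G1 female drive carriers.

```{r pedigree}
params <- DriveParams(x = 0.95, y = 0.87)
on  <- pedigreeG2(params, maternalEffect = TRUE)
off <- pedigreeG2(params, maternalEffect = FALSE)
rbind(on  = genotypeProbs(on)[c("R/WT", "R/RSTAR")],
      off = c(genotypeProbs(off)["R/WT"], 0))
```

The factor structure is transparent: the G1 gamete pool of a converted
GD/WT father is $\{GD: 0.975,\; R: 0.025\}$; homozygous resistants
arise only when a G1 GD/WT *female* transmits `R` (probability
$0.025$) and her maternal load converts the paternal `WT`
(probability $0.87$), weighted by her pedigree share
$\tfrac{1}{2}\times 0.975$:
$\tfrac{1}{2}\cdot 0.975\cdot 0.025\cdot 0.87 = 0.0106$.

Two readings of the published heterozygote pair "2.6 or 3.7%
excluding/including" exist, because exact enumeration gives **2.6% for
the maternal-effect-on case** and 3.7% for off — and the off value also
equals the on-case sum R/+ + R/R\* (3.69%). The numbers themselves are
unambiguous; only the excluding/including labels attached to them are
swapped relative to the enumeration. The package exposes the toggle and
reports both; `reproduceSummary()` matches each printed number at its
printed precision.

### Arithmetic

Enumeration uses double precision rather than rational arithmetic: every
probability in a two-generation pedigree is a sum of products of at most
eight decimal factors, exact to ~1e-15, while all comparisons happen at
one or two printed decimals. The worked-example values above are exact
to the last printed digit (0.026271875, 0.010603125, 0.036875).

## Dynamics

`propagateDrive()` iterates the deterministic recursion under either
panmixia (`random_mating`) or serial outcrossing
(`backcross_to_wildtype`); `wrightFisherDrive()` is its
finite-population counterpart — one multinomial resampling of
`popSize` offspring genotypes per generation, non-overlapping
generations, a private seeded RNG stream. The backcross recursion from
`founderCohort("GD/WT", "male")` reproduces `pedigreeG2()` exactly at
generation 2; the test suite uses this as an internal consistency
oracle, and checks the Wright–Fisher mean against the deterministic
limit (200 replicates at $N = 10^4$ over 5 generations, within three
standard errors — drift variance accumulates over generations, so
per-generation checks use a $\sqrt{t}$-scaled binomial bound).

## Estimation

Progeny class counts (GAL4+/dGAL4/QF2+, the dual-reporter readout of
the targeted locus) are trinomial with probabilities
$(1-d,\; d(1-h),\; dh)$. `fitTrinomial()` returns the MLEs
$\hat d = (n_{dGAL4}+n_{QF2+})/n$ and
$\hat h = n_{QF2+}/(n_{dGAL4}+n_{QF2+})$ with 95% Wilson score
intervals; Wald intervals degenerate at the observed operating points
($d \approx 0.98$ at $n = 164$). `compareRates()` gives a Newcombe
score-based interval for $d_A - d_B$; no p-values are reported because
the underlying experiments support interval estimates, not designed
hypothesis tests. `estimateMaternalRate()` is $\hat d$ of the cross
whose progeny carry no genomic editing components — the direct
estimator of $y$.

Two calibration facts, established by exact binomial summation rather
than simulation, bound what interval coverage can be asserted:

- at $n = 50$ the Wilson interval's exact coverage oscillates outside
  93–97% (97.03% at $p = 0.1$, 92.16% at $p = 0.98$);
- at $(p = 0.982, n = 164)$ the exact coverage is 97.02%, so empirical
  coverage in a 500-replicate experiment will exceed 97% about half the
  time — a property of the interval at that operating point, not of any
  seed.

The tests therefore compare empirical coverage against the exact
coverage of each cell and apply the nominal 93–97% band only where the
exact coverage itself lies inside it.

When $h = 0$ truly, $\hat h$'s interval is $[0, u]$ whenever no HDR
event is observed, so boundary recovery is certain by construction and
a coverage *band* is meaningless there; rows with zero disrupted
offspring are flagged `h_degenerate`.

## Synthetic data

The generators emulate the two experimental designs so everything is
testable without any external data:

- `simulateGermlineCounts()` — trinomial broods at true $(d, h)$, at
  the real sample-size scale ($n = 164$–$413$);
- `simulateBrainCounts()` — per-brain labeled-cell counts among
  $10^5$ cells. The published between-brain spreads (e.g. 800 ± 55)
  are not identified as SD or SEM, and if read as SD exceed the
  binomial SD (~28); the generator therefore has a beta-binomial
  intra-class-correlation knob `rho` but defaults to `rho = 0` —
  no calibration to an ambiguous figure is attempted.
- `simulateDriveCohort()` — finite cohorts through any pedigree/scheme,
  feeding the estimators end-to-end.

What passing tests on these data do **not** show about real data:
broods from one father are assumed binomial (germline mosaicism would
cluster them), somatic editing is per-cell independent (early embryonic
edits propagate clonally), and reporter expression equals genetic state
(perdurance ignored).

## Problem sizes

The shipped suite enumerates all $10\times10$ parental genotype pairs
over parameter grids, cross-validates enumeration against $10^6$-draw
Monte-Carlo sampling for 20 randomised crosses, runs 500-replicate
coverage experiments per $(d,h,n)$ cell and 200 Wright–Fisher
replicates at $N=10^4$ — sizes chosen so standard errors are small
relative to the assertion bounds while the whole suite stays
interactive (under a minute).

## Limitations

Single locus, single gRNA, autosomal, two sexes, no fitness costs, no
spatial structure or migration, no grand-maternal carry-over, no
evolution of cutting rates. The estimation layer deliberately excludes
hierarchical (brood-structured) models; if brood clustering matters,
the Wilson intervals here are anti-conservative.
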