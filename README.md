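# matdrive

Population-genetic modelling of a CRISPR/Cas9 homing gene drive with a
**dominant maternal effect**, for researchers studying drive efficiency
and resistance-allele dynamics, and for experimentalists estimating
germline editing rates from progeny counts.

## The model

A single autosomal locus carries one of four alleles: wild type (WT),
the drive cassette (GD, Cas9 + gRNA), an NHEJ-derived resistant allele
(R), or a maternally induced resistant allele (R\*). R and R\* are
genetically identical — a destroyed target site with no drive cargo —
and differ only in provenance; the star resets to R at meiosis. Two
parameters govern the dynamics:

- **x** — in the germline of a GD/WT heterozygote, the wild-type
  homolog is converted to GD by homology-directed repair with
  probability *x*; with probability 1 − *x* NHEJ destroys the target
  site instead, leaving R.
- **y** — a mother carrying GD deposits Cas9/gRNA into the egg; each
  wild-type allele of the zygote is mutated to R\* with probability
  *y*, independent of the zygote's own genotype (the dominant maternal
  effect).

Crosses are computed by exact enumeration of all discrete outcomes
(germline conversion → Mendelian gametes → zygotic maternal effect),
and composed into two-generation pedigrees, deterministic recursions,
and finite-population Wright–Fisher simulations. A trinomial estimator
with Wilson score intervals recovers the disruption rate
*d* = P(target allele mutated) and HDR fraction
*h* = P(knock-in | mutated) from progeny class counts
(GAL4+/dGAL4/QF2+ in the dual-reporter design the package's
phenotype module encodes).

## Worked example

The canonical pedigree: a GD/WT male is crossed to wild-type females;
all G1 offspring (sex ratio 1:1) are backcrossed to wild type. With
x = 0.95 and y = 0.87:

```r
library(matdrive)
params <- DriveParams(x = 0.95, y = 0.87)
pedigreeG2(params, maternalEffect = TRUE)
#> GenotypeDistribution over 5 genotype(s)
#>  genotype probability percentage
#>     GD/R*  0.41352187   41.3522%
#>      R/R*  0.01060313    1.0603%
#>     GD/WT  0.53710313   53.7103%
#>      R/WT  0.02627188    2.6272%
#>     WT/WT  0.01250000    1.2500%
```

With the maternal effect active, 1.06% of G2 are already homozygous
resistant (R/R\*) — a class that cannot arise at all in this pedigree
without it — and 2.6% are resistant heterozygotes (R/+). Switching the
effect off (`maternalEffect = FALSE`) gives R/+ = 3.7% and R/R\* = 0:
the zygotic effect converts part of the heterozygote flow into
homozygotes rather than creating resistance *de novo* here, so the two
heterozygote figures differ by exactly the R/R\* frequency.

Estimating the maternal-effect rate from progeny counts (87.2%
disruption among 413 offspring scored from fathers lacking any genomic
Cas9/gRNA):

```r
fitTrinomial(data.frame(GAL4plus = 53, dGAL4 = 360, QF2plus = 0))
#>   cross_id   n         d   d_lower   d_upper h h_lower    h_upper h_degenerate
#> 1   cross1 413 0.8716707 0.8359562 0.9005349 0       0 0.01055806        FALSE
```

A shell interface wraps the same functions:
`inst/scripts/matdrive {cross,g2,drive,fit,simulate,reproduce}`.

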