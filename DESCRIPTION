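Package: matdrive
Title: Dominant Maternal Effects in CRISPR Homing Gene Drive Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a CRISPR/Cas9 homing gene drive at a single autosomal
    locus with a dominant maternal effect: germline homing converts a
    wild-type allele to the drive with probability x (failure yields an
    NHEJ-resistant allele R), and maternally deposited Cas9/gRNA mutates
    wild-type alleles in the zygote with probability y (yielding the
    maternally induced resistant allele R*). Provides an exact
    cross-enumeration engine over the four-allele genotype algebra,
    deterministic and Wright-Fisher multi-generation drive dynamics, a
    dual-reporter genotype-to-phenotype map for GAL4/QF2 progeny
    classification, trinomial estimation of disruption and HDR rates with
    Wilson and Newcombe score intervals, and seeded synthetic-data
    generators for progeny class counts and per-brain labeled-cell counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alleles.R'
    'AllClasses.R'
    'phenotype.R'
    'estimation.R'
    'cross.R'
    'pedigree.R'
    'dynamics.R'
    'simulate.R'
    'io.R'
    'cli.R'
    'matdrive-package.R'
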