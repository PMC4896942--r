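---
title: "polycap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polycap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycap)
```

polycap analyses hybridization target-capture sequencing of high-ploidy
plant genomes — the setting of the *Saccharum* (sugarcane) complex, where
accessions are hexa- to dodecaploid, reads are aligned to a diploid
relative (sorghum), and every downstream question (genotype, copy number,
divergence) must be asked through the lens of ploidy. This vignette
documents the models, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
choices that a maintainer would otherwise have to reverse-engineer.

## Variant hard filtering

Multi-caller variant sets are reduced to high-confidence calls by six
conjunctive hard filters, all strict inequalities: mapping quality > 30,
base quality > 20, alternate-supporting reads per carrying accession > 2,
summed depth across accessions < 3000 and > 600, and site QUAL > 80. The
pass/fail decision is order-free; the printed order (1)–(6) is used only
to attribute each rejected record to its *first* failing rule in the
rejection tally, so the tally always sums to the rejected count.

Two wordings in the underlying protocol are ambiguous and are resolved by
configuration:

* the "minimum depth … quality > 600" rule is read as a **depth sum**
  (symmetric with the maximum-depth rule); `filter_config(rule5 =
  "qual_sum")` selects the alternative reading;
* the per-accession alternate-read rule applies, by default, only to
  accessions that actually carry the alternate allele with non-missing
  data (`alt_rule = "carriers"`).

Records lacking a required annotation (MQ, base quality, QUAL, AD) are
*retained and tagged* `unfilterable`, and routed to their own bucket —
silently dropping them would bias caller-concordance counts. Either
`BQ` or `BaseQRankSum` is accepted as the base-quality INFO key.

## Allele-dosage genotyping

At a bi-allelic site in an accession of even ploidy $m$, the dosage $d
\in \{0,\dots,m\}$ is the number of chromosome copies carrying the
alternate allele. With a symmetric per-read miscall rate $e$ the expected
alternate-read fraction is

$$ f_d = \frac{d}{m}(1 - e) + \Bigl(1 - \frac{d}{m}\Bigr)e, $$

and the call maximizes the binomial likelihood
$\mathrm{Bin}(\text{alt} \mid n, f_d)$ under a prior (uniform by
default). This replaces the unpublished model of the external genotyper
the protocol delegated to; it is standard, fully specified, and
desk-testable. Defaults: $e = 0.01$ (typical post-filter Illumina
miscall), minimum depth 5 to call. Exact likelihood ties resolve to the
*smaller* dosage — deterministic and conservative about heterozygosity.
Multi-allelic sites (up to 4 alleles, the observed maximum) maximize the
multinomial likelihood over all compositions of $m$, an exhaustive search
of at most $\binom{m+3}{3}$ candidates at $m = 12$.

A locus is a **single-dose marker** (SDM) — the marker class usable for
polyploid linkage mapping — when one allele is present in exactly one
copy. The protocol's wording does not fix which allele; polycap flags
$d \in \{1, m-1\}$ and additionally reports the strict $d = 1$ count
(`n_sdm_alt`). Heterozygosity is heterozygous sites divided by aligned
length.

Practical accuracy limit: adjacent dosage classes are separated by
$1/m$ in expected allele fraction, so discrimination at $m = 12$ needs
depth of order $m^2$; at the default simulated depth of 150 the $d = 1$
vs $d = 2$ confusion is the dominant error mode and decreases
monotonically with depth (this is asserted by a test).

## Gene CNV and PAV

Per-gene depth is normalized as

$$ \text{depth} = \frac{10^9 \times \text{reads in gene}}
   {\text{total mapped reads} \times \text{gene length}} $$

and copy-number change between a query and a subject accession is
assessed on $\log_2(\text{query}/\text{subject})$ over all genes with
positive depth on both sides. Up-CNVs lie strictly above the empirical
99th percentile of that distribution; down-CNVs strictly below the
mirrored cut-off, operationalized as the 1st percentile of the same
ratio — this makes `call_cnv` on (A, B) exactly antisymmetric to (B, A),
a property the tests assert. Percentiles use linear interpolation between
order statistics (`stats::quantile` type 7); the protocol names no
estimator, so the choice is documented and config-exposed. The threshold
is computed per accession pair, not pooled. By construction the null
call rate is ~1% per side; the percentile rule measures *outlyingness
within the pair*, not absolute copy number.

PAV (presence/absence) is deterministic given counts: a gene is absent in
the query iff the query has zero reads and the subject has ≥ 10 reads
with normalized depth ≥ 0.1. Genes with zero depth on either side are
excluded from CNV calling, so PAV and CNV call sets are disjoint.
An optional per-accession ploidy divisor before the ratio is available
(`gene_depth_pairs(..., ploidy_map=)`) but off by default, because the
normalization formula itself omits it.

## Functional annotation

Variants are classified against single-transcript gene models in
mutually exclusive priority order CDS-exon > UTR > splice site > intron >
intergenic; a variant in an exon annotated as UTR is classed UTR so that
class percentages partition. The splice-site window is the 2 intronic
bases flanking each junction — the canonical donor/acceptor dinucleotide;
the protocol names the category without defining the window. With
multiple overlapping genes the primary assignment goes to the longest
CDS. Coding effects are computed on the spliced CDS honoring strand and
phase, with `start_lost` (reference ATG disrupted) taking precedence over
`stop_gained`. A CDS whose length is not a multiple of 3 yields effect
`"unknown"` rather than a guess. InDels in CDS are `in_frame` iff their
length is a multiple of 3.

## Probe thermodynamics and capture efficiency

For each 120-mer probe: GC content; melting temperature from
nearest-neighbor RNA/DNA-hybrid enthalpy/entropy sums (Sugimoto-style
parameter table shipped as `inst/extdata/nn_rna_dna_hybrid.csv`; 1 M
Na⁺, strand concentration 10⁻⁴ M); PHFE, the hybrid free energy at 65 °C;
PMFE from a weighted Nussinov-type folding recursion (minimum loop 3,
pair weights GC −3, AT −2, GT −1, negative = stable); a hairpin score
(longest self-complementary stem with loop ≥ 3); and a dimer score
(longest contiguous complementary duplex between two antiparallel
copies). The PMFE recursion is a deliberate simplification of a full
thermodynamic folding engine: its acceptance is equivalence with an
exhaustive structure enumeration (a second, memoization-free
implementation in C++, cross-checked against a pure-R recursion), not
equality with any published folding tool.

Successful probes have read counts strictly between 10% of the mean and
the 99th percentile (a mean of 260 reads/probe reproduces the classic
lower bound of 26). Features with |r| > 0.95 are grouped into connected
components and one representative kept, by the documented priority GC >
Tm > PHFE > PMFE > hairpin > dimer (in real capture data GC, Tm and PHFE
are nearly collinear). The capture-efficiency model is ordinary least
squares with backward elimination by partial F test (α = 0.001) and an
exact LMG relative-importance decomposition — sequential R²
contributions averaged over all feature orderings, computed from all
2^p subset fits (p ≤ 6), whose shares are non-negative and sum to R².

One scale caveat, surfaced honestly: the published efficiency equation
(reads = 5.08·GC + 13.3·PMFE − 2.11·Dimer − 10.67·Hairpin + 164.46) was
fitted to PMFE in kcal/mol, where a 120-mer scores roughly −16…0. The
pairing-weight PMFE here spans roughly −160…0 for the same probes, so
`simulate_probes()` maps PMFE through a fixed factor `pmfe_scale = 0.1`
before applying the printed coefficients; otherwise every expected count
is negative. Model *fitting* is unaffected — it estimates whatever
coefficients the data carry.

Coverage summaries extend each probe by a 100 bp flank on both sides,
merge overlapping targets (so merged probes count once in denominators),
and report per-target median sequence depth (MSD) plus the cumulative
fraction of targets at or above a depth grid.

## Divergence and phylogeny

Ka/Ks uses Nei–Gojobori-style counting: per-codon synonymous site
fractions from the universal code (mutations to stop codons count as
nonsynonymous), averaged over both sequences; differences counted by
averaging over all minimal mutational pathways between differing codons,
excluding pathways through stop codons (if every pathway is blocked, a
flagged all-pathway average is used); Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ applied to both proportions,
with $p \ge 3/4$ reported as saturated rather than corrected. The
counting estimator replaces a maximum-likelihood codon model by design:
it is deterministic and desk-verifiable, and its acceptance is simulation
recovery (simulated pairs at Ks 0.01–0.1 are recovered within a few
percent at 2,000 codons), not equality with ML values. Divergence time is
$T = K_s / (2\lambda)$ with the grass synonymous rate
$\lambda = 6.9\times10^{-9}$ per site per year, so $K_s = 0.0138$ dates
to 1.0 Mya.

Trees are neighbor-joining on pairwise genotype-mismatch distances over
bi-allelic loci without missing data (a dosage-aware distance,
mean $|d_i/m_i - d_j/m_j|$, is available). Bootstrap support resamples
loci with replacement, rebuilds the NJ tree, and reports split
frequencies as internal node labels; given a seed the output Newick is
byte-identical across runs. NJ + bootstrap replaces a parsimony program
by design — deterministic, standard, and exact on additive distances
(guaranteed recovery of 4-taxon additive matrices is asserted).

## The synthetic world

The generator's defaults describe the study design this package targets,
fixed once and not tuned to tests: 12 accessions at ploidies 6/8/12 (2,
8, 2 — a plausible mix for the complex); mean capture depth 150
reads/locus (deep targeted capture); miscall rate 1%; a hom-dominant
dosage prior (55% dosage 0, 20% dosage $m$, 10% dosage 1, 5% dosage
$m{-}1$, the rest spread over interior dosages) reflecting the observed
ordering hom-ref > hom-alt > single-dose > other heterozygous classes
with total heterozygosity under 25%; ~200 expected reads per gene; 1%
planted CNVs at log₂ effect ±2 and 1% planted PAVs; 120-nt probes with
GC drawn across 20–80%; CDS pairs of 2,000 codons at target Ks 0.01–0.1.
Depths are Poisson — one parameter, sufficient for dosage/CNV
testability; a negative-binomial option (`overdispersion`) exists because
real capture depth is overdispersed, but no study-derived value is
available, so it defaults off.

The CDS-pair generator substitutes only third positions of 4-fold
degenerate codons, calibrated so the *counting estimator's* expected Ks
matches the target (with $S$ synonymous sites and $n_4$ 4-fold sites, the
per-site difference probability is $p_4 = p_S^{target} S / n_4$, erroring
when the target exceeds what the sites can carry). This makes Ka = 0
exact and the Ks recovery test an estimator-consistency check rather than
a tautology.

What the generator does **not** emulate — and therefore what a green test
does not establish: alignment and mapping artifacts, reference bias
against a diverged reference genome, capture chemistry (GC-dependent
efficiency curves), linkage between loci, aneuploidy within accessions,
and InDel realignment ambiguity. Tests establish that the *computations*
are correct on data matching their stated models, not that the models
capture every property of real capture reads.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the filters, the CNV percentile rule and
  the probe window, exactly as printed; a degenerate constant
  distribution therefore yields zero CNV calls and an empty probe window
  (with a warning).
* Dosage likelihoods are computed in log space; ties take the smaller
  dosage; the dosage likelihood surface is unimodal for $e < 0.5$.
* `quantile` type 7 everywhere a percentile is needed.
* Zero-depth loci below `min_depth` are no-calls, counted separately.
* Division-by-zero guards: zero gene length or zero total mapped reads
  are errors; zero-length aligned regions are errors; `Ts/Tv` with zero
  transversions reports `Inf` with an explicit flag.
* Seeds: every generator derives its stream from the config seed and a
  fixed stage offset, keeping derived seeds below $2^{31}$.

## Known limitations

The thermodynamic scores are rank-faithful stand-ins, not calibrated
energies; the annotation model is one transcript per gene; the VCF/GFF3
readers implement the subset dialects this pipeline emits and consumes,
not the full specifications; CNV detection is relative between two
accessions and cannot see a change shared by both; and Ka/Ks by counting
underestimates at high divergence where ML codon models would not.
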