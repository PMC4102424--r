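---
title: "Models and methods behind imsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imsat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsat)
library(dplyr)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic-data tests do and do
not establish.

## Repeat detection and the extension algorithm

A *seed* is a maximal stretch of perfect tandem repeats of a primitive
1–4 bp motif. `find_perfect_seeds()` scans every period directly
(vectorized shifted-equality runs), reports one seed per maximal
periodic region, left-aligned to complete units, and suppresses motifs
that are repetitions of shorter motifs, so a poly-A run is never also
reported as an "AA" dinucleotide. N bases are hard breaks: they never
join a seed, a gap or an interruption.

Two threshold presets are shipped as configuration
(`threshold_config()`). The comparative preset requires 9/5/4/3 units
for mono–tetranucleotides and the threshold comparison is inclusive (a
seed of exactly 9 units counts); the population preset restricts locus
lengths to 8–10/10–18/12–24/16–28 bp, where the lower bounds are the
mutability thresholds and the upper bounds the lengths at which
short-read indel calling stays reliable. The two presets deliberately
disagree for tetranucleotides (16 bp = 4 units vs 3 units); both are
kept verbatim rather than reconciled, and the choice is always explicit
in the `cfg` argument.

`extend_seed()` grows a focal seed on both flanks, absorbing runs of at
least two complete units of the same motif class across intervening
non-repeat runs of at most one motif length; every absorbed gap becomes
an interruption. Three readings had to be fixed:

* *Phase shifts.* Runs like `[CA]_2` abutting `[AC]_6` are the same
  repeat in a different phase; they merge without creating an
  interruption when every base belongs to a complete unit.
* *Terminal additions.* "Smaller than two repeats" is read literally: a
  candidate addition of exactly one complete unit is rejected, two or
  more are accepted.
* *Compound loci.* A locus whose final span touches or overlaps a seed
  of a different motif class is flagged `compound-discarded` (both
  partners are), with identical-span ties broken by canonical motif
  order.

The repeat number of a locus of length $L$ with motif size $m$ and
interrupting bases totalling $I$ is $(L - I)/m$, a whole number by
construction; the invariant $L = r\,m + I$ is property-tested. Position
classes of interruptions use the midpoint $o + (l-1)/2$ of an
interruption at offset $o$ spanning $l$ bases: *middle* for fractional
positions in $[0.375, 0.625)$, *fringe* below $0.25$ or at/above
$0.75$, *other* between.

Correctness is established against an independent brute-force
enumerator (a character-level re-derivation of the textual definition,
kept with the test helpers), with zero tolerated discrepancies over a
thousand random repeat-enriched sequences.

## Ortholog filtering and mutability

Mutability is the mean squared repeat-number difference between the two
orthologous alleles of a locus, $\mu = \mathbb{E}[(r_A - r_B)^2]$, in
squared repeat units. It is computed on two genomes at a time; bins
never pool motif sizes, and binning is driven by the repeat number of
the declared reference species (species A) with the other direction
available as an option.

The eight comparability filters run in a fixed order and the rejection
log charges each rejected pair to its *first* failing filter, so the
log's column sums reconcile with the input. One filter required a
design decision: "low-complexity flank" has no standard definition, so
`is_low_complexity()` flags flanks containing a mono- or dinucleotide
run of ≥ 8 bp or base-composition entropy below 1 bit — a conventional
proxy, and configurable.

Confidence bands are percentile bootstrap intervals (2.5th/97.5th) over
resampled loci, defaulting to B = 1000. Because the squared differences
take few distinct values, resampling the mean is implemented as a
multinomial draw over the distinct values — statistically identical to
naive resampling and much cheaper at cohort sizes in the tens of
thousands. Bins with fewer than 20 loci are reported but flagged
low-confidence. Fold-changes between cohorts use independent resampling
of numerator and denominator; resamples with a zero denominator
honestly widen the upper tail.

## The slippage simulator

`gen_ortholog_pairs()` evolves each locus independently along two
lineages for $g$ generations of symmetric stepwise (±1 unit) slippage:
a perfect locus steps with probability $r$ per generation, an
interrupted one with probability $r/k$. The expected mutability of the
perfect cohort is exactly $2gr$ (each lineage contributes $gr$ steps of
unit variance), which is the closed-form oracle the tests check; the
expected cohort ratio is $k$. The fold-reduction $k$ *is* the model of
the tract-shortening effect of interruptions — an additional explicit
scaling by longest-perfect-tract length would double-count the effect
and break parameter identifiability, so the rates are exactly $r$ and
$r/k$. Defaults ($r = 0.01$, $g = 20$, ancestral repeat number 12)
keep repeat numbers well inside the detection windows while giving a
perfect-cohort mutability of 0.4, comparable to upper repeat-number
bins of real two-genome contrasts. The model is symmetric and
memoryless; it does not emulate length-dependent rate growth within a
cohort, directional bias, or range constraints, so tests against it
validate the estimator arithmetic and interval coverage, not the
realism of any particular genome.

## Interruption calling

A variant call is an interruption of a perfect locus when (i) its
population allele frequency is at least 0.05 (inclusive), (ii) its
affected span lies inside the locus minus one whole repeat unit at each
end — the exclusion applies to the unit, not just the terminal base —
(iii) an indel's net length is not a multiple of the motif size (whole-
motif indels, including 2× and 3× the motif, are length polymorphisms),
and (iv) applying the allele actually breaks motif periodicity (a
variant that leaves a perfect, possibly partial-unit, repeat is not an
interruption). Variants must arrive normalized: left-aligned,
biallelic; multi-allelic records are rejected with instructions rather
than silently mishandled.

Fate classification applies the allele and measures every residual
perfect tract in *complete* motif units: *degeneration* if the longest
residual reaches the population-preset lower length bound
(8/10/12/16 bp) inclusively, else *death*. Complete-unit counting plus
the inclusive comparison is the only reading consistent across the
boundary cases we validate (a 10-unit poly-A SNP after unit 8
degenerates via its residual (A)$_8$; an 8-unit poly-A mid-SNP dies; a
central insertion in (AC)$_9$ leaves 4 complete units per side and
dies). The bound is configurable for users who prefer unit-threshold
semantics.

Population sharing partitions distinct (locus, variant) keys by the
exact subset of populations they were called in; counts are invariant
to processing order and sum to the number of distinct interruptions.
Exonic annotation handles one CDS block at a time with a declared
strand and GFF-style phase; codons spanning CDS-block boundaries are
outside the synthetic data's scope and degrade to `noncoding` with a
warning rather than a wrong translation. Disease-locus tabulation
expands annotated repeat-structure strings, applies each overlapping
variant, and re-encodes the allele greedily against the locus motif;
the reference allele's frequency is one minus the summed variant
frequencies, which assumes a complete, mutually exclusive variant set.

## Population-genetic statistics

$H = 2pq$; $H_S$ is the unweighted mean of within-population
heterozygosities; $P$ the unweighted mean frequency; $H_T = 2PQ$; and
$F_{ST} = (H_T - H_S)/H_T$, undefined (reported `NA`, never dropped)
when $H_T = 0$. Unweighted means are the method's definition; sample-
size weighting is deliberately not the default. Heterozygosity
histograms use 25 left-closed bins of width 0.02 on $[0, 0.5]$ with a
closed top bin.

The two-sample KS comparison uses a pooled-resampling bootstrap: D is
the maximum ECDF gap evaluated tie-safely (only the last step at a tied
value counts), the null redraws both samples with replacement from the
pool, and the p-value is the fraction of bootstrap statistics at least
the observed one (`>=`, so heavily tied data — the reason to bootstrap
at all — are handled exactly). Calibration is verified as a type-I
error within [0.03, 0.07] at α = 0.05 over 500 null replicates on a
discrete support.

LD is computed from phased haplotypes only:
$r^2 = (p_{AB} - p_A p_B)^2 / (p_A q_A p_B q_B)$, identical to the
squared Pearson correlation of the 0/1 vectors (tested as an
equivalence). Partner search takes the maximum $r^2$ within ±500 kb,
breaking ties by distance then coordinate, and flags perfect LD at
$|r^2 - 1| \le 10^{-12}$. An EM fallback for unphased genotypes is out
of scope.

## Polymerase error calculus

The reporter model: a template is an in-frame, stop-free coding
sequence with the microsatellite inserted at a known offset
(`make_reporter_template()` assembles synthetic ones; real reporter
sequences can be supplied as the same one-row registry). Mutants are
aligned globally (Biostrings), and indels are normalized to the 3′ end
of repeat runs so that placement inside a run is deterministic — the
alignment itself cannot decide it. An edit script that fails to
reconstruct the sequenced mutant quarantines the record with a reason.

Event classes are decided by periodicity-break counting on the repeat
region: an indel whose net length is a whole number of units *and*
leaves the break count unchanged is a unit-based indel; anything else
inside the repeat is an interruption event, and events that *reduce*
breaks on an interrupted template are flagged as interruption removals.
Detectability follows reporter selection: all frameshifts (net indel
length not divisible by 3); substitutions in coding sequence if they
change the amino acid or create a stop; substitutions inside the
repeat only if they create a stop. Events at most 1 nt apart form one
tandem group.

The error frequencies: $\text{MF} = $ mutant colonies / total colonies;
$\text{Pol EF} = \text{MF}_{obs} - \text{MF}_{ssDNA} -
\text{MF}_{outside}$, floored at zero with a warning. The multiple-
event correction multiplies Pol EF by the number of detectable
nontandem event groups per sequenced record; the cited original formula
is not restated in the source text, so this reconstruction is isolated
in `correct_multiple_events()` and tested only for its stated limiting
behaviors (identity at one group per record; a tandem pair counts
once). Class-specific frequencies multiply the corrected EF by the
class's share of *detectable* events — numerator and denominator both —
so an interruption-removal tally of 2 among 74 detectable events at a
corrected EF of 3.4×10⁻⁴ gives 9.2×10⁻⁶; spectra, by contrast, include
undetectable interruptions.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic given its seed and emits ground truth
sufficient to score pipeline output without re-running the pipeline.
Flanks are built base-by-base so that no 1–4 bp motif ever completes
two units inside a flank, and boundary bases cannot continue a planted
locus's phase — detection on synthetic genomes is therefore
unambiguous by construction, not by luck. Planted interruption bases
are chosen to break periodicity against both neighboring tracts, and
interrupted classes keep one tract at or above the seed threshold
(otherwise the locus would, correctly, be undetectable). Population
VCFs plant expected calls alongside three decoy families (sub-cutoff
frequency, terminal-unit, whole-motif indel) and cycle sharing sets
through all subset sizes; mutant collections allocate event classes by
largest-remainder rounding so planted spectra are recovered exactly at
compatible n.

What passing these tests shows: the estimators and rules implement
their definitions, exactly where exactness is claimed, within sampling
error where the check is stochastic. What they do not show: performance
on real genomes — no sequencing error, alignment artifacts, flanking
repeat ambiguity, demography or selection are modeled, and the
slippage simulator's simplifications are listed above.

## Numerical and scale choices

Bootstrap draws use a restorable RNG scope (`rng_seed` arguments never
perturb the caller's RNG stream). Percentile quantiles are type 7.
Problem sizes in the test-suite: a thousand oracle sequences of
120–420 bp; mutability coverage at 100 replicates × 10⁴ pairs per
cohort with B = 1000; KS calibration at 500 replicates × 2000
iterations; 5000 classified mutants. These sizes give the property
checks sharp expected outcomes while keeping the whole suite in a few
minutes of one-CPU time.

## Known limitations

Penta-/hexanucleotide motifs are out of scope. Multi-exon codons are
not translated. Unphased LD is not computed. The multiple-event
correction is a documented reconstruction. `F_ST` is biallelic-only.
The scanner is exhaustive rather than engineered for whole-genome
throughput; desk-scale contigs (up to a few hundred kb) are its
intended regime.
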