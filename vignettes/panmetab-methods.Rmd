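---
title: "Methods and design of the panmetab characterization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the panmetab characterization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmetab)
```

`panmetab` packages the computations used to characterize a draft
bacterial genome against its relatives: assembly statistics, average
nucleotide and amino-acid identity, pangenome presence/absence
analytics, COG enrichment testing, homology-guided expansion of a
genome-scale metabolic model, flux balance analysis, and rule-based
classification of symbiosis proteins. This vignette explains each
method, its assumptions, the tunable parameters, and the design
decisions taken where the procedure was genuinely open.

## Assembly filtering and statistics

Scaffolds are filtered by the rule "remove anything with less than
`min_coverage` (default 10×) fold-coverage or shorter than `min_length`
(default 200 nt)". The comparisons are strict removals: a scaffold at
exactly 10× and 200 nt is retained. Coverage is not part of FASTA, so
two carriers are supported: an `id<TAB>coverage` sidecar, or
assembler-style `_cov_<x>` header suffixes.

`assembly_stats()` defines N50 as the length of the scaffold at which
the cumulative length, in descending length order, first reaches half
the total; L50 is that scaffold's rank. With equal-length scaffolds the
rank is made deterministic by a secondary lexicographic sort on id, and
L50 is the smallest qualifying rank. GC content excludes ambiguous
bases (`N`) from both numerator and denominator — the standard
convention; it is what fraction of *called* bases are G or C. The
"large scaffold" count uses a strict `>` at the 40-kb default
threshold. Mean coverage is reported length-weighted; an unweighted
per-scaffold mean is an equally defensible reading, and the
documentation flags the ambiguity rather than hiding it.

## ANI, BBH orthology, AAI, and species clustering

One-way ANI is fragment-based: the query is chopped into consecutive,
non-overlapping 1000-nt fragments (terminal remainders discarded), each
fragment is aligned to its best location in the reference with
`blastn`, and a fragment counts as *mapped* when its best hit reaches
70% identity. ANI is the mean identity over mapped fragments; the
averaged ANI of a pair is the arithmetic mean of the two one-way
values. This is the classical fragment-alignment ANI; minimizer-based
tools can differ by small fractions of a percentage point, so absolute
agreement with other software at the second decimal is not promised.
Local alignment can trim a mismatching fragment end, which biases
identity upward by well under a tenth of a point at the divergences of
interest (≤10%); the planted-recovery tests bound the total error at
±0.5 points on 100-kb genomes.

Bidirectional best hits operate on tabular similarity-hit tables. A
pair `(a, b)` is an ortholog candidate iff `b` is `a`'s highest-bitscore
subject and vice versa, and both direction hits satisfy the identity and
coverage thresholds (defaults 70%/70%; AAI uses 40%/70% plus an e-value
ceiling of 1e-12). Coverage is `alignment_length / query_length` of the
querying direction; the threshold statement "70% the length of the
protein" does not name which protein, so the query-side reading is the
default and a `coverage_mode = "both"` flag additionally requires
subject-side coverage. Bitscore ties break deterministically: lower
e-value, then longer alignment, then lexicographic subject id. AAI is
the mean over ortholog pairs of the pairwise mean identity
`(identityAB + identityBA)/2` — the "pair means" convention; averaging
the two directions separately first gives the same value only when the
ortholog sets coincide, and the pair-means reading was chosen because
it is defined per ortholog. Zero qualifying pairs is an explicit error,
never a silent 0, because an AAI of 0 is a meaningful (and wrong)
number.

Species clustering builds a graph over strains with an edge where *both*
ANI and AAI reach the threshold (default 96%), and reports connected
components — single linkage, so a species is a chain of
above-threshold pairs. AND-semantics is the default because the species
assignment is stated "on the basis of ANI and AAI values"; OR-semantics
is available behind a flag. Missing AAI entries are treated as passing
(with a message) so that an ANI-only matrix can still be clustered.
Lowering the threshold can only merge components, which yields the
monotonicity property the tests assert; partitions at 96% and 94% are
expected to agree on well-separated data.

## Pangenome analytics

The presence/absence matrix is boolean, families × strains, read from
the pangenome CSV dialect (a `Gene` column, optional annotation
columns, one column per strain holding the representative gene id).
Core families are present in 100% of strains. The Venn partition over
2–4 focal strains counts families per non-empty presence pattern
restricted to those strains; the cells partition the families present
in at least one focal strain, which gives the sum rule used as a test
invariant. Unique families are present in the focal strain and absent
everywhere else in the matrix.

Genomic islands are detected with a deliberately simple rule, because
the source analysis shows islands without defining a detector: per
scaffold, genes are ranked by position; maximal runs of unique genes in
which consecutive unique genes are separated by at most `max_gap_genes`
(default 3) non-unique genes are candidates, and candidates with at
least `min_island_genes` (default 4) unique genes are reported. Both
parameters are exposed in the configuration; they are heuristics, not
estimates.

COG profiles count, per single-letter category, the proteins annotated
with it. A protein carrying k categories increments all k counts by
default, matching the "percentage of proteins annotated with each
category" reading (percentages can then sum over 100); a
single-assignment mode takes the first letter only. Category S
(function unknown) can be excluded from the annotated total. Profile
comparison tests, per category, the 2×2 table of (count, rest) in the
two strains with a two-sided Fisher exact test at α = 0.05,
deliberately without multiple-testing correction — mirroring the
original pairwise analysis; a Bonferroni flag exists but defaults off.

`fisher_exact_2x2()` computes the exact two-sided p-value by
hypergeometric enumeration: the sum of the probabilities of all tables
with the observed margins whose probability does not exceed the
observed table's. Probability ties are included within a relative
tolerance of 1e-12 (floating-point equality would otherwise make the
answer depend on rounding direction). The suite checks the function
against an independent binomial-coefficient enumeration for every table
with N ≤ 60, and against `stats::fisher.test` on random tables.

## Metabolic-model expansion

The model container is deliberately minimal: genes, metabolites with
compartments, reactions with signed stoichiometries, bounds, a boolean
gene–protein–reaction (GPR) rule, and one objective reaction. GPRs use
`and`/`or` with parentheses; an empty rule means "not
gene-constrained" and always evaluates true.

The expansion procedure takes a draft (recipient) model and an ordered
list of curated donor models with donor→recipient ortholog maps (built
from BBH at 70%/70%):

1. **Orthology pruning.** Donor genes without an ortholog are deleted;
   a reaction is removed iff its GPR is non-empty and unsatisfiable with
   the deleted genes false and all surviving genes present. Surviving
   GPRs are simplified (deleted literals become false; `and(false, x) =
   false`, `or(false, x) = x`).
2. **Signature comparison.** Reactions are compared by canonical
   equation signature: metabolites sorted per side, near-integral
   stoichiometries normalized by their GCD (so `2a → 2b` equals
   `a → b`), backward-only reactions flipped to forward, and reversible
   reactions normalized so the lexicographically smaller side is on the
   left. The arrow (`->` vs `<=>`) is part of the signature: an
   irreversible and a reversible reaction over the same metabolites are
   *not* identical, because a reaction's equation includes its
   direction. A donor reaction is classified against the recipient as
   `identical`, `proton_variant` (equal after dropping protons),
   `stoich_variant` (equal per-side metabolite sets ignoring protons,
   different coefficients), or `distinct`; the classification is
   symmetric and applied in that precedence order. Protons are
   recognized by compartment-stripped metabolite id (default set `h`,
   `h+`, `proton`), configurable because naming conventions differ; the
   default ignores the proton's compartment only insofar as the
   compartment suffix is stripped.
3. **Transfer.** Only `distinct` reactions are copied, with their
   bounds; GPR gene literals are rewritten to recipient gene names
   through the ortholog map, and an unmapped literal on a transferred
   reaction is a hard error rather than a silently dropped gene. New
   metabolites are added; id collisions get a deterministic `_t<k>`
   suffix.
4. **Dead-end removal.** A metabolite is a dead end iff, considering
   directionality (a reversible reaction both produces and consumes its
   participants; an irreversible one produces its products and consumes
   its substrates; exchanges follow their bounds), it cannot be both
   produced and consumed. Removal iterates to fixpoint: every reaction
   in which a current dead-end metabolite *participates* is removed,
   then unreferenced metabolites are dropped. The participant reading
   (rather than producers only) was chosen because removing only
   producers leaves consume-only reactions that can never carry flux,
   and because set-based participant removal makes the fixpoint
   independent of processing order and the operation idempotent — both
   are asserted against a randomized-order oracle. A producer-only mode
   exists behind a flag. Removing the objective reaction is an error
   that names the offending metabolites.

Dead-end removal runs once after all donors have been transferred
("following the expansions"); a per-donor flag exists because the
original wording admits either reading. Gap-filling, biomass-template
selection, and thermodynamic checks are out of scope: the draft model
is an input.

## Flux balance analysis and the carbon screen

FBA maximizes the objective flux subject to steady state (S·v = 0) and
bounds, with medium overrides applied to the listed exchange reactions.
The LP is solved by simplex on shifted non-negative variables
(v = x + lb), which keeps every variable and right-hand side finite and
well-scaled; infinite bounds are capped at ±1000 mmol gDW⁻¹ h⁻¹. The
objective value is the contract; individual fluxes are degenerate under
alternative optima and are never asserted in tests. Optimal solutions
are checked to satisfy |S·v| ≤ 1e-6 componentwise.

The carbon screen closes every declared carbon exchange (lower bound
0), opens one source at a time at −`uptake_rate` (default 10
mmol gDW⁻¹ h⁻¹), and calls growth when the optimum exceeds
`growth_epsilon` (default 1e-6). Both parameters are conventions, not
measurements — the source analysis states neither — and both are
config-exposed. Panel sources absent from the model are reported as
absent and non-growing rather than erroring, since a 163-source panel
routinely includes compounds a model lacks exchanges for; results are
independent of panel order.

## Symbiosis-protein classification

The two-stage HMM procedure is bookkeeping over externally produced
HMMER tables: stage one collects every query hit by the seed HMMs
*regardless of e-value* (the permissive stage only gathers candidates);
stage two takes each candidate's top-scoring hit against the combined
Pfam/TIGRFAM database and applies an exact rule table (NodA ⇐
TIGR04245 or Pfam NodA; NodB ⇐ TIGR04243; NodC ⇐ TIGR04242; NifH ⇐
TIGR01287 or Fer4_NifH; NifD ⇐ TIGR01282/TIGR01860/TIGR01861; NifK ⇐
TIGR02932/TIGR02931/TIGR01286; otherwise none). Score ties across
databases are not addressed by the original rule, so the package breaks
them by lower e-value, then lexicographic accession — deterministic and
documented. The composite calls `nodABC` and `nifHDK` require all three
members. Accession version suffixes (`TIGR04245.1`) are stripped before
matching.

## The synthetic-data generators

The generators exist so that every downstream stage can be tested
against planted, analytically known truth. Their defaults are the study
conditions: 45 scaffolds at 61.47% GC with 10–230× coverage; 100-kb
genome pairs at 1.5% substitution divergence (planted ANI 98.5%); 20
reciprocal orthologs near 98.9% identity; a 46-strain matrix with 1652
core families, 656 focal-unique families, and shared blocks of 243 and
812 families that place 899 and 812 families in the focal four-strain
Venn cells; two genomic islands of 120 and 97 unique genes on scaffolds
11 and 8 (together 217 genes, matching the two mobilizable replicons of
the motivating strain); and a donor model planting two identical
copies, two proton variants, one stoichiometry variant, three
transferable reaction units, two three-reaction dead-end chains, and
one orthology-pruned reaction.

Divergence is substitution-only (no indels), which keeps the planted
ANI exactly `1 − divergence`; at divergence 1 every site differs
because the substituted base is drawn from the three alternatives.
Decoy hits are strictly dominated in bitscore so BBH ground truth is
unambiguous — ties are never planted. Every generator is deterministic
under its seed (the RNG state is restored afterwards), and fixtures
serialize in the same on-disk formats the pipeline reads, so the I/O
paths are exercised.

What the generators do *not* emulate: real gene content or codon
structure, phylogenetic signal, indels and rearrangements, alignment
noise in hit tables, or a thermodynamically meaningful metabolism.
Passing the planted-recovery tests therefore demonstrates the
correctness of the computations, not the behaviour of the upstream
aligners and annotators on real data.

## Problem sizes and numerical choices

The test suite uses 100-kb genomes for ANI recovery (±0.5 points at
divergences up to 5%), 25–30-row-pair ortholog tables across 50 seeds
for the BBH/AAI oracle checks, exhaustive Fisher enumeration for all
2×2 tables with N ≤ 60, and 100 seeded model fixtures for merge
ground-truth recovery — sizes at which the oracles are exact and the
suite completes in a few minutes. Numerical tolerances: 1e-9 on matrix
symmetry for species clustering, 1e-9 on near-integrality in GCD
normalization of stoichiometries, 1e-12 relative on Fisher probability
ties, 1e-6 on steady-state residuals, 1e-9 reproducibility on LP
objectives. Degenerate inputs fail loudly and specifically: empty
assemblies, zero-fragment ANI queries, zero ortholog pairs, unmappable
ANI directions, all-zero Fisher margins, and objective-removing
dead-end cascades are all typed errors, not NA propagation.

## Known limitations

The ANI engine requires BLAST+ on `PATH` and inherits blastn's
alignment heuristics; the island detector is a rank-gap heuristic, not
a composition-based method; the LP solver is a dense simplex suited to
the curated-model scale (thousands of reactions are fine, genome-scale
community models are not the target); and the pangenome clustering that
*produces* a presence/absence matrix at scale is out of scope — the
package analyzes such matrices, it does not build them from raw
proteomes.
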