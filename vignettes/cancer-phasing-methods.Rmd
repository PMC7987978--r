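---
title: "Phasing cancer genomes from Hi-C: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing cancer genomes from Hi-C: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicphaser)
```

This vignette is the package's own account of the statistics and
algorithms it implements, the parameters that matter, and the design
decisions taken where several readings were defensible. The companion
README shows a worked run; here we explain *why* the pieces look the way
they do.

## The problem

A tumour genome differs from the germline it arose from in three ways that
matter for phasing: somatic SNVs that carry no population linkage
information, loss-of-heterozygosity (LOH) regions in which one homolog is
gone so there is nothing left to phase, and copy-number changes that leave
the two homologs present in unequal numbers. Hi-C read pairs provide
linkage at all genomic distances, which is what makes chromosome-scale
phasing possible from one library; the package's job is to clear the first
two obstacles and exploit the third.

## LOH detection: an exact binomial window test

For each 1 Mb window (`window_bp`) we observe `N` called SNPs of which `k`
are heterozygous, and take from a normal-genome profile the heterozygous
proportion `p` expected in that window. Under the no-LOH null,
`k ~ Binomial(N, p)`; the window's `p`-value is the inclusive lower tail
`P(X <= k)`, computed by explicit summation of `dbinom` terms — no normal
approximation, exact to machine precision (the test suite checks it against
the closed-form CDF to 1e-12). A window is labelled LOH when the `p`-value
falls below `alpha = 0.05`; maximal runs of LOH windows merge into regions
(half-open, window-aligned). Windows with fewer than `min_snps = 10` SNPs
are not tested; they inherit the label of the nearest labelled window, with
ties resolved towards LOH so that sparse chromosome ends attached to an LOH
arm are not spuriously called heterozygous.

Two consequences of this design are worth stating plainly. First, the test
is *exact*, so its size is conservative: under the null the LOH call rate
is at most `alpha` (property-tested on 10,000 simulated windows). Second,
there is **no multiple-testing correction** — each window is judged on its
own at `alpha`. Across a genome this emits false-positive windows at a rate
close to `alpha` per adequately-powered window; on a 20 Mb chromosome with
15 non-LOH windows, roughly half of simulation seeds produce at least one
false 1 Mb LOH call, which costs ~17 points of LOH precision and removes
that window's SNPs from phasing. We kept the literal uncorrected procedure
because it is the method as defined; users who prefer genome-wide control
can lower `alpha`.

The normal profile is a per-window table (`chrom`, `start`, `end`,
`p_het`); a single genome-wide proportion (`p_het_default`) is accepted for
synthetic work. What SNP universe the profile's denominator uses (all known
sites vs called sites) is left to the profile's producer; the simulator
uses the called-site convention throughout.

## Fragments and allelic depth

A *fragment* is the set of alleles one read pair observes at the SNPs it
covers: the atomic linkage record. Alignments must be primary,
non-duplicate and uniquely mapped with MAPQ strictly above `mapq_min = 30`
(applied per mate); read bases matching neither allele make no call, and a
SNP covered by both mates with disagreeing bases makes none either.
Fragments with fewer than two calls carry no linkage and are dropped from
phasing — but their calls still count towards **allelic depth**. Depth is
tallied over every passing pair because coverage is a property of the
alignment pile-up, not of the linkage subset; restricting depth to
multi-call fragments would systematically starve isolated SNPs (their calls
arrive mostly in single-call pairs) below the assembly coverage threshold.
The `hic_fragments` container therefore carries the phasing calls, the full
call set with mate positions (needed later to link LOH regions), and the
per-SNP depth.

## The built-in phaser

The package phases through HAPCUT2 when the executable is available, but is
self-contained without it. The fallback phaser is deliberately simple: for
every SNP pair co-observed in at least one fragment, count cis
(same-allele) versus trans votes; pairs with `|cis − trans| >=
min_support = 2` become edges weighted by that margin (exact ties are
dropped — the SNP can be rescued later). Each connected component is
phased along a maximum-weight spanning forest and becomes one block;
isolated SNPs become singleton blocks with the alt allele on h1 by
convention. Edges never join SNPs from different non-LOH stretches, so no
block spans an LOH region.

A spanning tree has a known failure mode: one wrong low-margin bridge
inverts an entire subtree, and when that subtree is interior to the block
the error is invisible to suffix-based switch correction. Two defences are
built in. Inside the phaser, every weak tree edge (margin ≤ 6) is
re-examined against *all* linkage edges crossing its split, and the child
subtree is flipped when that strictly increases the total vote-margin
agreement (two passes; with error-free data nothing ever changes, which the
tests assert). Downstream, coverage imbalance provides an independent check
(next section).

## Switch-error correction from coverage imbalance

In an aneuploid region the homolog present in more copies collects more
reads, so each SNP's haplotype-resolved depth pair (`cov1`, `cov2`) votes
on the block's local orientation. For every inter-SNP position the four
counts `c1_before, c2_before, c1_after, c2_after` (SNPs whose depth favours
h1 resp. h2, before resp. from the position; ties count nowhere) come from
forward/backward recurrences checked against brute-force recounts. The
ratios `r_before = c1_before/c2_before` and `r_after` (zero denominators
give `+Inf`) define a potential switching point when one exceeds
`switch_hi = 2` while the other is below `switch_lo = 0.5`; among
qualifiers the lowest ratio-of-ratios `min(r)/max(r)` wins and the suffix
is flipped, iterating until no point qualifies (bounded by block length).

Two numerical conventions deserve note. With integer counts the
ratio-of-ratios ties at exactly 0 whenever a count vanishes; tied
qualifiers are ranked by a half-pseudocount smoothed ratio-of-ratios and
then position, so a complete dominance inversion beats a position that
merely grazes the thresholds past a stray SNP. And a position with both
ratios infinite never qualifies — uniform imbalance is not a switch.

The suffix criterion has a geometric blind spot: an interior inverted
window qualifies only if it outweighs the remainder of the block on its
side (`r_after < 0.5` needs the tail shorter than the window). Paired
switches deep inside a long block therefore pass unseen. `fix_inverted_runs()`
closes this gap with the same physical signal: inside a block whose
aggregate depth is decisively h1-dominant (one-tailed binomial evidence
below 1e-4), any run of at least 5 consecutive SNPs whose depth
contradicts the consensus — again with binomial evidence below 1e-4 — is
flipped. Balanced-copy blocks have no consensus and are never touched; at
typical depths the double evidence requirement makes a false flip
essentially impossible, while a genuine 20-SNP inverted window at 2:1 is
flagged with near certainty.

## Assembly: the coverage matching graph and minimum multiple s-t cut

Fragmented blocks are stitched using coverage proportions. Each SNP
contributes two vertices (side *a* = the allele its block puts on h1, side
*b* the complement). A cross-block SNP pair is *eligible* when (1) the
genomic distance is at most `max_dist` = 1 Mb, (2) each SNP is among the
other's `n_nearest` = 5 closest eligible cross-block SNPs (mutual
nearest, counted among cross-block SNPs of the same stretch only), (3) at
least one of the two belongs to a block of at least `min_block` = 100
SNPs, and (4) all four side depths exceed `min_cov` = 10 strictly.

Eligible pairs get a four-edge bundle weighted under a binomial model of
coverage proportions, in one of two modes:

* `"as-printed"` follows the reciprocal-of-normalized-log-likelihood
  transform verbatim: per-edge components
  `w_i(x, y) = −1/[p(s_j^y)·ln p_i^x]`, summed over both directions and
  normalized to sum 1. This transform has a documented pathology: for
  coverage-matched skewed pairs (e.g. both proportions 0.75) it puts the
  *larger* summed weight on the mismatched orientation, so the minimum cut
  prefers the wrong merge and the reliability filter removes exactly the
  pairs the method wants. It is provided for fidelity and pinned by tests
  to its worked values.
* `"matched-support"` (default) keeps the same coverage-normalized
  binomial log-likelihoods but converts them into a pair-level posterior
  `W(aa|bb) = 1/(1 + exp(L(ab|ba) − L(aa|bb)))`, split equally over each
  hypothesis's two edges. This is guaranteed to favour the
  coverage-matched orientation.

Bundles where the smaller orientation-support sum exceeds
`reliability_thresh = 0.4` of the larger are removed as ambiguous. Note
the operating range this implies for the default weights: a bundle
survives only when the posterior odds clear (1−0.4)/0.4 = 2.5, i.e.
`W >= 5/7 ≈ 0.714`. Exact coverage proportions of 2/3 on both sides give
`W ≈ 0.61` — at a true 2:1 allelic ratio only pairs whose sampled
proportions overshoot survive, so assembly at 2:1 rescues stragglers
opportunistically rather than merging everything; at 3:1 (proportion 0.75,
`W = 0.75`) the filter passes matched pairs systematically. This
interaction between the printed threshold and the weight scale is inherent
to the published constants and is documented rather than re-tuned.

Adjacent SNPs within a block are linked by infinite-weight same-haplotype
edges, realized exactly by treating each block as a pre-merged vertex group
the solver can never split. The assembly problem is then the **minimum
multiple s-t cut**: partition the vertices into two sides, exactly one
vertex of each pair per side, minimizing the crossing weight. The problem
is NP-hard by reduction from Max-Cut (each source vertex becomes a pair,
each source edge (i, j) one edge (i_a, j_b); `reduce_maxcut()` implements
the construction executably and the tests verify
`total = maxcut + min-multi-cut` exactly on random graphs).

The solver is a revised randomized-contraction heuristic. An association
graph puts one vertex per SNP pair and weights each surviving bundle by the
inverse binary entropy `1/(−r1·ln r1 − r2·ln r2)` of its orientation
support `r1` (clamped to `[1e-12, 1 − 1e-12]` since the entropy is
undefined at 0 and 1): near-certain bundles get large weights. Each of `M`
(default 100) runs draws a random permutation of association edges with
probabilities proportional to these weights — realized as exponential-race
ordering `order(rexp(E)/w)`, equivalent to sequential weighted sampling
without replacement — and contracts edges in order. A contraction merges
the two pair-groups in the orientation with the larger current inter-group
supporting weight (exact ties resolved by a pre-drawn uniform); edges whose
groups are already merged are skipped. Union-find with parity bits and
small-into-large edge-list merging keeps a run linear, O((|E|+|V|)·M)
overall; the kernel is C++ (Rcpp) with *all* randomness generated on the R
side from `set.seed`, so one integer seed reproduces the solution
bit-for-bit. The best (minimum-cut) run wins; an exhaustive
`brute_force_min_multi_cut()` (2^(k−1) orientations, lexicographic
tie-break) serves as the oracle on small instances, where the heuristic at
`M = 500` matches the optimum in ≥ 95% of random ≤ 8-pair instances and
never beats it (soundness is asserted, not sampled).

`apply_cut()` merges each connected component into one block, flipping
whole blocks only — internal phasing is preserved exactly because infinite
edges are never cut.

## Gap filling and completion

Tiny blocks left in coverage-balanced regions are clustered to the nearest
main haplotype (blocks of ≥ `min_block` SNPs are centres; distance is the
minimum SNP-position difference, ties to the leftmost centre) and handed to
a pluggable LD phasing engine as unphased sites alongside the centre's
phased seed genotypes. The engine is any function from the seed-input table
to phased sites; a Beagle adapter is provided, tests use mock engines. The
merge step trusts the seeds absolutely: if the engine inverted the majority
of seed sites its output is globally flipped, seed phases are never
altered, no SNP is ever removed, and sites the engine skipped stay in
their tiny blocks. Without an engine the step is skipped with a warning.

Completion links LOH sequences to stretch haplotypes. Each LOH region and
each stretch's two haplotypes (represented by the stretch's largest block)
become vertices; the edge weight between LOH region L and haplotype h
counts read pairs with one mate inside L and the other mate making a call
matching h (a pair with discordant calls may count towards both — rare and
error-driven; pairs matching neither count nowhere). The partition fixes
the first linked stretch's orientation (global flip symmetry), enumerates
one orientation bit per further linked stretch and one side bit per LOH
region, and minimizes removed weight; ties break to the lexicographically
smallest assignment. Beyond `max_bits = 19` enumeration bits the problem is
mapped onto an equivalent pairing and given to the contraction solver
(logged). Stretches with no LOH link cannot be mutually oriented and are
emitted in input orientation as independent phase sets — completion is only
defined where LOH regions intervene. Chromosomes that are entirely LOH
bypass phasing and are emitted as a single LOH segment.

## The simulator: what it emulates and what it does not

`simulate_genome()` plants the truth the pipeline is tested against. Its
defaults describe one near-triploid-like study chromosome: 20 Mb,
Poisson-spaced sites at mean gap 2 kb (~10,000 sites), heterozygous
proportion 0.6, two LOH segments (5–8 Mb with haplotype 1 surviving, 14–16
Mb with haplotype 2), residual LOH heterozygosity 2%, somatic fraction 5%
(absent from the known-site list), and a 2:1 allelic copy ratio elsewhere.
LOH conversion is allele-aware: a heterozygous site losing its alt allele
becomes an uncalled hom-ref site and disappears from the call set, which is
why LOH windows lose roughly half their called SNPs as well as nearly all
heterozygosity. `simulate_hic()` draws pair distances with density ∝
d^(−1) (the approximate Hi-C contact decay; the exact exponent is
irrelevant to correctness tests), assigns each pair to a haplotype with
probability proportional to its copy number at either end — a molecule
with an end inside an LOH interval can only be the surviving haplotype —
and lets each mate report the haplotype allele of every cancer-het SNP
within a 2 kb span (restriction-fragment scale), flipped with probability
`eps = 0.01`. Everything is deterministic given one integer seed.

The simulator does **not** model GC, mappability or restriction-site
coverage bias, h-trans ligation noise, subclonal copy-number mixtures,
indels, or reference mapping artefacts. Passing tests therefore demonstrate
the statistical machinery — exactness of the tests, soundness and
near-optimality of the solver, correct bookkeeping through every format —
under clean allele-frequency and contact-distance models; they do not
certify performance on real libraries, where coverage bias in particular
will widen the depth dispersion the switch and assembly steps rely on.

## Problem sizes and determinism in the test suite

The suite runs the full study instance (20 Mb, 500,000 pairs) once — about
half a minute — plus module-scale simulations: 10,000-window null/power
calibrations of the LOH test, 1,000 random DP recount vectors, 100
planted-switch replicates at Poisson(30) depth split 3:1, 200 random
≤ 8-pair cut instances at `M = 500` against brute force, 50 random Max-Cut
reductions, and 100 random completion graphs against an independent
enumerator. All stochastic tests fix their seeds; the pipeline is
deterministic end to end given `pipeline_config(seed = )`, which the suite
asserts by exact rerun comparison.

## Known limitations

* The per-window LOH test without multiple-testing correction produces
  false-positive windows at rate ≈ `alpha`; LOH precision on clean
  simulations is 100% only on seeds without such a draw (~83% otherwise on
  a 20 Mb chromosome).
* The default matched-support weights together with the 0.4 reliability
  threshold merge systematically only above ~2.7:1 allelic ratios; at 2:1
  assembly completes the large blocks and rescues most but not all
  singletons, so large-block completeness sits near (usually just above)
  99% rather than at 100% without an LD engine.
* The suffix-flip switch criterion cannot see interior inverted windows;
  `fix_inverted_runs()` covers them only where allelic imbalance exists.
  In truly balanced regions, window-scale phaser errors would persist.
* Two haplotypes per chromosome are assumed throughout; multi-copy
  haplotype resolution and indel evidence are out of scope.
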