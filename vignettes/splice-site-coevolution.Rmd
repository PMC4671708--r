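---
title: "Methods: correlated evolution of splice-site positions"
author: "spliceCoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated evolution of splice-site positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methodology: the
models, the estimation choices that were genuinely open, the synthetic data
the tests rely on, and the limits of what those tests show.

## Data model and coordinates

A `SpliceSiteSet` holds orthologous splice-site triples: for each site, one
30-nt window per genome (human, mouse, dog), a splicing-type label
(constitutive or cassette), and an age in synonymous-substitution units
(K~s~; sites at or above 1 K~s~ are "old"). Donor windows are exon-first —
offsets 0–9 are exonic positions −10…−1, offsets 10–11 the invariant GT,
offsets 12–29 intronic +3…+20. Acceptor windows are intron-first, with the
invariant AG at offsets 18–19. Only sites carrying the canonical
dinucleotide in all three genomes are retained; the published table format
does not state the string orientation, so the reader locates the canonical
dinucleotide at the two offsets the two orientations imply and takes a
majority vote, recording the decision in the provenance. Sequences
containing N are kept; every counting operation skips the affected
positions (pairwise handling downstream), which uses all available data
without imputation.

The default analysis windows are −3…−1, +3…+6 for donors and −20…−3,
+1…+3 for acceptors; the invariant dinucleotide is never part of a window.
Both windows are arguments everywhere, because the informative acceptor
range is not sharply defined — reports often restrict to −13…+3.

## Per-position substitution model

The phylogeny is simplified to a star: the internal branch between the
human–mouse ancestor and the three-species ancestor is short enough that a
trifurcation loses little, and it buys a model with three independent
branch matrices. For each position, the parameters are an ancestral
nucleotide distribution $p(Z)$ and three row-stochastic $4\times4$
matrices $p(X|Z)$; the model-implied probability of an observed
(human, mouse, dog) triple is
$p(h,m,d) = \sum_r p(r)\,p(h|r)\,p(m|r)\,p(d|r)$.
Estimation minimizes the sum of squared differences between the 64 implied
probabilities and the observed triple frequencies — 64 equations in 39
free parameters.

Choices we had to make that the problem statement leaves open:

* **Constraint handling.** Rows and the ancestral vector are expressed as
  softmax transforms of unconstrained logits (52 logits, 13 of them
  redundant), so a quasi-Newton search (BFGS with analytic gradients,
  implemented in C++ with a pure-R reference kept for testing) never
  leaves the feasible set. Penalties or projected gradients would work
  too; the softmax keeps the objective smooth.
* **Restarts.** Ten random starts, uniform on each simplex, with seeds
  derived deterministically from a master seed, plus one data-informed
  start (ancestral vector from the mean descendant marginal,
  near-identity matrices). The extra start matters for highly conserved
  positions, whose optimum lies near the simplex boundary where random
  starts tend to stall in local minima. Each start runs a cheap descent;
  the best is polished to tight tolerance (relative tolerance 1e-15,
  up to 1000 iterations).
* **Label anchoring.** The objective is *exactly* invariant under a joint
  permutation of the ancestral states (permute $p(Z)$ together with the
  matrix rows), so every dataset has 24 equivalent global minima. We
  return the permutation that maximizes the summed matrix diagonals: the
  ancestor of a position is the state that is predominantly conserved.
  Without this anchor the restart that happens to win decides the
  labelling arbitrarily.
* **Identifiability.** A matrix row whose ancestral mass is below 1e-3
  receives essentially no gradient; such rows are flagged and excluded
  from recovery claims. More broadly, the elementwise precision of a row
  scales with the number of effective observations $n\,p(Z=r)$: at
  $n=5000$, a row with 7% ancestral mass rests on ~350 observations and
  its entries carry binomial-scale errors of a few percent. Tests assert
  0.03 elementwise accuracy where a row has at least 500 effective
  observations and 0.08 on the rare-ancestor rows of strong-consensus
  positions.
* **Parsimony ties.** The parsimony alternative assigns each site's
  ancestor by majority among the three descendants; when all three
  differ, the site contributes 1/3 of a count to each candidate — an
  unbiased split among equally parsimonious labelings. Never-observed
  ancestor rows fall back to the identity row (conservation), keeping the
  matrices stochastic.

## Strengths, neutral controls, and ω

Position strength is the PWM log-odds $W(\alpha,i)=\log_2
p_F(\alpha,i)/0.25$ against a uniform background. The foreground comes
from the pooled human+mouse+dog descendant sequences by default (an
ancestral-PWM variant using the fitted $p(Z)$ is exposed for comparison);
a pseudocount of 0.5 per nucleotide keeps $W$ finite at near-consensus
positions. The base is 2 (bits); every sign and every ratio statistic
(covariances, ω) is base-invariant, which the tests verify numerically.

The neutral expectation for a position pools joint ancestor–descendant
probability matrices from presumed-unconstrained positions and
row-normalizes: the donor intron +7…+12 for donor intronic positions,
frame-matched exonic pairs ({−4,−7} for −1, etc.) for exonic positions.
Acceptor intronic positions have no clean local control (the
polypyrimidine tract has no sharp boundary), so they borrow the donor
intron control from a companion donor dataset of the same splicing type —
the published site tables do not link acceptor and donor sites of the same
exon, so pooling the companion file is the closest feasible reading of
"the intronic region of the donor site of the same exon".

The observed strength change of a position is
$\Delta\hat W_O = \hat W(\text{descendant, empirical}) - \hat
W(\text{ancestor}, p(Z))$; the expected change applies the neutral matrix
to the fitted ancestor. The relative strength change
$\omega = (\Delta\hat W_E - \Delta\hat W_O)/\Delta\hat W_E$ is 0 under
neutral drift and 1 under perfect preservation. When
$|\Delta\hat W_E| < 10^{-9}$ the ratio is reported as undefined rather
than exploded; note that positions with weak consensus have small
$\Delta\hat W_E$, and their ω is intrinsically unstable — the bootstrap
CI, not the point estimate, is the meaningful summary there.

## Bootstrap

All significance statements resample *site triples* with replacement — a
site moves as a unit across positions and branches — 1,500 trials by
default, percentile 95% intervals, and two-sided sign-counting p-values
floored at 1/trials. Model-dependent statistics are re-estimated per trial
by a warm-started descent from the full-data solution (tolerance 1e-9):
resampled frequency tables are small perturbations, and cold 10-restart
fits per trial would multiply the cost ~50-fold without changing the
replicates. Resampling uses canonically sorted ids, so permuting the input
order changes nothing.

## Simulation under independent evolution

To ask whether substitutions at different positions depend on each other,
each site's descendants are re-simulated position by position: the
simulated nucleotide is drawn from the ancestral posterior given the real
triple, pushed through the branch's own matrix. All three branches are
re-simulated, conditioned on the same real triple but drawn independently.
Draws use inverse-CDF sampling in fixed A,C,G,T order for cross-platform
seed reproducibility. Two properties matter for interpretation: simulated
marginals converge to the fitted model's marginals, and — because the
simulation conditions on the real triple — covariance that lives in the
*ancestors* is retained by construction. The real-minus-simulated
covariance comparison therefore detects only epistasis in the substitution
process itself, which is exactly the question it is meant to answer. The
comparison's point estimate subtracts the mean covariance of 20 full-data
re-simulations; its p-values come from a paired bootstrap in which every
trial resamples sites and regenerates one simulated dataset.

## PPT dinucleotide analysis

Within the acceptor polypyrimidine tract (positions −12…−7) we count all
overlapping adjacent pairs, pooled over sites, and divide by the
expectation from the region's pooled mononucleotide content. Overlapping
pairs are counted because that is what a first-order Markov estimate needs
and the standard in dinucleotide-bias statistics. The shuffling control
fits a first-order Markov chain (initial = first-position frequencies,
transitions = conditional pair frequencies; never-observed conditioning
rows fall back to uniform and are flagged) and regenerates only the region,
preserving pair content while destroying dependencies at lag ≥ 2.
Run-length histograms of tandem dinucleotide repeats complete the picture.

## The synthetic generator, and what passing tests do not show

`generateTriples` draws, per site: an ancestor class (optional coupling),
ancestral nucleotides per modelled position, and three independent branch
descendants per position. Invariant dinucleotides are inserted; all other
offsets are flanks. Study-condition defaults, chosen once:

* **Consensus shape.** Donor ancestral vectors peak at the consensus
  MAG|GTRAGT with weights 0.40–0.80 (strongest at −1(G) and +5(G)),
  matching the qualitative profile of mammalian donor sites; branch
  conservation is 0.93 per position with substitutions biased toward the
  consensus.
* **Flanks.** Ancestor flanks are i.i.d. with GC 0.42 (intron-like), then
  evolved along each branch through a neutral flank matrix
  (`neutralFlankMatrix`, conservation 0.75). Purely i.i.d. flanks in all
  three genomes would present the neutral-control estimator with
  uncorrelated triples — unlike any real flank — and would make "evolving
  with the neutral matrix" unconstructible; evolving them on the same
  star tree keeps the controls honest and gives ω-recovery tests their
  ground truth.
* **Ages** are lognormal (meanlog 0.1, sdlog 0.75), putting roughly 45%
  of sites under the 1 K~s~ young/old threshold, so both strata are
  populated.
* **Coupling** has two levels, used together by
  `defaultGeneratorSpec(coupled = TRUE)`: a two-class ancestor mixture
  (strong-exon/weak-intron vs the reverse) that creates standing
  exon–intron anticorrelation, and a substitution-level knob that
  switches the intronic matrices on the exonic −2 ancestor (drift when
  the exon is consensus, frozen otherwise) — epistasis in substitutions,
  which is the only planted signal the independence comparison can see.
* **PPT bias** (acceptors): a pyrimidine-rich chain with a near-zero
  A→G transition (the AG-exclusion zone) and a depressed C→G step.

What the generator does not emulate: indels and alignment error, loss or
gain of sites, GC-content heterogeneity along the intron, CpG
hypermutability as a process (CG depletion is imposed, not evolved),
branch-length asymmetry between the three lineages, and any linkage
between donor and acceptor sites of the same exon. Passing the property
suite therefore shows that the estimators recover what they model — not
that real splice sites satisfy the model.

## Problem sizes and numerics

The test suite and the acceptance script use: n = 5000 for parameter
recovery (the scale at which 0.03 elementwise precision is attainable for
well-populated rows), n = 4000 for covariance calibration and planted
coupling (matching the scale of the real constitutive-site samples),
n = 3000 with 200 bootstrap trials for ω recovery, 10⁵ draws for sampler
calibration, and 1000 runs × 1500 trials for CI coverage. Degenerate
inputs are handled explicitly: empty datasets and zero-usable-position
counts raise errors; an observation impossible under a model raises a
degenerate-posterior error rather than returning NaN; covariance cells
with fewer than two complete pairs are reported missing; bootstrap trials
whose statistic fails are dropped and counted, with more than 10% dropped
aborting the run.

## Known limitations

The star phylogeny ignores the short human–mouse internal branch, slightly
inflating apparent mouse–human independence. Least squares on triple
frequencies is the prescribed estimator but is not efficient relative to
multinomial maximum likelihood, and the latent ancestor makes rare-row
entries noisy at realistic sample sizes. Covariance p-values are reported
raw, with no multiple-testing correction, mirroring how such matrices are
usually presented — cells should be read jointly, not cherry-picked. The
acceptor neutral control borrows the donor intron of a *different* set of
exons, a pooling approximation. ω is a ratio statistic and explodes where
the neutral expectation is near zero; always read it with its CI.
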