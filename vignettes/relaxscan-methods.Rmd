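---
title: "Drift versus selection in symbiont genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift versus selection in symbiont genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Vertically inherited bacterial symbionts pass through a tight
population bottleneck every host generation.  The resulting small
effective population size weakens selection relative to drift, which
leaves a genome-wide signature: elevated dN/dS, accumulating
pseudogenes, and gene loss.  `relaxscan` implements the comparative
machinery used to quantify that signature for a symbiont clade nested
among free-living relatives: a branch-partitioned codon model that
asks, orthogroup by orthogroup, whether the symbiont branches evolve
under a *drift-affected* (relaxed) or *selection-dominated*
(intensified) regime; genome-wide per-branch dN/dS; parsimony mapping
of gene losses; and enrichment analyses over pathway annotations.

## The codon model

The substitution process acts on the 61 sense codons of the standard
genetic code.  Following the MG94xHKY parameterization, a single
nucleotide exchange from codon $i$ to codon $j$ occurs at rate

$$q_{ij} = \kappa^{\,1[\mathrm{transition}]}\;
          \omega^{\,1[\mathrm{nonsynonymous}]}\; f_p(b),$$

where $\kappa$ is the transition/transversion ratio, $\omega$ the
nonsynonymous/synonymous rate ratio, and $f_p(b)$ the F3x4 frequency of
the target nucleotide $b$ at the changed codon position $p$; exchanges
touching more than one position have rate zero, and stop codons are
outside the state space.  With F3x4 stationary frequencies this
process is time-reversible (detailed balance holds exactly), so the
likelihood is invariant to root placement and the transition
probabilities $P(t) = e^{Qt}$ can be computed through the
eigendecomposition of the symmetrized generator
$D^{1/2} Q D^{-1/2}$.

Site-to-site variation in selective pressure is modeled by a mixture
of $\omega$ categories $\{(\omega_c, p_c)\}$ (three by default — a
descriptive compromise between flexibility and the number of free
parameters a few hundred codons can support; configurable).  Each site
draws one category for the whole tree.  Generators are rescaled so one
unit of branch length equals one expected substitution per codon site
under the reference-branch mixture; the simulator and the estimator
share this convention.

## The branch-partitioned relaxation test

Branches of the rooted species tree are partitioned into `test` (the
symbiont clade: its terminal branches and the internal branches
ancestral only to it), `reference` (everything else), and `excluded`
(the symbiont stem branch, along which the transition to symbiosis
happened at an unknown point, so it belongs to neither regime; in the
likelihood, excluded branches simply evolve under the reference
omegas).  On test branches every category's ratio is raised to a power
$k$: $\omega_c \mapsto \omega_c^{\,k}$.  Because $x^k$ pulls values
toward 1 when $k < 1$ and pushes them away when $k > 1$, $k$ measures
whether the whole distribution of selective effects is compressed
toward neutrality (drift-affected) or spread away from it
(selection-dominated) on the symbiont side.

The hypothesis test compares the null model ($k = 1$) with the
alternative ($k$ free) by a likelihood-ratio test with one degree of
freedom.  $k = 1$ is interior to the parameter space, so the plain
$\chi^2_1$ reference distribution applies with no boundary correction.
Per orthogroup, raw p-values are corrected across all converged fits
with Benjamini–Hochberg, and each orthogroup is labeled
`drift-affected` (corrected $p \le \alpha$, $\hat k < 1$),
`selection-dominated` (corrected $p \le \alpha$, $\hat k > 1$) or
`not-significant`, with $\alpha = 0.1$ by default.  We use $\le$ on
the boundary.

### How the fit is organized

Likelihood evaluation is Felsenstein pruning over site patterns,
implemented in compiled code with per-rate-class generators; codons
containing a gap or ambiguity are missing data (partial-likelihood
vectors of ones), preserving per-taxon information instead of dropping
whole columns.

The optimization is deliberately structured:

1. **Stage A** fits a single-$\omega$ model for $\kappa$, one global
   branch-length scale, and $\omega$ (Nelder–Mead over log-transformed
   parameters).  Branch lengths are taken from the species tree *up to
   that one global scale*.  Refitting every branch length under a
   single-$\omega$ model would absorb part of the $\omega^k$ signal
   into the test-branch lengths and bias $\hat k$ toward 1; holding
   relative lengths fixed keeps the generating process inside the
   fitted family.
2. **Stage B** fits the mixture.  The category weights are profiled
   out of the outer problem by an inner EM on the per-category pattern
   likelihoods: once the free branch scale absorbs the mixture-rate
   normalization, the weights are pure mixture weights and their
   conditional optimum is a small concave subproblem.  The outer
   optimization (omega increments on the log scale, scale, and for the
   alternative $\log k$) is Nelder–Mead followed by a quasi-Newton
   (finite-difference BFGS) polish, whose local quadratic convergence
   removes Nelder–Mead's slow tail.
3. The alternative starts from the null solution with a deterministic
   $k$ multistart ($k \in \{0.2, 1, 5\}$ probe points plus a 1-D
   bracket refinement), and the null is then *re-polished from the
   alternative's solution*.  This symmetry matters: if the alternative
   received more optimization effort than the null, the LRT would be
   inflated and the type-I error would drift upward.
4. A fit is declared non-converged when the polish stage fails to
   stabilize (a restart still improves the log-likelihood by more than
   0.01); such orthogroups are labeled `failed` and excluded from the
   BH family, mirroring how non-converging orthogroups are dropped in
   practice.

Because the alternative nests the null, $\ln L_{alt} \ge
\ln L_{null}$ is enforced by construction (the alternative can always
adopt the null solution with $k = 1$); the LRT statistic is clamped at
zero.

## Per-branch dN/dS

Genome-wide rates come from a separate "local" MG94 fit on the
concatenated single-copy alignment: every branch has its own $\omega$
and its own length (expected substitutions per codon site under its
own process), with shared $\kappa$ and F3x4 frequencies, optimized by
coordinate ascent (a global $\kappa$ sweep alternating with per-branch
$(t, \omega)$ optimization).  Expected substitutions are split into
synonymous and nonsynonymous classes and divided by the site fractions
of the neutral ($\omega = 1$) process, a convention under which
dN/dS equals the branch's fitted $\omega$ exactly — a property the
tests assert to $10^{-9}$.  Branches with $dS < 5\times10^{-5}$ are
masked: at that depth a ratio denominator is numerical noise.  The
pairwise-dS genome subsampling control removes a minimal set of
genomes so that every retained pair has $dS$ above 0.01; the removal
set is a minimum vertex cover of the conflict graph, found exactly for
up to 22 conflicted genomes (enumeration in increasing size,
lexicographically smallest optimum), with a greedy most-conflicted-
first fallback beyond that.  The exact search replaces a pure greedy
rule because greedy max-degree does not always attain the minimum, and
minimality is the property the accounting relies on.

## Genome accounting

Orthogroup bookkeeping follows a small set of rules with large
consequences:

* **Annotation propagation** is inclusive: every gene name, KO and
  pathway attached to any member locus propagates to the whole
  orthogroup; disagreements between member gene names are flagged, not
  resolved.
* **Pseudogenes** never enter alignments.  They are assigned to the
  orthogroup of their lowest-e-value hit among intact loci (ties:
  higher bit score, then lexicographically smallest orthogroup id, so
  the assignment is deterministic), and annotations reach them through
  the orthogroup.
* **Core/pan genomes** are computed at the orthogroup level or at the
  annotation level.  At the annotation level a gene counts as intact
  in a genome if *any* orthogroup carrying that annotation has an
  intact locus there — no single orthogroup needs to be core for the
  gene to be core.
* **Eligibility** for the relaxation test: genomes contributing more
  than one locus to an orthogroup are dropped from it first (paralogs
  violate the model), then at least three single-copy ingroup and
  three single-copy outgroup genomes are required.
* **Gene loss** is mapped by Dollo parsimony: the genes analyzed are
  core to the free-living relatives, so ancestral presence is forced
  and evolution is losses-only.  Under that constraint the
  minimum-loss reconstruction is unique — one loss on the stem of each
  maximal absent clade — which also realizes the rootward tie-break
  (one stem loss rather than several below it).  Loss branches can be
  annotated with externally supplied divergence-age intervals; the
  package never computes dates.

## The synthetic-data generator

`simulate_dataset()` generates every input the pipeline consumes, with
the statistical structure the analysis assumes: a species tree whose
symbiont ingroup is a short-branched monophyletic clade (branch
lengths scaled by 0.15 by default, stem 0.2, free-living branches
0.05–0.35 expected substitutions per codon site); per-orthogroup codon
alignments evolved forward under the mixture model with the configured
ingroup $k$ (default a point mass at 0.5, the genome-wide regime the
analysis is designed to detect) and a lognormal per-orthogroup rate
multiplier (sd 0.25); and the derived tables — intact / pseudogene /
absent statuses with a 10-fold ingroup excess in pseudogene rates
concentrated in a pseudogene-prone subset of orthogroups (15% prone;
within a prone orthogroup, ingroup genomes pseudogenize at 0.5 and
free-living at 0.05), multicopy loci, a small unplaced-locus fraction,
pathway labels, and a pseudogene-vs-gene hit table whose best hit
points at the true orthogroup.  Genome lengths derive from coding
content through clade-typical coding densities (symbionts lowest), so
the length/gene-count collinearity of real panels holds.  One pathway
is *planted*: its orthogroups are pseudogene-prone at three times the
baseline rate, giving the enrichment stage a known positive.  A single
global seed derives per-orthogroup child seeds by counter, so any
subset regenerates independently and byte-identically.

Desk-scale defaults (8 + 12 genomes, 60 orthogroups of 300 codons)
shrink a multi-thousand-orthogroup genome panel to sizes a laptop
fits in minutes; the acceptance checks run the recovery suites on
12-taxon, 600-codon replicates and the pipeline check on a 40-
orthogroup scan.  The planted-enrichment check runs at table scale (a
60-orthogroup pathway in a 400-orthogroup panel): an exact binomial
test at a 3-fold contrast has essentially no power at a dozen
category members, and when the planted block is a large share of the
annotated family the empirical null absorbs its own signal, so the
planted condition is only meaningful where the category is large and
a minority of the family.  What passing these tests shows is that the
implementation recovers truths planted *under its own model*; real
data add alignment error, recombination, model misspecification and
annotation noise that the generator deliberately does not emulate.

## Numerical choices and limitations

* F3x4 frequencies use a 0.5 pseudocount per (position, nucleotide)
  cell so the reversible similarity transform stays defined on short
  alignments.
* Transition matrices are eigendecomposition-based with clamping of
  tiny negative entries; partial likelihoods are rescaled per pattern
  to avoid underflow.
* The two-sided binomial test uses the minimum-likelihood convention
  of the classical exact test (sum of all outcome probabilities no
  larger than the observed one, with the standard $1+10^{-7}$
  comparison tolerance).
* The empirical null for enrichment is recomputed from the supplied
  (already filtered) results table, never from stale genome-wide
  totals.  Pseudogene enrichment is restricted to orthogroups with
  loci in at least six genomes and a pathway annotation.
* Known limitations: no synonymous-rate variation across sites, HKY
  rather than GTR nucleotide exchangeabilities, ambiguity codes beyond
  gaps are treated as missing, and the relaxation test reports no
  site-level posteriors.  These mirror the scope of the analysis the
  package reproduces.
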