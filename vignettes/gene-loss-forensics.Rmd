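---
title: "Gene-loss forensics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-loss forensics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudochron)
```

## The problem

A protein-coding gene that has become dispensable stops being policed by
purifying selection. Its coding sequence then accumulates frameshifting
indels, premature stop codons and start-codon losses, and — more subtly —
its nonsynonymous substitution rate drifts up toward the neutral rate.
`pseudochron` reconstructs this history from three kinds of evidence:

1. **ORF forensics.** Observed exon sequences are compared against an
   intact reference to call disrupting mutations and classify each species'
   copy as intact, disrupted or missing.
2. **Event clustering.** Disruptions shared identically between species are
   treated as inherited from a common ancestor (Dollo parsimony: a complex
   character is lost once and never regained), so the species set of a
   shared mutation maps to a single loss event on the stem branch of its
   most recent common ancestor.
3. **Molecular dating.** On the branch where the loss happened (a *mixed*
   branch — functional for duration $t_f$, pseudogenic for $t_p$, total
   $T = t_f + t_p$), the observed dN/dS ratio $\omega_m$ is a rate-weighted
   mixture of the functional ratio $\omega_f$ and the neutral ratio 1.
   Solving the mixture for $t_p$ dates the inactivation.

## Scanning for disruptions

Each observed exon is globally aligned to its reference exon with affine
gap penalties (match $+1$, mismatch $-1$, gap open $-4$, gap extend $-1$).
Alignment columns are reduced to substitution/insertion/deletion records in
reference exon-local, 1-based coordinates; insertions anchor *after* a base
(position 0 = before base 1), and codon-anchored catalog entries resolve to
base coordinates through the exon phase (the number of 5'-terminal bases
completing the codon begun in the previous exon). The spliced observed
sequence is translated from its start; a stop codon is premature when its
aligned reference position falls before the reference terminal stop. A
gene is *disrupted* when it has at least one premature stop, a terminal
frame offset not divisible by 3, or a lost start codon. A substitution that
destroys the terminal stop is recorded as stop-loss but does not by itself
flag disruption.

Two conventions deserve note. First, when the optimal alignment is not
unique (for example two deletions separated by a few bases can score
exactly like one long gap plus compensating mismatches), the scanner
reports *an* optimal edit set deterministically; downstream logic treats
edit-equivalent catalogs identically, and the tests assert equivalence by
re-applying the recovered records. Second, exons shorter than 3 bases after
editing still contribute their bases to the spliced frame.

## Event inference

Two mutation records match when exon, kind, resolved position, length and
replacement agree. One asymmetry is allowed: a mutation *containing* a
shared mutation's interval at the same anchor (a longer insertion at the
same position, a deletion whose interval covers the shared one) counts as
the shared mutation plus a private extension — this is what joins a species
whose shared insertion has grown further into the clade event. Species are
clustered by single-linkage over shared mutations; each cluster becomes one
event on the stem branch of its MRCA (terminal branch for singletons). A
shared mutation across a non-monophyletic set is kept as one MRCA event and
flagged homoplastic rather than silently split. Event branches are labeled
`mixed`, everything below them `pseudogenic`, the rest `functional`; two
events nested on one root-to-leaf path are an error because a lineage
cannot lose the same gene twice.

## The codon model

Selection intensity is estimated under an MG94$\times$HKY codon model on
the 61 sense codons: single-nucleotide exchanges only, target-codon
frequency $\pi_j$, transition factor $\kappa$, nonsynonymous factor
$\omega$, matrix normalized to one expected substitution per codon at
equilibrium. Codon frequencies come from F3x4 by default (equal and F1x4
are selectable; the worked examples in this vignette use `equal` because
the simulator draws root codons uniformly). The likelihood is computed by
Felsenstein pruning with per-column scaling; gaps and ambiguous codons are
uninformative (all-ones partials), and in-frame stops — which occur
legitimately in pseudogenic sequences — are recoded as missing so the state
space stays on sense codons. Stops in a sequence declared functional are an
error, not data.

Fitting alternates two steps until the log-likelihood improves by less than
$10^{-6}$ (at most 8 passes): a bounded quasi-Newton step on
$(\log\kappa, \log\omega_1, \ldots)$, started from the best of a small grid
($\omega \in \{0.1, 0.5, 1.5\}$, $\kappa \in \{1, 2, 5\}$), and a Brent
pass over branch lengths using cached outside partials, accepted jointly
when it improves the likelihood and branch-by-branch otherwise. Branch
lengths start from the tree's time lengths scaled by the ratio of mean
pairwise codon divergence to mean patristic distance. Everything is
deterministic for fixed inputs.

The relaxation test compares a single shared $\omega$ against a separate
foreground $\omega$ (df = 1, $\chi^2_1$; the 50:50 boundary mixture is
available but off by default), and also reports the auxiliary test of
foreground $\omega$ fixed at 1.

## Dating the inactivation

With portion-specific synonymous rates $s_f$ and $s_p = r\,s_f$, equating
nonsynonymous accumulation on the mixed branch,

$$\omega_m\,(s_f t_f + s_p t_p) = \omega_f\,s_f t_f + s_p t_p,$$

gives

$$t_p = T\,\frac{\omega_m - \omega_f}{r\,(1 - \omega_m) + (\omega_m - \omega_f)},$$

which reduces to $t_p = T(\omega_m - \omega_f)/(1 - \omega_f)$ under the
one-rate (1ds) model. The two-rate (2ds) model uses
$\hat r$ = mean synonymous substitutions per MY on fully pseudogenic
branches divided by the same on functional branches, and collapses to 1ds
when no fully pseudogenic branch exists. $\omega_m$ estimates outside
$[\omega_f, 1]$ are clamped to the interval and flagged — sampling noise
can exceed the mixture bounds, and a clamp at 1 dates the loss at the top
of the branch. The reported range is the min/max over the two models (no
confidence interval unless the seeded site bootstrap is requested).
$\omega_f \ge 1$ is an error: if the functional class is not under
purifying selection the mixture carries no date information.

```{r dating-example}
obs <- mixed_branch_obs(T = 10, omega_f = 0.2, omega_m = 0.6, r = 2)
pseudogenic_time(obs)
```

## Retention and muscle-fiber composition

Gene retention (0/1) is regressed on the percentage of fast-glycolytic
(white) pectoralis fiber with a phylogenetic logistic model:
$\mathrm{logit}\,P(y_i = 1) = \beta_0 + \beta_1 x_i$, with working
correlation $\exp(-\alpha d_{ij})$ between species at patristic distance
$d_{ij}$ (MY), so $\alpha \to \infty$ recovers independence.
`logistic_IG10` solves the estimating equations with this correlation;
`logistic_MPLE` adds a Firth-type penalty ($\tfrac12 \log\det$ of the
working information), which keeps estimates finite under separation — a
real concern at $n \approx 24$ with strong effects. $\alpha$ is profiled by
a Gaussian working quasi-likelihood on a 13-point log grid over
$[10^{-4}, 10^4]$ and refined by Brent; boundary hits are flagged.
p-values for $\beta_1$ come from a Wald test, with a seeded parametric
bootstrap (default 499 replicates when requested) as the reporting option;
the large calibration studies in the test suite use the Wald p-value for
tractability. Since published analyses of this kind report significance
but not coefficient values, validation is sign- and calibration-based
rather than value-matching.

Ancestral fiber compositions are estimated per component under Brownian
motion — the GLS/ML solution minimizes squared changes weighted by inverse
branch length, a sparse linear system in the internal states — and then
renormalized to sum to 100 (an isometric log-ratio analysis was considered
and left out; componentwise estimation matches how such compositions are
usually displayed and keeps the convex-hull property per component).

## The synthetic-data generator

The simulator is the package's ground-truth instrument, not a fixture
dump. Codon sites evolve independently along the time tree by exact
stochastic simulation (per-site Gillespie jumps) from the MG94$\times$HKY
generator scaled to a neutral rate of 0.006 substitutions per codon per MY
(2e-9 per base per year, a typical mammalian nuclear rate). At a loss
point, evolution switches to neutral nucleotide-level HKY — stop codons are
then reachable and retained, since they are exactly the signal the scanner
must find — and an indel process starts: 0.002 indels per codon site per
MY, geometric(0.5) lengths, insertion/deletion with equal probability.
Indels never occur before inactivation (observed disruptions are post-loss
decay). Deleted codons appear as gaps in the reference-coordinate
alignment; insertions are applied to the emitted per-tip sequences and
logged in the truth table but excluded from the alignment matrix, which
stays in reference coordinates. The truth table records per-event
inactivation ages and per-branch realized synonymous/nonsynonymous event
counts; all generators are pure functions of (spec, seed).

What the generator does *not* emulate: assembly and sequencing error,
alignment uncertainty from diverged flanks, rate variation across sites
and lineages, GC-biased gene conversion, and biased codon usage drift.
Passing the recovery criteria therefore demonstrates correctness of the
inference chain under the stated model, not robustness to every artifact
of real genome assemblies.

The worked-example fixtures are engineered synthetic reference genes, not
real COA1 sequences: fillers avoid T entirely so stop codons can only
arise at motifs placed to be read in the intended frameshift class, which
makes every catalogued consequence (the exon of each premature stop, the
shared-deletion events, the start-codon loss) hold by construction and
verifiable by the scanner.

## Numerical choices and degenerate inputs

* Ultrametricity is checked to a relative tolerance of $10^{-6}$; leaf ages
  within tolerance are snapped to zero.
* Transition matrices come from the symmetrized eigendecomposition of the
  reversible generator; tiny negative entries from roundoff are clamped to
  zero, and pruning partials are floored at $10^{-300}$ with per-column
  log-scaling.
* Branch lengths are optimized in $[10^{-7}, 5]$ substitutions per codon;
  all-identical data drive them to the lower bound.
* In the logistic fit, coefficients are bounded at $\pm 12$ on the logit
  scale and steps are damped; the correlation matrix carries a $10^{-9}$
  ridge.
* Zero-length branches in the ancestral-state system are perturbed by
  $10^{-8}$ with a warning.
* Ties in alignment are broken by the aligner's deterministic placement;
  scanning is reproducible byte-for-byte.

## Problem sizes used in validation

The shipped validation suite runs: 100 end-to-end recovery datasets
(8 taxa, 300 codons, a 30 MY terminal mixed branch with truth 10 MYA,
$\omega_f = 0.15$); 200 null relaxation LRTs (6 taxa, 100 codons,
$\omega = 0.2$); 500 null and 100 strong-effect phylogenetic logistic fits
at $n = 24$; and brute-force likelihood enumeration on all test trees with
up to 4 taxa and 3 sites. The acceptance script recomputes the same
quantities at 30/100/200/100 replicates. These sizes are the package's
validation design; the underlying functions accept arbitrary problem
sizes.

## Known limitations

* Dating rests on the mixture premise ($\omega = 1$ after loss, constant
  $\omega_f$ before); lineage-specific shifts in selective constraint
  masquerade as earlier or later losses.
* A single mixed branch contributes on the order of tens of substitutions
  at typical rates, so individual inactivation ages carry several MY of
  sampling noise; ranges over the 1ds/2ds models understate this.
* Mutation identity across species assumes a correct orthologous
  alignment; paralog mixing would create spurious shared events.
* The breakpoint detector works at adjacency level only; it does not
  reconstruct rearrangement order or mechanism.
* The RELAX-style selection-intensity parameterization and branch-site
  models are out of scope; the branch model here detects shifts in mean
  $\omega$ only.
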