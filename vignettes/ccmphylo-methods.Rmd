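---
title: "Models and methods in ccmphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ccmphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmphylo)
```

`ccmphylo` studies how members of a multigene family are recruited
("co-opted") into the C4 and CAM carbon-concentrating pathways — the
motivating case being the phosphoenolpyruvate carboxylase (PEPC) family,
whose *ppc* lineages have repeatedly evolved C4- and CAM-specific forms.
Three kinds of evidence are computed: branch-site codon-model tests of
adaptive protein evolution on a-priori foreground branches; phylogenetic
assignment of transcriptome contigs to gene lineages with
reads-per-million (rpm) quantification across diel/drought conditions; and
diagnostic-residue screening against a reference protein numbering
(the Ser780/Ala780 marker). A synthetic-data layer generates every input
the pipeline needs, so all claims the package makes about itself are
testable without any sequence downloads.

## Codon substitution model

The engine is a Goldman–Yang-style codon model over the 61 sense codons of
the standard code. The instantaneous rate from codon $i$ to $j$ is

$$q_{ij} = \begin{cases}
0 & \text{more than one nucleotide change} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}$$

with $\kappa$ the transition/transversion rate ratio, $\omega = d_N/d_S$,
and $\pi$ the stationary sense-codon frequencies. Frequencies default to
the F3x4 estimate (products of position-specific nucleotide frequencies,
renormalized over sense codons), computed from the alignment and held
fixed; nine free frequency parameters are counted. Zero frequencies are
floored at $10^{-8}$ and renormalized so the chain stays irreducible.

Site-class mixtures follow the standard model family:

* **M0** — one $\omega$ for all sites and branches.
* **M1a** — "nearly neutral": a purifying class ($\omega_0 < 1$,
  proportion $p_0$) and a neutral class ($\omega = 1$).
* **M2a** — M1a plus a selected class $\omega_2 \ge 1$ on all branches.
* **model A** — the branch-site model: classes 0 and 1 as in M1a
  everywhere; classes 2a/2b behave like 0 and 1 on background branches but
  share $\omega_2 \ge 1$ on the foreground branches, with proportions
  $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and
  $p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0+p_1)$. The null variant fixes
  $\omega_2 = 1$.

Branch lengths are measured in expected substitutions per codon under the
mixture; all class generators share one scaling factor, the
proportion-weighted mean background rate. Because the simulator uses the
identical convention, forward simulation followed by fitting closes the
loop exactly — the core consistency property the test suite leans on.

Likelihoods are computed by Felsenstein pruning over compressed site
patterns, with transition probabilities from an eigendecomposition of the
generator in the $\pi$-symmetrized basis (the generator is reversible, so
the symmetrized matrix has a real spectrum; tiny negative probabilities
from roundoff are clamped to zero). Per-edge rescaling of partial
likelihoods guards against underflow. Gaps, stop codons and codons
containing IUPAC ambiguity codes contribute all-ones partials (fully
missing) — the conservative convention, chosen because gene-family
alignments legitimately contain pseudogenes with stop codons. The
nucleotide engine (GTR+$\Gamma$, used for placement) instead interprets
IUPAC codes as partial information, which is standard for single-base
states; its discrete Gamma uses four equal-probability categories with
mean-1 rates.

## Fitting, tests and model ranking

M0 is fitted by joint maximization over branch lengths (log scale),
$\log\kappa$ and $\log\omega$ with a bounded quasi-Newton optimizer. A
three-parameter pre-stage (common branch length, $\kappa$, $\omega$)
supplies the start, and the branch-length gradient is computed analytically
by the standard two-pass (up/down partial) algorithm, with finite
differences only for $\kappa$ and $\omega$. Mixture models (M1a, M2a,
model A) then keep the M0 branch lengths fixed — tractable at desk scale
and close to common practice — and optimize $\kappa$ plus the mixture
parameters on their natural scales under box constraints
($\omega_0 \in [10^{-4}, 1]$, $\omega_2 \in [1, 50]$,
$\kappa \in [0.01, 100]$); the two-proportion simplex is parameterized as
the box $(s = p_0 + p_1,\; r = p_0/s)$. Mixture fits use three optimizer
starts by default (one informed, two seeded jitters); fits are bit-for-bit
reproducible given data, seed and restart count.

Parameter counts follow the convention of the model family's standard
software: branch lengths + 9 frequency parameters + $\kappa$ + mixture
parameters (1 for M0, 2 for M1a, 4 for M2a and model A), so M2a and model
A each add two free parameters over M1a. The LRT of model A against M1a
uses df = 2; against its $\omega_2 = 1$ null, df = 1. The statistic is
clamped at zero when the alternative optimum does not exceed the null —
with $\omega_2$ on the boundary the null distribution is a mixture
stochastically below $\chi^2$, so the test is conservative, which the
calibration study confirms. `rank_hypotheses()` sorts fits by
AIC $= 2k - 2\ln L$ with a $\Delta$AIC column; a difference above 10
(configurable) is annotated as decisive, and ties break toward fewer
foreground branches, then name. The headline quantity of a model A fit is
the foreground site fraction $p_{2a} + p_{2b} = 1 - p_0 - p_1$.

## Annotating contigs and quantifying lineages

A contig is first scanned against the ungapped reference sequences by
local alignment (match +1, mismatch −2, affine gap penalties 5/2, both
strands); the matched region must be strictly longer than `min_len`
(50 bp by default; 500 bp is the appropriate setting when screening
external transcriptome assemblies). The segment is then aligned into the
fixed-column reference alignment against position-specific nucleotide
frequencies; reference columns are never created or destroyed, and query
characters that would need new columns are dropped (counted), so every
augmented alignment shares the reference coordinate system and placements
are comparable across contigs.

Placement attaches the query by a pendant edge at the midpoint of each
reference branch in turn, optimizes the pendant length under GTR+$\Gamma$,
and records the log-likelihood. Rather than re-inferring a full tree per
contig, the reference topology is held fixed — the same nesting
information at a fraction of the cost. "Clearly nested within a lineage"
is made operational as: the best attachment branch lies strictly inside
the lineage's clade (not on its stem) *and* the likelihood weight ratio
(softmax of per-branch log-likelihoods) is at least 0.8 by default.
Raising the threshold can only shrink the assigned set.

rpm is reads per million alignable reads
($\mathrm{rpm}_i = c_i / N \times 10^6$); lineage abundance is the sum of
rpm over assigned contigs, with an explicit `unassigned` bucket so
per-sample totals are conserved exactly.

## Residue diagnostics

Queries are globally aligned to the reference protein (BLOSUM62, affine
gaps 10/0.5) and reference positions are read off the alignment; numbering
is 1-based on the ungapped reference, and alignments under 30% identity
are flagged unreliable. Position 780 is classified — serine is the
recurrent C4/CAM-associated state, alanine the conserved state of
non-CCM PEPCs, anything else (including a gap) "other". Other listed
positions (531, 572, 665, 761) are reported descriptively only, since they
are examples of convergent change rather than binary criteria. Protein
rather than codon-level mapping is used: the diagnostic is an amino-acid
state. Packaged tests use a synthetic 970-residue stand-in for the maize
reference; the real CAA33317 sequence is a user-supplied input, never
fetched.

## What the synthetic data does and does not emulate

`simulate_codon_alignment()` draws a class per site, root codons from
$\pi$, and evolves each branch with the class's (foreground or background)
generator — so fitted models see data from exactly the process they
assume. `simulate_reference_panel()` builds lineage clades with deep stems
(0.25–0.5 substitutions/site) and shallow within-lineage divergence
(≤ 0.08), the signature of a family shaped by ancient duplications.
`simulate_diel_experiment()` fragments lineage sequences (uniform start,
clamped-normal length around 500 bp, 2% point mutations, random strand)
and draws per-sample read counts multinomially from a $10^6$-read library,
so expected rpm equals the planted design. The default design places five
lineages in eight samples (two individuals × two watering regimes × day
and night) with one day-dominant C4-like lineage and one CAM-like lineage
induced more than 100-fold at night under infrequent watering — the
qualitative diel pattern of a facultative CAM plant that uses C4
photosynthesis.

Deliberately not emulated: alignment error (codon columns are simulated
gap-free), indel evolution, read-level sequencing noise and mapping
ambiguity (counts substitute for reads), assembly chimerism, and
model misspecification (real sequences do not evolve under the fitted
family). Passing tests therefore demonstrate internal correctness and
statistical calibration under the model, not robustness to those
real-data pathologies.

## Reference simulation studies

The `study_*()` functions freeze the package's working conditions:
$\kappa = 2.5$, $\omega_0 = 0.1$; null simulations use M1a with
$p_0 = 0.7$; the power study plants $\omega_2 = 2$ on a 20% site fraction
($p_0 = 0.5$, $p_1 = 0.3$); the recovery study plants fraction 0.107 with
$\omega_2 = 1.35$ — the magnitude reported for adaptive PEPC evolution at
the base of C4 clades — split $p_0 : p_1 \approx 0.6 : 0.29$. Foreground
branches are the longest internal branches of the simulated tree (two for
calibration/power, three for recovery), chosen a priori because long
internal branches carry the most substitution signal, as real foreground
clades do. Problem sizes are 8 taxa × 300 codons (calibration, 200
replicates), 8 × 500 (power, 50 replicates), 12 × 600 (recovery, 20
replicates), and 100 placed queries on a 5-lineage × 4-taxon panel of
1200 columns; the simulation loops use a single optimizer start from the
informed initial values, which the low-dimensional mixture likelihoods
tolerate well.

## Known limitations

* Branch lengths are not re-optimized under the mixture models; very long
  branches combined with strong selection could bias $\omega_2$ upward.
* F3x4 is the only frequency model currently wired into fitting.
* The placement lwr is a relative confidence among reference branches; a
  query from an unsampled lineage can still be confidently (and wrongly)
  placed inside its nearest sampled relative.
* "Identical sequences" in `dedupe_keep_longest()` means exact substring
  containment; near-duplicates with sequencing errors are retained.
* The LRT's conservatism under the boundary null means df = 2 p-values are
  upper bounds; no attempt is made to use the mixture null distribution.
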