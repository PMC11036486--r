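---
title: "Restraining fixed-backbone sequence design with language-model probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraining fixed-backbone sequence design with language-model probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspmdesign)
```

## The problem

Fixed-backbone sequence design searches for amino-acid sequences that are
low-energy for a given backbone.  Energy-guided combinatorial design is
known to drift toward compositions that a protein language model (PLM)
considers highly improbable — most notoriously, hydrophobic residues on the
solvent-exposed surface.  One remedy is to let the PLM's per-position
amino-acid probabilities restrain the design energy: run an unrestrained
first round, ask the model for a position-specific probability matrix
(PSPM) of the best first-round sequence, convert that matrix into a
per-residue profile bonus, and redesign under the combined energy.  This
package implements that two-round workflow end to end, together with the
audits used to characterise it (worst-position analysis, burial-layer
breakdown, sequence recovery, score correlations), in a form that runs
offline and deterministically.

## Scores and matrices

**Pseudoperplexity.** A sequence $x_1 \dots x_L$ is scored against an
$L \times 20$ probability matrix $p$ as

$$\mathrm{PPL}(x) = \exp\!\Big(-\tfrac{1}{L}\sum_{i=1}^{L}\ln p_i(x_i)\Big),$$

the exponential of the mean negative log-probability of the realised
residues (natural logarithm paired with natural exponentiation).  It is
bounded below by 1, reached exactly when every realised residue has
probability 1, and a matrix that is uniform at every position gives exactly
20 for any sequence.  Lower is more probable.

**Masked marginals.** `maskedMarginals()` builds the PSPM one position at a
time: row $i$ is the provider's distribution for the sequence with position
$i$ masked and everything else as given.  This is the canonical scoring
mode; a cheaper single-unmasked-pass mode exists (`mode = "unmasked"`) but
is flagged non-canonical, because providers that can see the queried
residue tend to echo it.

**Profile restraint.** `pspmToProfile()` turns a PSPM into a
`SequenceProfile` in one of three scalings: `logodds`
($s_{ia} = \mathrm{scale}\cdot\ln(p_{ia}/b_a)$, probabilities floored at
`floorProb` first), `prob` (raw probabilities) or `global` (probabilities
divided by the matrix maximum).  The restraint energy of a sequence is the
per-residue bonus

$$E_\mathrm{restraint} = -w \sum_i s_{i,x_i},$$

linear in the weight $w$ and additive over positions.  The profile is
computed once, before the restrained round, and is **never updated during a
design trajectory**: the matrix represents conditional probabilities given
the query context, and re-deriving it after every substitution would
multiply the query cost by the trajectory length.  Design under a fixed
conditional profile does not guarantee samples from the model's joint
distribution; it is a deliberate, documented approximation.

Defaults: `logodds` mode, uniform background $b_a = 1/20$ (no external
frequency tables), scale 1, floor $10^{-6}$, weight $w = 1$.  The weight is
ordinary config, not a constant; $w = 0$ reproduces unrestrained design
trajectory-for-trajectory at equal seeds, and a very large $w$ with a flat
base energy forces the per-position argmax of the PSPM.

## The coarse design energy

All-atom energy functions, rotamer packing and structure relaxation are out
of scope here.  The design energy is a sequence-level stand-in:

$$E_\mathrm{base}(x) = \sum_{(i,j)\in\mathcal{C}} U(x_i, x_j)
  + \sum_i r(x_i),$$

where $\mathcal{C}$ contains residue pairs with side-chain proxy atoms
(C$\beta$, C$\alpha$ for glycine) within 8 Å and sequence separation
$\ge 2$.  The bundled 20×20 table $U$ is built from Kyte–Doolittle
hydropathy $\tilde h$ (scaled to $[-1,1]$) and formal side-chain charge
$q$:

$$U(a,b) = -0.6\,\tfrac{\tilde h_a + \tilde h_b}{2}
           \;-\; 0.3\,\tilde h_a \tilde h_b \;+\; 0.4\, q_a q_b ,$$

a burial term that rewards hydrophobics at contact-rich (buried) positions,
a like-with-like mixing term, and a like-charge penalty.  The reference
energies $r(a) = 0.2\,\tilde h_a$ act as a mild composition penalty.  The
table is deterministic, symmetric, and fully replaceable through
`EnergyModel()`.  It reproduces the pathology the restraint is meant to
fix: unrestrained design covers the surface with aliphatic residues.

## Layers, secondary structure, and LayerDesign

Burial is measured by Shrake–Rupley quadrature over a deterministic
Fibonacci sphere point set (960 points per atom by default, probe 1.4 Å,
radii N 1.55 / C 1.70 / O 1.52 Å) on the backbone+CB atoms only — a burial
proxy, not an all-atom SASA, since side chains do not exist in this
representation.  Residues are classified core (SASA ≤ 20 Å², inclusive),
surface (≥ 40 Å²) or boundary; the cutoffs are configuration, chosen for
the backbone+CB proxy, not published values.  Secondary structure is a
simple dihedral-region assignment (helix for $\phi \in [-100,-30]$,
$\psi \in [-80,-5]$; strand for $\phi \in [-180,-80]$,
$\psi \in [80,180] \cup [-180,-170]$; loop otherwise, termini loop, H/E
runs shorter than 3 demoted).  The layer-design task allows
`A F I L M P V W Y` in the core, `D E G H K N P Q R S T` on the surface,
their union at boundary positions, and additionally glycine at loops; the
sets are a documented simplification, overridable via `layerRules()`.

## The packer

`pack()` runs Metropolis simulated annealing over single-position
substitutions: per sweep, $L$ attempts of (uniform random position, uniform
random allowed amino acid different from the current one), acceptance
$\min(1, e^{-\Delta E/T})$, geometric cooling from 3 to 0.3 across 100
sweeps by default, returning the best-energy sequence ever visited.
$\Delta E$ is computed incrementally from the contacts touching the mutated
position; tests cross-check against full recomputation.  `bruteForceDesign()`
enumerates every allowed sequence (up to $10^6$ states) in lexicographic
order and is the exact oracle for small instances.

The default schedule is deliberately short — it matches a packer's "one
round" character — and on strongly coupled toy landscapes it trades away
some optimality: on random 3-position instances with a random coupled
contact, the default 300-attempt budget recovers the exhaustive optimum in
roughly half of the runs, while 500 sweeps recover it in ≥ 95% and 1000
sweeps in ~100%.  The near-zero-temperature `greedySchedule()` provably
never accepts an uphill move, so a trajectory started at the optimum stays
there.

## The two-round workflow

`runEsmRestrained()` is the orchestration: stage 1 designs `nDesigns`
sequences unrestrained (per-design seeds `masterSeed + i`), the lowest
total energy design — "top scoring" resolved explicitly as minimal energy —
is queried for its PSPM, the PSPM becomes a weighted profile restraint, and
stage 2 redesigns `nDesigns` sequences under the combined energy with the
same derived seeds (so `restraintWeight = 0` makes stage 2 byte-identical
to stage 1).  One PSPM per run, from the single best stage-1 design; no
ensemble averaging.  Every run directory contains the stage-1 and stage-2
FASTA/scorefiles, the selected sequence, the PSPM as TSV, a PSI-BLAST-style
PSSM, and a log carrying the config hash, so identical configs give
byte-identical artifacts.

## Offline test system

`makeFixture()` builds an ideal α-helical bundle: φ = −57°, ψ = −47°, ideal
bond geometry, CB by ideal tetrahedral construction, 2–4 helices of ≥ 8
residues.  Because every consecutive CA–CA distance must stay at the
trans-peptide value (~3.80 Å), the bundle is one continuous chain; the
three turn dihedral pairs connecting helices are fixed constants found once
by numeric search so that consecutive helices run antiparallel with ~10 Å
axis spacing and no steric clash.  An exact rectangular grid placement is
impossible for a continuous ideal-geometry chain, so "grid" is approximate
by construction.

The ground-truth profile emulates layer-dependent composition: each row is
a Dirichlet draw (total concentration 25) centred on a hydrophobic-enriched
base for buried positions and a polar-enriched base for exposed ones, with
the native sequence sampled from those rows.  The synthetic provider
returns profile rows either as-is (`couplingStrength = 0`, context-free) or
modulated by a seeded random symmetric 20×20 coupling over the two
sequence-adjacent neighbours — a minimal stand-in for the
context-conditional character of a real language model.  What passing tests
on this system show is that the machinery is correct and directionally
faithful (restrained designs score better under the provider than
unrestrained ones); they say nothing about real proteins, real PLM
probability mass, or tertiary-context effects that a profile-plus-chain
coupling cannot represent.

## Numerical choices and degenerate inputs

* Probabilities are validated to sum to 1 within $10^{-6}$ per row;
  provider outputs violating this raise an error naming the position.
* A zero probability for a realised residue is an error in
  `pseudoPerplexity()` — no silent flooring; flooring exists only in the
  log-odds profile conversion (`floorProb`, default $10^{-6}$).
* PSSM files hold integer score columns `round(2·log2(p/b))` in PSI-BLAST
  column order and integer percentage columns `round(100·p)`; reading
  reconstructs probabilities exactly to the 0.005 percent-rounding bound,
  and the renormalisation needed for a strict row-stochastic matrix happens
  in `profileToPSPM()` so the bound is not amplified.
* Worst-position ties break toward the lower position index; replacement
  (argmax) ties toward the earlier letter in the canonical alphabet
  `A C D E F G H I K L M N P Q R S T V W Y`.
* Start sequences that violate a design task are projected to the nearest
  allowed amino acid in alphabet-index distance.
* Coincident duplicate atoms contribute their sphere area once in the SASA
  quadrature (the later twin counts as fully occluded).
* SASA exactly at a layer cutoff: core at the core cutoff, surface at the
  surface cutoff (boundary-inclusive rules, documented in
  `classifyLayers()`).
* Zero-variance score terms yield `NA` correlations with a warning, never
  a silent 0.

## Problem sizes

The bundled studies use a 3-helix, 42-residue fixture with 50 designs per
round, 25 three-position oracle instances × 4 seeded runs, 100 random
PSPMs for file round trips, and 960-point quadrature — sizes chosen so the
full study re-runs in seconds while every claim stays statistically easy to
read.  All randomness flows from explicit seeds; re-running any entry point
with the same configuration reproduces its outputs byte for byte.

## Known limitations

* The design energy is a coarse contact model; its absolute values are not
  comparable to any all-atom score, and "sequence recovery" against
  profile-sampled natives is accordingly low in absolute terms.
* Inputs are taken as-is: no relaxation or minimisation of user backbones.
* Single chain only; no hetero-atoms, waters, ligands, or mmCIF.
* The real-PLM adapter is a contract (`MaskedProvider`), not a bundled
  model; external adapters must map their vocabulary onto the canonical
  alphabet, drop non-amino-acid token mass and renormalise.
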