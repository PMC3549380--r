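---
title: "Weighted residue interaction networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted residue interaction networks: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aanet)
```

## The model

A protein structure is reduced to a graph. Each residue contributes one
node placed at the geometric center of its side chain — the unweighted mean
of the heavy side-chain atoms, i.e. everything except backbone N, CA, C, O
(and terminal OXT). Glycine has no side-chain heavy atom and falls back to
its alpha carbon, as does any residue whose side chain is unresolved in the
coordinates. Hydrogens are ignored throughout: X-ray structures mostly lack
them, and including them only where present would make the node positions
depend on the experiment rather than the molecule.

Two residues are linked when their centers lie strictly within a cutoff
r_c, default 6.5 Å. That specific value is not free: it is the contact
cutoff under which the pairwise contact potential supplying the link
weights was itself derived, so links and weights describe the same notion
of "contact". Sequence neighbours (i, i±1) are additionally joined by their
covalent backbone bond and that link always carries weight zero.

Every non-covalent link gets the contact energy w_ij of its residue-type
pair. The potential carries both signs: negative entries mark pairs that
attract on balance (hydrophobic–hydrophobic above all), positive entries
pairs that repel (like-charged side chains most strongly). In network
terms a negative w is a *similar* weight — it should pull the nodes
effectively closer — and a positive w a *dissimilar* weight that pushes
them apart.

## From weights to distances

Graph algorithms need distances, and the conversion is where the two weight
types matter. Definition 1, the recommended one, treats each sign by its
meaning:

\[
d_{ij} =
\begin{cases}
1/(1-w_{ij}) & w_{ij}<0 \quad(\text{attraction: } d<1)\\
1 & w_{ij}=0 \quad(\text{covalent bond})\\
1+w_{ij} & w_{ij}>0 \quad(\text{repulsion: } d>1)
\end{cases}
\]

It is continuous at w = 0 and monotonically increasing in w over the
table's range (both facts are asserted by tests). Two single-minded
alternatives serve as controls. Definition 2 treats every weight as
dissimilar, d = (1 + w)/2.19. Definition 3 treats every weight as similar,
d = 1/(1 − w). Under definition 3 the most repulsive pair (w = 0.76) is
stretched to d = 1/0.24 ≈ 4.17 while the most attractive (w = −1.19) is
compressed to 1/2.19 ≈ 0.46 — a max/min ratio of 9.125, far beyond the
roughly 1.7 spread of the physical center-to-center distances, which is the
quantitative argument against reading repulsion as similarity.

Three numerical details:

- **The 2.19 divisor** in definition 2 equals 1 + 1.19, i.e. one minus the
  table minimum; it is treated as an opaque, configurable normalisation
  constant (`normConstant`).
- **Clamping.** Definition 2 turns weights at or below −1 into
  non-positive distances, which no shortest-path algorithm tolerates. Such
  distances are clamped to ε = 1e-6 (configurable `clampEps`); the number
  of clamped links is recorded on the `DistanceMatrix` object. Clamping
  preserves the intended ranking "strong attraction = very short". The
  bundled table has 9 entries at or below −1, so clamps do occur in
  practice.
- **The ∞ sentinel.** Unlinked pairs carry `Inf`; path routines treat that
  as "no edge", never as a numeric length.

### The covalent link rule

The weight-zeroing for sequence neighbours is unconditional: whenever
residues i and i±1 of the same chain are linked, that link has w = 0, even
if their side-chain centers happen to be close. Separately, if their
centers fall *outside* the cutoff, the covalent link is still forced to
exist — the backbone exists whether or not the side chains touch, and it
guarantees a connected graph. Forcing is suppressed only when the geometry
contradicts an intact bond: a gap in residue numbering or alpha carbons
more than 4.5 Å apart, both signatures of a chain break in real files.

An earlier draft applied the 4.5 Å alpha-carbon test to *every* sequence-
neighbour link, not just forced ones. That version misbehaves on the
synthetic expansion series: at a uniform scale factor of ~1.18 the
pseudo-bonds cross 4.5 Å, every backbone link abruptly switches from
covalent (d = 1) to an ordinary weighted link (d < 1 for attractive type
pairs), and the average path length *drops* mid-series — an artifact, since
the series emulates a loosening structure whose bonds do not break. The
unconditional zeroing removes the artifact and is the more literal reading
of the model's definition.

## Graph metrics

Per node: degree K_i; strength S_i = Σ_j |a^w_ij| (covalent links
contribute zero); weighted clustering

\[
C_i=\frac{1}{S_i(K_i-1)}\sum_{j,h}a_{ij}a_{ih}a_{jh}\frac{|w_{ij}|+|w_{ih}|}{2},
\]

defined as 0 when K_i < 2 or S_i = 0 (a node linked only covalently).
Covalent links count in the adjacency triangle test and in K_i but add no
weight — the same convention as in S_i. Whether they should instead be
excluded from K_i is genuinely open; including them is the literal reading
and is what the package does.

Betweenness B_u sums, over unordered node pairs {i, j} with u excluded,
the fraction of shortest i–j paths through u. Two conventions had to be
fixed: *unordered* pairs (ordered counting would double every value
uniformly, which cancels in the Z-scores that downstream analysis
consumes), and *tie handling* — with floating-point link distances, exact
equality of path lengths is fragile, so lengths within a relative 1e-9
(configurable) count as tied and split the credit. The implementation is a
Brandes-style accumulation written in the package; tests check it against
exhaustive path enumeration on ~100 small random networks and against an
independent graph library.

Z-scores standardise betweenness within one protein:
Z_u = (B_u − B̄)/σ with the *population* standard deviation (σ divides by
N). The choice is visible only through a constant factor √(N/(N−1)) and is
switchable (`sdType = "sample"`); Z values always sum to zero. A zero σ
(all B equal) yields all-zero Z with a warning. Z ≥ 3.0 is the
conventional significance bound for hot-spot candidacy.

The network summary reports C (mean C_i), L (mean shortest-path distance
over *connected* unordered pairs, with the connected fraction disclosed —
real backbones keep the graph connected, synthetic edge cases need not),
and the size-matched random baselines C_r = ⟨K⟩/N and L_r = ln N/ln⟨K⟩
(undefined, and reported as missing, when ⟨K⟩ ≤ 1). The small-world
signature is C/C_r ≫ 1 with L/L_r of order one; the ratios themselves are
the deliverable, no pass/fail threshold is imposed.

## Hot-spot analysis of protein–drug complexes

For a complex, heavy-atom contacts are counted at a 4.5 Å cutoff
(`contactCutoff`; 5.0 is the documented alternative — the literature uses
both) between every residue and every non-water HETATM group, and between
residue pairs. The residue side includes backbone atoms. Residues whose
betweenness Z-score reaches the threshold are then classified: **direct**
(own ligand contacts), **one-hop** (no own contacts but a network
neighbour has some; the mediator reported is the contacting neighbour
sharing the most atom contacts with the candidate), or **unconnected**.
The classes are exhaustive and mutually exclusive, and contact counts are
monotone in the cutoff — both tested properties.

## Trajectory profiling

`profileSeries()` rebuilds the network per frame of a conformer series and
reports L under each requested definition plus mean clustering, mean
strength and the radius of gyration (computed on centroids by default for
speed; mass-weighted atom mode by flag). Frames are required to share one
residue roster — a mismatch aborts rather than re-indexes, since
conformational series preserve topology and divergence signals an input
error. A frame with no connected pair is flagged (NA) rather than fatal.

As a structure loosens, spatial links — the short attractive ones of the
hydrophobic core among them — disappear and L rises. Definition 1 shows
the largest rise of the three conversions *in absolute terms*, and that is
the comparison the package's sensitivity test makes. Comparing rises
after rescaling each curve by its own starting value would instead favour
definition 2 mechanically: its baseline L is compressed by the clamped
near-zero distances of the strongly attractive links, so any change is
amplified relative to it. That normalisation says more about the clamp
than about sensitivity, which is why it is not used.

## The synthetic generator: what it does and does not emulate

All tests run without downloads on generated structures:

- `makeCompactChain(n, seed)` grows a self-avoiding bead chain (one
  pseudo-atom per residue, serving as both alpha carbon and side-chain
  centroid), consecutive beads 3.8 Å apart — the alpha-carbon virtual bond
  length — minimum bead separation 3.4 Å, with the walk biased toward the
  running centroid so the globule's radius of gyration approximates the
  empirical scaling for folded proteins, Rg ≈ 2.5 n^0.38 Å. Dead ends are
  resolved by deterministic backtracking. Residue types are drawn from an
  approximate natural composition (overridable by an explicit sequence or
  weights). Identical spec and seed give bit-identical structures, and
  generators restore the global RNG state.
- `makeExpansionSeries(base, factors)` scales coordinates about the
  centroid, so Rg scales exactly by the factor and links break
  monotonically — a geometric caricature of unfolding.
- `makeToyComplex(seed)` plants a small HETATM ligand against a surface
  residue, guaranteeing direct-contact residues and, through that
  residue's neighbours, one-hop cases.

What passing on these fixtures shows: the machinery — parsing, network
construction, metric evaluation, classification — is correct against
independent oracles, and the qualitative phenomenology (small-world
ratios, L–size correlation, unfolding monotonicity) emerges under
realistic packing. What it does not show: quantitative agreement with real
proteins. Beads are not side chains, the composition has no sequence
correlation, uniform scaling is not molecular dynamics, and the toy ligand
is not a drug. Published per-protein values (specific correlation
coefficients, specific hot-spot residues) require the corresponding
experimental structures as inputs.

One quantitative consequence worth spelling out: C/C_r = C·N/⟨K⟩ grows
linearly with N at fixed density. At the 6.5 Å cutoff realistic packing
gives ⟨K⟩ ≈ 6–7 (6.1 measured on a real lysozyme structure with this
pipeline) so chains near the short end of the 51–200 range used in the
small-world test bed sit at C/C_r ≈ 4–5 even though C exceeds C_r several
times over; the ratio climbs well past 10 by n ≈ 150. "C ≫ C_r" is a
statement about the signature, not a fixed ratio across sizes.

## Problem sizes and defaults

The reference test conditions, chosen once: 30 compact chains spanning
n = 51–200 for the small-world and size-correlation checks; a 20-frame
expansion series (factors 1.00–1.25) of a 100-residue chain for the
unfolding checks; ~100 random 5–10-node geometric networks for oracle
equivalence; fixed seeds throughout. Defaults: r_c = 6.5 Å,
normConstant = 2.19, clampEps = 1e-6, contact cutoff 4.5 Å, Z threshold
3.0, path-tie tolerance 1e-9 — each either the model's stated value or
documented above.

## Known limitations

- The bundled potential is a calibrated synthetic reconstruction (see
  `inst/extdata/README.md`), exact only in its global range and sign
  structure; substitute the genuine table for production use.
- mmCIF, XTC/DCD and other binary trajectory formats are out of scope;
  PDB (including multi-model) is the contractual format.
- No structure repair: missing atoms shift side-chain centroids; residues
  with no usable atoms are skipped with a warning.
- `atomContacts()` builds a dense atom-pair distance matrix; fine to a few
  thousand heavy atoms, wasteful beyond.
- Betweenness is exact, not sampled; on networks far larger than a typical
  single-domain protein it becomes the dominant cost (it is optional in
  the network summary for that reason).
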