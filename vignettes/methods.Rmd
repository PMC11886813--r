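---
title: "Side-chain packing by torsional flow matching: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-chain packing by torsional flow matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Under idealized covalent geometry a residue's side chain has at most four
degrees of freedom, the χ dihedrals, so a conformation of an R-residue
protein is a point on a product of circles (a flat torus). Most angles live
on the full circle of period 2π; the terminal groups of Asp, Glu, Phe and
Tyr are chemically indistinguishable under a 180° rotation, so χ₂ of
Asp/Phe/Tyr and χ₃ of Glu are treated on the half-circle of period π.
`chiflow` fixes one canonical chart per period: `[-π, π)` for the full
circle and `[0, π)` for symmetry-reduced angles.

Conditional flow matching trains a continuous normalizing flow without
simulating it. For a prior draw χ₀ (uniform on each circle) and a data point
χ₁, the conditional path is the constant-speed geodesic

χ_t = exp_{χ₀}( t · log_{χ₀}(χ₁) ),

whose velocity is the constant `log_{χ₀}(χ₁)`. On the circle both maps are
closed-form: `exp` is wrapped addition, `log` is the signed shortest arc
(`atan2` applied to the rescaled difference, with the antipodal tie broken
to +period/2 by the `atan2(0, −1) = π` convention). The network v̂(χ_t, t)
is regressed on that constant field with the squared error weighted by
1/(1−t)². The equivalent endpoint form `log_{χ_t}(χ₁)/(1−t)` is also
implemented; the two coincide along exact geodesics and the endpoint form
guards `t ≥ 1 − 10⁻⁵` by returning the exact field, since the division
degenerates at the data end.

At sampling time the flow starts from the uniform torus prior and follows
the *exponential* schedule rather than the linear one: the network output is
first converted to the implied endpoint `χ̂₁ = exp_{χ_t}((1−t)·v̂)` —
inverting the training parameterisation, which is the mathematically
consistent conversion for the linear schedule and is stated here explicitly
because the mapping between the two parameterisations is a genuine design
choice — and the integrated field is `c · log_{χ_t}(χ̂₁)`. With the exact
conditional field every Euler step contracts the remaining wrapped distance
by |1 − cΔt|; at the operating point (10 uniform steps, c = 5, so cΔt = 0.5)
the residual after ten steps is 2⁻¹⁰ ≈ 10⁻³ of the initial distance, which
the test-suite verifies. Intermediate states are wrapped into their
canonical charts after every step.

## Geometry and reconstruction

Atoms are stored in the fixed 14-slot (atom14) heavy-atom layout. Idealized
residue geometry is vendored as plain-text tables (ideal coordinates,
within-residue bonds, χ definitions with π-symmetry flags); rotating sets
are derived from the bond graph as the atoms distal to each χ axis, with the
proline ring's N–CD closure excluded so that proline χ behaves like any
other angle (ring closure is not enforced; a documented limitation).
Reconstruction rigidly aligns the template to the observed N/CA/C frame and
applies χ rotations in order about the current bond axes, which makes
`measure_chi(build_atoms(χ)) = χ` exact by construction; the test-suite
checks the roundtrip at 10⁻⁶ rad for all 18 χ-bearing amino acids. The
π-symmetric terminal groups of the vendored coordinates carry sub-0.01 Å
asymmetries, so those groups are symmetrized at load time by averaging with
their flipped image (an exact involution); without this the symmetry
reduction would not be lossless. Virtual Cβ positions (including glycine)
use the internal coordinates of the idealized alanine (CA–Cβ 1.529 Å,
N–CA–Cβ 109.5°, C–N–CA–Cβ 120°), a fixed tetrahedral construction applied
uniformly.

## Features and network

Nodes sit at idealized Cβ positions and connect to their k = 30 nearest
neighbours (directed, deterministic tie-break toward the lower index). Node
features: 21-class amino-acid one-hot, sin/cos of φ/ψ/ω with validity bits
at chain termini, and a 32-dimensional sinusoidal embedding of t with
geometric frequency spacing (both the torsion set and the embedding width
are configuration defaults, not claims). Edge features: a 65-bin one-hot of
the relative sequence offset clamped to ±32 — pinned to the +32 bin for
edges between different chains, which is the only change needed for
multimers — and the 196 pairwise atom14 distances between the two residues
at the *current* (noised or partially integrated) coordinates, rebuilt from
χ_t at every step, with availability bits for missing atoms. All features
are rigid-motion invariant, so the whole pipeline is invariant under global
rotations and translations; since the predicted quantities (torsional
fields, per-residue RMSDs) are invariant scalars, an invariant-feature
network suffices and no equivariant machinery is used.

The denoiser is a compact edge-conditioned graph attention network: linear
+ ReLU encoders for node and edge features, then two blocks of single-head
attention (a message MLP over `[h_i, h_j, e_ij]`, a bounded tanh logit per
edge normalised over each neighbourhood, attention-weighted aggregation,
gated residual update), and a linear 4-channel head; the confidence model
shares the trunk shape with a softplus 1-channel head. χ_t enters as
period-scaled sin/cos channels (so symmetry-reduced angles are continuous on
their chart) plus the existence mask. Forward and backward passes are
hand-written matrix algebra; the gradients are checked against numerical
differentiation in the tests. The test-scale instantiation is 64 channels ×
2 blocks (≈76k parameters); width, depth and the 256-channel/4-block
full-scale operating point are configuration.

By default the 196 edge distances enter the network scaled by 1/10; a
16-centre Gaussian radial-basis expansion over 0–20 Å is implemented
(`rbf_expand`, `chi_net_config(rbf_centers = )`) but off by default because
it multiplies the dominant matrix product by the number of centres for no
measurable gain at the desk-scale problem sizes used here.

## Training

Each iteration draws, per structure, `t ~ U(0, 1 − t_epsilon)` and a
period-aware uniform χ₀, forms χ_t on the geodesic, rebuilds the noised
atoms, and takes an Adam step (learning rate 10⁻⁴ by default, gradient norm
clipped at 1.0) on the weighted CFM loss averaged over unmasked angles.
Structures longer than `crop_length` (512) are cropped to a random
contiguous window, preserving local graph context. An exponential moving
average of the weights (decay 0.999) is maintained every iteration.

Two numerical choices matter at small scale and are worth stating plainly.
First, the 1/(1−t)² weight diverges at t = 1; with `t_epsilon = 10⁻³` the
weight can reach 10⁶, and in short runs with tiny batches those rare draws
dominate every clipped gradient — empirically the loss stays flat. The
default keeps `t_epsilon = 10⁻³`, but the desk-scale configurations used in
the tests and the acceptance script set `t_epsilon = 0.09` (the upper end of
the configuration's allowed range), capping the weight near 10². Second,
with decay 0.999 the EMA averages over a ~1000-iteration window, so after a
≤2000-iteration run the shadow still remembers a large part of the learning
trajectory; the accumulator is therefore debiased (Adam-style), the EMA
remains what confidence training samples from, and the short-run recovery
evaluations sample with the final weights instead.

The confidence model is trained by sampling side chains with the main
model, computing the true per-residue side-chain RMSD against the ground
truth (heavy atoms from Cβ outward, no superposition, symmetric termini
matched), and regressing the softplus head on it with squared error; one
sample per structure is refreshed every `resample_every` iterations to
amortise the sampling cost.

## Evaluation

Angle errors use the minimum arc on the angle's own circle (so π-symmetric
errors never exceed 90°) and are reported in degrees; accuracy is the
fraction strictly below 20° (boundary ties are measure-zero; the strict
inequality is a documented choice). Per-residue RMSD is computed without
superposition over side-chain heavy atoms, with the symmetric-pair
assignment applied for Asp/Glu/Phe/Tyr (amide/imidazole/guanidinium flips
for Asn/Gln/His/Arg are available but off by default, matching the
crystallographic convention that those flips are *not* degenerate). MAE is
micro-averaged over all evaluated residues; per-structure macro-averaging
is available. Core residues have ≥20 other Cβ within 10 Å, surface ≤15;
the classes depend only on backbone geometry.

Clashes count non-bonded heavy-atom pairs closer than the sum of van der
Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å) minus 0.4 Å, implemented
with a cell list and checked against a brute-force pair scan. Same-residue
pairs are excluded, as are pairs within `max_bond_span` bonds across the
peptide link. The span defaults to 3 (excluding 1-4 pairs as well as
1-2/1-3): ideal trans-peptide geometry itself places O(i)–CA(i+1) at
2.77 Å, inside the 2.82 Å threshold, so a 1-2/1-3-only rule would count
every peptide bond of an ideal backbone as a clash; `max_bond_span = 2`
restores the stricter rule for anyone who wants it.

## Synthetic fixtures: what they do and do not show

The generator lays down ideal-geometry backbones by internal-coordinate
chaining at canonical (φ, ψ) — helix (−57, −47), strand (−139, 135), trans
ω — draws random sequences guaranteed to cover all 18 χ-bearing amino
acids, and assigns χ angles from the gauche⁻/gauche⁺/trans rotamer centres
(−60/60/180°) with 5° Gaussian jitter, chosen so that recovery tests have
nonzero but learnable variance. Multi-chain fixtures are rigid, clash-free
copies. Everything is a deterministic function of the seeds.

These fixtures emulate idealized geometry and rotameric side chains; they do
**not** emulate rotamer-library frequencies, packing-driven correlations
between neighbouring rotamers, experimental coordinate noise, missing atoms,
or alternate conformations. Passing the recovery tests therefore
demonstrates that the flow-matching machinery — noising, field regression,
exponential-schedule integration, inpainting, selection and scoring — is
implemented correctly and can be driven to memorise and reproduce a small
conformation set end to end; it says nothing about accuracy on real
proteins, which would require the full-scale training regime on curated PDB
data that is outside this package's desk-scale scope.

The problem sizes used by the test-suite and the acceptance script — three
fixtures of 40–60 residues, a 64-channel/2-block network, 1500 training
iterations, 4 samples per case — were chosen as the smallest configuration
at which the end-to-end recovery targets (χ₁ MAE below 15°, overall 20°
accuracy above 60%) are met comfortably on a single CPU.

## Known limitations

Proline's ring closure is not enforced; OXT and hydrogens are not modelled;
non-canonical residues map to `UNK` (extra one-hot class, no χ angles);
B-factor output carries at most two decimals (PDB format); the mmCIF writer
emits a minimal `atom_site` loop only. The sampler is a plain Euler
integrator by design — higher-order solvers add cost without accuracy gains
for this flow — and χ angles are generated jointly, not autoregressively.
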