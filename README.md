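# chiflow

Torsional flow matching for protein side-chain packing in R.

Given a protein backbone and sequence, the side-chain conformation is fully
determined (under idealized covalent geometry) by up to four χ dihedral
angles per residue. `chiflow` treats the vector of χ angles as a point on a
hypertorus — the product of one circle per angle, with period 2π in general
and period π for the chemically π-symmetric angles (χ₂ of Asp/Phe/Tyr, χ₃ of
Glu) — and learns a generative model of side-chain conformations by
**conditional flow matching** on that manifold:

- The conditional flow between a uniform prior sample χ₀ and the data χ₁ is
  the geodesic interpolant χ_t = exp_{χ₀}(t · log_{χ₀}(χ₁)), where on each
  circle exp is wrapped addition and log is the signed shortest arc.
- A graph network v̂(χ_t, t) is regressed on the conditional vector field
  χ̇_t = log_{χ₀}(χ₁) with the time weight 1/(1−t)², on noised structures
  rebuilt from χ_t with idealized (atom14) geometry.
- Sampling starts from the uniform torus prior and integrates with a 10-step
  Euler solver under the exponential schedule v_t = c · log_{χ_t}(χ̂₁) with
  c = 5, where χ̂₁ = exp_{χ_t}((1−t) · v̂) is the endpoint implied by the
  predicted field. Each exact-field Euler step contracts the remaining
  wrapped distance by |1 − cΔt|.

The denoiser is an invariant-feature graph attention network over a
residue-level k-nearest-neighbour graph (k = 30, nodes at idealized Cβ
positions): amino-acid one-hot, backbone φ/ψ/ω and a sinusoidal time
embedding as node features; clamped relative sequence position (±32, with
cross-chain edges pinned to +32 for multimers) and all 14×14 pairwise atom
distances as edge features. Forward and backward passes are written directly
in base-R matrix algebra and verified against numerical differentiation.

The package also provides side-chain **inpainting** (pinning any subset of
residues to known rotamers while generating the rest), **confidence-based
selection** (an auxiliary per-residue RMSD regressor ranks multiple
samples), the standard evaluation suite (per-χ MAE with the minimum-arc
metric, accuracy within 20°, per-residue atom RMSD with symmetric-terminus
matching, core/surface splits by Cβ burial, clash counts), PDB/mmCIF I/O
with the usual dataset curation filters (≥40 residues, ≤25% unknown,
overlapping-Cα removal), and a deterministic synthetic mini-protein
generator so that everything is testable offline.

## Worked example

Train a small model on three synthetic mini-proteins, sample four
conformations, keep the best by true RMSD, and evaluate:

```r
library(chiflow)

trio <- fixture_trio(seed = 7)                      # 48/40/60-residue fixtures
net  <- chi_net_init(chi_net_config(hidden = 64, blocks = 2), seed = 1)
fit  <- train_pack_model(trio, net,
                         train_config(learning_rate = 3e-3, iterations = 1500,
                                      batch_size = 3, t_epsilon = 0.09,
                                      seed = 42))

fx  <- trio[[1]]
ref <- build_structure_atoms(fx$structure, fx$chi)
samples <- sample_sidechains(fx$structure, fit$net,
                             sampler_config(num_samples = 4, seed = 100))
best <- select_by_confidence(samples, fx$structure,
                             score_fn = function(s) structure_rmsd(s$structure, ref))
pack_report(best$sample$structure, ref)
```

```
<packing_report>
  chi MAE (deg):    8.39  15.76  47.34  121.60
  chi acc (<20deg): 0.977  0.871  0.500  0.000
  RMSD all/core/surface: 0.453 / NA / 0.453 A
  clashes: 148
```

Read: χ₁ of this overfit fixture is recovered to ~8° mean absolute error
with 98% of χ₁ angles within 20° of the ground truth; errors grow sharply
for the distal χ₃/χ₄ (the usual lever effect, amplified here because the
fixture has only a handful of χ₄-bearing residues), and the all-helix
fixture has no core residues. A fresh backbone is packed the same way from
a PDB file via
`read_structure()`; `inst/scripts/chiflow` wraps packing, inpainting,
evaluation and fixture generation for shell use.

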