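# confmap

Mapping discrete and continuous macromolecular conformations from
heterogeneous snapshot datasets by manifold embedding.

Single-particle experiments — cryo-electron microscopy and XFEL
"diffract-then-destroy" imaging — record large sets of noisy 2D snapshots of
molecules frozen in unknown orientations *and* unknown conformations.  Each
snapshot of `p` pixels is a point in `p`-dimensional intensity space; as
orientation and conformation vary, these points trace a low-dimensional
manifold.  `confmap` implements the spectral toolkit for discovering and
interpreting that manifold:

* **Defocus-invariant snapshot distance.**  Cryo-EM snapshots differ by the
  microscope contrast transfer function (CTF) as well as by orientation and
  conformation.  The double-filtered distance
  `D_ij = || PSF_j ⊗ I_i − PSF_i ⊗ I_j ||`
  convolves each image with the *other* image's point-spread function before
  differencing, so two snapshots of the same projected potential taken at
  different defocus are at distance zero.  It is evaluated in Fourier space
  (`CTF_j·Î_i − CTF_i·Î_j`, Parseval-scaled) with optional band-limiting to
  the analysis resolution and a soft particle-support mask.
* **Orientation-gated diffusion-map kernel.**  Orientational changes dominate
  conformational ones, so the kernel
  `W_ij = exp(−D_ij²/2σ²)` if `Δθ_ij ≤ θ_ε`, else 0,
  compares only snapshots whose known viewing directions agree within
  `θ_ε` (conventionally two Shannon angles, `2·d/D` for a particle of
  diameter `D` at resolution `d`), keeps the `k` shortest distances per
  snapshot, and selects `σ` automatically from the log–log kernel-sum scan.
* **Embeddings and conformational readout.**  Diffusion maps
  (density-normalized Markov-chain eigenvectors; `ψ₁` is constant, `ψ₂, ψ₃,
  …` carry the structure) and Isomap (graph geodesics + classical MDS);
  deterministic two-means sorting with a perpendicular-bisector cutting line
  in the `(ψ₂, ψ₃)` plane; sorting fidelity (label-permutation-maximized
  accuracy); manifold thickness/separation statistics; continuous
  conformational coordinates read off `ψ₂` with a histogram-resolution
  report.
* **A synthetic snapshot forge.**  Gaussian-blob phantoms with tunable
  conformational differences (hinge pair, bound-cofactor pair with
  ratcheting, continuous unfolding path), Haar-uniform / aligned-viewing /
  single-axis orientations, analytic projections, CTF with defocus spread,
  calibrated background + shot noise (e.g. −12 dB SNR), and photon-sparse
  Poisson diffraction patterns — so every stage of the pipeline can be
  exercised end-to-end without external data.  Stacks are written as
  MRC/MRCS with CSV metadata sidecars.

## Worked example

Forge diffraction snapshots of a molecule unfolding through 12
conformations, each viewed in a random orientation, embed them with a
diffusion map, and read the conformational coordinate off the first
non-trivial eigenfunction:

```r
library(confmap)

spec  <- conformation_spec("continuous_path", n_conformations = 12,
                           motion_amplitude = 80)
stack <- forge_dataset(spec, n = 1800, imaging = "diffraction",
                       mean_photons_per_pixel = 50, seed = 1)
stack
#> <snapshot_stack> 1800 diffraction snapshots, 64x64 px at 5 A/px
#> class_label
#>   0   1   2   3   4   5   6   7   8   9  10  11
#> 150 150 150 150 150 150 150 150 150 150 150 150

D   <- pairwise_distances(stack, "euclidean", normalize = FALSE,
                          resolution = 30)
W   <- gated_kernel(D, NULL, gating_params(Inf, k_nn = 10, sigma = "auto"))
emb <- diffusion_map(W, n_components = 5)
emb
#> <confmap_embedding> diffusion_map, 1800 snapshots x 5 components
#> eigenvalues: 1.0000 0.9772 0.9691 0.9667 0.9624 0.9383

cc <- conformational_coordinate(emb, stack$metadata$true_class)
cor(cc$psi2, stack$metadata$conf_coord, method = "spearman")
#> [1] 0.8492377
```

`ψ₂` orders the 1800 snapshots along the unfolding path (Spearman 0.85
against the true conformational coordinate) with no knowledge of
orientations, class count, or the nature of the motion; with a larger box
and unfolding range the correlation exceeds 0.9 (that configuration is
exercised in the test suite).  The methods vignette gives the quantitative
picture of how performance scales with snapshot count, detector size and
noise.

The same analysis runs from the shell:

```sh
inst/cli/confmap forge     --config conf.yaml --out run/ --seed 17
inst/cli/confmap distances --stack run/ --out run/D.csv
inst/cli/confmap embed     --distances run/D.csv --meta run/stack_meta.csv \
                           --theta-eps inf --knn 20 --out run/emb.csv
inst/cli/confmap sort      --embedding run/emb.csv --meta run/stack_meta.csv
```

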