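# nfsom — neural-field self-organizing maps and their stability

`nfsom` is an R package for simulating and analyzing a self-organizing map
(SOM) whose neighborhood function is not hand-designed but *emerges* from
the activity bump of a dynamic neural field — a model of topographic map
formation and maintenance in primary somatosensory cortex (area 3b). It is
aimed at computational neuroscientists and SOM practitioners who want to
study when such a map forms at all, and to test the analytic stability
conditions that predict it.

## The model in brief

On a compact sheet Ω = [0,1]² the mean membrane potential u and the
per-node codebook w_f ∈ [0,1]^m evolve as

    τ ∂u/∂t   = −u + ∫_Ω w_l(|r−r′|) rect(u(r′)) dr′ + I,
    ∂w_f/∂t  = γ (s(p) − w_f) ∫_Ω w_e(|r−r′|) rect(u(r′)) dr′,

with lateral coupling w_l = w_e − w_i a difference of Gaussians
(amplitudes K_e, K_i; widths σ_e, σ_i), input drive
I = 1 − |w_f − s(p)|₁/m, and one uniform stimulus p ~ U(0,1)² per training
epoch. Lyapunov analysis of this system yields a closed-form sufficient
condition for local exponential stability of the equilibrium (u*, s(p)):
the squared L2 norm of w_l over Ω,

    K_e² ξ(σ_e/√2) + K_i² ξ(σ_i/√2) − 2 K_e K_i ξ(σ_e σ_i / √(σ_e²+σ_i²)) < 1,

where √ξ_{a,b}(σ) is the Gaussian double integral over [a,b]² (an Erf
expression). Balanced excitation/inhibition keeps the value small; strong
gains push it past 1, and the map fails to organize. The package computes
this condition in closed form and by lattice quadrature, solves the
equilibrium field, trains maps with a compiled forward-Euler engine, and
scores map quality (quantization distortion, δx–δy topology cloud,
performance index 𝒫).

## Worked example

```r
library(nfsom)

spec <- kernel_spec(Ke = 0.90, sigma_e = 0.1, Ki = 0.86, sigma_i = 1.0)
stability_report(spec, spatial_grid(40))
#> <nfsom_stability_report>
#>   kernel: Ke = 0.9 (sigma_e = 0.1), Ki = 0.86 (sigma_i = 1) on [0, 1]^2
#>   condition LHS: closed form 0.4900 | 40x40 quadrature 0.4900 (< 1 required)
#>   kernel L2 norm: 0.7000 (condition: < 1/ell_l) -> ok
#>   excitation at equilibrium: inf = 0.01061 -> ok
#>   verdict: stable
```

The condition value 0.49 < 1 predicts a stable learning equilibrium: this
parameter set forms a topographic map. The strong-gain set loses that
guarantee:

```r
stability_report(kernel_spec(3.0, 0.1, 2.80, 1.0), spatial_grid(40))
#>   condition LHS: closed form 5.1851 | 40x40 quadrature 5.1855 (< 1 required)
#>   kernel L2 norm: 2.2772 (condition: < 1/ell_l) -> violated
#>   verdict: not_guaranteed
```

Training and map quality (a full-scale stable run; several minutes):

```r
fit <- train_som(model_params(), spec, spatial_grid(40), seed = 10,
                 log_stride = 50)
tail(fit$trace$distortion, 1)
#> [1] 0.004634065
map_quality(fit$codebook, spatial_grid(40))$P
#> [1] 0.04530402
```

Distortion is the mean squared distance from stimuli to their nearest
codebook vector; a few times 10⁻³ on a 40×40 map means the input square is
tiled finely, limited mainly by boundary shrinkage. 𝒫 compares the δx–δy
cloud's centroid line with its origin-constrained regression line
(root-mean-square gap over evaluation abscissae); values near 0 mean
pairwise codebook distances track lattice distances, i.e. the map preserves
the topology of the input space. The same run with
`kernel_spec(3.0, 0.1, 2.80, 1.0)` never settles: the distortion trace
keeps oscillating over a five-fold range (0.002–0.012) as the map is
repeatedly disrupted, exactly the signature the stability condition
predicts.

A small command-line interface wraps these pipelines:

    inst/exec/nfsom run --config my.cfg --out results/ [--full | --ci]
    inst/exec/nfsom sweep --config my.cfg --out results/
    inst/exec/nfsom stability --config my.cfg
    inst/exec/nfsom metrics --snapshot results/snapshot.json

Configs are flat `key = value` files (`?read_config`); `mode = stable_demo`
and `mode = unstable_demo` provide the two reference parameter sets, and
`mode = sweep` the eight-pair (K_e, K_i) amplitude sweep.

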