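# neulay

Network layouts by force-directed energy minimization, accelerated by graph
neural reparametrization.

## The problem

Force-directed layout (FDL) is the workhorse of network visualization: links
act as springs, a short-range repulsion keeps nodes apart, and gradient
descent on the node coordinates minimizes the total energy

```
L(X) = ½ Tr[XᵀLX] + a_N Σ_{i<j} exp(−|x_i−x_j|² / 4r₀²),    L = D − A.
```

On large networks plain FDL is slow and gets trapped in high-energy
"hairball" configurations, because the layout's large-scale structure lives
in the slow modes of the dynamics: with repulsion off and a near-regular
graph, the overlap of the layout with an adjacency eigenvector ψᵢ decays at
rate ε(⟨k⟩ − λᵢ) per step, so precisely the community/geometry modes (large
λᵢ) relax last.

The NeuLay family attacks this by reparametrizing the coordinates through a
small trainable network and running gradient descent on its parameters with
the *same* energy:

* **NodeMLP** — `X = σ(ZW + b)` with a trainable N×h embedding Z;
* **NeuLay** — one graph-convolution layer `G₁ = tanh(f(A) Z W⁽¹⁾)` with
  `f(A) = D̃^{-1/2}(A+I)D̃^{-1/2}`, concatenated with Z;
* **NeuLay-2** — two stacked GCN layers, `G = [Z | G₁ | G₂]`,
  `X = G W + b`.

Propagation through f(A) amplifies the slow outlier modes from the first
iteration, so community-structured (SBM) and geometric (RGG) graphs lay out
in roughly an order of magnitude fewer steps at equal or lower final energy.
The package also implements the spectral analysis behind that claim:
outlier-eigenvalue detection, the `A_top`/`A_bulk` operator split and its
substitution into the GCN, mode-overlap tracking, and layout-quality metrics
(energy ratios, steps-to-target speedups, link-length distributions,
community localization against a geometric-randomization null, silhouette
cluster separation).

Audience: anyone laying out biological or other real-world networks in 2-D/3-D
and anyone studying why neural reparametrization accelerates graph
optimization.

## Worked example

```r
library(neulay)

g <- sbm_graph(rep(50, 8), 0.5, 0.02, seed = 881)   # 400 nodes, 8 planted blocks

fdl <- run_fdl(g, seed = 1, optimizer = "adam")
nl2 <- train_model(g, "neulay2", seed = 1, optimizer = "adam")

sp <- speedup(fdl$trajectory, nl2$trajectory, delta = 0.05)
cat(sprintf("FDL:      E = %.2f after %d steps\n",
            tail(fdl$trajectory$energies, 1), max(fdl$trajectory$steps)))
cat(sprintf("NeuLay-2: E = %.2f after %d steps\n",
            tail(nl2$trajectory$energies, 1), max(nl2$trajectory$steps)))
cat(sprintf("steps-to-FDL-energy ratio: %.1f\n", sp$step_ratio))
cat(sprintf("cluster separation FDL %.2f vs NeuLay-2 %.2f\n",
            cluster_separation(fdl$layout, attr(g, "partition")),
            cluster_separation(nl2$layout, attr(g, "partition"))))
```

```
FDL:      E = 107.93 after 3892 steps
NeuLay-2: E = 107.79 after 1407 steps
steps-to-FDL-energy ratio: 11.4
cluster separation FDL 0.82 vs NeuLay-2 0.83
```

Both optimizers find the same energy basin (the eight blocks separate
cleanly in either layout — the silhouette scores match), but NeuLay-2 needs
~11× fewer gradient steps to get within 5% of FDL's final energy. The spectral
mechanism is directly inspectable:

```r
dec <- eigendecompose(normalized_operator(g))
length(outlier_set(dec))   # 8 — one outlier eigenvalue per planted block
```

A command-line interface wraps the same functions
(`inst/cli/layout.R`; subcommands `generate`, `run`, `spectral`, `metrics`,
`bench`):

```sh
Rscript inst/cli/layout.R generate --family sbm --blocks 25,25,25,25 \
    --p-in 0.5 --p-out 0.02 --seed 7 --out g.gml
Rscript inst/cli/layout.R run --model neulay2 --input g.gml --dim 3 \
    --seed 1 --optimizer adam --out coords.csv --traj traj.csv
```

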