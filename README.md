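# ls2wmv

Modelling, estimation and classification for **multivariate locally
stationary 2D wavelet (LS2Wmv) processes** — multichannel random fields,
such as colour-textured images, whose second-order structure varies across
space and across spatial scale, and whose channels are mutually correlated.

Audience: statisticians and image analysts who need a *model-based*
description of colour texture — for instance to discriminate visually
similar product images — rather than generic feature engineering.

## The model in brief

Each channel of an $m$-variate field on a dyadic $R \times S$ lattice is a
sum over scale–direction pairs $\eta$ of non-decimated discrete wavelets
modulated by transfer functions:

$$X^{(i)}_{\mathbf r} = \sum_\eta \sum_{\mathbf u}
  W^{(i)}_\eta(\mathbf u/\mathbf R)\, \psi_{\eta,\mathbf u-\mathbf r}\,
  \xi^{(i)}_{\eta,\mathbf u},$$

with Gaussian increments $\xi$ that are correlated *across channels* at the
same scale and location with coherence $\rho^{p,q}_\eta(\mathbf z) \in
[-1,1]$. The local wavelet cross-spectrum is $S^{p,q}_\eta = W^{(p)}_\eta
W^{(q)}_\eta \rho^{p,q}_\eta$, and the estimation pipeline —
raw wavelet cross-periodogram, Nadaraya–Watson smoothing, bias correction by
the inverse autocorrelation-wavelet inner-product matrix $A_J^{-1}$, then
the normalised ratio $\hat\rho = \hat S^{p,q}/(\hat S^{p,p}\hat
S^{q,q})^{1/2}$ — gives consistent estimates of spectra and coherence.
A nearest-centroid linear-discriminant classifier built on location-averaged
spectra and coherences provides colour-texture classification.

Main entry points:

| function | role |
| --- | --- |
| `ls2w_process()`, `demo_process()` | process specifications |
| `simulate()` | generate realisations (seeded, reproducible) |
| `mvlws()` | fit spectra + coherence to a field; `print`, `summary`, `plot`, `coef` methods |
| `local_autocov()` | model-implied cross-covariance (analytic oracle) |
| `lws_features()`, `texture_lda()`, `texture_experiment()` | classification |
| `read_multichannel_image()`, `write_field()`, `write_estimate()` | I/O |
| `ls2wmv_cli()` (+ `inst/cli/ls2wmv`) | command-line front end |

## Worked example

Simulate the trivariate demonstration process (flat spectra equal to 2;
channel 1–2 coherence constant at 0.2; channel 2–3 coherence ramping from 0
to 0.8 left to right) and fit the spectral model:

```r
library(ls2wmv)
x <- simulate(demo_process("coherence_demo"), seed = 42, dim = c(128, 128))
x
#> Multichannel field: 3 channel(s), 128 x 128, process coherence_demo
fit <- mvlws(x)
fit
#> Local wavelet spectral fit (LS2Wmv)
#>   field: 128 x 128, 3 channel(s), J = 7 (21 scale-direction pairs)
#>   filter: haar  smoothing: uniform kernel, h = 11.31371
#>   coherence guard rails: 678618 floored, 686235 clipped
s <- summary(fit)
s$table[1:4, c("eta", "j", "direction", "S11", "S22", "rho1,2", "rho2,3")]
#>   eta j direction  S11  S22 rho1,2  rho2,3
#> 1   1 1         v 2.00 2.10 0.1409  0.4158
#> 2   2 2         v 2.23 2.05 0.1525  0.2466
#> 3   3 3         v 2.57 3.13 0.0290  0.2223
#> 4   4 4         v 3.28 3.21 0.0493 -0.0122
```

Reading the output: at the finest vertical scale the estimated auto-spectra
(`S11`, `S22`) sit at the true value 2, the location-averaged channel 1–2
coherence is near its true 0.2 (single realisations are noisy; averaging
over replicates recovers it closely), and the channel 2–3 average of 0.42
matches the mean of the 0-to-0.8 ramp. Coarser scales carry fewer
independent coefficients and are correspondingly rougher. The "guard rails"
line counts pointwise floors/clips applied inside the coherence ratio —
concentrated at coarse scales, where pointwise estimates are weakest.
`plot(fit, p = 2, q = 3, eta = 1)` shows the estimated ramp surface.

Classification of three visually similar synthetic colour textures:

```r
src <- list(P1 = simulate(demo_process("P1"), seed = 101, dim = c(256, 256)),
            P2 = simulate(demo_process("P2"), seed = 102, dim = c(256, 256)),
            P3 = simulate(demo_process("P3"), seed = 103, dim = c(256, 256)))
texture_experiment(src, size = 128, seed = 109, J = 4)
```

which prints the correct-classification rate (typically around 90-95
percent across seeds; see below) and the confusion matrix.

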