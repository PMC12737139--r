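# aldtf — adaptive layer-dependent threshold wavelet denoising

`aldtf` denoises quasi-periodic physiological signals — electrocardiograms
and fiber-optic cardiorespiratory recordings — **without a clean
reference**. It is aimed at people processing ambulatory or wearable-sensor
waveforms, where baseline wander, electrode-motion transients and muscle
artifact are the norm and ground truth never exists.

## The method

The noisy signal $y_{in}(n)$ is decomposed with the biorthogonal 6.8
discrete wavelet transform into detail bands $D_1,\dots,D_J$ and an
approximation $A_J$. Every detail coefficient is shrunk with the
layer-dependent tanh rule

$$\hat\omega = \mathrm{sgn}(\omega)\,\tfrac{|\omega|}{2}
\left[\tanh\bigl(\alpha_j(|\omega|-\lambda_j)\bigr)+1\right],$$

where $\lambda_j$ is the layer's threshold (median-absolute-deviation
universal rule by default) and the tuning factor $\alpha_j$ morphs the rule
from smooth soft-like shrinkage (small $\alpha_j$, suppresses pseudo-Gibbs
ringing) to hard thresholding (large $\alpha_j$, preserves amplitude).
Each $\alpha_j$ is chosen by maximizing the **non-zero periodic peak
(NZOPP)** of the reconstruction's normalized autocorrelation

$$\mathrm{NACF}(k) = \frac{\sum_{n=0}^{N-k-1} y(n)y(n+k)}
{\sqrt{\sum_{n=0}^{N-1} y^2(n)}\sqrt{\sum_{n=0}^{N-k-1} y^2(n+k)}}$$

over lags beyond a 0.25 s exclusion (a 240 bpm ceiling), via a five-point
binary-interpolation search to $10^{-6}$ precision. Signal is periodic,
noise is not — so the autocorrelation peak is a reference-free quality
measure. Classical soft/hard DWT baselines, the reference-based metrics
SNR/SINAD/RMSE/PRD, and seeded generators for ECG-like and
cardiorespiratory-like signals with BW/EM/MA/MIX/white noise are included.

## Worked example

```r
library(aldtf)

clean <- synth_ecg(fs = 360, duration_s = 10, heart_rate_bpm = 72, seed = 1)
noise <- synth_noise("MA", fs = 360, n = length(clean$samples), seed = 2)
pair  <- mix_at_snr(clean, noise, target_snr_db = 5)

res <- aldtf_denoise(pair$noisy)
print(res)
#> <denoise_result> method aldtf, 4 level(s)
#>   D1: lambda = 0.221732, alpha = 182.513
#>   D2: lambda = 0.773705, alpha = 52.3053
#>   D3: lambda = 0.817337, alpha = 48.9132
#>   D4: lambda = 0.520829, alpha = 2.89459e-07
#>   periodicity objective: 0.4462 -> 0.6405 (226 objective evaluations)

delta_metrics(pair$clean, pair$noisy, res$output)
#> <metrics_report>
#>   SNR:    15.2123 dB (input 5.0000 dB, delta 10.2123 dB)
#>   SINAD:  4.3278 dB (input 5.0000 dB, delta -0.6722 dB)
#>   RMSE:   0.0383251
#>   PRD:    17.3534 %
```

Reading the rules: the three fine layers (which carry the 20–100 Hz muscle
artifact) learned large tuning factors — effectively hard thresholding that
keeps surviving QRS coefficients untouched — while the coarsest layer
learned $\alpha_4 \approx 0$, the gentlest shrinkage. The periodicity
objective rose from 0.45 to 0.64, and against the known clean signal that
corresponds to a +10.2 dB SNR improvement. (The SINAD delta uses the
printed power convention in which the removed-noise power counts as
distortion; see the methods vignette.)

The same pipeline is available from the shell:

```sh
Rscript inst/cli/aldtf.R simulate --kind ecg --noise ma --snr 5 --seed 1 --out /tmp/sim
Rscript inst/cli/aldtf.R denoise  --input /tmp/sim.noisy.csv --out /tmp/den
Rscript inst/cli/aldtf.R evaluate --clean /tmp/sim.clean.csv --noisy /tmp/sim.noisy.csv \
                                  --denoised /tmp/den.csv
Rscript inst/cli/aldtf.R bench    --seeds 5 --noise white,ma --snr 5
```

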