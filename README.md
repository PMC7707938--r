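# wwpe — wavelet weighted permutation entropy features for surface EMG

`wwpe` is an R toolkit for recognising hand movements from multi-channel
surface electromyography (sEMG). It implements the **wavelet weighted
permutation entropy (WWPE)** feature set: each channel of a trial is
decomposed with a 4-level discrete wavelet transform (`sym8`), the five
sub-band signals (a4, d4, d3, d2, d1) are reconstructed at full length, and
the weighted permutation entropy of every band is collected into one
feature vector — 4 channels × 5 bands = 20 features — which feeds an SVM or
a three-layer feed-forward network.

It is written for researchers in myoelectric control and biomedical signal
processing who want ordinal-complexity features that keep amplitude
information, a reproducible classification protocol, and a synthetic sEMG
benchmark to exercise the whole pipeline.

## The statistic

For embedding dimension $m$ and delay $\tau$ (defaults $m=4$, $\tau=1$),
each window $(x_i, x_{i+\tau}, \dots, x_{i+(m-1)\tau})$ is mapped to the
permutation that sorts it ascending (ties broken by position). Permutation
entropy is the Shannon entropy of the pattern frequencies,

$$H = -\sum_\pi p(\pi) \ln p(\pi) \in [0,\ \ln m!],$$

and the *weighted* variant counts each window by its population variance
$\omega = \tfrac1m \sum_k (x_k - \bar{x})^2$ instead of 1, so
high-amplitude episodes dominate — both measures are invariant to $a x + b$
($a>0$). WWPE applies the weighted measure to every wavelet sub-band of
every channel.

## Worked example

```r
library(wwpe)

x <- c(4, 7, 9, 10, 6, 11, 3)
cfg <- embedding_config(m = 3, tau = 1)
pattern_distribution(x, cfg)
#> plain ordinal-pattern distribution (m = 3, 5 windows, support 3/6)
#> 3-1-2 2-1-3 1-2-3
#>   0.4   0.2   0.4
permutation_entropy(x, cfg)
#> [1] 1.05492
weighted_permutation_entropy(x, cfg)
#> [1] 0.9800835
```

The five embedding windows produce patterns `1-2-3` (twice), `3-1-2`
(twice) and `2-1-3` (once), hence probabilities 0.4/0.4/0.2 and a PE of
1.055 nats; weighting by window variance shifts mass toward the
high-excursion `3-1-2` windows and lowers the entropy to 0.980 nats.

A full trial-level feature vector, on a synthetic 4-channel, 3 s, 1000 Hz
trial:

```r
set.seed(1)
tr <- generate_trial(1, generator_config())
tr
#> emg_trial: 4 channels x 3000 samples @ 1000 Hz, label = open
round(wwpe_features(tr), 3)
#> ch1_a4_wpe ch1_d4_wpe ch1_d3_wpe ch1_d2_wpe ch1_d1_wpe ch2_a4_wpe ch2_d4_wpe
#>      0.725      0.826      1.207      2.240      2.414      0.722      0.827
#> ch2_d3_wpe ch2_d2_wpe ch2_d1_wpe ch3_a4_wpe ch3_d4_wpe ch3_d3_wpe ch3_d2_wpe
#>      1.166      2.302      2.366      0.726      0.802      1.515      2.169
#> ch3_d1_wpe ch4_a4_wpe ch4_d4_wpe ch4_d3_wpe ch4_d2_wpe ch4_d1_wpe
#>      2.424      0.723      0.807      1.521      2.359      2.363
```

Entropies rise from the slow a4 band (few oscillations per window) toward
the broadband d1 band; the class-specific values sit in the mid bands. An
end-to-end comparison — generate a 210-trial dataset, extract several
feature families, train and evaluate over seeded 70/30 stratified splits:

```r
ds  <- generate_dataset(generator_config(seed = 1))
res <- compare_feature_sets(ds,
         list(feature_spec("wwpe"), feature_spec("subband_wpe", band = "d3"),
              feature_spec("raw_pe")),
         classifiers = "svm", seeds = 0:4)
aggregate(accuracy ~ feature_set, res, mean)
#>      feature_set  accuracy
#> 1         raw_pe 0.8603175
#> 2 subband_wpe_d3 0.8412698
#> 3           wwpe 1.0000000
```

The combined 20-dimensional WWPE set separates all seven movements, while
any single sub-band or the undecomposed signal separates them only
partially — the qualitative result the feature set exists for.

## Command line

A thin CLI over the same functions lives at `inst/cli/wwpe`
(`generate`, `decompose`, `entropy`, `extract`, `train`, `evaluate`,
`compare`, `run`), e.g.

```sh
Rscript inst/cli/wwpe generate --out-dir data/ --seed 1
Rscript inst/cli/wwpe entropy --in data/trial_001.csv --m 4 --tau 1 --weighted
```

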