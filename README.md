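# semgrid

Signal processing and pattern recognition for **high-density surface
electromyography (HD-sEMG)** electrode grids.

HD-sEMG systems record muscle activity through many closely spaced bipolar
electrodes over one muscle region (here: a 16-channel grid, 1 kHz sampling,
microvolt scale, e.g. on the forearm flexor group). Rather than decoding a
single envelope, such systems exploit the *spatial* pattern of activation
across the grid to estimate motion — which finger is flexing, for instance.
`semgrid` implements the complete offline analysis chain for such
recordings, plus a calibrated synthetic-session generator so that every
stage can be exercised and validated without access to recording hardware.

## The method

1. **Conditioning.** Each channel is filtered with an order-4 Butterworth
   bandpass (5–450 Hz, the sEMG band) and a biquad notch (default 60 Hz,
   Q = 30) against power-line interference.
2. **Amplitude features.** Each channel is cut into 200 ms windows sliding
   every 5 ms and summarized by its RMS amplitude
   RMS(w) = sqrt(mean(x²)), the standard EMG amplitude feature.
3. **Pooled 1D Gaussian mixture.** The RMS amplitudes of *all* channels are
   pooled into one sample and a K-component univariate Gaussian mixture
   p(x) = Σₖ wₖ N(x; μₖ, σₖ²) is fitted by expectation–maximization.
   Components are relabeled by ascending mean, so cluster 0 is always the
   quietest activation level.
4. **Simplified 2D spatial pattern.** Every window's per-channel amplitude
   is replaced by the index of its maximum-posterior mixture component and
   the indices are arranged on the electrode grid — a compact, discrete
   picture of which muscle regions are how active. Already K = 2 separates
   distinct motions; K = 10 is the default for classification.
5. **Classification.** A single-hidden-layer network (one-hot pattern
   encoding → 20 tanh units → softmax) maps patterns to motion classes;
   a causal majority vote over the last 41 decisions smooths the stream.
   The cluster-index patterns also rank electrodes by mutual information
   with the motion label, for channel selection.

## Worked example

```r
library(semgrid)

cfg   <- default_finger_flexion_config(seed = 42)   # 16 ch, 6 classes, 82 s
rec   <- generate_session(cfg)
feats <- sliding_rms(notch(bandpass(rec)))          # 200 ms / 5 ms RMS
model <- fit_gmm(feats, K = 10, stride = 4)         # pooled 1D GMM
idx   <- discretize(feats, model)                   # cluster indices

# one middle-finger-flexion window as a spatial pattern
w <- which(feats$labels == "middle" &
           steady_mask(feats$labels, feats$times))[1]
to_spatial_pattern(idx[w, ], cfg$layout, model$K, time = feats$times[w])
#> spatial_pattern: 4x4 grid, K = 10, t = 18.399 s
#>   8  0  0  8
#>   9  0  0  8
#>   0  8  8  0
#>   0  6  6  6

sp   <- block_split(feats$times)                    # first half trains
clf  <- train_classifier(idx[sp$train, ],
                         labels = droplevels(feats$labels[sp$train]),
                         K = model$K, seed = 0)
pred <- majority_vote(predict(clf, idx[sp$test, ]), 41)
evaluate(factor(as.character(feats$labels[sp$test]), levels = clf$classes),
         pred, classes = clf$classes)
#> semg_eval: overall accuracy 0.9647 on 8131 windows
```

The pattern shows the common flexor channels (1, 4, 8 — top corners and
right edge) at high cluster indices, channel 5 (row 2, col 1) at the top
cluster 9 — it is active *only* during middle-finger flexion — and the rest
of the grid near cluster 0. Held-out windowed accuracy after majority-vote
smoothing is 96% on this session; errors concentrate at motion onsets,
where windows straddle two labels.

Channel ranking for "middle vs other flexions" puts the middle-selective
electrode first:

```r
head(select_channels(idx[feats$labels != "rest", ],
     ifelse(feats$labels[feats$labels != "rest"] == "middle",
            "middle", "other")), 3)
#>    channel   mi_bits
#> 5     ch05 0.7219281
#> 10    ch10 0.3221642
#> 11    ch11 0.3220872
```

A command-line front end over the same functions lives at
`inst/cli/semgrid.R`
(`Rscript semgrid.R simulate|preprocess|features|fit-gmm|pattern|train|evaluate|pipeline`).

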