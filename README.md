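# ssvepOSP

Toolkit for a four-class hybrid brain–computer interface driven by
repetitive visual flickers with **missing events**. Four discs flicker at
10 or 12 Hz on a 60 Hz display; every third flicker period is omitted, and
discs sharing a frequency differ only in the timing of their omissions.
The steady flicker elicits a steady-state visually evoked potential
(SSVEP) at the flicker frequency; each omission elicits a tri-phasic
omitted-stimulus potential (OSP) with components near 160, 210 and 290 ms.
A fixated disc is decoded in two stages:

1. **frequency** — canonical correlation analysis (CCA) between the
   occipital EEG segment and sin/cos references at each candidate
   frequency and its second harmonic;
2. **omission timing** — omission-onset-locked epochs are averaged,
   sliced into ten 25 ms windows on [125, 375) ms, classified by a bank of
   ten linear SVMs, and fused with the naive-Bayes likelihood ratio
   *P* = ∏ₖ p<sub>k01</sub><sup>(1−dₖ)</sup> p<sub>k11</sub><sup>dₖ</sup> /
   ∏ₖ p<sub>k00</sub><sup>(1−dₖ)</sup> p<sub>k10</sub><sup>dₖ</sup>,
   with p<sub>kmn</sub> = P(dₖ = m | c = n).

Performance is reported as accuracy and information transfer rate,
ITR = 60/DTI · [log₂N + Acc·log₂Acc + (1−Acc)·log₂((1−Acc)/(N−1))]
bits/min. The package provides the frame-accurate stimulus scheduler, a
seeded forward-model EEG simulator (SSVEP + OSP in 1/f noise on a
10-electrode posterior montage at 1200 Hz), preprocessing, both decoding
stages, session-level evaluation, and EDF/CSV/JSON/YAML interchange. It is
aimed at BCI researchers who want a tested, reproducible reference
implementation of the paradigm and decoder to benchmark against.

## Worked example

```r
library(ssvepOSP)

sched <- defaultParadigm("missing_black")     # 4 discs, 2.5 s, 60 Hz
round(missingOnsets(sched, 1)[1:3], 3)
#> [1] 0.467 0.717 0.967

## simulate a training session (2 runs x 8 trials per task) and train
cfg   <- forwardModelConfig(seed = 2, noiseSd = 2)
train <- simulateSession(trainingProtocol(nRuns = 2, nTrialsPerRun = 8),
                         sched, cfg)
model <- trainDecoder(train, nAvg = 4, foldSeed = 3)

## decode a fresh online block
online <- simulateSession(onlineProtocol(nRuns = 1, nTrialsPerRun = 64),
                          sched, forwardModelConfig(seed = 500, noiseSd = 15))
decodeSession(online, model, nAvg = 4)
#> SessionResult: 64 trials, nAvg 4, Acc 89.06 %, ITR 26.57 bits/min (DTI 3 s)
```

At 15 µV noise the decoder recovers the fixated disc in 57 of 64 trials;
with the noise turned off accuracy reaches 100 % (ITR 40 bits/min at a
3 s decision interval), and accuracy falls monotonically as noise grows.
The published nine-subject online results ship with the package:

```r
pub <- publishedResults()
chk <- table1Check(pub$accuracy_pct[pub$pattern == "black"],
                   pub$averaging_times[pub$pattern == "black"])
round(c(chk$meanAcc, chk$meanItr), 2)
#> [1] 79.29 19.45
```

A thin command-line wrapper lives at `inst/cli/ssvepOSP.R`
(`simulate`, `train`, `decode`, `table1-check` subcommands).

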