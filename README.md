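# neuroreplay

Template-matching detection of memory **replay** in binned neural recordings
from a brain-controlled sequence task.

During learning, cortical populations produce characteristic spatiotemporal
firing patterns; during subsequent rest or light sleep, fragments of those
patterns can recur ("replay"), a candidate mechanism of memory
consolidation. `neuroreplay` implements a complete, testable pipeline for
detecting such replay in intracortical brain-computer-interface recordings
of a 4-target sequence-copying game: one **repeated** target ordering is
played many times, interleaved with **control** orderings that share none of
its target-to-target transitions, and rest blocks recorded before (Rest1)
and after (Rest2) the game are scanned for re-occurrences of the task
patterns. The controls, being veridical neural activity recorded under
identical conditions, serve as the within-task null.

## The method

Given binned neural features (20 ms bins x F features, adaptively z-scored
with a 120 s time constant to suppress slow nonstationarities):

- **Templates.** Either per-target averages (each target's trajectory
  segments resampled to their mean duration and averaged) or one T x F
  template per correctly played trial.
- **Matching.** Each template is slid along a rest block; at lag `l` the
  score is the Pearson correlation between the flattened template and the
  flattened T x F window (normalized 2D cross-correlation), giving a CC
  series. Candidate replay events are local CC peaks above a centile
  threshold of the template's pooled Rest1+Rest2 CC distribution, pruned by
  non-maximum suppression with 0% overlap (at most one peak per template
  length).
- **Sequenced single-target replay.** The four single-target peak sets are
  interleaved into one labeled time series; every 4 consecutive labels are a
  *hit* if they equal a tested ordering. Hits/windows are accumulated across
  sessions and Rest2 vs Rest1 proportions compared with a pooled
  two-proportion chi-square (1 df, no continuity correction).
- **Replay Index.** For each trial template, `m1` and `m2` are the mean peak
  CCs in Rest1 and Rest2 and `RI = (m2 - m1) / m1`. Repeated-trial RIs are
  compared with control-trial RIs within session (pooled-variance one-tailed
  t) and across sessions (paired one-tailed t on session means), over a
  sweep of time dilation factors (0.05x-2.5x) and centile thresholds (75,
  90, 95, 99, 99.9). The same tests with the groups exchanged (*swapped*
  tests) form the empirical multiple-comparison null.
- **Sleep restriction.** The 4-7 Hz (theta) Hilbert envelope of the 1 kHz
  LFP, thresholded at the 80th percentile of task-period theta, delineates
  putative NREM1 from putative waking rest bins (with used-bin counts
  equalized), and the RI analysis is repeated per state.

Because the clinical recordings behind the original analysis are not
publicly available, the package ships a synthetic-session generator
(`synth_config()`, `synthesize_session()`) that emulates the full session
structure — 66 repeated + 22 control trials, jittered per-target motifs in
autocorrelated drifting noise, two rest blocks with ground-truth replay
events embedded at controlled compression and rate, and an LFP with theta
bursts during scheduled NREM1 epochs — so every stage is verifiable against
known ground truth.

## Worked example

Ten-times-compressed repeated-template events embedded only in Rest2 should
produce a Replay Index excess for repeated over control templates at (and
only at) dilation 0.1:

```r
library(neuroreplay)

cfg <- synth_config(
  n_features = 16, n_repeated_trials = 12, n_control_trials = 11,
  per_target_duration = 0.6, rest1_duration = 4, rest2_duration = 4,
  event_rate_rest1 = 0, event_rate_rest2 = 2.5,
  event_compression = 0.1, event_gain = 1.3, seed = 42
)
synthesize_session(cfg)
#> <replay_session> seed 42: 23 trials (12 repeated, 11 control), 16 features
#>   Rest1 4.0 min, Rest2 4.0 min; 9 embedded events

sessions <- lapply(1:6, function(i) { cfg$seed <- 42L + i; synthesize_session(cfg) })
sweep <- run_sweep(sessions, dilations = c(0.05, 0.1, 0.5, 1, 2),
                   centiles = 95, tau = 45)
tidy(sweep)
#> # A tibble: 5 x 10
#>   dilation centile state n_sessions mean_ri_repeated mean_ri_control       t       p t_swapped p_swapped
#> 1     0.05      95 all            6          -0.0158         -0.0202  1.35   0.118     -1.35       0.882
#> 2     0.1       95 all            6           0.0136         -0.0257  4.99   0.00207   -4.99       0.998
#> 3     0.5       95 all            6          -0.0633         -0.0629 -0.0497 0.519      0.0497     0.481
#> 4     1         95 all            6          -0.0832         -0.0759 -1.11   0.841      1.11       0.159
#> 5     2         95 all            6          -0.0920         -0.0836 -0.476  0.673      0.476      0.327

glance(sweep)
#> # A tibble: 1 x 6
#>   n_cells best_dilation best_centile   min_p n_significant n_significant_swapped
#> 1       5           0.1           95 0.00207             1                     0
```

The paired one-tailed test is significant only at the true timescale
(dilation 0.1, p = 0.002: repeated-template RIs exceed control-template RIs
across sessions), and no swapped test approaches significance —
the multiple-comparison null is quiet. `autoplot(sweep)` draws the
RI-difference profile; `plot_ri_distributions()` shows the per-trial RI
distributions behind any cell.

The same objects drive the rest of the pipeline:
`single_target_replay_counts()` + `sequenced_replay_test()` for sequenced
single-target hits, `behavioral_summary()` for the learning check,
`score_session_states()` + `state_restricted_replay()` for sleep/wake
restriction, and `analyze_sessions()` to run everything and write
TSV/JSON reports. A thin command-line wrapper lives in
`inst/cli/replay-pipeline.R` (`simulate` / `analyze`).

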