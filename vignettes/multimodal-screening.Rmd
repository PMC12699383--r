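---
title: "Multimodal early dyslexia screening: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal early dyslexia screening: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexiscreen)
```

Developmental dyslexia affects roughly one child in ten, and most affected
children in low-resource settings are never formally assessed. lexiscreen
implements an offline, scriptable screening toolkit built on four low-cost
digital biomarkers — oculomotor reading behaviour, oral-reading fluency,
handwriting orthography, and a behavioural questionnaire — plus a
syllable-level reading-support transformer. This vignette explains the
models and rules each module implements, the parameters that matter, what
the synthetic generators do and do not emulate, and the design decisions
taken where the design was genuinely open.

## Oculomotor screening

Dyslexic reading shows longer fixations, more regressive (backward)
saccades and slower overall progress through the text. From a fixation
event table (one row per fixation with onset/offset times, horizontal and
vertical displacement since the previous fixation, and the text line it
fell on) the package computes four trial-level features:

* `n_fix` — fixation count;
* `mean_fix` — mean fixation duration (ms);
* `regression_ratio` — fraction of fixations whose horizontal displacement
  is strictly negative (a zero displacement is *not* a regression);
* `total_read_time` — `max(end_ms) − min(start_ms)` (ms).

The number of distinct text lines visited (`line_switches`) is computed as
a diagnostic but deliberately excluded from the classifier: line-based
measures generalize poorly under webcam-quality gaze estimation, so the
classifier consumes exactly the four features above. Candidate features
such as fixation-duration variance and horizontal dispersion are
intentionally not computed at all.

`gaze_mlp()` fits the classifier: a multilayer perceptron with one hidden
layer of 64 rectified linear units and a two-way softmax, trained with
full-batch Adam (step size 0.001, the optimizer's conventional default) on
a cross-entropy loss. The data are split 80/20 by stratified sampling;
features are z-scored with mean and standard deviation estimated on the
training split only, and the scaler travels with the weights — at
prediction time the identical transform is applied, and
`save_gaze_model()` serializes both into one JSON artifact with 17
significant digits so a reloaded model reproduces probabilities
bit-for-bit. Training runs at most 500 epochs with early stopping once the
loss has not improved by a relative 1e-6 for 25 consecutive epochs; the
network and optimizer are implemented directly in the package because the
architecture is small enough that a dependency would cost more than it
saves. A held-out probability of exactly 0.5 resolves to "typical" — the
conservative choice for a screening tool, where a coin-flip case should
not be flagged.

The live-gaze path is distinct by design. A bounded buffer
(`gaze_buffer()`, capacity 100, oldest evicted first) accumulates webcam
gaze samples; `extract_live_gaze_features()` refuses to work with fewer
than 5 points ("insufficient data") and otherwise reports the number of
fixations from a classical dispersion-threshold detector, mean gaze
velocity (mean consecutive-point step divided by mean inter-sample
interval), the count of leftward jumps exceeding a configurable threshold
(default 2% of screen width — the literature does not quantify "backward",
so this is an explicit, configurable choice), and the observation span.
The offline classifier is trained on the offline four-feature vector; the
live vector is *not* fed to it, because the two feature sets measure
different things and no mapping between them is established.

`detect_fixations_dispersion()` uses the classical I-DT scheme: a fixation
is a maximal run whose bounding-box width + height stays within the
dispersion threshold (default 50 screen units) and whose span reaches the
minimum fixation duration (default 40 ms, a conventional minimum used in
pediatric eye-tracking preprocessing). Timestamps must be non-decreasing;
the detector is deterministic.

## Speech fluency

The speech module consumes a reference passage, a transcript (any ASR
engine can sit upstream; none is bundled) and per-word timestamps. Word
error rate is the minimal word-level edit distance normalized by the
reference length, over case-folded, punctuation-stripped, whitespace-split
tokens; the same tokenizer is shared with the handwriting module so the
two WERs are commensurable. Pauses are the strictly positive gaps between
consecutive words — contiguous words contribute nothing, and overlapping
ASR timestamps (negative gaps) are discarded rather than treated as
negative pauses.

From the timings the module derives total time (last end − first start),
speech time (sum of word durations), words per minute
(`n / total_time × 60`), and articulation rate (`n / speech_time`).
Articulation rate is in words per *second* — there is deliberately no ×60
— measuring speed over actual speaking time with pauses excluded; the
unit difference from WPM is easy to miss and is flagged in the
documentation. Mean word duration and mean pause are computed for reports
but do not enter the decision rule.

The decision rule scores one point per criterion, all boundaries
inclusive: WER ≥ 0.15, count of pauses longer than 0.2 s ≥ 5, and
WPM ≤ 80. Two or more points yield "Likely Dyslexia". These constants
live in `lexi_config()` so a single test enumerates every boundary.

## Handwriting orthography

Both the expected sentence and the transcribed handwriting (OCR output in
a deployed system; any transcriber can be plugged in) are normalized with
Unicode NFKC and lowercased, then aligned at character level by a
matching-blocks (Ratcliff–Obershelp-style) matcher with deterministic
tie-breaking — always the earliest, longest common block. This matcher
mirrors the behaviour of classic sequence-matcher diffs; its opcodes are
*not* guaranteed minimal, which is why the package also exposes a
minimal-Levenshtein mode (`compute_error_rates(..., minimal = TRUE)`) for
sensitivity analysis, and why the test suite asserts the opcode-based CER
is always at least the minimal-distance CER.

CER is (substitutions + insertions + deletions) divided by the character
length of the normalized expected sentence. Spaces count in the
denominator: the cap is a fixed reference sentence, the choice is
documented, and changing it would rescale CER by a known constant.
A `replace` span of unequal lengths counts position-wise substitutions up
to the shorter side, with the overhang booked as insertions or deletions.
Letter reversals — aligned pairs from {b↔d, p↔q}, the hallmark
mirror-confusions of early dyslexic writing — are counted only inside
`replace` spans, position-aligned, so a reversal is always also a
substitution (`reversal_count ≤ substitutions` is an enforced invariant).

Risk scoring assigns each of six features (CER, WER, substitutions,
insertions, deletions, reversals) 0, 1 or 2 points by severity. The
published description fixes the banding (≥ 7 High, 4–6 Moderate, < 4 Low)
but not the per-feature point thresholds; the default table
(CER 0.10/0.25, WER 0.15/0.40, each edit counter 2/4, reversals 1/2 for
one/two points) is therefore a declared artifact decision of this
package, chosen so that both bands remain reachable and a single severe
feature cannot dominate. It is config-overridable and serialized into
every report. Expected sentences are capped at 500 words.

## Behavioural questionnaire

Nine items on a 4-point Likert scale (0–3) give a 0–27 total, banded
0–6 "Unlikely dyslexia", 7–13 "Mild signs", 14–20 "Moderate concern",
21–27 "High concern". The canonical item wording is not published; the
shipped bank (`inst/extdata/quiz_items.json`) is a clearly labelled
synthetic stand-in covering the usual screening themes
(reversal confusion, rhyming difficulty, inconsistent spelling, slow
reading, avoidance) and is editable configuration, not a validated
instrument. Responses stay local; there is no network I/O.

## Fusion and reports

Each present modality is mapped onto [0, 1]: the gaze dyslexia
probability; speech rule score / 3; handwriting risk score divided by the
maximum attainable score under the active severity table (12 by default);
quiz total / 27. The combined score is a weighted average over *present*
modalities with renormalized weights (default equal), banded Low /
Moderate / High at 1/3 and 2/3. No published fusion formula exists; a
renormalized weighted mean was chosen over a second-stage classifier
because it is transparent, monotone in every modality, degrades gracefully
to a single modality (pass-through — a tested identity), and requires no
training data. Weights and cut points are configuration serialized into
every report.

Reports render as lossless JSON (round-tripping to an equal session
record; doubles at 17 significant digits) and self-contained HTML with all
metrics, the character-level diff, band messages and the fusion
configuration. Sessions append to a newline-delimited JSON log; the reader
skips and flags corrupt lines instead of failing, so one damaged record
never hides the rest.

## Reading support

`syllabify_passage()` tokenizes a passage preserving every non-alphabetic
character verbatim, caps input at 5000 words, and segments each word with
a rule-based English syllabifier: vowel-nucleus grouping (with `y` as a
vowel except word-initially), V-CV division before a single consonant,
VC-CV between two (keeping the digraphs ch/sh/th/ph/wh/ck/qu/gh intact),
silent final e, consonant-le endings, and the -ing suffix. Hyphenation
pattern dictionaries are the usual engine for this job; the rule set here
approximates them for English and trades dictionary coverage for a hard
guarantee that matters more in this context: stripping the separator from
the output reproduces the input byte-for-byte, so the display layer can
never corrupt the text. Line chunks are produced at sentence boundaries
(default) or a fixed width, for line-by-line highlighting. Text-to-speech
and gaze-triggered advancement are exposed only as metadata for a front
end; no audio is produced.

## Synthetic generators

The generators exist so every pipeline stage — including the trained
classifier — is exercisable with no cameras, microphones or external
corpora. `gen_fixation_table()` draws fixation durations from a truncated
normal and flips each fixation's displacement sign with the profile's
regression probability; defaults (typical 220 ± 30 ms and regression
probability 0.12; dyslexic 330 ± 50 ms and 0.30, with more fixations per
trial) are literature-plausible magnitudes chosen once to give roughly a
2.5-pooled-SD separation in mean fixation duration. They are generator
parameters, not published estimates, and the documentation says so.
`gen_word_timings()` fixes the total span to `n / wpm × 60` seconds so the
recomputed WPM equals the target exactly, inserting a specified number of
pauses at seeded positions. `corrupt_text()` flips b/d/p/q characters with
a given probability and applies uniform substitutions, insertions and
deletions, returning the injected counts as ground truth.

Every generator is a pure function of its arguments and a seed: the
caller's RNG state is saved and restored, per-trial seeds are derived
arithmetically from the cohort seed, and identical calls are
bit-identical. What the generators do **not** emulate is worth stating:
real gaze noise (blinks, track loss, calibration drift), the long-tailed
and autocorrelated structure of real fixation sequences, ASR-specific
error patterns, or OCR confusion beyond the four reversal letters.
Passing tests on synthetic cohorts demonstrates that the pipeline
recovers what was injected and that the classifier learns a separable
signal — not that the defaults match any clinical population's effect
size.

A subtlety the tests encode: when adjacent letters are both flipped
(e.g. "bd" → "db") the aligner may legitimately resolve the difference as
an insertion plus a deletion rather than two replacements, so the detected
reversal count is asserted as a lower bound of the injected count
(equality holds for isolated flips).

## Numerical and testing choices

Problem sizes were chosen to keep the full suite fast while leaving the
statistical assertions well-powered: classifier properties use cohorts of
200 trials across 10 seeds (held-out accuracy ≥ 0.9 in at least 8 of 10
under ≥ 2-pooled-SD separation, and mean held-out accuracy within
0.5 ± 0.1 when both classes share identical generating parameters);
word-level edit distances are verified exhaustively against an
independent dynamic-programming oracle for all sequence pairs up to
length 6 over a two-word alphabet plus randomized checks over a three-word
alphabet; opcode-versus-minimal CER ordering is checked on 1000 random
string pairs. Degenerate inputs are first-class: empty fixation tables
signal an unusable trial (`NULL`) rather than erroring, an empty reference
is an error, a zero-length recording is an error, and a constant feature
column gets unit variance in the scaler instead of producing NaNs.

Known limitations: the gaze classifier is only as good as upstream
fixation events (no event detection from raw gaze is included beyond the
live dispersion counter); the speech rule is a fixed heuristic, not a
fitted model; the handwriting severity points are package defaults, not
validated clinical weights; the syllabifier is English-only and rule
based; and none of the outputs is a diagnosis — the tool flags children
for professional follow-up.
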