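---
title: "Scoring sound-evoked chaining behavior from chamber video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sound-evoked chaining behavior from chamber video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychain)
```

## The behavior and the measurement problem

When groups of *Drosophila* males hear courtship-song playback, they chase
one another in trains — chaining behavior. The group-level response is
quantified per video frame as the **chain index**: the number of flies
participating in chains, counting both the chasers and the passive
recipients they orient to (the leader of a train is in the chain even
though it chases nobody). Scoring this by eye is slow — hours per
recording — and `flychain` automates it for backlit chambers filmed from
above, up to four chambers per camera frame, six males per chamber at the
standard 50 × 10 mm chamber and 0.12 mm/px scale.

## Detection model

Scoring runs at 1 frame per second; the recording (typically 30 fps) is
down-sampled by keeping the first frame of each one-second bin. The rule is
deliberately deterministic — averaging frames would blur moving flies, and
any single-frame pick is equivalent for a 1-Hz behavior score.

**Background.** The static background is the pixel-wise mean of 40 frames
drawn uniformly without replacement (caller-seeded, so runs reproduce).
Because flies are small, dark and mobile, the sample mean approximates the
empty chamber; the residue at a pixel is bounded by
(silhouette contrast) × (occupied samples)/40. With 40 samples the residue
at a visited pixel cannot fall below contrast/40 — about 1.8% of range for
high-contrast backlit silhouettes — which is why tests assert that exact
bound rather than an arbitrarily small one.

**Segmentation.** Flies are darker than the backlit background, so the
foreground signal is `background − frame` clipped at zero, binarized with
Otsu's threshold. Connected components are kept inside an area band
derived from the body statistics of *D. melanogaster* (2.27 ± 0.44 mm long,
~19 px at 0.12 mm/px, ~120 px² silhouette): `min_area = 40` px² rejects
debris, and components above `max_area = 180` px² (1.5× the nominal
single-fly area) are flagged as merged blobs. The merged threshold is set
low enough that even two flies overlapping by a third exceed it; flagged
blobs are split into the chamber's expected fly count by k-means on pixel
coordinates. This split is a pragmatic recovery heuristic, not a tracker —
its only guarantee is that the parts partition the blob.

**Pose.** Each silhouette's centroid, axes and orientation come from the
eigen-decomposition of the pixel-coordinate covariance matrix; a full axis
length is `4·sqrt(eigenvalue)`, the convention under which a uniform solid
ellipse recovers its own axes. Blobs with an eigenvalue ratio under 1.2 are
near-circular: their axis is noise, so they are flagged degenerate and
build no chain region that frame.

**Head/tail.** The abdominal tip of a fly is sharper than its head. A
Harris–Stephens corner response is computed on the silhouette mask
(Gaussian-smoothed at σ = 1 px — the response on raw binary edges is
noise-dominated), and of the two major-axis endpoints the one with the
larger maximal response within 3 px is the tail. When the two responses
are within 10% of each other the corner cue is treated as ambiguous and
the assignment that best preserves the previous frame's heading wins;
identity across frames is simple nearest-centroid linking used only for
this tie-break. At 1 fps, linking is reliable only while per-frame
displacement stays below half the inter-fly spacing — the package makes no
long-range identity claims.

## The chain region and the chain index

Each fly projects a fan-shaped **chain region** in front of its head,
anchored at the head base *Q* — the point on segment *TH* 5 px (0.6 mm)
behind the head *H*. The region is the circular sector of radius
`q_offset + L` about *Q*, restricted to directions within `k·π/2` radians
of the heading `H − T`; boundary points count as inside. It therefore
extends exactly *L* beyond the head tip along the body axis. The defaults
`L = 13` px (1.56 mm) and `k = 0.66` (half-angle ≈ 59°) are the constants
at which automated scores match manual inspection; the whole geometry sits
behind a single predicate (`chain_region_contains()`) so the
parameterization can be swapped without touching the graph code.

A directed chasing edge `i → j` is drawn when any pixel of fly *j*'s body
(its silhouette when available, else the fitted-ellipse interior
rasterized) lies in fly *i*'s region; a fly's own body is excluded, so
there are no self-edges. The chain index of the frame is the number of
distinct flies incident to at least one edge, as source or target — one
chaser–recipient pair scores 2, a three-fly train 3. Mutual edges are
possible and count each fly once.

## Behavioral metrics

All metrics assume the 1-Hz series. Time courses are smoothed by
non-overlapping 10-frame block means (a trailing partial block averages
its remaining frames). A **cumulative chain index** sums the series over a
half-open phase window `[start, end)`; the standard phases are 60 s
(silent / immediate / later, or phases I–V of the plasticity protocol).
**Chain probability** divides the cumulative index by flies × window
frames; for the 2.5-min window at 1 fps the per-fly maximum is 150.
Probabilities are variance-stabilized with the arcsine-square-root
(**angular**) transform `asin(sqrt(p))` before computing a rate between a
window pair as `(AC₂ − AC₁)/AC₁` — the suppression, recovery or drop rate
depending on the pair. The transform's form is the standard one for
proportion data; the probability normalization above is the denominator
used throughout.

Window timing follows the playback protocol: silence for 5 min, then
playback. "5′11″ to 6′10″" is interpreted as the half-open 60-s interval
`[311, 371)` so that all phases are exactly one minute; the suppression
pair is `[311, 371)` vs `[1431, 1491)`, and the recovery and drop pairs
bracket the song shifts at 25 and 40 min with the minute before and the
minute after each shift. The five named phases of the plasticity protocol
are playback onset, end of the first continuous playback, the minute after
the 25-min shift, and the minutes before and after the 40-min shift —
five non-overlapping windows; note the recovery pair's pre-shift window
(`[1440, 1500)`) intentionally differs from phase II (`[1431, 1491)`),
which is tied to the printed playback-end timestamps.

## Stimulus synthesis

Pulse songs are trains of brief sine pulses at a fixed **inter-pulse
interval** (IPI, onset to onset), with carrier (intrapulse) frequency
167 Hz for *D. melanogaster*-type stimuli and 333 Hz for
*D. simulans*-type; sine songs are a continuous carrier. Bursts of 1 s are
separated by 2 s of silence unless the song is continuous (no silence).

A pulse lasts **2 carrier cycles** (~12 ms at 167 Hz) with a 10%
raised-cosine taper against clicks. Two cycles is the unique simple pulse
length under which the "every pulse ends within its burst" counting rule —
`(n−1)·IPI + pulse ≤ burst` — simultaneously yields 66 pulses per 1-s
burst at 15-ms IPI, 29 at 35 ms, and 10 at 105 ms, the stimulus arithmetic
the package reproduces; it is a reconstruction hypothesis and is
overridable (`pulse_cycles`). A fixed-pulse-count mode extends the burst
instead (29 pulses at 105-ms IPI span 2.95 s ≈ 3 s).

Oscillating IPIs emulate the natural *D. melanogaster* song rhythm: each
successive interval is read off a sinusoid of period 58 s spanning
29–40 ms, evaluated at the current pulse time. Evaluation is
phase-continuous across bursts rather than reset per burst, so the 58-s
rhythm survives the burst structure. Waveforms are written as mono PCM WAV
(16-bit integer or 32-bit float).

## Synthetic scenes and validation

The renderer draws dark teardrop silhouettes (~19 × 8 px, intensity 0.2 on
a 0.9 background — the strong contrast of backlit imaging) into a
417 × 83 px chamber at 1 fps, with optional seeded Gaussian noise. The
teardrop's posterior half tapers linearly to a point while the anterior is
a blunt superellipse (exponent 3): with that shape the tail's Harris
response exceeds the head's by at least 1.5× at every orientation, which
keeps the head/tail test a real test rather than a trivially easy one.
Scripted scenarios provide idle (dispersed, chain index 0), chain trains
(following at a 6-px tip gap — near contact, as real chains — translating
at 20 px/frame so consecutive 1-fps footprints do not overlap), per-frame
randomized dispersed configurations, and a patrol path of disjoint
footprints for background-model checks.

Ground truth — exact tip positions and the true chain index — comes from a
**clean-room oracle** that shares no code with the detection geometry: it
rasterizes every chain region and body mask over the full chamber grid and
intersects pixel sets. Validation then has three tiers, at the problem
sizes the suite uses: exact equivalence of detection geometry and oracle
on 100 randomized 6-fly configurations; pose recovery on 200 rendered
single-fly frames (median centroid error < 1 px, median axis error < 3°,
head/tail ≥ 95%); and end-to-end reproduction of scripted chain indices
through the full pipeline (≥ 95% of frames exact on non-touching
scenarios, stable under intensity noise up to 5% of contrast and under
`L ∈ {12, 13, 14}`, `k ∈ {0.5, 0.66, 0.75}`).

The renderer emulates silhouette geometry, not fly biology: no wings,
legs, grooming postures, occlusion by chamber walls, illumination
gradients, or realistic locomotion statistics. Passing these suites shows
the geometry, pose estimation and scoring are internally correct and
mutually consistent — it does not certify performance on real video, where
segmentation contrast and touching-fly frequency are the binding
constraints.

## Numerical and design notes

- All region boundaries are inclusive; containment uses a cosine
  comparison with a 1e-12 slack so boundary pixels do not flicker across
  parameter sweeps.
- *Q* construction requires `|H − T| > q_offset`; shorter bodies raise an
  error rather than silently flipping the region.
- Degenerate or unreliable poses emit no outgoing edges but can still be
  chased (they remain valid recipients).
- Background sampling, k-means splitting, scenario randomization and noise
  are all explicitly seeded; the package never consumes the global RNG
  state without restoring it.
- Video containers are not decoded; recordings are ingested as numbered
  PNG/TIFF frame directories or in-memory matrices.
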