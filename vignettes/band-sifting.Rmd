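---
title: "Band-sifting material editing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-sifting material editing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandsift)
```

## The model

Human material perception — judging gloss, roughness, blemishedness or
freshness from an image — is driven to a large extent by the statistics
of spatial-frequency subbands of the lightness signal. `bandsift`
exploits this: rather than modelling the physics of a surface, it
isolates the lightness structure at particular combinations of scale,
contrast and polarity and rescales it. Small bright high-contrast
elements read as gloss and wetness; small dark high-contrast blobs read
as spots and wrinkles; low-contrast high-frequency texture reads as
roughness; large smooth dark gradients read as shading.

The pipeline is:

1. **Colour separation.** sRGB → CIELAB (D65, 2° observer). Only the
   lightness channel L is edited; the a/b opponent channels pass
   through untouched, so hue and chroma are preserved by construction
   (only the final gamut clip to `[0, 1]` sRGB can move colours, and
   only for out-of-gamut results).
2. **Log lightness.** L is floored at `epsilon` and log-transformed.
   Multiplicative lightness structure (shading × reflectance) becomes
   additive, which is what makes feature rescaling behave like a
   contrast change rather than an additive haze.
3. **Scale decomposition.** Repeated self-guided guided filtering at
   doubling radii peels off `K = floor(log2(N)) - 1` subbands for a
   shorter side of `N` px, plus a residual. The decomposition
   telescopes, so subbands + residual reconstruct the input exactly
   (to `1e-9` in the tests).
4. **Sifting.** Each subband splits at one standard deviation of its
   own pixel values into high/low amplitude, then by sign, into four
   quadrants with disjoint supports. Quadrants group across the
   first `floor(K/2)` (high-frequency) and remaining (low-frequency)
   subbands into the eight BS features.
5. **Editing and reconstruction.** Each quadrant is multiplied by its
   factor from the factor table, everything is summed with the
   residual, exponentiated, clipped to `[0, 100]`, recombined with the
   original a/b and converted back to sRGB.

Because the edit is a per-quadrant multiplication, the output responds
linearly (in log-lightness) to the strength, effects compose
commutatively (tables combine by cell-wise product), and strength 1 is
the exact identity — the engine short-circuits an all-ones table and
returns the input array bit-for-bit, so no colorspace round-off ever
contaminates control stimuli.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `strength` | 1 | multiplicative factor | 1 = identity; 1.5–4 boosts; < 1 reduces; negative inverts (useful for visualisation, rarely for stimuli) |
| `max_size` | 1280 | px | shorter-side cap before editing; a 2000×3000 input becomes 1280×1920. `NA` disables |
| `guided_filter_eps` | 0.01 | squared log-lightness | edge-preservation threshold: structures with local variance well above it survive smoothing; texture below it is smoothed |
| `radius_base` | 2 | — | subband *i* is peeled at radius `radius_base^i`, giving octave spacing that matches the log₂ subband count |
| `log_epsilon` | 1e-4 | L units | floor before the log; keeps black pixels finite and is inverted exactly for L ≥ epsilon |

The paper-level interface mirrors the method's published surface:
`modif()` with effect aliases, `modif2()` with explicit
freq/amp/sign/strength selectors (including integer subband indices,
e.g. `freq = 1:2` to exclude a noisy scale), and `modif_dim()` for the
subband bookkeeping. The sign selector canonically uses `"N"` for
negative; `"L"` is accepted as a synonym because both spellings
circulate.

## Design choices where the design was open

* **Radius schedule and eps.** The published description fixes the
  filter family (guided filter) and the subband count but not the
  per-level radii or regularization. We use radii `2^i` so subband `i`
  isolates detail between scales `2^(i-1)` and `2^i` px — the unique
  geometric schedule consistent with one subband per octave — and
  default `eps = 0.01`, exposed in `bs_config()`. Pixel-exact agreement
  with other implementations is therefore not claimable; the structural
  invariants (counts, grouping, reconstruction, no-op identity) are
  what the tests pin down.
* **Boundary handling.** Box windows are truncated at the image border
  and normalised by the actual window area, rather than padded;
  reflective padding would create halo bias at strong border edges.
* **SD definition.** The amplitude threshold is the population SD of
  all subband pixels (including zeros); subbands are near-zero-mean
  difference images, so this is the natural scale. A pixel exactly at
  one SD counts as low amplitude (deterministic, measure-zero choice).
* **Factor granularity.** Factors live at (subband, amplitude, sign)
  granularity, not merely at the eight-feature level, because explicit
  per-subband selection (`freq = 1:2`) requires it; the eight BS
  features are derived views, and scaling every quadrant of a group is
  provably identical to scaling the grouped feature.
* **Overlapping selectors** multiply. This is the only commutative,
  associative rule consistent with order-independent multi-effect
  calls, and it makes `aging` (= HLA + HHN) alongside an explicit HHN
  well defined regardless of listing order.
* **Single-pass semantics.** Multiple effects in one call share one
  decomposition and one combined table. Sequential application of the
  same effects gives a close but not identical result (the first edit
  changes the statistics the second sees); the single-pass form is the
  recommended, reproducible semantics.
* **`shadow` → LLN** is provisional: shadows are large-scale dark
  gradients, which is LLN territory, but the alias has no published
  per-feature test to pin it; the low-level selectors are authoritative.
* **Mask blending in sRGB.** `out = mask·edited + (1−mask)·original`
  per channel, computed after colour conversion. Blending in Lab
  instead would differ at second order; sRGB blending guarantees
  bit-exact passthrough where the mask is 0 and bit-exact edits where
  it is 1.
* **Log base.** Natural log. The base only rescales every subband by a
  constant, which the SD threshold absorbs, so any base produces
  identical outputs.
* **Resampling.** `max_size` downscaling uses area averaging
  (implemented with sparse overlap-weight matrices). An interpolating
  kernel would alias fine texture into exactly the high-frequency
  subbands the method edits. The long side rounds half away from zero.
  JPEG output is written at quality 95 for reproducible artifacts.

## What the fixtures emulate — and what they do not

The procedural fixtures carry the statistical signatures the effects
target: `make_glossy_surface()` stamps small bright Gaussian highlights
(HHP energy) on smooth mid-gray texture, `make_spotted_surface()` dark
blobs (HHN energy) on a bright base, `make_shaded_surface()` a smooth
large-scale illumination gradient (low-frequency/residual energy). They
are bit-reproducible functions of `(size, seed, parameters)`, and blob
centres are drawn pairwise so enlarging the count keeps earlier blobs
in place (feature energy is monotone in the count).

They are deliberately not photorealistic: near-achromatic, noise-based,
with no geometry, specular BRDF, or semantic content. Passing tests on
them demonstrates that the engine moves the intended feature in the
intended direction with the intended arithmetic — not that any given
photograph of skin or food will look natural at a given strength. On
real photographs the perceptual effect per unit strength varies with
image content, and features absent from the input cannot be boosted
into existence; pilot your strengths per image set.

## Numerical notes and degenerate inputs

* Images below 4×4 px are rejected (they would yield zero subbands).
  `K = 1` is legal: the high-frequency group is then empty and the four
  H* features are all-zero.
* A constant image decomposes into all-zero subbands (the guided filter
  is exactly identity-preserving on constants); its SD is 0 and every
  pixel sifts to the low-amplitude quadrants as zero.
* Reconstruction clips lightness to `[0, 100]` and the final sRGB to
  `[0, 1]`; extreme strengths are legal and simply saturate there.
* All randomness in the package lives in the fixture generators, which
  seed locally and restore global RNG state.

## Problem sizes used by the test-suite

Property suites run at 8–256 px (brute-force guided-filter oracles at
≤ 16 px, reconstruction at up to 512 px); the factorial batch check
builds 4 synthetic 500×500 inputs × 6 effects × 7 strengths = 168
stimuli, matching a realistic stimulus-set design at the resolution
typical for on-screen rating experiments.
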