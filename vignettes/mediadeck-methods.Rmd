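---
title: "MediaDeck: methods, conventions and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MediaDeck: methods, conventions and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MediaDeck)
```

MediaDeck curates exported biomedical image and video collections in a
managed local library and derives deterministic per-image descriptors for
dataset-structure analysis. This vignette is the package's own account of
what it computes, the conventions it fixes, and why the open design choices
were made the way they were.

## The managed library

A library is a directory holding `library.db` (SQLite) and six fixed
subdirectories: `originals/`, `thumbnails/`, `previews/`, `posters/`,
`zips/`, `logs/`. Originals are immutable and content-addressed: an imported
file is copied to `originals/<sha256>.<ext>`, its copy digest verified
against the source before the asset row is inserted. This copy–verify–insert
ordering means a crash can strand at most an unreferenced file in
`originals/` (reported by `auditLibrary()` as an orphan), never a registered
asset without verified bytes.

Duplicate detection is **library-wide**: a candidate whose SHA-256 matches
any existing asset — from any source label — is recorded as a duplicate
event and not re-imported. Within one job, candidates are processed in
lexicographic (bytewise) order of their relative paths, so when a tree
contains two byte-identical new files the first becomes the asset and the
second the duplicate event, deterministically.

Import accounting distinguishes *skipped* (never attempted: hidden files,
unsupported extensions) from *failed* (attempted and errored: undecodable or
vanished files, videos without a prober). Hidden or unreadable directories
are logged and not descended; their contents are never discovered, so they
appear in no counter. On every completed job
`discovered = processed + duplicates + skipped + failed` exactly.

Supported extensions are images `.jpg/.jpeg/.png/.tif/.tiff` and videos
`.mp4/.mov/.avi/.webm/.mkv`. The image list matches the decoders the
package actually carries (PNG, JPEG, TIFF); claiming formats that would
invariably fail at decode time would only convert skips into failures.

Full-text search uses an FTS5 index with the `unicode61` tokenizer and `-`
and `_` declared as token separators, because biomedical export names are
overwhelmingly snake- or kebab-cased (`he_stain_tile-042.png` should match
`stain`). The searchable text of an asset is the concatenation of filename,
display name, source label, folder context and tag names, rebuilt on every
tag change. Ranking is bm25 rank, with ties broken by `imported_at`
descending then id ascending so results are reproducible. Bare query terms
containing separators are wrapped as phrases before matching, so a plain
tag or filename query works verbatim while explicit `AND`/`OR`/`NOT`/prefix
syntax passes through; genuinely malformed syntax raises a query error.

Timestamps are UTC ISO-8601 at seconds precision (sortable text). Asset ids
are surrogate integer keys; the hash is a uniquely indexed *content*
property, not the identity. Tag names are unique case-insensitively with
the first spelling kept. The configuration file is YAML
(`<root>/config.yaml`), one transparent text file beside the database;
unknown keys are rejected by name so typos cannot silently disable an
option.

## Derivatives

Thumbnails (longest edge ≤ 256 px) and previews (≤ 1024 px) are baseline
JPEGs at quality 82, named by the asset's hash stem for auditability.
Scaling preserves aspect ratio with half-up rounding
(`floor(x * s + 0.5)`, minimum 1 px) and never upscales. Video derivatives
take the poster frame at 10 % of the duration (avoiding black lead-in
frames), a preview clip of `min(3 s, duration)` from that point re-encoded
to web-playable MP4, and a thumbnail from the poster; both video paths
require an `ffmpeg`-compatible toolkit and degrade to per-file failures
with an environment message when it is absent. Derivatives are disposable:
`regenerateDerivatives()` rebuilds them from originals with identical
dimensions (byte identity across encoder versions is not promised, and not
needed — integrity claims attach to originals only).

## The feature pipeline

All descriptors operate on an `H x W x 3` array in `[0, 1]`: grayscale
is promoted by replication, alpha flattened onto white, because that is how
the images are viewed. Coordinates are 0-based pixel centres;
off-grid samples use bilinear interpolation.

**Line profiles.** Four canonical segments — main diagonal `(0,0) ->
(W-1,H-1)`, anti-diagonal `(W-1,0) -> (0,H-1)`, middle row, middle column —
are resampled at `P` points evenly spaced in the segment parameter. Each
profile is summarized per channel by mean, population SD, min, quartiles
(linear interpolation between order statistics, the standard type-7 rule),
median, max and range, plus the mean and max absolute first difference of
the resampled values as gradient measures. Population (not sample) SD is
used everywhere in the package, so constant inputs give exactly 0 and
oracle comparisons have one fixed convention.

**Histograms.** Per channel, `B` equal-width bins over the channel's
canonical range — RGB `[0,1]`; hue `[0,360)`, S, V `[0,1]`; L `[0,100]`,
a, b clamped to `[-128,127]` — with the upper edge inclusive in the last
bin, normalized to sum 1. HSV comes from the standard hexcone conversion;
Lab from the published sRGB → XYZ (D65) → Lab constants, implemented
directly because the conversion must agree with an independent
recomputation to 1e-6 and stock converters differ at the 0.1-Lab-unit
level in their matrices.

**Global color statistics** are per-channel mean and population SD in each
space; hue uses the circular mean and the resultant-length-based circular
SD (`sqrt(-2 ln R)`, in degrees), so hues of 350° and 10° average to 0°,
not 180°.

**Tile means.** The image is partitioned into `T x T` half-open rectangles
with boundaries at `round(i W / T)` and `round(j H / T)` (half-up), full
coverage and no overlap even for uneven sizes; per-tile channel means are
emitted row-major. Images smaller than the grid raise a validation error
advising a smaller `T`.

**Texture.** Grayscale is luma (`0.299 R + 0.587 G + 0.114 B`); gradients
are central differences with replicated borders — the simplest operator
consistent with "simple descriptors", and the replicated border keeps the
magnitude field the same size as the image. Edge density thresholds the
magnitude field with Otsu's criterion on a 256-bin magnitude histogram,
making it parameter-free; when all magnitudes are equal the density is
defined as 0. Intensity entropy is the Shannon entropy in bits of the
`entropyBins`-bin grayscale histogram; global contrast is the grayscale
population SD (RMS contrast). A constant image scores 0 on all five.

**Assembly.** The vector layout is a pure function of the
`FeatureConfig` — summaries (120), optional raw profiles (`4 P x 3`),
histograms (`9 B`), global statistics (18), tiles (`3 T^2`), texture (5);
1679 features at the defaults `P = 100`, `B = 32`, `T = 4`. Feature counts
in the literature for pipelines of this family depend on unstated
composition choices, so MediaDeck makes dimensionality config-driven and
stamps every matrix (and its CSV sidecar) with a fingerprint of the
configuration rather than hard-coding any particular total. NaN is never
emitted; every degenerate case resolves to 0 by the conventions above.

## Embedding and diagnostics

Standardization centers each column and scales to population SD 1,
leaving constant columns at 0. PCA is the SVD of the centered matrix
(no covariance matrix is formed); explained-variance ratios are eigenvalue
shares of total variance, and the per-axis sign is fixed by making the
largest-magnitude loading positive, so small worked examples are exactly
reproducible. UMAP runs on the standardized matrix directly (an optional
`pcaPre` reduces first; the pipeline default does not, since nothing in the
descriptor design requires it), with cosine distance, `n_neighbors = 10`,
`min_dist = 0.01`, single-threaded with a recorded seed — the same seed and
input give identical coordinates. Separation is operationalized as the mean
silhouette over labels with Euclidean distance in embedding space, reported
with per-label centroids and their pairwise distances; "the groups separate
clearly" is thus a number, not a judgement of a scatter plot.

## Synthetic fixtures: what they emulate and what they do not

The generator produces clustered populations of PNGs with controllable
mean color (per-image jitter, SD 0.02), per-pixel Gaussian noise
(default SD 0.05), and texture (flat, stripes of a given period, or smooth
blobs). PNG is used for byte-determinism; each image is seeded as
`seed + index` so populations extend without shifting existing files. The
canonical three-population workload — 3 x 100 images, 64 x 64, base colors
pairwise ≥ 0.3 apart in RGB L2, noise SD 0.05 — emulates collections that
differ in overall stain/color regime and texture scale, which is exactly
the signal the descriptors target. It does **not** emulate histological
content (nuclei, glands, tissue architecture), compression artifacts, or
scanner-specific color calibration; a passing separation test therefore
shows the pipeline recovers color/texture population structure, not that it
distinguishes arbitrary real pathology datasets. Duplicate trees plant
byte-identical copies, unsupported and truncated files with a ground-truth
manifest written *outside* the imported tree.

Problem sizes throughout the tests (images ≤ 64 x 64, libraries ≤ 300
assets, 20-image oracle sweeps) were chosen as the smallest scales at which
every contract is exercised — dedup inside and across jobs, uneven tile
partitions, full-rank and rank-deficient PCA, 10-seed k-means recovery at
ARI ≥ 0.9, UMAP silhouette — while staying comfortably reproducible on one
CPU.

## Known limitations

* EXIF handling is limited to the orientation tag (a minimal APP1 scan);
  orientations 5–8 swap the reported dimensions but pixel data are analyzed
  as decoded.
* No whole-slide or multidimensional microscopy container support; no
  learned embeddings.
* The SQLite store is single-writer; concurrent workers are serialized by
  the claim transaction, which is correct but not high-throughput.
* Video paths depend on an external `ffprobe`/`ffmpeg`; without it, video
  candidates fail per file with an environment message rather than
  aborting imports.
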