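# MediaDeck

MediaDeck is a local-first curation layer for exported biomedical media —
the JPEG/PNG/TIFF stills and short review videos that accumulate after
acquisition and primary analysis in histology, fluorescence microscopy and
high-throughput imaging work. It is an R package plus a thin command-line
tool for people who need to organize, deduplicate, search and re-package
large folder trees of derived images on a workstation, and then ask
quantitative questions about the structure of those collections.

Two things live in one package:

1. **A managed media library.** Recursive import copies files into an
   immutable, content-addressed store (`originals/<sha256>.<ext>`), detects
   duplicates by SHA-256 across the whole library, extracts metadata,
   generates thumbnail/preview derivatives, and records everything — assets,
   tags, collections, import/export jobs, duplicate events, saved searches —
   in a single SQLite file with an FTS5 full-text index. Every completed
   import job satisfies the accounting identity
   `discovered = processed + duplicates + skipped + failed`, and a full
   `audit` re-hashes every original against its stored digest.

2. **A deterministic image-feature pipeline.** Each image is summarized by:
   RGB profiles resampled to `P` points along the four canonical lines
   (main diagonal, anti-diagonal, middle row, middle column), with per-channel
   mean, population SD, min/quartiles/median/max, range, and mean/max
   absolute first differences; `B`-bin histograms per channel in RGB, HSV and
   CIE Lab (sRGB, D65); global color statistics (circular mean/dispersion for
   hue); mean colors on a `T x T` tile grid; and five texture descriptors
   (gradient mean and dispersion from central differences, Otsu-thresholded
   edge density, Shannon intensity entropy in bits, RMS contrast). The
   default configuration (`P = 100`, `B = 32`, `T = 4`, raw profiles
   included) yields 1679 named features per image. Feature matrices feed
   column standardization (`z = (x - mean) / sd`, population SD), optional
   L2 row normalization, PCA (SVD of the centered matrix, explained-variance
   ratios `lambda_i / sum(lambda)`), and seed-deterministic UMAP (cosine
   distance, `n_neighbors = 10`, `min_dist = 0.01`), with silhouette-based
   separation diagnostics.

## Worked example

```r
library(MediaDeck)

lib  <- initLibrary("~/deck")
tree <- makeDuplicateTree(tempfile(), nUnique = 5, nDup = 3, seed = 7)
job  <- importDirectory(lib, tree$root, sourceLabel = "demo")
job[, c("status", "discovered_count", "processed_count",
        "duplicate_count", "skipped_count", "failed_count")]
#>      status discovered_count processed_count duplicate_count skipped_count failed_count
#>   completed                8               5               3             0            0

ftsSearch(lib, "unique_003")$original_filename
#> [1] "unique_003.png"

fs <- featureMatrix(lib, config = featureConfig())
dim(featureValues(fs))
#> [1]    5 1679

p <- runPCA(standardizeFeatures(fs), 2)
explainedVariance(p)          # fraction of variance on PC1, PC2
closeLibrary(lib)
```

The import row reads: 8 files were discovered, 5 novel images became
assets, 3 byte-identical copies were recorded as duplicate events and not
re-imported, and nothing was skipped or failed — so the accounting identity
holds exactly. The feature matrix has one row per image asset and one named
column per descriptor.

The same operations are available from the shell via
`inst/scripts/mediadeck`:

```sh
mediadeck init --library ~/deck
mediadeck import ~/exports/run42 --source run42 --wait --library ~/deck
mediadeck search "he_stain" --library ~/deck
mediadeck audit --library ~/deck --json
```

## Scope

MediaDeck handles exported, review-friendly formats. It does not parse
whole-slide pyramidal images or multidimensional microscopy containers, does
not modify or move user source files (import copies, never moves), and the
single-writer SQLite store targets single-user or small-group use. See
`vignettes/mediadeck-methods.Rmd` for the models, conventions and their
rationale.
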