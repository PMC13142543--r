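Package: MediaDeck
Title: Local-First Media Library Management and Quantitative Image
    Features for Biomedical Collections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A local-first curation layer for exported biomedical images
    and short videos: recursive duplicate-aware import with SHA-256
    content addressing into immutable managed storage, an embedded
    SQLite metadata store with FTS5 full-text retrieval, thumbnail and
    preview derivative generation, asynchronous import and export job
    queues, and ZIP packaging. On top of the managed library it provides
    a deterministic per-image feature pipeline (canonical RGB line
    profiles with channel summaries, RGB/HSV/CIE Lab histograms, global
    colour statistics, tile-grid regional means, and simple texture
    descriptors) feeding standardization, PCA and UMAP for
    dataset-structure analysis of image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    DBI,
    RSQLite,
    digest,
    jsonlite,
    yaml,
    png,
    jpeg,
    tiff,
    EBImage,
    uwot,
    zip,
    cluster,
    mclust,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MediaDeck-package.R'
    'audit.R'
    'cli.R'
    'derivatives.R'
    'embedding.R'
    'export.R'
    'features.R'
    'ingest.R'
    'library-store.R'
    'synthetic.R'
    'utils.R'
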