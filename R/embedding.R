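## Standardization, optional row normalization, PCA and UMAP over feature
## matrices, plus dataset-separation diagnostics.

asFeatureInput <- function(x) {
  if (is(x, "DeckFeatureSet")) featureValues(x) else as.matrix(x)
}

#' Column-standardize a feature matrix
#'
#' Centers every column to mean 0 and scales it to population standard
#' deviation 1. Constant columns are centered and left at 0 rather than
#' divided by zero, so the result never contains NaN. Idempotent on
#' non-constant columns.
#'
#' @param x Numeric matrix (assets x features) or a [DeckFeatureSet-class].
#' @return Standardized numeric matrix of the same shape.
#' @export
standardizeFeatures <- function(x) {
  m <- asFeatureInput(x)
  if (nrow(m) < 2L) deckValidationError("standardization needs at least 2 rows")
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  s <- sqrt(colMeans(centered^2))             # population SD
  s[s == 0] <- 1
  sweep(centered, 2, s, "/")
}

#' Scale rows to unit Euclidean norm
#'
#' The "optional normalization" step: each nonzero row is divided by its L2
#' norm; zero rows are left unchanged.
#'
#' @param x Numeric matrix (assets x features) or a [DeckFeatureSet-class].
#' @return Row-normalized matrix.
#' @export
l2NormalizeRows <- function(x) {
  m <- asFeatureInput(x)
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

#' Principal component analysis of a feature matrix
#'
#' Computes the top-`k` principal axes of the column-centered matrix via
#' singular-value decomposition (numerically stable; no covariance matrix is
#' formed). Explained-variance ratios are the eigenvalue shares of the total
#' variance. The per-axis sign ambiguity is fixed by making the
#' largest-magnitude loading of each axis positive, so results are fully
#' deterministic.
#'
#' @param x Numeric matrix (assets x features) or a [DeckFeatureSet-class];
#'   typically already passed through [standardizeFeatures()].
#' @param k Number of components, `1 <= k <= min(n - 1, d)`.
#' @return An [EmbeddingResult-class] with `method = "pca"`, coordinates
#'   `n x k`, and `explainedVariance` of length `k`.
#' @export
runPCA <- function(x, k = 2) {
  m <- asFeatureInput(x)
  n <- nrow(m); d <- ncol(m)
  k <- as.integer(k)
  if (n < 2L) deckValidationError("PCA needs at least 2 rows")
  if (k < 1L || k > min(n - 1L, d))
    deckValidationError(sprintf("k must be in 1..%d", min(n - 1L, d)))
  centered <- sweep(m, 2, colMeans(m))
  sv <- svd(centered)
  ev <- sv$d^2                               # eigenvalue shares of total variance
  total <- sum(ev)
  ratios <- if (total > 0) ev[seq_len(k)] / total else rep(0, k)
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                    # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; coords[, j] <- -coords[, j] }
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PC", seq_len(k))
  new("EmbeddingResult", method = "pca", coordinates = coords,
      explainedVariance = ratios, params = list(k = k, loadings = load),
      seed = NA_integer_)
}

#' UMAP embedding of a feature matrix
#'
#' Two-dimensional uniform manifold approximation and projection with the
#' defaults used for dataset-structure visualization of image collections:
#' cosine distance, `n_neighbors = 10`, `min_dist = 0.01`. Runs
#' single-threaded with a recorded seed, so the same input and seed yield
#' identical coordinates. Optionally reduces to `pcaPre` principal
#' components first.
#'
#' @param x Numeric matrix (assets x features) or a [DeckFeatureSet-class];
#'   typically standardized first.
#' @param nNeighbors Neighborhood size (default 10); requires `n > nNeighbors`.
#' @param minDist Minimum embedding distance (default 0.01).
#' @param metric Distance metric (default `"cosine"`).
#' @param seed Integer seed, recorded in the result (default 42).
#' @param pcaPre Optional number of PCA components to reduce to beforehand.
#' @return An [EmbeddingResult-class] with `method = "umap"` and `n x 2`
#'   coordinates.
#' @export
runUMAP <- function(x, nNeighbors = 10, minDist = 0.01, metric = "cosine",
                    seed = 42, pcaPre = NULL) {
  m <- asFeatureInput(x)
  if (!is.null(pcaPre)) m <- embeddingCoords(runPCA(m, pcaPre))
  if (nrow(m) <= nNeighbors)
    deckValidationError(sprintf("UMAP needs n > n_neighbors (%d rows, %d neighbors)",
                                nrow(m), nNeighbors))
  set.seed(as.integer(seed))
  coords <- uwot::umap(m, n_neighbors = nNeighbors, min_dist = minDist,
                       metric = metric, n_components = 2L,
                       n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  rownames(coords) <- rownames(m)
  colnames(coords) <- c("UMAP1", "UMAP2")
  new("EmbeddingResult", method = "umap", coordinates = coords,
      explainedVariance = numeric(0),
      params = list(n_neighbors = nNeighbors, min_dist = minDist,
                    metric = metric, seed = as.integer(seed),
                    pca_pre = pcaPre),
      seed = as.integer(seed))
}

#' Quantify label separation in an embedding
#'
#' Operationalizes "how clearly do the labelled groups separate" as the mean
#' silhouette width over the labels (Euclidean distance in embedding space),
#' with per-label centroids and pairwise centroid distances; for PCA
#' embeddings the explained-variance table is included. Optionally writes a
#' scatter plot colored by label.
#'
#' @param embedding An [EmbeddingResult-class] or a coordinate matrix.
#' @param labels Per-row labels (at least two distinct values).
#' @param plotFile Optional PNG path for the labelled scatter plot.
#' @return List with `mean_silhouette`, `silhouette` (per point),
#'   `centroids`, `centroid_distances`, and `variance_table` (PCA only).
#' @export
separationReport <- function(embedding, labels, plotFile = NULL) {
  coords <- if (is(embedding, "EmbeddingResult")) embeddingCoords(embedding)
            else as.matrix(embedding)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    deckValidationError("labels must align with embedding rows")
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L)
    deckValidationError("separation needs at least two distinct labels")
  cl <- as.integer(factor(labels, levels = ulab))
  sil <- cluster::silhouette(cl, dist(coords))
  centroids <- t(vapply(ulab, function(l)
    colMeans(coords[labels == l, , drop = FALSE]), numeric(ncol(coords))))
  cd <- as.matrix(dist(centroids))
  out <- list(mean_silhouette = mean(sil[, "sil_width"]),
              silhouette = sil[, "sil_width"],
              centroids = centroids, centroid_distances = cd)
  if (is(embedding, "EmbeddingResult") && embedding@method == "pca")
    out$variance_table <- data.frame(
      component = colnames(coords),
      explained_variance_ratio = explainedVariance(embedding)[seq_len(ncol(coords))])
  if (!is.null(plotFile)) {
    grDevices::png(plotFile, width = 900, height = 800, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    pal <- grDevices::hcl.colors(length(ulab), "Dark 3")
    plot(coords[, 1], coords[, 2], col = pal[cl], pch = 19, cex = 0.6,
         xlab = colnames(coords)[1], ylab = colnames(coords)[2],
         main = sprintf("Label separation (mean silhouette %.3f)",
                        out$mean_silhouette))
    graphics::legend("topright", legend = ulab, col = pal, pch = 19, cex = 0.8)
  }
  out
}

#' Write embedding coordinates (and PCA variance table) as CSV
#'
#' @param embedding An [EmbeddingResult-class].
#' @param labels Per-row source labels.
#' @param outPath Coordinates CSV path (`asset_id`, `source_label`, dims).
#' @return `outPath`, invisibly.
#' @export
writeEmbeddingCSV <- function(embedding, labels, outPath) {
  coords <- embeddingCoords(embedding)
  df <- data.frame(asset_id = rownames(coords) %||% seq_len(nrow(coords)),
                   source_label = labels, coords, check.names = FALSE)
  utils::write.csv(df, outPath, row.names = FALSE)
  if (length(explainedVariance(embedding)))
    utils::write.csv(
      data.frame(component = colnames(coords),
                 explained_variance_ratio = explainedVariance(embedding)),
      paste0(tools::file_path_sans_ext(outPath), "-variance.csv"),
      row.names = FALSE)
  invisible(outPath)
}
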