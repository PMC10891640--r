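#' PCA of a descriptor matrix
#'
#' Principal component analysis of the (optionally centered and scaled)
#' compound x descriptor matrix, reported as scores, loadings and
#' percent explained variance `100 * sigma_i^2 / sum(sigma^2)`. The sign
#' of each component is fixed by making the largest-magnitude loading
#' entry positive, so results are reproducible across platforms.
#'
#' @param x Numeric matrix (compound x descriptor).
#' @param center,scale Center / autoscale columns before decomposition.
#' @return Object of class `"descriptor_pca"`: `scores` (sample x
#'   component), `loadings` (descriptor x component, orthonormal),
#'   `ev_percent`, `sdev`, and the centering/scaling record.
#' @export
pca_descriptors <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least two samples")
  if (scale && any(apply(x, 2, stats::sd) == 0))
    stop("zero-variance column: call drop_constant_columns() first")
  p <- stats::prcomp(x, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  structure(
    list(scores = p$x, loadings = p$rotation,
         ev_percent = 100 * p$sdev^2 / sum(p$sdev^2), sdev = p$sdev,
         center = p$center, scale = p$scale),
    class = "descriptor_pca")
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "samples x", nrow(x$loadings),
      "descriptors\n")
  ev <- round(x$ev_percent[seq_len(min(5, length(x$ev_percent)))], 2)
  cat("  explained variance (%):", paste(ev, collapse = ", "),
      if (length(x$ev_percent) > 5) "...", "\n")
  invisible(x)
}

#' Pairwise Pearson correlations between descriptors
#'
#' @param x Numeric matrix with at least three rows and no constant
#'   column.
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `"pearson_matrix"`.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least three samples are required")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant column")
  r <- stats::cor(x)
  class(r) <- c("pearson_matrix", class(r))
  r
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Joint score/loading coordinates for a biplot
#'
#' Returns the sample scores and the descriptor loadings on a common
#' scale (loadings multiplied by the component standard deviations) for
#' the chosen pair of components. Pure data preparation; rendering is
#' left to the caller (see `plot` examples in the vignette).
#'
#' @param pca A [pca_descriptors()] result.
#' @param pc_x,pc_y Component indices for the two axes.
#' @return List of two data frames, `scores` and `loadings`, each with
#'   `label`, `x`, `y`.
#' @export
biplot_data <- function(pca, pc_x = 1, pc_y = 2) {
  stopifnot(inherits(pca, "descriptor_pca"))
  k <- length(pca$ev_percent)
  if (pc_x < 1 || pc_y < 1 || pc_x > k || pc_y > k)
    stop("component index out of range")
  sc <- pca$scores
  lo <- sweep(pca$loadings, 2, pca$sdev, "*")
  lab_s <- rownames(sc)
  if (is.null(lab_s)) lab_s <- paste0("sample", seq_len(nrow(sc)))
  lab_l <- rownames(lo)
  if (is.null(lab_l)) lab_l <- paste0("descriptor", seq_len(nrow(lo)))
  list(scores = data.frame(label = lab_s, x = sc[, pc_x], y = sc[, pc_y],
                           row.names = NULL),
       loadings = data.frame(label = lab_l, x = lo[, pc_x], y = lo[, pc_y],
                             row.names = NULL))
}

#' Write PCA results to disk
#'
#' `scores.csv`, `loadings.csv` and `ev.json` in `dir`.
#'
#' @param pca A `"descriptor_pca"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pca <- function(pca, dir) {
  stopifnot(inherits(pca, "descriptor_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pca$scores, file.path(dir, "scores.csv"))
  utils::write.csv(pca$loadings, file.path(dir, "loadings.csv"))
  jsonlite::write_json(list(ev_percent = pca$ev_percent),
                       file.path(dir, "ev.json"), digits = NA)
  invisible(dir)
}
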