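#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = sum|a_i - b_i| / sum(a_i + b_i), computed on counts by default
#' or on relative abundances with `relative = TRUE` (recommended when library
#' sizes differ).  Values lie in \[0, 1\]: 0 for identical composition, 1 for
#' disjoint supports.
#'
#' @param x an [otu_table()] with at least two samples
#' @param relative if `TRUE`, convert each sample to relative abundances
#'   before computing distances
#' @return a symmetric `distance_matrix` with zero diagonal
#' @export
bray_curtis <- function(x, relative = FALSE) {
  m <- otu_counts(x)
  if (nrow(m) < 2L) stop("need at least two samples", call. = FALSE)
  if (relative) {
    ls <- rowSums(m)
    if (any(ls == 0))
      stop("relative abundances undefined for zero-library sample(s): ",
           paste(rownames(m)[ls == 0], collapse = ", "), call. = FALSE)
    m <- m / ls
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0)
        stop("Bray-Curtis undefined between two all-zero samples: ",
             rownames(m)[i], ", ", rownames(m)[j], call. = FALSE)
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("expected a square distance matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  d
}

## Gower-centered matrix G = -1/2 J D^2 J with J = I - 11'/n
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1L, rm), 2L, colMeans(a)) + mean(a)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers the squared distance matrix (Gower centering), takes the
#' symmetric eigendecomposition, and returns coordinates only for positive
#' eigenvalues (eigenvectors scaled by the square root of their eigenvalue).
#' Negative eigenvalues, which arise for non-Euclidean dissimilarities such
#' as Bray-Curtis, are not corrected; their total magnitude is reported.
#'
#' @param d a symmetric distance matrix (e.g. from [bray_curtis()]) or a
#'   `dist` object
#' @return a `pcoa` object: `coordinates` (samples x positive axes),
#'   `eigenvalues` (descending, all of them), `proportion_explained`
#'   (positive eigenvalues over their sum) and `negative_eigenvalue_mass`
#' @export
pcoa <- function(d) {
  d <- as_distance_matrix(d)
  g <- gower_center(d)
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(abs(eig$values), 1e-12) * 1e-9
  pos <- which(eig$values > tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), nrow = length(pos))
  dimnames(coords) <- list(rownames(d),
                           if (length(pos)) paste0("Axis", seq_along(pos)))
  structure(list(coordinates = coords,
                 eigenvalues = eig$values,
                 proportion_explained =
                   if (length(pos)) eig$values[pos] / sum(eig$values[pos])
                   else numeric(0),
                 negative_eigenvalue_mass =
                   sum(abs(eig$values[eig$values < -tol]))),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), k))
  if (k)
    cat("proportion explained (first axes):",
        paste(sprintf("%.1f%%",
                      100 * utils::head(x$proportion_explained, 3)),
              collapse = ", "), "\n")
  if (x$negative_eigenvalue_mass > 0)
    cat(sprintf("negative eigenvalue mass: %.4g (no correction applied)\n",
                x$negative_eigenvalue_mass))
  invisible(x)
}

#' @export
plot.pcoa <- function(x, axes = c(1, 2), col = 1, pch = 19, ...) {
  if (ncol(x$coordinates) < max(axes))
    stop("requested axes not available", call. = FALSE)
  pe <- 100 * x$proportion_explained[axes]
  graphics::plot(x$coordinates[, axes[1]], x$coordinates[, axes[2]],
                 col = col, pch = pch,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1], pe[1]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2], pe[2]), ...)
  invisible(x)
}
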