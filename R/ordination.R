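# Jaccard distances between abundance profiles and principal-coordinates
# embedding. The quantitative (Ruzicka) form works directly on abundance
# values; the binary form needs a presence call, so it takes a threshold.

#' Jaccard distance between two abundance vectors
#'
#' Quantitative (Ruzicka) form, the default:
#' `1 - sum(pmin(x, y)) / sum(pmax(x, y))` -- distances computed on the
#' abundance values themselves. Binary form: classic Jaccard on presence
#' calls at `presence_threshold` (strictly greater). Two all-zero (or, in
#' binary mode, all-absent) vectors are at distance 0.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @param mode `"quantitative"` (default) or `"binary"`.
#' @param presence_threshold Presence call threshold in percent (binary
#'   mode only).
#' @return A distance in \[0, 1\].
#' @export
#' @examples
#' jaccard_distance(c(50, 50, 0), c(25, 25, 50))  # 1 - 50/150
jaccard_distance <- function(x, y, mode = c("quantitative", "binary"),
                             presence_threshold = 0.5) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  }
  stopifnot(all(x >= 0), all(y >= 0))
  if (mode == "binary") {
    x <- as.numeric(x > presence_threshold)
    y <- as.numeric(y > presence_threshold)
  }
  hi <- sum(pmax(x, y))
  if (hi == 0) return(0)
  1 - sum(pmin(x, y)) / hi
}

#' Pairwise Jaccard distance matrix of an abundance table
#'
#' @param table An [abundance_table()].
#' @inheritParams jaccard_distance
#' @return A [stats::dist] object labelled by sample id (symmetric,
#'   zero diagonal, entries in \[0, 1\]).
#' @export
distance_matrix <- function(table, mode = c("quantitative", "binary"),
                            presence_threshold = 0.5) {
  mode <- match.arg(mode)
  v <- table$values
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- jaccard_distance(v[i, ], v[j, ], mode,
                                             presence_threshold)
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric multidimensional scaling: the squared distances are
#' double-centered, eigendecomposed, and the top-`k` axes returned scaled by
#' the square root of their eigenvalues. Non-Euclidean distance matrices
#' (such as Jaccard) can produce negative eigenvalues; these are reported
#' untouched (no Cailliez/Lingoes correction) and excluded from the
#' explained-fraction denominator. Axes beyond the rank of the
#' configuration are zero-filled.
#'
#' @param D A [stats::dist] object or symmetric distance matrix.
#' @param k Number of axes to return (at most `n - 1`).
#' @return List of class `ordination_result` with `coordinates` (n x k
#'   matrix, columns `PC1..PCk`), `eigenvalues` (length `k`,
#'   non-increasing), `explained` (fraction of positive eigenvalue mass per
#'   returned axis), and `all_eigenvalues` (the full spectrum, including
#'   any negative values).
#' @export
pcoa <- function(D, k = 2L) {
  if (!inherits(D, "dist")) D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (k > n - 1L) stop(sprintf("k = %d exceeds n - 1 = %d", k, n - 1L))
  if (k < 1L) stop("k must be at least 1")
  fit <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    pad <- matrix(0, n, k - ifelse(is.null(pts), 0L, ncol(pts)))
    pts <- cbind(pts, pad)
  }
  labels <- attr(D, "Labels")
  dimnames(pts) <- list(labels, paste0("PC", seq_len(k)))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos_mass <- sum(eig[eig > 0])
  explained <- if (pos_mass > 0) pmax(eig[seq_len(k)], 0) / pos_mass
               else rep(0, k)
  structure(list(coordinates = pts,
                 eigenvalues = eig[seq_len(k)],
                 explained = explained,
                 all_eigenvalues = eig),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("ordination_result: %d samples, %d axes\n",
              nrow(x$coordinates), k))
  cat(sprintf("explained (positive eigenvalue mass): %s\n",
              paste(sprintf("%s %.1f%%", colnames(x$coordinates),
                            100 * x$explained), collapse = ", ")))
  neg <- sum(x$all_eigenvalues < 0)
  if (neg > 0) cat(sprintf("%d negative eigenvalue(s) reported\n", neg))
  invisible(x)
}

#' Ordinate an abundance table by Jaccard distance
#'
#' Convenience wrapper: [distance_matrix()] then [pcoa()].
#'
#' @param table An [abundance_table()].
#' @param k Number of axes.
#' @inheritParams jaccard_distance
#' @return An `ordination_result` (see [pcoa()]).
#' @export
ordinate <- function(table, k = 2L, mode = c("quantitative", "binary"),
                     presence_threshold = 0.5) {
  pcoa(distance_matrix(table, mode, presence_threshold), k = k)
}
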