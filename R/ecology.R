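# Regional community comparison: Bray-Curtis dissimilarity, principal
# coordinates, PERMANOVA permutation test.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over genera, computed with
#' `vegan::vegdist`.
#'
#' @param table a [genus_table()] with no all-zero rows.
#' @return Symmetric n x n matrix with zero diagonal, participant IDs as
#'   dimnames.
#' @export
bray_curtis <- function(table) {
  zero <- rowSums(table) == 0
  if (any(zero))
    stop("all-zero abundance row for participant '",
         rownames(table)[which(zero)[1]], "'")
  d <- as.matrix(vegan::vegdist(unclass(table), method = "bray"))
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: eigendecomposition of the double-centred `-D^2/2`
#' matrix. Axes are ordered by eigenvalue; negative eigenvalues are excluded
#' from the explained-variance denominator (no Lingoes/Cailliez correction);
#' the sign of each axis is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param d a dissimilarity matrix (as from [bray_curtis()]).
#' @param k number of axes requested (`k <= n - 1`). If `k` exceeds the
#'   number of positive eigenvalues, the result is truncated with a warning.
#' @return List with `coordinates` (n x k' matrix) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(k >= 1, k <= n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > length(pos)) {
    warning(sprintf("only %d positive eigenvalues; truncating k from %d",
                    length(pos), k))
    k <- length(pos)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCoA", seq_len(k))
  list(coordinates = coords,
       explained_variance = eig[pos][seq_len(k)] / sum(eig[pos]))
}

#' PERMANOVA permutation test for group differences
#'
#' Pseudo-F statistic on a dissimilarity matrix with whole-label
#' permutations (`vegan::adonis2`); the p value uses the add-one convention
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so the smallest attainable
#' p is `1/(1 + n_perm)`.
#'
#' @param d dissimilarity matrix.
#' @param groups group labels (>= 2 groups, each with >= 2 members).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return List with `f` (pseudo-F), `p_value`, `n_perm`.
#' @export
permutation_test <- function(d, groups, n_perm = 1000, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 members each")
  d <- stats::as.dist(as.matrix(d))
  set.seed(seed)
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  list(f = fit$F[1], p_value = fit$`Pr(>F)`[1], n_perm = n_perm)
}
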