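#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)` computed on relative abundances
#' (each vector is normalized to sum to one first, so the measure is
#' invariant to sequencing depth). 0 means identical composition, 1 means
#' disjoint supports.
#'
#' @param x,y equal-length non-negative vectors (raw counts or relative
#'   abundances; normalization is applied either way).
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 && sy == 0) stop("both profiles are all-zero", call. = FALSE)
  if (sx == 0 || sy == 0) return(1)
  p <- x / sx; q <- y / sy
  sum(abs(p - q)) / sum(p + q)
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param table a `count_table` (columns all non-zero).
#' @return symmetric matrix with zero diagonal, sample IDs as dimnames,
#'   class `dist_matrix`.
#' @export
bray_curtis_matrix <- function(table) {
  m <- relative_abundance(table)
  if (any(colSums(table$counts) == 0)) {
    stop("all-zero sample(s) present; drop or impute before beta-diversity", call. = FALSE)
  }
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / 2
    }
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

check_dist_matrix <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square roots of the positive eigenvalues. Negative eigenvalues (which
#' arise because Bray-Curtis is not Euclidean-embeddable) are counted and
#' discarded without correction; the reported variance proportions use the
#' positive eigenvalues only and therefore sum to at most one.
#'
#' @param dist square symmetric dissimilarity matrix (sample IDs as dimnames).
#' @param n_axes number of coordinate axes requested (default 3, matching the
#'   usual 3-D ordination display). Truncated with a warning if fewer
#'   positive eigenvalues exist.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), `proportion`
#'   (variance share per returned axis), `n_negative`.
#' @export
pcoa <- function(dist, n_axes = 3) {
  d <- check_dist_matrix(dist)
  if (n_axes < 1) stop("n_axes must be at least 1", call. = FALSE)
  n <- nrow(d)
  a <- -d^2 / 2
  # double-centering: B = J A J with J = I - 11'/n
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12 & e$values > 0)
  n_negative <- sum(e$values < -abs(max(e$values)) * 1e-12)
  k <- min(n_axes, length(pos))
  if (k < n_axes) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes", length(pos), k),
            call. = FALSE)
  }
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion = e$values[pos[seq_len(k)]] / sum(e$values[pos]),
                 n_negative = n_negative),
            class = "pcoa_result")
}

#' PERMANOVA pseudo-F statistic
#'
#' One-way pseudo-F computed directly from a distance matrix:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed analogously within
#' groups, `F = (SS_between / (a - 1)) / (SS_within / (n - a))`.
#'
#' @param dist square symmetric dissimilarity matrix.
#' @param labels group label per sample (matrix order).
#' @return the pseudo-F value.
#' @export
permanova_pseudo_F <- function(dist, labels) {
  d <- check_dist_matrix(dist)
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stop("labels must match the matrix order", call. = FALSE)
  n <- nrow(d)
  groups <- unique(labels)
  a <- length(groups)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

#' Permutation test for group separation in distance space
#'
#' PERMANOVA-style test: the observed pseudo-F is compared against the
#' pseudo-F distribution under random reassignment of the group labels.
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so the minimum attainable
#' p is `1 / (1 + n_perm)`.
#'
#' With `n_perm = "all"` (two groups only) every distinct assignment of the
#' labels to samples is enumerated instead and
#' `p = #[F_perm >= F_obs] / #assignments` (the identity assignment is one of
#' them, so the minimum is `1 / #assignments`).
#'
#' @param dist square symmetric dissimilarity matrix.
#' @param labels group label per sample; every group needs >= 2 members.
#' @param n_perm number of label permutations (default 999), or `"all"`.
#' @param seed integer seed (mandatory unless `n_perm = "all"`).
#' @return list with `pseudo_F`, `p`, `n_perm`, `seed`.
#' @export
permutation_group_test <- function(dist, labels, n_perm = 999, seed = NULL) {
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least two groups with at least two members each", call. = FALSE)
  }
  f_obs <- permanova_pseudo_F(dist, labels)
  if (identical(n_perm, "all")) {
    if (length(sizes) != 2) stop("exhaustive enumeration supports two groups only", call. = FALSE)
    g1 <- names(sizes)[1]
    combos <- utils::combn(length(labels), sizes[[1]])
    fs <- apply(combos, 2, function(idx) {
      lab <- rep(names(sizes)[2], length(labels))
      lab[idx] <- g1
      permanova_pseudo_F(dist, lab)
    })
    return(list(pseudo_F = f_obs, p = mean(fs >= f_obs - 1e-12),
                n_perm = ncol(combos), seed = NULL))
  }
  if (is.null(seed)) stop("seed is mandatory for the permutation test", call. = FALSE)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (permanova_pseudo_F(dist, sample(labels)) >= f_obs) exceed <- exceed + 1L
  }
  list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm, seed = seed)
}
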