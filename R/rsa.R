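# Representational similarity analysis between time-averaged confusion
# matrices, with a joint row/column label-permutation null.

#' Time-average a confusion tensor
#'
#' Averages the confusion matrices over a window in which stimulus
#' information is available (default 50-250 ms), yielding the K x K
#' representation matrix used for RSA and tuning analyses.
#'
#' @param conf A [confusion_tensor()].
#' @param window Two-element time window in ms (inclusive).
#' @return K x K matrix with `classes`, `window` and `feature` attributes.
#' @export
time_average_confusion <- function(conf, window = c(50, 250)) {
  stopifnot(inherits(conf, "confusion_tensor"))
  sel <- which(conf$time >= window[1] & conf$time <= window[2])
  if (!length(sel)) stop("averaging window contains no time points")
  K <- length(conf$classes)
  m <- matrix(0, K, K)
  for (t in sel) m <- m + matrix(conf$probs[t, , ], K, K)
  m <- m / length(sel)
  attr(m, "classes") <- conf$classes
  attr(m, "window") <- window
  attr(m, "feature") <- conf$feature
  m
}

off_diagonal <- function(m) m[row(m) != col(m)]

#' Representational similarity between two confusion matrices
#'
#' Pearson correlation over the K(K-1) off-diagonal cells of the two
#' matrices, flattened in the same order (the diagonal is removed; both
#' off-diagonal triangles are kept since confusions need not be
#' symmetric).
#'
#' @param A,B K x K matrices (same K).
#' @param method "pearson" (default) or "spearman".
#' @return Correlation coefficient, or NA (with a warning) when either
#'   off-diagonal is constant.
#' @export
representational_similarity <- function(A, B, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have the same dimensions")
  a <- off_diagonal(A); b <- off_diagonal(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant off-diagonal: similarity undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Permutation test for representational similarity
#'
#' The stimulus labels of one matrix are randomly reassigned to its rows
#' and columns simultaneously (`n_perm` draws) and the off-diagonal
#' correlation recomputed; the two-sided p-value is the fraction of
#' permutations whose |r| is at least |r_observed|, with the
#' (b+1)/(m+1) convention.
#'
#' @param A,B K x K matrices.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed RNG seed.
#' @param method Correlation method.
#' @return List: `r`, `p`, `n_permutations`.
#' @export
rsa_permutation_test <- function(A, B, n_perm = 10000, seed = 1,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- as.matrix(A); B <- as.matrix(B)
  r_obs <- representational_similarity(A, B, method)
  if (is.na(r_obs)) stop("similarity undefined (constant off-diagonal)")
  K <- nrow(B)
  a <- off_diagonal(A)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pi <- sample(K)
      stats::cor(a, off_diagonal(B[pi, pi]), method = method)
    }, numeric(1))
  })
  p <- (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n_permutations = n_perm)
}

#' Pairwise similarity table across entities
#'
#' Computes the representational similarity (and permutation p) for every
#' unordered pair of named representation matrices, mirroring the
#' area x signal-class similarity structure of multi-scale comparisons.
#'
#' @param mats Named list of K x K matrices.
#' @param n_perm Permutations per pair.
#' @param seed RNG seed.
#' @return Data frame: `entity1`, `entity2`, `r`, `p`.
#' @export
similarity_table <- function(mats, n_perm = 10000, seed = 1) {
  stopifnot(length(mats) >= 2, !is.null(names(mats)))
  pairs <- utils::combn(names(mats), 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    res <- rsa_permutation_test(mats[[pr[1]]], mats[[pr[2]]], n_perm,
                                seed = seed + i)
    data.frame(entity1 = pr[1], entity2 = pr[2], r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
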