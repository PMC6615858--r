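# Time-resolved multi-class LDA decoding with probabilistic outputs.
# The classifier is fit independently at every time point of the epoch;
# held-out posterior probabilities are accumulated into time-resolved
# confusion matrices (ConfusionTensor), the pipeline's central object.

#' Fit a multi-class shrinkage LDA model
#'
#' Gaussian classifier with a shared within-class covariance. The pooled
#' covariance is shrunk toward a scaled identity,
#' `(1 - s) * S + s * mean(diag(S)) * I`, which keeps the fit defined
#' when channels outnumber trials. Priors are uniform: the design is
#' balanced by stratification.
#'
#' @param x Trials x features numeric matrix.
#' @param y Class labels (one per trial; >= 2 classes, >= 1 trial each).
#' @param shrinkage Shrinkage weight in `[0, 1]` (default 0.1).
#' @return An `lda_model`: class means, inverse shared covariance,
#'   class levels.
#' @export
fit_lda <- function(x, y, shrinkage = 0.1) {
  x <- as.matrix(x)
  y <- as.factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) < 2) stop("need at least 2 classes")
  y <- factor(y, levels = lev)
  n <- nrow(x); p <- ncol(x)
  means <- matrix(0, length(lev), p)
  ss <- matrix(0, p, p)
  for (k in seq_along(lev)) {
    xi <- x[y == lev[k], , drop = FALSE]
    if (nrow(xi) < 1) stop("every class needs at least 1 trial")
    mu <- colMeans(xi)
    means[k, ] <- mu
    xc <- sweep(xi, 2, mu)
    ss <- ss + crossprod(xc)
  }
  df <- max(n - length(lev), 1)
  S <- ss / df
  if (shrinkage > 0) {
    target <- mean(diag(S))
    if (target == 0) target <- 1e-12
    S <- (1 - shrinkage) * S + shrinkage * target * diag(p)
  }
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance; use shrinkage > 0"))
  structure(list(means = means, Sinv = Sinv, levels = lev, p = p),
            class = "lda_model")
}

#' Posterior class probabilities from an LDA model
#'
#' Softmax over the Gaussian log-discriminants
#' `x' Sinv mu_k - mu_k' Sinv mu_k / 2` with uniform priors; with a
#' shared covariance this equals the exact Gaussian-Bayes posterior.
#'
#' @param model An `lda_model` from [fit_lda()].
#' @param x Trials x features matrix.
#' @return Trials x K matrix of probabilities; rows sum to 1.
#' @export
predict_lda <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$p)
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(x), model$p))
  A <- model$means %*% model$Sinv            # K x p
  disc <- x %*% t(A) - matrix(0.5 * rowSums(A * model$means),
                              nrow(x), nrow(model$means), byrow = TRUE)
  disc <- disc - apply(disc, 1, max)
  e <- exp(disc)
  pr <- e / rowSums(e)
  colnames(pr) <- model$levels
  pr
}

#' Cross-validation scheme
#'
#' @param n_folds Number of folds (>= 2). 10 for sensor-level decoding,
#'   2 for sparse invasive recordings.
#' @param stratify_by_sequence_position Balance each stimulus at each
#'   sequence position by oversampling within folds.
#' @param oversample Enable the oversampling step.
#' @param shrinkage LDA shrinkage weight.
#' @param seed Seed for fold assignment and oversampling.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 10, stratify_by_sequence_position = FALSE,
                      oversample = stratify_by_sequence_position,
                      shrinkage = 0.1, seed = 1) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds),
                 stratify_by_sequence_position = stratify_by_sequence_position,
                 oversample = oversample, shrinkage = shrinkage, seed = seed),
            class = "cv_scheme")
}

# Per-cell RNG seed derived from the member indices rather than the label
# value, so that relabeling classes (which permutes labels but leaves the
# partition of trials unchanged) yields identically permuted results.
cell_seed <- function(seed, ix) {
  as.integer((seed + 1664525 * length(ix) + sum(as.numeric(ix))) %%
               .Machine$integer.max)
}

# Seeded fold assignment, stratified by class: within each class, trials
# are randomly permuted and dealt out over folds, keeping per-fold class
# counts as equal as possible.
assign_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    idx <- with_seed(cell_seed(seed, members), sample(members))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Oversample stimulus x sequence-position cells within folds
#'
#' Within each fold, every (stimulus x sequence position) cell is brought
#' up to the fold's maximum cell count by resampling indices with
#' replacement from the same cell of the same fold; indices never cross
#' folds, so duplicated trials cannot leak between training and test.
#'
#' @param labels Class label per trial.
#' @param sequence_positions Sequence position per trial.
#' @param fold_indices Fold id per trial.
#' @param seed RNG seed.
#' @return List (one element per fold) of augmented trial indices.
#' @export
stratify_oversample <- function(labels, sequence_positions, fold_indices,
                                seed = 1) {
  with_seed(seed, {
    folds <- sort(unique(fold_indices))
    lapply(folds, function(f) {
      in_fold <- which(fold_indices == f)
      cell <- interaction(labels[in_fold], sequence_positions[in_fold],
                          drop = FALSE)
      counts <- table(cell)
      empty <- counts[counts == 0]
      if (length(empty))
        stop("empty stimulus x position cell in fold ", f, ": ",
             paste(names(empty), collapse = ", "))
      target <- max(counts)
      out <- in_fold
      for (cl in names(counts)) {
        members <- in_fold[cell == cl]
        deficit <- target - length(members)
        if (deficit > 0)
          out <- c(out, with_seed(cell_seed(seed, members),
                                  sample(members, deficit, replace = TRUE)))
      }
      sort(out)
    })
  })
}

# Subsample trials (seeded) so every (color x motion) joint cell has the
# minimum joint-cell count; returns retained trial indices.
balance_joint_cells <- function(trials, seed) {
  cell <- interaction(trials$color_angle, trials$motion_angle, drop = TRUE)
  m <- min(table(cell))
  sort(unlist(lapply(split(seq_len(nrow(trials)), cell), function(ix) {
    if (length(ix) > m) with_seed(cell_seed(seed, ix), sample(ix, m)) else ix
  }), use.names = FALSE))
}

#' Time-resolved cross-validated confusion tensor
#'
#' The full decoding pipeline for one recording: trials are first
#' balanced so each color x motion combination occurs equally often
#' (subsampling to the minimum joint-cell count), split into stratified
#' folds, optionally oversampled per stimulus x sequence-position cell
#' within folds, and decoded with multi-class LDA independently at every
#' time point. Row `i` of the confusion matrix at time `t` is the mean
#' predicted-probability vector over held-out trials of true class `i`,
#' pooled over folds.
#'
#' @param epoched An [epoched_data()] object.
#' @param feature "color" or "motion".
#' @param scheme A [cv_scheme()].
#' @param balance Balance joint color x motion cells first (default TRUE).
#' @return A [confusion_tensor()].
#' @export
crossvalidated_confusion <- function(epoched, feature = c("color", "motion"),
                                     scheme = cv_scheme(), balance = TRUE) {
  stopifnot(inherits(epoched, "epoched_data"))
  feature <- match.arg(feature)
  keep <- if (balance) balance_joint_cells(epoched$trials, scheme$seed)
          else seq_len(nrow(epoched$trials))
  labels_all <- if (feature == "color") epoched$trials$color_angle
                else epoched$trials$motion_angle
  labels <- labels_all[keep]
  classes <- sort(unique(labels_all))
  K <- length(classes)
  tab <- table(factor(labels, levels = classes))
  if (any(tab < scheme$n_folds))
    stop(sprintf("class %s has %d trials; need at least n_folds = %d",
                 names(tab)[which.min(tab)], min(tab), scheme$n_folds))
  fold <- assign_folds(labels, scheme$n_folds, scheme$seed)
  fold_idx <- if (scheme$oversample) {
    seqpos <- if (scheme$stratify_by_sequence_position)
      epoched$trials$sequence_position[keep] else rep(1L, length(keep))
    stratify_oversample(labels, seqpos, fold, seed = scheme$seed + 1L)
  } else {
    lapply(sort(unique(fold)), function(f) which(fold == f))
  }
  n_time <- length(epoched$time)
  probs <- array(0, c(n_time, K, K))
  counts <- matrix(0, n_time, K)
  y <- factor(labels, levels = classes)
  splits <- lapply(seq_along(fold_idx), function(f) {
    test_loc <- fold_idx[[f]]
    train_loc <- unlist(fold_idx[-f], use.names = FALSE)
    list(tr_rows = keep[train_loc], te_rows = keep[test_loc],
         y_tr = y[train_loc], y_te = y[test_loc])
  })
  for (t in seq_len(n_time)) {
    x_all <- epoched$data[, , t]
    if (is.null(dim(x_all))) x_all <- matrix(x_all, ncol = 1)
    for (sp in splits) {
      model <- fit_lda(x_all[sp$tr_rows, , drop = FALSE], sp$y_tr,
                       scheme$shrinkage)
      pr <- predict_lda(model, x_all[sp$te_rows, , drop = FALSE])
      for (k in seq_len(K)) {
        sel <- which(sp$y_te == classes[k])
        if (length(sel)) {
          probs[t, k, ] <- probs[t, k, ] + colSums(pr[sel, , drop = FALSE])
          counts[t, k] <- counts[t, k] + length(sel)
        }
      }
    }
  }
  for (k in seq_len(K)) probs[, k, ] <- probs[, k, ] / counts[, k]
  confusion_tensor(probs, epoched$time, classes, feature)
}

#' Average decoding over small unit subsets
#'
#' Restricts decoding to `n_units` channels of one area at a time and
#' averages the resulting confusion tensors over all combinations, or at
#' most `max_combos` distinct seeded random combinations, before any
#' statistics. This equalizes feature counts across areas.
#'
#' @param epoched An [epoched_data()] object.
#' @param area Area label to decode (channels are selected by
#'   `channels$area`); NULL uses all channels.
#' @param feature "color" or "motion".
#' @param scheme A [cv_scheme()].
#' @param n_units Units per subset (default 5).
#' @param max_combos Cap on combinations (default 40).
#' @param seed Seed for sampling combinations.
#' @return A [confusion_tensor()] averaged over subsets, with attribute
#'   `n_combos`.
#' @export
subsample_units <- function(epoched, area = NULL,
                            feature = c("color", "motion"),
                            scheme = cv_scheme(n_folds = 2), n_units = 5,
                            max_combos = 40, seed = 1) {
  feature <- match.arg(feature)
  ch <- if (is.null(area)) seq_len(nrow(epoched$channels))
        else which(epoched$channels$area == area)
  if (length(ch) < n_units)
    stop(sprintf("area has %d channels; need at least %d", length(ch), n_units))
  n_total <- choose(length(ch), n_units)
  combos <- if (n_total <= max_combos) {
    utils::combn(ch, n_units, simplify = FALSE)
  } else {
    with_seed(seed, {
      seen <- character(0); out <- list()
      while (length(out) < max_combos) {
        cand <- sort(sample(ch, n_units))
        key <- paste(cand, collapse = ",")
        if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1]] <- cand }
      }
      out
    })
  }
  acc <- NULL
  for (cmb in combos) {
    ct <- crossvalidated_confusion(subset_epochs(epoched, channels = cmb),
                                   feature, scheme)
    acc <- if (is.null(acc)) ct$probs else acc + ct$probs
  }
  out <- confusion_tensor(acc / length(combos), epoched$time,
                          sort(unique(if (feature == "color")
                            epoched$trials$color_angle else
                            epoched$trials$motion_angle)), feature)
  attr(out, "n_combos") <- length(combos)
  out
}

#' Interpolate a 12x12 confusion tensor to 8x8
#'
#' Recordings with 12 classes (30-degree spacing) are brought onto the
#' common 8-class (45-degree) grid by bilinear interpolation on the torus
#' of true x predicted angles, followed by row renormalization so each
#' row remains a probability vector.
#'
#' @param conf A [confusion_tensor()] with K = 12.
#' @return A [confusion_tensor()] with K = 8.
#' @export
interpolate_confusion <- function(conf) {
  stopifnot(inherits(conf, "confusion_tensor"))
  if (length(conf$classes) != 12)
    stop("interpolation is defined for 12-class tensors only")
  src <- conf$classes                      # 0, 30, ..., 330
  dst <- (0:7) * 45
  # circular linear interpolation weights from the 30-degree grid
  wmat <- matrix(0, 8, 12)
  for (i in seq_along(dst)) {
    pos <- dst[i] / 30
    lo <- floor(pos) %% 12; hi <- (lo + 1) %% 12
    frac <- pos - floor(pos)
    wmat[i, lo + 1] <- wmat[i, lo + 1] + (1 - frac)
    wmat[i, hi + 1] <- wmat[i, hi + 1] + frac
  }
  n_time <- length(conf$time)
  out <- array(0, c(n_time, 8, 8))
  for (t in seq_len(n_time)) {
    m <- wmat %*% matrix(conf$probs[t, , ], 12, 12) %*% t(wmat)
    out[t, , ] <- m / rowSums(m)
  }
  confusion_tensor(out, conf$time, dst, conf$feature)
}

#' Accuracy (hit-rate) timecourse from a confusion tensor
#'
#' Classifier performance per time point is the mean of the confusion
#' matrix diagonal; chance is 1/K.
#'
#' @param conf A [confusion_tensor()].
#' @param session_id Optional identifier carried through.
#' @return An [info_timecourse()].
#' @export
accuracy_timecourse <- function(conf, session_id = NA) {
  stopifnot(inherits(conf, "confusion_tensor"))
  K <- length(conf$classes)
  vals <- vapply(seq_along(conf$time),
                 function(t) mean(diag(matrix(conf$probs[t, , ], K, K))),
                 numeric(1))
  info_timecourse(vals, conf$time, 1 / K, session_id)
}
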