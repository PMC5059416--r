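#' Training configuration for semi-supervised PSM rescoring
#'
#' @param n_folds Number of cross-validation folds (default 3).
#' @param q_train q-value threshold defining positive training examples
#'   (default 0.01).
#' @param iterations Number of semi-supervised refinement iterations
#'   (default 10).
#' @param c_pos,c_neg SVM misclassification costs for positives (confident
#'   targets) and negatives (decoys); defaults 10 and 30.
#' @param subset_size Optional number of PSMs to downsample to for training;
#'   `NULL` trains on everything.
#' @param seed Integer seed controlling fold assignment and subsetting.
#' @return Object of class `train_config`.
#' @export
train_config <- function(n_folds = 3L, q_train = 0.01, iterations = 10L,
                         c_pos = 10, c_neg = 30, subset_size = NULL,
                         seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (q_train <= 0 || q_train >= 1) stop("q_train must be in (0, 1)")
  if (iterations < 0L) stop("iterations must be >= 0")
  if (c_pos <= 0 || c_neg <= 0) stop("costs must be positive")
  structure(list(n_folds = n_folds, q_train = q_train,
                 iterations = as.integer(iterations), c_pos = c_pos,
                 c_neg = c_neg,
                 subset_size = if (is.null(subset_size)) NULL else as.integer(subset_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Downsample a PSM set by whole spectra
#'
#' Spectra (`spec_id` equivalence classes) are sampled without replacement
#' until the accumulated PSM count first reaches `subset_size`; all PSMs of
#' a selected spectrum are included together, so a target/decoy pair
#' belonging to one spectrum is never split. Deterministic given the seed.
#'
#' @param psms A `psm_set`.
#' @param subset_size Requested number of PSMs (>= 1).
#' @param seed Integer seed.
#' @return The sampled `psm_set` (all PSMs, with a warning, if
#'   `subset_size` exceeds the total).
#' @export
subset_sample <- function(psms, subset_size, seed = 1L) {
  stopifnot(subset_size >= 1)
  if (subset_size >= nrow(psms)) {
    if (subset_size > nrow(psms)) {
      warning("subset_size exceeds the number of PSMs; using all of them")
    }
    return(psms)
  }
  counts <- table(psms$spec_id)
  spectra <- names(counts)
  picked <- withr::with_seed(seed, sample(spectra))
  k <- which(cumsum(as.integer(counts[picked])) >= subset_size)[1L]
  sel <- psms$spec_id %in% picked[seq_len(k)]
  out <- psms[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- attr(psms, "feature_names")
  class(out) <- c("psm_set", "data.frame")
  out
}

# count targets at q <= q_train for a candidate score vector
count_at_q <- function(score, is_target, q_train) {
  q <- td_qvalues(score, is_target)
  sum(is_target & q <= q_train)
}

#' Choose the initial scoring direction
#'
#' Evaluates every feature with both signs as a standalone score and
#' returns the (feature, sign) pair that yields the most targets at
#' `q <= q_train`; ties are broken by lowest feature index, then positive
#' sign.
#'
#' @param features Numeric feature matrix (one row per PSM).
#' @param is_target Logical label vector.
#' @param q_train Positive-set q-value threshold.
#' @return List with `feature` (column index), `sign` (+1/-1) and
#'   `n_positives`.
#' @export
initial_direction <- function(features, is_target, q_train = 0.01) {
  stopifnot(ncol(features) >= 1L)
  best <- list(feature = 1L, sign = 1, n_positives = -1L)
  for (j in seq_len(ncol(features))) {
    for (sg in c(1, -1)) {
      cnt <- count_at_q(sg * features[, j], is_target, q_train)
      if (cnt > best$n_positives) {
        best <- list(feature = j, sign = sg, n_positives = cnt)
      }
    }
  }
  best
}

# train one fold's scoring vector on its training partition.
# Returns weights (d + 1 with bias last, standardized feature space) plus
# the decoy score mean/sd recorded on the training partition.
train_one_fold <- function(X, is_target, config) {
  d <- ncol(X)
  init <- initial_direction(X, is_target, config$q_train)
  w <- numeric(d + 1L)
  w[init$feature] <- init$sign
  Xb <- cbind(X, 1)
  cost <- ifelse(is_target, config$c_pos, config$c_neg)
  y <- ifelse(is_target, 1, -1)
  for (iter in seq_len(config$iterations)) {
    scores <- drop(Xb %*% w)
    q <- td_qvalues(scores, is_target)
    pos <- is_target & q <= config$q_train
    if (!any(pos)) next                     # keep previous direction
    use <- pos | !is_target
    w <- svm_l2_primal(Xb[use, , drop = FALSE], y[use], cost[use], w0 = w)
  }
  scores <- drop(Xb %*% w)
  dsc <- scores[!is_target]
  list(weights = w, init = init,
       decoy_mean = mean(dsc), decoy_sd = max(stats::sd(dsc), 1e-12))
}

# assign spectra to folds, keeping all PSMs of a spectrum together
fold_assignment <- function(spec_id, n_folds, seed) {
  spectra <- unique(spec_id)
  f <- withr::with_seed(seed, {
    sample(rep_len(seq_len(n_folds), length(spectra)))
  })
  f[match(spec_id, spectra)]
}

#' Semi-supervised SVM rescoring of PSMs
#'
#' Implements iterative semi-supervised rescoring with three-fold
#' cross-validation: per fold, an initial scoring direction is chosen from
#' the single best feature, then for a fixed number of iterations the
#' training partition is scored, targets at `q <= q_train` become
#' positives, all decoys negatives, and a linear squared-hinge SVM is
#' refit. In cross-validation mode each PSM's final score comes from the
#' classifier whose test fold contained it. When `subset_size` is set, the
#' same three-fold procedure is run on a spectrum-preserving random subset
#' and every PSM is scored by the average of the three classifiers
#' (downsampled training). Fold scores are made commensurable by
#' standardizing with each classifier's training-partition decoy mean and
#' standard deviation.
#'
#' @param psms A `psm_set` (see [read_pin()]) or a path to a PIN file.
#' @param config A [train_config()].
#' @param competition Optional PSM competition before training; see
#'   [compete_psms()]. Default `"none"`.
#' @return An object of class `rescore_fit`; see [print.rescore_fit()].
#'   The element `psms` carries `score`, `q_value` and `pep` per PSM.
#' @export
rescore <- function(psms, config = train_config(),
                    competition = c("none", "tdc", "rank1")) {
  if (is.character(psms)) psms <- read_pin(psms)
  competition <- match.arg(competition)
  feat_names <- attr(psms, "feature_names")
  if (competition != "none") psms <- compete_psms(psms, mode = competition)
  n <- nrow(psms)
  X_raw <- as.matrix(psms[, feat_names, drop = FALSE])
  if (any(!is.finite(X_raw))) stop("PSM features must be finite")
  center <- colMeans(X_raw)
  scale_ <- pmax(apply(X_raw, 2L, stats::sd), 1e-12)
  X <- sweep(sweep(X_raw, 2L, center), 2L, scale_, "/")

  train_psms_idx <- seq_len(n)
  mode <- "cross_validation"
  if (!is.null(config$subset_size)) {
    if (config$subset_size > n) {
      warning("subset_size exceeds the number of PSMs; training on all of them")
    } else {
      sub <- subset_sample(psms, config$subset_size, seed = config$seed)
      # the subset keeps whole spectra, so spectrum membership recovers it
      train_psms_idx <- which(psms$spec_id %in% unique(sub$spec_id))
      mode <- "subset_average"
    }
  }
  fold <- fold_assignment(psms$spec_id[train_psms_idx], config$n_folds,
                          config$seed)
  fits <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    tr <- train_psms_idx[fold != k]
    if (!any(psms$is_target[tr]) || all(psms$is_target[tr])) {
      stop("both labels must be present in every training partition")
    }
    fits[[k]] <- train_one_fold(X[tr, , drop = FALSE], psms$is_target[tr],
                                config)
  }
  Xb <- cbind(X, 1)
  norm_scores <- vapply(fits, function(f) {
    (drop(Xb %*% f$weights) - f$decoy_mean) / f$decoy_sd
  }, numeric(n))
  if (mode == "cross_validation") {
    score <- numeric(n)
    # PSMs in a test fold are scored by that fold's classifier; in CV mode
    # every PSM is in exactly one fold
    full_fold <- integer(n)
    full_fold[train_psms_idx] <- fold
    for (k in seq_len(config$n_folds)) {
      score[full_fold == k] <- norm_scores[full_fold == k, k]
    }
  } else {
    score <- rowMeans(norm_scores)
  }
  psms$score <- score
  psms$q_value <- td_qvalues(score, psms$is_target)
  psms$pep <- estimate_peps(score, psms$is_target)
  structure(list(psms = psms,
                 weights = vapply(fits, `[[`, numeric(ncol(X) + 1L), "weights"),
                 normalization = lapply(fits, function(f) {
                   c(decoy_mean = f$decoy_mean, decoy_sd = f$decoy_sd)
                 }),
                 initial = lapply(fits, `[[`, "init"),
                 feature_names = feat_names,
                 center = center, scale = scale_,
                 mode = mode, config = config,
                 n_train = length(train_psms_idx)),
            class = "rescore_fit")
}

#' @export
print.rescore_fit <- function(x, ...) {
  n <- nrow(x$psms)
  nt <- sum(x$psms$is_target)
  cat(sprintf("semi-supervised PSM rescoring fit (%s)\n", x$mode))
  cat(sprintf("  %d PSMs (%d targets, %d decoys), %d trained on, %d folds\n",
              n, nt, n - nt, x$n_train, x$config$n_folds))
  cat(sprintf("  targets at q <= 0.01: %d; at q <= 0.05: %d\n",
              sum(x$psms$is_target & x$psms$q_value <= 0.01),
              sum(x$psms$is_target & x$psms$q_value <= 0.05)))
  invisible(x)
}

#' @describeIn rescore Average feature weights (standardized space, bias
#'   last) across folds.
#' @param object,x A `rescore_fit`.
#' @param ... Unused.
#' @export
coef.rescore_fit <- function(object, ...) {
  w <- rowMeans(object$weights)
  names(w) <- c(object$feature_names, "(bias)")
  w
}

#' @export
summary.rescore_fit <- function(object, ...) {
  w <- object$weights
  rownames(w) <- c(object$feature_names, "(bias)")
  colnames(w) <- sprintf("fold%d", seq_len(ncol(w)))
  out <- list(weights = w, mode = object$mode,
              n_psms = nrow(object$psms),
              n_significant_01 = sum(object$psms$is_target &
                                       object$psms$q_value <= 0.01))
  class(out) <- "summary.rescore_fit"
  out
}

#' @export
print.summary.rescore_fit <- function(x, ...) {
  cat(sprintf("rescoring fit (%s): %d PSMs, %d targets at q <= 0.01\n",
              x$mode, x$n_psms, x$n_significant_01))
  cat("per-fold weights (standardized features):\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @describeIn rescore Score new PSMs with the fitted classifiers
#'   (subset-average mode: mean of decoy-standardized fold scores).
#' @param newdata A `psm_set` with the same feature columns.
#' @export
predict.rescore_fit <- function(object, newdata, ...) {
  X_raw <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (ncol(X_raw) != length(object$center)) stop("feature dimensionality mismatch")
  X <- sweep(sweep(X_raw, 2L, object$center), 2L, object$scale, "/")
  Xb <- cbind(X, 1)
  norm_scores <- vapply(seq_len(ncol(object$weights)), function(k) {
    nrm <- object$normalization[[k]]
    (drop(Xb %*% object$weights[, k]) - nrm[["decoy_mean"]]) / nrm[["decoy_sd"]]
  }, numeric(nrow(Xb)))
  rowMeans(norm_scores)
}
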