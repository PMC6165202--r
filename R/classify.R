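# MA-vs-LC decoding: per-band common spatial patterns on a region of
# interest, log-variance features, shrinkage LDA, and 10x10-fold stratified
# cross-validation with all fitting confined to the training folds.

#' The five canonical EEG frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-13, beta 14-29, gamma 30-50 Hz.
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
band_set <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 14, 30),
    hi = c(3, 7, 13, 29, 50)
  )
}

# Per-trial channel covariance of each band-filtered task window:
# covs[, , trial, band] (unnormalized, X X^T / n). Shared by the fitting
# and application paths so fold-wise refitting stays consistent.
trial_band_covs <- function(epochs, bands, window = c(0, 10), order = 4) {
  fs <- epochs$fs
  tsel <- which(epochs$times >= window[1] & epochs$times < window[2])
  nt <- n_trials(epochs)
  nc <- length(epochs$channels)
  nb <- nrow(bands)
  covs <- array(0, dim = c(nc, nc, nt, nb))
  for (bi in seq_len(nb)) {
    if (bands$hi[bi] >= fs / 2) abort("band above Nyquist")
    filt <- butter_design(bands$lo[bi], bands$hi[bi], fs, order)
    for (tr in seq_len(nt)) {
      xf <- matrix(0, nc, length(tsel))
      for (ci in seq_len(nc)) {
        xf[ci, ] <- zero_phase(epochs$data[tr, ci, ], filt)[tsel]
      }
      covs[, , tr, bi] <- tcrossprod(xf) / length(tsel)
    }
  }
  covs
}

#' Trace-normalized class covariance matrices
#'
#' Each trial's channel covariance over the task window is normalized by
#' its trace and averaged within class; the normalization equalizes trial
#' contributions regardless of overall amplitude.
#'
#' @param epochs An `eeg_epochs` restricted to one ROI's channels.
#' @param labels Per-trial class labels (two classes).
#' @param window Task window in seconds.
#' @return List with `cov1`, `cov2` (trace-1 matrices) and `classes`
#'   (class of `cov1` first).
#' @export
class_covariances <- function(epochs, labels = epochs$labels,
                              window = c(0, 10)) {
  classes <- class_order(labels)
  covs <- trial_band_covs(epochs, tibble::tibble(band = "broad", lo = 1,
                                                 hi = epochs$fs / 2 * 0.98),
                          window)[, , , 1, drop = FALSE]
  dim(covs) <- dim(covs)[1:3]
  avg <- function(cls) {
    idx <- which(labels == cls)
    if (length(idx) < 2) abort("need >= 2 trials per class")
    m <- 0
    for (i in idx) m <- m + covs[, , i] / sum(diag(covs[, , i]))
    m / length(idx)
  }
  list(cov1 = avg(classes[1]), cov2 = avg(classes[2]), classes = classes)
}

# MA first when present (fixed tie-break class), otherwise sorted order.
class_order <- function(labels) {
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) abort("exactly two classes required")
  if ("MA" %in% cls) c("MA", setdiff(cls, "MA")) else cls
}

#' Fit common spatial patterns for one band
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` via
#' whitening of the composite covariance. Eigenvalues lie in `[0, 1]` and
#' are sorted decreasing; the retained filters are the first and last
#' `n_keep` (largest variance ratio for either class). Because a
#' common-average-referenced six-channel group is rank 5, the whitening is
#' restricted to the numerical rank of the composite (directions below
#' `rank_tol` of the leading eigenvalue are dropped) on top of a small
#' ridge; the null direction carries no signal and its log-variance would
#' be numerical noise.
#'
#' @param cov1,cov2 Symmetric PSD class covariance matrices, equal size.
#' @param n_keep Components kept per side (default 2, giving `2 * n_keep`
#'   filters); requires `2 * n_keep <=` the composite rank.
#' @param ridge Relative ridge added to the composite covariance.
#' @param rank_tol Relative eigenvalue threshold for the rank truncation.
#' @return A `csp_model`: `filters` (channels x rank), `eigenvalues`
#'   (decreasing, one per retained component), `selected` (indices of the
#'   `2 * n_keep` kept filters), `n_keep`.
#' @export
csp_fit <- function(cov1, cov2, n_keep = 2, ridge = 1e-8, rank_tol = 1e-9) {
  if (!all(dim(cov1) == dim(cov2))) abort("covariance dimension mismatch")
  m <- nrow(cov1)
  comp <- cov1 + cov2
  ec <- eigen(comp, symmetric = TRUE)
  keep <- ec$values > rank_tol * ec$values[1]
  r <- sum(keep)
  if (2 * n_keep > r) abort("2 * n_keep exceeds the composite covariance rank")
  vals <- ec$values[keep] + ridge * sum(diag(comp))
  whiten <- ec$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(vals), r)
  mid <- t(whiten) %*% cov1 %*% whiten
  ew <- eigen((mid + t(mid)) / 2, symmetric = TRUE)
  w_all <- whiten %*% ew$vectors          # eigen() sorts decreasing
  selected <- c(seq_len(n_keep), seq(r - n_keep + 1L, r))
  structure(
    list(filters = w_all, eigenvalues = ew$values, selected = selected,
         n_keep = n_keep),
    class = "csp_model"
  )
}

csp_features_from_cov <- function(model, cov_trial) {
  w <- model$filters[, model$selected, drop = FALSE]
  v <- diag(t(w) %*% cov_trial %*% w)
  log(pmax(v, .Machine$double.xmin))
}

#' Multi-band CSP log-variance features
#'
#' Per band: zero-phase bandpass of each trial, projection onto the
#' retained CSP filters, and the natural log of the variance over the task
#' window per component; band blocks are concatenated. With the default
#' five bands and `n_keep = 2` this yields 20 features per trial. When
#' `models` is supplied the filters are applied without refitting (the
#' held-out-fold path); otherwise models are fitted from `epochs` and
#' attached to the result as attribute `"csp_models"`.
#'
#' @param epochs An `eeg_epochs` restricted to one ROI's channels.
#' @param bands Band table as from [band_set()].
#' @param n_keep CSP components kept per side and band.
#' @param models Optional list of fitted `csp_model`s (one per band).
#' @param labels Class labels (used only when fitting).
#' @param window Task window, seconds.
#' @return Trials x features numeric matrix with attribute `csp_models`.
#' @export
multiband_csp_features <- function(epochs, bands = band_set(), n_keep = 2,
                                   models = NULL, labels = epochs$labels,
                                   window = c(0, 10)) {
  covs <- trial_band_covs(epochs, bands, window)
  fit <- is.null(models)
  if (fit) {
    classes <- class_order(labels)
    models <- purrr::map(seq_len(nrow(bands)), function(bi) {
      cc <- avg_class_covs(covs[, , , bi, drop = FALSE], labels, classes)
      csp_fit(cc$cov1, cc$cov2, n_keep)
    })
  }
  feats <- features_from_covs(covs, models)
  colnames(feats) <- paste(rep(bands$band, each = 2 * models[[1]]$n_keep),
                           seq_len(2 * models[[1]]$n_keep), sep = "_")
  attr(feats, "csp_models") <- models
  feats
}

avg_class_covs <- function(covs_b, labels, classes) {
  dim(covs_b) <- dim(covs_b)[1:3]
  avg <- function(cls) {
    idx <- which(labels == cls)
    m <- 0
    for (i in idx) m <- m + covs_b[, , i] / sum(diag(covs_b[, , i]))
    m / length(idx)
  }
  list(cov1 = avg(classes[1]), cov2 = avg(classes[2]))
}

features_from_covs <- function(covs, models) {
  nt <- dim(covs)[3]
  nb <- dim(covs)[4]
  do.call(cbind, purrr::map(seq_len(nb), function(bi) {
    t(vapply(seq_len(nt),
             function(tr) csp_features_from_cov(models[[bi]], covs[, , tr, bi]),
             numeric(2 * models[[bi]]$n_keep)))
  }))
}

#' Ledoit-Wolf shrinkage intensity
#'
#' Analytic shrinkage of a sample covariance towards `nu * I` with `nu` the
#' average eigenvalue, clipped to `[0, 1]`. Rows of `x` are observations.
#' Degenerate constant input (zero dispersion) returns 1, i.e. full
#' shrinkage to the scaled identity.
#'
#' @param x Observations x features matrix (>= 2 rows), assumed centred
#'   (subtract class or overall means first).
#' @return Shrinkage intensity in `[0, 1]`.
#' @export
ledoit_wolf_gamma <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) abort("need >= 2 observations")
  s <- crossprod(x) / n
  nu <- sum(diag(s)) / p
  d2 <- sum((s - diag(nu, p))^2) / p
  if (d2 < .Machine$double.eps) return(1)
  b2_sum <- 0
  for (k in seq_len(n)) {
    xk <- x[k, ]
    b2_sum <- b2_sum + sum((tcrossprod(xk) - s)^2)
  }
  b2 <- min(b2_sum / n^2 / p, d2)
  max(0, min(1, b2 / d2))
}

#' Fit / apply shrinkage linear discriminant analysis
#'
#' Binary LDA with the pooled covariance regularized as
#' `(1 - gamma) S + gamma nu I`, `nu` the average eigenvalue of the pooled
#' sample covariance `S`, and `gamma` the Ledoit-Wolf intensity estimated
#' from the pooled class-centred data unless given. The weight vector is
#' `w = Sigma^-1 (mu1 - mu2)`; the bias places the decision boundary midway
#' between the projected class means. A score of exactly zero is assigned
#' to the first class (MA when present).
#'
#' @param x Trials x features matrix.
#' @param y Class labels (exactly two classes, both present).
#' @param gamma Optional fixed shrinkage intensity in `[0, 1]`.
#' @return An `slda_model`: `w`, `b`, `gamma`, `nu`, `means`, `classes`.
#' @export
slda_fit <- function(x, y, gamma = NULL) {
  x <- as.matrix(x)
  classes <- class_order(y)
  i1 <- which(y == classes[1]); i2 <- which(y == classes[2])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[i2, , drop = FALSE])
  xc <- rbind(sweep(x[i1, , drop = FALSE], 2, mu1),
              sweep(x[i2, , drop = FALSE], 2, mu2))
  s <- crossprod(xc) / nrow(xc)
  p <- ncol(x)
  nu <- sum(diag(s)) / p
  if (is.null(gamma)) gamma <- ledoit_wolf_gamma(xc)
  sigma <- (1 - gamma) * s + diag(gamma * nu, p)
  w <- solve(sigma, mu1 - mu2)
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, b = b, gamma = gamma, nu = nu,
                 means = rbind(mu1, mu2), classes = classes),
            class = "slda_model")
}

#' @rdname slda_fit
#' @param model A fitted `slda_model`.
#' @return `slda_predict()` returns a character vector of predicted labels.
#' @export
slda_predict <- function(model, x) {
  score <- drop(as.matrix(x) %*% model$w) + model$b
  ifelse(score >= 0, model$classes[1], model$classes[2])
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so every fold keeps the class balance.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the full decoder
#'
#' The evaluation protocol for one region of interest: per repetition a
#' stratified random fold assignment; per fold, the multi-band CSP filters
#' and the shrinkage LDA are fitted on the training trials only and
#' evaluated on the held-out trials (no information leaks across the fold
#' boundary). Accuracy is the percentage of correct held-out predictions,
#' pooled per fold.
#'
#' @param epochs An `eeg_epochs` restricted to one ROI's channels.
#' @param labels Per-trial class labels.
#' @param k Folds (default 10).
#' @param reps Repetitions (default 10).
#' @param n_keep CSP components per side and band.
#' @param bands Band table as from [band_set()].
#' @param seed Optional integer seed for the fold assignments.
#' @param window Task window, seconds.
#' @return An `eeg_cv` object: tibble `folds` (rep, fold, n_test, accuracy),
#'   scalars `mean` and `sd` (percent), and the call parameters.
#' @export
cross_validate <- function(epochs, labels = epochs$labels, k = 10, reps = 10,
                           n_keep = 2, bands = band_set(), seed = NULL,
                           window = c(0, 10)) {
  classes <- class_order(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf("need >= k = %d trials per class for stratified folds", k))
  }
  covs <- trial_band_covs(epochs, bands, window)
  run <- function() {
    rows <- purrr::map_dfr(seq_len(reps), function(rep_i) {
      fold <- stratified_folds(labels, k)
      purrr::map_dfr(seq_len(k), function(fi) {
        test <- which(fold == fi)
        train <- which(fold != fi)
        models <- purrr::map(seq_len(dim(covs)[4]), function(bi) {
          cc <- avg_class_covs(covs[, , train, bi, drop = FALSE],
                               labels[train], classes)
          csp_fit(cc$cov1, cc$cov2, n_keep)
        })
        ftr <- features_from_covs(covs[, , train, , drop = FALSE], models)
        fte <- features_from_covs(covs[, , test, , drop = FALSE], models)
        mdl <- slda_fit(ftr, labels[train])
        pred <- slda_predict(mdl, fte)
        tibble::tibble(rep = rep_i, fold = fi, n_test = length(test),
                       accuracy = 100 * mean(pred == labels[test]))
      })
    })
    structure(
      list(folds = rows, mean = mean(rows$accuracy), sd = stats::sd(rows$accuracy),
           k = k, reps = reps, n_keep = n_keep, seed = seed,
           n_trials = length(labels), classes = classes),
      class = "eeg_cv"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv> %dx%d-fold CV on %d trials: %.2f +/- %.2f %%\n",
              x$reps, x$k, x$n_trials, x$mean, x$sd))
  invisible(x)
}
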