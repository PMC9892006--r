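#' Zero-phase component analysis (ZCA) whitening
#'
#' Centres the feature matrix and multiplies by the symmetric inverse
#' square root of its covariance, so the output covariance is the identity
#' while staying maximally close to the input (zero-phase). Rank-deficient
#' covariances are ridge-regularized with a warning.
#'
#' @param X numeric matrix (rows = observations, >= 2).
#' @param ridge regularization added to eigenvalues below `tol`.
#' @param tol eigenvalue threshold for rank deficiency.
#' @return list: `X` (whitened), `transform` (the symmetric `C^{-1/2}`),
#'   `center`.
#' @export
zca_whiten <- function(X, ridge = 1e-6, tol = 1e-10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- stats::cov(Xc)
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  if (any(vals < tol)) {
    warning("rank-deficient covariance; ridge-regularizing")
    vals <- vals + ridge
  }
  W <- e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  list(X = Xc %*% W, transform = W, center = mu)
}

#' Binned behavioural feature table for the averaged encoding model
#'
#' For each session, instance peaks and behavioural outcomes (same-syllable
#' counts, pooled entropy, velocity) are aggregated over the following
#' `bin_size` syllables, averaged per syllable, then features are z-scored
#' within each mouse. One row per (mouse, syllable, bin_size).
#'
#' @param tables list of peak tables (one per session) carrying `mouse`.
#' @param bin_sizes syllable-step bin sizes.
#' @return data.frame: mouse, syllable, bin_size, counts, entropy,
#'   velocity, peak.
#' @export
build_binned_features <- function(tables,
                                  bin_sizes = c(5, 10, 25, 50, 100, 200,
                                                300, 400, 800, 1600)) {
  rows <- list()
  for (tb in tables) {
    n <- nrow(tb)
    labels <- tb$syllable
    K <- max(labels)
    for (bs in bin_sizes[bin_sizes < n]) {
      t_idx <- seq_len(n - bs)
      for (i in sort(unique(labels))) {
        sel <- t_idx[labels[t_idx] == i]
        if (length(sel) < 2) next
        cnt <- vapply(sel, function(t) sum(labels[(t + 1):(t + bs)] == i),
                      numeric(1))
        ent <- pooled_transition_entropy(
          labels, unique(unlist(lapply(sel, function(t) t:(t + bs - 1)))), K)
        vel <- mean(vapply(sel, function(t)
          mean(tb$velocity[(t + 1):(t + bs)]), numeric(1)))
        rows[[length(rows) + 1]] <- data.frame(
          mouse = tb$mouse[1], session = tb$session[1], syllable = i,
          bin_size = bs, counts = mean(cnt), entropy = ent,
          velocity = vel, peak = mean(tb$peak[labels == i]))
      }
    }
  }
  out <- do.call(rbind, rows)
  # average over sessions, then z-score features within mouse
  agg <- stats::aggregate(cbind(counts, entropy, velocity, peak) ~
                            mouse + syllable + bin_size, data = out, FUN = mean)
  for (m in unique(agg$mouse)) {
    sel <- agg$mouse == m
    for (cl in c("counts", "entropy", "velocity"))
      agg[[cl]][sel] <- zscore(agg[[cl]][sel])
  }
  agg
}

#' Bayesian linear regression with conjugate normal-inverse-gamma posterior
#'
#' The likelihood is normal, `y ~ N(X beta, sigma^2)`, with a normal prior
#' on the coefficients and a weak inverse-gamma prior on the variance
#' standing in for the exponential scale prior; the posterior over `beta`
#' and `sigma` is available in closed form. Predictors are ZCA-whitened
#' before fitting. Held-out performance is the Pearson correlation between
#' cross-validated predictions and outcomes.
#'
#' @param X feature matrix.
#' @param y outcome vector.
#' @param prior_sd prior s.d. of the coefficients (relative to sigma).
#' @param folds cross-validation folds (0 disables CV).
#' @param whiten whiten features before fitting.
#' @param seed integer seed for fold assignment.
#' @return list: `beta_mean`, `beta_sd`, `sigma_mean`, `heldout_r`,
#'   `whitening`.
#' @export
fit_binned_encoding <- function(X, y, prior_sd = 10, folds = 5,
                                whiten = TRUE, seed = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= ncol(X) + 2, nrow(X) == length(y))
  wh <- NULL
  if (whiten) {
    wh <- zca_whiten(X)
    X <- wh$X
  }
  post <- function(Xt, yt) {
    # N(0, sigma^2 prior_sd^2 I) prior on beta, IG(a0, b0) on sigma^2
    p <- ncol(Xt); n <- nrow(Xt)
    a0 <- 1e-3; b0 <- 1e-3
    V0i <- diag(1 / prior_sd^2, p)
    Vn <- solve(V0i + crossprod(Xt))
    bn <- Vn %*% crossprod(Xt, yt)
    an <- a0 + n / 2
    bnn <- b0 + 0.5 * (sum(yt^2) - t(bn) %*% (V0i + crossprod(Xt)) %*% bn)
    s2 <- as.numeric(bnn) / (an - 1)
    list(beta = as.numeric(bn), beta_sd = sqrt(s2 * diag(Vn)),
         sigma = sqrt(s2))
  }
  full <- post(X, y)
  heldout_r <- NA_real_
  if (folds >= 2) {
    set.seed(seed)
    fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
    pred <- numeric(nrow(X))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      fit <- post(X[!te, , drop = FALSE], y[!te])
      pred[te] <- X[te, , drop = FALSE] %*% fit$beta
    }
    heldout_r <- if (stats::sd(pred) > 0) stats::cor(pred, y) else 0
  }
  list(beta_mean = full$beta, beta_sd = full$beta_sd,
       sigma_mean = full$sigma, heldout_r = heldout_r, whitening = wh)
}

# build the lagged convolution design matrix for one session:
# columns ordered feature-major, lag from -max_lag to +max_lag
kernel_design <- function(F, max_lag) {
  F <- as.matrix(F)
  n <- nrow(F); p <- ncol(F)
  lags <- (-max_lag):max_lag
  D <- matrix(0, n, p * length(lags))
  for (j in seq_len(p)) {
    for (li in seq_along(lags)) {
      l <- lags[li]
      col <- (j - 1) * length(lags) + li
      if (l >= 0) {
        if (l < n) D[(l + 1):n, col] <- F[1:(n - l), j]
      } else {
        if (-l < n) D[1:(n + l), col] <- F[(1 - l):n, j]
      }
    }
  }
  D
}

#' Convolution-kernel encoding model of instantaneous dopamine
#'
#' Predicts the (2-s boxcar smoothed) dopamine trace as the sum over
#' behavioural features of the feature convolved with a learned kernel
#' spanning -2 s to +2 s (121 taps at 30 Hz). Kernels are fitted jointly
#' with a Huber loss (IRLS) and mild L2 regularization, with twofold
#' cross-validation by session; features are standardized before fitting.
#'
#' @param sessions list of lists with `features` (matrix, frames x
#'   features) and `dlight` (vector).
#' @param max_lag kernel half-width in frames.
#' @param huber_k Huber threshold in residual s.d. units.
#' @param l2 ridge penalty.
#' @param smooth_frames boxcar width applied to the target.
#' @param folds cross-validation folds over sessions.
#' @return list: `kernels` (lags x features matrix), `lags`, `heldout_r`.
#' @export
fit_kernel_encoding <- function(sessions, max_lag = 60, huber_k = 1.345,
                                l2 = 1e-4, smooth_frames = 60, folds = 2) {
  stopifnot(length(sessions) >= folds)
  p <- ncol(as.matrix(sessions[[1]]$features))
  nl <- 2 * max_lag + 1
  # standardize features across all sessions
  allF <- do.call(rbind, lapply(sessions, function(s) as.matrix(s$features)))
  mu <- colMeans(allF); sdv <- apply(allF, 2, stats::sd)
  sdv[sdv == 0] <- 1
  prep <- lapply(sessions, function(s) {
    F <- sweep(sweep(as.matrix(s$features), 2, mu), 2, sdv, "/")
    y <- boxcar_smooth(s$dlight, smooth_frames)
    list(D = kernel_design(F, max_lag), y = y)
  })
  huber_fit <- function(idx) {
    D <- do.call(rbind, lapply(prep[idx], `[[`, "D"))
    y <- unlist(lapply(prep[idx], `[[`, "y"))
    beta <- rep(0, ncol(D))
    for (it in 1:10) {
      r <- y - D %*% beta
      s <- stats::mad(r)
      if (s == 0) break
      w <- pmin(1, huber_k * s / pmax(abs(r), 1e-12))
      Dw <- D * as.numeric(sqrt(w))
      yw <- y * sqrt(w)
      beta_new <- solve(crossprod(Dw) + diag(l2, ncol(D)),
                        crossprod(Dw, yw))
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- beta_new
    }
    as.numeric(beta)
  }
  fold_id <- rep_len(seq_len(folds), length(sessions))
  rs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    beta <- huber_fit(tr)
    pred <- unlist(lapply(prep[te], function(s) s$D %*% beta))
    ytest <- unlist(lapply(prep[te], `[[`, "y"))
    rs[f] <- if (stats::sd(pred) > 0) stats::cor(pred, ytest) else 0
  }
  beta_all <- huber_fit(seq_along(sessions))
  kernels <- matrix(beta_all, nrow = nl, ncol = p)
  rownames(kernels) <- as.character((-max_lag):max_lag)
  list(kernels = kernels, lags = (-max_lag):max_lag,
       heldout_r = mean(rs))
}
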