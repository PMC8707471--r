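#' Canonical spatial transform of EEG epochs
#'
#' Aligns raw epochs into a canonical feature space that is invariant to
#' per-epoch gain and offset (the dominant artifacts of capacitive
#' coupling): each epoch is standardized to zero mean and unit variance,
#' then mapped to a fixed band-power feature vector — alpha power, beta
#' power, their log-ratio, and the spectral entropy of the normalized
#' Welch spectrum up to 45 Hz. Zero-variance epochs carry no information
#' and are excluded with a warning.
#'
#' @param epochs list of EEG [signal_trace()]s (equal length and rate).
#' @return A list: `features` (matrix, one row per retained epoch, columns
#'   `alpha`, `beta`, `log_ratio`, `entropy`), `kept` (indices of retained
#'   epochs).
#' @export
spatial_transform <- function(epochs) {
  if (!length(epochs)) stop("no epochs supplied", call. = FALSE)
  feats <- vector("list", length(epochs))
  kept <- logical(length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    x <- ep$samples
    if (length(x) < 32L || stats::sd(x) == 0) next
    xs <- (x - mean(x)) / stats::sd(x)
    tr <- trace_with(ep, xs)
    M <- min(length(tr), max(64L, floor(2 * tr$fs)))
    psd <- welch_psd(tr, welch_spec(M = M, fs = tr$fs))
    a <- band_power(psd, 8, 12)
    b <- band_power(psd, 14, 25)
    keep_f <- psd$freqs <= 45 & psd$power > 0
    p <- psd$power[keep_f] / sum(psd$power[keep_f])
    entropy <- -sum(p * log(p)) / log(length(p))
    feats[[i]] <- c(alpha = a, beta = b,
                    log_ratio = log((a + 1e-12) / (b + 1e-12)),
                    entropy = entropy)
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("all epochs degenerate", call. = FALSE)
  if (!all(kept)) warning(sum(!kept), " degenerate epoch(s) excluded")
  list(features = do.call(rbind, feats[kept]), kept = which(kept))
}

#' Synthetic cognitive-state epoch dataset
#'
#' Labelled EEG epochs for the four driving-relevant cognitive states,
#' generated with distinct alpha/beta/noise signatures: relaxation
#' (alpha-dominant), stress (beta-dominant), emotion (balanced, strong
#' rhythms), distraction (weak rhythms under raised broadband noise).
#' Amplitudes receive seeded per-epoch variation so classes overlap
#' realistically.
#'
#' @param n_per_class epochs per class (default 40).
#' @param epoch_s epoch length in seconds (default 8).
#' @param fs sampling rate in Hz (default 250; the analysis bands end at
#'   45 Hz, so this keeps the benchmark light without touching them).
#' @param seed integer seed.
#' @return A list of class `epoch_dataset`: `epochs` (list of traces),
#'   `labels` (factor with levels relaxation, stress, emotion,
#'   distraction).
#' @export
make_cognitive_dataset <- function(n_per_class = 40, epoch_s = 8, fs = 250,
                                   seed = 1) {
  base <- list(
    relaxation  = c(alpha = 45, beta = 8, noise = 6),
    stress      = c(alpha = 8, beta = 40, noise = 6),
    emotion     = c(alpha = 28, beta = 30, noise = 6),
    distraction = c(alpha = 10, beta = 12, noise = 28)
  )
  states <- names(base)
  with_seed(seed, {
    epochs <- list(); labels <- character(0)
    for (st in states) {
      for (k in seq_len(n_per_class)) {
        jit <- exp(stats::rnorm(3, 0, 0.15))
        amp <- base[[st]] * jit
        amp["alpha"] <- min(max(amp["alpha"], 5), 150)
        spec <- eeg_state_spec(
          state = switch(st, relaxation = "eyes_closed_relaxed",
                         stress = "stress", emotion = "emotion",
                         distraction = "distraction"),
          alpha_amp = amp["alpha"], beta_amp = amp["beta"],
          broadband_noise_amp = amp["noise"])
        epochs[[length(epochs) + 1L]] <-
          gen_eeg(spec, epoch_s, fs, seed = NULL)
        labels <- c(labels, st)
      }
    }
    structure(list(epochs = epochs,
                   labels = factor(labels, levels = states)),
              class = "epoch_dataset")
  })
}

#' Fit the RBF-feature cognitive-state classifier
#'
#' Pipeline: spatial transform to band-power features, z-scoring with
#' training statistics, `K` prototype centres by seeded k-means, Gaussian
#' RBF activations `exp(-gamma * ||x - c||^2)` around the centres, and a
#' softmax MLP head (single hidden layer) trained on the activations.
#' Everything random is governed by `seed`, so refitting reproduces the
#' parameters exactly, regardless of training-set order.
#'
#' @param dataset an `epoch_dataset` (>= 10 epochs per class
#'   recommended).
#' @param K number of RBF centres (default 12; must not exceed the number
#'   of training epochs and should be at least the number of classes).
#' @param gamma RBF width; `NULL` (default) sets
#'   `1 / (2 * median pairwise squared distance)` from the training
#'   features.
#' @param hidden hidden units of the MLP head (default 8).
#' @param seed integer seed (default 1).
#' @param maxit optimizer iteration budget (default 300).
#' @return An object of class `rbfmod` holding the transform statistics,
#'   centres, `gamma`, the fitted head and the class levels.
#' @export
rbfmod_fit <- function(dataset, K = 12, gamma = NULL, hidden = 8, seed = 1,
                       maxit = 300) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  st <- spatial_transform(dataset$epochs)
  X <- st$features
  y <- dataset$labels[st$kept]
  if (K > nrow(X)) stop("`K` exceeds the number of epochs", call. = FALSE)
  if (K < nlevels(y)) stop("`K` must be >= number of classes", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  # canonical row order so the fit is invariant to training-set order
  ord <- do.call(order, as.data.frame(Z))
  Z <- Z[ord, , drop = FALSE]
  y <- y[ord]
  with_seed(seed, {
    km <- stats::kmeans(Z, centers = K, nstart = 5, iter.max = 50)
    centers <- km$centers
    if (is.null(gamma)) {
      d2 <- as.numeric(stats::dist(Z[sample(nrow(Z),
                                            min(200L, nrow(Z))), ]))^2
      gamma <- 1 / (2 * stats::median(d2))
    }
    A <- rbf_activations(Z, centers, gamma)
    target <- nnet::class.ind(y)
    fit <- nnet::nnet(A, target, size = hidden, softmax = TRUE,
                      maxit = maxit, decay = 1e-3, trace = FALSE)
    structure(list(mu = mu, sdv = sdv, centers = centers, gamma = gamma,
                   mlp = fit, levels = levels(y), K = K, hidden = hidden,
                   seed = seed),
              class = "rbfmod")
  })
}

rbf_activations <- function(Z, centers, gamma) {
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") -
    2 * Z %*% t(centers)
  exp(-gamma * pmax(d2, 0))
}

#' Predict cognitive states for EEG epochs
#'
#' Runs the fitted pipeline; per-epoch class scores sum to one and the
#' label is the arg-max (ties broken by the fixed class order). An
#' optional exponential smoothing of scores across consecutive epochs
#' (`smooth` in `[0, 1)`, default 0 = off) stabilizes state sequences the
#' way a recurrent read-out would.
#'
#' @param params a fitted `rbfmod`.
#' @param epochs list of EEG [signal_trace()]s.
#' @param smooth exponential smoothing factor across consecutive epochs.
#' @return A list: `labels` (factor), `scores` (matrix, rows sum to 1),
#'   `kept` (indices of non-degenerate epochs scored).
#' @export
rbfmod_predict <- function(params, epochs, smooth = 0) {
  stopifnot(inherits(params, "rbfmod"))
  st <- spatial_transform(epochs)
  X <- st$features
  if (ncol(X) != length(params$mu)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, params$mu), 2, params$sdv, "/")
  A <- rbf_activations(Z, params$centers, params$gamma)
  S <- stats::predict(params$mlp, A)
  S <- S / rowSums(S)
  colnames(S) <- params$levels
  if (smooth > 0 && nrow(S) > 1) {
    for (i in 2:nrow(S)) {
      S[i, ] <- smooth * S[i - 1, ] + (1 - smooth) * S[i, ]
      S[i, ] <- S[i, ] / sum(S[i, ])
    }
  }
  idx <- apply(S, 1, which.max)
  list(labels = factor(params$levels[idx], levels = params$levels),
       scores = S, kept = st$kept)
}

#' Persist / restore a fitted classifier as JSON
#'
#' Versioned plain-text serialization of all fitted parameters, including
#' the MLP weight vector; the restored model predicts identically.
#'
#' @param params a fitted `rbfmod`.
#' @param path file path.
#' @return `rbfmod_save` invisibly returns `path`; `rbfmod_load` returns
#'   the restored `rbfmod`.
#' @export
rbfmod_save <- function(params, path) {
  stopifnot(inherits(params, "rbfmod"))
  obj <- list(schema = "rbfmod/1", mu = params$mu, sdv = params$sdv,
              centers = params$centers, gamma = params$gamma,
              levels = params$levels, K = params$K, hidden = params$hidden,
              seed = params$seed,
              wts = params$mlp$wts, n = params$mlp$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rbfmod_save
#' @export
rbfmod_load <- function(path) {
  obj <- jsonlite::fromJSON(path)
  # rebuild an nnet skeleton with the stored weights
  n <- as.integer(obj$n)
  dummy_x <- matrix(0, max(4L, n[3] + 1L), n[1])
  dummy_y <- diag(n[3])[rep(seq_len(n[3]), length.out = nrow(dummy_x)), ]
  mlp <- nnet::nnet(dummy_x, dummy_y, size = n[2], softmax = TRUE,
                    maxit = 1, trace = FALSE)
  mlp$wts <- as.numeric(obj$wts)
  structure(list(mu = stats::setNames(as.numeric(obj$mu), names(obj$mu)),
                 sdv = stats::setNames(as.numeric(obj$sdv), names(obj$sdv)),
                 centers = as.matrix(obj$centers), gamma = obj$gamma,
                 mlp = mlp, levels = obj$levels, K = obj$K,
                 hidden = obj$hidden, seed = obj$seed),
            class = "rbfmod")
}
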