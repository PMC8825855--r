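#' CNN architecture and training hyperparameters
#'
#' Tetrode-wise 1-D convolution over a shared 10 ms grid of LFP (down-
#' averaged) and per-unit spike counts; filters are not shared across
#' tetrodes. Time-averaged convolution features are concatenated and passed
#' through two rectified hidden layers with dropout to a softmax over odors.
#' Training is stochastic gradient descent with momentum and early stopping
#' on a validation split.
#'
#' @param n_filters filters per tetrode; `filter_width` in grid steps.
#' @param hidden hidden layer widths; `dropout` drop probability.
#' @param grid_bin grid step (s); `train_window` seconds relative to poke_in.
#' @param epochs,lr,momentum,batch SGD parameters.
#' @param val_frac validation fraction; `patience` early-stopping patience.
#' @param seed seed for initialization, batching and dropout.
#' @return list of class `seqmem_cnn_spec`.
#' @export
cnn_spec <- function(n_filters = 8, filter_width = 5, hidden = c(64, 32),
                     dropout = 0.5, grid_bin = 0.01,
                     train_window = c(0.15, 0.40), epochs = 100, lr = 0.02,
                     momentum = 0.9, batch = 16, val_frac = 0.15,
                     patience = 10, seed = 1) {
  structure(as.list(environment()), class = "seqmem_cnn_spec")
}

# multivariate time series per tetrode: LFP (down-averaged) + unit counts on
# a common grid; returns list(tetrode -> trial x channel x T array)
cnn_inputs <- function(session, trials, window, grid_bin = 0.01) {
  Tn <- as.integer(round(diff(window) / grid_bin))
  cnt <- window_spike_counts(session, trials, "poke_in", window, bin = grid_bin)
  tets <- sort(unique(session$tetrode_of_neuron))
  fs <- session$sample_rate_lfp
  per_bin <- as.integer(round(grid_bin * fs))
  out <- list()
  for (tet in tets) {
    units <- names(session$tetrode_of_neuron)[session$tetrode_of_neuron == tet]
    has_lfp <- tet %in% names(session$lfp)
    C <- length(units) + has_lfp
    if (C == 0) next
    arr <- array(0, dim = c(nrow(trials), C, Tn))
    if (has_lfp) {
      ch <- session$lfp[[tet]]
      for (i in seq_len(nrow(trials))) {
        i0 <- round((trials$poke_in[i] + window[1] - ch$t0) * fs)
        seg <- ch$samples[(i0 + 1):(i0 + Tn * per_bin)]
        arr[i, 1, ] <- colMeans(matrix(seg, nrow = per_bin))
      }
    }
    if (length(units))
      arr[, (1 + has_lfp):C, ] <- cnt[, units, , drop = FALSE]
    out[[tet]] <- arr
  }
  out
}

# z-scale each channel using supplied (or freshly computed) moments
scale_inputs <- function(inputs, moments = NULL) {
  if (is.null(moments))
    moments <- lapply(inputs, function(a) {
      mu <- apply(a, 2, mean); sdv <- apply(a, 2, sd); sdv[sdv == 0] <- 1
      list(mu = mu, sd = sdv)
    })
  scaled <- lapply(names(inputs), function(tet) {
    a <- inputs[[tet]]; m <- moments[[tet]]
    sweep(sweep(a, 2, m$mu, `-`), 2, m$sd, `/`)
  })
  names(scaled) <- names(inputs)
  list(inputs = scaled, moments = moments)
}

# im2col: trial x channel x T -> (trial*positions) x (channel*width)
unroll <- function(a, w) {
  Tn <- dim(a)[3]; P <- Tn - w + 1; C <- dim(a)[2]; B <- dim(a)[1]
  U <- matrix(0, B * P, C * w)
  for (p in seq_len(P)) {
    rows <- (seq_len(B) - 1) * P + p   # trial i occupies rows (i-1)*P + 1..P
    U[rows, ] <- matrix(a[, , p:(p + w - 1)], B, C * w)
  }
  attr(U, "P") <- P
  U
}

cnn_forward <- function(net, U_list, drop_masks = NULL) {
  P <- attr(U_list[[1]], "P")
  B <- nrow(U_list[[1]]) / P
  pooled <- lapply(seq_along(U_list), function(g) {
    Z <- sweep(U_list[[g]] %*% net$Wc[[g]], 2, net$bc[[g]], `+`)
    A <- relu(Z)
    pool <- t(vapply(seq_len(B), function(i)
      colMeans(A[((i - 1) * P + 1):(i * P), , drop = FALSE]),
      numeric(ncol(A))))
    list(Z = Z, pool = pool)
  })
  x <- do.call(cbind, lapply(pooled, `[[`, "pool"))
  h1 <- relu(sweep(x %*% net$W1, 2, net$b1, `+`))
  if (!is.null(drop_masks)) h1 <- h1 * drop_masks$m1
  h2 <- relu(sweep(h1 %*% net$W2, 2, net$b2, `+`))
  if (!is.null(drop_masks)) h2 <- h2 * drop_masks$m2
  logits <- sweep(h2 %*% net$W3, 2, net$b3, `+`)
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  probs <- el / rowSums(el)
  list(pooled = pooled, x = x, h1 = h1, h2 = h2, probs = probs)
}

cnn_init <- function(spec, Cw_list, n_classes) {
  k <- spec$n_filters
  Wc <- lapply(Cw_list, function(cw) matrix(rnorm(cw * k, 0, sqrt(2 / cw)), cw, k))
  bc <- lapply(Cw_list, function(cw) numeric(k))
  nin <- k * length(Cw_list)
  W1 <- matrix(rnorm(nin * spec$hidden[1], 0, sqrt(2 / nin)), nin, spec$hidden[1])
  W2 <- matrix(rnorm(spec$hidden[1] * spec$hidden[2], 0, sqrt(2 / spec$hidden[1])),
               spec$hidden[1], spec$hidden[2])
  W3 <- matrix(rnorm(spec$hidden[2] * n_classes, 0, sqrt(2 / spec$hidden[2])),
               spec$hidden[2], n_classes)
  list(Wc = Wc, bc = bc, W1 = W1, b1 = numeric(spec$hidden[1]),
       W2 = W2, b2 = numeric(spec$hidden[2]), W3 = W3, b3 = numeric(n_classes))
}

#' Train the tetrode-wise convolutional odor decoder
#'
#' Trained on the 150-400 ms window after port entry of the supplied trials
#' (typically correct InSeq odors A-D) with early stopping on a stratified
#' validation split. The penultimate hidden layer is exposed as the latent
#' space.
#'
#' @param session session.
#' @param trials training trials with odor labels.
#' @param spec `seqmem_cnn_spec`.
#' @param shuffle_labels permute labels before training (chance calibration).
#' @return `seqmem_cnn` decoder: weights, channel moments, classes, spec, and
#'   the training/validation trial ids.
#' @export
train_cnn <- function(session, trials, spec = cnn_spec(), shuffle_labels = FALSE) {
  classes <- sort(unique(trials$odor))
  if (length(classes) < 2) stop("train_cnn: need >= 2 odor classes")
  y <- trials$odor
  with_seed(spec$seed, {
    if (shuffle_labels) y <- sample(y)
    val <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1, round(spec$val_frac * length(ix))))))
  })
  raw <- cnn_inputs(session, trials, spec$train_window, spec$grid_bin)
  sc <- scale_inputs(raw)
  U_all <- lapply(sc$inputs, unroll, w = spec$filter_width)
  P <- attr(U_all[[1]], "P")
  rows_of <- function(ix) as.vector(vapply(ix, function(i)
    ((i - 1) * P + 1):(i * P), integer(P)))
  sub_U <- function(ix) lapply(U_all, function(U) {
    V <- U[rows_of(ix), , drop = FALSE]; attr(V, "P") <- P; V
  })
  tr_ix <- setdiff(seq_along(y), val)
  Y <- outer(y, classes, `==`) * 1
  net <- with_seed(spec$seed + 1L,
                   cnn_init(spec, vapply(U_all, ncol, integer(1)), length(classes)))
  vnet <- rapply(net, function(x) x * 0, how = "replace")
  best <- list(loss = Inf, net = net, epoch = 0)
  nG <- length(U_all)
  with_seed(spec$seed + 2L, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(tr_ix)
      for (s in seq(1, length(ord), by = spec$batch)) {
        ix <- ord[s:min(s + spec$batch - 1, length(ord))]
        B <- length(ix)
        Ub <- sub_U(ix)
        masks <- list(
          m1 = matrix(rbinom(B * spec$hidden[1], 1, 1 - spec$dropout),
                      B) / (1 - spec$dropout),
          m2 = matrix(rbinom(B * spec$hidden[2], 1, 1 - spec$dropout),
                      B) / (1 - spec$dropout))
        fw <- cnn_forward(net, Ub, masks)
        dlogit <- (fw$probs - Y[ix, , drop = FALSE]) / B
        gW3 <- crossprod(fw$h2, dlogit); gb3 <- colSums(dlogit)
        dh2 <- (dlogit %*% t(net$W3)) * masks$m2 * (fw$h2 > 0)
        gW2 <- crossprod(fw$h1, dh2); gb2 <- colSums(dh2)
        dh1 <- (dh2 %*% t(net$W2)) * masks$m1 * (fw$h1 > 0)
        gW1 <- crossprod(fw$x, dh1); gb1 <- colSums(dh1)
        dx <- dh1 %*% t(net$W1)
        k <- spec$n_filters
        for (g in seq_len(nG)) {
          dpool <- dx[, ((g - 1) * k + 1):(g * k), drop = FALSE]
          # expand pooled gradient back over positions
          dA <- matrix(0, B * P, k)
          for (i in seq_len(B))
            dA[((i - 1) * P + 1):(i * P), ] <-
              matrix(dpool[i, ] / P, P, k, byrow = TRUE)
          dZ <- dA * (fw$pooled[[g]]$Z > 0)
          gWc <- crossprod(Ub[[g]], dZ); gbc <- colSums(dZ)
          vnet$Wc[[g]] <- spec$momentum * vnet$Wc[[g]] - spec$lr * gWc
          vnet$bc[[g]] <- spec$momentum * vnet$bc[[g]] - spec$lr * gbc
          net$Wc[[g]] <- net$Wc[[g]] + vnet$Wc[[g]]
          net$bc[[g]] <- net$bc[[g]] + vnet$bc[[g]]
        }
        for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
          g <- get(paste0("g", nm))
          vnet[[nm]] <- spec$momentum * vnet[[nm]] - spec$lr * g
          net[[nm]] <- net[[nm]] + vnet[[nm]]
        }
      }
      fwv <- cnn_forward(net, sub_U(val))
      vloss <- -mean(log(pmax(fwv$probs[cbind(seq_along(val),
                                              match(y[val], classes))], 1e-12)))
      if (vloss < best$loss - 1e-6) best <- list(loss = vloss, net = net, epoch = ep)
      if (ep - best$epoch >= spec$patience) break
    }
  })
  structure(list(net = best$net, moments = sc$moments, classes = classes,
                 spec = spec, val_ids = trials$trial_id[val],
                 train_ids = trials$trial_id[tr_ix],
                 val_loss = best$loss, labels_used = y),
            class = "seqmem_cnn")
}

#' Apply a trained CNN decoder to one time window
#'
#' @param decoder `seqmem_cnn`; `session` session; `trials` trials to decode.
#' @param window c(start, end) seconds relative to poke_in.
#' @return list(probs = trial x class probability matrix, latent =
#'   penultimate-layer activations).
#' @export
cnn_apply <- function(decoder, session, trials, window) {
  raw <- cnn_inputs(session, trials, window, decoder$spec$grid_bin)
  sc <- scale_inputs(raw, decoder$moments)
  U <- lapply(sc$inputs, unroll, w = decoder$spec$filter_width)
  fw <- cnn_forward(decoder$net, U)
  list(probs = fw$probs, latent = fw$h2)
}

#' Odor decoding probabilities on a grid of 250 ms windows
#'
#' Applies a trained decoder to each 250 ms window from -400 to +1450 ms
#' relative to port entry (the training-window trials are flagged in-sample).
#'
#' @param decoder `seqmem_cnn`.
#' @param session session; `trials` trials to decode.
#' @param starts window start times (s) relative to poke_in.
#' @param width window width (s).
#' @return list(probs = tidy data.frame(trial_id, window_start, p_<odor>...,
#'   argmax, in_sample), latent = list of latent matrices per window).
#' @export
decode_windows <- function(decoder, session, trials,
                           starts = seq(-0.4, 1.2, by = 0.25), width = 0.25) {
  rows <- list(); lat <- list()
  for (s0 in starts) {
    res <- cnn_apply(decoder, session, trials, c(s0, s0 + width))
    colnames(res$probs) <- paste0("p_", decoder$classes)
    d <- data.frame(trial_id = trials$trial_id,
                    window_start = s0, res$probs,
                    argmax = decoder$classes[max.col(res$probs)],
                    in_sample = trials$trial_id %in% decoder$train_ids,
                    stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- d
    lat[[sprintf("%.3f", s0)]] <- res$latent
  }
  list(probs = do.call(rbind, rows), latent = lat)
}

#' Two-dimensional projection of the decoder latent space
#'
#' Top two principal components of the latent vectors with linearized class
#' boundaries from a multinomial logistic regression on the 2-D coordinates.
#'
#' @param latent matrix of latent vectors; `argmax` decoder class per row.
#' @return list(coords, boundary_model, consistency = fraction of points
#'   whose linear region agrees with the decoder argmax).
#' @export
latent_projection <- function(latent, argmax) {
  if (any(!is.finite(latent))) stop("latent_projection: non-finite latent")
  pc <- stats::prcomp(latent, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2) stop("latent_projection: degenerate latent covariance")
  xy <- pc$x[, 1:2, drop = FALSE]
  df <- data.frame(x = xy[, 1], y = xy[, 2], cls = factor(argmax))
  fit <- nnet::multinom(cls ~ x + y, data = df, trace = FALSE)
  pred <- as.character(predict(fit, df))
  list(coords = xy, boundary_model = fit,
       consistency = mean(pred == as.character(argmax)))
}

#' Window-wise multinomial statistics for decoding probabilities
#'
#' Pools trials per window by argmax class, computes Goodman simultaneous
#' multinomial confidence intervals and a chi-square test per window, and the
#' per-trial least-squares slope of a probability difference across windows
#' with a one-sample t test.
#'
#' @param probs tidy table from [decode_windows()].
#' @param pair c(x, y): slope test on P_x - P_y.
#' @param conf CI level.
#' @return list(ci = per-window CI table, chisq = per-window chi-square p,
#'   slopes, slope_t, slope_p).
#' @export
window_stats <- function(probs, pair = c("C", "B"), conf = 0.95) {
  classes <- sub("^p_", "", grep("^p_", names(probs), value = TRUE))
  ws <- sort(unique(probs$window_start))
  ci <- do.call(rbind, lapply(ws, function(w) {
    d <- probs[probs$window_start == w, ]
    counts <- table(factor(d$argmax, levels = classes))
    cbind(data.frame(window_start = w, odor = classes),
          multinomial_ci(as.numeric(counts), conf))
  }))
  chisq <- vapply(ws, function(w) {
    d <- probs[probs$window_start == w, ]
    counts <- table(factor(d$argmax, levels = classes))
    if (sum(counts) == 0) return(NA_real_)
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }, numeric(1))
  dif <- probs[[paste0("p_", pair[1])]] - probs[[paste0("p_", pair[2])]]
  wix <- match(probs$window_start, ws)
  slopes <- vapply(split(seq_len(nrow(probs)), probs$trial_id), function(ix) {
    if (length(ix) < 2) return(NA_real_)
    unname(coef(lm(dif[ix] ~ wix[ix]))[2])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  tt <- t.test(slopes)
  list(ci = ci, chisq = setNames(chisq, ws), slopes = slopes,
       slope_t = unname(tt$statistic), slope_p = tt$p.value,
       slope_mean = mean(slopes))
}

#' Pre-entry predictive-coding comparison on OutSeq trials
#'
#' Decodes the 250 ms window before port entry on OutSeq trials (positions
#' 2-4) and compares the probability assigned to the expected InSeq odor
#' between correct and incorrect trials (two-sample KS test; optional
#' downsampled repetitions).
#'
#' @param decoder `seqmem_cnn`; `session` session.
#' @param window pre-entry window, default c(-0.25, 0).
#' @param positions sequence positions included.
#' @param n_downsample,seed downsampled repetitions of the KS test.
#' @return list(table, ks_D, ks_p, downsample).
#' @export
outcome_pretrial_comparison <- function(decoder, session, window = c(-0.25, 0),
                                        positions = 2:4, n_downsample = 0,
                                        seed = 1) {
  outs <- select_trials(session$trials, in_seq = FALSE, positions = positions)
  if (!any(outs$correct) || all(outs$correct))
    stop("outcome_pretrial_comparison: need both outcome groups")
  res <- cnn_apply(decoder, session, outs, window)
  expected <- c("A", "B", "C", "D", "E")[outs$position]
  p_exp <- res$probs[cbind(seq_len(nrow(outs)), match(expected, decoder$classes))]
  d <- data.frame(trial_id = outs$trial_id, correct = outs$correct,
                  p_expected = p_exp)
  ks <- suppressWarnings(ks.test(d$p_expected[d$correct], d$p_expected[!d$correct]))
  down <- NULL
  if (n_downsample > 0) {
    idxC <- which(d$correct); nI <- sum(!d$correct)
    draws <- perm_stream(length(idxC), n_downsample, seed, "downsample",
                         size = min(nI, length(idxC)))
    down <- do.call(rbind, lapply(draws, function(ix) {
      k <- suppressWarnings(ks.test(d$p_expected[idxC[ix]],
                                    d$p_expected[!d$correct]))
      data.frame(D = unname(k$statistic), p = k$p.value)
    }))
  }
  list(table = d, ks_D = unname(ks$statistic), ks_p = ks$p.value,
       downsample = down)
}

#' Cochran-Mantel-Haenszel control for subject effects
#'
#' Builds leave-one-session-out group confusion matrices and tests whether
#' predicted odors vary across them, stratified by true odor.
#'
#' @param confusions named list of per-session confusion matrices (true x
#'   predicted, same dimnames).
#' @return list(statistic, df, p, loo_tables).
#' @export
cmh_subject_control <- function(confusions) {
  if (length(confusions) < 2) stop("cmh_subject_control: need >= 2 sessions")
  total <- Reduce(`+`, confusions)
  loo <- lapply(confusions, function(cm) total - cm)
  arr <- array(0, dim = c(dim(total), length(loo)),
               dimnames = c(dimnames(total), list(names(loo))))
  for (i in seq_along(loo)) arr[, , i] <- loo[[i]]
  # strata = true odor: test predicted x leave-one-out-table association
  arr2 <- aperm(arr, c(2, 3, 1))  # predicted x group x true
  mh <- mantelhaen.test(arr2)
  list(statistic = unname(mh$statistic), df = unname(mh$parameter),
       p = mh$p.value, loo_tables = loo)
}
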