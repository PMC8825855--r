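#' Sliding sub-window input matrices for the autoencoder
#'
#' Divides each trial's 250 ms analysis window into 100 ms sub-windows
#' advanced in 10 ms steps (16 per window), each binned at 10 ms per neuron,
#' giving input vectors of length n_neurons x 10.
#'
#' @param session session.
#' @param trials selected trials.
#' @param anchor "poke_in" or "poke_out".
#' @param offset window start in seconds relative to the anchor (e.g. 0,
#'   0.25, or -0.25).
#' @param width window length (s); `sub` sub-window length; `step` sub-window
#'   advance; `bin` count bin.
#' @return list(X = (n_kept_trials * n_sub) x (n_neurons * sub/bin) matrix,
#'   info = data.frame(trial_id, subwindow), trials = kept trial table).
#' @export
make_windows <- function(session, trials, anchor = "poke_in", offset = 0,
                         width = 0.25, sub = 0.1, step = 0.01, bin = 0.01) {
  # drop trials whose window is not contained in [poke_in - 0.5, poke_out + 0.5]
  lo <- trials[[anchor]] + offset
  hi <- lo + width
  ok <- lo >= trials$poke_in - 0.5 & hi <= trials$poke_out + 0.5
  if (any(!ok)) sm_log("make_windows: dropping %d short trials", sum(!ok))
  trials <- trials[ok, , drop = FALSE]
  if (nrow(trials) == 0) stop("make_windows: no trials long enough")
  cnt <- window_spike_counts(session, trials, anchor,
                             window = c(offset, offset + width), bin = bin)
  nsub <- as.integer(round((width - sub) / step)) + 1L
  bins_per_sub <- as.integer(round(sub / bin))
  n <- dim(cnt)[2]
  X <- matrix(0, nrow(trials) * nsub, n * bins_per_sub)
  info <- data.frame(trial_id = rep(trials$trial_id, each = nsub),
                     subwindow = rep(seq_len(nsub), nrow(trials)))
  r <- 0
  for (i in seq_len(nrow(trials))) {
    m <- matrix(cnt[i, , ], nrow = n)   # neuron x bin
    for (k in seq_len(nsub)) {
      r <- r + 1
      X[r, ] <- as.numeric(t(m[, k:(k + bins_per_sub - 1), drop = FALSE]))
    }
  }
  list(X = X, info = info, trials = trials)
}

#' Autoencoder architecture and training hyperparameters
#'
#' Encoder of two rectified layers, a 2-node linear bottleneck, and a
#' mirrored decoder; trained by stochastic gradient descent with momentum to
#' minimize reconstruction MSE.
#'
#' @param input_dim input dimension (n_neurons x 10).
#' @param widths encoder layer widths (decoder mirrors them).
#' @param epochs,lr,momentum,batch training hyperparameters.
#' @param seed seed for initialization and batch order.
#' @return list of class `seqmem_ae_spec`.
#' @export
ae_spec <- function(input_dim, widths = c(500, 500), epochs = 200, lr = 1e-3,
                    momentum = 0.9, batch = 64, seed = 1) {
  stopifnot(input_dim >= 1, length(widths) >= 1, all(widths >= 2))
  structure(list(input_dim = input_dim, widths = widths, bottleneck = 2L,
                 epochs = epochs, lr = lr, momentum = momentum, batch = batch,
                 seed = seed), class = "seqmem_ae_spec")
}

relu <- function(x) (x > 0) * x

mlp_forward <- function(W, b, X, act) {
  H <- list(X)
  for (l in seq_along(W)) {
    Z <- H[[l]] %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], `+`)
    H[[l + 1]] <- if (act[l] == "relu") relu(Z) else Z
  }
  H
}

#' Train the bottleneck autoencoder
#'
#' Inputs are standardized per feature (centered and scaled). Hidden layers
#' are rectified; the bottleneck and the reconstruction output are linear
#' (the output regresses standardized counts, which take both signs).
#' Training is single-threaded and fully determined by the spec's seed.
#'
#' @param X input matrix from [make_windows()].
#' @param spec `seqmem_ae_spec`.
#' @return list(encode = function(Xnew) -> 2-D coordinates, latent = training
#'   coordinates, loss = per-epoch MSE, spec, center, scale).
#' @export
train_autoencoder <- function(X, spec) {
  stopifnot(ncol(X) == spec$input_dim, all(is.finite(X)))
  ctr <- colMeans(X)
  sc <- apply(X, 2, sd); sc[sc == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, `-`), 2, sc, `/`)
  sizes <- c(spec$input_dim, spec$widths, spec$bottleneck,
             rev(spec$widths), spec$input_dim)
  nl <- length(sizes) - 1
  act <- rep("relu", nl)
  act[length(spec$widths) + 1] <- "linear"   # bottleneck
  act[nl] <- "linear"                        # reconstruction output
  bidx <- length(spec$widths) + 1            # H index of bottleneck output
  with_seed(spec$seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1],
                   0, sqrt(1 / sizes[l])), sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1]))
    vW <- lapply(W, function(w) w * 0); vb <- lapply(b, function(x) x * 0)
    n <- nrow(Xs)
    loss <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1, n, by = spec$batch)) {
        ix <- ord[s:min(s + spec$batch - 1, n)]
        Xb <- Xs[ix, , drop = FALSE]
        H <- mlp_forward(W, b, Xb, act)
        err <- H[[nl + 1]] - Xb
        tot <- tot + sum(err^2)
        # squared error summed over features, averaged over the batch
        delta <- 2 * err / nrow(err)
        for (l in nl:1) {
          if (act[l] == "relu") delta <- delta * (H[[l + 1]] > 0)
          gW <- crossprod(H[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) delta <- delta %*% t(W[[l]])
          # clip gradient norms: plain SGD on a deep bottleneck net can blow
          # up in early epochs
          gn <- sqrt(sum(gW^2) + sum(gb^2))
          if (is.finite(gn) && gn > 10) { gW <- gW * 10 / gn; gb <- gb * 10 / gn }
          vW[[l]] <- spec$momentum * vW[[l]] - spec$lr * gW
          vb[[l]] <- spec$momentum * vb[[l]] - spec$lr * gb
          W[[l]] <- W[[l]] + vW[[l]]
          b[[l]] <- b[[l]] + vb[[l]]
        }
      }
      loss[ep] <- tot / length(Xs)
      if (!is.finite(loss[ep]))
        stop("train_autoencoder: training diverged; reduce the learning rate")
    }
    std <- function(Xnew) sweep(sweep(Xnew, 2, ctr, `-`), 2, sc, `/`)
    encode <- function(Xnew) {
      H <- mlp_forward(W[1:bidx], b[1:bidx], std(Xnew), act[1:bidx])
      H[[bidx + 1]]
    }
    reconstruct <- function(Xnew) {
      H <- mlp_forward(W, b, std(Xnew), act)
      H[[nl + 1]]
    }
    list(encode = encode, reconstruct = reconstruct,
         latent = encode(X), loss = loss, spec = spec, center = ctr, scale = sc)
  })
}

#' Reconstruction MSE of a trained autoencoder on new inputs
#' @param ae result of [train_autoencoder()]; `X` inputs on the raw scale.
#' @return mean squared error on the scaled feature space.
#' @export
ae_mse <- function(ae, X) {
  Xs <- sweep(sweep(X, 2, ae$center, `-`), 2, ae$scale, `/`)
  mean((ae$reconstruct(X) - Xs)^2)
}

#' k-NN label separability in the latent space with permutation chance
#'
#' 70/30 stratified split at the trial level; each test trial is classified
#' from its 16 latent points: every point takes the label of its two nearest
#' training points (disagreements resolved by the nearer neighbor,
#' equidistant ties by training-point index), and the trial takes the
#' majority point vote. Chance is the percentile interval of the accuracy
#' under label shuffles.
#'
#' @param latent m x 2 latent coordinates.
#' @param info data.frame(trial_id, subwindow) aligned with `latent`.
#' @param labels named vector: trial_id -> label.
#' @param split training fraction; `k` fixed at 2 by the method.
#' @param n_perm label permutations; `seed` seed; `conf` CI level.
#' @return list(accuracy, chance_lower, chance_upper, significant,
#'   chance = permutation accuracies).
#' @export
knn_separability <- function(latent, info, labels, split = 0.7, n_perm = 100,
                             seed = 1, conf = 0.95) {
  tid <- unique(info$trial_id)
  lab <- labels[tid]
  if (any(is.na(lab))) stop("knn_separability: missing labels")
  with_seed(seed, {
    tr_ids <- unlist(lapply(split(tid, lab), function(g)
      sample(g, max(1, round(split * length(g))))))
  })
  if (!all(table(lab[tr_ids]) >= 1)) stop("knn_separability: class absent from training split")
  te_ids <- setdiff(tid, tr_ids)
  if (!length(te_ids)) stop("knn_separability: empty test split")
  is_tr <- info$trial_id %in% tr_ids
  Xtr <- latent[is_tr, , drop = FALSE]; Xte <- latent[!is_tr, , drop = FALSE]
  tr_trial <- info$trial_id[is_tr]; te_trial <- info$trial_id[!is_tr]
  # two nearest training points per test point (precomputed once; label
  # permutations reuse the neighbor structure)
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) - 2 * Xte %*% t(Xtr)
  nn <- t(apply(d2, 1, function(r) order(r)[1:2]))
  acc_for <- function(lb) {
    l1 <- lb[tr_trial[nn[, 1]]]; l2 <- lb[tr_trial[nn[, 2]]]
    vote <- ifelse(l1 == l2, l1, l1)  # disagreement -> nearer neighbor (col 1)
    pred <- vapply(split(vote, te_trial), function(v)
      names(sort(table(v), decreasing = TRUE))[1], character(1))
    mean(pred == lb[names(pred)])
  }
  acc <- acc_for(lab)
  perms <- perm_stream(length(tid), n_perm, seed + 1L, "label-shuffle")
  ch <- vapply(perms, function(pr) {
    lb <- setNames(unname(lab[pr]), tid)
    acc_for(lb)
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- quantile(ch, c(a, 1 - a), names = FALSE)
  list(accuracy = acc, chance_lower = ci[1], chance_upper = ci[2],
       significant = acc > ci[2], chance = ch)
}

#' Mahalanobis distance between trial centroids by sequence lag
#'
#' Centroid of each trial's 16 latent points; pairwise Mahalanobis distance
#' under the pooled centroid covariance (Euclidean fallback if singular);
#' pairs classed by lag: odor distance for InSeq trials, position distance of
#' the same odor for OutSeq trials.
#'
#' @param latent,info as in [knn_separability()].
#' @param trials trial table covering the embedded trials.
#' @param type "inseq" or "outseq".
#' @return list(pairs = data.frame(lag, distance), anova_p, trend_slope,
#'   trend_p, quad_p).
#' @export
cluster_lag_distance <- function(latent, info, trials, type = c("inseq", "outseq")) {
  type <- match.arg(type)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(info)), info$trial_id),
                                function(ix) colMeans(latent[ix, , drop = FALSE])))
  tr <- trials[match(rownames(cent), trials$trial_id), ]
  keep <- if (type == "inseq")
    tr$in_seq & tr$correct & tr$odor %in% c("B", "C", "D", "E")
  else !tr$in_seq & tr$odor %in% c("B", "C", "D", "E")
  cent <- cent[keep, , drop = FALSE]; tr <- tr[keep, , drop = FALSE]
  if (nrow(cent) < 3) stop("cluster_lag_distance: too few trials")
  S <- cov(cent)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    sm_log("cluster_lag_distance: singular covariance; using Euclidean")
    Sinv <- diag(2)
  }
  pr <- which(upper.tri(matrix(0, nrow(cent), nrow(cent))), arr.ind = TRUE)
  lag <- if (type == "inseq")
    abs(odor_index(tr$odor[pr[, 1]]) - odor_index(tr$odor[pr[, 2]]))
  else ifelse(tr$odor[pr[, 1]] == tr$odor[pr[, 2]],
              abs(tr$position[pr[, 1]] - tr$position[pr[, 2]]), NA)
  dvec <- vapply(seq_len(nrow(pr)), function(i) {
    dd <- cent[pr[i, 1], ] - cent[pr[i, 2], ]
    sqrt(drop(t(dd) %*% Sinv %*% dd))
  }, numeric(1))
  d <- data.frame(lag = lag, distance = dvec)
  d <- d[!is.na(d$lag), , drop = FALSE]
  av <- aov(distance ~ factor(lag), data = d)
  lt <- lm(distance ~ lag, data = d)
  qt_ <- lm(distance ~ lag + I(lag^2), data = d)
  list(pairs = d, anova_p = summary(av)[[1]][["Pr(>F)"]][1],
       trend_slope = unname(coef(lt)[2]),
       trend_p = summary(lt)$coefficients[2, 4],
       quad_p = summary(qt_)$coefficients[3, 4])
}
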