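#' @title The 10-block convolutional classifier
#' @description
#' A binary CNN shared by all modalities: ten 3x3 convolution blocks with
#' ReLU activations, batch normalization in the first and last blocks only,
#' 2x2 max-pooling after blocks 4, 6, 9 and 10 (a 16-fold spatial reduction
#' per axis), global average pooling, and a 2-way softmax head. Training
#' uses Adam on the cross-entropy loss with soft (mixup-compatible) labels;
#' the checkpoint with the best development-split AUC is kept.
#'
#' The block skeleton is fixed; channel widths are configurable. The
#' `"tiny"` profile keeps the identical skeleton at widths small enough for
#' CPU-bound tests.
#' @name cnn-classifier
NULL

CNN_BN_BLOCKS <- c(1L, 10L)
CNN_POOL_BLOCKS <- c(4L, 6L, 9L, 10L)

#' CNN configuration
#'
#' @param input_shape integer pair (height, width) of the single-channel
#'   input grid, e.g. `c(243, 128)` for log-Mel segments or `c(512, 512)`
#'   for 12-lead page crops.
#' @param channels integer vector of length 10: output channels per block.
#'   `NULL` selects the profile default (16 doubling after each pooled
#'   block for `"default"`; 4/6/8 for `"tiny"`).
#' @param profile `"default"` or `"tiny"`.
#' @param kernel odd convolution kernel side (3).
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param seed integer seed fixing initialization and batch order.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_shape, channels = NULL, profile = "default",
                       kernel = 3L, epochs = 10L, batch_size = 16L,
                       learning_rate = 1e-3, seed = 1L) {
  profile <- match_one(profile, c("default", "tiny"), "profile")
  channels <- channels %||% switch(profile,
    default = c(16L, 16L, 16L, 16L, 32L, 32L, 64L, 64L, 64L, 128L),
    tiny = c(4L, 4L, 4L, 4L, 6L, 6L, 6L, 6L, 8L, 8L))
  if (length(channels) != 10L || any(channels < 1L))
    stopf("channels must be 10 positive integers")
  if (kernel %% 2L != 1L) stopf("kernel must be odd")
  structure(list(input_shape = as.integer(input_shape),
                 channels = as.integer(channels), profile = profile,
                 kernel = as.integer(kernel), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Architecture audit of a configuration
#'
#' Walks the block list and traces spatial shapes, for programmatic checks
#' of the skeleton (10 convolutions; batch norm in blocks 1 and 10; pooling
#' after blocks 4, 6, 9, 10).
#'
#' @param config a `cnn_config`.
#' @return data frame with one row per block: `block`, `channels`,
#'   `batchnorm`, `maxpool`, `out_h`, `out_w`.
#' @export
cnn_audit <- function(config) {
  h <- config$input_shape[1]; w <- config$input_shape[2]
  out <- data.frame(block = 1:10, channels = config$channels,
                    batchnorm = (1:10) %in% CNN_BN_BLOCKS,
                    maxpool = (1:10) %in% CNN_POOL_BLOCKS,
                    out_h = NA_integer_, out_w = NA_integer_)
  for (b in 1:10) {
    if (out$maxpool[b]) { h <- h %/% 2L; w <- w %/% 2L }
    out$out_h[b] <- h; out$out_w[b] <- w
  }
  out
}

#' Build (initialize) a CNN from a configuration
#'
#' He-normal weight initialization from the configured seed; two models
#' built from the same configuration are identical.
#'
#' @param config a `cnn_config`.
#' @return list of class `cnn_model` holding weights, batch-norm state and
#'   the configuration.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel
  with_seed(config$seed, {
    in_ch <- c(1L, config$channels[-10L])
    blocks <- lapply(1:10, function(b) {
      fan_in <- k * k * in_ch[b]
      blk <- list(
        w = matrix(rnorm(config$channels[b] * fan_in, 0, sqrt(2 / fan_in)),
                   nrow = config$channels[b]),
        b = numeric(config$channels[b]))
      if (b %in% CNN_BN_BLOCKS)
        blk$bn <- list(gamma = rep(1, config$channels[b]),
                       beta = numeric(config$channels[b]),
                       run_mean = numeric(config$channels[b]),
                       run_var = rep(1, config$channels[b]))
      blk
    })
    c_last <- config$channels[10L]
    head <- list(w = matrix(rnorm(2 * c_last, 0, sqrt(1 / c_last)), nrow = 2),
                 b = numeric(2))
    structure(list(blocks = blocks, head = head, config = config),
              class = "cnn_model")
  })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(z, bn, train) {
  d <- dim(z)
  C <- d[3]
  zc <- z
  cache <- list(mu = numeric(C), var = numeric(C), zhat = NULL)
  zhat <- z
  for (c0 in seq_len(C)) {
    v <- z[, , c0, , drop = FALSE]
    if (train) {
      mu <- mean(v); va <- mean((v - mu)^2)
    } else {
      mu <- bn$run_mean[c0]; va <- bn$run_var[c0]
    }
    zh <- (v - mu) / sqrt(va + BN_EPS)
    zhat[, , c0, ] <- zh
    zc[, , c0, ] <- bn$gamma[c0] * zh + bn$beta[c0]
    cache$mu[c0] <- mu; cache$var[c0] <- va
  }
  cache$zhat <- zhat
  list(out = zc, cache = cache)
}

bn_backward <- function(dz, z, bn, cache) {
  d <- dim(dz)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  dx <- dz
  dgamma <- dbeta <- numeric(C)
  for (c0 in seq_len(C)) {
    g <- dz[, , c0, , drop = FALSE]
    zh <- cache$zhat[, , c0, , drop = FALSE]
    dgamma[c0] <- sum(g * zh)
    dbeta[c0] <- sum(g)
    inv_sd <- 1 / sqrt(cache$var[c0] + BN_EPS)
    dzh <- g * bn$gamma[c0]
    # standard batch-norm gradient, vectorized per channel
    dx[, , c0, ] <- inv_sd / m * (m * dzh - sum(dzh) - zh * sum(dzh * zh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

cnn_forward_pass <- function(model, x, train = FALSE) {
  cfg <- model$config
  caches <- vector("list", 10L)
  for (b in 1:10) {
    blk <- model$blocks[[b]]
    cache <- list(x_in = x)
    z <- conv2d_forward(x, blk$w, blk$b, cfg$kernel)
    if (!is.null(blk$bn)) {
      bf <- bn_forward(z, blk$bn, train)
      cache$z <- z
      cache$bn <- bf$cache
      z2 <- bf$out
    } else z2 <- z
    cache$mask <- z2 > 0
    a <- z2 * cache$mask
    if (b %in% CNN_POOL_BLOCKS) {
      cache$prepool_dim <- dim(a)
      mp <- maxpool_forward(a)
      cache$pool_idx <- mp$idx
      x <- mp$y
    } else x <- a
    caches[[b]] <- cache
  }
  d <- dim(x)
  # global average pool: (H,W,C,N) -> N x C
  feat <- t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3]))
  logits <- feat %*% t(model$head$w) +
    matrix(model$head$b, nrow(feat), 2, byrow = TRUE)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  list(prob = p, feat = feat, gap_dim = d, caches = caches)
}

cnn_backward_pass <- function(model, fwd, y_soft) {
  cfg <- model$config
  n <- nrow(y_soft)
  grads <- list(blocks = vector("list", 10L), head = NULL)
  dlogits <- (fwd$prob - y_soft) / n
  grads$head <- list(w = t(dlogits) %*% fwd$feat, b = colSums(dlogits))
  dfeat <- dlogits %*% model$head$w                        # N x C
  d <- fwd$gap_dim
  hw <- d[1] * d[2]
  dx <- array(rep(t(dfeat) / hw, each = hw), dim = d)
  for (b in 10:1) {
    cache <- fwd$caches[[b]]
    blk <- model$blocks[[b]]
    if (b %in% CNN_POOL_BLOCKS)
      dx <- maxpool_backward(cache$pool_idx, dx,
                             cache$prepool_dim[1], cache$prepool_dim[2])
    dz2 <- dx * cache$mask
    g <- list()
    if (!is.null(blk$bn)) {
      bb <- bn_backward(dz2, cache$z, blk$bn, cache$bn)
      dz1 <- bb$dx
      g$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
    } else dz1 <- dz2
    cb <- conv2d_backward(cache$x_in, blk$w, dz1, cfg$kernel)
    g$w <- cb$dw; g$b <- cb$db
    grads$blocks[[b]] <- g
    dx <- cb$dx
  }
  grads
}

bn_update_running <- function(model, fwd) {
  for (b in CNN_BN_BLOCKS) {
    cache <- fwd$caches[[b]]$bn
    bn <- model$blocks[[b]]$bn
    bn$run_mean <- (1 - BN_MOMENTUM) * bn$run_mean + BN_MOMENTUM * cache$mu
    bn$run_var <- (1 - BN_MOMENTUM) * bn$run_var + BN_MOMENTUM * cache$var
    model$blocks[[b]]$bn <- bn
  }
  model
}

adam_init <- function(model) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(model[c("blocks", "head")]),
       v = zero_like(model[c("blocks", "head")]), t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (b in 1:10) {
    for (nm in c("w", "b")) {
      u <- upd(model$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
               state$m$blocks[[b]][[nm]], state$v$blocks[[b]][[nm]])
      model$blocks[[b]][[nm]] <- u$p
      state$m$blocks[[b]][[nm]] <- u$m
      state$v$blocks[[b]][[nm]] <- u$v
    }
    if (!is.null(model$blocks[[b]]$bn)) {
      for (nm in c("gamma", "beta")) {
        u <- upd(model$blocks[[b]]$bn[[nm]], grads$blocks[[b]]$bn[[nm]],
                 state$m$blocks[[b]]$bn[[nm]], state$v$blocks[[b]]$bn[[nm]])
        model$blocks[[b]]$bn[[nm]] <- u$p
        state$m$blocks[[b]]$bn[[nm]] <- u$m
        state$v$blocks[[b]]$bn[[nm]] <- u$v
      }
    }
  }
  for (nm in c("w", "b")) {
    u <- upd(model$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    model$head[[nm]] <- u$p
    state$m$head[[nm]] <- u$m
    state$v$head[[nm]] <- u$v
  }
  list(model = model, state = state)
}

stack_batch <- function(x_list) {
  d <- dim(x_list[[1]])
  array(unlist(x_list, use.names = FALSE), dim = c(d[1], d[2], 1L, length(x_list)))
}

#' Class probabilities for a list of input grids
#'
#' Evaluation path: deterministic, no augmentation, batch-norm uses running
#' statistics.
#'
#' @param model a trained `cnn_model`.
#' @param x_list list of height x width matrices matching the configured
#'   input shape.
#' @param batch_size evaluation batch size.
#' @return numeric vector of positive-class (anomaly) probabilities.
#' @export
cnn_predict <- function(model, x_list, batch_size = 32L) {
  n <- length(x_list)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- stack_batch(x_list[i:j])
    out[i:j] <- cnn_forward_pass(model, x, train = FALSE)$prob[, 2L]
    i <- j + 1L
  }
  out
}

#' Train the CNN on in-memory grids
#'
#' Cross-entropy on soft labels, Adam, and per-epoch monitoring of the
#' development split (evaluation path, augmentation off); the returned
#' model is the checkpoint with the best development AUC.
#'
#' @param x_train list of input matrices; `y_train` binary labels (0/1).
#' @param x_dev,y_dev development split, monitored each epoch.
#' @param config a `cnn_config`.
#' @param augment_fn optional `function(x_list, y_soft)` applied to each
#'   training batch (training path only); must return
#'   `list(x = x_list, y = y_soft)`.
#' @return list of class `cnn_fit`: `model`, `history` (epoch, train_loss,
#'   dev_auc) and `best_epoch`.
#' @export
cnn_train <- function(x_train, y_train, x_dev, y_dev, config,
                      augment_fn = NULL) {
  if (sum(y_train == 1) == 0 || sum(y_train == 0) == 0)
    stopf("training split must contain both classes")
  model <- build_model(config)
  state <- adam_init(model)
  n <- length(x_train)
  best_auc <- -Inf
  best_model <- model
  best_epoch <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_auc = numeric())
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        sel <- ord[i:j]
        xb <- x_train[sel]
        yb <- cbind(1 - y_train[sel], y_train[sel])
        if (!is.null(augment_fn)) {
          aug <- augment_fn(xb, yb)
          xb <- aug$x; yb <- aug$y
        }
        x <- stack_batch(xb)
        fwd <- cnn_forward_pass(model, x, train = TRUE)
        model <- bn_update_running(model, fwd)
        loss <- -mean(rowSums(yb * log(pmax(fwd$prob, 1e-12))))
        grads <- cnn_backward_pass(model, fwd, yb)
        st <- adam_step(model, grads, state, config$learning_rate)
        model <- st$model; state <- st$state
        total_loss <- total_loss + loss
        nb <- nb + 1L
        i <- j + 1L
      }
      dev_p <- cnn_predict(model, x_dev)
      dev_auc <- roc_auc(dev_p, y_dev)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = total_loss / nb, dev_auc = dev_auc))
      if (dev_auc > best_auc) {
        best_auc <- dev_auc
        best_model <- model
        best_epoch <- ep
      }
    }
  })
  structure(list(model = best_model, history = history,
                 best_epoch = best_epoch, dev_auc = best_auc),
            class = "cnn_fit")
}

#' Record-level anomaly probability
#'
#' Aggregates per-segment positive-class probabilities into one probability
#' per record; the evaluation-time segment set is the deterministic
#' grade-"none" segmentation for heart sounds and the unshifted crop for
#' ECG views.
#'
#' @param model a trained `cnn_model` (or a `cnn_fit`).
#' @param x_list list of the record's evaluation-time input grids.
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return scalar anomaly probability in [0, 1].
#' @export
predict_record <- function(model, x_list, aggregate = "mean") {
  if (inherits(model, "cnn_fit")) model <- model$model
  if (!length(x_list)) stopf("no segments/views supplied for the record")
  p <- cnn_predict(model, x_list)
  switch(match_one(aggregate, c("mean", "max"), "aggregate"),
         mean = mean(p), max = max(p))
}
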