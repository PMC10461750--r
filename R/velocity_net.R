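#' Convolutional LSTM-UNet for frame-sequence velocimetry
#'
#' The network maps a T x H x W magnitude clip to a 2 x H x W velocity map
#' (magnitude px/ms, angle scaled to [0, 1]). Each frame passes a shared
#' feature-extraction path (input block of two conv3x3-BN-ReLU layers, then
#' `depth` encoder blocks of 2x2 max-pool + two conv-BN-ReLU, doubling
#' channels and halving resolution); the per-frame bottleneck features are
#' fed sequentially to a ConvLSTM whose final hidden state is decoded by
#' `depth` decoder blocks (bilinear x2 upsampling + two conv-BN-ReLU,
#' halving channels) with UNet skip connections, and a final 3x3 convolution
#' with 2 output channels. The ConvLSTM replaces the classical UNet
#' bottleneck and performs the temporal reduction.
#'
#' @name velocity_net
NULL

#' Network configuration
#'
#' @param depth number of encoder/decoder levels (H, W must be divisible by
#'   `2^depth`).
#' @param base_width feature channels after the input block.
#' @param lstm_hidden ConvLSTM hidden channels; defaults to the bottleneck
#'   width `base_width * 2^depth`.
#' @param kernel convolution kernel size (3).
#' @param skip_mode how UNet skips cross the temporal reduction:
#'   `"temporal_mean"` (mean of per-frame encoder features), `"last_frame"`,
#'   or `"none"`.
#' @export
net_config <- function(depth = 3L, base_width = 32L, lstm_hidden = NULL,
                       kernel = 3L,
                       skip_mode = c("temporal_mean", "last_frame", "none")) {
  skip_mode <- match.arg(skip_mode)
  stopifnot(depth >= 1, base_width >= 1, kernel == 3L)
  if (is.null(lstm_hidden)) lstm_hidden <- base_width * 2^depth
  structure(list(depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 lstm_hidden = as.integer(lstm_hidden),
                 kernel = as.integer(kernel), skip_mode = skip_mode),
            class = "net_config")
}

#' Initialize a velocity network
#' @param cfg a [net_config()].
#' @param seed RNG seed for the weight initialization.
#' @export
init_velocity_net <- function(cfg = net_config(), seed = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  w <- cfg$base_width; d <- cfg$depth; k <- cfg$kernel; L <- cfg$lstm_hidden
  with_seed(seed, {
    params <- list(
      inp = list(conv1 = conv_init(k, 1L, w), bn1 = bn_init(w),
                 conv2 = conv_init(k, w, w), bn2 = bn_init(w)),
      enc = lapply(seq_len(d), function(i) {
        ci <- w * 2^(i - 1L)
        list(conv1 = conv_init(k, ci, 2L * ci), bn1 = bn_init(2L * ci),
             conv2 = conv_init(k, 2L * ci, 2L * ci), bn2 = bn_init(2L * ci))
      }),
      lstm = lstm_init(k, w * 2^d, L),
      dec = local({
        cur <- L
        lapply(seq_len(d), function(j) {
          outc <- w * 2^(d - j)
          skipc <- if (cfg$skip_mode == "none") 0L else outc
          blk <- list(conv1 = conv_init(k, cur + skipc, outc),
                      bn1 = bn_init(outc),
                      conv2 = conv_init(k, outc, outc), bn2 = bn_init(outc))
          cur <<- outc
          blk
        })
      }),
      out = conv_init(k, w, 2L))
    buffers <- list(
      inp = list(bn1 = bn_buf_init(w), bn2 = bn_buf_init(w)),
      enc = lapply(seq_len(d), function(i) {
        c2 <- w * 2^i
        list(bn1 = bn_buf_init(c2), bn2 = bn_buf_init(c2))
      }),
      dec = lapply(seq_len(d), function(j) {
        outc <- w * 2^(d - j)
        list(bn1 = bn_buf_init(outc), bn2 = bn_buf_init(outc))
      }))
    structure(list(cfg = cfg, params = params, buffers = buffers),
              class = "velocity_net")
  })
}

#' @export
print.velocity_net <- function(x, ...) {
  np <- length(flatten_params(x$params))
  cat(sprintf(
    "<velocity_net> depth %d, base width %d, ConvLSTM hidden %d, %d params\n",
    x$cfg$depth, x$cfg$base_width, x$cfg$lstm_hidden, np))
  invisible(x)
}

# Two conv-BN-ReLU layers applied to a list of frames with pooled BN stats.
block_fwd <- function(xs, prm, buf, k, training) {
  a1 <- lapply(xs, conv_fwd, prm = prm$conv1, k = k)
  b1 <- bn_fwd(a1, prm$bn1, buf$bn1, training)
  r1 <- lapply(b1$y, relu_fwd)
  a2 <- lapply(r1, conv_fwd, prm = prm$conv2, k = k)
  b2 <- bn_fwd(a2, prm$bn2, buf$bn2, training)
  r2 <- lapply(b2$y, relu_fwd)
  buf$bn1 <- b1$buf; buf$bn2 <- b2$buf
  list(y = r2, buf = buf,
       cache = list(xs = xs, b1 = b1, r1 = r1, b2 = b2))
}

block_bwd <- function(gys, prm, cache, k) {
  g2 <- mapply(relu_bwd, cache$b2$y, gys, SIMPLIFY = FALSE)
  bb2 <- bn_bwd(g2, prm$bn2, cache$b2$cache)
  cb2 <- mapply(conv_bwd, cache$r1, bb2$gx,
                MoreArgs = list(prm = prm$conv2, k = k), SIMPLIFY = FALSE)
  g1 <- mapply(function(b, cb) relu_bwd(b, cb$gx), cache$b1$y, cb2,
               SIMPLIFY = FALSE)
  bb1 <- bn_bwd(g1, prm$bn1, cache$b1$cache)
  cb1 <- mapply(conv_bwd, cache$xs, bb1$gx,
                MoreArgs = list(prm = prm$conv1, k = k), SIMPLIFY = FALSE)
  gW <- list(conv1 = list(W = Reduce(`+`, lapply(cb1, `[[`, "gW")),
                          b = Reduce(`+`, lapply(cb1, `[[`, "gb"))),
             bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
             conv2 = list(W = Reduce(`+`, lapply(cb2, `[[`, "gW")),
                          b = Reduce(`+`, lapply(cb2, `[[`, "gb"))),
             bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta))
  list(gxs = lapply(cb1, `[[`, "gx"), grads = gW)
}

# Single-tensor variant used in the decoder.
block1_fwd <- function(x, prm, buf, k, training) {
  r <- block_fwd(list(x), prm, buf, k, training)
  list(y = r$y[[1]], buf = r$buf, cache = r$cache)
}

block1_bwd <- function(gy, prm, cache, k) {
  r <- block_bwd(list(gy), prm, cache, k)
  list(gx = r$gxs[[1]], grads = r$grads)
}

#' Forward pass of the velocity network
#'
#' @param net a `velocity_net`.
#' @param clip T x H x W array (H, W divisible by `2^depth`).
#' @param training use batch statistics (TRUE) or running statistics.
#' @param want_cache keep intermediate activations for [backward_velocity_net()].
#' @return list(pred = H x W x 2 array, cache, net) — `net` carries updated
#'   batch-norm running statistics when `training = TRUE`.
#' @export
forward_velocity_net <- function(net, clip, training = TRUE,
                                 want_cache = FALSE) {
  cfg <- net$cfg; k <- cfg$kernel; d <- cfg$depth
  stopifnot(length(dim(clip)) == 3L)
  Tn <- dim(clip)[1]; H <- dim(clip)[2]; W <- dim(clip)[3]
  if (H %% 2^d != 0L || W %% 2^d != 0L)
    stop("spatial dims must be divisible by 2^depth; got ",
         H, "x", W, " at depth ", d)
  xs <- lapply(seq_len(Tn), function(t) array(clip[t, , ], c(H, W, 1L)))
  cache <- list(pool = vector("list", d), blocks = vector("list", d + 1L),
                lstm = vector("list", Tn), dec = vector("list", d))

  bf <- block_fwd(xs, net$params$inp, net$buffers$inp, k, training)
  net$buffers$inp <- bf$buf
  cache$blocks[[1L]] <- bf$cache
  feats <- list(bf$y)                      # feats[[lvl+1]] = level lvl output
  cur <- bf$y
  for (i in seq_len(d)) {
    pooled <- lapply(cur, function(a) cpp_maxpool_fwd(a))
    cache$pool[[i]] <- lapply(pooled, `[[`, "idx")
    pin <- lapply(pooled, `[[`, "y")
    bf <- block_fwd(pin, net$params$enc[[i]], net$buffers$enc[[i]], k,
                    training)
    net$buffers$enc[[i]] <- bf$buf
    cache$blocks[[i + 1L]] <- bf$cache
    cur <- bf$y
    feats[[i + 1L]] <- cur
  }

  L <- cfg$lstm_hidden
  hb <- H %/% 2^d; wb <- W %/% 2^d
  h <- array(0, c(hb, wb, L)); cc <- array(0, c(hb, wb, L))
  for (t in seq_len(Tn)) {
    st <- lstm_fwd(feats[[d + 1L]][[t]], h, cc, net$params$lstm, L, k)
    h <- st$h; cc <- st$c
    cache$lstm[[t]] <- st$cache
  }

  skip_of <- function(lvl) {
    fs <- feats[[lvl + 1L]]
    switch(cfg$skip_mode,
           temporal_mean = Reduce(`+`, fs) / length(fs),
           last_frame = fs[[length(fs)]],
           none = NULL)
  }
  cur1 <- h
  for (j in seq_len(d)) {
    up <- cpp_upsample2_fwd(cur1)
    sk <- skip_of(d - j)
    xin <- if (is.null(sk)) up else concat_c(up, sk)
    bf <- block1_fwd(xin, net$params$dec[[j]], net$buffers$dec[[j]], k,
                     training)
    net$buffers$dec[[j]] <- bf$buf
    cache$dec[[j]] <- list(cache = bf$cache, up_ch = dim(up)[3],
                           in_dim = dim(cur1)[1:2])
    cur1 <- bf$y
  }
  pred <- conv_fwd(cur1, net$params$out, k)
  cache$out_in <- cur1
  cache$Tn <- Tn
  list(pred = pred,
       cache = if (want_cache) cache else NULL,
       net = net)
}

#' Backward pass: parameter gradients for one clip
#'
#' @param net a `velocity_net`.
#' @param cache cache from [forward_velocity_net()] with `want_cache = TRUE`.
#' @param gpred gradient of the loss w.r.t. the H x W x 2 prediction.
#' @return nested gradient list matching `net$params`.
#' @export
backward_velocity_net <- function(net, cache, gpred) {
  cfg <- net$cfg; k <- cfg$kernel; d <- cfg$depth
  Tn <- cache$Tn
  grads <- zero_params(net$params)
  cb <- conv_bwd(cache$out_in, net$params$out, gpred, k)
  grads$out$W <- cb$gW; grads$out$b <- cb$gb
  g <- cb$gx
  skip_g <- vector("list", d + 1L)          # gradient into feats[[lvl+1]]
  for (j in rev(seq_len(d))) {
    dc <- cache$dec[[j]]
    bb <- block1_bwd(g, net$params$dec[[j]], dc$cache, k)
    grads$dec[[j]] <- bb$grads
    gin <- bb$gx
    if (cfg$skip_mode != "none") {
      sp <- split_c(gin, dc$up_ch)
      gup <- sp[[1]]; skip_g[[d - j + 1L]] <- sp[[2]]
    } else gup <- gin
    g <- cpp_upsample2_bwd(gup, dc$in_dim[1], dc$in_dim[2])
  }

  L <- cfg$lstm_hidden
  gh <- g
  gc <- gh * 0
  gx_t <- vector("list", Tn)
  gl_W <- net$params$lstm$W * 0; gl_b <- net$params$lstm$b * 0
  for (t in rev(seq_len(Tn))) {
    lb <- lstm_bwd(gh, gc, net$params$lstm, cache$lstm[[t]], L, k)
    gx_t[[t]] <- lb$gx
    gh <- lb$gh_prev; gc <- lb$gc_prev
    gl_W <- gl_W + lb$gW; gl_b <- gl_b + lb$gb
  }
  grads$lstm$W <- gl_W; grads$lstm$b <- gl_b

  # distribute skip gradients to per-frame features (skip_g indexed lvl + 1)
  feat_g <- function(lvl, base) {
    gs <- base
    sg <- if (lvl + 1L <= length(skip_g)) skip_g[[lvl + 1L]] else NULL
    if (!is.null(sg)) {
      if (cfg$skip_mode == "temporal_mean") {
        gs <- lapply(gs, function(a) a + sg / Tn)
      } else if (cfg$skip_mode == "last_frame") {
        gs[[Tn]] <- gs[[Tn]] + sg
      }
    }
    gs
  }

  gfeat <- feat_g(d, gx_t)
  for (i in rev(seq_len(d))) {
    bb <- block_bwd(gfeat, net$params$enc[[i]], cache$blocks[[i + 1L]], k)
    grads$enc[[i]] <- bb$grads
    Hin <- dim(cache$blocks[[i]]$b2$y[[1]])[1]
    Win <- dim(cache$blocks[[i]]$b2$y[[1]])[2]
    gprev <- mapply(function(gp, idx) cpp_maxpool_bwd(idx, gp, Hin, Win),
                    bb$gxs, cache$pool[[i]], SIMPLIFY = FALSE)
    gfeat <- feat_g(i - 1L, gprev)
  }
  bb <- block_bwd(gfeat, net$params$inp, cache$blocks[[1L]], k)
  grads$inp <- bb$grads
  grads
}

#' Mean squared error loss
#'
#' Mean over all elements of the squared prediction-target differences.
#' @param pred,target numeric arrays of identical shape.
#' @export
mse_loss <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)) ||
              length(pred) == length(target))
  mean((pred - target)^2)
}

#' Training configuration
#' @param lr Adam learning rate.
#' @param batch minibatch size (gradients averaged over the batch).
#' @param epochs training epochs.
#' @param seed RNG seed (shuffling, initialization).
#' @param checkpoint keep the parameters with the best validation loss.
#' @export
train_config <- function(lr = 0.001, batch = 4L, epochs = 100L, seed = 1L,
                         checkpoint = TRUE) {
  stopifnot(lr >= 0, batch >= 1, epochs >= 1)
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), seed = seed,
                 checkpoint = checkpoint),
            class = "train_config")
}

sample_pred_target <- function(sample) {
  tgt <- aperm(sample$target, c(2, 3, 1))   # 2 x H x W -> H x W x 2
  list(clip = sample$input, target = tgt)
}

#' Train the velocity network
#'
#' Adam + MSE over minibatches (gradient accumulation), with per-epoch train
#' and validation loss history and optional best-validation checkpointing.
#' Fully deterministic for a fixed seed. Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param dataset a `training_set` from [make_training_set()].
#' @param net_cfg a [net_config()]; ignored when `net` is supplied.
#' @param train_cfg a [train_config()].
#' @param net optionally a pre-initialized or pre-trained `velocity_net`.
#' @param verbose print per-epoch losses.
#' @return the trained `velocity_net` with a `history` data.frame attached.
#' @export
train_velocity_net <- function(dataset, net_cfg = net_config(),
                               train_cfg = train_config(), net = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(dataset, "training_set"))
  tr_idx <- dataset$train
  va_idx <- dataset$validation
  stopifnot(length(tr_idx) >= 1)
  with_seed(train_cfg$seed, {
    if (is.null(net)) net <- init_velocity_net(net_cfg)
    p <- flatten_params(net$params)
    m <- p * 0; v <- p * 0; step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    best <- list(loss = Inf, params = net$params, buffers = net$buffers)
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch))
      ep_loss <- 0
      for (bt in batches) {
        gsum <- NULL; bloss <- 0
        for (s in bt) {
          st <- sample_pred_target(dataset$samples[[s]])
          fw <- forward_velocity_net(net, st$clip, training = TRUE,
                                     want_cache = TRUE)
          net <- fw$net
          loss <- mse_loss(fw$pred, st$target)
          if (!is.finite(loss))
            stop("training diverged: non-finite loss at epoch ", ep)
          bloss <- bloss + loss
          gpred <- 2 * (fw$pred - st$target) / length(st$target)
          gr <- backward_velocity_net(net, fw$cache, gpred)
          gf <- flatten_params(gr)
          gsum <- if (is.null(gsum)) gf else gsum + gf
        }
        g <- gsum / length(bt)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        p <- p - train_cfg$lr * mhat / (sqrt(vhat) + eps)
        net$params <- unflatten_params(net$params, p)
        ep_loss <- ep_loss + bloss
      }
      tl <- ep_loss / length(ord)
      vl <- NA_real_
      if (length(va_idx)) {
        vl <- mean(vapply(va_idx, function(s) {
          st <- sample_pred_target(dataset$samples[[s]])
          fw <- forward_velocity_net(net, st$clip, training = FALSE)
          mse_loss(fw$pred, st$target)
        }, 0))
        if (train_cfg$checkpoint && vl < best$loss)
          best <- list(loss = vl, params = net$params,
                       buffers = net$buffers)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", ep, tl,
                        ifelse(is.na(vl), "-", sprintf("%.5f", vl))))
    }
    if (train_cfg$checkpoint && is.finite(best$loss)) {
      net$params <- best$params
      net$buffers <- best$buffers
    }
    net$history <- hist
    net
  })
}

#' Predict a velocity map from a clip
#'
#' Runs the network in evaluation mode (running batch-norm statistics) and
#' packages the output as a `velocity_map` (magnitude clipped at 0, angle
#' clipped to [0, 1]).
#' @param net a trained `velocity_net`.
#' @param clip T x H x W array.
#' @export
predict_velocity_map <- function(net, clip) {
  fw <- forward_velocity_net(net, clip, training = FALSE)
  velocity_map(pmax(fw$pred[, , 1L], 0),
               pmin(pmax(fw$pred[, , 2L], 0), 1))
}

#' Save / load a trained network
#'
#' The parameter container is RDS; a JSON sidecar records the architecture,
#' seed and pixel calibration, and the training history goes to CSV.
#' @param net a `velocity_net`.
#' @param path RDS path; sidecars take `.json` / `_history.csv` suffixes.
#' @param pixel_size,frame_interval calibration metadata for the sidecar.
#' @export
save_velocity_net <- function(net, path, pixel_size = 4.9,
                              frame_interval = 1) {
  saveRDS(net, path)
  meta <- list(cfg = unclass(net$cfg), pixel_size = pixel_size,
               frame_interval = frame_interval,
               n_params = length(flatten_params(net$params)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(net$history))
    write.csv(net$history, sub("\\.rds$", "_history.csv", path),
              row.names = FALSE)
  invisible(path)
}

#' @rdname save_velocity_net
#' @export
load_velocity_net <- function(path) readRDS(path)
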