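# 3-D U-Net for per-tooth binary segmentation, implemented natively on
# BLAS-backed matrix multiplication: feature maps are C x nvox matrices
# (voxel index linear over the cube, first axis fastest) and every 3x3x3
# convolution is one GEMM against an im2col matrix.  Downsampling uses
# stride-2 convolutions (batch norm + LeakyReLU); all other convolutions
# use batch norm + ReLU; the expansive path uses 2x2x2 nearest-neighbour
# upsampling with skip concatenation; the head is a 1x1x1 convolution with
# a sigmoid.

#' Specify a 3D U-Net
#'
#' @param input_size input cube edge in voxels; must be divisible by
#'   `2^levels`.
#' @param levels number of downsampling levels.
#' @param base_channels channels at full resolution; doubled per level.
#' @param leaky_slope negative slope of the LeakyReLU on downsampling
#'   layers.
#' @return A `unet_spec`.
#' @export
unet_spec <- function(input_size = 128, levels = 4, base_channels = 16,
                      leaky_slope = 0.01) {
  input_size <- as.integer(input_size)
  levels <- as.integer(levels)
  if (input_size %% (2^levels) != 0) {
    stop("input size ", input_size, " is not divisible by 2^", levels)
  }
  structure(list(input_size = input_size, levels = levels,
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "unet_spec")
}

new_conv <- function(c_in, c_out, stride, act, kernel = 27L) {
  W <- matrix(stats::rnorm(c_out * kernel * c_in,
                           sd = sqrt(2 / (kernel * c_in))),
              nrow = c_out)
  list(W = W, b = numeric(c_out),
       gamma = rep(1, c_out), beta = numeric(c_out),
       rmean = numeric(c_out), rvar = rep(1, c_out),
       stride = as.integer(stride), act = act,
       c_in = as.integer(c_in), c_out = as.integer(c_out),
       bn = kernel == 27L)
}

#' Build a 3D U-Net model
#'
#' Initializes all weights (He-normal, seeded) for the architecture
#' described by the spec.
#'
#' @param spec a `unet_spec`.
#' @param seed integer seed for the weight initialization.
#' @return A `unet_model`; its parameter count is reported by `print()`.
#' @export
#' @examples
#' m <- build_unet(unet_spec(input_size = 32, levels = 3,
#'                           base_channels = 4))
build_unet <- function(spec, seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  L <- spec$levels
  ch <- spec$base_channels * 2^(0:L)
  layers <- list(enc0 = new_conv(1, ch[1], 1, "relu"))
  for (l in seq_len(L)) {
    layers[[paste0("down", l)]] <- new_conv(ch[l], ch[l + 1], 2, "leaky")
    layers[[paste0("enc", l)]] <- new_conv(ch[l + 1], ch[l + 1], 1, "relu")
  }
  for (l in rev(seq_len(L) - 1)) {
    layers[[paste0("dec", l)]] <- new_conv(ch[l + 2] + ch[l + 1], ch[l + 1],
                                           1, "relu")
  }
  layers$head <- new_conv(ch[1], 1, 1, "none", kernel = 1L)
  n_par <- sum(vapply(layers, function(ly) {
    length(ly$W) + length(ly$b) + if (ly$bn) 2 * length(ly$gamma) else 0
  }, numeric(1)))
  structure(list(spec = spec, layers = layers, n_parameters = n_par),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> input ", x$spec$input_size, "^3, ", x$spec$levels,
      " levels, base ", x$spec$base_channels, " channels, ",
      format(x$n_parameters, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

conv_forward <- function(layer, xs, dims, training, slope) {
  cols <- lapply(xs, function(x) im2col3_cpp(x, dims, layer$stride))
  zs <- lapply(cols, function(cl) layer$W %*% cl + layer$b)
  cache <- list(cols = cols, dims = dims)
  if (layer$bn) {
    if (training) {
      ntot <- sum(vapply(zs, ncol, 0))
      m <- Reduce(`+`, lapply(zs, rowSums)) / ntot
      v <- Reduce(`+`, lapply(zs, function(z) rowSums(z^2))) / ntot - m^2
      v <- pmax(v, 0)
      cache$batch_mean <- m
      cache$batch_var <- v
    } else {
      m <- layer$rmean
      v <- layer$rvar
    }
    invstd <- 1 / sqrt(v + bn_eps)
    zhat <- lapply(zs, function(z) (z - m) * invstd)
    ys <- lapply(zhat, function(z) layer$gamma * z + layer$beta)
    cache$zhat <- zhat
    cache$invstd <- invstd
  } else {
    ys <- zs
  }
  ys <- switch(layer$act,
    relu = lapply(ys, function(y) y * (y > 0)),
    leaky = lapply(ys, function(y) y * ((y > 0) + slope * (y <= 0))),
    none = ys
  )
  cache$ys <- ys
  list(ys = ys, cache = cache)
}

conv_backward <- function(layer, cache, dys, slope) {
  dzs <- switch(layer$act,
    relu = mapply(function(dy, y) dy * (y > 0), dys, cache$ys,
                  SIMPLIFY = FALSE),
    leaky = mapply(function(dy, y) dy * ((y > 0) + slope * (y <= 0)), dys,
                   cache$ys, SIMPLIFY = FALSE),
    none = dys
  )
  grads <- list()
  if (layer$bn) {
    N <- sum(vapply(dzs, ncol, 0))
    grads$gamma <- Reduce(`+`, mapply(function(dz, zh) rowSums(dz * zh),
                                      dzs, cache$zhat, SIMPLIFY = FALSE))
    grads$beta <- Reduce(`+`, lapply(dzs, rowSums))
    dzh <- lapply(dzs, function(dz) dz * layer$gamma)
    s1 <- Reduce(`+`, lapply(dzh, rowSums))
    s2 <- Reduce(`+`, mapply(function(d, zh) rowSums(d * zh), dzh,
                             cache$zhat, SIMPLIFY = FALSE))
    dzs <- mapply(function(d, zh) {
      cache$invstd * (d - s1 / N - zh * (s2 / N))
    }, dzh, cache$zhat, SIMPLIFY = FALSE)
  }
  grads$W <- Reduce(`+`, mapply(function(dz, cl) tcrossprod(dz, cl), dzs,
                                cache$cols, SIMPLIFY = FALSE))
  grads$b <- Reduce(`+`, lapply(dzs, rowSums))
  dxs <- lapply(dzs, function(dz) {
    gcol <- crossprod(layer$W, dz)
    col2im3_cpp(gcol, layer$c_in, cache$dims, layer$stride)
  })
  list(grads = grads, dxs = dxs)
}

head_forward <- function(layer, xs) {
  lapply(xs, function(x) layer$W %*% x + layer$b)
}

upsample2 <- function(x, dims) {
  C <- nrow(x)
  a <- array(x, c(C, dims))
  a <- a[, rep(seq_len(dims[1]), each = 2), rep(seq_len(dims[2]), each = 2),
         rep(seq_len(dims[3]), each = 2), drop = FALSE]
  matrix(a, nrow = C)
}

downsum2 <- function(g, dims_big) {
  C <- nrow(g)
  a <- array(g, c(C, 2, dims_big[1] / 2, 2, dims_big[2] / 2, 2,
                  dims_big[3] / 2))
  acc <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    acc <- acc + a[, i, , j, , k, , drop = FALSE]
  }
  matrix(acc, nrow = C)
}

normalize_image <- function(img) {
  m <- mean(img)
  s <- stats::sd(img)
  if (!is.finite(s) || s < 1e-8) s <- 1
  (img - m) / s
}

sigmoid <- function(z) 1 / (1 + exp(-z))

unet_forward <- function(model, images, training = FALSE) {
  spec <- model$spec
  L <- spec$levels
  slope <- spec$leaky_slope
  dims0 <- rep(spec$input_size, 3)
  for (img in images) {
    if (!identical(dim(img), as.integer(dims0))) {
      stop("input shape ", paste(dim(img), collapse = "x"),
           " does not match the model input size ", spec$input_size, "^3")
    }
  }
  xs <- lapply(images, function(img) {
    matrix(as.numeric(normalize_image(img)), nrow = 1)
  })
  caches <- list()
  f <- vector("list", L + 1)
  r <- conv_forward(model$layers$enc0, xs, dims0, training, slope)
  caches$enc0 <- r$cache
  f[[1]] <- r$ys
  dims <- dims0
  dims_at <- list(dims0)
  for (l in seq_len(L)) {
    r <- conv_forward(model$layers[[paste0("down", l)]], f[[l]], dims,
                      training, slope)
    caches[[paste0("down", l)]] <- r$cache
    dims <- dims %/% 2L
    dims_at[[l + 1]] <- dims
    r2 <- conv_forward(model$layers[[paste0("enc", l)]], r$ys, dims,
                       training, slope)
    caches[[paste0("enc", l)]] <- r2$cache
    f[[l + 1]] <- r2$ys
  }
  d <- f[[L + 1]]
  for (l in rev(seq_len(L) - 1)) {
    dd <- dims_at[[l + 1]]
    up <- lapply(d, upsample2, dims = dims_at[[l + 2]])
    cat_in <- mapply(function(u, s) rbind(u, s), up, f[[l + 1]],
                     SIMPLIFY = FALSE)
    r <- conv_forward(model$layers[[paste0("dec", l)]], cat_in, dd,
                      training, slope)
    caches[[paste0("dec", l)]] <- r$cache
    d <- r$ys
  }
  zs <- head_forward(model$layers$head, d)
  probs <- lapply(zs, sigmoid)
  list(probs = probs, caches = caches, dims_at = dims_at,
       head_in = d)
}

# soft-Dice loss (mean over the batch) and its gradient w.r.t. the
# probabilities
soft_dice_loss <- function(probs, masks, eps = 1) {
  B <- length(probs)
  losses <- numeric(B)
  dprobs <- vector("list", B)
  for (i in seq_len(B)) {
    p <- probs[[i]]
    t <- matrix(as.numeric(masks[[i]] != 0), nrow = 1)
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    losses[i] <- 1 - num / den
    dprobs[[i]] <- -(2 * t * den - num) / den^2 / B
  }
  list(loss = mean(losses), dprobs = dprobs)
}

unet_backward <- function(model, fwd, dprobs) {
  spec <- model$spec
  L <- spec$levels
  slope <- spec$leaky_slope
  grads <- list()
  # head: sigmoid + 1x1 conv
  dzs <- mapply(function(dp, p) dp * p * (1 - p), dprobs, fwd$probs,
                SIMPLIFY = FALSE)
  head <- model$layers$head
  grads$head <- list(
    W = Reduce(`+`, mapply(tcrossprod, dzs, fwd$head_in, SIMPLIFY = FALSE)),
    b = Reduce(`+`, lapply(dzs, rowSums))
  )
  d <- lapply(dzs, function(dz) crossprod(head$W, dz))
  dskip <- vector("list", L + 1)   # gradients flowing into f[[l]]
  for (l in seq_len(L) - 1) {
    nm <- paste0("dec", l)
    r <- conv_backward(model$layers[[nm]], fwd$caches[[nm]], d, slope)
    grads[[nm]] <- r$grads
    # split the concatenated gradient: upsampled part on top, skip below
    skip_layer <- if (l == 0) "enc0" else paste0("enc", l)
    n_up <- nrow(r$dxs[[1]]) - model$layers[[skip_layer]]$c_out
    dup <- lapply(r$dxs, function(g) g[seq_len(n_up), , drop = FALSE])
    dskip[[l + 1]] <- lapply(r$dxs, function(g) {
      g[-seq_len(n_up), , drop = FALSE]
    })
    d <- lapply(dup, downsum2, dims_big = fwd$dims_at[[l + 1]])
  }
  # bottom: d is the gradient into f[[L+1]]
  dskip[[L + 1]] <- d
  dcur <- NULL
  for (l in rev(seq_len(L))) {
    g_in <- dskip[[l + 1]]
    if (!is.null(dcur)) {
      g_in <- mapply(`+`, g_in, dcur, SIMPLIFY = FALSE)
    }
    nm <- paste0("enc", l)
    r <- conv_backward(model$layers[[nm]], fwd$caches[[nm]], g_in, slope)
    grads[[nm]] <- r$grads
    nm <- paste0("down", l)
    r <- conv_backward(model$layers[[nm]], fwd$caches[[nm]], r$dxs, slope)
    grads[[nm]] <- r$grads
    dcur <- r$dxs
  }
  g_in <- dskip[[1]]
  if (!is.null(dcur)) g_in <- mapply(`+`, g_in, dcur, SIMPLIFY = FALSE)
  r <- conv_backward(model$layers$enc0, fwd$caches$enc0, g_in, slope)
  grads$enc0 <- r$grads
  grads
}

update_running_stats <- function(model, fwd) {
  for (nm in names(fwd$caches)) {
    cache <- fwd$caches[[nm]]
    if (!is.null(cache$batch_mean)) {
      ly <- model$layers[[nm]]
      ly$rmean <- (1 - bn_momentum) * ly$rmean +
        bn_momentum * cache$batch_mean
      ly$rvar <- (1 - bn_momentum) * ly$rvar + bn_momentum * cache$batch_var
      model$layers[[nm]] <- ly
    }
  }
  model
}

adam_init <- function(model) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    st$m[[nm]] <- list(W = ly$W * 0, b = ly$b * 0,
                       gamma = ly$gamma * 0, beta = ly$beta * 0)
    st$v[[nm]] <- st$m[[nm]]
  }
  st
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    ly <- model$layers[[nm]]
    for (p in names(grads[[nm]])) {
      g <- grads[[nm]][[p]]
      state$m[[nm]][[p]] <- beta1 * state$m[[nm]][[p]] + (1 - beta1) * g
      state$v[[nm]][[p]] <- beta2 * state$v[[nm]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[p]] / corr1
      vhat <- state$v[[nm]][[p]] / corr2
      ly[[p]] <- ly[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
    model$layers[[nm]] <- ly
  }
  list(model = model, state = state)
}

#' Define a training protocol
#'
#' The resampled-round protocol: per round, `round_size` samples are drawn
#' from the corpus (seeded), split into training and model-selection
#' subsets, and optimized with Adam on a soft-Dice loss for
#' `epochs_per_round` epochs; the best-validation weights are kept and the
#' next round draws fresh samples, until `total_epochs` is reached.  The
#' reference protocol is `round_size = 500`, `split = 0.8`,
#' `epochs_per_round = 50`, `total_epochs = 2000`.
#'
#' @param round_size samples drawn per round (capped at the corpus size).
#' @param split training fraction of each round's draw, in (0, 1).
#' @param epochs_per_round,total_epochs epoch counts.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed for draws and shuffles.
#' @param val_every epochs between validation evaluations (model selection
#'   considers only evaluated epochs).
#' @param holdout_teeth tooth IDs excluded from training draws.
#' @return A `train_protocol`.
#' @export
train_protocol <- function(round_size = 500, split = 0.8,
                           epochs_per_round = 50, total_epochs = 2000,
                           lr = 1e-4, batch_size = 2, seed = 1,
                           val_every = 1, holdout_teeth = integer(0)) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  if (total_epochs < epochs_per_round) {
    stop("total_epochs must be at least epochs_per_round")
  }
  structure(list(round_size = round_size, split = split,
                 epochs_per_round = epochs_per_round,
                 total_epochs = total_epochs, lr = lr,
                 batch_size = batch_size, seed = seed,
                 val_every = as.integer(val_every),
                 holdout_teeth = as.integer(holdout_teeth)),
            class = "train_protocol")
}

corpus_samples <- function(corpus) {
  if (is.character(corpus)) {
    manifest <- utils::read.csv(file.path(corpus, "manifest.csv"),
                                stringsAsFactors = FALSE)
    manifest <- manifest[manifest$status == "ok", ]
    lapply(seq_len(nrow(manifest)), function(i) {
      smp <- read_tooth_sample(file.path(corpus, manifest$file[i]))
      smp$meta$tooth_id <- manifest$tooth_id[i]
      smp
    })
  } else {
    corpus
  }
}

#' Train a U-Net on a tooth corpus
#'
#' @param model a `unet_model` from [build_unet()].
#' @param corpus a list of `tooth_sample`s, or a dataset directory written
#'   by [generate_dataset()].
#' @param protocol a `train_protocol`.
#' @return The trained `unet_model`, with a `history` data frame (epoch,
#'   round, training loss, validation DSC) attached.
#' @export
train <- function(model, corpus, protocol = train_protocol()) {
  samples <- corpus_samples(corpus)
  if (length(protocol$holdout_teeth) > 0) {
    keep <- vapply(samples, function(s) {
      !(s$meta$tooth_id %in% protocol$holdout_teeth)
    }, TRUE)
    samples <- samples[keep]
  }
  if (length(samples) == 0) stop("training corpus is empty")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(protocol$seed))

  state <- adam_init(model)
  history <- list()
  epoch <- 0
  rounds <- ceiling(protocol$total_epochs / protocol$epochs_per_round)
  for (round in seq_len(rounds)) {
    n_draw <- min(protocol$round_size, length(samples))
    draw <- sample(length(samples), n_draw)
    n_tr <- max(1, round(protocol$split * n_draw))
    tr_idx <- draw[seq_len(n_tr)]
    va_idx <- if (n_tr < n_draw) draw[(n_tr + 1):n_draw] else tr_idx
    best_val <- -Inf
    best_layers <- model$layers
    for (e in seq_len(protocol$epochs_per_round)) {
      if (epoch >= protocol$total_epochs) break
      epoch <- epoch + 1
      order_idx <- sample(tr_idx)
      batch_losses <- c()
      for (b0 in seq(1, length(order_idx), by = protocol$batch_size)) {
        bidx <- order_idx[b0:min(b0 + protocol$batch_size - 1,
                                 length(order_idx))]
        imgs <- lapply(samples[bidx], `[[`, "image")
        msks <- lapply(samples[bidx], `[[`, "mask")
        fwd <- unet_forward(model, imgs, training = TRUE)
        loss <- soft_dice_loss(fwd$probs, msks)
        grads <- unet_backward(model, fwd, loss$dprobs)
        model <- update_running_stats(model, fwd)
        upd <- adam_step(model, grads, state, protocol$lr)
        model <- upd$model
        state <- upd$state
        batch_losses <- c(batch_losses, loss$loss)
      }
      val_dsc <- NA_real_
      if (e %% protocol$val_every == 0 ||
          e == protocol$epochs_per_round) {
        val_dsc <- mean(vapply(va_idx, function(i) {
          dice(predict_mask(model, samples[[i]]$image), samples[[i]]$mask)
        }, numeric(1)))
        if (val_dsc >= best_val) {
          best_val <- val_dsc
          best_layers <- model$layers
        }
      }
      history[[length(history) + 1]] <- data.frame(
        epoch = epoch, round = round, train_loss = mean(batch_losses),
        val_dsc = val_dsc)
    }
    model$layers <- best_layers
  }
  model$history <- do.call(rbind, history)
  model
}

#' Predict a binary tooth mask
#'
#' Runs the model in evaluation mode (batch-norm running statistics) and
#' thresholds the sigmoid output at 0.5, ties to foreground.
#'
#' @param model a `unet_model`.
#' @param image input cube matching the model's input size.
#' @return Integer 0/1 array, same shape as the input.
#' @export
predict_mask <- function(model, image) {
  fwd <- unet_forward(model, list(image), training = FALSE)
  p <- fwd$probs[[1]]
  out <- array(as.integer(p >= 0.5), dim = dim(image))
  out
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary grids; 1 when both
#' are empty.
#'
#' @param pred,truth binary arrays of identical shape (any nonzero voxel
#'   counts as foreground).
#' @return DSC in \[0, 1\].
#' @export
#' @examples
#' a <- array(0, c(4, 4, 4)); a[1:2, , ] <- 1
#' dice(a, a)  # 1
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have the same shape")
  }
  a <- pred != 0
  b <- truth != 0
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Evaluate a model on test samples
#'
#' Computes the per-sample DSC between predictions and ground-truth masks,
#' with the mean and the population standard deviation.
#'
#' @param model a `unet_model`.
#' @param samples list of `tooth_sample`s (or a dataset directory).
#' @param label grouping label recorded in the report (model/input source).
#' @return A `dice_report`: data frame of per-sample DSC with attributes
#'   `mean` and `sd`.
#' @export
evaluate <- function(model, samples, label = "virtual") {
  samples <- corpus_samples(samples)
  if (length(samples) == 0) stop("need at least one test sample")
  dsc <- vapply(samples, function(s) {
    dice(predict_mask(model, s$image), s$mask)
  }, numeric(1))
  tooth <- vapply(samples, function(s) {
    as.integer(s$meta$tooth_id %||% NA_integer_)
  }, integer(1))
  rep <- data.frame(sample = seq_along(dsc), tooth_id = tooth,
                    source = label, dsc = dsc)
  structure(rep, mean = mean(dsc),
            sd = sqrt(mean((dsc - mean(dsc))^2)),
            class = c("dice_report", "data.frame"))
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report> n = ", nrow(x), ", DSC ",
      sprintf("%.3f +/- %.3f", attr(x, "mean"), attr(x, "sd")),
      " (", x$source[1], ")\n", sep = "")
  invisible(x)
}

#' Save / load a U-Net model
#'
#' Weights go to an RDS file with a JSON spec sidecar for inspection.
#'
#' @param model a `unet_model`.
#' @param path output `.rds` path.
#' @return `path` (write) or a `unet_model` (read).
#' @export
write_unet <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(c(unclass(model$spec),
                         list(n_parameters = model$n_parameters)),
                       sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_unet
#' @export
read_unet <- function(path) readRDS(path)
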