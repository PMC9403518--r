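#' Configuration for the residual U-Net segmentation model
#'
#' Collects the architecture and training hyper-parameters. Defaults follow
#' the reference protocol: learning rate 0.001, at most 100 epochs, batch
#' size 4, early stopping after 10 epochs without validation-mIoU
#' improvement, a hold-out validation split, and a 64-channel encoder stem
#' whose four residual stages bottleneck a 256 x 256 input to 8 x 8 x 2048.
#' `base_width` and `encoder_depth` can be reduced to obtain a miniature
#' model trainable on a desktop CPU.
#'
#' @param in_layers number of input layers (1-4), matching the chosen band
#'   combination.
#' @param base_width channels after the encoder stem (default 64).
#' @param encoder_depth number of residual stages (default 4).
#' @param blocks_per_stage bottleneck residual blocks per stage (default 1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs training epoch cap (default 100).
#' @param batch_size chips per gradient step (default 4).
#' @param patience epochs without validation mIoU improvement before early
#'   stop (default 10).
#' @param val_fraction hold-out share of tiles used for validation
#'   (default 0.2).
#' @param seed integer seed controlling weight initialisation, the hold-out
#'   split and batch shuffling.
#' @param pretrained use locally supplied pretrained encoder weights. No
#'   weight file ships with the package, so this defaults to `FALSE` (random
#'   initialisation); setting it without providing weights is an error.
#' @return a `resunet_config` list.
#' @export
resunet_config <- function(in_layers, base_width = 64L, encoder_depth = 4L,
                           blocks_per_stage = 1L, learning_rate = 0.001,
                           max_epochs = 100L, batch_size = 4L, patience = 10L,
                           val_fraction = 0.2, seed = 42L,
                           pretrained = FALSE) {
  in_layers <- as.integer(in_layers)
  if (is.na(in_layers) || in_layers < 1L || in_layers > 4L)
    stop("in_layers must be an integer in 1..4")
  if (patience > max_epochs) stop("patience must not exceed max_epochs")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must lie strictly between 0 and 1")
  if (isTRUE(pretrained))
    stop("no pretrained encoder weights are bundled; supply your own ",
         "checkpoint via load_resunet() or use pretrained = FALSE")
  structure(list(
    in_layers = in_layers, base_width = as.integer(base_width),
    encoder_depth = as.integer(encoder_depth),
    blocks_per_stage = as.integer(blocks_per_stage),
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size), patience = as.integer(patience),
    val_fraction = val_fraction, seed = as.integer(seed),
    pretrained = isTRUE(pretrained)), class = "resunet_config")
}

#' Build the residual U-Net
#'
#' Encoder: a 7 x 7 stride-2 convolution followed by a 3 x 3 stride-2 max
#' pool reduces the input to a quarter of its size at `base_width` channels;
#' bottleneck residual stages (1x1 / 3x3 / 1x1 convolutions with a projected
#' shortcut, 4x channel expansion) then halve the spatial size per stage. At
#' the defaults a 256 x 256 chip bottoms out at 8 x 8 with 2048 channels.
#' Decoder: repeated 2 x 2 stride-2 transposed convolutions, concatenation
#' with the equal-size encoder feature, and a 3 x 3 convolution with batch
#' normalisation and ReLU; a final 1 x 1 convolution emits a one-channel
#' per-pixel crown score at the input resolution.
#'
#' @param config a [resunet_config()].
#' @return a `resunet` model object (graph, parameters, batch-norm state).
#' @export
build_resunet <- function(config) {
  stopifnot(inherits(config, "resunet_config"))
  set.seed(config$seed)
  w <- config$base_width
  d <- config$encoder_depth
  expansion <- 4L

  nodes <- list(); params <- list(); state <- list(); nid <- 0L
  add_node <- function(op, inputs = integer(), args = list(),
                       pnames = character(), sname = NULL) {
    inputs <- as.integer(inputs) # force before taking a node id (lazy args)
    nid <<- nid + 1L
    nodes[[nid]] <<- list(op = op, inputs = as.integer(inputs), args = args,
                          pnames = pnames, sname = sname)
    nid
  }
  add_conv <- function(name, from, kh, cin, cout, stride = 1L, pad = NULL) {
    if (is.null(pad)) pad <- (kh - 1L) %/% 2L
    params[[paste0(name, ".w")]] <<- he_init(kh, kh, cin, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    add_node("conv", from, list(stride = stride, pad = pad),
             c(w = paste0(name, ".w"), b = paste0(name, ".b")))
  }
  add_convT <- function(name, from, cin, cout) {
    params[[paste0(name, ".w")]] <<- he_init(2L, 2L, cin, cout)
    params[[paste0(name, ".b")]] <<- numeric(cout)
    add_node("convT", from, list(stride = 2L, pad = 0L),
             c(w = paste0(name, ".w"), b = paste0(name, ".b")))
  }
  add_bn <- function(name, from, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- numeric(c)
    state[[name]] <<- list(mean = numeric(c), var = rep(1, c))
    add_node("bn", from,
             pnames = c(gamma = paste0(name, ".gamma"),
                        beta = paste0(name, ".beta")),
             sname = name)
  }
  cbr <- function(name, from, kh, cin, cout, stride = 1L) {
    n1 <- add_conv(name, from, kh, cin, cout, stride)
    n2 <- add_bn(paste0(name, ".bn"), n1, cout)
    add_node("relu", n2)
  }

  inp <- add_node("input")
  # stem: 7x7 stride-2 conv (+BN/ReLU), then 3x3 stride-2 max pool
  stem <- cbr("stem", inp, 7L, config$in_layers, w, stride = 2L)
  pool <- add_node("maxpool", stem, list(k = 3L, stride = 2L, pad = 1L))

  # residual stages
  cur <- pool
  cin <- w
  stage_out <- integer(d)
  stage_ch <- integer(d)
  for (s in seq_len(d)) {
    mid <- w * 2L^(s - 1L)
    cout <- mid * expansion
    for (b in seq_len(config$blocks_per_stage)) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      nm <- sprintf("enc%d.%d", s, b)
      n1 <- cbr(paste0(nm, ".a"), cur, 1L, cin, mid, stride = stride)
      n2 <- cbr(paste0(nm, ".b"), n1, 3L, mid, mid)
      n3 <- add_conv(paste0(nm, ".c"), n2, 1L, mid, cout)
      n3 <- add_bn(paste0(nm, ".c.bn"), n3, cout)
      if (stride != 1L || cin != cout) {
        sc <- add_conv(paste0(nm, ".sc"), cur, 1L, cin, cout, stride = stride)
        sc <- add_bn(paste0(nm, ".sc.bn"), sc, cout)
      } else sc <- cur
      cur <- add_node("relu", add_node("add", c(n3, sc)))
      cin <- cout
    }
    stage_out[s] <- cur
    stage_ch[s] <- cin
  }
  bottleneck <- cur

  # decoder: up through the stages, then to half and full resolution
  for (s in rev(seq_len(d - 1L))) {
    up <- add_convT(sprintf("dec%d.up", s), cur, cin, stage_ch[s])
    cat_ <- add_node("concat", c(up, stage_out[s]))
    cur <- cbr(sprintf("dec%d.fuse", s), cat_, 3L, 2L * stage_ch[s],
               stage_ch[s])
    cin <- stage_ch[s]
  }
  up <- add_convT("decS.up", cur, cin, w)          # to H/2, meet the stem
  cat_ <- add_node("concat", c(up, stem))
  cur <- cbr("decS.fuse", cat_, 3L, 2L * w, w)
  up <- add_convT("dec0.up", cur, w, w)            # to full resolution
  cur <- cbr("dec0.fuse", up, 3L, w, w)
  out <- add_conv("head", cur, 1L, w, 1L)

  structure(list(
    nodes = nodes, params = params, state = state, config = config,
    tags = list(input = inp, post_stem = pool, bottleneck = bottleneck,
                output = out),
    downsample_factor = 4L * 2L^(d - 1L)), class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("<resunet> in_layers=%d base_width=%d depth=%d ",
                     "(%s parameters)\n"),
              x$config$in_layers, x$config$base_width,
              x$config$encoder_depth, format(np, big.mark = ",")))
  invisible(x)
}

#' Trace layer shapes through the network
#'
#' Analytic shape propagation (no weights are touched): walks the graph and
#' reports the (rows, cols, channels) each node would emit for a given input
#' size. Used to verify the architecture contract, e.g. that the default
#' model turns a 256 x 256 chip into a 64 x 64 x 64 post-stem feature and an
#' 8 x 8 x 2048 bottleneck.
#'
#' @param model a `resunet`.
#' @param input_size integer vector (rows, cols).
#' @return list with `post_stem`, `bottleneck`, `output` shape vectors and
#'   `all` (matrix of every node's shape).
#' @export
resunet_shapes <- function(model, input_size = c(256L, 256L)) {
  shp <- matrix(0L, length(model$nodes), 3L,
                dimnames = list(NULL, c("rows", "cols", "channels")))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    ins <- nd$inputs
    shp[i, ] <- switch(nd$op,
      input = c(input_size[1], input_size[2], model$config$in_layers),
      conv = {
        s <- shp[ins[1], ]
        k <- dim(model$params[[nd$pnames["w"]]])
        c((s[1] + 2L * nd$args$pad - k[1]) %/% nd$args$stride + 1L,
          (s[2] + 2L * nd$args$pad - k[2]) %/% nd$args$stride + 1L, k[4])
      },
      convT = {
        s <- shp[ins[1], ]
        k <- dim(model$params[[nd$pnames["w"]]])
        c((s[1] - 1L) * nd$args$stride + k[1] - 2L * nd$args$pad,
          (s[2] - 1L) * nd$args$stride + k[2] - 2L * nd$args$pad, k[4])
      },
      maxpool = {
        s <- shp[ins[1], ]
        c((s[1] + 2L * nd$args$pad - nd$args$k) %/% nd$args$stride + 1L,
          (s[2] + 2L * nd$args$pad - nd$args$k) %/% nd$args$stride + 1L, s[3])
      },
      concat = {
        a <- shp[ins[1], ]; b <- shp[ins[2], ]
        c(a[1], a[2], a[3] + b[3])
      },
      shp[ins[1], ]) # bn / relu / add keep shape
  }
  list(post_stem = shp[model$tags$post_stem, ],
       bottleneck = shp[model$tags$bottleneck, ],
       output = shp[model$tags$output, ],
       all = shp)
}

check_input_grid <- function(model, x) {
  d <- dim(x)
  if (d[3] != model$config$in_layers)
    stop("input has ", d[3], " layer(s) but the model expects ",
         model$config$in_layers)
  f <- model$downsample_factor
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop("input size ", d[1], " x ", d[2], " is not divisible by the ",
         "network's total downsampling factor (", f, ")")
  invisible(TRUE)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Mean intersection-over-union of two binary masks
#'
#' Average of the per-class IoU over the background (0) and crown (255)
#' classes; a class absent from both masks is skipped.
#'
#' @param pred_mask,label_mask matrices with values in \{0, 255\} (or
#'   logical).
#' @return scalar in \[0, 1\].
#' @export
miou <- function(pred_mask, label_mask) {
  if (!all(dim(pred_mask) == dim(label_mask)))
    stop("masks must share dimensions")
  p <- pred_mask != 0; l <- label_mask != 0
  ious <- c()
  for (cls in c(FALSE, TRUE)) {
    a <- p == cls; b <- l == cls
    u <- sum(a | b)
    if (u == 0) next
    ious <- c(ious, sum(a & b) / u)
  }
  mean(ious)
}

val_miou <- function(model, tiles, idx) {
  scores <- vapply(idx, function(i) {
    t <- tiles$tiles[[i]]
    fw <- nn_forward(model, t$input, train = FALSE)
    pred <- (sigmoid(fw$out[, , 1, 1]) > 0.5) * 255
    miou(pred, t$label)
  }, 1.0)
  mean(scores)
}

#' Train the segmentation model
#'
#' Splits the tiles into a training and a hold-out validation set, optimises
#' per-pixel binary cross-entropy with Adam, evaluates validation mIoU after
#' every epoch, and stops early when mIoU has not improved for
#' `config$patience` consecutive epochs. The returned model carries the
#' parameters of the best-mIoU epoch (only improving checkpoints are kept).
#'
#' @param model a `resunet` from [build_resunet()].
#' @param tiles a `crown_tileset` with binary \{0, 255\} labels.
#' @param config a [resunet_config()]; defaults to the model's own.
#' @param verbose print a line per epoch.
#' @return list with `model` (best checkpoint), `log` (data frame of epoch,
#'   loss, val_miou), `best_epoch`, and `stopped_early`.
#' @export
train_resunet <- function(model, tiles, config = model$config,
                          verbose = FALSE) {
  stopifnot(inherits(model, "resunet"), inherits(tiles, "crown_tileset"))
  n <- length(tiles$tiles)
  if (n == 0L) stop("empty tile set")
  for (t in tiles$tiles)
    if (!all(t$label %in% c(0, 255)))
      stop("labels must be binary with values in {0, 255}")
  set.seed(config$seed)
  nval <- max(1L, round(config$val_fraction * n))
  if (nval >= n) stop("too few tiles for a ", config$val_fraction,
                      " hold-out split")
  val_idx <- sort(sample.int(n, nval))
  tr_idx <- setdiff(seq_len(n), val_idx)

  states <- list(m = list(), v = list(), t = 0L)
  log <- data.frame(epoch = integer(), loss = numeric(), val_miou = numeric())
  best <- -Inf; best_epoch <- 0L
  best_params <- model$params; best_state <- model$state
  stopped_early <- FALSE

  ts <- tiles$tile_size
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      ids <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      bn <- length(ids)
      nlay <- model$config$in_layers
      xb <- array(0, c(ts, ts, nlay, bn))
      yb <- array(0, c(ts, ts, 1L, bn))
      for (k in seq_len(bn)) {
        xb[, , , k] <- tiles$tiles[[ids[k]]]$input
        yb[, , 1L, k] <- tiles$tiles[[ids[k]]]$label / 255
      }
      fw <- nn_forward(model, xb, train = TRUE)
      model <- fw$model # batch-norm running stats advanced
      z <- fw$out
      p <- sigmoid(z)
      m <- length(z)
      # binary cross-entropy with logits (numerically safe form)
      loss <- mean(pmax(z, 0) - z * yb + log1p(exp(-abs(z))))
      dlogits <- (p - yb) / m
      grads <- nn_backward(model, fw, dlogits)
      upd <- adam_step(model$params, grads, states, config$learning_rate)
      model$params <- upd$params
      states <- upd$states
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    vm <- val_miou(model, tiles, val_idx)
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / nb,
                                 val_miou = vm))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val mIoU %.4f", epoch,
                      ep_loss / nb, vm))
    if (vm > best + 1e-9) {
      best <- vm; best_epoch <- epoch
      best_params <- model$params; best_state <- model$state
    } else if (epoch - best_epoch >= config$patience) {
      stopped_early <- TRUE
      break
    }
  }
  model$params <- best_params
  model$state <- best_state
  list(model = model, log = log, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

#' Predict a binary crown mask
#'
#' Runs the model over the input grid and thresholds the per-pixel sigmoid
#' score. Rasters larger than one tile are processed in overlapping windows
#' (stride = `tile_size / 2`); window scores are averaged before
#' thresholding, which suppresses tile-seam artifacts.
#'
#' @param model a trained `resunet`.
#' @param input_grid 3-D array (rows x cols x layers), layers matching the
#'   model.
#' @param threshold score cut for the crown class (default 0.5).
#' @param tile_size processing window in pixels (default 256).
#' @return matrix of \{0, 255\} the size of the input grid.
#' @export
predict_mask <- function(model, input_grid, threshold = 0.5,
                         tile_size = 256L) {
  if (is.matrix(input_grid))
    input_grid <- array(input_grid, c(dim(input_grid), 1L))
  check_input_grid(model, input_grid)
  d <- dim(input_grid)
  if (d[1] <= tile_size && d[2] <= tile_size) {
    fw <- nn_forward(model, input_grid, train = FALSE)
    return((sigmoid(fw$out[, , 1, 1]) > threshold) * 255)
  }
  step <- tile_size %/% 2L
  starts <- function(total) {
    s <- seq(1L, max(1L, total - tile_size + 1L), by = step)
    unique(c(s, total - tile_size + 1L))
  }
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (r0 in starts(d[1])) for (c0 in starts(d[2])) {
    rows <- r0:(r0 + tile_size - 1L); cols <- c0:(c0 + tile_size - 1L)
    fw <- nn_forward(model, input_grid[rows, cols, , drop = FALSE],
                     train = FALSE)
    acc[rows, cols] <- acc[rows, cols] + sigmoid(fw$out[, , 1, 1])
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  ((acc / cnt) > threshold) * 255
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file; its configuration is also
#' written to a human-readable JSON sidecar (`<path>.json`).
#'
#' @param model a `resunet`.
#' @param path destination file.
#' @return `save_resunet` the path invisibly; `load_resunet` the model.
#' @export
save_resunet <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_resunet
#' @export
load_resunet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "resunet"))
  model
}
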