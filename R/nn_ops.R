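# Minimal computation-graph engine for the segmentation network.
# Tensors are numeric arrays [H, W, C, N] (column-major, batch last).
# A model holds an ordered node list (the graph is built in topological
# order), a central parameter store, and mutable batch-norm running stats.

as_tensor4 <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# ---- per-op forward/backward ------------------------------------------------

nn_forward <- function(model, x, train = FALSE) {
  x <- as_tensor4(x)
  nodes <- model$nodes
  outs <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    ins <- lapply(nd$inputs, function(j) outs[[j]])
    res <- switch(nd$op,
      input = list(y = x),
      conv = {
        w <- model$params[[nd$pnames["w"]]]
        b <- model$params[[nd$pnames["b"]]]
        list(y = cpp_conv2d_forward(ins[[1]], w, b, nd$args$stride, nd$args$pad),
             cache = ins[[1]])
      },
      convT = {
        w <- model$params[[nd$pnames["w"]]]
        b <- model$params[[nd$pnames["b"]]]
        list(y = cpp_convT2d_forward(ins[[1]], w, b, nd$args$stride, nd$args$pad),
             cache = ins[[1]])
      },
      bn = {
        r <- bn_forward(ins[[1]],
                        model$params[[nd$pnames["gamma"]]],
                        model$params[[nd$pnames["beta"]]],
                        model$state[[nd$sname]], train)
        if (train) model$state[[nd$sname]] <- r$state
        r
      },
      relu = list(y = pmax(ins[[1]], 0), cache = ins[[1]] > 0),
      maxpool = {
        r <- cpp_maxpool_forward(ins[[1]], nd$args$k, nd$args$stride, nd$args$pad)
        list(y = r$y, cache = list(idx = r$idx, in_dim = dim(ins[[1]])))
      },
      add = list(y = ins[[1]] + ins[[2]]),
      concat = {
        d1 <- dim(ins[[1]]); d2 <- dim(ins[[2]])
        y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        y[, , seq_len(d1[3]), ] <- ins[[1]]
        y[, , d1[3] + seq_len(d2[3]), ] <- ins[[2]]
        list(y = y, cache = c(d1[3], d2[3]))
      },
      stop("unknown op ", nd$op))
    outs[[i]] <- res$y
    caches[[i]] <- res$cache
  }
  list(out = outs[[length(outs)]], outs = outs, caches = caches, model = model)
}

bn_forward <- function(x, gamma, beta, state, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[3]
  y <- x
  if (train) {
    mu <- numeric(C); va <- numeric(C); xhat <- x
    for (c in seq_len(C)) {
      xs <- x[, , c, , drop = FALSE]
      mu[c] <- mean(xs)
      va[c] <- mean((xs - mu[c])^2)
      xh <- (xs - mu[c]) / sqrt(va[c] + eps)
      xhat[, , c, ] <- xh
      y[, , c, ] <- gamma[c] * xh + beta[c]
    }
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
    list(y = y, cache = list(xhat = xhat, std = sqrt(va + eps)), state = state)
  } else {
    for (c in seq_len(C)) {
      y[, , c, ] <- gamma[c] * (x[, , c, , drop = FALSE] - state$mean[c]) /
        sqrt(state$var[c] + eps) + beta[c]
    }
    list(y = y, cache = NULL, state = state)
  }
}

nn_backward <- function(model, fw, dout) {
  nodes <- model$nodes
  n <- length(nodes)
  douts <- vector("list", n)
  douts[[n]] <- dout
  grads <- list()
  addg <- function(grads, name, g) {
    if (is.null(grads[[name]])) grads[[name]] <- g
    else grads[[name]] <- grads[[name]] + g
    grads
  }
  for (i in rev(seq_len(n))) {
    dy <- douts[[i]]
    if (is.null(dy)) next
    nd <- nodes[[i]]
    if (nd$op == "input") next
    cache <- fw$caches[[i]]
    din <- switch(nd$op,
      conv = {
        w <- model$params[[nd$pnames["w"]]]
        r <- cpp_conv2d_backward(cache, w, dy, nd$args$stride, nd$args$pad)
        grads <- addg(grads, nd$pnames["w"], r$dw)
        grads <- addg(grads, nd$pnames["b"], r$db)
        list(r$dx)
      },
      convT = {
        w <- model$params[[nd$pnames["w"]]]
        r <- cpp_convT2d_backward(cache, w, dy, nd$args$stride, nd$args$pad)
        grads <- addg(grads, nd$pnames["w"], r$dw)
        grads <- addg(grads, nd$pnames["b"], r$db)
        list(r$dx)
      },
      bn = {
        gamma <- model$params[[nd$pnames["gamma"]]]
        xhat <- cache$xhat; std <- cache$std
        d <- dim(dy); C <- d[3]
        dx <- dy; dgamma <- numeric(C); dbeta <- numeric(C)
        for (c in seq_len(C)) {
          dyc <- dy[, , c, , drop = FALSE]
          xhc <- xhat[, , c, , drop = FALSE]
          dgamma[c] <- sum(dyc * xhc)
          dbeta[c] <- sum(dyc)
          dxh <- dyc * gamma[c]
          m <- length(dyc)
          dx[, , c, ] <- (dxh - mean(dxh) - xhc * mean(dxh * xhc)) / std[c]
        }
        grads <- addg(grads, nd$pnames["gamma"], dgamma)
        grads <- addg(grads, nd$pnames["beta"], dbeta)
        list(dx)
      },
      relu = list(dy * cache),
      maxpool = list(cpp_maxpool_backward(dy, cache$idx, cache$in_dim)),
      add = list(dy, dy),
      concat = {
        c1 <- cache[1]; c2 <- cache[2]
        list(dy[, , seq_len(c1), , drop = FALSE],
             dy[, , c1 + seq_len(c2), , drop = FALSE])
      })
    for (k in seq_along(nd$inputs)) {
      j <- nd$inputs[k]
      if (is.null(douts[[j]])) douts[[j]] <- din[[k]]
      else douts[[j]] <- douts[[j]] + din[[k]]
    }
    douts[[i]] <- NULL # free memory as we go
    fw$caches[[i]] <- NULL
  }
  grads
}

# Adam update; states is a list of m/v per param, t the step count
adam_step <- function(params, grads, states, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  states$t <- states$t + 1L
  t <- states$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(states$m[[nm]])) {
      states$m[[nm]] <- g * 0
      states$v[[nm]] <- g * 0
    }
    states$m[[nm]] <- beta1 * states$m[[nm]] + (1 - beta1) * g
    states$v[[nm]] <- beta2 * states$v[[nm]] + (1 - beta2) * g^2
    mhat <- states$m[[nm]] / (1 - beta1^t)
    vhat <- states$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, states = states)
}
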