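# Minimal neural-network engine used by the ANN and CNN families.
#
# Design: a network is a list of layer descriptors. Feature maps travel
# through the convolutional stages as ONE stacked matrix of
# (batch * positions) x channels, each example occupying a contiguous
# block of rows (2D maps are stored column-major over (h, w)); the
# flatten layer turns the stack into an (examples x features) matrix for
# the dense head. Convolutions are batched gathers plus a single BLAS
# matmul per layer; training is Adam on softmax cross-entropy. All
# randomness is seeded, so runs are reproducible.

glorot_uniform <- function(n_in, n_out, dim_out = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(prod(dim_out), -lim, lim), dim_out[1L], dim_out[2L])
}

nn_layer <- function(type, ...) {
  l <- list(type = type, ...)
  class(l) <- "nn_layer"
  l
}

# ---- layer constructors (parameters initialized at build time) --------

nn_conv1d <- function(c_in, c_out, k = 9L) {
  nn_layer("conv1d", k = as.integer(k), c_in = c_in, c_out = c_out,
           W = glorot_uniform(k * c_in, c_out, c(k * c_in, c_out)),
           b = numeric(c_out))
}

nn_conv2d <- function(c_in, c_out, k = 3L) {
  nn_layer("conv2d", k = as.integer(k), c_in = c_in, c_out = c_out,
           W = glorot_uniform(k * k * c_in, c_out, c(k * k * c_in, c_out)),
           b = numeric(c_out))
}

nn_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  nn_layer("bn", channels = channels, momentum = momentum, eps = eps,
           gamma = rep(1, channels), beta = numeric(channels),
           run_mean = numeric(channels), run_var = rep(1, channels))
}

nn_relu <- function() nn_layer("relu")

nn_pool1d <- function(size) nn_layer("pool1d", size = as.integer(size))

nn_pool2d <- function(size = 2L) nn_layer("pool2d", size = as.integer(size))

nn_flatten <- function() nn_layer("flatten")

nn_dense <- function(n_in, n_out) {
  nn_layer("dense", n_in = n_in, n_out = n_out,
           W = glorot_uniform(n_in, n_out), b = numeric(n_out))
}

nn_dropout <- function(p) nn_layer("dropout", p = p)

# ---- stacked-batch helpers -------------------------------------------
# A map batch is list(x = (B*P) x C matrix, n = B, p = P).

stack_maps <- function(mats) {
  list(x = do.call(rbind, mats), n = length(mats), p = nrow(mats[[1L]]))
}

add_bias_cols <- function(x, b) {
  if (all(b == 0)) return(x)
  x + rep(b, each = nrow(x))
}

# per-offset gather indices for a batched 'same' 1D convolution: result
# is a list of k index vectors of length B*P; index 0 marks the zero pad
conv1d_gather_idx <- function(n, p, k) {
  half <- (k - 1L) %/% 2L
  pos <- rep(seq_len(p), n)
  base <- rep((seq_len(n) - 1L) * p, each = p)
  lapply(0:(k - 1L), function(o) {
    src <- pos + o - half
    ok <- src >= 1L & src <= p
    idx <- src + base
    idx[!ok] <- 0L
    idx
  })
}

# gather with a zero sentinel: rows where idx == 0 become zeros
gather_rows <- function(x, idx) {
  out <- x[pmax(idx, 1L), , drop = FALSE]
  z <- idx == 0L
  if (any(z)) out[z, ] <- 0
  out
}

im2col_batch <- function(x, idx_list, c_in) {
  k <- length(idx_list)
  out <- matrix(0, nrow(x), k * c_in)
  for (o in seq_len(k)) {
    out[, ((o - 1L) * c_in + 1L):(o * c_in)] <- gather_rows(x, idx_list[[o]])
  }
  out
}

col2im_batch <- function(dcol, idx_list, c_in, n_rows) {
  dx <- matrix(0, n_rows, c_in)
  for (o in seq_along(idx_list)) {
    idx <- idx_list[[o]]
    ok <- idx != 0L
    # within one offset the target rows are distinct, so += is exact
    dx[idx[ok], ] <- dx[idx[ok], , drop = FALSE] +
      dcol[ok, ((o - 1L) * c_in + 1L):(o * c_in), drop = FALSE]
  }
  dx
}

# per-offset gather indices for a batched 'same' 3x3 (k x k) 2D conv on
# column-major (h, w) maps
conv2d_gather_idx <- function(n, h, w, k) {
  half <- (k - 1L) %/% 2L
  p <- h * w
  i <- rep(rep(seq_len(h), w), n)
  j <- rep(rep(seq_len(w), each = h), n)
  base <- rep((seq_len(n) - 1L) * p, each = p)
  out <- vector("list", k * k)
  o <- 0L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      o <- o + 1L
      si <- i + di - half
      sj <- j + dj - half
      ok <- si >= 1L & si <= h & sj >= 1L & sj <= w
      idx <- si + (sj - 1L) * h + base
      idx[!ok] <- 0L
      out[[o]] <- idx
    }
  }
  out
}

# block-regroup row order for 2x2 (s x s) pooling of one column-major
# (h, w) map: cells within a block first, blocks ordered column-major
pool2d_ord <- function(h, w, s) {
  ho <- h %/% s; wo <- w %/% s
  gi <- array(seq_len(h * w), c(h, w))
  ord <- integer(s * s * ho * wo)
  p <- 0L
  for (bj in seq_len(wo)) {
    for (bi in seq_len(ho)) {
      cells <- as.vector(gi[((bi - 1L) * s + 1L):(bi * s),
                            ((bj - 1L) * s + 1L):(bj * s)])
      ord[(p + 1L):(p + s * s)] <- cells
      p <- p + s * s
    }
  }
  ord
}

# columnwise block max over an (s x M) regrouped matrix
block_max <- function(g) {
  s <- nrow(g)
  y <- g[1L, ]
  wmax <- rep(1L, ncol(g))
  if (s > 1L) {
    for (k in 2:s) {
      gk <- g[k, ]
      upd <- gk > y
      y[upd] <- gk[upd]
      wmax[upd] <- k
    }
  }
  list(y = y, wmax = wmax)
}

# ---- forward / backward ----------------------------------------------

# batch: either list(x, n, p [, nothing else]) for map stages or a plain
# (examples x features) matrix for dense stages.
nn_forward <- function(net, batch, training = FALSE) {
  layers <- net$layers
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv1d") {
      l$cache <- list(x = batch$x, n = batch$n, p = batch$p)
      batch$x <- cpp_conv1d_fwd(batch$x, batch$n, batch$p, l$W, l$b, l$k)
    } else if (l$type == "conv2d") {
      idx <- conv2d_gather_idx(batch$n, l$h, l$w, l$k)
      xc <- im2col_batch(batch$x, idx, l$c_in)
      l$cache <- list(xc = xc, idx = idx, n_rows = nrow(batch$x))
      batch$x <- add_bias_cols(xc %*% l$W, l$b)
    } else if (l$type == "bn") {
      x <- batch$x
      n_tot <- nrow(x)
      if (training) {
        st <- cpp_col_stats(x)
        mu <- as.vector(st$mean)
        v <- as.vector(st$var)
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
        l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
      } else {
        mu <- l$run_mean
        v <- l$run_var
      }
      inv_sd <- 1 / sqrt(v + l$eps)
      xhat <- cpp_affine_cols(x, inv_sd, -mu * inv_sd)
      batch$x <- cpp_affine_cols(xhat, l$gamma, l$beta)
      l$cache <- list(xhat = xhat, inv_sd = inv_sd, n_tot = n_tot)
    } else if (l$type == "relu") {
      if (is.list(batch)) {
        batch$x <- cpp_relu(batch$x)
        l$cache <- batch$x
      } else {
        batch <- cpp_relu(batch)
        l$cache <- batch
      }
    } else if (l$type == "pool1d") {
      s <- l$size
      x <- batch$x
      pf <- cpp_pool1d_fwd(x, s)
      l$cache <- list(sel = pf$sel, l_in = nrow(x))
      batch$x <- pf$y
      batch$p <- batch$p %/% s
    } else if (l$type == "pool2d") {
      s <- l$size
      x <- batch$x
      ord1 <- pool2d_ord(l$h, l$w, s)
      gord <- rep(ord1, batch$n) +
        rep((seq_len(batch$n) - 1L) * l$h * l$w, each = length(ord1))
      xg <- x[gord, , drop = FALSE]
      dim(xg) <- c(s * s, length(gord) %/% (s * s) * ncol(x))
      bm <- block_max(xg)
      l$cache <- list(gord = gord, wmax = bm$wmax, l_in = nrow(x),
                      c = ncol(x))
      batch$x <- matrix(bm$y, length(gord) %/% (s * s), ncol(x))
      batch$p <- batch$p %/% (s * s)
    } else if (l$type == "flatten") {
      x <- batch$x
      a <- array(x, c(batch$p, batch$n, ncol(x)))
      a <- aperm(a, c(2L, 1L, 3L))
      dim(a) <- c(batch$n, batch$p * ncol(x))
      l$cache <- list(n = batch$n, p = batch$p, c = ncol(x))
      batch <- a
    } else if (l$type == "dense") {
      l$cache <- batch
      batch <- add_bias_cols(batch %*% l$W, l$b)
    } else if (l$type == "dropout") {
      if (training && l$p > 0) {
        mask <- matrix(stats::runif(length(batch)) >= l$p,
                       nrow(batch), ncol(batch)) / (1 - l$p)
        batch <- batch * mask
        l$cache <- mask
      } else {
        l$cache <- NULL
      }
    } else {
      stop("unknown layer type: ", l$type)
    }
    layers[[li]] <- l
  }
  net$layers <- layers
  list(net = net, out = batch)
}

nn_backward <- function(net, grad_out) {
  layers <- net$layers
  grads <- vector("list", length(layers))
  g <- grad_out                       # matrix in dense stages, then map
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    if (l$type == "conv1d") {
      ch <- l$cache
      r <- cpp_conv1d_bwd(ch$x, g, l$W, ch$n, ch$p, l$k)
      grads[[li]] <- list(W = r$W, b = as.vector(r$b))
      g <- r$dx
    } else if (l$type == "conv2d") {
      ch <- l$cache
      grads[[li]] <- list(W = crossprod(ch$xc, g), b = colSums(g))
      g <- col2im_batch(tcrossprod(g, l$W), ch$idx, l$c_in, ch$n_rows)
    } else if (l$type == "bn") {
      ch <- l$cache
      n_tot <- ch$n_tot
      dgamma <- colSums(g * ch$xhat)
      dbeta <- colSums(g)
      a <- l$gamma * ch$inv_sd
      g <- cpp_bn_bwd(g, ch$xhat, a, a * dgamma / n_tot, a * dbeta / n_tot)
      grads[[li]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$type == "relu") {
      g <- cpp_relu_bwd(g, l$cache)
    } else if (l$type == "pool1d") {
      ch <- l$cache
      g <- cpp_pool1d_bwd(g, ch$sel, ch$l_in)
    } else if (l$type == "pool2d") {
      ch <- l$cache
      s <- l$size
      dxg <- matrix(0, s * s, length(ch$wmax))
      dxg[cbind(ch$wmax, seq_along(ch$wmax))] <- as.vector(g)
      dx <- matrix(0, ch$l_in, ch$c)
      dx[ch$gord, ] <- matrix(as.vector(dxg), length(ch$gord), ch$c)
      g <- dx
    } else if (l$type == "flatten") {
      ch <- l$cache
      a <- g
      dim(a) <- c(ch$n, ch$p, ch$c)
      a <- aperm(a, c(2L, 1L, 3L))
      dim(a) <- c(ch$p * ch$n, ch$c)
      g <- a
    } else if (l$type == "dense") {
      grads[[li]] <- list(W = crossprod(l$cache, g), b = colSums(g))
      g <- tcrossprod(g, l$W)
    } else if (l$type == "dropout") {
      if (!is.null(l$cache)) g <- g * l$cache
    }
  }
  grads
}

# ---- training ---------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class labels 1..K; returns list(loss, dlogits)
ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    ps <- intersect(c("W", "b", "gamma", "beta"), names(l))
    if (length(ps) == 0L) return(NULL)
    stats::setNames(lapply(ps, function(p) {
      list(m = l[[p]] * 0, v = l[[p]] * 0)
    }), ps)
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (li in seq_along(net$layers)) {
    gl <- grads[[li]]
    if (is.null(gl)) next
    for (p in names(gl)) {
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gl[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * gl[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[li]][[p]] <- net$layers[[li]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# inputs: list of per-example (positions x channels) maps, or a plain
# (examples x features) matrix for dense-only nets; y: integer labels.
nn_train <- function(net, inputs, y, epochs = 30L, batch_size = 8L,
                     lr = 1e-3, seed = 1L, verbose = FALSE) {
  is_map <- is.list(inputs) && !is.data.frame(inputs)
  n <- if (is_map) length(inputs) else nrow(inputs)
  stopifnot(length(y) == n)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  state <- adam_init(net)
  t <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_b <- 0L
    for (b0 in seq(1L, n, by = batch_size)) {
      sel <- ord[b0:min(n, b0 + batch_size - 1L)]
      xb <- if (is_map) stack_maps(inputs[sel]) else inputs[sel, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      ls <- ce_loss(fw$out, y[sel])
      grads <- nn_backward(fw$net, ls$dlogits)
      t <- t + 1L
      upd <- adam_step(fw$net, grads, state, lr, t)
      # carry updated parameters and running stats, drop caches
      for (li in seq_along(net$layers)) {
        for (p in intersect(c("W", "b", "gamma", "beta", "run_mean", "run_var"),
                            names(upd$net$layers[[li]]))) {
          net$layers[[li]][[p]] <- upd$net$layers[[li]][[p]]
        }
      }
      state <- upd$state
      ep_loss <- ep_loss + ls$loss
      n_b <- n_b + 1L
    }
    history[ep] <- ep_loss / n_b
    if (!is.finite(history[ep])) {
      stop("nn_train: NaN loss at epoch ", ep)
    }
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, history[ep]))
  }
  net$history <- history
  net
}

nn_predict_proba <- function(net, inputs) {
  is_map <- is.list(inputs) && !is.data.frame(inputs)
  n <- if (is_map) length(inputs) else nrow(inputs)
  bs <- 8L                             # bounded memory for long 1D maps
  out <- NULL
  for (b0 in seq(1L, n, by = bs)) {
    sel <- b0:min(n, b0 + bs - 1L)
    xb <- if (is_map) stack_maps(inputs[sel]) else inputs[sel, , drop = FALSE]
    fw <- nn_forward(net, xb, training = FALSE)
    out <- rbind(out, softmax_rows(fw$out))
  }
  out
}
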