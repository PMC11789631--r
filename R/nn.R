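# Minimal seeded feed-forward network engine used by the autoencoder, the
# variational autoencoder and the progression classifier.  Dense layers only;
# samples are rows.  Everything is deterministic given the seed argument of
# the calling function: weight init, minibatch shuffling, dropout masks and
# (for the VAE) reparameterization noise all consume R's RNG stream.

# activation forward: z -> a
.act_forward <- function(z, act) {
  switch(act,
    linear  = z,
    tanh    = tanh(z),
    relu    = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      e <- exp(z - apply(z, 1L, max))
      e / rowSums(e)
    },
    stop("unknown activation: ", act)
  )
}

# activation backward: gradient w.r.t. pre-activation z, from gradient w.r.t.
# activation output a.  Uses a (not z) so caches stay small.
.act_backward <- function(da, a, act) {
  switch(act,
    linear  = da,
    tanh    = da * (1 - a^2),
    relu    = da * (a > 0),
    sigmoid = da * a * (1 - a),
    softmax = a * (da - rowSums(da * a)),
    stop("unknown activation: ", act)
  )
}

#' @noRd
nn_new <- function(sizes, activations) {
  stopifnot(length(sizes) >= 2L, length(activations) == length(sizes) - 1L)
  layers <- vector("list", length(activations))
  for (l in seq_along(layers)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    # Glorot uniform
    lim <- sqrt(6 / (n_in + n_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
      b = rep(0, n_out),
      act = activations[l]
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "scp_nn")
}

# Forward pass.  dropout: numeric vector, one rate per layer, applied to that
# layer's OUTPUT activation (inverted dropout).  masks are drawn here when
# training = TRUE.  Returns list(out, cache) where cache holds activations
# (post-dropout, as fed to the next layer) and the masks.
#' @noRd
nn_forward <- function(net, x, dropout = NULL, training = FALSE) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)  # post-dropout (what the next layer sees)
  raw <- vector("list", L)        # pre-dropout activation, for derivatives
  masks <- vector("list", L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    z <- acts[[l]] %*% ly$W
    z <- sweep(z, 2L, ly$b, "+")
    a <- .act_forward(z, ly$act)
    raw[[l]] <- a
    if (training && !is.null(dropout) && dropout[l] > 0) {
      keep <- 1 - dropout[l]
      m <- matrix(stats::runif(length(a)) < keep, nrow(a), ncol(a)) / keep
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1L]] <- a
  }
  list(out = acts[[L + 1L]], acts = acts, raw = raw, masks = masks)
}

# Backward pass from gradient w.r.t. the network output activation.
# Returns parameter gradients and the gradient w.r.t. the input.
#' @noRd
nn_backward <- function(net, cache, d_out) {
  L <- length(net$layers)
  grads <- vector("list", L)
  da <- d_out
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    if (!is.null(cache$masks[[l]])) da <- da * cache$masks[[l]]
    dz <- .act_backward(da, cache$raw[[l]], ly$act)
    grads[[l]] <- list(
      dW = crossprod(cache$acts[[l]], dz),
      db = colSums(dz)
    )
    da <- tcrossprod(dz, ly$W)
  }
  list(grads = grads, d_in = da)
}

# Loss value and gradient w.r.t. the output activation.  Mean over all
# entries (mse, bce) or over samples (cce).
#' @noRd
nn_loss <- function(a, y, loss) {
  n <- nrow(a); k <- ncol(a)
  eps <- 1e-12
  switch(loss,
    mse = list(
      value = mean((a - y)^2),
      grad  = 2 * (a - y) / (n * k)
    ),
    bce = {
      ac <- pmin(pmax(a, eps), 1 - eps)
      list(
        value = -mean(y * log(ac) + (1 - y) * log(1 - ac)),
        grad  = (ac - y) / (ac * (1 - ac) * n * k)
      )
    },
    cce = {
      ac <- pmax(a, eps)
      list(
        value = -sum(y * log(ac)) / n,
        grad  = -(y / ac) / n
      )
    },
    stop("unknown loss: ", loss)
  )
}

#' @noRd
opt_init <- function(net, optimizer = c("adam", "sgd"), lr = 1e-3) {
  optimizer <- match.arg(optimizer)
  st <- list(optimizer = optimizer, lr = lr, t = 0L)
  if (optimizer == "adam") {
    st$beta1 <- 0.9; st$beta2 <- 0.999; st$eps <- 1e-8
    st$m <- lapply(net$layers, function(ly)
      list(W = ly$W * 0, b = ly$b * 0))
    st$v <- st$m
  }
  st
}

#' @noRd
opt_step <- function(net, grads, st) {
  if (st$optimizer == "sgd") {
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$W <- net$layers[[l]]$W - st$lr * grads[[l]]$dW
      net$layers[[l]]$b <- net$layers[[l]]$b - st$lr * grads[[l]]$db
    }
    return(list(net = net, state = st))
  }
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[paste0("d", p)]]
      st$m[[l]][[p]] <- st$beta1 * st$m[[l]][[p]] + (1 - st$beta1) * g
      st$v[[l]][[p]] <- st$beta2 * st$v[[l]][[p]] + (1 - st$beta2) * g^2
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] -
        st$lr * (st$m[[l]][[p]] / bc1) / (sqrt(st$v[[l]][[p]] / bc2) + st$eps)
    }
  }
  list(net = net, state = st)
}

# Minibatch training driver.  x, y: samples in rows.  Returns the trained net
# and the per-epoch mean training loss.  Consumes the current RNG stream;
# callers set the seed.
#' @noRd
nn_fit <- function(net, x, y, epochs = 10L, batch_size = 128L,
                   optimizer = "adam", lr = 1e-3, loss = "mse",
                   dropout = NULL) {
  n <- nrow(x)
  st <- opt_init(net, optimizer, lr)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      fw <- nn_forward(net, xb, dropout = dropout, training = TRUE)
      ls <- nn_loss(fw$out, yb, loss)
      if (!is.finite(ls$value))
        stop("non-finite training loss at epoch ", ep,
             "; lower the learning rate or inspect the input for NaN")
      bw <- nn_backward(net, fw, ls$grad)
      up <- opt_step(net, bw$grads, st)
      net <- up$net; st <- up$state
      ep_loss <- ep_loss + ls$value * length(idx)
      ep_n <- ep_n + length(idx)
    }
    history[ep] <- ep_loss / ep_n
  }
  list(net = net, history = history)
}

#' @noRd
nn_predict <- function(net, x) nn_forward(net, x, training = FALSE)$out
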