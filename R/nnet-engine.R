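# Internal fully-connected network engine: ReLU hidden layers with inverted
# dropout, softmax + cross-entropy output, mini-batch Adam, optional early
# stopping on validation accuracy. Written in plain matrix algebra; weights
# are stored input x output so a batch forward pass is X %*% W + b.

mlp_init <- function(dims) {
  # He initialization for the ReLU layers
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     nrow = dims[l], ncol = dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = NULL, keep = FALSE) {
  L <- length(par$W)
  A <- X
  Z <- vector("list", L)
  As <- vector("list", L + 1L)
  As[[1]] <- A
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      A <- pmax(Z[[l]], 0)
      if (!is.null(dropout) && dropout[l] > 0) {
        mask <- matrix(rbinom(length(A), 1L, 1 - dropout[l]), nrow = nrow(A)) /
          (1 - dropout[l])
        A <- A * mask
      }
    } else {
      A <- Z[[l]]
    }
    As[[l + 1L]] <- A
  }
  logits <- A
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  if (keep) list(Z = Z, A = As, logits = logits, prob = prob) else prob
}

# One forward/backward pass on a batch; returns gradients and mean loss.
mlp_backward <- function(par, X, y_onehot, dropout, l2 = 0) {
  L <- length(par$W)
  nb <- nrow(X)
  A <- X
  Zs <- vector("list", L)
  As <- vector("list", L)     # layer inputs
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    As[[l]] <- A
    Zs[[l]] <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      A <- pmax(Zs[[l]], 0)
      if (!is.null(dropout) && dropout[l] > 0) {
        mask <- matrix(rbinom(length(A), 1L, 1 - dropout[l]), nrow = nb) /
          (1 - dropout[l])
        A <- A * mask
        masks[[l]] <- mask
      }
    }
  }
  logits <- Zs[[L]]
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  loss <- -mean(log(pmax(prob[y_onehot > 0], 1e-12)))

  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (prob - y_onehot) / nb
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(As[[l]], delta) + l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
      delta <- delta * (Zs[[l - 1L]] > 0)
    }
  }
  list(gW = gW, gb = gb, loss = loss)
}

adam_state <- function(par) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(mW = lapply(par$W, zero_like), vW = lapply(par$W, zero_like),
       mb = lapply(par$b, zero_like), vb = lapply(par$b, zero_like), t = 0)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (l in seq_along(par$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grad$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grad$gW[[l]]^2
    par$W[[l]] <- par$W[[l]] - lr * (st$mW[[l]] / bc1) / (sqrt(st$vW[[l]] / bc2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grad$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grad$gb[[l]]^2
    par$b[[l]] <- par$b[[l]] - lr * (st$mb[[l]] / bc1) / (sqrt(st$vb[[l]] / bc2) + eps)
  }
  list(par = par, st = st)
}

# Core trainer. X: n x p matrix; y: integer classes 1..C. val_idx rows of X
# are held out for early stopping; patience = Inf disables early stopping.
mlp_train <- function(X, y, n_classes, hidden, dropout, lr = 1e-3,
                      batch_size = 32, max_epochs = 500, patience = 30,
                      val_idx = NULL, l2 = 0, seed = 1L) {
  dims <- c(ncol(X), hidden, n_classes)
  onehot <- diag(n_classes)[y, , drop = FALSE]
  train_rows <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[train_rows, , drop = FALSE]
  Ytr <- onehot[train_rows, , drop = FALSE]
  history <- tibble(epoch = integer(0), train_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(par = NULL, val_acc = -Inf, epoch = 0L)

  withr::with_seed(seed, {
    par <- mlp_init(dims)
    st <- adam_state(par)
    since_improve <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      losses <- numeric(0)
      for (start in seq(1L, nrow(Xtr), by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, nrow(Xtr))]
        g <- mlp_backward(par, Xtr[rows, , drop = FALSE], Ytr[rows, , drop = FALSE],
                          dropout, l2 = l2)
        if (!is.finite(g$loss)) abort("Non-finite training loss; aborting.")
        upd <- adam_step(par, g, st, lr)
        par <- upd$par; st <- upd$st
        losses <- c(losses, g$loss)
      }
      val_acc <- NA_real_
      if (length(val_idx)) {
        pv <- mlp_forward(par, X[val_idx, , drop = FALSE])
        val_acc <- mean(max.col(pv, ties.method = "first") == y[val_idx])
        if (val_acc > best$val_acc) {
          best <- list(par = par, val_acc = val_acc, epoch = epoch)
          since_improve <- 0L
        } else {
          since_improve <- since_improve + 1L
        }
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = epoch, train_loss = mean(losses), val_accuracy = val_acc))
      if (length(val_idx) && is.finite(patience) && since_improve >= patience) break
    }
    if (is.null(best$par)) best <- list(par = par, val_acc = NA_real_, epoch = epoch)
  })

  list(par = best$par, best_epoch = best$epoch, val_accuracy = best$val_acc,
       history = history, dims = dims, dropout = dropout)
}
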