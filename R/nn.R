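# Internal neural-network primitives: parameter initialization, sigmoid /
# binary-cross-entropy head, Adam, and per-architecture forward/backward
# passes. Everything is plain matrix algebra over batches; all randomness
# (init, shuffling, dropout) goes through R's RNG so seeded training is
# reproducible. Gradients are verified against finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out, n = fan_in * fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n, -limit, limit), fan_in, fan_out)
}

# mean over samples of the summed per-class binary cross-entropy
bce_loss <- function(probs, y, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(rowSums(y * log(p) + (1 - y) * log(1 - p)))
}

dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(n * m) >= rate) / (1 - rate), n, m)
}

apply_dropout <- function(h, mask) if (is.null(mask)) h else h * mask

# embedding lookup with pad id 0 -> zero vector; returns n x dim for one
# position column
embed_col <- function(E_aug, ids_col) E_aug[ids_col + 1L, , drop = FALSE]

augment_embedding <- function(E) rbind(0, unclass(E))  # row 1 = pad

## ---- FFNN -----------------------------------------------------------------

ffnn_init <- function(dim, hidden, K) {
  sizes <- c(dim, hidden)
  params <- list()
  for (l in seq_along(hidden)) {
    params[[paste0("W", l)]] <- glorot(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  params$W_out <- glorot(sizes[length(sizes)], K)
  params$b_out <- rep(0, K)
  params
}

# mask-aware mean pooling over token embeddings
ffnn_pool <- function(E_aug, batch) {
  n <- nrow(batch$ids)
  dim <- ncol(E_aug)
  lens <- rowSums(batch$mask)
  pooled <- matrix(0, n, dim)
  for (t in seq_len(ncol(batch$ids))) {
    pooled <- pooled + embed_col(E_aug, batch$ids[, t])
  }
  pooled / pmax(lens, 1)
}

ffnn_forward <- function(params, E_aug, batch, dropout = 0, training = FALSE) {
  X <- ffnn_pool(E_aug, batch)
  n_hidden <- (length(params) - 2) / 2
  h <- X
  acts <- list()
  masks <- list()
  for (l in seq_len(n_hidden)) {
    z <- sweep(h %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]], "+")
    a <- pmax(z, 0)
    mask <- if (training) dropout_mask(nrow(a), ncol(a), dropout) else NULL
    a_drop <- apply_dropout(a, mask)
    acts[[l]] <- list(input = h, relu = a, dropped = a_drop)
    masks[l] <- list(mask)   # keep NULL placeholders (no dropout)
    h <- a_drop
  }
  logits <- sweep(h %*% params$W_out, 2, params$b_out, "+")
  probs <- sigmoid(logits)
  list(probs = probs,
       cache = list(X = X, acts = acts, masks = masks, head_in = h))
}

ffnn_backward <- function(params, cache, dprobs_logits) {
  grads <- list()
  grads$W_out <- t(cache$head_in) %*% dprobs_logits
  grads$b_out <- colSums(dprobs_logits)
  dh <- dprobs_logits %*% t(params$W_out)
  n_hidden <- length(cache$acts)
  for (l in rev(seq_len(n_hidden))) {
    a <- cache$acts[[l]]
    dh <- apply_dropout(dh, cache$masks[[l]])
    dh <- dh * (a$relu > 0)
    grads[[paste0("W", l)]] <- t(a$input) %*% dh
    grads[[paste0("b", l)]] <- colSums(dh)
    dh <- dh %*% t(params[[paste0("W", l)]])
  }
  grads
}

## ---- CNN ------------------------------------------------------------------

cnn_init <- function(dim, kernel_size, filter_count, dense_units, K) {
  list(W_conv = glorot(kernel_size * dim, filter_count),
       b_conv = rep(0, filter_count),
       W_dense = glorot(filter_count, dense_units),
       b_dense = rep(0, dense_units),
       W_out = glorot(dense_units, K),
       b_out = rep(0, K))
}

cnn_forward <- function(params, E_aug, batch, kernel_size,
                        dropout = 0, training = FALSE) {
  n <- nrow(batch$ids); L <- ncol(batch$ids); dim <- ncol(E_aug)
  if (kernel_size > L) {
    tt_abort(sprintf("cnn: kernel_size (%d) exceeds sequence length (%d)",
                     kernel_size, L))
  }
  P <- L - kernel_size + 1
  X <- lapply(seq_len(L), function(t) embed_col(E_aug, batch$ids[, t]))
  F_ <- ncol(params$W_conv)
  pooled <- matrix(-Inf, n, F_)
  argmax_p <- matrix(1L, n, F_)
  Z_list <- vector("list", P)
  C_list <- vector("list", P)
  for (p in seq_len(P)) {
    Z <- do.call(cbind, X[p:(p + kernel_size - 1)])
    C <- pmax(sweep(Z %*% params$W_conv, 2, params$b_conv, "+"), 0)
    upd <- C > pooled
    pooled[upd] <- C[upd]
    argmax_p[upd] <- p
    Z_list[[p]] <- Z
    C_list[[p]] <- C
  }
  mask_d <- if (training) dropout_mask(n, ncol(params$W_dense), dropout) else NULL
  dense_relu <- pmax(sweep(pooled %*% params$W_dense, 2, params$b_dense, "+"), 0)
  h <- apply_dropout(dense_relu, mask_d)
  logits <- sweep(h %*% params$W_out, 2, params$b_out, "+")
  list(probs = sigmoid(logits),
       cache = list(Z_list = Z_list, C_list = C_list, pooled = pooled,
                    argmax_p = argmax_p, dense_relu = dense_relu,
                    mask_d = mask_d, head_in = h, n = n, P = P))
}

cnn_backward <- function(params, cache, dlogits) {
  grads <- list()
  grads$W_out <- t(cache$head_in) %*% dlogits
  grads$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(params$W_out)
  dh <- apply_dropout(dh, cache$mask_d)
  dh <- dh * (cache$dense_relu > 0)
  grads$W_dense <- t(cache$pooled) %*% dh
  grads$b_dense <- colSums(dh)
  dpooled <- dh %*% t(params$W_dense)

  grads$W_conv <- matrix(0, nrow(params$W_conv), ncol(params$W_conv))
  grads$b_conv <- rep(0, length(params$b_conv))
  n <- cache$n
  for (p in seq_len(cache$P)) {
    sel <- (cache$argmax_p == p) * dpooled        # route grad to argmax pos
    sel <- sel * (cache$C_list[[p]] > 0)          # ReLU gate
    if (all(sel == 0)) next
    grads$W_conv <- grads$W_conv + t(cache$Z_list[[p]]) %*% sel
    grads$b_conv <- grads$b_conv + colSums(sel)
  }
  grads
}

## ---- BiLSTM ---------------------------------------------------------------

lstm_dir_init <- function(dim, H) {
  W <- glorot(dim + H, 4 * H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1   # forget-gate bias starts open
  list(W = W, b = b)
}

bilstm_init <- function(dim, H, dense_units, K) {
  fw <- lstm_dir_init(dim, H)
  bw <- lstm_dir_init(dim, H)
  list(W_f = fw$W, b_f = fw$b, W_b = bw$W, b_b = bw$b,
       W_dense = glorot(2 * H, dense_units), b_dense = rep(0, dense_units),
       W_out = glorot(dense_units, K), b_out = rep(0, K))
}

# one masked LSTM pass over time order `steps`; pads carry state through
lstm_run <- function(W, b, E_aug, ids, mask, steps, H) {
  n <- nrow(ids)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", length(steps))
  for (s in seq_along(steps)) {
    t <- steps[s]
    A <- cbind(embed_col(E_aug, ids[, t]), h)
    z <- sweep(A %*% W, 2, b, "+")
    i_g <- sigmoid(z[, 1:H, drop = FALSE])
    f_g <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o_g <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g_g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_hat <- f_g * cc + i_g * g_g
    tanh_c <- tanh(c_hat)
    h_hat <- o_g * tanh_c
    m <- mask[, t]
    c_new <- m * c_hat + (1 - m) * cc
    h_new <- m * h_hat + (1 - m) * h
    cache[[s]] <- list(A = A, i = i_g, f = f_g, o = o_g, g = g_g,
                       c_prev = cc, h_prev = h, c_hat = c_hat,
                       tanh_c = tanh_c, m = m)
    cc <- c_new; h <- h_new
  }
  list(h = h, cache = cache)
}

lstm_backprop <- function(W, cache, dh_final, H) {
  n <- nrow(dh_final)
  dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
  dh <- dh_final; dc <- matrix(0, n, H)
  dim_in <- nrow(W) - H
  for (s in rev(seq_along(cache))) {
    cc <- cache[[s]]
    m <- cc$m
    dh_hat <- dh * m
    dh_prev <- dh * (1 - m)
    dc_hat <- dc * m
    dc_prev_carry <- dc * (1 - m)
    do_ <- dh_hat * cc$tanh_c
    dc_hat <- dc_hat + dh_hat * cc$o * (1 - cc$tanh_c^2)
    df <- dc_hat * cc$c_prev
    di <- dc_hat * cc$g
    dg <- dc_hat * cc$i
    dc_prev <- dc_hat * cc$f + dc_prev_carry
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + t(cc$A) %*% dz
    db <- db + colSums(dz)
    dA <- dz %*% t(W)
    dh <- dh_prev + dA[, (dim_in + 1):(dim_in + H), drop = FALSE]
    dc <- dc_prev
  }
  list(dW = dW, db = db)
}

bilstm_forward <- function(params, E_aug, batch, H,
                           dropout = 0, training = FALSE) {
  L <- ncol(batch$ids); n <- nrow(batch$ids)
  fw <- lstm_run(params$W_f, params$b_f, E_aug, batch$ids, batch$mask,
                 seq_len(L), H)
  bw <- lstm_run(params$W_b, params$b_b, E_aug, batch$ids, batch$mask,
                 rev(seq_len(L)), H)
  u <- cbind(fw$h, bw$h)
  mask_d <- if (training) dropout_mask(n, ncol(params$W_dense), dropout) else NULL
  dense_relu <- pmax(sweep(u %*% params$W_dense, 2, params$b_dense, "+"), 0)
  h <- apply_dropout(dense_relu, mask_d)
  logits <- sweep(h %*% params$W_out, 2, params$b_out, "+")
  list(probs = sigmoid(logits),
       cache = list(fw = fw, bw = bw, u = u, dense_relu = dense_relu,
                    mask_d = mask_d, head_in = h, H = H))
}

bilstm_backward <- function(params, cache, dlogits) {
  H <- cache$H
  grads <- list()
  grads$W_out <- t(cache$head_in) %*% dlogits
  grads$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(params$W_out)
  dh <- apply_dropout(dh, cache$mask_d)
  dh <- dh * (cache$dense_relu > 0)
  grads$W_dense <- t(cache$u) %*% dh
  grads$b_dense <- colSums(dh)
  du <- dh %*% t(params$W_dense)
  gf <- lstm_backprop(params$W_f, cache$fw$cache, du[, 1:H, drop = FALSE], H)
  gb <- lstm_backprop(params$W_b, cache$bw$cache,
                      du[, (H + 1):(2 * H), drop = FALSE], H)
  grads$W_f <- gf$dW; grads$b_f <- gf$db
  grads$W_b <- gb$dW; grads$b_b <- gb$db
  grads
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
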