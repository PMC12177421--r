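# Bidirectional GRU classification head: one GRU layer per direction over
# the encoder output, concatenated final states through a sigmoid unit.
# Forward caches everything the backward-through-time pass needs.

sigmoid <- function(x) 1 / (1 + exp(-x))

# one direction; idx is the processing order of rows of X
gru_dir <- function(p, X, idx, dir, hidden) {
  Wz <- p[[paste0("gru.Wz", dir)]]; Uz <- p[[paste0("gru.Uz", dir)]]
  Wr <- p[[paste0("gru.Wr", dir)]]; Ur <- p[[paste0("gru.Ur", dir)]]
  Wn <- p[[paste0("gru.Wn", dir)]]; Un <- p[[paste0("gru.Un", dir)]]
  bz <- p[[paste0("gru.bz", dir)]]; br <- p[[paste0("gru.br", dir)]]
  bn <- p[[paste0("gru.bn", dir)]]
  L <- length(idx)
  Z <- Rg <- N <- Hprev <- matrix(0, L, hidden)
  h <- matrix(0, 1, hidden)
  for (s in seq_len(L)) {
    x <- X[idx[s], , drop = FALSE]
    z <- sigmoid(x %*% Wz + h %*% Uz + rep(bz, each = 1))
    r <- sigmoid(x %*% Wr + h %*% Ur + rep(br, each = 1))
    n <- tanh(x %*% Wn + (r * h) %*% Un + rep(bn, each = 1))
    Hprev[s, ] <- h
    Z[s, ] <- z; Rg[s, ] <- r; N[s, ] <- n
    h <- (1 - z) * n + z * h
  }
  list(h_final = h, Z = Z, Rg = Rg, N = N, Hprev = Hprev, idx = idx)
}

gru_forward <- function(model, X1, cache = FALSE) {
  h <- model$gru_hidden
  if (is.null(h)) abort("model has no Bi-GRU head; call add_bigru_head()")
  p <- model$params
  L <- nrow(X1)
  fw <- gru_dir(p, X1, seq_len(L), "f", h)
  bw <- gru_dir(p, X1, rev(seq_len(L)), "b", h)
  feat <- c(fw$h_final, bw$h_final)
  z <- sum(feat * p$gru.wout) + p$gru.bout
  out <- list(p = sigmoid(z), feat = feat)
  if (cache) out$cache <- list(fw = fw, bw = bw, X1 = X1)
  out
}

# backward for one direction; dh_last is the gradient at the final state.
# dc is the direction cache from gru_dir(); X is the encoder output.
# Returns parameter grads and dX (same shape as X).
gru_dir_bwd <- function(p, dc, X, dh_last, dir, hidden) {
  Wz <- p[[paste0("gru.Wz", dir)]]; Uz <- p[[paste0("gru.Uz", dir)]]
  Wr <- p[[paste0("gru.Wr", dir)]]; Ur <- p[[paste0("gru.Ur", dir)]]
  Wn <- p[[paste0("gru.Wn", dir)]]; Un <- p[[paste0("gru.Un", dir)]]
  L <- length(dc$idx)
  g <- list()
  for (gate in c("z", "r", "n")) {
    g[[paste0("gru.W", gate, dir)]] <- matrix(0, nrow(Wz), hidden)
    g[[paste0("gru.U", gate, dir)]] <- matrix(0, hidden, hidden)
    g[[paste0("gru.b", gate, dir)]] <- numeric(hidden)
  }
  dX <- matrix(0, nrow(X), ncol(X))
  dh <- dh_last
  for (s in rev(seq_len(L))) {
    x <- X[dc$idx[s], , drop = FALSE]
    z <- dc$Z[s, , drop = FALSE]
    r <- dc$Rg[s, , drop = FALSE]
    n <- dc$N[s, , drop = FALSE]
    hp <- dc$Hprev[s, , drop = FALSE]
    dn <- dh * (1 - z)
    dan <- dn * (1 - n^2)
    dz <- dh * (hp - n)
    daz <- dz * z * (1 - z)
    dh_prev <- dh * z
    drh <- dan %*% t(Un)
    dr <- drh * hp
    dh_prev <- dh_prev + drh * r
    dar <- dr * r * (1 - r)
    g[[paste0("gru.Wn", dir)]] <- g[[paste0("gru.Wn", dir)]] + t(x) %*% dan
    g[[paste0("gru.Un", dir)]] <- g[[paste0("gru.Un", dir)]] + t(r * hp) %*% dan
    g[[paste0("gru.bn", dir)]] <- g[[paste0("gru.bn", dir)]] + as.numeric(dan)
    g[[paste0("gru.Wr", dir)]] <- g[[paste0("gru.Wr", dir)]] + t(x) %*% dar
    g[[paste0("gru.Ur", dir)]] <- g[[paste0("gru.Ur", dir)]] + t(hp) %*% dar
    g[[paste0("gru.br", dir)]] <- g[[paste0("gru.br", dir)]] + as.numeric(dar)
    g[[paste0("gru.Wz", dir)]] <- g[[paste0("gru.Wz", dir)]] + t(x) %*% daz
    g[[paste0("gru.Uz", dir)]] <- g[[paste0("gru.Uz", dir)]] + t(hp) %*% daz
    g[[paste0("gru.bz", dir)]] <- g[[paste0("gru.bz", dir)]] + as.numeric(daz)
    dh_prev <- dh_prev + dar %*% t(Ur) + daz %*% t(Uz)
    dX[dc$idx[s], ] <- dX[dc$idx[s], ] +
      as.numeric(daz %*% t(Wz) + dar %*% t(Wr) + dan %*% t(Wn))
    dh <- dh_prev
  }
  list(grads = g, dX = dX)
}

# full head backward: dz is d(loss)/d(logit)
gru_backward <- function(model, fwd, dz) {
  h <- model$gru_hidden
  p <- model$params
  grads <- list(
    gru.wout = dz * fwd$feat,
    gru.bout = dz
  )
  dfeat <- dz * p$gru.wout
  X1 <- fwd$cache$X1
  bf <- gru_dir_bwd(p, fwd$cache$fw, X1, matrix(dfeat[seq_len(h)], 1), "f", h)
  bb <- gru_dir_bwd(p, fwd$cache$bw, X1, matrix(dfeat[h + seq_len(h)], 1), "b", h)
  list(grads = c(grads, bf$grads, bb$grads), dX1 = bf$dX + bb$dX)
}
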