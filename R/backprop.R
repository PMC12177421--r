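# Hand-written backward passes for the encoder and the three heads.
# Gradient lists are named like the parameter list; absent entries mean
# zero. Correctness is pinned by finite-difference tests.

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# Backward through the encoder given d(loss)/dX1. Consumes the cache from
# enc_forward(..., cache = TRUE); returns parameter grads including the
# embedding tables.
enc_backward <- function(model, cc, dX1) {
  cfg <- model$config
  p <- model$params
  H <- cfg$n_heads
  dh <- cfg$d_head
  g <- list()
  dX <- dX1
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("enc", l, ".")
    lc <- cc$layers[[l]]
    ln2b <- layernorm_bwd(dX, lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- ln2b$dg
    g[[paste0(pre, "ln2_b")]] <- ln2b$db
    dR2 <- ln2b$dX
    dF2 <- dR2
    dY1 <- dR2
    g[[paste0(pre, "W2")]] <- t(lc$F1d) %*% dF2
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    dF1d <- dF2 %*% t(p[[paste0(pre, "W2")]])
    dF1 <- apply_mask(dF1d, lc$mf)
    dH1pre <- dF1 * gelu_grad(lc$H1pre)
    g[[paste0(pre, "W1")]] <- t(lc$Y1) %*% dH1pre
    g[[paste0(pre, "b1")]] <- colSums(dH1pre)
    dY1 <- dY1 + dH1pre %*% t(p[[paste0(pre, "W1")]])
    ln1b <- layernorm_bwd(dY1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- ln1b$dg
    g[[paste0(pre, "ln1_b")]] <- ln1b$db
    dR1 <- ln1b$dX
    dOd <- dR1
    dO <- apply_mask(dOd, lc$mo)
    dXres <- dR1
    g[[paste0(pre, "Wo")]] <- t(lc$Cc) %*% dO
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dCc <- dO %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dCc), H * dh)
    dK <- matrix(0, nrow(dCc), H * dh)
    dV <- matrix(0, nrow(dCc), H * dh)
    for (h in seq_len(H)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      A <- lc$A_h[[h]]
      dHead <- dCc[, ix, drop = FALSE]
      dA <- dHead %*% t(lc$V[, ix, drop = FALSE])
      dV[, ix] <- t(A) %*% dHead
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dh)
      dQ[, ix] <- dS %*% lc$K[, ix, drop = FALSE]
      dK[, ix] <- t(dS) %*% lc$Q[, ix, drop = FALSE]
    }
    g[[paste0(pre, "Wq")]] <- t(lc$Xin) %*% dQ
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- t(lc$Xin) %*% dK
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- t(lc$Xin) %*% dV
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dX <- dXres +
      dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) +
      dV %*% t(p[[paste0(pre, "Wv")]])
  }
  dX0raw <- apply_mask(dX, cc$memb)
  dEc <- matrix(0, cfg$vocab_size, cfg$d_model)
  rs <- rowsum(dX0raw, group = cc$token_ids)
  dEc[as.integer(rownames(rs)), ] <- rs
  g$E_code <- dEc
  dEv <- matrix(0, cfg$max_visits + 1L, cfg$d_model)
  rs2 <- rowsum(dX0raw, group = cc$vrow)
  dEv[as.integer(rownames(rs2)), ] <- rs2
  g$E_visit <- dEv
  g
}

# MLM objective on one corrupted sample: mean NLL at supervised positions.
loss_grad_mlm <- function(model, sample, train = TRUE) {
  fwd <- enc_forward(model, sample$input_ids, sample$visit_numbers,
                     train = train, cache = TRUE)
  sup <- which(sample$target_ids > 0L)
  if (length(sup) == 0) {
    warn("MLM sample has no supervised positions; zero loss")
    return(list(loss = 0, grads = list(), n_sup = 0L))
  }
  Xs <- fwd$X1[sup, , drop = FALSE]
  logits <- Xs %*% model$params$mlm.W +
    rep(model$params$mlm.b, each = length(sup))
  P <- softmax_rows(logits)
  tgt <- sample$target_ids[sup]
  loss <- -mean(log(pmax(P[cbind(seq_along(sup), tgt)], 1e-12)))
  dlog <- P
  dlog[cbind(seq_along(sup), tgt)] <- dlog[cbind(seq_along(sup), tgt)] - 1
  dlog <- dlog / length(sup)
  g <- list(
    mlm.W = t(Xs) %*% dlog,
    mlm.b = colSums(dlog)
  )
  dX1 <- matrix(0, nrow(fwd$X1), ncol(fwd$X1))
  dX1[sup, ] <- dlog %*% t(model$params$mlm.W)
  g <- add_grads(g, enc_backward(model, fwd$cache, dX1))
  list(loss = loss, grads = g, n_sup = length(sup))
}

# TOO objective on one ordered/permuted sample: binary cross-entropy from
# the CLS representation.
loss_grad_too <- function(model, sample, train = TRUE) {
  fwd <- enc_forward(model, sample$input_ids, sample$visit_numbers,
                     train = train, cache = TRUE)
  p <- model$params
  cl <- fwd$X1[1, , drop = FALSE]
  u <- cl %*% p$too.Wp + rep(p$too.bp, each = 1)
  pool <- tanh(u)
  z <- sum(pool * p$too.w) + p$too.b
  prob <- plogis(z)
  y <- sample$y_state
  loss <- -(y * log(pmax(prob, 1e-12)) + (1 - y) * log(pmax(1 - prob, 1e-12)))
  dz <- prob - y
  du <- (dz * p$too.w) * (1 - as.numeric(pool)^2)
  g <- list(
    too.w = dz * as.numeric(pool),
    too.b = dz,
    too.Wp = t(cl) %*% matrix(du, 1),
    too.bp = du
  )
  dX1 <- matrix(0, nrow(fwd$X1), ncol(fwd$X1))
  dX1[1, ] <- matrix(du, 1) %*% t(p$too.Wp)
  g <- add_grads(g, enc_backward(model, fwd$cache, dX1))
  list(loss = loss, grads = g, prob = prob)
}

# downstream binary classification through the Bi-GRU head
loss_grad_cls <- function(model, seq, y, train = TRUE) {
  fwd <- enc_forward(model, seq$token_ids, seq$visit_numbers,
                     train = train, cache = TRUE)
  gfwd <- gru_forward(model, fwd$X1, cache = TRUE)
  prob <- gfwd$p
  loss <- -(y * log(pmax(prob, 1e-12)) + (1 - y) * log(pmax(1 - prob, 1e-12)))
  gb <- gru_backward(model, gfwd, prob - y)
  g <- add_grads(gb$grads, enc_backward(model, fwd$cache, gb$dX1))
  list(loss = loss, grads = g, prob = prob)
}
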