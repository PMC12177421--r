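# The trajectory transformer: summed code/visit/sinusoidal embeddings, a
# multihead self-attention encoder, an MLM softmax head and a binary
# order-classification (TOO) head, plus an optional Bi-GRU fine-tuning
# head. All tensors are plain R matrices; backpropagation is hand-written
# (see backprop.R) and verified against finite differences in the tests.

#' Model configuration
#'
#' Defaults follow the compact published architecture: one encoder layer,
#' 5 attention heads, and d_k = d_v = d_model = 36 — each head uses the
#' full 36-dimensional key/value size with a (5*36) -> 36 output
#' projection, the only reading under which all three dimensions are equal.
#'
#' @param vocab_size total vocabulary size including the 5 specials.
#' @param d_model embedding width, default 36.
#' @param n_heads attention heads, default 5.
#' @param d_head per-head key/value width, default `d_model`.
#' @param n_layers encoder layers, default 1.
#' @param d_ff feed-forward inner width, default `4 * d_model`.
#' @param max_visits largest representable visit number, default 64.
#' @param max_len maximum sequence length in tokens.
#' @param dropout dropout rate in [0, 1), default 0.1.
#' @return a `tb_config` list.
#' @export
tb_config <- function(vocab_size, d_model = 36, n_heads = 5,
                      d_head = d_model, n_layers = 1, d_ff = 4 * d_model,
                      max_visits = 64, max_len = 256, dropout = 0.1) {
  stopifnot(vocab_size > 5, dropout >= 0, dropout < 1, n_layers >= 1)
  structure(
    list(vocab_size = as.integer(vocab_size), d_model = as.integer(d_model),
         n_heads = as.integer(n_heads), d_head = as.integer(d_head),
         n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
         max_visits = as.integer(max_visits), max_len = as.integer(max_len),
         dropout = dropout),
    class = "tb_config"
  )
}

# fixed sinusoidal table over visit numbers (row v+1 = visit number v)
sinusoidal_table <- function(max_visits, d_model) {
  pos <- 0:max_visits
  P <- matrix(0, length(pos), d_model)
  for (i in seq_len(ceiling(d_model / 2))) {
    freq <- 1 / (10000^((2 * (i - 1)) / d_model))
    P[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d_model) P[, 2 * i] <- cos(pos * freq)
  }
  P
}

trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  while (any(bad <- abs(x) > 2 * sd)) x[bad] <- rnorm(sum(bad), 0, sd)
  x
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

#' Initialise a trajectory transformer
#'
#' Weights are truncated-normal (sd 0.02); layer-norm gains start at 1. A
#' parameter-count report is emitted at build time.
#'
#' @param config a `tb_config`.
#' @param seed integer seed fixing the initialisation.
#' @param quiet suppress the parameter-count message.
#' @return a `tb_model`: list with `config`, `params` (named matrices/
#'   vectors), and the fixed sinusoidal table.
#' @export
tb_init_model <- function(config, seed = 1L, quiet = FALSE) {
  d <- config$d_model
  hd <- config$n_heads * config$d_head
  withr::with_seed(seed, {
    p <- list(
      E_code = tn_mat(config$vocab_size, d),
      E_visit = tn_mat(config$max_visits + 1L, d)
    )
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("enc", l, ".")
      p[[paste0(pre, "Wq")]] <- tn_mat(d, hd)
      p[[paste0(pre, "bq")]] <- numeric(hd)
      p[[paste0(pre, "Wk")]] <- tn_mat(d, hd)
      p[[paste0(pre, "bk")]] <- numeric(hd)
      p[[paste0(pre, "Wv")]] <- tn_mat(d, hd)
      p[[paste0(pre, "bv")]] <- numeric(hd)
      p[[paste0(pre, "Wo")]] <- tn_mat(hd, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- tn_mat(d, config$d_ff)
      p[[paste0(pre, "b1")]] <- numeric(config$d_ff)
      p[[paste0(pre, "W2")]] <- tn_mat(config$d_ff, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
    }
    p$mlm.W <- tn_mat(d, config$vocab_size)
    p$mlm.b <- numeric(config$vocab_size)
    p$too.Wp <- tn_mat(d, d)
    p$too.bp <- numeric(d)
    p$too.w <- trunc_normal(d)
    p$too.b <- 0
    model <- structure(
      list(config = config, params = p,
           pe = sinusoidal_table(config$max_visits, d)),
      class = "tb_model"
    )
  })
  if (!quiet) {
    inform(sprintf("tb_model built: %s learnable parameters",
                   format(count_parameters(model), big.mark = ",")))
  }
  model
}

#' Attach a Bi-GRU classification head
#'
#' One bidirectional GRU layer (default 64 hidden units per direction) run
#' over the encoder output; the concatenated final states feed a sigmoid
#' unit. Added before fine-tuning on a downstream task.
#'
#' @param model a `tb_model`.
#' @param hidden hidden units per direction, default 64.
#' @param seed initialisation seed.
#' @return the model with `gru.*` parameters attached.
#' @export
add_bigru_head <- function(model, hidden = 64, seed = 1L) {
  d <- model$config$d_model
  withr::with_seed(seed, {
    for (dir in c("f", "b")) {
      for (gate in c("z", "r", "n")) {
        model$params[[paste0("gru.W", gate, dir)]] <- tn_mat(d, hidden)
        model$params[[paste0("gru.U", gate, dir)]] <- tn_mat(hidden, hidden)
        model$params[[paste0("gru.b", gate, dir)]] <- numeric(hidden)
      }
    }
    model$params$gru.wout <- trunc_normal(2 * hidden)
    model$params$gru.bout <- 0
  })
  model$gru_hidden <- as.integer(hidden)
  model
}

#' Count learnable parameters
#' @param model a `tb_model`.
#' @return integer total; the fixed sinusoidal table is excluded.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.tb_model <- function(x, ...) {
  cat("<tb_model> d_model=", x$config$d_model, ", heads=", x$config$n_heads,
      ", layers=", x$config$n_layers, ", vocab=", x$config$vocab_size,
      ", params=", format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Model summary
#' @param x a `tb_model`.
#' @param ... unused.
#' @return one-row tibble of architecture facts and parameter count.
#' @method glance tb_model
#' @export
glance.tb_model <- function(x, ...) {
  tibble::tibble(
    d_model = x$config$d_model, n_heads = x$config$n_heads,
    n_layers = x$config$n_layers, d_ff = x$config$d_ff,
    vocab_size = x$config$vocab_size, max_len = x$config$max_len,
    dropout = x$config$dropout, n_parameters = count_parameters(x),
    has_bigru = any(startsWith(names(x$params), "gru."))
  )
}

# ---- forward primitives ----------------------------------------------------

softmax_rows <- function(M) {
  M <- exp(M - apply(M, 1, max))
  M / rowSums(M)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

drop_mask <- function(nr, nc, rate, train) {
  if (!train || rate <= 0) return(NULL)
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(X, m) if (is.null(m)) X else X * m

# Encoder forward pass over one sequence. Returns X1 and, when `cache` is
# TRUE, every intermediate needed for the backward pass; attention maps are
# always retained.
enc_forward <- function(model, token_ids, visit_numbers, train = FALSE,
                        cache = FALSE) {
  cfg <- model$config
  if (length(token_ids) > cfg$max_len) {
    abort(sprintf("sequence length %d exceeds max_len %d",
                  length(token_ids), cfg$max_len))
  }
  if (any(visit_numbers > cfg$max_visits)) {
    abort("visit number exceeds configured maximum")
  }
  p <- model$params
  L <- length(token_ids)
  d <- cfg$d_model
  H <- cfg$n_heads
  dh <- cfg$d_head
  vrow <- visit_numbers + 1L
  X0raw <- p$E_code[token_ids, , drop = FALSE] +
    p$E_visit[vrow, , drop = FALSE] + model$pe[vrow, , drop = FALSE]
  memb <- drop_mask(L, d, cfg$dropout, train)
  X <- apply_mask(X0raw, memb)
  cc <- list(token_ids = token_ids, vrow = vrow, memb = memb, layers = list())
  attn <- list()
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("enc", l, ".")
    Q <- X %*% p[[paste0(pre, "Wq")]] + rep(p[[paste0(pre, "bq")]], each = L)
    K <- X %*% p[[paste0(pre, "Wk")]] + rep(p[[paste0(pre, "bk")]], each = L)
    V <- X %*% p[[paste0(pre, "Wv")]] + rep(p[[paste0(pre, "bv")]], each = L)
    Cc <- matrix(0, L, H * dh)
    A_h <- vector("list", H)
    for (h in seq_len(H)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      A_h[[h]] <- A
      Cc[, ix] <- A %*% V[, ix, drop = FALSE]
    }
    O <- Cc %*% p[[paste0(pre, "Wo")]] + rep(p[[paste0(pre, "bo")]], each = L)
    mo <- drop_mask(L, d, cfg$dropout, train)
    Od <- apply_mask(O, mo)
    R1 <- X + Od
    ln1 <- layernorm_fwd(R1, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    H1pre <- ln1$Y %*% p[[paste0(pre, "W1")]] + rep(p[[paste0(pre, "b1")]], each = L)
    F1 <- gelu(H1pre)
    mf <- drop_mask(L, cfg$d_ff, cfg$dropout, train)
    F1d <- apply_mask(F1, mf)
    F2 <- F1d %*% p[[paste0(pre, "W2")]] + rep(p[[paste0(pre, "b2")]], each = L)
    R2 <- ln1$Y + F2
    ln2 <- layernorm_fwd(R2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    attn[[l]] <- A_h
    if (cache) {
      cc$layers[[l]] <- list(Xin = X, Q = Q, K = K, V = V, A_h = A_h, Cc = Cc,
                             mo = mo, ln1 = ln1, Y1 = ln1$Y, H1pre = H1pre,
                             F1d = F1d, mf = mf, ln2 = ln2)
    }
    X <- ln2$Y
  }
  list(X1 = X, attention = attn, cache = if (cache) cc else NULL)
}

#' Encode a tokenized sequence
#'
#' Runs the embedding sum and the transformer encoder in eval mode
#' (dropout off) and returns the per-token representation together with the
#' per-head attention matrices.
#'
#' @param model a `tb_model`.
#' @param seq a `tb_tokens` (or any list with `token_ids`, `visit_numbers`).
#' @return list with `X1` (L x d matrix) and `attention` (list over layers
#'   of lists over heads of L x L row-stochastic matrices).
#' @export
tb_encode <- function(model, seq) {
  out <- enc_forward(model, seq$token_ids, seq$visit_numbers, train = FALSE)
  list(X1 = out$X1, attention = out$attention)
}

#' MLM head: per-position vocabulary distributions
#'
#' @param model a `tb_model`.
#' @param X1 encoder output (L x d).
#' @return L x vocab_size matrix of row-stochastic probabilities.
#' @export
mlm_head <- function(model, X1) {
  softmax_rows(X1 %*% model$params$mlm.W +
                 rep(model$params$mlm.b, each = nrow(X1)))
}

#' TOO head: probability that the sequence is in its true order
#'
#' A tanh pooling of the CLS position's representation followed by a
#' sigmoid unit.
#'
#' @param model a `tb_model`.
#' @param X1 encoder output; row 1 must be the CLS position.
#' @return a single probability in (0, 1).
#' @export
too_head <- function(model, X1) {
  p <- model$params
  pool <- tanh(X1[1, , drop = FALSE] %*% p$too.Wp +
                 rep(p$too.bp, each = 1))
  plogis(sum(pool * p$too.w) + p$too.b)
}

#' Bi-GRU head: downstream event probability
#'
#' @param model a `tb_model` with [add_bigru_head()] applied.
#' @param X1 encoder output.
#' @return a single probability in (0, 1).
#' @export
bigru_head <- function(model, X1) {
  gru_forward(model, X1)$p
}

#' Full sequence-classification forward pass (eval mode)
#'
#' @param model a `tb_model` with a Bi-GRU head.
#' @param seq a `tb_tokens`.
#' @return probability of the positive class.
#' @export
predict_proba <- function(model, seq) {
  bigru_head(model, tb_encode(model, seq)$X1)
}

#' Extract attention maps
#'
#' Returns the raw row-stochastic attention matrices of every head and
#' display copies normalised to [0, 1]. Normalisation is per head by
#' default (each head's matrix min-max scaled on its own); `per_matrix`
#' scales all heads jointly. A constant matrix maps to all zeros.
#'
#' @param model a `tb_model`.
#' @param seq a `tb_tokens`.
#' @param per_matrix normalise across all heads jointly instead of per head.
#' @return list with `raw` and `normalized`, each a list (layers) of lists
#'   (heads) of L x L matrices, plus `token_ids`.
#' @export
extract_attention <- function(model, seq, per_matrix = FALSE) {
  att <- tb_encode(model, seq)$attention
  norm_one <- function(A, lo, hi) {
    if (hi - lo < 1e-12) return(A * 0)
    (A - lo) / (hi - lo)
  }
  normalized <- lapply(att, function(layer) {
    if (per_matrix) {
      lo <- min(vapply(layer, min, 0))
      hi <- max(vapply(layer, max, 0))
      lapply(layer, norm_one, lo = lo, hi = hi)
    } else {
      lapply(layer, function(A) norm_one(A, min(A), max(A)))
    }
  })
  list(raw = att, normalized = normalized, token_ids = seq$token_ids)
}

#' Plot attention maps
#'
#' @param object a `tb_model`.
#' @param seq a `tb_tokens`.
#' @param layer which encoder layer, default 1.
#' @param ... unused.
#' @return a ggplot faceted by head.
#' @method autoplot tb_model
#' @export
autoplot.tb_model <- function(object, seq, layer = 1, ...) {
  ex <- extract_attention(object, seq)
  heads <- ex$normalized[[layer]]
  L <- nrow(heads[[1]])
  df <- purrr::map_dfr(seq_along(heads), function(h) {
    tibble::tibble(
      head = paste0("head ", h),
      query = rep(seq_len(L), times = L),
      key = rep(seq_len(L), each = L),
      weight = as.vector(heads[[h]])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "attention") +
    ggplot2::facet_wrap(~head, nrow = 1) +
    ggplot2::labs(x = "key position", y = "query position") +
    ggplot2::theme_minimal()
}

# ---- persistence -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A single-file archive holding the config header, all named parameter
#' tensors, and the GRU hidden size when a Bi-GRU head is attached.
#' Round-trips bit-identically.
#'
#' @param model a `tb_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); a `tb_model`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               gru_hidden = model$gru_hidden), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  cfg <- structure(x$config, class = "tb_config")
  m <- structure(
    list(config = cfg, params = x$params,
         pe = sinusoidal_table(cfg$max_visits, cfg$d_model)),
    class = "tb_model"
  )
  if (!is.null(x$gru_hidden)) m$gru_hidden <- x$gru_hidden
  m
}

#' Warm-start a model from another checkpoint
#'
#' Copies every tensor whose name and shape match; mismatched-head tensors
#' stay at their fresh initialisation. Vocabulary (code-embedding shape) or
#' width mismatches are errors.
#'
#' @param target a freshly initialised `tb_model`.
#' @param source a trained `tb_model` (e.g. from [load_checkpoint()]).
#' @return the target model with transferred weights; attribute
#'   `transferred` lists the tensor names copied.
#' @export
warm_start <- function(target, source) {
  if (!identical(dim(target$params$E_code), dim(source$params$E_code))) {
    abort("vocabulary mismatch: code-embedding shapes differ")
  }
  if (target$config$d_model != source$config$d_model) {
    abort("d_model mismatch")
  }
  moved <- character(0)
  for (nm in names(target$params)) {
    src <- source$params[[nm]]
    if (!is.null(src) &&
        identical(dim(target$params[[nm]]), dim(src)) &&
        length(target$params[[nm]]) == length(src)) {
      target$params[[nm]] <- src
      moved <- c(moved, nm)
    }
  }
  inform(paste0("warm_start: transferred ", length(moved), "/",
                length(target$params), " tensors"))
  attr(target, "transferred") <- moved
  target
}
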