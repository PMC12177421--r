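# Alternating multitask pretraining (MLM + TOO), fine-tuning with a Bi-GRU
# head and layer-wise learning-rate decay, and rank-based AUC evaluation.

# ---- AdamW -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# which parameters receive weight decay: 2-D weight matrices only (never
# biases or layer-norm gains)
decay_set <- function(params) {
  names(params)[vapply(params, function(x) !is.null(dim(x)), TRUE)]
}

# lr_scale: named numeric of per-parameter learning-rate multipliers
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      lr_scale = NULL, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, decay_names = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  if (is.null(decay_names)) decay_names <- decay_set(params)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    lr_p <- if (is.null(lr_scale)) lr else lr * lr_scale[[nm]]
    if (weight_decay > 0 && nm %in% decay_names) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr_p * step
  }
  list(params = params, state = state)
}

# layer index of a parameter: 0 = embeddings, 1..n = encoder layers,
# n + 1 = heads
param_layer <- function(nm, n_layers) {
  if (startsWith(nm, "E_")) return(0L)
  m <- regmatches(nm, regexec("^enc([0-9]+)\\.", nm))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  n_layers + 1L
}

# per-parameter multipliers under geometric layer-wise decay
layer_lr_scale <- function(params, n_layers, factor) {
  lmax <- n_layers + 1L
  s <- vapply(names(params), function(nm) {
    factor^(lmax - param_layer(nm, n_layers))
  }, 0)
  setNames(s, names(params))
}

# ---- pretraining -----------------------------------------------------------

#' Pretraining configuration
#'
#' @param lr Adam learning rate, default 7e-5.
#' @param weight_decay decoupled weight decay, default 0.015.
#' @param w_mlm,w_too non-negative loss weights; their sum must be positive.
#' @param batch_size sequences per step, default 8.
#' @param epochs maximum passes over the pretraining split, default 20.
#' @param mask_rate,replace_probs MLM corruption parameters.
#' @param too_method `"rcs"`, `"ccs"`, `"rvs"` or `"cvs"`.
#' @param too_fraction swap fraction for TOO training batches; a vector is
#'   sampled from uniformly per batch (fraction curriculum). Default 0.5.
#' @param monitor_fraction held-out monitoring share, default 0.10.
#' @param patience plateau patience (evaluations), default 3.
#' @param min_rel_improve relative monitor-loss improvement below which an
#'   evaluation counts toward the plateau, default 0.001.
#' @param seed integer seed governing all pretraining randomness.
#' @return a `tb_pretrain_config` list.
#' @export
pretrain_config <- function(lr = 7e-5, weight_decay = 0.015,
                            w_mlm = 1, w_too = 1, batch_size = 8,
                            epochs = 20, mask_rate = 0.15,
                            replace_probs = c(0.8, 0.1, 0.1),
                            too_method = "rcs", too_fraction = 0.5,
                            monitor_fraction = 0.10, patience = 3,
                            min_rel_improve = 0.001, seed = 1L) {
  stopifnot(w_mlm >= 0, w_too >= 0, w_mlm + w_too > 0)
  structure(
    list(lr = lr, weight_decay = weight_decay, w_mlm = w_mlm, w_too = w_too,
         batch_size = batch_size, epochs = epochs, mask_rate = mask_rate,
         replace_probs = replace_probs, too_method = too_method,
         too_fraction = too_fraction, monitor_fraction = monitor_fraction,
         patience = patience, min_rel_improve = min_rel_improve,
         seed = as.integer(seed)),
    class = "tb_pretrain_config"
  )
}

batch_indices <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# mean MLM/TOO loss and grads over a batch of samples
batch_mlm <- function(model, samples, train = TRUE) {
  tot <- list()
  loss <- 0
  for (s in samples) {
    r <- loss_grad_mlm(model, s, train = train)
    loss <- loss + r$loss
    tot <- add_grads(tot, r$grads)
  }
  list(loss = loss / length(samples), grads = scale_grads(tot, 1 / length(samples)))
}

batch_too <- function(model, samples, train = TRUE) {
  tot <- list()
  loss <- 0
  correct <- 0
  for (s in samples) {
    r <- loss_grad_too(model, s, train = train)
    loss <- loss + r$loss
    correct <- correct + as.integer((r$prob > 0.5) == (s$y_state == 1L))
    tot <- add_grads(tot, r$grads)
  }
  list(loss = loss / length(samples),
       grads = scale_grads(tot, 1 / length(samples)),
       acc = correct / length(samples))
}

#' Pretrain a trajectory transformer on MLM + TOO
#'
#' Batches strictly alternate between the two objectives (MLM, TOO, MLM,
#' ...); each step optimises that batch's weighted loss with AdamW. A
#' `monitor_fraction` share of sequences is held out; after every epoch the
#' monitor MLM loss and TOO accuracy are logged, and training stops when the
#' monitor loss has improved by less than `min_rel_improve` for `patience`
#' consecutive evaluations (plateau) or `epochs` is reached. An objective
#' with zero weight is skipped entirely, so `w_too = 0` degenerates to
#' MLM-only pretraining.
#'
#' @param model a `tb_model`.
#' @param seqs list of `tb_tokens` (the pretraining split, already
#'   windowed).
#' @param cfg a [pretrain_config()].
#' @param vocab the `tb_vocab`.
#' @param weights `tb_swap_weights`; required when `too_method` is
#'   `"ccs"` or `"cvs"`.
#' @return a `tb_pretrained`: `model`, `steps` (per-step log tibble),
#'   `monitor` (per-epoch tibble), `config`.
#' @export
pretrain <- function(model, seqs, cfg = pretrain_config(), vocab,
                     weights = NULL) {
  if (cfg$too_method %in% c("ccs", "cvs") && cfg$w_too > 0 && is.null(weights)) {
    abort(paste0("too_method '", cfg$too_method, "' requires swap weights"))
  }
  withr::with_seed(cfg$seed, {
    n_mon <- max(1L, floor(cfg$monitor_fraction * length(seqs)))
    mon_ix <- sample(length(seqs), n_mon)
    monitor_seqs <- seqs[mon_ix]
    train_seqs <- seqs[-mon_ix]
    # TOO batches draw only from sequences that can be permuted, keeping the
    # ordered/permuted labels balanced (a skipped sequence would otherwise
    # contribute a second ordered copy and bias the head's intercept)
    too_pool <- Filter(function(s) too_eligible(s, cfg$too_method), train_seqs)
    mon_pool <- Filter(function(s) too_eligible(s, cfg$too_method), monitor_seqs)
    opt <- adam_init(model$params)
    steps <- list()
    monitor <- list()
    best <- Inf
    stale <- 0L
    step_id <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(train_seqs))
      objective <- "mlm"
      for (bi in batch_indices(length(ord), cfg$batch_size)) {
        batch <- train_seqs[ord[bi]]
        if (objective == "mlm" && cfg$w_mlm > 0) {
          samples <- lapply(batch, mlm_corrupt, vocab = vocab,
                            mask_rate = cfg$mask_rate,
                            replace_probs = cfg$replace_probs)
          r <- batch_mlm(model, samples, train = TRUE)
          upd <- adam_step(model$params, scale_grads(r$grads, cfg$w_mlm),
                           opt, cfg$lr, cfg$weight_decay)
          model$params <- upd$params
          opt <- upd$state
          step_id <- step_id + 1L
          steps[[step_id]] <- tibble::tibble(
            step = step_id, epoch = ep, objective = "mlm",
            loss = r$loss, accuracy = NA_real_
          )
        } else if (objective == "too" && cfg$w_too > 0 && length(too_pool) > 0) {
          half <- too_pool[sample(length(too_pool),
                                  min(length(too_pool),
                                      max(1L, cfg$batch_size %/% 2L)))]
          frac <- if (length(cfg$too_fraction) > 1) {
            sample(cfg$too_fraction, 1)
          } else {
            cfg$too_fraction
          }
          samples <- make_too_batch(half, method = cfg$too_method,
                                    fraction = frac,
                                    vocab = vocab, weights = weights)
          r <- batch_too(model, samples, train = TRUE)
          upd <- adam_step(model$params, scale_grads(r$grads, cfg$w_too),
                           opt, cfg$lr, cfg$weight_decay)
          model$params <- upd$params
          opt <- upd$state
          step_id <- step_id + 1L
          steps[[step_id]] <- tibble::tibble(
            step = step_id, epoch = ep, objective = "too",
            loss = r$loss, accuracy = r$acc
          )
        }
        objective <- if (objective == "mlm") "too" else "mlm"
      }
      ev <- monitor_eval(model, monitor_seqs, mon_pool, cfg, vocab, weights)
      monitor[[ep]] <- tibble::tibble(
        epoch = ep, mlm_loss = ev$mlm_loss, too_loss = ev$too_loss,
        too_acc = ev$too_acc, total = ev$total
      )
      if (ev$total < best * (1 - cfg$min_rel_improve)) {
        best <- ev$total
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= cfg$patience) break
    }
    structure(
      list(model = model, steps = dplyr::bind_rows(steps),
           monitor = dplyr::bind_rows(monitor), config = cfg),
      class = "tb_pretrained"
    )
  })
}

# can this sequence be permuted under the given method?
too_eligible <- function(s, method) {
  if (method %in% c("rvs", "cvs")) {
    max(s$visit_numbers) >= 2
  } else {
    vn <- s$visit_numbers[s$token_ids > 5L]
    length(vn) >= 2 && length(unique(vn)) >= 2
  }
}

# deterministic monitor evaluation (eval mode, fixed corruption stream);
# TOO metrics are computed on the permutable subset so labels stay balanced
monitor_eval <- function(model, monitor_seqs, mon_pool, cfg, vocab, weights) {
  withr::with_seed(cfg$seed + 7L, {
    mlm_loss <- NA_real_
    too_loss <- NA_real_
    too_acc <- NA_real_
    if (cfg$w_mlm > 0) {
      ls <- vapply(monitor_seqs, function(s) {
        smp <- mlm_corrupt(s, vocab, cfg$mask_rate, cfg$replace_probs)
        if (all(smp$target_ids == 0L)) return(NA_real_)
        fwd <- enc_forward(model, smp$input_ids, smp$visit_numbers, train = FALSE)
        sup <- which(smp$target_ids > 0L)
        P <- mlm_head(model, fwd$X1[sup, , drop = FALSE])
        -mean(log(pmax(P[cbind(seq_along(sup), smp$target_ids[sup])], 1e-12)))
      }, 0)
      mlm_loss <- mean(ls, na.rm = TRUE)
    }
    if (cfg$w_too > 0 && length(mon_pool) > 0) {
      samples <- make_too_batch(mon_pool, method = cfg$too_method,
                                fraction = max(cfg$too_fraction), vocab = vocab,
                                weights = weights)
      probs <- vapply(samples, function(s) {
        too_head(model, enc_forward(model, s$input_ids, s$visit_numbers,
                                    train = FALSE)$X1)
      }, 0)
      ys <- vapply(samples, `[[`, 0L, "y_state")
      too_loss <- -mean(ys * log(pmax(probs, 1e-12)) +
                          (1 - ys) * log(pmax(1 - probs, 1e-12)))
      too_acc <- mean((probs > 0.5) == (ys == 1L))
    }
    total <- sum(c(cfg$w_mlm * mlm_loss, cfg$w_too * too_loss), na.rm = TRUE)
    list(mlm_loss = mlm_loss, too_loss = too_loss, too_acc = too_acc,
         total = total)
  })
}

#' @export
print.tb_pretrained <- function(x, ...) {
  cat("<tb_pretrained> ", nrow(x$steps), " steps over ",
      max(x$monitor$epoch), " epochs; final monitor MLM loss ",
      sprintf("%.4f", utils::tail(x$monitor$mlm_loss, 1)), "\n", sep = "")
  invisible(x)
}

#' Per-epoch monitor log of a pretraining run
#' @param x a `tb_pretrained`.
#' @param ... unused.
#' @return the monitor tibble.
#' @method tidy tb_pretrained
#' @export
tidy.tb_pretrained <- function(x, ...) x$monitor

#' @rdname tidy.tb_pretrained
#' @method glance tb_pretrained
#' @export
glance.tb_pretrained <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$steps), n_epochs = max(x$monitor$epoch),
    final_mlm_loss = utils::tail(x$monitor$mlm_loss, 1),
    final_too_acc = utils::tail(x$monitor$too_acc, 1),
    w_mlm = x$config$w_mlm, w_too = x$config$w_too,
    too_method = x$config$too_method
  )
}

#' Plot pretraining monitor curves
#' @param object a `tb_pretrained`.
#' @param ... unused.
#' @return a ggplot of monitor losses and TOO accuracy by epoch.
#' @method autoplot tb_pretrained
#' @export
autoplot.tb_pretrained <- function(object, ...) {
  df <- object$monitor |>
    tidyr::pivot_longer(c("mlm_loss", "too_loss", "too_acc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Permutation-detection accuracy across swap fractions
#'
#' For each fraction, builds a balanced ordered/permuted sample set from
#' held-out sequences and reports the model's classification accuracy —
#' the learnability curve of the order objective.
#'
#' @param model a `tb_model`.
#' @param seqs held-out `tb_tokens` list.
#' @param method swapping method.
#' @param fractions numeric grid of swap fractions.
#' @param vocab the `tb_vocab`.
#' @param weights optional `tb_swap_weights` for conditional methods.
#' @param seed seed for sample construction.
#' @return tibble with `fraction`, `accuracy`, `n` (support count).
#' @export
evaluate_too <- function(model, seqs, method, fractions, vocab,
                         weights = NULL, seed = 1L) {
  seqs <- Filter(function(s) too_eligible(s, method), seqs)
  if (length(seqs) == 0) abort("no permutable sequences to evaluate on")
  # common random numbers across fraction points: each point reuses the
  # same RNG stream, so differences along the curve are not drowned in
  # independent sampling noise
  purrr::map_dfr(fractions, function(f) {
    withr::with_seed(seed, {
      samples <- make_too_batch(seqs, method = method, fraction = f,
                                vocab = vocab, weights = weights)
      probs <- vapply(samples, function(s) {
        too_head(model, enc_forward(model, s$input_ids, s$visit_numbers,
                                    train = FALSE)$X1)
      }, 0)
      ys <- vapply(samples, `[[`, 0L, "y_state")
      tibble::tibble(fraction = f, accuracy = mean((probs > 0.5) == (ys == 1L)),
                     n = length(ys))
    })
  })
}

# ---- fine-tuning -----------------------------------------------------------

#' Fine-tuning configuration
#'
#' @param n_splits cross-fitting splits, default 5: each model trains on
#'   `n_splits - 1` splits and early-stops on the remaining one.
#' @param lr head learning rate, default 1e-3.
#' @param layer_decay geometric layer-wise decay factor in (0, 1], default
#'   0.9; layer l (0 = embeddings) trains at `lr * layer_decay^(L - l)`.
#' @param epochs maximum epochs per split, default 10.
#' @param patience early-stopping patience in evaluations, default 3.
#' @param batch_size examples per gradient step, default 8.
#' @param weight_decay AdamW weight decay, default 0.015.
#' @param gru_hidden Bi-GRU hidden units per direction, default 64.
#' @param seed integer seed.
#' @return a `tb_finetune_config` list.
#' @export
finetune_config <- function(n_splits = 5, lr = 1e-3, layer_decay = 0.9,
                            epochs = 10, patience = 3, batch_size = 8,
                            weight_decay = 0.015, gru_hidden = 64,
                            seed = 1L) {
  stopifnot(n_splits >= 2, layer_decay > 0, layer_decay <= 1)
  structure(
    list(n_splits = n_splits, lr = lr, layer_decay = layer_decay,
         epochs = epochs, patience = patience, batch_size = batch_size,
         weight_decay = weight_decay, gru_hidden = gru_hidden,
         seed = as.integer(seed)),
    class = "tb_finetune_config"
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

#' Fine-tune a pretrained model on a labeled cohort
#'
#' The examples are divided into `n_splits` stratified splits; for each
#' split, a model initialised from the checkpoint (with a fresh Bi-GRU
#' head) trains on the other splits and early-stops on that split's AUC.
#' Layer-wise learning-rate decay gives earlier layers geometrically
#' smaller steps so pretrained features move less than the head.
#'
#' @param model a pretrained `tb_model` (the checkpoint).
#' @param examples list from [cohort_to_examples()].
#' @param cfg a [finetune_config()].
#' @return a `tb_finetuned`: `models` (one per split), `metrics` tibble
#'   (split, best epoch, validation AUC), `config`.
#' @export
finetune <- function(model, examples, cfg = finetune_config()) {
  y <- vapply(examples, `[[`, 0, "y")
  if (length(unique(y)) < 2) abort("cohort has a single class")
  withr::with_seed(cfg$seed, {
    fold <- stratified_folds(y, cfg$n_splits)
    models <- vector("list", cfg$n_splits)
    metrics <- list()
    for (k in seq_len(cfg$n_splits)) {
      tr <- examples[fold != k]
      va <- examples[fold == k]
      ytr <- y[fold != k]
      if (length(unique(ytr)) < 2) abort("training split has a single class")
      m <- add_bigru_head(model, hidden = cfg$gru_hidden,
                          seed = cfg$seed + k)
      scale <- layer_lr_scale(m$params, m$config$n_layers, cfg$layer_decay)
      opt <- adam_init(m$params)
      best_auc <- -Inf
      best_params <- m$params
      best_epoch <- 0L
      stale <- 0L
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(length(tr))
        for (bi in batch_indices(length(ord), cfg$batch_size)) {
          tot <- list()
          for (i in ord[bi]) {
            r <- loss_grad_cls(m, tr[[i]]$seq, tr[[i]]$y, train = TRUE)
            tot <- add_grads(tot, r$grads)
          }
          upd <- adam_step(m$params, scale_grads(tot, 1 / length(bi)), opt,
                           cfg$lr, cfg$weight_decay, lr_scale = scale)
          m$params <- upd$params
          opt <- upd$state
        }
        scores <- vapply(va, function(e) predict_proba(m, e$seq), 0)
        val_auc <- auc_rank(scores, vapply(va, `[[`, 0, "y"))
        if (val_auc > best_auc) {
          best_auc <- val_auc
          best_params <- m$params
          best_epoch <- ep
          stale <- 0L
        } else {
          stale <- stale + 1L
        }
        if (stale >= cfg$patience) break
      }
      m$params <- best_params
      models[[k]] <- m
      metrics[[k]] <- tibble::tibble(split = k, best_epoch = best_epoch,
                                     val_auc = best_auc)
    }
    structure(
      list(models = models, metrics = dplyr::bind_rows(metrics), config = cfg),
      class = "tb_finetuned"
    )
  })
}

#' @export
print.tb_finetuned <- function(x, ...) {
  cat("<tb_finetuned> ", length(x$models), " split models; mean validation AUC ",
      sprintf("%.3f", mean(x$metrics$val_auc)), "\n", sep = "")
  invisible(x)
}

#' Per-split fine-tuning metrics
#' @param x a `tb_finetuned`.
#' @param ... unused.
#' @return the per-split metrics tibble.
#' @method tidy tb_finetuned
#' @export
tidy.tb_finetuned <- function(x, ...) x$metrics

#' Rank-based ROC AUC with tie credit
#'
#' The Wilcoxon/Mann-Whitney estimator: mean rank of positives, with tied
#' scores receiving 0.5 credit via midranks.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean and SD of test AUC across fine-tuned split models
#'
#' @param fitted a `tb_finetuned` (or list of `tb_model`s).
#' @param test_examples untouched test examples.
#' @return tibble: per-model AUC rows plus attribute-free summary columns
#'   `mean_auc`, `sd_auc` repeated per row; use [glance()] on the result of
#'   [finetune()] workflows for a single row.
#' @export
evaluate_auc <- function(fitted, test_examples) {
  models <- if (inherits(fitted, "tb_finetuned")) fitted$models else fitted
  if (length(models) < 1) abort("need at least one model")
  yt <- vapply(test_examples, `[[`, 0, "y")
  if (length(unique(yt)) < 2) abort("test labels have a single class")
  aucs <- vapply(seq_along(models), function(i) {
    s <- vapply(test_examples, function(e) predict_proba(models[[i]], e$seq), 0)
    auc_rank(s, yt)
  }, 0)
  tibble::tibble(model = seq_along(models), auc = aucs,
                 mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
}

#' @rdname tidy.tb_finetuned
#' @method glance tb_finetuned
#' @export
glance.tb_finetuned <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    mean_val_auc = mean(x$metrics$val_auc),
    sd_val_auc = stats::sd(x$metrics$val_auc),
    layer_decay = x$config$layer_decay
  )
}
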