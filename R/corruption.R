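# Input corruption for the two pretraining objectives: masked-code samples
# for MLM, and ordered/permuted sample pairs for the trajectory-order
# objective (TOO) via random or conditionally weighted code/visit swapping.

#' Mask medical codes for MLM pretraining
#'
#' Each non-special token is independently selected with probability
#' `mask_rate`; a selected token is replaced by MASK with probability 0.8,
#' by a uniformly random real code with probability 0.1, and left unchanged
#' (but still supervised) with probability 0.1. CLS/SEP/PAD are never
#' touched.
#'
#' @param seq a `tb_tokens`.
#' @param vocab the `tb_vocab`.
#' @param mask_rate selection probability, default 0.15.
#' @param replace_probs length-3 numeric `(mask, random, keep)` summing to
#'   1, default `c(0.8, 0.1, 0.1)`.
#' @return a `tb_mlm_sample`: `input_ids` (corrupted), `target_ids`
#'   (original id at supervised positions, 0 elsewhere), `visit_numbers`.
#' @export
mlm_corrupt <- function(seq, vocab, mask_rate = 0.15,
                        replace_probs = c(0.8, 0.1, 0.1)) {
  stopifnot(abs(sum(replace_probs) - 1) < 1e-9, mask_rate > 0, mask_rate < 1)
  ids <- seq$token_ids
  maskable <- which(ids > length(vocab$specials))
  if (length(maskable) == 0) abort("sequence has no maskable (code) tokens")
  sel <- maskable[runif(length(maskable)) < mask_rate]
  if (length(sel) == 0) {
    # guarantee supervision: short sequences would otherwise frequently
    # select nothing (negligible bias: P(none) = (1-rate)^n)
    sel <- maskable[sample.int(length(maskable), 1L)]
  }
  input <- ids
  target <- integer(length(ids))
  if (length(sel) > 0) {
    target[sel] <- ids[sel]
    u <- runif(length(sel))
    to_mask <- sel[u < replace_probs[1]]
    to_rand <- sel[u >= replace_probs[1] & u < replace_probs[1] + replace_probs[2]]
    input[to_mask] <- vocab$specials[["MASK"]]
    if (length(to_rand) > 0) {
      input[to_rand] <- sample(seq.int(length(vocab$specials) + 1L, vocab$size),
                               length(to_rand), replace = TRUE)
    }
  }
  structure(
    list(input_ids = input, target_ids = target,
         visit_numbers = seq$visit_numbers, patient_id = seq$patient_id),
    class = "tb_mlm_sample"
  )
}

# positions of code tokens (non-special) and their visit numbers
code_positions <- function(seq, vocab) {
  pos <- which(seq$token_ids > length(vocab$specials))
  list(pos = pos, vn = seq$visit_numbers[pos])
}

# sample k disjoint pairs from an enumerated pair set with weights;
# returns a matrix with columns p, q (row indices into the pair table)
sample_disjoint_pairs <- function(pairs, w, k) {
  chosen <- matrix(integer(0), 0, 2)
  used <- integer(0)
  for (s in seq_len(k)) {
    ok <- !(pairs[, 1] %in% used) & !(pairs[, 2] %in% used)
    if (!any(ok)) break
    idx <- which(ok)
    pick <- if (length(idx) == 1) idx else idx[sample.int(length(idx), 1, prob = w[idx])]
    chosen <- rbind(chosen, pairs[pick, , drop = FALSE])
    used <- c(used, pairs[pick, ])
  }
  chosen
}

#' Swap code pairs across visits (RCS / CCS)
#'
#' Selects `k = max(1, round(fraction * n_codes / 2))` disjoint cross-visit
#' code-position pairs and exchanges the two tokens in place. Without
#' `weights` the pair is drawn uniformly over all cross-visit pairs (random
#' code swapping, RCS). With `weights`, eligible pairs are occurrence pairs
#' `(later, earlier)` and are drawn with probability proportional to
#' `CCS(code_later, code_earlier)` (conditional code swapping, CCS), so the
#' swap preferentially destroys observed transition directions. Visit
#' structure — SEP positions and the `visit_numbers` track — is unchanged.
#'
#' @param seq a `tb_tokens`.
#' @param fraction target fraction of code positions touched (`2k/n`).
#' @param vocab the `tb_vocab`.
#' @param weights optional `tb_swap_weights` enabling the conditional
#'   variant.
#' @return a `tb_too_sample` with `state = "permutated"`, `y_state = 0`,
#'   `swap_fraction` the realised `2k/n`, and `method` `"rcs"` or `"ccs"`.
#' @export
swap_codes <- function(seq, fraction, vocab, weights = NULL) {
  cp <- code_positions(seq, vocab)
  if (length(cp$pos) < 2 || length(unique(cp$vn)) < 2) {
    abort("trajectory too short: need >= 2 codes in >= 2 distinct visits")
  }
  n <- length(cp$pos)
  k <- max(1L, as.integer(round(fraction * n / 2)))
  # ordered eligible pairs: first element strictly later visit than second
  grid <- which(outer(cp$vn, cp$vn, ">"), arr.ind = TRUE)
  pairs <- cbind(cp$pos[grid[, 1]], cp$pos[grid[, 2]])
  if (is.null(weights)) {
    w <- rep(1, nrow(pairs))
    method <- "rcs"
  } else {
    ci <- vocab$code_of[seq$token_ids[pairs[, 1]]]
    cj <- vocab$code_of[seq$token_ids[pairs[, 2]]]
    w <- ccs_lookup(weights, ci, cj)
    method <- "ccs"
  }
  chosen <- sample_disjoint_pairs(pairs, w, k)
  ids <- seq$token_ids
  for (r in seq_len(nrow(chosen))) {
    tmp <- ids[chosen[r, 1]]
    ids[chosen[r, 1]] <- ids[chosen[r, 2]]
    ids[chosen[r, 2]] <- tmp
  }
  structure(
    list(input_ids = ids, visit_numbers = seq$visit_numbers,
         state = "permutated", y_state = 0L,
         swap_fraction = 2 * nrow(chosen) / n, method = method,
         patient_id = seq$patient_id),
    class = "tb_too_sample"
  )
}

#' Swap whole visits (RVS / CVS)
#'
#' Selects `k = max(1, round(fraction * n_visits / 2))` disjoint visit
#' pairs — uniformly (random visit swapping, RVS) or with probability
#' proportional to the CVS weight of the pair (conditional visit swapping,
#' CVS) — and exchanges the full code blocks between the two visit slots.
#' Contents move, slots do not: the `visit_numbers` track is re-derived so
#' every position keeps its slot's number.
#'
#' @inheritParams swap_codes
#' @return a `tb_too_sample` with `method` `"rvs"` or `"cvs"`.
#' @export
swap_visits <- function(seq, fraction, vocab, weights = NULL) {
  blocks <- detok_ids(seq, vocab)
  O <- length(blocks)
  if (O < 2) abort("trajectory too short: need >= 2 visits")
  k <- max(1L, as.integer(round(fraction * O / 2)))
  grid <- which(outer(seq_len(O), seq_len(O), "<"), arr.ind = TRUE) # x < y
  pairs <- cbind(grid[, 1], grid[, 2])
  if (is.null(weights)) {
    w <- rep(1, nrow(pairs))
    method <- "rvs"
  } else {
    w <- vapply(seq_len(nrow(pairs)), function(r) {
      compute_cvs(weights,
                  vocab$code_of[blocks[[pairs[r, 1]]]],
                  vocab$code_of[blocks[[pairs[r, 2]]]])
    }, 0)
    if (all(w <= 0)) w <- rep(1, nrow(pairs))
    method <- "cvs"
  }
  chosen <- sample_disjoint_pairs(pairs, w, k)
  for (r in seq_len(nrow(chosen))) {
    tmp <- blocks[[chosen[r, 1]]]
    blocks[[chosen[r, 1]]] <- blocks[[chosen[r, 2]]]
    blocks[[chosen[r, 2]]] <- tmp
  }
  sp <- vocab$specials
  ids <- sp[["CLS"]]
  vn <- 0L
  for (s in seq_len(O)) {
    ids <- c(ids, blocks[[s]], sp[["SEP"]])
    vn <- c(vn, rep(s, length(blocks[[s]]) + 1L))
  }
  structure(
    list(input_ids = as.integer(ids), visit_numbers = as.integer(vn),
         state = "permutated", y_state = 0L,
         swap_fraction = 2 * nrow(chosen) / O, method = method,
         patient_id = seq$patient_id),
    class = "tb_too_sample"
  )
}

# per-visit blocks of raw token ids (codes only, no CLS/SEP)
detok_ids <- function(seq, vocab) {
  keep <- seq$token_ids > length(vocab$specials)
  vn <- seq$visit_numbers[keep]
  ids <- seq$token_ids[keep]
  out <- vector("list", max(seq$visit_numbers))
  for (v in seq_along(out)) out[[v]] <- ids[vn == v]
  out
}

# an ordered (uncorrupted) TOO sample from a source sequence
ordered_sample <- function(seq, method) {
  structure(
    list(input_ids = seq$token_ids, visit_numbers = seq$visit_numbers,
         state = "ordered", y_state = 1L, swap_fraction = 0,
         method = method, patient_id = seq$patient_id),
    class = "tb_too_sample"
  )
}

#' Build a balanced TOO batch
#'
#' Each source sequence contributes an ordered copy (label 1) and a
#' permuted copy (label 0) according to `pos_neg_ratio`; the batch is then
#' shuffled. Sequences too short to permute under the chosen method
#' contribute ordered-only and are counted in the `skipped` attribute.
#'
#' @param seqs list of `tb_tokens`.
#' @param method one of `"rcs"`, `"ccs"`, `"rvs"`, `"cvs"`.
#' @param fraction swap fraction passed to the swapper.
#' @param vocab the `tb_vocab`.
#' @param weights `tb_swap_weights`, required for `"ccs"` and `"cvs"`.
#' @param pos_neg_ratio integer length-2: ordered and permuted copies per
#'   source, default `c(1, 1)`.
#' @return list of `tb_too_sample`, shuffled, with attribute `skipped`.
#' @export
make_too_batch <- function(seqs, method = c("rcs", "ccs", "rvs", "cvs"),
                           fraction, vocab, weights = NULL,
                           pos_neg_ratio = c(1L, 1L)) {
  method <- match.arg(method)
  if (length(seqs) == 0) abort("batch must be non-empty")
  conditional <- method %in% c("ccs", "cvs")
  if (conditional && is.null(weights)) {
    abort(paste0("method '", method, "' requires swap weights"))
  }
  swapper <- if (method %in% c("rcs", "ccs")) swap_codes else swap_visits
  w <- if (conditional) weights else NULL
  out <- list()
  skipped <- 0L
  for (s in seqs) {
    for (i in seq_len(pos_neg_ratio[1])) {
      out[[length(out) + 1L]] <- ordered_sample(s, method)
    }
    for (i in seq_len(pos_neg_ratio[2])) {
      perm <- tryCatch(swapper(s, fraction, vocab, w), error = function(e) NULL)
      if (is.null(perm)) {
        skipped <- skipped + 1L
        out[[length(out) + 1L]] <- ordered_sample(s, method)
      } else {
        out[[length(out) + 1L]] <- perm
      }
    }
  }
  out <- out[sample.int(length(out))]
  attr(out, "skipped") <- skipped
  out
}
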