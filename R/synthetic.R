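# Synthetic trajectory corpora with controllable, known structure: long-tail
# (Zipf) code frequencies, planted directed transition dependencies
# (code a in an earlier visit multiplies code b's odds in later visits), and
# an order-dependent target-onset rule. Every other module is testable
# against these known ground truths without access to clinical data.

#' Specify a synthetic trajectory corpus
#'
#' Two named presets mirror the short-encounter and long-registry regimes of
#' typical hospital versus cohort data: `"short"` draws visit counts with
#' mean ~2.5, `"long"` with mean ~18.
#'
#' @param n_patients number of patients.
#' @param preset `"short"` or `"long"` visit-count regime.
#' @param n_dx,n_rx diagnosis and medication vocabulary sizes.
#' @param zipf_exponent exponent of the rank-frequency law, default 1.1.
#' @param n_planted number of planted directed pairs (a -> b), default 20.
#' @param lift odds multiplier for code b once a was seen earlier; > 1.
#' @param codes_per_visit mean codes per visit (1 + Poisson(mean - 1));
#'   defaults of 8 (short) and 6 (long) reflect that real encounters carry
#'   many codes, which is also what makes planted transitions fire often
#'   enough to be measurable.
#' @param seed integer; fixes the corpus bit-exactly.
#' @return a `tb_synth_spec` list, including the planted-pair table.
#' @export
synthetic_spec <- function(n_patients = 500,
                           preset = c("short", "long"),
                           n_dx = 60, n_rx = 20,
                           zipf_exponent = 1.1,
                           n_planted = 20, lift = 8,
                           codes_per_visit = NULL,
                           seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(lift > 1, n_planted >= 0, n_dx >= 2)
  visit_mean <- if (preset == "short") 2.5 else 18
  if (is.null(codes_per_visit)) {
    codes_per_visit <- if (preset == "short") 8 else 6
  }
  if (codes_per_visit > n_dx + n_rx) abort("codes_per_visit exceeds vocabulary")
  codes <- c(sprintf("D%03d", seq_len(n_dx)), sprintf("R%03d", seq_len(n_rx)))
  kind <- c(rep("dx", n_dx), rep("rx", n_rx))
  # interleave kinds along the frequency ranks so both kinds span the tail
  ord <- order(withr::with_seed(seed, runif(n_dx + n_rx)))
  base_w <- numeric(n_dx + n_rx)
  base_w[ord] <- seq_len(n_dx + n_rx)^(-zipf_exponent)
  base_w <- base_w / sum(base_w)
  # plant node-disjoint directed pairs among the most frequent codes: each
  # code belongs to at most one pair, so no pair's target is lifted by a
  # different edge and the marginal temporal asymmetry of every pair
  # reflects its own planted direction (shared nodes would let chains
  # reverse a pair's marginal order)
  if (2 * n_planted > n_dx + n_rx) abort("too many planted pairs for vocabulary")
  planted <- withr::with_seed(seed + 1L, {
    top <- order(base_w, decreasing = TRUE)[seq_len(2 * n_planted)]
    out <- matrix(integer(0), 0, 2)
    for (i in seq_len(n_planted)) {
      ab <- top[c(2 * i - 1, 2 * i)]
      if (runif(1) < 0.5) ab <- rev(ab) # randomize which end is the source
      out <- rbind(out, ab)
    }
    out
  })
  structure(
    list(
      n_patients = n_patients, preset = preset,
      visit_mean = visit_mean, codes_per_visit = codes_per_visit,
      codes = codes, kind = kind, base_w = base_w,
      planted = tibble::tibble(
        from = codes[planted[, 1]], to = codes[planted[, 2]], lift = lift
      ),
      zipf_exponent = zipf_exponent, lift = lift, seed = seed
    ),
    class = "tb_synth_spec"
  )
}

#' @export
print.tb_synth_spec <- function(x, ...) {
  cat("<tb_synth_spec> ", x$n_patients, " patients, preset '", x$preset,
      "' (mean visits ", x$visit_mean, "), vocab ", length(x$codes),
      ", ", nrow(x$planted), " planted pairs (lift ", x$lift, ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic trajectory corpus
#'
#' Per patient: draw a visit count (1 + Poisson(mean - 1)); per visit draw
#' codes (with replacement, so visits are multisets) from the Zipf base law;
#' once a planted pair's source code has occurred, the target code's
#' sampling odds in all later visits are multiplied by the pair's lift.
#' Visits carry lognormal `los_days` and dates spaced by random gaps.
#'
#' @param spec a `tb_synth_spec`.
#' @return a corpus tibble (see [trajectory_tbl()]).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "tb_synth_spec"))
  V <- length(spec$codes)
  from_idx <- match(spec$planted$from, spec$codes)
  to_idx <- match(spec$planted$to, spec$codes)
  withr::with_seed(spec$seed + 2L, {
    rows <- vector("list", spec$n_patients)
    for (p in seq_len(spec$n_patients)) {
      O <- 1L + rpois(1, spec$visit_mean - 1)
      w <- spec$base_w
      fired <- rep(FALSE, length(from_idx))
      pid <- sprintf("P%05d", p)
      day <- 0
      ids_v <- vector("list", O)
      days_v <- integer(O)
      los_v <- numeric(O)
      for (v in seq_len(O)) {
        nc <- 1L + rpois(1, spec$codes_per_visit - 1)
        ci <- sample.int(V, nc, replace = TRUE, prob = w)
        ids_v[[v]] <- ci
        days_v[v] <- day
        los_v[v] <- round(stats::rlnorm(1, meanlog = 1.2, sdlog = 0.6), 1)
        hit <- which(!fired & from_idx %in% ci)
        if (length(hit) > 0) {
          w[to_idx[hit]] <- w[to_idx[hit]] * spec$planted$lift[hit]
          fired[hit] <- TRUE
        }
        day <- day + 200 + rpois(1, 30) # gaps wider than a 183-day window
      }
      nlen <- lengths(ids_v)
      ci_all <- unlist(ids_v)
      rows[[p]] <- tibble::tibble(
        patient_id = pid, visit = rep(seq_len(O), nlen),
        date = as.Date("2000-01-01") + rep(days_v, nlen),
        los_days = rep(los_v, nlen),
        code = spec$codes[ci_all], kind = spec$kind[ci_all]
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Estimate planted transition lifts from a generated corpus
#'
#' For each planted pair (a -> b), visits are split into exposed (a occurred
#' in an earlier visit of the same trajectory) and unexposed. The lift is
#' estimated as a ratio of ratios against a control code that is part of no
#' planted pair: `(n_b/n_c | exposed) / (n_b/n_c | unexposed)`. Because both
#' the target and the control share the same multinomial renormalisation
#' within a visit, the estimator recovers the planted odds multiplier
#' directly.
#'
#' @param corpus a corpus tibble produced by [generate_corpus()].
#' @param spec the `tb_synth_spec` that generated it.
#' @return tibble: `from`, `to`, `lift`, `lift_hat`.
#' @export
recover_lifts <- function(corpus, spec) {
  planted <- spec$planted
  involved <- unique(c(planted$from, planted$to))
  ctl_pool <- setdiff(spec$codes[order(spec$base_w, decreasing = TRUE)], involved)
  control <- ctl_pool[1]
  tr <- corpus_to_visits(corpus)
  out <- planted
  out$lift_hat <- NA_real_
  for (r in seq_len(nrow(planted))) {
    a <- planted$from[r]
    b <- planted$to[r]
    # sources of other planted pairs with the same target would lift b in
    # visits this pair counts as unexposed; such visits are excluded
    rivals <- planted$from[planted$to == b & planted$from != a]
    nb_e <- nc_e <- nb_u <- nc_u <- 0
    for (p in tr) {
      seen_a <- FALSE
      seen_rival <- FALSE
      for (v in p$codes) {
        if (seen_a && !seen_rival) {
          nb_e <- nb_e + sum(v == b)
          nc_e <- nc_e + sum(v == control)
        } else if (!seen_a && !seen_rival) {
          nb_u <- nb_u + sum(v == b)
          nc_u <- nc_u + sum(v == control)
        }
        if (!seen_a && a %in% v) seen_a <- TRUE
        if (!seen_rival && length(rivals) > 0 && any(rivals %in% v)) {
          seen_rival <- TRUE
        }
      }
    }
    if (nc_e > 0 && nb_u > 0 && nc_u > 0) {
      out$lift_hat[r] <- (nb_e / nc_e) / (nb_u / nc_u)
    }
  }
  out
}

#' Order-dependent outcome rule for labeled synthetic cohorts
#'
#' Defines a logistic risk over trigger pairs: `presence` counts pairs with
#' both codes anywhere in the trajectory; `order` counts pairs whose source
#' occurs in a strictly earlier visit than the target. With
#' `beta_presence = 0` and `beta_order > 0`, event ordering is the only
#' signal, so an order-blind (bag-of-codes) classifier has no headroom
#' beyond presence correlation.
#'
#' @param trigger_pairs tibble with `from`, `to` code columns.
#' @param beta0 intercept (ignored when `target_prevalence` is set).
#' @param beta_presence,beta_order logistic coefficients.
#' @param target_code,target_kind injected onset code, default `"HF"` / dx.
#' @param target_prevalence optional; when set, the intercept is calibrated
#'   so the expected prevalence matches.
#' @return a `tb_task_rule` list.
#' @export
task_rule <- function(trigger_pairs, beta0 = -1.0,
                      beta_presence = 0, beta_order = 2.5,
                      target_code = "HF", target_kind = "dx",
                      target_prevalence = NULL) {
  structure(
    list(trigger_pairs = trigger_pairs, beta0 = beta0,
         beta_presence = beta_presence, beta_order = beta_order,
         target_code = target_code, target_kind = target_kind,
         target_prevalence = target_prevalence),
    class = "tb_task_rule"
  )
}

# per-patient trigger features (presence and order counts)
trigger_features <- function(corpus, trigger_pairs) {
  tr <- corpus_to_visits(corpus)
  purrr::map_dfr(names(tr), function(pid) {
    visits <- tr[[pid]]$codes
    first_v <- function(code) {
      hit <- which(vapply(visits, function(v) code %in% v, TRUE))
      if (length(hit) == 0) NA_integer_ else min(hit)
    }
    fa <- vapply(trigger_pairs$from, first_v, 0L)
    fb <- vapply(trigger_pairs$to, first_v, 0L)
    tibble::tibble(
      patient_id = pid,
      presence = sum(!is.na(fa) & !is.na(fb)),
      order = sum(!is.na(fa) & !is.na(fb) & fa < fb)
    )
  })
}

#' Default trigger pairs for the order-dependent outcome rule
#'
#' Pairs are formed from frequent codes with no planted edge — direct or
#' chained through one intermediate — between the two in either direction.
#' For such pairs the direction of co-occurrence is (approximately) a fair
#' coin under the generator, so with a presence coefficient of zero the
#' event ordering is the only usable signal: order-blind (bag-of-codes)
#' classifiers have no purchase beyond chance, which is what gives
#' order-aware models measurable headroom. (Planted pairs themselves would
#' not work here: their lift makes forward order near-certain whenever
#' both codes co-occur, collapsing order into presence.)
#'
#' @param spec a `tb_synth_spec`.
#' @param n_pairs number of disjoint trigger pairs, default 6.
#' @return tibble with `from`, `to`.
#' @export
default_trigger_pairs <- function(spec, n_pairs = 6) {
  pool <- spec$codes[order(spec$base_w, decreasing = TRUE)]
  pool <- utils::head(pool, max(20, 2 * n_pairs + 4))
  pl <- spec$planted
  edge <- paste(pl$from, pl$to)
  # does a directed planted path of length <= 2 connect u to v?
  reaches <- function(u, v) {
    if (paste(u, v) %in% edge) return(TRUE)
    mids <- pl$to[pl$from == u]
    any(paste(mids, v) %in% edge)
  }
  used <- character(0)
  out_from <- out_to <- character(0)
  for (u in pool) {
    if (u %in% used || length(out_from) >= n_pairs) next
    for (v in pool) {
      if (v == u || v %in% used) next
      if (!reaches(u, v) && !reaches(v, u)) {
        out_from <- c(out_from, u)
        out_to <- c(out_to, v)
        used <- c(used, u, v)
        break
      }
    }
  }
  if (length(out_from) < n_pairs) {
    abort("not enough direction-neutral code pairs for triggers")
  }
  tibble::tibble(from = out_from, to = out_to)
}

#' Generate a labeled synthetic cohort with order-dependent onset
#'
#' Generates a corpus with [generate_corpus()], computes each patient's
#' trigger features, draws the outcome from the logistic rule, and injects
#' the target code as a new final visit for positives. The generating
#' probability is returned per patient, so the Bayes-optimal (oracle)
#' discrimination of the task is computable.
#'
#' @param spec a `tb_synth_spec`.
#' @param rule a `tb_task_rule`; default uses the first six planted pairs.
#' @return list: `corpus` (tibble with injected onsets), `labels` (tibble
#'   `patient_id`, `y`, `p_oracle`, `presence`, `order`), `rule`.
#' @export
generate_labeled_cohort <- function(spec, rule = NULL) {
  if (is.null(rule)) {
    rule <- task_rule(default_trigger_pairs(spec), target_prevalence = 0.30)
  }
  corpus <- generate_corpus(spec)
  feats <- trigger_features(corpus, rule$trigger_pairs)
  score <- rule$beta_presence * feats$presence + rule$beta_order * feats$order
  beta0 <- rule$beta0
  if (!is.null(rule$target_prevalence)) {
    f <- function(b0) mean(plogis(b0 + score)) - rule$target_prevalence
    beta0 <- stats::uniroot(f, c(-30, 30))$root
  }
  p <- plogis(beta0 + score)
  withr::with_seed(spec$seed + 3L, {
    y <- rbinom(length(p), 1, p)
  })
  prev <- mean(y)
  if (prev < 0.05 || prev > 0.95) {
    warn(sprintf("degenerate rule: realised prevalence %.3f", prev))
  }
  labels <- tibble::tibble(patient_id = feats$patient_id, y = y,
                           p_oracle = p, presence = feats$presence,
                           order = feats$order)
  pos <- labels$patient_id[labels$y == 1]
  if (length(pos) > 0) {
    last <- corpus |>
      dplyr::filter(.data$patient_id %in% pos) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(visit = max(.data$visit),
                       date = max(.data$date), .groups = "drop")
    onset <- tibble::tibble(
      patient_id = last$patient_id, visit = last$visit + 1L,
      date = last$date + 200, los_days = NA_real_,
      code = rule$target_code, kind = rule$target_kind
    )
    corpus <- dplyr::bind_rows(corpus, onset) |>
      dplyr::arrange(.data$patient_id, .data$visit)
  }
  list(corpus = corpus, labels = labels, rule = rule,
       oracle_auc = auc_rank(labels$p_oracle, labels$y))
}
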