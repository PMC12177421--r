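# Downstream cohort construction: code-onset tasks (heart-failure or
# Alzheimer style) truncate each positive's history before the first visit
# carrying a target code; the length-of-stay task labels the last visit.
# Target code sets are prefix lists, matching the hierarchical structure of
# ICD/ATC codes.

match_prefix <- function(codes, prefixes) {
  if (length(prefixes) == 0) return(rep(FALSE, length(codes)))
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
}

#' Reconstructed default target-code prefixes
#'
#' Heart failure: ICD-9 428* / ICD-10 I50*; Alzheimer disease: ICD-10 G30*.
#' These are this package's documented reconstructions of conventional code
#' groups, not an authoritative clinical list; supply your own prefixes for
#' real analyses.
#'
#' @param task `"hf"` or `"ad"`.
#' @return character vector of code prefixes.
#' @export
default_target_codes <- function(task = c("hf", "ad")) {
  switch(match.arg(task), hf = c("428", "I50", "HF"), ad = c("G30", "AD"))
}

#' Build a code-onset prediction cohort
#'
#' Positives are patients with at least one visit containing a target code:
#' their history is truncated strictly before that first target visit (the
#' target visit and everything after are excluded), so no target code can
#' leak into any history. Negatives keep their full history. Medication
#' codes in `excluded_rx` (treatment-of-target prefixes) are removed from
#' every history. Examples whose history has fewer than `min_visits` visits
#' are dropped.
#'
#' @param corpus a corpus tibble.
#' @param target_codes character vector of target code prefixes.
#' @param excluded_rx medication code prefixes to strip from histories.
#' @param min_visits minimum history length in visits.
#' @param task label carried on the result, default `"onset"`.
#' @return a `tb_cohort`: list with `history` (corpus tibble of truncated
#'   trajectories), `labels` (tibble `patient_id`, `label`), `task`, and a
#'   `summary` tibble with class counts and mean visits per class.
#' @export
build_code_onset_cohort <- function(corpus, target_codes,
                                    excluded_rx = character(0),
                                    min_visits = 3, task = "onset") {
  if (length(target_codes) == 0) abort("target_codes must be non-empty")
  validate_corpus(corpus)
  hit <- corpus |>
    dplyr::filter(match_prefix(.data$code, target_codes)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_target = min(.data$visit), .groups = "drop")
  hist <- corpus |>
    dplyr::left_join(hit, by = "patient_id") |>
    dplyr::filter(is.na(.data$first_target) | .data$visit < .data$first_target)
  labels <- tibble::tibble(
    patient_id = unique(corpus$patient_id),
    label = as.integer(unique(corpus$patient_id) %in% hit$patient_id)
  )
  if (length(excluded_rx) > 0) {
    hist <- hist |>
      dplyr::filter(!(.data$kind == "rx" & match_prefix(.data$code, excluded_rx)))
  }
  hist <- hist |> dplyr::select(-"first_target")
  # drop patients emptied by truncation/exclusion, renumber surviving visits
  hist <- renumber_visits(hist)
  nv <- hist |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_visits = dplyr::n_distinct(.data$visit), .groups = "drop")
  keep <- nv$patient_id[nv$n_visits >= min_visits]
  hist <- hist |> dplyr::filter(.data$patient_id %in% keep)
  labels <- labels |> dplyr::filter(.data$patient_id %in% keep)
  if (sum(labels$label) == 0) warn("cohort has zero positive cases")
  new_cohort(hist, labels, task)
}

new_cohort <- function(hist, labels, task) {
  nv <- hist |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_visits = dplyr::n_distinct(.data$visit), .groups = "drop") |>
    dplyr::left_join(labels, by = "patient_id")
  summ <- nv |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean_visits = mean(.data$n_visits),
                     .groups = "drop")
  structure(list(history = hist, labels = labels, task = task,
                 summary = summ),
            class = "tb_cohort")
}

#' @export
print.tb_cohort <- function(x, ...) {
  n <- nrow(x$labels)
  cat("<tb_cohort> task '", x$task, "': ", n, " examples, prevalence ",
      sprintf("%.3f", mean(x$labels$label)), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Cohort summary
#' @param x a `tb_cohort`.
#' @param ... unused.
#' @return one-row tibble: n, prevalence, mean visits per class.
#' @method glance tb_cohort
#' @export
glance.tb_cohort <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    task = x$task,
    n = nrow(x$labels),
    prevalence = mean(x$labels$label),
    mean_visits_neg = s$mean_visits[s$label == 0][1],
    mean_visits_pos = s$mean_visits[s$label == 1][1]
  )
}

#' Build a prolonged length-of-stay cohort
#'
#' The index visit is each patient's last visit; the label is 1 iff its
#' length of stay strictly exceeds `threshold_days` ("longer than" read as
#' strict). History is everything before the index visit. Trajectories with
#' fewer than `min_visits` visits in total are excluded, and patients
#' missing `los_days` at the index visit are skipped with a message.
#'
#' @param corpus a corpus tibble with `los_days`.
#' @param threshold_days positive-label threshold, default 5.
#' @param min_visits minimum total trajectory length in visits, default 3.
#' @return a `tb_cohort` (see [build_code_onset_cohort()]).
#' @export
build_pls_cohort <- function(corpus, threshold_days = 5, min_visits = 3) {
  validate_corpus(corpus)
  nv <- corpus |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_visits = dplyr::n_distinct(.data$visit), .groups = "drop")
  keep <- nv$patient_id[nv$n_visits >= min_visits]
  sub <- corpus |> dplyr::filter(.data$patient_id %in% keep)
  idx <- sub |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_visit = max(.data$visit), .groups = "drop")
  index_los <- sub |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(.data$visit == .data$index_visit) |>
    dplyr::distinct(.data$patient_id, .data$los_days)
  missing <- index_los$patient_id[is.na(index_los$los_days)]
  if (length(missing) > 0) {
    inform(paste0("skipping ", length(missing),
                  " patient(s) with missing los_days at the index visit"))
    index_los <- index_los |> dplyr::filter(!is.na(.data$los_days))
  }
  labels <- tibble::tibble(
    patient_id = index_los$patient_id,
    label = as.integer(index_los$los_days > threshold_days)
  )
  hist <- sub |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(.data$visit < .data$index_visit,
                  .data$patient_id %in% labels$patient_id) |>
    dplyr::select(-"index_visit")
  hist <- renumber_visits(hist)
  labels <- labels |> dplyr::filter(.data$patient_id %in% hist$patient_id)
  new_cohort(hist, labels, "pls")
}

#' Verify that no positive's history carries a target code
#'
#' @param cohort a `tb_cohort`.
#' @param target_codes the prefixes used to build it.
#' @return number of leaking code rows (0 when clean), invisibly; errors if
#'   any leak is found.
#' @export
check_cohort_leaks <- function(cohort, target_codes) {
  pos <- cohort$labels$patient_id[cohort$labels$label == 1]
  leaks <- cohort$history |>
    dplyr::filter(.data$patient_id %in% pos,
                  match_prefix(.data$code, target_codes))
  if (nrow(leaks) > 0) {
    abort(paste0(nrow(leaks), " target-code rows leaked into positive histories"))
  }
  invisible(0L)
}

#' Tokenized classification examples from a cohort
#'
#' Tokenizes each history; histories longer than `max_len` keep their most
#' recent whole visits (the decision-relevant tail).
#'
#' @param cohort a `tb_cohort`.
#' @param vocab a `tb_vocab`.
#' @param max_len maximum sequence length in tokens.
#' @return list of examples, each `list(seq = tb_tokens, y = 0/1,
#'   patient_id)`.
#' @export
cohort_to_examples <- function(cohort, vocab, max_len = 128) {
  tr <- corpus_to_visits(cohort$history)
  lab <- setNames(cohort$labels$label, cohort$labels$patient_id)
  out <- vector("list", length(tr))
  for (i in seq_along(tr)) {
    pid <- names(tr)[i]
    visits <- tr[[i]]$codes
    # keep the most recent visits that fit the budget
    lens <- vapply(visits, length, 0L) + 1L # + SEP
    while (length(visits) > 1 && 1 + sum(lens) > max_len) {
      visits <- visits[-1]
      lens <- lens[-1]
    }
    s <- tokenize_trajectory(visits, vocab, patient_id = pid)
    if (length(s$token_ids) > max_len) {
      s$token_ids <- c(s$token_ids[seq_len(max_len - 1L)], vocab$specials[["SEP"]])
      s$visit_numbers <- s$visit_numbers[seq_len(max_len)]
    }
    out[[i]] <- list(seq = s, y = unname(lab[pid]), patient_id = pid)
  }
  out
}

#' Stratified subsample of fine-tuning examples
#'
#' Draws `round(fraction * n)` examples preserving label proportions within
#' one example; deterministic under `seed`.
#'
#' @param examples list of examples from [cohort_to_examples()].
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return subsampled example list.
#' @export
subsample_finetune <- function(examples, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(examples)
  y <- vapply(examples, `[[`, 0, "y")
  pos <- which(y == 1)
  neg <- which(y == 0)
  n_target <- round(fraction * length(y))
  n_pos <- round(fraction * length(pos))
  n_neg <- n_target - n_pos
  if (n_pos < 1 || n_neg < 1) abort("subsample would lose a class")
  keep <- withr::with_seed(seed, {
    c(sample(pos, n_pos), sample(neg, n_neg))
  })
  examples[sort(keep)]
}
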