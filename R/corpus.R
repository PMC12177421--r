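#' @importFrom rlang .data abort warn inform
#' @importFrom stats quantile rbinom rnorm runif rpois setNames plogis
#' @importFrom utils head tail
NULL

# Special-token ids are fixed for the life of a vocabulary: PAD=1, CLS=2,
# SEP=3, MASK=4, UNK=5; real codes start at 6.
SPECIAL_TOKENS <- c(PAD = 1L, CLS = 2L, SEP = 3L, MASK = 4L, UNK = 5L)

#' Build a tidy trajectory corpus tibble
#'
#' The canonical container for coded patient trajectories is a long tibble
#' with one row per code occurrence and columns `patient_id`, `visit`
#' (1-based order within patient), `date`, `los_days`, `code`, `kind`
#' (`"dx"` for diagnoses, `"rx"` for medications). All user-facing functions
#' in the package take this tibble first.
#'
#' @param patient_id character vector of patient identifiers.
#' @param visit integer vector of 1-based visit indices.
#' @param code character vector of medical codes (no whitespace).
#' @param kind character vector, `"dx"` or `"rx"`.
#' @param date optional `Date` vector (may be `NA`).
#' @param los_days optional non-negative numeric length of stay (may be `NA`).
#' @return a tibble with the canonical corpus columns.
#' @export
trajectory_tbl <- function(patient_id, visit, code, kind,
                           date = as.Date(NA), los_days = NA_real_) {
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    visit = as.integer(visit),
    date = as.Date(date),
    los_days = as.numeric(los_days),
    code = as.character(code),
    kind = as.character(kind)
  )
  validate_corpus(out)
  out
}

#' Validate a trajectory corpus tibble
#'
#' Checks the corpus invariants: required columns present, codes non-empty
#' with no whitespace, kinds in `{dx, rx}`, visit indices positive and, per
#' patient, forming a contiguous 1..O sequence.
#'
#' @param corpus a corpus tibble as built by [trajectory_tbl()].
#' @return the corpus, invisibly, after checks.
#' @export
validate_corpus <- function(corpus) {
  need <- c("patient_id", "visit", "code", "kind")
  miss <- setdiff(need, names(corpus))
  if (length(miss) > 0) {
    abort(paste0("corpus is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(corpus) == 0) abort("corpus has no rows")
  if (any(!nzchar(corpus$code)) || anyNA(corpus$code)) {
    abort("codes must be non-empty strings")
  }
  if (any(grepl("\\s", corpus$code))) abort("codes must not contain whitespace")
  if (!all(corpus$kind %in% c("dx", "rx"))) {
    abort("kind must be 'dx' or 'rx'")
  }
  if (any(corpus$visit < 1L)) abort("visit indices must be >= 1")
  bad <- corpus |>
    dplyr::distinct(.data$patient_id, .data$visit) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      ok = all(sort(.data$visit) == seq_along(.data$visit)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0(
      "visit indices must be contiguous 1..O within patient; offenders: ",
      paste(head(bad$patient_id, 3), collapse = ", ")
    ))
  }
  invisible(corpus)
}

#' Truncate a medical code to its 4-character stem
#'
#' Strips any dot separator and keeps the first 4 characters, the
#' conventional granularity-reduction step for ICD and ATC codes; shorter
#' codes are returned unchanged. Vectorised over `code`.
#'
#' @param code character vector of codes.
#' @param kind ignored except for interface symmetry; truncation is the same
#'   rule for diagnoses and medications.
#' @return character vector of truncated codes.
#' @examples
#' truncate_code("I50.12")  # "I501"
#' truncate_code("C03")     # "C03"
#' @export
truncate_code <- function(code, kind = NULL) {
  if (length(code) == 0 || any(is.na(code)) || any(!nzchar(code))) {
    abort("codes must be non-empty strings")
  }
  substr(gsub(".", "", code, fixed = TRUE), 1L, 4L)
}

#' Group a date-stamped code stream into visits
#'
#' For continuously recorded registries with no predefined encounters, a
#' visit is opened at a code's date and absorbs every later code falling
#' within `window_days` of the opening date (boundary inclusive: an event
#' exactly `window_days` later still joins). A later event re-opens a new
#' visit. This is a greedy left-to-right rule anchored on each visit's first
#' event.
#'
#' @param events tibble with `patient_id`, `date`, `code`, `kind` and
#'   optionally `los_days`; dates must be sorted non-decreasing within
#'   patient.
#' @param window_days visit window in days; default 183 (six months).
#' @return a corpus tibble with derived 1-based `visit` indices.
#' @export
window_visits <- function(events, window_days = 183) {
  stopifnot(window_days >= 1)
  need <- c("patient_id", "date", "code", "kind")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) abort(paste0("events missing columns: ", paste(miss, collapse = ", ")))
  if (anyNA(events$date)) abort("window_visits requires non-missing dates")
  if (!"los_days" %in% names(events)) events$los_days <- NA_real_
  assign_one <- function(d) {
    if (is.unsorted(d)) abort("events must be sorted by date within patient")
    v <- integer(length(d))
    anchor <- d[1]
    cur <- 1L
    for (i in seq_along(d)) {
      if (as.numeric(d[i] - anchor) > window_days) {
        cur <- cur + 1L
        anchor <- d[i]
      }
      v[i] <- cur
    }
    v
  }
  events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(visit = assign_one(.data$date)) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "visit", "date", "los_days", "code", "kind")
}

#' Drop rare codes and build the vocabulary over survivors
#'
#' Codes whose corpus frequency is below `min_count` are removed from every
#' visit; visits emptied by the filter are dropped and visit indices
#' re-numbered so each patient keeps a contiguous 1..O trajectory; patients
#' emptied entirely are dropped.
#'
#' @param corpus a corpus tibble.
#' @param min_count minimum corpus frequency a code needs to be retained.
#' @return a list with elements `corpus` (filtered tibble) and `vocab`
#'   (a `tb_vocab`, see [build_vocab()]).
#' @export
filter_rare_codes <- function(corpus, min_count = 50) {
  stopifnot(min_count >= 1)
  validate_corpus(corpus)
  keep <- corpus |>
    dplyr::count(.data$code, name = "n") |>
    dplyr::filter(.data$n >= min_count) |>
    dplyr::pull(.data$code)
  out <- corpus |> dplyr::filter(.data$code %in% keep)
  if (nrow(out) == 0) {
    abort(paste0("no codes survive min_count = ", min_count))
  }
  out <- renumber_visits(out)
  list(corpus = out, vocab = build_vocab(out))
}

renumber_visits <- function(corpus) {
  corpus |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(visit = match(.data$visit, sort(unique(.data$visit)))) |>
    dplyr::ungroup()
}

#' Build a code vocabulary
#'
#' Assigns contiguous integer ids to all distinct codes in the corpus,
#' reserving ids 1..5 for the special tokens PAD, CLS, SEP, MASK, UNK. Codes
#' are ordered by descending corpus frequency (ties broken alphabetically)
#' so low ids are frequent codes.
#'
#' @param corpus a corpus tibble.
#' @return an object of class `tb_vocab`: a list with `table` (tibble of
#'   id, code, kind, count), `specials` (named integer vector), and
#'   constant-time lookup vectors.
#' @export
build_vocab <- function(corpus) {
  counts <- corpus |>
    dplyr::count(.data$code, .data$kind, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$code)
  if (any(duplicated(counts$code))) {
    abort("a code appears with more than one kind; kinds must be consistent")
  }
  tab <- tibble::tibble(
    id = seq_len(nrow(counts)) + length(SPECIAL_TOKENS),
    code = counts$code,
    kind = counts$kind,
    count = counts$count
  )
  new_vocab(tab)
}

new_vocab <- function(tab) {
  id_of <- setNames(tab$id, tab$code)
  code_of <- character(max(tab$id))
  code_of[SPECIAL_TOKENS] <- names(SPECIAL_TOKENS)
  code_of[tab$id] <- tab$code
  kind_of <- rep("special", max(tab$id))
  kind_of[tab$id] <- tab$kind
  structure(
    list(
      table = tab, specials = SPECIAL_TOKENS,
      id_of = id_of, code_of = code_of, kind_of = kind_of,
      size = max(tab$id)
    ),
    class = "tb_vocab"
  )
}

#' @export
print.tb_vocab <- function(x, ...) {
  cat("<tb_vocab> ", nrow(x$table), " codes (+5 specials), ",
      sum(x$table$kind == "dx"), " dx / ", sum(x$table$kind == "rx"), " rx\n",
      sep = "")
  invisible(x)
}

#' Persist a vocabulary as a plain-text table
#'
#' Two columns (id, code) with `#`-prefixed header lines recording the five
#' special-token ids, plus kind and count columns for reproducibility.
#'
#' @param vocab a `tb_vocab`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
save_vocab <- function(vocab, path) {
  hdr <- paste0("# special ", names(vocab$specials), " ", vocab$specials)
  body <- sprintf("%d\t%s\t%s\t%d", vocab$table$id, vocab$table$code,
                  vocab$table$kind, vocab$table$count)
  writeLines(c(hdr, "# id\tcode\tkind\tcount", body), path)
  invisible(path)
}

#' Load a vocabulary written by [save_vocab()]
#' @param path file path.
#' @return a `tb_vocab`.
#' @export
load_vocab <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  tab <- tibble::tibble(
    id = as.integer(vapply(parts, `[[`, "", 1L)),
    code = vapply(parts, `[[`, "", 2L),
    kind = vapply(parts, `[[`, "", 3L),
    count = as.integer(vapply(parts, `[[`, "", 4L))
  )
  new_vocab(tab)
}

# ---- tokenization ----------------------------------------------------------

# Internal nested form: named list per patient with fields
#   codes: list of character vectors (one per visit)
#   los:   numeric per visit, date: Date per visit (first event date)
corpus_to_visits <- function(corpus) {
  validate_corpus(corpus)
  split_idx <- split(seq_len(nrow(corpus)), corpus$patient_id)
  lapply(split_idx, function(ix) {
    sub <- corpus[ix, ]
    o <- order(sub$visit)
    sub <- sub[o, ]
    vs <- split(seq_len(nrow(sub)), sub$visit)
    list(
      codes = lapply(vs, function(j) sub$code[j]),
      los = vapply(vs, function(j) sub$los_days[j][1], 0),
      date = as.Date(vapply(vs, function(j) as.character(sub$date[j][1]), ""),
                     optional = TRUE)
    )
  })
}

#' Tokenize one trajectory
#'
#' Flattens a trajectory into the model's input form: a CLS token, then each
#' visit's codes followed by a SEP. A parallel `visit_numbers` track carries
#' each token's visit index; CLS gets 0 and every code and its trailing SEP
#' get that visit's 1-based number.
#'
#' @param visits list of character vectors of codes, one element per visit.
#' @param vocab a `tb_vocab`.
#' @param patient_id optional identifier carried along.
#' @return a `tb_tokens` list: `token_ids`, `visit_numbers`, `patient_id`.
#' @export
tokenize_trajectory <- function(visits, vocab, patient_id = NA_character_) {
  if (length(visits) < 1) abort("trajectory must have at least one visit")
  sp <- vocab$specials
  ids <- sp[["CLS"]]
  vn <- 0L
  unknown <- character(0)
  for (v in seq_along(visits)) {
    cs <- visits[[v]]
    ci <- unname(vocab$id_of[cs])
    if (anyNA(ci)) {
      unknown <- c(unknown, cs[is.na(ci)])
      ci[is.na(ci)] <- sp[["UNK"]]
    }
    ids <- c(ids, ci, sp[["SEP"]])
    vn <- c(vn, rep(v, length(ci) + 1L))
  }
  if (length(unknown) > 0) {
    warn(paste0("mapped ", length(unknown), " unknown code(s) to UNK: ",
                paste(head(unique(unknown), 5), collapse = ", ")))
  }
  structure(
    list(token_ids = as.integer(ids), visit_numbers = as.integer(vn),
         patient_id = patient_id),
    class = "tb_tokens"
  )
}

#' Recover visit structure from a tokenized sequence
#'
#' Inverse of [tokenize_trajectory()]: returns the list of per-visit code
#' vectors. MASK/UNK/PAD tokens are reported by their special names.
#'
#' @param seq a `tb_tokens`.
#' @param vocab the `tb_vocab` used to tokenize.
#' @return list of character vectors, one per visit.
#' @export
detokenize <- function(seq, vocab) {
  sp <- vocab$specials
  ids <- seq$token_ids
  vn <- seq$visit_numbers
  keep <- !(ids %in% c(sp[["CLS"]], sp[["SEP"]], sp[["PAD"]]))
  ids <- ids[keep]
  vn <- vn[keep]
  if (length(ids) == 0) return(list())
  out <- split(vocab$code_of[ids], vn)
  unname(out)
}

#' Visit-aligned sliding windows over a tokenized sequence
#'
#' Long sequences are tiled into windows that never split a visit: each
#' window is re-prefixed with CLS and contains whole visits whose tokens fit
#' in `max_len`. The stride is half the realised window length in visits
#' (at least 1), and a final window always covers the trajectory tail. A
#' sequence already within `max_len` yields itself. A single visit too long
#' to fit is tail-truncated (its SEP kept) with a message.
#'
#' @param seq a `tb_tokens`.
#' @param max_len maximum window length in tokens (>= 3).
#' @param stride_visits optional fixed stride in visits; default half window.
#' @return list of `tb_tokens` windows.
#' @export
sliding_window <- function(seq, max_len, stride_visits = NULL) {
  stopifnot(max_len >= 3)
  if (length(seq$token_ids) <= max_len) return(list(seq))
  sp_cls <- 2L
  vis <- visit_spans(seq)          # matrix: start, end, visit number
  n_vis <- nrow(vis)
  lens <- vis[, "end"] - vis[, "start"] + 1L
  budget <- max_len - 1L           # room after the CLS prefix
  windows <- list()
  s <- 1L
  repeat {
    # grow window [s, e] while the token budget allows whole visits
    tot <- 0L
    e <- s - 1L
    while (e < n_vis && tot + lens[e + 1L] <= budget) {
      e <- e + 1L
      tot <- tot + lens[e]
    }
    if (e < s) {
      # single visit longer than the budget: tail-truncate it
      inform(paste0("visit ", vis[s, "visit"], " exceeds max_len; tail-truncated"))
      e <- s
      ids <- seq$token_ids[vis[s, "start"]:vis[s, "end"]]
      vns <- seq$visit_numbers[vis[s, "start"]:vis[s, "end"]]
      ids <- c(head(ids, budget - 1L), 3L)  # keep SEP terminator
      vns <- head(vns, length(ids))
      w <- list(token_ids = c(sp_cls, ids), visit_numbers = c(0L, vns),
                patient_id = seq$patient_id)
    } else {
      rng <- vis[s, "start"]:vis[e, "end"]
      w <- list(token_ids = c(sp_cls, seq$token_ids[rng]),
                visit_numbers = c(0L, seq$visit_numbers[rng]),
                patient_id = seq$patient_id)
    }
    class(w) <- "tb_tokens"
    windows[[length(windows) + 1L]] <- w
    if (e >= n_vis) break
    step <- if (is.null(stride_visits)) max(1L, (e - s + 1L) %/% 2L) else as.integer(stride_visits)
    s <- min(s + step, e + 1L)
  }
  windows
}

# token spans of each visit (excluding the leading CLS), as a matrix
visit_spans <- function(seq) {
  vn <- seq$visit_numbers
  pos <- which(vn > 0L)
  sp <- split(pos, vn[pos])
  m <- t(vapply(sp, function(p) c(start = min(p), end = max(p)), c(1L, 1L)))
  cbind(m, visit = as.integer(names(sp)))
}

#' Tokenize a whole corpus
#'
#' Applies [tokenize_trajectory()] per patient and [sliding_window()] where
#' a flattened trajectory exceeds `max_len`.
#'
#' @param corpus a corpus tibble.
#' @param vocab a `tb_vocab`.
#' @param max_len maximum sequence length in tokens; default the 0.7
#'   quantile of flattened trajectory lengths (see [max_len_quantile()]).
#' @return list of `tb_tokens`.
#' @export
tokenize_corpus <- function(corpus, vocab, max_len = NULL) {
  tr <- corpus_to_visits(corpus)
  seqs <- lapply(names(tr), function(pid) {
    tokenize_trajectory(tr[[pid]]$codes, vocab, patient_id = pid)
  })
  if (is.null(max_len)) max_len <- max_len_quantile(seqs)
  out <- list()
  for (s in seqs) out <- c(out, sliding_window(s, max_len))
  out
}

#' Maximum sequence length as a trajectory-length quantile
#'
#' The pretraining convention caps sequences at the 0.7 quantile of
#' flattened trajectory lengths, trading tail coverage for batch economy.
#'
#' @param seqs list of `tb_tokens`.
#' @param q quantile, default 0.7.
#' @return integer length (at least 4).
#' @export
max_len_quantile <- function(seqs, q = 0.7) {
  lens <- vapply(seqs, function(s) length(s$token_ids), 0L)
  max(4L, as.integer(ceiling(quantile(lens, q, names = FALSE))))
}

#' Patient-level random split of a corpus
#'
#' Partitions patients (not rows) into pretraining, fine-tuning and test
#' subsets. Deterministic under `seed`; sizes follow `fractions` with
#' largest-remainder rounding so they always sum to the patient count.
#'
#' @param corpus a corpus tibble.
#' @param fractions length-3 numeric summing to 1; default c(0.70, 0.20, 0.10).
#' @param seed integer seed.
#' @return named list of corpus tibbles: `pretrain`, `finetune`, `test`.
#' @export
split_corpus <- function(corpus, fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  validate_corpus(corpus)
  pids <- unique(corpus$patient_id)
  n <- length(pids)
  base <- floor(fractions * n)
  rem <- fractions * n - base
  short <- n - sum(base)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1
  }
  perm <- withr::with_seed(seed, sample(pids))
  cuts <- cumsum(base)
  groups <- list(
    pretrain = perm[seq_len(cuts[1])],
    finetune = if (cuts[2] > cuts[1]) perm[(cuts[1] + 1):cuts[2]] else character(0),
    test = if (cuts[3] > cuts[2]) perm[(cuts[2] + 1):cuts[3]] else character(0)
  )
  lapply(groups, function(g) dplyr::filter(corpus, .data$patient_id %in% g))
}

#' Summary statistics of a corpus
#'
#' @param corpus a corpus tibble.
#' @return a one-row tibble: patients, visits, codes, distinct codes, mean
#'   visits per patient, mean codes per visit.
#' @export
corpus_stats <- function(corpus) {
  validate_corpus(corpus)
  per_pat <- corpus |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_visits = dplyr::n_distinct(.data$visit), .groups = "drop")
  tibble::tibble(
    n_patients = nrow(per_pat),
    n_visits = sum(per_pat$n_visits),
    n_codes = nrow(corpus),
    n_distinct_codes = dplyr::n_distinct(corpus$code),
    mean_visits = mean(per_pat$n_visits),
    mean_codes_per_visit = nrow(corpus) / sum(per_pat$n_visits)
  )
}
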