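# Corpus interchange formats: JSON-Lines (one patient per line) and a flat
# CSV of date-stamped events that is visit-windowed on read.

#' Read a trajectory corpus
#'
#' Two formats are supported. `"jsonl"`: one patient per line,
#' `{"patient_id": str, "visits": [{"index": int, "date": str|null,
#' "los_days": num|null, "codes": [{"code": str, "kind": "dx"|"rx"}]}]}`.
#' `"csv"`: a flat event table (`patient_id, date, code, kind, los_days`)
#' which is grouped into visits with [window_visits()].
#'
#' @param path input file.
#' @param format `"jsonl"` or `"csv"`.
#' @param window_days visit window for the CSV path; default 183.
#' @return a corpus tibble.
#' @export
read_trajectories <- function(path, format = c("jsonl", "csv"),
                              window_days = 183) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- purrr::map_dfr(lines, function(ln) {
      p <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      purrr::map_dfr(p$visits, function(v) {
        tibble::tibble(
          patient_id = p$patient_id,
          visit = as.integer(v$index),
          date = if (is.null(v$date)) as.Date(NA) else as.Date(v$date),
          los_days = if (is.null(v$los_days)) NA_real_ else as.numeric(v$los_days),
          code = vapply(v$codes, function(cd) cd$code, ""),
          kind = vapply(v$codes, function(cd) cd$kind, "")
        )
      })
    })
    validate_corpus(rows)
    rows
  } else {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
    ev$date <- as.Date(ev$date)
    if (!"los_days" %in% names(ev)) ev$los_days <- NA_real_
    ev <- ev[order(ev$patient_id, ev$date), ]
    window_visits(tibble::as_tibble(ev), window_days = window_days)
  }
}

#' Write a corpus as JSON-Lines
#'
#' @param corpus a corpus tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(corpus, path) {
  validate_corpus(corpus)
  tr <- split(corpus, corpus$patient_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pid in names(tr)) {
    sub <- tr[[pid]][order(tr[[pid]]$visit), ]
    visits <- lapply(split(seq_len(nrow(sub)), sub$visit), function(ix) {
      v <- sub[ix, ]
      list(
        index = v$visit[1],
        date = if (is.na(v$date[1])) NULL else as.character(v$date[1]),
        los_days = if (is.na(v$los_days[1])) NULL else v$los_days[1],
        codes = lapply(seq_len(nrow(v)), function(i) {
          list(code = v$code[i], kind = v$kind[i])
        })
      )
    })
    writeLines(jsonlite::toJSON(list(patient_id = pid, visits = unname(visits)),
                                auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
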