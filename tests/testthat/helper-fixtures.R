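# Shared fixtures and independent oracles, built in code at test time.

# a corpus tibble from a compact list spec: list(P1 = list(c("A"), c("B","C")))
mk_corpus <- function(patients, kinds = NULL, los = NULL) {
  rows <- list()
  for (pid in names(patients)) {
    visits <- patients[[pid]]
    for (v in seq_along(visits)) {
      cs <- visits[[v]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, visit = v,
        date = as.Date("2000-01-01") + 200 * (v - 1),
        los_days = if (is.null(los)) NA_real_ else los[[pid]][v],
        code = cs,
        kind = if (is.null(kinds)) rep("dx", length(cs)) else kinds[[pid]][[v]]
      )
    }
  }
  dplyr::bind_rows(rows)
}

# O(n^2) brute-force oracle for directed cross-visit occurrence-pair counts
brute_pair_counts <- function(corpus) {
  out <- list()
  for (pid in unique(corpus$patient_id)) {
    sub <- corpus[corpus$patient_id == pid, ]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (sub$visit[j] < sub$visit[i]) { # j strictly earlier than i
          key <- paste(sub$code[i], sub$code[j], sep = "\r")
          out[[key]] <- (out[[key]] %||% 0) + 1
        }
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random toy corpus for randomized oracle comparisons
random_toy_corpus <- function(n_traj = 5, max_visits = 6, codes = LETTERS[1:6]) {
  pats <- list()
  for (t in seq_len(n_traj)) {
    O <- sample.int(max_visits, 1)
    pats[[paste0("T", t)]] <- lapply(seq_len(O), function(v) {
      sample(codes, sample.int(3, 1), replace = TRUE)
    })
  }
  mk_corpus(pats)
}

# tiny model on a tiny synthetic vocabulary, for NN tests
tiny_setup <- function(n_patients = 30, seed = 7, min_count = 2,
                       d_model = 12, n_heads = 2, dropout = 0) {
  spec <- synthetic_spec(n_patients = n_patients, preset = "short", seed = seed)
  corpus <- generate_corpus(spec)
  fr <- filter_rare_codes(corpus, min_count = min_count)
  vocab <- fr$vocab
  seqs <- tokenize_corpus(fr$corpus, vocab, max_len = 64)
  cfg <- tb_config(vocab_size = vocab$size, d_model = d_model,
                   n_heads = n_heads, d_head = d_model %/% n_heads,
                   max_len = 64, dropout = dropout)
  model <- tb_init_model(cfg, seed = seed, quiet = TRUE)
  list(spec = spec, corpus = fr$corpus, vocab = vocab, seqs = seqs,
       cfg = cfg, model = model)
}
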