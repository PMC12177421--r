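test_that("code truncation strips dots and keeps 4 characters", {
  expect_equal(truncate_code("I50.12"), "I501")
  expect_equal(truncate_code("C03"), "C03")
  expect_equal(truncate_code("4280"), "4280")
  expect_equal(truncate_code(c("E11.9", "N18.32")), c("E119", "N183"))
  expect_error(truncate_code(""), "non-empty")
})

test_that("rare-code filtering drops below-threshold codes and empty visits", {
  corpus <- mk_corpus(list(
    P1 = list(c("A", "B"), c("A", "C")),
    P2 = list(c("A"), c("B")),
    P3 = list(c("A", "A"), c("C"))
  ))
  # counts: A = 5, B = 2, C = 2
  fr <- filter_rare_codes(corpus, min_count = 2)
  expect_setequal(fr$vocab$table$code, c("A", "B", "C"))
  fr2 <- filter_rare_codes(corpus, min_count = 3)
  expect_setequal(fr2$vocab$table$code, "A")
  expect_false("B" %in% fr2$corpus$code)
  # P3 visit 2 only held C -> dropped, visits renumbered contiguously
  p3 <- fr2$corpus[fr2$corpus$patient_id == "P3", ]
  expect_equal(sort(unique(p3$visit)), 1L)
  # min_count = 1 is the identity on codes
  fr3 <- filter_rare_codes(corpus, min_count = 1)
  expect_equal(nrow(fr3$corpus), nrow(corpus))
  expect_error(filter_rare_codes(corpus, min_count = 100), "min_count")
})

test_that("visit windowing groups events greedily with inclusive boundary", {
  ev <- tibble::tibble(
    patient_id = "P1",
    date = as.Date("2001-01-01") + c(0, 10, 200),
    code = c("A", "B", "C"), kind = "dx"
  )
  w <- window_visits(ev, window_days = 183)
  expect_equal(w$visit, c(1L, 1L, 2L))
  # boundary: event exactly window_days later joins the open visit
  ev2 <- ev[1:2, ]
  ev2$date <- as.Date("2001-01-01") + c(0, 183)
  expect_equal(window_visits(ev2, 183)$visit, c(1L, 1L))
  ev3 <- ev2
  ev3$date <- as.Date("2001-01-01") + c(0, 184)
  expect_equal(window_visits(ev3, 183)$visit, c(1L, 2L))
  # single event, and unsorted input errors
  expect_equal(window_visits(ev[1, ], 183)$visit, 1L)
  expect_error(window_visits(ev[c(3, 1, 2), ], 183), "sorted")
  # internal date span of every produced visit is within the window
  set.seed(42)
  ev4 <- tibble::tibble(
    patient_id = "Q",
    date = sort(as.Date("2001-01-01") + sample.int(2000, 60)),
    code = "A", kind = "dx"
  )
  w4 <- window_visits(ev4, 183)
  spans <- tapply(as.numeric(w4$date), w4$visit, function(d) max(d) - min(d))
  expect_true(all(spans <= 183))
})

test_that("tokenization emits CLS/SEP structure with per-visit numbers", {
  corpus <- mk_corpus(list(P1 = list("A", c("B", "C"))))
  vocab <- build_vocab(corpus)
  s <- tokenize_trajectory(list("A", c("B", "C")), vocab)
  ids <- vocab$id_of
  expect_equal(s$token_ids,
               as.integer(c(2, ids[["A"]], 3, ids[["B"]], ids[["C"]], 3)))
  expect_equal(s$visit_numbers, c(0L, 1L, 1L, 2L, 2L, 2L))
  s1 <- tokenize_trajectory(list("A"), vocab)
  expect_equal(length(s1$token_ids), 3L)
  expect_error(tokenize_trajectory(list(), vocab), "at least one")
  expect_warning(tokenize_trajectory(list("ZZZ"), vocab), "UNK")
})

test_that("detokenize inverts tokenize exactly", {
  set.seed(1)
  corpus <- random_toy_corpus(6)
  vocab <- build_vocab(corpus)
  tr <- split(corpus$code, list(corpus$patient_id, corpus$visit), drop = TRUE)
  for (pid in unique(corpus$patient_id)) {
    sub <- corpus[corpus$patient_id == pid, ]
    visits <- lapply(sort(unique(sub$visit)), function(v) sub$code[sub$visit == v])
    s <- tokenize_trajectory(visits, vocab)
    back <- detokenize(s, vocab)
    expect_equal(lapply(back, sort), lapply(visits, sort))
    expect_equal(back, visits) # order within visit preserved too
  }
})

test_that("sliding windows are visit-aligned, CLS-prefixed, and cover the tail", {
  corpus <- mk_corpus(list(P1 = lapply(1:6, function(i) c("A", "B"))))
  vocab <- build_vocab(corpus)
  s <- tokenize_trajectory(lapply(1:6, function(i) c("A", "B")), vocab)
  expect_equal(length(s$token_ids), 1 + 6 * 3)
  # short sequence: identity
  expect_identical(sliding_window(s, max_len = 50), list(s))
  # max_len fitting 3 visits of 3 tokens each (+CLS)
  ws <- sliding_window(s, max_len = 10)
  expect_true(length(ws) >= 2)
  for (w in ws) {
    expect_equal(w$token_ids[1], 2L)           # CLS
    expect_equal(w$visit_numbers[1], 0L)
    expect_lte(length(w$token_ids), 10)
    # window never splits a visit: each visit inside has its full 3 tokens
    vn <- w$visit_numbers[-1]
    expect_true(all(table(vn) == 3))
  }
  covered <- sort(unique(unlist(lapply(ws, function(w) w$visit_numbers))))
  expect_equal(setdiff(1:6, covered), integer(0)) # tail covered
  # an oversized single visit is tail-truncated, not dropped
  big <- tokenize_trajectory(list(rep("A", 30)), vocab)
  expect_message(wt <- sliding_window(big, max_len = 10))
  expect_lte(length(wt[[1]]$token_ids), 10)
})

test_that("corpus split is patient-level, exhaustive, and seed-deterministic", {
  set.seed(2)
  corpus <- random_toy_corpus(25)
  parts <- split_corpus(corpus, seed = 9)
  pids <- lapply(parts, function(p) unique(p$patient_id))
  expect_equal(length(intersect(pids$pretrain, pids$finetune)), 0)
  expect_equal(length(intersect(pids$pretrain, pids$test)), 0)
  expect_setequal(unlist(pids), unique(corpus$patient_id))
  # sizes follow fractions (25 patients -> 17/18, 5, 2/3)
  expect_equal(sum(lengths(pids)), 25)
  parts2 <- split_corpus(corpus, seed = 9)
  expect_identical(parts, parts2)
  parts3 <- split_corpus(corpus, seed = 10)
  expect_false(identical(pids$pretrain, unique(parts3$pretrain$patient_id)))
  expect_error(split_corpus(corpus, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  # 100 patients split exactly 70/20/10
  big <- random_toy_corpus(100)
  p100 <- split_corpus(big, seed = 1)
  expect_equal(vapply(p100, function(p) length(unique(p$patient_id)), 0L),
               c(pretrain = 70L, finetune = 20L, test = 10L))
})

test_that("vocabulary and corpus round-trip through their text formats", {
  set.seed(3)
  corpus <- random_toy_corpus(8)
  corpus$kind[corpus$code %in% c("E", "F")] <- "rx"
  vocab <- build_vocab(corpus)
  vf <- withr::local_tempfile(fileext = ".tsv")
  save_vocab(vocab, vf)
  v2 <- load_vocab(vf)
  expect_equal(v2$table, vocab$table)
  expect_equal(v2$specials, vocab$specials)
  jf <- withr::local_tempfile(fileext = ".jsonl")
  write_trajectories(corpus, jf)
  back <- read_trajectories(jf, format = "jsonl")
  key <- function(x) dplyr::arrange(x[, c("patient_id", "visit", "code", "kind")],
                                    patient_id, visit, code)
  expect_equal(key(back), key(corpus))
})

test_that("flat CSV events are windowed into visits on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    patient_id = "P1",
    date = as.Date("2001-01-01") + c(0, 10, 400),
    code = c("A", "B", "C"), kind = "dx", los_days = NA_real_
  ), f, row.names = FALSE)
  got <- read_trajectories(f, format = "csv", window_days = 183)
  expect_equal(got$visit, c(1L, 1L, 2L))
})
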