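vocab6 <- local({
  corpus <- mk_corpus(list(P1 = list(c("A", "B"), c("C", "D"), c("E", "F"))))
  build_vocab(corpus)
})

test_that("MLM corruption hits the target rate with the 80/10/10 split", {
  set.seed(21)
  seq100 <- tokenize_trajectory(
    lapply(1:10, function(i) rep(c("A", "B", "C", "D", "E"), 2)), vocab6
  )
  n_maskable <- sum(seq100$token_ids > 5)
  expect_equal(n_maskable, 100)
  n_rep <- 2000
  n_sel <- n_mask <- n_rand <- n_keep <- 0
  for (r in seq_len(n_rep)) {
    s <- mlm_corrupt(seq100, vocab6)
    sel <- which(s$target_ids > 0)
    n_sel <- n_sel + length(sel)
    n_mask <- n_mask + sum(s$input_ids[sel] == 4L)
    changed <- s$input_ids[sel] != s$target_ids[sel] & s$input_ids[sel] != 4L
    n_rand <- n_rand + sum(changed)
    n_keep <- n_keep + sum(s$input_ids[sel] == s$target_ids[sel])
    # specials never corrupted, targets exactly at corrupted positions
    expect_true(all(seq100$token_ids[sel] > 5))
    expect_identical(s$visit_numbers, seq100$visit_numbers)
  }
  n_tot <- n_rep * n_maskable
  ci <- qnorm(0.995) * sqrt(0.15 * 0.85 / n_tot)
  expect_lt(abs(n_sel / n_tot - 0.15), ci + 1e-3)
  expect_lt(abs(n_mask / n_sel - 0.80), 3 * sqrt(0.8 * 0.2 / n_sel))
  # the random-code arm redraws the original with probability 1/n_codes, so
  # observed keeps are 0.10 + 0.10/6 on this 6-code vocabulary
  keep_exp <- 0.10 + 0.10 / 6
  expect_lt(abs(n_keep / n_sel - keep_exp), 3 * sqrt(keep_exp * (1 - keep_exp) / n_sel))
  # the "random code" arm can draw the original id, so it is bounded above
  expect_lt(n_rand / n_sel, 0.10 + 3 * sqrt(0.1 * 0.9 / n_sel))
  expect_gt(n_rand / n_sel, 0.05)
})

test_that("MLM corruption is deterministic under a fixed RNG state", {
  s0 <- tokenize_trajectory(list(c("A", "B", "C"), c("D", "E")), vocab6)
  a <- withr::with_seed(5, mlm_corrupt(s0, vocab6))
  b <- withr::with_seed(5, mlm_corrupt(s0, vocab6))
  expect_identical(a, b)
  cls_only <- structure(list(token_ids = c(2L, 3L), visit_numbers = c(0L, 1L),
                             patient_id = NA), class = "tb_tokens")
  expect_error(mlm_corrupt(cls_only, vocab6), "maskable")
})

test_that("code swapping exchanges cross-visit pairs and preserves structure", {
  # single eligible pair: deterministic outcome
  s <- tokenize_trajectory(list("A", "B"), vocab6)
  out <- withr::with_seed(1, swap_codes(s, fraction = 0, vocab = vocab6))
  expect_equal(out$input_ids, s$token_ids[c(1, 4, 3, 2, 5)][c(1, 2, 3, 4, 5)])
  expect_equal(out$input_ids[2], s$token_ids[4]) # B moved to front
  expect_equal(out$input_ids[4], s$token_ids[2])
  expect_identical(out$visit_numbers, s$visit_numbers)
  expect_equal(out$y_state, 0L)
  expect_equal(out$state, "permutated")
  # multiset preserved under arbitrary swaps
  set.seed(31)
  big <- tokenize_trajectory(
    lapply(1:5, function(i) sample(c("A", "B", "C", "D", "E", "F"), 3, TRUE)),
    vocab6
  )
  for (f in c(0.2, 0.5, 1)) {
    o <- swap_codes(big, f, vocab6)
    expect_equal(sort(o$input_ids), sort(big$token_ids))
    expect_identical(o$visit_numbers, big$visit_numbers)
    # SEP/CLS positions untouched
    expect_equal(which(o$input_ids %in% c(2L, 3L)),
                 which(big$token_ids %in% c(2L, 3L)))
  }
  # too-short sequences error
  s1 <- tokenize_trajectory(list(c("A", "B")), vocab6)
  expect_error(swap_codes(s1, 0.5, vocab6), "short")
})

test_that("visit swapping exchanges blocks and re-derives slot numbers", {
  s <- tokenize_trajectory(list("A", c("B", "C")), vocab6)
  out <- withr::with_seed(2, swap_visits(s, 1, vocab6))
  # [[A],[B,C]] -> [[B,C],[A]]
  back <- detokenize(structure(list(token_ids = out$input_ids,
                                    visit_numbers = out$visit_numbers),
                               class = "tb_tokens"), vocab6)
  expect_equal(back, list(c("B", "C"), "A"))
  expect_equal(out$visit_numbers, c(0L, 1L, 1L, 1L, 2L, 2L))
  # fraction 1 on 4 visits moves all 4 (2 disjoint pairs)
  s4 <- tokenize_trajectory(list("A", "B", "C", "D"), vocab6)
  o4 <- withr::with_seed(3, swap_visits(s4, 1, vocab6))
  expect_equal(o4$swap_fraction, 1)
  b4 <- unlist(detokenize(structure(list(token_ids = o4$input_ids,
                                         visit_numbers = o4$visit_numbers),
                                    class = "tb_tokens"), vocab6))
  expect_true(all(b4 != c("A", "B", "C", "D"))) # every slot changed
  expect_setequal(b4, c("A", "B", "C", "D"))
  expect_error(swap_visits(tokenize_trajectory(list("A"), vocab6), 1, vocab6),
               "short")
})

test_that("TOO batches are balanced, shuffled and multiset-preserving", {
  set.seed(41)
  seqs <- lapply(1:8, function(i) {
    tokenize_trajectory(list(sample(LETTERS[1:6], 2), sample(LETTERS[1:6], 2)),
                        vocab6)
  })
  batch <- make_too_batch(seqs, method = "rvs", fraction = 1, vocab = vocab6)
  expect_length(batch, 16)
  ys <- vapply(batch, `[[`, 0L, "y_state")
  expect_equal(sum(ys), 8)
  for (b in batch) {
    src <- seqs[[which(vapply(seqs, function(s)
      identical(sort(s$token_ids), sort(b$input_ids)), TRUE))[1]]]
    expect_equal(sort(b$input_ids), sort(src$token_ids))
    if (b$y_state == 1L) expect_identical(b$input_ids, src$token_ids)
  }
  # sequences that cannot be permuted fall back to ordered and are counted
  seqs2 <- c(seqs[1:3], list(tokenize_trajectory(list("A"), vocab6)))
  b2 <- make_too_batch(seqs2, method = "rvs", fraction = 1, vocab = vocab6)
  expect_equal(attr(b2, "skipped"), 1L)
  expect_equal(sum(vapply(b2, `[[`, 0L, "y_state")), 5)
  expect_error(make_too_batch(seqs, method = "ccs", fraction = 1, vocab = vocab6),
               "weights")
})

test_that("conditional samplers follow the CCS/CVS weights", {
  # corpus where only (B <- A) carries evidence; all other pairs at the floor
  corpus <- mk_corpus(list(
    P1 = list("A", "B"), P2 = list("A", "B"), P3 = list("A", "B"),
    P4 = list(c("C", "D")) # same visit: no directional evidence
  ))
  w <- compute_ccs(count_pairs(corpus), epsilon = 0.01)
  vocab <- build_vocab(corpus)
  s <- tokenize_trajectory(list(c("A", "C"), c("B", "D")), vocab)
  # eligible later<-earlier pairs: (B,A),(B,C),(D,A),(D,C); CCS(B,A) dominates
  probs <- ccs_lookup(w, c("B", "B", "D", "D"), c("A", "C", "A", "C"))
  probs <- probs / sum(probs)
  set.seed(51)
  n_draw <- 4000
  hits <- integer(4)
  keys <- c("BA", "BC", "DA", "DC")
  for (r in seq_len(n_draw)) {
    o <- swap_codes(s, 0, vocab, weights = w) # k = 1 pair
    moved <- which(o$input_ids != s$token_ids)
    lab <- paste0(vocab$code_of[s$token_ids[moved[2]]],
                  vocab$code_of[s$token_ids[moved[1]]])
    hits[match(lab, keys)] <- hits[match(lab, keys)] + 1L
  }
  expect_gt(hits[1] / n_draw, 0.8) # dominant pair drawn overwhelmingly
  chi <- suppressWarnings(chisq.test(hits, p = probs))
  expect_gt(chi$p.value, 0.01)
  # CVS: the visit pair carrying the planted evidence dominates
  s3 <- tokenize_trajectory(list("A", "B", c("C", "D")), vocab)
  cvs12 <- compute_cvs(w, "A", "B")
  cvs13 <- compute_cvs(w, "A", c("C", "D"))
  cvs23 <- compute_cvs(w, "B", c("C", "D"))
  pv <- c(cvs12, cvs13, cvs23) / sum(cvs12, cvs13, cvs23)
  cnt <- integer(3)
  for (r in seq_len(n_draw)) {
    o <- swap_visits(s3, 0, vocab, weights = w) # one visit pair
    blocks <- detokenize(structure(list(token_ids = o$input_ids,
                                        visit_numbers = o$visit_numbers),
                                   class = "tb_tokens"), vocab)
    if (identical(blocks[[1]], "B")) cnt[1] <- cnt[1] + 1L
    else if (identical(blocks[[3]], "A")) cnt[2] <- cnt[2] + 1L
    else cnt[3] <- cnt[3] + 1L
  }
  chi2 <- suppressWarnings(chisq.test(cnt, p = pv))
  expect_gt(chi2$p.value, 0.01)
})

test_that("expected corruption distance grows with the swap fraction", {
  set.seed(61)
  base <- tokenize_trajectory(
    lapply(1:6, function(i) sample(LETTERS[1:6], 3, TRUE)), vocab6
  )
  mean_dist <- vapply(c(0.2, 0.6, 1), function(f) {
    mean(vapply(1:150, function(r) {
      o <- swap_codes(base, f, vocab6)
      sum(o$input_ids != base$token_ids)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dist) >= 0))
})
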