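test_that("pair counting matches hand-derived counts on toy corpora", {
  corpus <- mk_corpus(list(
    P1 = list("A", "B"), P2 = list("A", "B"), P3 = list("B", "A")
  ))
  pc <- count_pairs(corpus)
  expect_equal(pc$mat["B", "A"], 2)
  expect_equal(pc$mat["A", "B"], 1)
  # single-visit trajectories contribute nothing
  pc1 <- count_pairs(mk_corpus(list(P1 = list(c("A", "B", "C")))))
  expect_true(all(pc1$mat == 0))
  # per-occurrence multiplicity: A twice in the earlier visit
  pc2 <- count_pairs(mk_corpus(list(P1 = list(c("A", "A"), "B"))))
  expect_equal(pc2$mat["B", "A"], 2)
})

test_that("pair counting equals brute-force enumeration on randomized corpora", {
  set.seed(11)
  for (rep in 1:25) {
    corpus <- random_toy_corpus(n_traj = sample.int(10, 1))
    pc <- count_pairs(corpus)
    oracle <- brute_pair_counts(corpus)
    # every nonzero oracle entry matches and nothing else is nonzero
    got <- tidy(pc)
    expect_equal(sum(got$n), sum(unlist(oracle)))
    for (k in names(oracle)) {
      ij <- strsplit(k, "\r", fixed = TRUE)[[1]]
      expect_equal(pc$mat[ij[1], ij[2]], oracle[[k]],
                   label = paste("pair", ij[1], "<-", ij[2], "rep", rep))
    }
  }
})

test_that("CCS algebra: closed form, unidirectionality, floor, monotonicity", {
  corpus <- mk_corpus(list(
    P1 = list("A", "B"), P2 = list("A", "B"), P3 = list("B", "A")
  ))
  w <- compute_ccs(count_pairs(corpus), epsilon = 0.01)
  # CCnt(B,A)=2, CCnt(A,B)=1 -> CCS(B,A) = 1/4 + eps, CCS(A,B) = eps
  expect_equal(w$ccs["B", "A"], 0.26)
  expect_equal(w$ccs["A", "B"], 0.01)
  # exhaustive over a 6-code vocabulary with random counts
  set.seed(5)
  for (rep in 1:10) {
    corpus2 <- random_toy_corpus(n_traj = 8)
    pc <- count_pairs(corpus2)
    w2 <- compute_ccs(pc, epsilon = 0.01)
    off <- which(row(w2$ccs) != col(w2$ccs))
    expect_true(all(w2$ccs[off] >= 0.01 - 1e-12)) # epsilon floor positivity
    # unidirectionality: at most one of a pair's two weights above the floor
    expect_true(all(pmin(w2$ccs, t(w2$ccs))[off] <= 0.01 + 1e-12))
    # symmetric counts give the floor on both sides
    sym <- which(pc$mat == t(pc$mat) & row(pc$mat) != col(pc$mat))
    expect_true(all(abs(w2$ccs[sym] - 0.01) < 1e-12))
  }
  # monotonicity: raising CCnt(i,j) with CCnt(j,i) fixed never decreases CCS
  pc0 <- count_pairs(corpus)
  base <- pc0$mat["B", "A"]
  prev <- -Inf
  for (add in 0:6) {
    pc0$mat["B", "A"] <- base + add
    cur <- compute_ccs(pc0, epsilon = 0.01)$ccs["B", "A"]
    expect_gte(cur, prev)
    prev <- cur
  }
  # all-zero counts: every off-diagonal weight is the floor
  w0 <- compute_ccs(count_pairs(mk_corpus(list(P1 = list(c("A", "B"))))), 0.01)
  off0 <- which(row(w0$ccs) != col(w0$ccs))
  expect_true(all(abs(w0$ccs[off0] - 0.01) < 1e-12))
})

test_that("kind scaling normalises to S(dx,dx)=1 and inversely weights shares", {
  corpus <- mk_corpus(
    list(P1 = list(c("A", "B", "M"), c("A", "M"))),
    kinds = list(P1 = list(c("dx", "dx", "rx"), c("dx", "rx")))
  )
  S <- kind_scaling(count_pairs(corpus))
  expect_equal(S["dx", "dx"], 1)
  # dx share 3/5, rx share 2/5: S(dx,rx) = (3/5)^2/((3/5)(2/5)) = 3/2
  expect_equal(S["dx", "rx"], 1.5)
  expect_equal(S["rx", "rx"], 2.25)
})

test_that("CVS sums directed CCS evidence over visit code pairs", {
  corpus <- mk_corpus(list(
    P1 = list("A", "B"), P2 = list("A", "B"), P3 = list("B", "A"),
    P4 = list("C", "B")
  ))
  w <- compute_ccs(count_pairs(corpus), epsilon = 0.01)
  expect_equal(compute_cvs(w, "A", "B"), w$ccs["B", "A"])
  expect_equal(compute_cvs(w, c("A", "C"), "B"),
               w$ccs["B", "A"] + w$ccs["B", "C"])
  # brute force over a larger cross product
  vx <- c("A", "C", "A")
  vy <- c("B", "B")
  manual <- 0
  for (a in vx) for (b in vy) manual <- manual + w$ccs[b, a]
  expect_equal(compute_cvs(w, vx, vy), manual)
  expect_equal(compute_cvs(w, character(0), "B"), 0)
  expect_equal(compute_cvs(w, "ZZZ", "B"), 0)
  # symmetric option adds the reverse direction
  expect_equal(compute_cvs(w, "A", "B", symmetric = TRUE),
               w$ccs["B", "A"] + w$ccs["A", "B"])
})

test_that("heatmap export restricts to the most frequent codes", {
  corpus <- mk_corpus(list(
    P1 = list("A", "B"), P2 = list("A", "B"), P3 = list("B", "A"),
    P4 = list(c("A", "C"), "B")
  ))
  w <- compute_ccs(count_pairs(corpus))
  hm <- export_ccs_heatmap(w, top_k = 2)
  expect_equal(dim(hm$matrix), c(2, 2))
  expect_setequal(hm$labels, c("A", "B")) # the two most frequent
  expect_true(all(diag(hm$matrix) == 0))
  expect_equal(hm$matrix["B", "A"], max(hm$matrix))
  expect_error(export_ccs_heatmap(w, top_k = 1))
  p <- autoplot(w, top_k = 3)
  expect_s3_class(p, "ggplot")
})

test_that("swap weights survive the text round-trip", {
  set.seed(8)
  corpus <- random_toy_corpus(10)
  corpus$kind[corpus$code == "F"] <- "rx"
  w <- compute_ccs(count_pairs(corpus), epsilon = 0.02)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_swap_weights(w, f)
  w2 <- load_swap_weights(f)
  expect_equal(w2$epsilon, w$epsilon)
  expect_equal(w2$scaling, w$scaling)
  expect_equal(w2$codes, w$codes)
  expect_equal(w2$ccs, w$ccs, tolerance = 1e-12)
})

test_that("planted transition asymmetry is recovered from synthetic corpora", {
  spec <- synthetic_spec(n_patients = 400, preset = "short", seed = 13)
  corpus <- generate_corpus(spec)
  fr <- filter_rare_codes(corpus, min_count = 5)
  w <- compute_ccs(count_pairs(fr$corpus))
  ok <- mapply(function(a, b) {
    ia <- match(a, w$codes); ib <- match(b, w$codes)
    if (is.na(ia) || is.na(ib)) return(NA)
    w$ccs[ib, ia] > w$ccs[ia, ib]
  }, spec$planted$from, spec$planted$to)
  expect_gte(mean(ok, na.rm = TRUE), 0.8)
})
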