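# Scripted desk-scale experiments: each function runs one self-contained
# study on synthetic data and returns the measured quantities. They are the
# package's empirical claims in executable form; the methods vignette
# discusses the problem sizes.

#' Order-objective learnability experiment
#'
#' Generates a short-regime corpus (1,000 patients), pretrains one model
#' with MLM + random visit swapping (30 epochs, fraction curriculum over
#' {0.5, 1}), and measures permutation-detection accuracy of the untrained
#' and trained model on held-out sequences across a swap-fraction grid.
#'
#' @param seed integer seed for the whole experiment.
#' @param n_patients corpus size, default 1000.
#' @param epochs pretraining epochs, default 30.
#' @param fractions evaluation grid, default 0.2, 0.4, ..., 1.0.
#' @return list: `untrained` and `curve` (tibbles from [evaluate_too()]),
#'   `monitor` (pretraining log).
#' @export
too_learnability_experiment <- function(seed = 11, n_patients = 1000,
                                        epochs = 30,
                                        fractions = seq(0.2, 1, by = 0.2)) {
  spec <- synthetic_spec(n_patients = n_patients, preset = "short",
                         seed = seed)
  corpus <- generate_corpus(spec)
  fr <- filter_rare_codes(corpus, min_count = 5)
  vocab <- fr$vocab
  seqs <- tokenize_corpus(fr$corpus, vocab, max_len = 64)
  n_hold <- max(40L, length(seqs) %/% 4L) # large held-out set: the curve
  # is the deliverable, so its accuracy estimates get the tight support
  hold <- seqs[seq_len(n_hold)]
  train <- seqs[-seq_len(n_hold)]
  cfg <- tb_config(vocab_size = vocab$size, max_len = 64)
  m0 <- tb_init_model(cfg, seed = seed, quiet = TRUE)
  untrained <- evaluate_too(m0, hold, "rvs", fractions, vocab, seed = seed + 1L)
  pcfg <- pretrain_config(epochs = epochs, too_method = "rvs",
                          too_fraction = c(0.5, 1), lr = 1e-3, w_too = 2,
                          seed = seed, patience = 8)
  pt <- pretrain(m0, train, pcfg, vocab)
  curve <- evaluate_too(pt$model, hold, "rvs", fractions, vocab,
                        seed = seed + 2L)
  list(untrained = untrained, curve = curve, monitor = pt$monitor)
}

#' Downstream headroom experiment: MLM + TOO(CCS) versus MLM-only
#'
#' One paired replicate: a 700-patient short-regime labeled corpus with an
#' order-dependent outcome; both arms share the corpus, vocabulary,
#' initialisation seed and fine-tuning examples. Each arm pretrains
#' (12 epochs), fine-tunes (3 stratified splits, 4 epochs, layer-wise decay
#' 0.7) on the ~140-example fine-tuning cohort and on 50% / 20% stratified
#' subsets, and is evaluated on a large independently generated test cohort
#' (400 patients) from the same generating process.
#'
#' @param seed integer seed; also offsets the test-cohort generator.
#' @param n_patients training-corpus size, default 700.
#' @param pre_epochs pretraining epochs per arm, default 12.
#' @return named numeric: test AUC of each arm at full/50%/20% fine-tuning
#'   (`mlm`, `too`, `mlm50`, `too50`, `mlm20`, `too20`), the generating
#'   oracle AUC on the test cohort, and the cohort sizes.
#' @export
headroom_experiment <- function(seed, n_patients = 700, pre_epochs = 12) {
  spec <- synthetic_spec(n_patients = n_patients, preset = "short",
                         seed = seed)
  lab <- generate_labeled_cohort(spec)
  parts <- split_corpus(lab$corpus, c(0.8, 0.2, 0.0), seed = seed)
  fr <- filter_rare_codes(parts$pretrain, min_count = 5)
  vocab <- fr$vocab
  seqs <- tokenize_corpus(fr$corpus, vocab, max_len = 64)
  w <- compute_ccs(count_pairs(fr$corpus))
  cfg <- tb_config(vocab_size = vocab$size, max_len = 64)
  m0 <- tb_init_model(cfg, seed = seed, quiet = TRUE)
  pc_mlm <- pretrain_config(epochs = pre_epochs, w_too = 0, lr = 5e-4,
                            seed = seed, patience = 4)
  pc_too <- pretrain_config(epochs = pre_epochs, too_method = "ccs",
                            too_fraction = 0.45, w_too = 2, lr = 5e-4,
                            seed = seed, patience = 4)
  pt_mlm <- pretrain(m0, seqs, pc_mlm, vocab)
  pt_too <- pretrain(m0, seqs, pc_too, vocab, weights = w)
  coh_ft <- suppressWarnings(
    build_code_onset_cohort(parts$finetune, "HF", min_visits = 1)
  )
  ex_ft <- suppressWarnings(cohort_to_examples(coh_ft, vocab, max_len = 64))
  spec_te <- synthetic_spec(n_patients = 400, preset = "short",
                            seed = seed + 5000L)
  lab_te <- generate_labeled_cohort(spec_te)
  coh_te <- suppressWarnings(
    build_code_onset_cohort(lab_te$corpus, "HF", min_visits = 1)
  )
  ex_te <- suppressWarnings(cohort_to_examples(coh_te, vocab, max_len = 64))
  fcfg <- finetune_config(n_splits = 3, epochs = 4, patience = 2, lr = 1e-3,
                          layer_decay = 0.7, seed = seed)
  fit_eval <- function(model, ex) {
    evaluate_auc(finetune(model, ex, fcfg), ex_te)$mean_auc[1]
  }
  ex50 <- subsample_finetune(ex_ft, 0.5, seed)
  ex20 <- subsample_finetune(ex_ft, 0.2, seed)
  c(
    mlm = fit_eval(pt_mlm$model, ex_ft),
    too = fit_eval(pt_too$model, ex_ft),
    mlm50 = fit_eval(pt_mlm$model, ex50),
    too50 = fit_eval(pt_too$model, ex50),
    mlm20 = fit_eval(pt_mlm$model, ex20),
    too20 = fit_eval(pt_too$model, ex20),
    oracle = lab_te$oracle_auc,
    n_finetune = length(ex_ft),
    n_test = length(ex_te)
  )
}
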