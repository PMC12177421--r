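# Temporal co-occurrence statistics behind the conditional swapping
# objectives. CCnt(c_i, c_j) counts, over all trajectories, occurrence pairs
# where code c_i appears in a strictly later visit than code c_j. The CCS
# weight turns the two directed counts for a pair into a one-sided
# transition-asymmetry score; CVS lifts it to visit pairs.

#' Count directed cross-visit code pairs
#'
#' For every trajectory and every ordered pair of code occurrences lying in
#' distinct visits with the first strictly earlier, increments
#' `CCnt(later_code, earlier_code)`. Multiplicity is per occurrence pair: a
#' code appearing twice in an earlier visit contributes two counts.
#'
#' @param corpus a corpus tibble (see [trajectory_tbl()]).
#' @return a `tb_pair_counts` object holding the dense count matrix (rows =
#'   later code, columns = earlier code), code labels, kinds and corpus
#'   token frequencies. Use [tidy()][generics::tidy] for a long tibble.
#' @export
count_pairs <- function(corpus) {
  validate_corpus(corpus)
  codes <- sort(unique(corpus$code))
  V <- length(codes)
  kind <- corpus$kind[match(codes, corpus$code)]
  freq <- as.integer(table(factor(corpus$code, levels = codes)))
  M <- matrix(0, V, V, dimnames = list(later = codes, earlier = codes))
  ci <- match(corpus$code, codes)
  for (ix in split(seq_len(nrow(corpus)), corpus$patient_id)) {
    vs <- corpus$visit[ix]
    if (length(unique(vs)) < 2L) next
    ids <- ci[ix]
    E <- numeric(V) # occurrence counts of codes in strictly earlier visits
    for (v in sort(unique(vs))) {
      cur <- ids[vs == v]
      cc <- tabulate(cur, nbins = V)
      nb <- which(cc > 0)
      na <- which(E > 0)
      if (length(nb) > 0 && length(na) > 0) {
        M[nb, na] <- M[nb, na] + outer(cc[nb], E[na])
      }
      E <- E + cc
    }
  }
  structure(
    list(mat = M, codes = codes, kind = kind, freq = freq),
    class = "tb_pair_counts"
  )
}

#' @export
print.tb_pair_counts <- function(x, ...) {
  cat("<tb_pair_counts> ", length(x$codes), " codes, ",
      sum(x$mat), " directed cross-visit occurrence pairs\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pair-count table
#'
#' @param x a `tb_pair_counts`.
#' @param ... unused.
#' @return tibble with `code_i` (later), `code_j` (earlier), `n`, sorted by
#'   descending count; zero-count pairs omitted.
#' @method tidy tb_pair_counts
#' @export
tidy.tb_pair_counts <- function(x, ...) {
  nz <- which(x$mat > 0, arr.ind = TRUE)
  tibble::tibble(
    code_i = x$codes[nz[, 1]],
    code_j = x$codes[nz[, 2]],
    n = x$mat[nz]
  ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$code_i, .data$code_j)
}

#' Type-pair scaling factors from corpus token shares
#'
#' Diagnosis and medication tokens can be far from balanced; the scaling
#' factor `S(kind_i, kind_j)` compensates by weighting a kind pair by the
#' inverse of its relative token share, normalised so `S(dx, dx) = 1`.
#'
#' @param pc a `tb_pair_counts`.
#' @return 2x2 named matrix over kinds `dx`, `rx`.
#' @export
kind_scaling <- function(pc) {
  tot <- sum(pc$freq)
  share <- c(
    dx = sum(pc$freq[pc$kind == "dx"]) / tot,
    rx = sum(pc$freq[pc$kind == "rx"]) / tot
  )
  S <- matrix(1, 2, 2, dimnames = list(c("dx", "rx"), c("dx", "rx")))
  if (share[["dx"]] > 0 && share[["rx"]] > 0) {
    for (a in c("dx", "rx")) for (b in c("dx", "rx")) {
      S[a, b] <- (share[["dx"]]^2) / (share[[a]] * share[[b]])
    }
  }
  S
}

#' Conditional code-swap weights (CCS)
#'
#' Converts directed pair counts into swap-sampling weights:
#' \deqn{CCS(i,j) = S_{k_i,k_j} \frac{\max(CCnt(i,j)-CCnt(j,i), 0)}
#'       {CCnt(i,j)+CCnt(j,i)+1} + \epsilon}
#' The max operator keeps only the dominant direction, turning the
#' bidirectional transition graph into a unidirectional one; the
#' denominator makes the score scale-free in corpus size; \eqn{\epsilon}
#' floors every pair at a nonzero selection probability. The closed form is
#' this package's reconstruction of the published method's statistic, whose
#' exact normalisation is not stated in the main text; the three stated
#' ingredients (max-difference numerator, kind scaling, additive epsilon)
#' are preserved.
#'
#' @param pc a `tb_pair_counts` from [count_pairs()].
#' @param epsilon additive floor, default 0.01.
#' @param scaling optional 2x2 kind-scaling matrix; default [kind_scaling()].
#' @return a `tb_swap_weights`: dense CCS matrix (rows = later code c_i,
#'   columns = earlier code c_j, diagonal 0), epsilon, scaling, code kinds
#'   and frequencies.
#' @export
compute_ccs <- function(pc, epsilon = 0.01, scaling = NULL) {
  stopifnot(epsilon > 0)
  if (is.null(scaling)) scaling <- kind_scaling(pc)
  M <- pc$mat
  Smat <- scaling[pc$kind, pc$kind, drop = FALSE]
  W <- Smat * pmax(M - t(M), 0) / (M + t(M) + 1) + epsilon
  diag(W) <- 0 # no self-pairs
  dimnames(W) <- dimnames(M)
  structure(
    list(ccs = W, codes = pc$codes, kind = pc$kind, freq = pc$freq,
         epsilon = epsilon, scaling = scaling),
    class = "tb_swap_weights"
  )
}

#' @export
print.tb_swap_weights <- function(x, ...) {
  n_dir <- sum(x$ccs > x$epsilon + 1e-12)
  cat("<tb_swap_weights> ", length(x$codes), " codes, ", n_dir,
      " directed pairs above the epsilon floor (epsilon = ", x$epsilon,
      ")\n", sep = "")
  invisible(x)
}

#' @rdname compute_ccs
#' @param x a `tb_swap_weights`.
#' @param ... unused.
#' @return for `tidy()`: tibble `code_i`, `code_j`, `ccs` sorted descending.
#' @method tidy tb_swap_weights
#' @export
tidy.tb_swap_weights <- function(x, ...) {
  idx <- which(row(x$ccs) != col(x$ccs), arr.ind = FALSE)
  ij <- arrayInd(idx, dim(x$ccs))
  tibble::tibble(
    code_i = x$codes[ij[, 1]],
    code_j = x$codes[ij[, 2]],
    ccs = x$ccs[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$ccs), .data$code_i, .data$code_j)
}

#' Look up CCS weights for code pairs
#'
#' @param weights a `tb_swap_weights`.
#' @param code_i later code(s).
#' @param code_j earlier code(s).
#' @return numeric vector of weights; pairs with an out-of-vocabulary code
#'   get the epsilon floor (unknown pairs carry no evidence).
#' @export
ccs_lookup <- function(weights, code_i, code_j) {
  ri <- match(code_i, weights$codes)
  rj <- match(code_j, weights$codes)
  out <- rep(weights$epsilon, length(ri))
  ok <- !is.na(ri) & !is.na(rj)
  out[ok] <- weights$ccs[cbind(ri[ok], rj[ok])]
  out
}

#' Conditional visit-swap weight (CVS)
#'
#' Evidence that the codes of the later visit conditionally follow those of
#' the earlier visit: the sum of `CCS(b, a)` over all code occurrences `a`
#' in the earlier visit and `b` in the later visit. Codes outside the
#' weight vocabulary are dropped; two vocabulary-empty visits give 0.
#'
#' @param weights a `tb_swap_weights`.
#' @param v_earlier,v_later character vectors of codes of the two visits
#'   (earlier visit must precede the later one in the trajectory).
#' @param symmetric if `TRUE`, also adds the reverse-direction terms
#'   `CCS(a, b)`; default `FALSE` (one-way, the reading used throughout).
#' @return a single non-negative number.
#' @export
compute_cvs <- function(weights, v_earlier, v_later, symmetric = FALSE) {
  a <- v_earlier[v_earlier %in% weights$codes]
  b <- v_later[v_later %in% weights$codes]
  if (length(a) == 0 || length(b) == 0) return(0)
  ia <- match(a, weights$codes)
  ib <- match(b, weights$codes)
  tot <- sum(weights$ccs[cbind(rep(ib, each = length(ia)),
                               rep(ia, times = length(ib)))])
  if (symmetric) {
    tot <- tot + sum(weights$ccs[cbind(rep(ia, each = length(ib)),
                                       rep(ib, times = length(ia)))])
  }
  tot
}

#' CCS heatmap over the most frequent codes
#'
#' Restricts the CCS matrix to the `top_k` most frequent codes (descending
#' corpus frequency) for display, and lists the highest-scoring directed
#' pairs.
#'
#' @param weights a `tb_swap_weights`.
#' @param top_k number of codes to keep (>= 2), default 30.
#' @return list with `matrix` (top_k x top_k, rows = later code), `labels`,
#'   and `top_pairs` (tibble of the strongest directed pairs).
#' @export
export_ccs_heatmap <- function(weights, top_k = 30) {
  stopifnot(top_k >= 2)
  ord <- order(weights$freq, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  m <- weights$ccs[keep, keep, drop = FALSE]
  tp <- tidy(weights) |> dplyr::slice_head(n = top_k)
  list(matrix = m, labels = weights$codes[keep], top_pairs = tp)
}

#' Plot the CCS heatmap
#'
#' @param object a `tb_swap_weights`.
#' @param top_k number of most frequent codes to display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tb_swap_weights
#' @export
autoplot.tb_swap_weights <- function(object, top_k = 30, ...) {
  hm <- export_ccs_heatmap(object, top_k)
  df <- tibble::tibble(
    code_i = factor(rep(hm$labels, times = length(hm$labels)), levels = hm$labels),
    code_j = factor(rep(hm$labels, each = length(hm$labels)), levels = hm$labels),
    ccs = as.vector(hm$matrix)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code_j, y = .data$code_i,
                                   fill = .data$ccs)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "CCS") +
    ggplot2::labs(x = "earlier code c_j", y = "later code c_i",
                  title = "Conditional code-swap weights") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Persist swap weights as a sorted text table
#'
#' Header lines record epsilon, the kind-scaling matrix and the code
#' vocabulary (code, kind, frequency); body lines are the directed pairs
#' whose weight exceeds the epsilon floor, sorted descending. The dense
#' matrix is reconstructed on load by flooring all other pairs at epsilon.
#'
#' @param weights a `tb_swap_weights`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_swap_weights <- function(weights, path) {
  hdr <- c(
    sprintf("# epsilon %.17g", weights$epsilon),
    sprintf("# scaling %s %s %.17g",
            rep(rownames(weights$scaling), each = 2),
            rep(colnames(weights$scaling), times = 2),
            as.vector(t(weights$scaling))),
    sprintf("# code %s %s %d", weights$codes, weights$kind, weights$freq)
  )
  tp <- tidy(weights) |>
    dplyr::filter(.data$ccs > weights$epsilon + 1e-12)
  body <- sprintf("%s\t%s\t%.17g", tp$code_i, tp$code_j, tp$ccs)
  writeLines(c(hdr, "# code_i\tcode_j\tccs", body), path)
  invisible(path)
}

#' Load swap weights written by [save_swap_weights()]
#' @param path input file.
#' @return a `tb_swap_weights`.
#' @export
load_swap_weights <- function(path) {
  lines <- readLines(path)
  eps <- as.numeric(sub("^# epsilon ", "", grep("^# epsilon ", lines, value = TRUE)))
  sc <- grep("^# scaling ", lines, value = TRUE)
  S <- matrix(1, 2, 2, dimnames = list(c("dx", "rx"), c("dx", "rx")))
  for (ln in sc) {
    p <- strsplit(ln, " +")[[1]]
    S[p[3], p[4]] <- as.numeric(p[5])
  }
  vb <- grep("^# code ", lines, value = TRUE)
  vp <- strsplit(vb, " +")
  codes <- vapply(vp, `[[`, "", 3L)
  kind <- vapply(vp, `[[`, "", 4L)
  freq <- as.integer(vapply(vp, `[[`, "", 5L))
  V <- length(codes)
  W <- matrix(eps, V, V, dimnames = list(later = codes, earlier = codes))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) > 0) {
    bp <- strsplit(body, "\t", fixed = TRUE)
    ri <- match(vapply(bp, `[[`, "", 1L), codes)
    rj <- match(vapply(bp, `[[`, "", 2L), codes)
    W[cbind(ri, rj)] <- as.numeric(vapply(bp, `[[`, "", 3L))
  }
  diag(W) <- 0
  structure(
    list(ccs = W, codes = codes, kind = kind, freq = freq,
         epsilon = eps, scaling = S),
    class = "tb_swap_weights"
  )
}
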