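#' Default HLA-A*02:01 anchor position weight matrix
#'
#' A 9 x 20 additive position weight matrix encoding the canonical
#' HLA-A*02:01 binding preferences: hydrophobic anchors at position 2
#' (leucine/methionine strongly favored) and position 9 (valine/leucine/
#' isoleucine), proline and charged residues penalized at the anchors, and
#' minor weights elsewhere. A peptide's score is the sum over positions of
#' the weight of its residue. This matrix is a deliberately simple,
#' fully-reproducible default — a declared simplification of neural binding
#' predictors, which can be plugged in through the same
#' [binding_predictor()] contract by anyone who has them installed.
#'
#' @return Numeric matrix, rows = positions 1..9, columns = [AA_STANDARD].
#' @export
anchor_pssm <- function() {
  w <- matrix(0, nrow = 9, ncol = 20, dimnames = list(NULL, AA_STANDARD))
  # P1: mild aromatic preference at the A pocket.
  w[1, c("F", "Y")] <- 0.5
  w[1, "W"] <- 0.3
  w[1, c("D", "E")] <- -0.3
  # P2: primary anchor (B pocket).
  w[2, "L"] <- 4
  w[2, "M"] <- 3
  w[2, "I"] <- 1.5
  w[2, "V"] <- 1
  w[2, c("Q", "A", "T")] <- 0.3
  w[2, "P"] <- -4
  w[2, "G"] <- -2
  w[2, c("D", "E")] <- -2
  w[2, c("K", "R")] <- -1
  # P9: C-terminal anchor (F pocket).
  w[9, "V"] <- 4
  w[9, "L"] <- 3.5
  w[9, "I"] <- 3
  w[9, c("A", "M")] <- 0.5
  w[9, c("T", "C")] <- 0.3
  w[9, "P"] <- -4
  w[9, "G"] <- -2
  w[9, c("D", "E")] <- -2
  w[9, c("K", "R")] <- -1
  w
}

#' Construct a binding predictor
#'
#' The predictor contract used throughout the pipeline: a named object whose
#' `score` function maps a character vector of peptides (of the supported
#' length) to a numeric vector where **higher = stronger predicted binding**,
#' deterministically. Adapters around external tools must invert
#' affinity-like scales (lower = stronger) before returning.
#'
#' @param score Function `character -> numeric`, vectorized over peptides.
#' @param name Identifier recorded in all outputs.
#' @param peptide_length Supported peptide length (default 9).
#' @return An object of class `"binding_predictor"`.
#' @export
binding_predictor <- function(score, name, peptide_length = 9L) {
  stopifnot(is.function(score), is_string(name))
  structure(
    list(score = score, name = name, peptide_length = as.integer(peptide_length)),
    class = "binding_predictor"
  )
}

#' Default matrix-based HLA-A*02:01 predictor
#'
#' Wraps [anchor_pssm()] in the [binding_predictor()] contract.
#'
#' @param weights Position weight matrix (positions x 20 residues).
#' @param name Identifier.
#' @return A `"binding_predictor"`.
#' @export
#' @examples
#' p <- pssm_predictor()
#' score_binding("FLSNDTVQL", p) > score_binding("FASNDTVQA", p)
pssm_predictor <- function(weights = anchor_pssm(), name = "anchorPSSM-A0201") {
  stopifnot(is.matrix(weights), ncol(weights) == 20L)
  if (any(!is.finite(weights))) stop("PSSM weights must be finite", call. = FALSE)
  k <- nrow(weights)
  colnames(weights) <- AA_STANDARD
  score <- function(peptides) {
    peptides <- toupper(peptides)
    vapply(peptides, function(pep) {
      codes <- aa_codes(aa_chars(pep))
      if (length(codes) != k || anyNA(codes)) {
        stop("predictor supports unambiguous ", k, "-mers only", call. = FALSE)
      }
      sum(weights[cbind(seq_len(k), codes)])
    }, numeric(1), USE.NAMES = FALSE)
  }
  binding_predictor(score, name, peptide_length = k)
}

#' Score predicted HLA binding of a peptide
#'
#' @param peptide Character vector of peptides.
#' @param predictor A [binding_predictor()].
#' @return Numeric score(s), higher = stronger predicted binding.
#' @export
score_binding <- function(peptide, predictor = pssm_predictor()) {
  stopifnot(inherits(predictor, "binding_predictor"))
  peptide <- toupper(as.character(peptide))
  if (any(nchar(peptide) != predictor$peptide_length)) {
    stop(
      "predictor '", predictor$name, "' supports length ",
      predictor$peptide_length, " peptides only",
      call. = FALSE
    )
  }
  predictor$score(peptide)
}

#' Sample a background peptide set from a proteome
#'
#' Draws `n` k-mer windows uniformly at random (with replacement, weighted by
#' each protein's window count) from the proteome, skipping windows with
#' ambiguity codes. Used as the reference distribution for percentile ranks,
#' so that ranks are self-contained and reproducible for any proteome.
#'
#' @param proteome Proteome data frame.
#' @param n Number of background peptides (default 100000).
#' @param k Peptide length (default 9).
#' @param seed Integer seed, recorded by the caller for provenance.
#' @return Character vector of `n` peptides.
#' @export
sample_background <- function(proteome, n = 100000L, k = 9L, seed = 1L) {
  stopifnot(is.data.frame(proteome), n >= 1)
  n_win <- pmax(nchar(proteome$sequence) - k + 1L, 0L)
  if (sum(n_win) == 0L) {
    stop("proteome has no windows of length ", k, call. = FALSE)
  }
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n && tries < 50L) {
      need <- n - length(out)
      prot <- sample.int(nrow(proteome), need, replace = TRUE, prob = n_win)
      off <- 1L + floor(runif(need) * n_win[prot])
      pep <- substring(proteome$sequence[prot], off, off + k - 1L)
      clean <- !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), pep)
      out <- c(out, pep[clean])
      tries <- tries + 1L
    }
    if (length(out) < n) {
      stop("could not sample enough unambiguous background windows", call. = FALSE)
    }
    out[seq_len(n)]
  })
}

#' Percentile rank of a peptide's binding score
#'
#' The fraction (as a percentage) of background peptides scoring **strictly**
#' higher than the peptide — 0 is the best possible rank, mirroring the
#' convention of IEDB-style percentile ranks where small means strong binder.
#' Ties do not count against the peptide.
#'
#' @param peptide Character vector of peptides.
#' @param predictor A [binding_predictor()].
#' @param background Nonempty character vector of background peptides
#'   (e.g. from [sample_background()]).
#' @return Numeric vector of ranks in `[0, 100]`.
#' @export
percentile_rank <- function(peptide, predictor, background) {
  if (length(background) == 0L) {
    stop("background must be nonempty", call. = FALSE)
  }
  bg <- sort(score_binding(background, predictor))
  s <- score_binding(peptide, predictor)
  # #(bg > s) via binary search on the sorted background.
  n_higher <- length(bg) - findInterval(s, bg, left.open = FALSE)
  100 * n_higher / length(bg)
}

#' Filter candidate peptides by HLA binding plausibility
#'
#' Retains candidates whose percentile rank is at or below `rank_threshold`
#' (default 2.0, the conventional "binder" cutoff for percentile-rank
#' predictors), annotating each retained row with `binding_score`,
#' `binding_rank`, and the predictor name.
#'
#' @param candidates Data frame with a `peptide` column (e.g. a
#'   [hit_table()] or the `candidates` of a [merge_searches()] result).
#' @param predictor A [binding_predictor()].
#' @param background Background peptide vector for rank computation.
#' @param rank_threshold Rank cutoff in `(0, 100]`.
#' @return The filtered, annotated data frame.
#' @export
filter_candidates <- function(candidates, predictor, background,
                              rank_threshold = 2.0) {
  stopifnot(is.data.frame(candidates), "peptide" %in% names(candidates))
  if (!(rank_threshold > 0 && rank_threshold <= 100)) {
    stop("rank_threshold must be in (0, 100]", call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    candidates$binding_score <- numeric(0)
    candidates$binding_rank <- numeric(0)
    candidates$predictor <- character(0)
    return(candidates)
  }
  candidates$binding_score <- score_binding(candidates$peptide, predictor)
  candidates$binding_rank <- percentile_rank(candidates$peptide, predictor, background)
  candidates$predictor <- predictor$name
  out <- candidates[candidates$binding_rank <= rank_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
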