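# Independent oracles used to cross-check the package implementations.
# Deliberately coded via different routes than the functions they check.

# Brute-force motif scan: PCRE lookahead regex over each protein (overlapping
# matches). Independent of the per-position membership scan in the package.
oracle_motif_scan <- function(proteome, motif) {
  cls <- vapply(
    motif$allowed,
    function(s) paste0("[", paste(s, collapse = ""), "]"),
    character(1)
  )
  rx <- paste0("(?=", paste(cls, collapse = ""), ")")
  parts <- lapply(seq_len(nrow(proteome)), function(i) {
    m <- gregexpr(rx, proteome$sequence[i], perl = TRUE)[[1]]
    offs <- as.integer(m[m > 0])
    if (length(offs) == 0L) return(NULL)
    data.frame(
      peptide = substring(proteome$sequence[i], offs, offs + motif$k - 1L),
      protein_id = proteome$id[i],
      offset = offs,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(
      peptide = character(), protein_id = character(), offset = integer(),
      stringsAsFactors = FALSE
    )
  }
  out[order(out$peptide, out$protein_id, out$offset), , drop = FALSE]
}

# Brute-force affine-gap Smith-Waterman, vectorized across windows
# (cell-by-cell over the 9x9 DP table, every cell computed for all windows at
# once) — structurally unlike the per-window scalar C++ kernel.
oracle_sw_scores <- function(query, windows, matrix) {
  qc <- match(strsplit(query, "")[[1]], AA_STANDARD)
  m <- length(qc)
  k <- nchar(windows[1])
  nw <- length(windows)
  wc <- base::matrix(
    match(unlist(strsplit(windows, "")), AA_STANDARD),
    nrow = k
  )
  S <- unname(matrix$scores)
  gfirst <- matrix$gap_open + matrix$gap_extend
  ge <- matrix$gap_extend
  best <- rep(0, nw)
  Hprev <- base::matrix(0, k + 1, nw)
  Fprev <- base::matrix(-Inf, k + 1, nw)
  for (i in seq_len(m)) {
    Hrow <- base::matrix(0, k + 1, nw)
    Frow <- base::matrix(-Inf, k + 1, nw)
    Ecur <- rep(-Inf, nw)
    for (j in seq_len(k)) {
      Ecur <- pmax(Hrow[j, ] - gfirst, Ecur - ge)
      Fj <- pmax(Hprev[j + 1, ] - gfirst, Fprev[j + 1, ] - ge)
      s <- S[cbind(qc[i], wc[j, ])]
      h <- pmax(0, Hprev[j, ] + s, Ecur, Fj)
      Hrow[j + 1, ] <- h
      Frow[j + 1, ] <- Fj
      best <- pmax(best, h)
    }
    Hprev <- Hrow
    Fprev <- Frow
  }
  best
}

# Brute-force window-level alignment hit set for a whole proteome.
oracle_align_search <- function(query, proteome, matrix, min_score, k = nchar(query)) {
  parts <- lapply(seq_len(nrow(proteome)), function(i) {
    wins <- enumerate_windows(proteome$sequence[i], k, proteome$id[i])
    if (nrow(wins) == 0L) return(NULL)
    sc <- oracle_sw_scores(query, wins$peptide, matrix)
    keep <- sc >= min_score
    if (!any(keep)) return(NULL)
    cbind(wins[keep, , drop = FALSE], score = sc[keep])
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(
      peptide = character(), protein_id = character(), offset = integer(),
      score = numeric(), stringsAsFactors = FALSE
    )
  }
  out[order(out$peptide, out$protein_id, out$offset), , drop = FALSE]
}

# Sort-based percentile rank (strictly-better convention).
oracle_percentile_rank <- function(peptide, predictor, background) {
  s <- score_binding(peptide, predictor)
  bs <- score_binding(background, predictor)
  vapply(s, function(x) 100 * sum(bs > x) / length(bs), numeric(1))
}

# A random unambiguous peptide.
random_peptide <- function(k = 9) {
  paste(sample(AA_STANDARD, k, replace = TRUE), collapse = "")
}

# Strip hit-set classes/attributes for plain data-frame comparisons.
plain_windows <- function(hits, cols = c("peptide", "protein_id", "offset")) {
  d <- as.data.frame(hits)[, cols, drop = FALSE]
  rownames(d) <- NULL
  d
}
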