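#' Substitution matrix for peptide local alignment
#'
#' Loads a protein substitution matrix (default BLOSUM62, from the tables
#' shipped with Biostrings), restricted to the 20 standard residues, together
#' with affine gap penalties. A gap of length L costs
#' `gap_open + gap_extend * L`. Symmetry and the diagonal-dominance property
#' (each diagonal entry is the maximum of its row — true of BLOSUM62, and the
#' property that makes a peptide's self-alignment maximal among equal-length
#' windows) are asserted at load.
#'
#' @param name Matrix name available via `data(package = "Biostrings")`,
#'   e.g. `"BLOSUM62"`, `"BLOSUM80"`, `"PAM250"`.
#' @param gap_open Nonnegative gap opening penalty (default 11).
#' @param gap_extend Nonnegative gap extension penalty (default 1).
#' @return An object of class `"substitution_matrix"`: list with `scores`
#'   (20x20 named numeric matrix), `name`, `gap_open`, `gap_extend`.
#' @export
#' @examples
#' substitution_matrix()$scores["F", "F"]
substitution_matrix <- function(name = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  full <- get(name, envir = env)
  scores <- full[AA_STANDARD, AA_STANDARD]
  if (!isTRUE(all.equal(scores, t(scores)))) {
    stop("substitution matrix is not symmetric", call. = FALSE)
  }
  if (!all(diag(scores) == apply(scores, 1, max))) {
    stop("substitution matrix diagonal entries are not row maxima", call. = FALSE)
  }
  structure(
    list(
      scores = scores, name = name,
      gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend)
    ),
    class = "substitution_matrix"
  )
}

# Integer codes for an unambiguous peptide/sequence; errors on residues
# absent from the matrix alphabet.
codes_or_stop <- function(sequence, what) {
  codes <- aa_codes(aa_chars(sequence))
  if (anyNA(codes)) {
    stop(what, " contains residue(s) absent from the substitution matrix",
      call. = FALSE
    )
  }
  codes
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman local alignment with affine gaps (Gotoh recurrences),
#' scores clamped at zero per local-alignment semantics. One optimal
#' traceback is returned; ties are broken by preferring the diagonal
#' (match/mismatch) move, then the vertical (gap in target), then the
#' horizontal (gap in query).
#'
#' @param query,target Peptide strings over the standard alphabet.
#' @param matrix A [substitution_matrix()].
#' @return An object of class `"alignment_hit"`: list with `score` and
#'   `aligned_pairs`, a data frame of (`query_pos`, `target_pos`) with `NA`
#'   marking a gap.
#' @export
#' @examples
#' local_align("FLSNDTVQL", "FLSNDTVQL")$score # 44 under BLOSUM62
local_align <- function(query, target, matrix = substitution_matrix()) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  query <- toupper(as.character(query))
  target <- toupper(as.character(target))
  if (!nzchar(query) || !nzchar(target)) {
    stop("query and target must be nonempty", call. = FALSE)
  }
  q <- codes_or_stop(query, "query")
  t <- codes_or_stop(target, "target")
  m <- length(q)
  n <- length(t)
  og <- matrix$gap_open
  ge <- matrix$gap_extend
  gfirst <- og + ge
  S <- matrix$scores
  neg <- -Inf
  H <- base::matrix(0, m + 1, n + 1)
  E <- base::matrix(neg, m + 1, n + 1) # gap in query (horizontal)
  F <- base::matrix(neg, m + 1, n + 1) # gap in target (vertical)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gfirst, E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gfirst, F[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(
        0,
        H[i, j] + S[q[i], t[j]],
        F[i + 1, j + 1],
        E[i + 1, j + 1]
      )
    }
  }
  score <- max(H)
  # Deterministic argmax: smallest i, then smallest j.
  hit <- which(H == score, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[[1]] - 1L
  j <- hit[[2]] - 1L
  pairs <- list()
  state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i + 1, j + 1] == 0) break
      if (i > 0 && j > 0 && H[i + 1, j + 1] == H[i, j] + S[q[i], t[j]]) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
        i <- i - 1L
        j <- j - 1L
      } else if (H[i + 1, j + 1] == F[i + 1, j + 1]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {
      pairs[[length(pairs) + 1L]] <- c(i, NA_integer_)
      from_h <- H[i, j + 1] - gfirst
      from_f <- F[i, j + 1] - ge
      state <- if (F[i + 1, j + 1] == from_h) "H" else "F"
      i <- i - 1L
    } else {
      pairs[[length(pairs) + 1L]] <- c(NA_integer_, j)
      from_h <- H[i + 1, j] - gfirst
      state <- if (E[i + 1, j + 1] == from_h) "H" else "E"
      j <- j - 1L
    }
  }
  aligned <- if (length(pairs) > 0) {
    do.call(rbind, rev(pairs))
  } else {
    base::matrix(integer(), 0, 2)
  }
  structure(
    list(
      score = score,
      aligned_pairs = data.frame(
        query_pos = aligned[, 1],
        target_pos = aligned[, 2]
      ),
      query = query, target = target, matrix = matrix$name
    ),
    class = "alignment_hit"
  )
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat("<alignment_hit> score", x$score, "(", x$matrix, ")\n")
  invisible(x)
}

#' Default minimum alignment score for the similarity search
#'
#' 60% of the query's self-alignment score, rounded down — recorded in the
#' pipeline provenance.
#'
#' @param query The epitope peptide.
#' @param matrix A [substitution_matrix()].
#' @return Integer threshold.
#' @export
default_min_score <- function(query, matrix = substitution_matrix()) {
  q <- codes_or_stop(toupper(as.character(query)), "query")
  floor(0.6 * sum(diag(matrix$scores)[q]))
}

#' Similarity search of an epitope against a proteome
#'
#' Aligns the query epitope against every length-k window of every protein
#' (exhaustive per-window Smith-Waterman) and keeps windows whose optimal
#' local score reaches `min_score`. For a short peptide query this exhaustive
#' search is exact and reproducible, serving as the in-package analog of a
#' protein BLAST search of the epitope. Self-hits are flagged as in
#' [scan_proteome()].
#'
#' @param query The epitope peptide.
#' @param proteome Proteome data frame ([read_fasta()] format).
#' @param matrix A [substitution_matrix()].
#' @param min_score Positive score threshold; default
#'   [default_min_score()] of the query.
#' @param k Window length (default: query length).
#' @param search Provenance label (default `"search3"`).
#' @return A `"peptide_hits"` data frame with an additional `score` column
#'   (per-window optimal local score).
#' @export
#' @examples
#' sim <- generate_proteome(n_proteins = 3, length_range = c(40, 60), seed = 5)
#' search_by_similarity("FLSNDTVQL", sim$proteome)
search_by_similarity <- function(query, proteome, matrix = substitution_matrix(),
                                 min_score = default_min_score(query, matrix),
                                 k = nchar(as.character(query)),
                                 search = "search3") {
  stopifnot(is.data.frame(proteome), inherits(matrix, "substitution_matrix"))
  query <- toupper(as.character(query))
  if (!(min_score > 0)) stop("min_score must be positive", call. = FALSE)
  q <- codes_or_stop(query, "query")
  parts <- lapply(seq_len(nrow(proteome)), function(i) {
    wins <- enumerate_windows(proteome$sequence[i], k, proteome$id[i])
    if (nrow(wins) == 0L) return(NULL)
    tcodes <- aa_codes(aa_chars(proteome$sequence[i]))
    tcodes[is.na(tcodes)] <- 1L # masked; such windows are never in `wins`
    scores <- sw_window_scores_cpp(
      q, tcodes, as.integer(k), wins$offset,
      matrix$scores, matrix$gap_open, matrix$gap_extend
    )
    keep <- scores >= min_score
    if (!any(keep)) return(NULL)
    cbind(wins[keep, , drop = FALSE], score = scores[keep])
  })
  windows <- do.call(rbind, c(parts, list(
    data.frame(
      peptide = character(), protein_id = character(), offset = integer(),
      score = numeric(), stringsAsFactors = FALSE
    )
  )))
  hits <- new_peptide_hits(windows, query, search)
  attr(hits, "min_score") <- min_score
  hits
}
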