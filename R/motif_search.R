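#' Physicochemical amino-acid similarity classes
#'
#' A partition of the 20 standard residues into physicochemical classes, used
#' to relax contact positions in the expanded motif search: a cross-reactive
#' peptide need not carry the identical contact residue if a chemically
#' similar one can make an equivalent TCR contact. The default grouping is
#' the conventional one — small (A, G), aliphatic (I, L, M, V), aromatic
#' (F, W, Y), basic (K, R, H), acidic (D, E), amide (N, Q), hydroxyl (S, T),
#' with cysteine and proline kept alone. Any partition may be supplied.
#'
#' @param groups Named list of character vectors partitioning [AA_STANDARD].
#' @return An object of class `"similarity_classes"`.
#' @export
#' @examples
#' cls <- similarity_classes()
#' expand_residue(cls, "S")
similarity_classes <- function(groups = list(
                                 small = c("A", "G"),
                                 aliphatic = c("I", "L", "M", "V"),
                                 aromatic = c("F", "W", "Y"),
                                 basic = c("K", "R", "H"),
                                 acidic = c("D", "E"),
                                 amide = c("N", "Q"),
                                 hydroxyl = c("S", "T"),
                                 cysteine = "C",
                                 proline = "P"
                               )) {
  all_res <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_res) || !setequal(all_res, AA_STANDARD)) {
    stop("groups must partition the 20 standard residues", call. = FALSE)
  }
  membership <- stats::setNames(
    rep(names(groups), lengths(groups)),
    unlist(groups, use.names = FALSE)
  )
  structure(list(groups = groups, membership = membership),
    class = "similarity_classes"
  )
}

#' @rdname similarity_classes
#' @param classes A `similarity_classes` object.
#' @param residue One-letter residue code.
#' @return `expand_residue()`: the sorted character vector of residues in the
#'   residue's class (always contains the residue itself).
#' @export
expand_residue <- function(classes, residue) {
  stopifnot(inherits(classes, "similarity_classes"))
  grp <- classes$membership[[residue]]
  sort(classes$groups[[grp]])
}

#' Identity similarity classes (each residue its own class)
#'
#' Under identity classes [expand_motif()] is a no-op; useful as a control.
#'
#' @return A `similarity_classes` object.
#' @export
identity_classes <- function() {
  similarity_classes(stats::setNames(as.list(AA_STANDARD), AA_STANDARD))
}

#' Expand a recognition motif by similarity classes
#'
#' Replaces the allowed set at every constrained (contact) position with the
#' union of the similarity classes of its members. Unconstrained positions
#' are unchanged. The expanded motif's language is always a superset of the
#' input's, so the expanded search can only add hits.
#'
#' @param motif A [build_motif()] result.
#' @param classes A [similarity_classes()] object.
#' @return A `"recognition_motif"`.
#' @export
expand_motif <- function(motif, classes = similarity_classes()) {
  stopifnot(inherits(motif, "recognition_motif"), inherits(classes, "similarity_classes"))
  allowed <- lapply(motif$allowed, function(s) {
    if (length(s) == length(AA_STANDARD)) {
      s
    } else {
      sort(unique(unlist(lapply(s, function(r) expand_residue(classes, r)))))
    }
  })
  structure(list(k = motif$k, allowed = allowed), class = "recognition_motif")
}

# Offsets of motif-matching windows in one sequence (vectorized per-position
# set membership; ambiguity codes never match).
motif_match_offsets <- function(sequence, motif) {
  L <- nchar(sequence)
  k <- motif$k
  if (L < k) return(integer())
  codes <- aa_codes(aa_chars(sequence))
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (p in seq_len(k)) {
    allowed_mask <- AA_STANDARD %in% motif$allowed[[p]]
    idx <- codes[p:(p + n_win - 1L)]
    ok <- ok & !is.na(idx) & allowed_mask[ifelse(is.na(idx), 1L, idx)]
  }
  which(ok)
}

# Assemble a window-level hit object. Sorted by peptide, protein_id, offset;
# is_self marks windows identical to the query epitope.
new_peptide_hits <- function(windows, query, search) {
  if (nrow(windows) > 0) {
    windows$search <- search
    windows$is_self <- if (is.null(query)) {
      FALSE
    } else {
      windows$peptide == as.character(query)
    }
    windows <- windows[order(windows$peptide, windows$protein_id, windows$offset), ,
      drop = FALSE
    ]
    rownames(windows) <- NULL
  } else {
    windows$search <- character()
    windows$is_self <- logical()
  }
  structure(windows,
    class = c("peptide_hits", "data.frame"),
    query = if (is.null(query)) NULL else as.character(query),
    search = search
  )
}

#' Scan a proteome for motif-matching peptides
#'
#' Linear scan of every k-mer window of every protein against a recognition
#' motif (the exact contact-motif search, or — with an [expand_motif()]ed
#' motif — the similarity-class-expanded search). Windows equal to the query
#' epitope itself are reported but flagged `is_self`; by construction the
#' source peptide is present in its own proteome and is not a
#' cross-reactivity candidate.
#'
#' @param proteome Proteome data frame ([read_fasta()] format).
#' @param motif A `"recognition_motif"`.
#' @param query The epitope peptide, used only to flag self-hits (optional).
#' @param search Provenance label stored with each hit (e.g. `"search1"`).
#' @return A `"peptide_hits"` data frame: one row per matching window with
#'   columns `peptide`, `protein_id`, `offset`, `search`, `is_self`, sorted
#'   by peptide, then protein id, then offset. Use [hit_table()] for the
#'   per-unique-peptide view.
#' @export
#' @examples
#' sim <- generate_proteome(n_proteins = 5, length_range = c(50, 80), seed = 3)
#' scan <- generate_scan_table(seed = 3)
#' motif <- build_motif(classify_positions(scan))
#' scan_proteome(sim$proteome, motif, query = scan$wild_type)
scan_proteome <- function(proteome, motif, query = NULL, search = "search1") {
  stopifnot(is.data.frame(proteome), inherits(motif, "recognition_motif"))
  parts <- lapply(seq_len(nrow(proteome)), function(i) {
    offs <- motif_match_offsets(proteome$sequence[i], motif)
    if (length(offs) == 0L) return(NULL)
    data.frame(
      peptide = substring(proteome$sequence[i], offs, offs + motif$k - 1L),
      protein_id = proteome$id[i],
      offset = as.integer(offs),
      stringsAsFactors = FALSE
    )
  })
  windows <- do.call(rbind, c(parts, list(
    data.frame(
      peptide = character(), protein_id = character(), offset = integer(),
      stringsAsFactors = FALSE
    )
  )))
  new_peptide_hits(windows, query, search)
}

#' Aggregate window-level hits to unique peptides
#'
#' @param hits A `"peptide_hits"` object (or the window-level data frame of a
#'   [merge_searches()] result).
#' @return Data frame with one row per distinct peptide sequence: `peptide`,
#'   `found_by` (semicolon-joined sorted search labels), `n_windows`,
#'   `protein_ids`, `offsets` (semicolon-joined, paired), `is_self`, and
#'   `align_score` (max over windows; `NA` when no alignment scores exist).
#'   Rows are sorted by peptide.
#' @export
hit_table <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(data.frame(
      peptide = character(), found_by = character(), n_windows = integer(),
      protein_ids = character(), offsets = character(), is_self = logical(),
      align_score = numeric(), stringsAsFactors = FALSE
    ))
  }
  hits <- as.data.frame(hits)
  hits <- hits[order(hits$peptide, hits$protein_id, hits$offset), , drop = FALSE]
  sp <- split(hits, hits$peptide)
  out <- do.call(rbind, lapply(sp, function(d) {
    win <- unique(d[, c("protein_id", "offset")])
    win <- win[order(win$protein_id, win$offset), , drop = FALSE]
    data.frame(
      peptide = d$peptide[1],
      found_by = paste(sort(unique(d$search)), collapse = ";"),
      n_windows = nrow(win),
      protein_ids = paste(win$protein_id, collapse = ";"),
      offsets = paste(win$offset, collapse = ";"),
      is_self = any(d$is_self),
      align_score = if ("score" %in% names(d) && any(!is.na(d$score))) {
        max(d$score, na.rm = TRUE)
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}
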