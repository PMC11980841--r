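#' Merge the three searches into a candidate set
#'
#' Union by peptide sequence of the hit lists of the exact-motif search, the
#' similarity-class-expanded search, and the alignment search, with per-search
#' provenance (`found_by`) and all window coordinates merged. Hits identical
#' to the query epitope are self-hits: by construction the source peptide is
#' in its own proteome, so they are reported separately and excluded from the
#' candidate list. Inputs claiming different peptides at the same
#' (protein, offset) coordinate indicate the searches were run on different
#' proteomes and are an error.
#'
#' @param s1,s2,s3 `"peptide_hits"` objects (any may be empty); typically the
#'   outputs of [scan_proteome()] on the plain and expanded motif and of
#'   [search_by_similarity()].
#' @param query The epitope peptide.
#' @param provenance Optional named list snapshotting the run configuration
#'   (thresholds, seeds, proteome digest); stored verbatim.
#' @return An object of class `"candidate_set"`: list with `candidates`
#'   (unique-peptide data frame, sorted by peptide, self-hits excluded),
#'   `self` (the excluded self-hit rows), `windows` (merged window-level data
#'   frame), `query`, and `provenance`.
#' @export
merge_searches <- function(s1, s2, s3, query, provenance = list()) {
  query <- validate_peptide(as.character(query))
  pieces <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(s1, s2, s3))
  cols <- c("peptide", "protein_id", "offset", "search", "is_self", "score")
  pieces <- lapply(pieces, function(d) {
    d <- as.data.frame(d)
    if (!"score" %in% names(d)) d$score <- NA_real_
    d[, cols]
  })
  windows <- do.call(rbind, c(pieces, list(
    data.frame(
      peptide = character(), protein_id = character(), offset = integer(),
      search = character(), is_self = logical(), score = numeric(),
      stringsAsFactors = FALSE
    )
  )))
  if (nrow(windows) > 0) {
    coord <- paste(windows$protein_id, windows$offset, sep = "\r")
    n_pep <- tapply(windows$peptide, coord, function(p) length(unique(p)))
    if (any(n_pep > 1)) {
      stop(
        "conflicting window provenance: the same (protein, offset) maps to ",
        "different peptides across searches — were the searches run on the ",
        "same proteome and k?",
        call. = FALSE
      )
    }
    windows <- windows[order(windows$peptide, windows$protein_id, windows$offset, windows$search), ]
    rownames(windows) <- NULL
  }
  tab <- hit_table(windows)
  candidates <- tab[!tab$is_self, , drop = FALSE]
  rownames(candidates) <- NULL
  structure(
    list(
      candidates = candidates,
      self = tab[tab$is_self, , drop = FALSE],
      windows = windows,
      query = query,
      provenance = provenance
    ),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(
    "<candidate_set> query ", unclass(x$query), ": ",
    nrow(x$candidates), " unique candidate peptide(s), ",
    nrow(x$self), " self-hit(s) excluded\n",
    sep = ""
  )
  if (nrow(x$candidates) > 0) {
    print(utils::head(x$candidates, 10), row.names = FALSE)
    if (nrow(x$candidates) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Export a candidate set
#'
#' TSV export writes one row per candidate with columns `peptide`,
#' `found_by`, `n_windows`, `protein_ids`, `offsets`, `align_score`,
#' `binding_score`, `binding_rank` (the last two `NA` unless
#' [filter_candidates()] annotated them). FASTA export writes one record per
#' candidate with headers `candidate_<i>|found_by=<searches>`.
#'
#' @param cset A [merge_searches()] result (or any data frame with the TSV
#'   columns, via `candidates =`).
#' @param path Output path.
#' @param format `"tsv"` or `"fasta"`.
#' @return Invisibly, `path`.
#' @export
export_candidates <- function(cset, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  cand <- if (inherits(cset, "candidate_set")) cset$candidates else cset
  stopifnot(is.data.frame(cand))
  for (col in c("align_score", "binding_score", "binding_rank")) {
    if (!col %in% names(cand)) cand[[col]] <- NA_real_
  }
  if (format == "tsv") {
    out <- cand[, c(
      "peptide", "found_by", "n_windows", "protein_ids", "offsets",
      "align_score", "binding_score", "binding_rank"
    )]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(cand) > 0) {
      recs <- Biostrings::AAStringSet(cand$peptide)
      names(recs) <- sprintf("candidate_%04d|found_by=%s", seq_len(nrow(cand)), cand$found_by)
      Biostrings::writeXStringSet(recs, path)
    } else {
      file.create(path)
    }
  }
  invisible(path)
}

#' Read back an exported candidate TSV
#'
#' @param path Path written by [export_candidates()] with `format = "tsv"`.
#' @return Data frame with the exported columns.
#' @export
read_candidates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    peptide = "character", found_by = "character", n_windows = "integer",
    protein_ids = "character", offsets = "character",
    align_score = "numeric", binding_score = "numeric", binding_rank = "numeric"
  ))
}

#' Write the provenance snapshot of a candidate set
#'
#' YAML sidecar recording everything needed to re-run the assembly
#' bit-identically: query, thresholds, similarity classes, predictor name,
#' seeds, and the proteome digest.
#'
#' @param cset A `"candidate_set"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(cset, path) {
  stopifnot(inherits(cset, "candidate_set"))
  yaml::write_yaml(
    c(list(query = as.character(cset$query)), cset$provenance),
    path
  )
  invisible(path)
}
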