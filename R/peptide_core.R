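#' Validate an epitope peptide
#'
#' Checks that a raw string is a peptide over the 20 standard amino acids and
#' normalizes it to uppercase. Epitope queries must be unambiguous: ambiguity
#' codes (X, B, Z, U) are rejected here, unlike in proteome sequences where
#' windows containing them are silently skipped.
#'
#' @param raw Character scalar, the peptide in one-letter code (any case).
#' @return A character scalar of class `"epitope_peptide"`, uppercase, with
#'   length accessible via [nchar()]. Positions are addressed 1-based
#'   (position 1 = N-terminal residue).
#' @export
#' @examples
#' validate_peptide("FLSNDTVQL")
#' nchar(validate_peptide("flsndtvql"))
validate_peptide <- function(raw) {
  if (!is_string(raw) || !nzchar(raw)) {
    stop("epitope peptide must be a nonempty string", call. = FALSE)
  }
  pep <- toupper(raw)
  bad <- setdiff(unique(aa_chars(pep)), AA_STANDARD)
  if (length(bad) > 0L) {
    stop(
      "epitope peptide contains non-standard residue(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(pep, class = "epitope_peptide")
}

#' @export
print.epitope_peptide <- function(x, ...) {
  cat("<epitope_peptide> ", unclass(x), " (k = ", nchar(x), ")\n", sep = "")
  invisible(x)
}

#' Enumerate k-mer windows of a protein
#'
#' Yields every contiguous length-`k` window of a protein sequence in offset
#' order. Windows containing any residue outside the 20-letter standard
#' alphabet (ambiguity codes such as X, B, Z, U) are skipped: match semantics
#' are undefined there and real proteomes do contain them.
#'
#' @param sequence Character scalar, the protein sequence (uppercase).
#' @param k Window length (>= 1).
#' @param protein_id Accession recorded in the output (default `"protein"`).
#' @return A data frame with columns `peptide`, `protein_id`, `offset`
#'   (1-based start). For an unambiguous protein of length L >= k there are
#'   exactly L - k + 1 rows; `k` longer than the protein gives zero rows.
#' @export
#' @examples
#' enumerate_windows("MKTAYIAKQR", 9, "demo")
enumerate_windows <- function(sequence, k, protein_id = "protein") {
  stopifnot(is_string(sequence), k >= 1)
  L <- nchar(sequence)
  empty <- data.frame(
    peptide = character(), protein_id = character(), offset = integer(),
    stringsAsFactors = FALSE
  )
  if (L < k) return(empty)
  codes <- aa_codes(aa_chars(sequence))
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (p in seq_len(k)) {
    ok <- ok & !is.na(codes[p:(p + n_win - 1L)])
  }
  offsets <- which(ok)
  if (length(offsets) == 0L) return(empty)
  data.frame(
    peptide = substring(sequence, offsets, offsets + k - 1L),
    protein_id = protein_id,
    offset = as.integer(offsets),
    stringsAsFactors = FALSE
  )
}

#' Read a proteome from FASTA
#'
#' Reads a multi-record amino-acid FASTA file. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description. Sequences are uppercased on read. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence` — the
#'   package's proteome representation.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  if (is.null(headers)) headers <- character(length(aas))
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate FASTA ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(as.character(aas))
  if (length(seqs) > 0 && any(!nzchar(seqs))) {
    stop("empty sequence in FASTA record", call. = FALSE)
  }
  data.frame(
    id = ids, description = desc, sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write a proteome to FASTA
#'
#' @param proteome Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  aas <- Biostrings::AAStringSet(proteome$sequence)
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  headers <- ifelse(nzchar(desc), paste(proteome$id, desc), proteome$id)
  names(aas) <- headers
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}
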