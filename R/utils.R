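#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard proteinogenic amino acids, in
#' alphabetical order. This is the alphabet over which epitopes, motifs and
#' scoring matrices are defined; anything else (X, B, Z, U, ...) is treated as
#' an ambiguity code.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' AA_STANDARD
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Integer codes 1..20 into AA_STANDARD; NA for ambiguity codes.
aa_codes <- function(chars) match(chars, AA_STANDARD)

aa_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# md5 of a proteome's id/sequence content, for provenance snapshots.
proteome_digest <- function(proteome) {
  stopifnot(is.data.frame(proteome))
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(paste(proteome$id, proteome$sequence, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}
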