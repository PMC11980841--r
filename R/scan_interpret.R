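#' Construct a positional scan table
#'
#' Container for a positional (alanine/glycine) substitution scan of an
#' epitope: one single-substitution variant per position, each with the
#' measured effector response (e.g. IFN-gamma pg/ml from a coculture
#' supernatant) and a predicted MHC-binding value. Where the wild-type
#' residue is alanine the scan variant is conventionally glycine; the table
#' simply records whichever residue was used.
#'
#' @param wild_type The epitope, a string or [validate_peptide()] result.
#' @param wt_response Wild-type response (> 0), same units as the variants.
#' @param wt_predicted_binding Wild-type predicted binding value (> 0).
#' @param variants Data frame with columns `position`, `substituted_residue`,
#'   `response`, `predicted_binding`; exactly one row per position `1..k`.
#' @param orientation How `predicted_binding` is oriented: `"affinity"`
#'   (affinity-like, lower = stronger binding, e.g. predicted IC50) or
#'   `"score"` (higher = stronger).
#' @return An object of class `"scan_table"`.
#' @seealso [classify_positions()], [generate_scan_table()],
#'   [read_scan_table()]
#' @export
scan_table <- function(wild_type, wt_response, wt_predicted_binding, variants,
                       orientation = c("affinity", "score")) {
  wild_type <- validate_peptide(as.character(wild_type))
  orientation <- match.arg(orientation)
  k <- nchar(wild_type)
  stopifnot(
    is.numeric(wt_response), length(wt_response) == 1L,
    is.numeric(wt_predicted_binding), length(wt_predicted_binding) == 1L,
    is.data.frame(variants)
  )
  if (!(wt_response > 0)) stop("wt_response must be positive", call. = FALSE)
  if (!(wt_predicted_binding > 0)) {
    stop("wt_predicted_binding must be positive", call. = FALSE)
  }
  need <- c("position", "substituted_residue", "response", "predicted_binding")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  variants <- variants[order(variants$position), need]
  if (!identical(as.integer(variants$position), seq_len(k))) {
    stop("scan is incomplete: need exactly one variant per position 1..", k,
      call. = FALSE
    )
  }
  variants$substituted_residue <- toupper(variants$substituted_residue)
  wt_res <- aa_chars(wild_type)
  if (any(variants$substituted_residue == wt_res)) {
    stop("substituted residue equals the wild-type residue at some position",
      call. = FALSE
    )
  }
  if (any(!variants$substituted_residue %in% AA_STANDARD)) {
    stop("substituted residues must be standard amino acids", call. = FALSE)
  }
  if (any(variants$response < 0) || any(variants$predicted_binding <= 0)) {
    stop("responses must be >= 0 and predicted binding values > 0", call. = FALSE)
  }
  structure(
    list(
      wild_type = wild_type,
      wt_response = as.numeric(wt_response),
      wt_predicted_binding = as.numeric(wt_predicted_binding),
      orientation = orientation,
      variants = variants
    ),
    class = "scan_table"
  )
}

#' @export
print.scan_table <- function(x, ...) {
  cat("<scan_table> ", unclass(x$wild_type),
    " | wt response ", format(x$wt_response),
    ", wt binding ", format(x$wt_predicted_binding),
    " (", x$orientation, ")\n",
    sep = ""
  )
  print(x$variants, row.names = FALSE)
  invisible(x)
}

# Fold-worsening of predicted binding for each variant, on the declared
# orientation (affinity-like: variant/wt; score-like: wt/variant).
binding_fold_worsening <- function(scan) {
  v <- scan$variants$predicted_binding
  wt <- scan$wt_predicted_binding
  switch(scan$orientation, affinity = v / wt, score = wt / v)
}

#' Classify epitope positions from a positional scan
#'
#' Labels every epitope position as `anchor`, `contact`, or `tolerant`:
#'
#' * **anchor** — the substitution worsens predicted MHC binding by at least
#'   `theta_b`-fold relative to wild type. Anchor takes precedence over
#'   contact: a substitution that destroys presentation abolishes the
#'   response for reasons other than TCR contact.
#' * **contact** — not an anchor, and the variant response is at most
#'   `theta_r` times the wild-type response (threshold inclusive).
#' * **tolerant** — neither.
#'
#' @param scan A [scan_table()].
#' @param theta_r Response fraction threshold in (0, 1); default 0.1.
#' @param theta_b Binding fold-worsening threshold (> 1); default 5.
#' @return An object of class `"position_classification"`: list with `labels`
#'   (character vector of length k), `theta_r`, `theta_b`, `wild_type`.
#'   Thresholds are recorded with the result for provenance.
#' @export
#' @examples
#' scan <- generate_scan_table(seed = 1)
#' classify_positions(scan)
classify_positions <- function(scan, theta_r = 0.1, theta_b = 5) {
  stopifnot(inherits(scan, "scan_table"))
  if (!(theta_r > 0 && theta_r < 1)) {
    stop("theta_r must be in (0, 1)", call. = FALSE)
  }
  if (!(theta_b > 1)) stop("theta_b must be > 1", call. = FALSE)
  fold <- binding_fold_worsening(scan)
  anchor <- fold >= theta_b
  contact <- !anchor & scan$variants$response <= theta_r * scan$wt_response
  labels <- ifelse(anchor, "anchor", ifelse(contact, "contact", "tolerant"))
  structure(
    list(
      labels = labels,
      theta_r = theta_r,
      theta_b = theta_b,
      wild_type = scan$wild_type
    ),
    class = "position_classification"
  )
}

#' @export
print.position_classification <- function(x, ...) {
  cat("<position_classification> ", unclass(x$wild_type), "\n", sep = "")
  cat("  anchors:  {", paste(which(x$labels == "anchor"), collapse = ","), "}\n")
  cat("  contacts: {", paste(which(x$labels == "contact"), collapse = ","), "}\n")
  cat("  tolerant: {", paste(which(x$labels == "tolerant"), collapse = ","), "}\n")
  cat("  theta_r =", x$theta_r, " theta_b =", x$theta_b, "\n")
  invisible(x)
}

#' Positions carrying a given label
#'
#' @param classification A [classify_positions()] result.
#' @param label One of `"anchor"`, `"contact"`, `"tolerant"`.
#' @return Integer vector of 1-based positions.
#' @export
positions_with_label <- function(classification, label) {
  stopifnot(inherits(classification, "position_classification"))
  which(classification$labels == match.arg(label, c("anchor", "contact", "tolerant")))
}

#' Build the TCR recognition motif from a position classification
#'
#' Contact positions are constrained to the wild-type residue; anchor and
#' tolerant positions are left unconstrained (full 20-letter alphabet).
#' Binding plausibility at anchor positions is enforced downstream by the
#' HLA filter, not by the motif. A scan yielding zero contact positions is
#' uninformative (the motif would match every k-mer) and is an error.
#'
#' @param classification A [classify_positions()] result.
#' @param wild_type The epitope; defaults to the one stored in the
#'   classification.
#' @return An object of class `"recognition_motif"`: list with `k` and
#'   `allowed`, a length-k list of allowed-residue character vectors. A
#'   peptide matches the motif iff its residue at every position is in that
#'   position's allowed set.
#' @export
#' @examples
#' scan <- generate_scan_table(seed = 1)
#' build_motif(classify_positions(scan))
build_motif <- function(classification, wild_type = classification$wild_type) {
  stopifnot(inherits(classification, "position_classification"))
  wild_type <- validate_peptide(as.character(wild_type))
  k <- nchar(wild_type)
  if (length(classification$labels) != k) {
    stop("classification and wild type have different lengths", call. = FALSE)
  }
  contacts <- which(classification$labels == "contact")
  if (length(contacts) == 0L) {
    stop(
      "no contact positions: the scan is uninformative and the motif would ",
      "match every peptide",
      call. = FALSE
    )
  }
  wt_res <- aa_chars(wild_type)
  allowed <- lapply(seq_len(k), function(p) {
    if (p %in% contacts) wt_res[p] else AA_STANDARD
  })
  structure(list(k = k, allowed = allowed), class = "recognition_motif")
}

#' @export
print.recognition_motif <- function(x, ...) {
  pat <- vapply(x$allowed, function(s) {
    if (length(s) == length(AA_STANDARD)) "x" else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  cat("<recognition_motif> k =", x$k, "\n  ", paste(pat, collapse = "-"), "\n")
  invisible(x)
}

#' Does a peptide match a recognition motif?
#'
#' @param peptide Character vector of length-k peptides.
#' @param motif A [build_motif()] or [expand_motif()] result.
#' @return Logical vector.
#' @export
matches_motif <- function(peptide, motif) {
  stopifnot(inherits(motif, "recognition_motif"))
  vapply(peptide, function(pep) {
    if (nchar(pep) != motif$k) return(FALSE)
    res <- aa_chars(pep)
    all(vapply(seq_len(motif$k), function(p) res[p] %in% motif$allowed[[p]], logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Read / write a scan table as TSV
#'
#' The TSV carries the wild-type metadata in `#key<TAB>value` header lines
#' (`wild_type`, `wt_response`, `wt_predicted_binding`, `orientation`)
#' followed by a standard header row and one row per variant.
#'
#' @param path File path.
#' @return `read_scan_table()` returns a [scan_table()];
#'   `write_scan_table()` invisibly returns `path`.
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, `[`, character(1), 2L),
    vapply(kv, `[`, character(1), 1L)
  )
  need <- c("wild_type", "wt_response", "wt_predicted_binding", "orientation")
  if (!all(need %in% names(meta))) {
    stop("scan TSV is missing header metadata: ",
      paste(setdiff(need, names(meta)), collapse = ", "),
      call. = FALSE
    )
  }
  body <- read.delim(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  scan_table(
    wild_type = meta[["wild_type"]],
    wt_response = as.numeric(meta[["wt_response"]]),
    wt_predicted_binding = as.numeric(meta[["wt_predicted_binding"]]),
    variants = body,
    orientation = meta[["orientation"]]
  )
}

#' @rdname read_scan_table
#' @param scan A [scan_table()].
#' @export
write_scan_table <- function(scan, path) {
  stopifnot(inherits(scan, "scan_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#wild_type\t", unclass(scan$wild_type)),
    paste0("#wt_response\t", format(scan$wt_response, digits = 15)),
    paste0("#wt_predicted_binding\t", format(scan$wt_predicted_binding, digits = 15)),
    paste0("#orientation\t", scan$orientation)
  ), con)
  write.table(scan$variants, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
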