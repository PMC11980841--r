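#' Run the full cross-reactivity screen
#'
#' Chains the whole pipeline: interpret the positional scan, build and expand
#' the recognition motif, run the three proteome searches (exact motif,
#' class-expanded motif, Smith-Waterman similarity), merge into a
#' deduplicated candidate set, and filter by HLA binding plausibility. All
#' parameters, seeds and a proteome digest are recorded in the result's
#' provenance so an identical re-run reproduces the output bit-identically.
#'
#' @param scan A [scan_table()] for the query epitope.
#' @param proteome Proteome data frame ([read_fasta()] format).
#' @param theta_r,theta_b Classification thresholds (see
#'   [classify_positions()]).
#' @param classes [similarity_classes()] for the expanded search.
#' @param matrix [substitution_matrix()] for the alignment search.
#' @param min_score Alignment score threshold (default
#'   [default_min_score()]).
#' @param predictor [binding_predictor()] for the HLA filter.
#' @param rank_threshold Percentile-rank cutoff (default 2.0).
#' @param background_size Background sample size for percentile ranks
#'   (default 100000).
#' @param seed Integer seed for the background sample.
#' @return A `"candidate_set"` whose `candidates` are the binding-filtered
#'   candidates; the unfiltered merge is kept in `$unfiltered` and the
#'   classification in `$classification`.
#' @export
#' @examples
#' sim <- generate_proteome(n_proteins = 20, length_range = c(100, 200), seed = 11)
#' scan <- generate_scan_table(seed = 11)
#' res <- run_screen(scan, sim$proteome, background_size = 2000, seed = 11)
#' res$candidates[, c("peptide", "found_by", "binding_rank")]
run_screen <- function(scan, proteome,
                       theta_r = 0.1, theta_b = 5,
                       classes = similarity_classes(),
                       matrix = substitution_matrix(),
                       min_score = NULL,
                       predictor = pssm_predictor(),
                       rank_threshold = 2.0,
                       background_size = 100000L,
                       seed = 1L) {
  stopifnot(inherits(scan, "scan_table"), is.data.frame(proteome))
  query <- scan$wild_type
  k <- nchar(query)
  if (is.null(min_score)) min_score <- default_min_score(query, matrix)

  classification <- classify_positions(scan, theta_r = theta_r, theta_b = theta_b)
  motif <- build_motif(classification)
  motif2 <- expand_motif(motif, classes)

  s1 <- scan_proteome(proteome, motif, query = query, search = "search1")
  s2 <- scan_proteome(proteome, motif2, query = query, search = "search2")
  s3 <- search_by_similarity(query, proteome,
    matrix = matrix,
    min_score = min_score, k = k, search = "search3"
  )

  provenance <- list(
    k = k,
    theta_r = theta_r,
    theta_b = theta_b,
    contact_positions = positions_with_label(classification, "contact"),
    anchor_positions = positions_with_label(classification, "anchor"),
    similarity_classes = lapply(classes$groups, paste, collapse = ""),
    matrix = matrix$name,
    gap_open = matrix$gap_open,
    gap_extend = matrix$gap_extend,
    min_score = min_score,
    predictor = predictor$name,
    rank_threshold = rank_threshold,
    background_size = as.integer(background_size),
    seed = as.integer(seed),
    proteome_digest = proteome_digest(proteome)
  )
  cset <- merge_searches(s1, s2, s3, query, provenance = provenance)

  background <- sample_background(proteome,
    n = background_size, k = k,
    seed = seed
  )
  unfiltered <- cset$candidates
  cset$candidates <- filter_candidates(unfiltered, predictor, background,
    rank_threshold = rank_threshold
  )
  cset$unfiltered <- unfiltered
  cset$classification <- classification
  cset
}
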