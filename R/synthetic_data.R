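#' Default planted peptide set for the synthetic proteome
#'
#' Planted ground truth keyed to the default epitope FLSNDTVQL and its
#' contact/anchor structure (contacts 3, 4, 5, 8; anchors 2, 9):
#'
#' * `exact_motif` — peptides sharing all contact residues verbatim
#'   (differing from the epitope only at open positions), recoverable by the
#'   exact contact-motif search.
#' * `class_variant` — one contact residue replaced *within* its
#'   physicochemical class (S3->T, N4->Q), recoverable only once the motif is
#'   class-expanded.
#' * `align_decoy` — one contact residue replaced *outside* its class but
#'   with a high substitution score (S3->A), invisible to both motif searches
#'   yet recovered by the alignment search.
#' * `nonbinder_decoy` — contact motif intact but both HLA-A*02:01 anchors
#'   replaced by proline (P2/P9), so the binding filter must remove it.
#'
#' @param copies Copies of each planted peptide (default 3).
#' @return Data frame with columns `peptide`, `label`, `copies`.
#' @export
default_plants <- function(copies = 3L) {
  data.frame(
    peptide = c(
      "ALSNDTVQL", "FLSNDTVQV",
      "FLTNDTVQL", "FLSQDTVQL",
      "FLANDTVQL",
      "FPSNDTVQP"
    ),
    label = c(
      "exact_motif", "exact_motif",
      "class_variant", "class_variant",
      "align_decoy",
      "nonbinder_decoy"
    ),
    copies = as.integer(copies),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Emits a proteome of i.i.d.-background proteins with known cross-reactive
#' peptides planted at recorded, non-overlapping coordinates, emulating (at
#' reduced scale) the role of the human proteome in a cross-reactivity
#' screen. Identical spec and seed give byte-identical output.
#'
#' @param n_proteins Number of proteins (default 50).
#' @param length_range Integer `c(min, max)` protein length in residues.
#' @param background_freqs Length-20 residue frequency vector (sums to 1;
#'   default uniform).
#' @param planted Data frame `peptide`, `label`, `copies` (default
#'   [default_plants()]); pass a zero-row data frame for a pure background
#'   proteome. All peptides must share one length k.
#' @param seed Integer seed.
#' @return List with `proteome` (data frame `id`, `description`, `sequence`)
#'   and `truth` (data frame `peptide`, `label`, `protein_id`, `offset`;
#'   every planted occurrence is present verbatim at its coordinates).
#' @export
#' @examples
#' sim <- generate_proteome(n_proteins = 10, length_range = c(60, 100), seed = 7)
#' head(sim$truth)
generate_proteome <- function(n_proteins = 50L,
                              length_range = c(200L, 500L),
                              background_freqs = rep(1 / 20, 20),
                              planted = default_plants(),
                              seed = 1L) {
  stopifnot(
    n_proteins >= 1, length(length_range) == 2L,
    length_range[1] >= 1, length_range[2] >= length_range[1],
    length(background_freqs) == 20L, all(background_freqs >= 0)
  )
  if (abs(sum(background_freqs) - 1) > 1e-9) {
    stop("background_freqs must sum to 1", call. = FALSE)
  }
  stopifnot(is.data.frame(planted))
  if (nrow(planted) > 0) {
    ks <- nchar(planted$peptide)
    if (length(unique(ks)) != 1L) {
      stop("all planted peptides must have the same length", call. = FALSE)
    }
    if (any(planted$copies < 1)) stop("copies must be >= 1", call. = FALSE)
    planted$peptide <- vapply(
      planted$peptide,
      function(p) as.character(validate_peptide(p)), character(1)
    )
  }
  with_seed(seed, {
    span <- length_range[2] - length_range[1] + 1L
    lens <- length_range[1] + sample.int(span, n_proteins, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = background_freqs),
        collapse = ""
      )
    }, character(1))
    ids <- sprintf("SYN%04d", seq_len(n_proteins))
    truth <- data.frame(
      peptide = character(), label = character(),
      protein_id = character(), offset = integer(),
      stringsAsFactors = FALSE
    )
    if (nrow(planted) > 0) {
      k <- nchar(planted$peptide[1])
      occupied <- vector("list", n_proteins)
      eligible <- pmax(lens - k + 1L, 0L)
      if (sum(eligible) == 0L) {
        stop("planted copies exceed available insertion space", call. = FALSE)
      }
      todo <- planted[rep(seq_len(nrow(planted)), planted$copies), c("peptide", "label")]
      for (r in seq_len(nrow(todo))) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          j <- sample.int(n_proteins, 1L, prob = eligible)
          if (eligible[j] == 0L) next
          off <- sample.int(eligible[j], 1L)
          ivs <- occupied[[j]]
          clash <- any(vapply(ivs, function(iv) off <= iv[2] && off + k - 1L >= iv[1], logical(1)))
          if (!clash) {
            substr(seqs[j], off, off + k - 1L) <- todo$peptide[r]
            occupied[[j]] <- c(ivs, list(c(off, off + k - 1L)))
            truth <- rbind(truth, data.frame(
              peptide = todo$peptide[r], label = todo$label[r],
              protein_id = ids[j], offset = as.integer(off),
              stringsAsFactors = FALSE
            ))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("planted copies exceed available insertion space", call. = FALSE)
        }
      }
    }
    list(
      proteome = data.frame(
        id = ids,
        description = "synthetic background protein",
        sequence = seqs,
        stringsAsFactors = FALSE
      ),
      truth = truth
    )
  })
}

#' Generate a synthetic positional scan table
#'
#' Emulates a positional alanine/glycine scan with planted anchor and contact
#' structure: variants at contact positions lose the T cell response (without
#' losing predicted binding); variants at anchor positions lose predicted
#' binding by a large fold and consequently also lose the response
#' (presentation loss); all other positions retain most of the response.
#' Multiplicative log-normal noise of standard deviation `noise_sd` (on the
#' log scale) is applied to every variant's response and binding value.
#' Positions whose wild-type residue is alanine are substituted with glycine.
#'
#' @param wild_type The epitope (default FLSNDTVQL).
#' @param contact_positions,anchor_positions Disjoint 1-based position sets
#'   (defaults: contacts 3, 4, 5, 8; anchors 2, 9).
#' @param wt_response Wild-type response (default 1000, e.g. IFN-gamma
#'   pg/ml).
#' @param wt_predicted_binding Wild-type predicted affinity (default 6,
#'   affinity-like: lower = stronger).
#' @param contact_response_frac Residual response fraction at contact (and
#'   anchor) positions (default 0.02).
#' @param tolerant_response_frac Residual response fraction elsewhere
#'   (default 0.9). Must exceed `contact_response_frac`.
#' @param anchor_binding_fold Fold-worsening of predicted binding at anchor
#'   positions (default 100).
#' @param noise_sd Log-normal sigma (default 0 = noise-free).
#' @param seed Integer seed.
#' @return A [scan_table()] with orientation `"affinity"`.
#' @export
#' @examples
#' classify_positions(generate_scan_table(noise_sd = 0.2, seed = 42))
generate_scan_table <- function(wild_type = "FLSNDTVQL",
                                contact_positions = c(3L, 4L, 5L, 8L),
                                anchor_positions = c(2L, 9L),
                                wt_response = 1000,
                                wt_predicted_binding = 6,
                                contact_response_frac = 0.02,
                                tolerant_response_frac = 0.9,
                                anchor_binding_fold = 100,
                                noise_sd = 0,
                                seed = 1L) {
  wild_type <- validate_peptide(as.character(wild_type))
  k <- nchar(wild_type)
  stopifnot(
    all(contact_positions %in% seq_len(k)),
    all(anchor_positions %in% seq_len(k)),
    length(intersect(contact_positions, anchor_positions)) == 0L,
    contact_response_frac > 0, contact_response_frac < 1,
    tolerant_response_frac > 0, tolerant_response_frac < 1,
    contact_response_frac < tolerant_response_frac,
    anchor_binding_fold > 1, noise_sd >= 0
  )
  wt_res <- aa_chars(wild_type)
  sub_res <- ifelse(wt_res == "A", "G", "A")
  with_seed(seed, {
    noise <- function() exp(stats::rnorm(k, 0, noise_sd))
    resp_frac <- rep(tolerant_response_frac, k)
    resp_frac[contact_positions] <- contact_response_frac
    resp_frac[anchor_positions] <- contact_response_frac # presentation loss
    bind_fold <- rep(1, k)
    bind_fold[anchor_positions] <- anchor_binding_fold
    variants <- data.frame(
      position = seq_len(k),
      substituted_residue = sub_res,
      response = resp_frac * wt_response * noise(),
      predicted_binding = bind_fold * wt_predicted_binding * noise(),
      stringsAsFactors = FALSE
    )
    scan_table(
      wild_type = wild_type,
      wt_response = wt_response,
      wt_predicted_binding = wt_predicted_binding,
      variants = variants,
      orientation = "affinity"
    )
  })
}
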