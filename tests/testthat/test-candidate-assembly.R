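# Minimal hand-built window-level hit sets for merge semantics.
mk_hits <- function(peptides, search, proteins = rep("P", length(peptides)),
                    offsets = seq_along(peptides), query = "FLSNDTVQL") {
  d <- data.frame(
    peptide = peptides, protein_id = proteins, offset = as.integer(offsets),
    stringsAsFactors = FALSE
  )
  xreact:::new_peptide_hits(d, query, search)
}

test_that("merging unions peptides and merges found_by provenance", {
  s1 <- mk_hits(c("AAAAAAAAA", "CCCCCCCCC"), "search1", offsets = c(1, 11))
  s2 <- mk_hits(c("CCCCCCCCC", "DDDDDDDDD"), "search2", offsets = c(11, 21))
  s3 <- mk_hits(c("DDDDDDDDD", "EEEEEEEEE"), "search3", offsets = c(21, 31))
  cset <- merge_searches(s1, s2, s3, "FLSNDTVQL")
  expect_equal(nrow(cset$candidates), 4L)
  tab <- cset$candidates
  expect_equal(tab$found_by[tab$peptide == "CCCCCCCCC"], "search1;search2")
  expect_equal(tab$found_by[tab$peptide == "DDDDDDDDD"], "search2;search3")
  expect_equal(tab$found_by[tab$peptide == "AAAAAAAAA"], "search1")
  # |candidates| <= sum of inputs, with equality iff pairwise disjoint
  expect_lte(nrow(cset$candidates), 6L)
})

test_that("merging three empty searches yields an empty candidate set", {
  e <- mk_hits(character(0), "search1")
  cset <- merge_searches(e, e, e, "FLSNDTVQL")
  expect_equal(nrow(cset$candidates), 0L)
  expect_equal(nrow(cset$windows), 0L)
})

test_that("self-hits are excluded from candidates but reported", {
  s1 <- mk_hits(c("FLSNDTVQL", "ALSNDTVQL"), "search1", offsets = c(1, 11))
  e <- mk_hits(character(0), "search2")
  cset <- merge_searches(s1, e, e, "FLSNDTVQL")
  expect_equal(cset$candidates$peptide, "ALSNDTVQL")
  expect_equal(cset$self$peptide, "FLSNDTVQL")
})

test_that("conflicting window provenance is rejected", {
  s1 <- mk_hits("AAAAAAAAA", "search1", offsets = 5)
  s2 <- mk_hits("CCCCCCCCC", "search2", offsets = 5) # same (protein, offset)
  e <- mk_hits(character(0), "search3")
  expect_error(merge_searches(s1, s2, e, "FLSNDTVQL"), "conflicting window provenance")
})

test_that("a synthetic run attributes planted peptides to the right searches", {
  sim <- generate_proteome(seed = 202)
  scan <- generate_scan_table(seed = 202)
  cl <- classify_positions(scan)
  motif <- build_motif(cl)
  s1 <- scan_proteome(sim$proteome, motif, query = scan$wild_type, search = "search1")
  s2 <- scan_proteome(sim$proteome, expand_motif(motif),
    query = scan$wild_type, search = "search2"
  )
  s3 <- search_by_similarity(scan$wild_type, sim$proteome)
  cset <- merge_searches(s1, s2, s3, scan$wild_type)
  tab <- merge(cset$candidates, unique(sim$truth[, c("peptide", "label")]), by = "peptide")
  expect_equal(nrow(tab), length(unique(sim$truth$peptide))) # all plants recovered
  by_label <- split(tab, tab$label)
  for (d in split(tab, seq_len(nrow(tab)))) {
    fb <- strsplit(d$found_by, ";")[[1]]
    switch(d$label,
      exact_motif = expect_true(all(c("search1", "search2") %in% fb)),
      class_variant = {
        expect_true("search2" %in% fb)
        expect_false("search1" %in% fb)
      },
      align_decoy = {
        expect_equal(fb, "search3")
      },
      nonbinder_decoy = {
        expect_true("search1" %in% fb)
      }
    )
  }
  # every planted window coordinate is present in the merged provenance
  expect_true(all(
    paste(sim$truth$protein_id, sim$truth$offset) %in%
      paste(cset$windows$protein_id, cset$windows$offset)
  ))
})

test_that("candidate TSV export round-trips and FASTA export has one record per candidate", {
  sim <- generate_proteome(n_proteins = 20, length_range = c(150, 250), seed = 203)
  scan <- generate_scan_table(seed = 203)
  res <- run_screen(scan, sim$proteome, background_size = 3000, seed = 203)
  tsv <- tempfile(fileext = ".tsv")
  export_candidates(res, tsv)
  back <- read_candidates(tsv)
  expect_equal(back$peptide, res$candidates$peptide)
  expect_equal(back$found_by, res$candidates$found_by)
  expect_equal(back$n_windows, res$candidates$n_windows)
  expect_equal(back$binding_rank, res$candidates$binding_rank, tolerance = 1e-9)

  fa <- tempfile(fileext = ".fa")
  export_candidates(res, fa, format = "fasta")
  recs <- read_fasta(fa)
  expect_equal(nrow(recs), nrow(res$candidates))
  expect_equal(recs$sequence, res$candidates$peptide)
})

test_that("identical configuration reproduces a byte-identical export", {
  sim <- generate_proteome(n_proteins = 15, length_range = c(150, 250), seed = 204)
  scan <- generate_scan_table(seed = 204)
  paths <- replicate(2, tempfile(fileext = ".tsv"))
  for (p in paths) {
    res <- run_screen(scan, sim$proteome, background_size = 3000, seed = 204)
    export_candidates(res, p)
  }
  expect_identical(unname(tools::md5sum(paths[1])), unname(tools::md5sum(paths[2])))
})

test_that("the provenance snapshot records the full configuration", {
  sim <- generate_proteome(n_proteins = 10, length_range = c(100, 150), seed = 205)
  scan <- generate_scan_table(seed = 205)
  res <- run_screen(scan, sim$proteome, background_size = 2000, seed = 205)
  path <- tempfile(fileext = ".yaml")
  write_provenance(res, path)
  prov <- yaml::read_yaml(path)
  expect_equal(prov$query, "FLSNDTVQL")
  expect_equal(prov$contact_positions, c(3L, 4L, 5L, 8L))
  expect_equal(prov$anchor_positions, c(2L, 9L))
  expect_equal(prov$min_score, 26L)
  expect_equal(prov$seed, 205L)
  expect_equal(prov$proteome_digest, unname(xreact:::proteome_digest(sim$proteome)))
})
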