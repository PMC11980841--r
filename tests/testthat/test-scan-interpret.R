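# Hand-built scan emulating the epitope's structure: anchors at 2/9 lose
# binding 100-fold, contacts at 3/4/5/8 lose the response, the rest tolerate.
fixture_scan <- function(resp_contact = 0.02, resp_tolerant = 0.9,
                         binding_fold = 100, orientation = "affinity") {
  wt <- "FLSNDTVQL"
  resp <- rep(resp_tolerant, 9)
  resp[c(3, 4, 5, 8)] <- resp_contact
  resp[c(2, 9)] <- resp_contact
  bind <- rep(10, 9)
  bind[c(2, 9)] <- if (orientation == "affinity") 10 * binding_fold else 10 / binding_fold
  scan_table(
    wild_type = wt, wt_response = 1000, wt_predicted_binding = 10,
    variants = data.frame(
      position = 1:9, substituted_residue = "A",
      response = resp * 1000, predicted_binding = bind
    ),
    orientation = orientation
  )
}

test_that("positions classify into anchors, contacts and tolerant at defaults", {
  for (orient in c("affinity", "score")) {
    cl <- classify_positions(fixture_scan(orientation = orient))
    expect_equal(positions_with_label(cl, "anchor"), c(2L, 9L))
    expect_equal(positions_with_label(cl, "contact"), c(3L, 4L, 5L, 8L))
    expect_equal(positions_with_label(cl, "tolerant"), c(1L, 6L, 7L))
    expect_equal(sort(unique(cl$labels)), sort(unique(c("anchor", "contact", "tolerant"))))
  }
})

test_that("a scan with unchanged responses and binding is all tolerant", {
  sc <- scan_table(
    wild_type = "FLSNDTVQL", wt_response = 500, wt_predicted_binding = 10,
    variants = data.frame(
      position = 1:9, substituted_residue = "A",
      response = 500, predicted_binding = 10
    )
  )
  cl <- classify_positions(sc)
  expect_equal(cl$labels, rep("tolerant", 9))
})

test_that("the response threshold is inclusive at the boundary", {
  theta_r <- 0.1
  wt_resp <- 1000
  resp <- rep(900, 9)
  resp[4] <- theta_r * wt_resp # exactly at the threshold
  resp[5] <- theta_r * wt_resp + 1e-9 # just above
  sc <- scan_table("FLSNDTVQL", wt_resp, 10,
    variants = data.frame(
      position = 1:9, substituted_residue = "A",
      response = resp, predicted_binding = 10
    )
  )
  cl <- classify_positions(sc, theta_r = theta_r)
  # Oracle: the defining inequalities, evaluated directly.
  expect_equal(cl$labels[4], if (resp[4] <= theta_r * wt_resp) "contact" else "tolerant")
  expect_equal(cl$labels[4], "contact")
  expect_equal(cl$labels[5], "tolerant")
})

test_that("incomplete or degenerate scans are rejected", {
  v <- data.frame(
    position = 1:8, substituted_residue = "A",
    response = 1, predicted_binding = 10
  )
  expect_error(scan_table("FLSNDTVQL", 100, 10, variants = v), "incomplete")
  v9 <- data.frame(
    position = 1:9, substituted_residue = "A",
    response = 1, predicted_binding = 10
  )
  expect_error(scan_table("FLSNDTVQL", 0, 10, variants = v9), "positive")
  # substitution equal to wild type (A at a position whose residue is A)
  va <- data.frame(
    position = 1:9, substituted_residue = "A",
    response = 1, predicted_binding = 10
  )
  expect_error(scan_table("ALSNDTVQL", 100, 10, variants = va), "wild-type")
})

test_that("classification is monotone in its thresholds", {
  for (seed in 1:20) {
    sc <- generate_scan_table(noise_sd = 0.6, seed = seed)
    base <- classify_positions(sc, theta_r = 0.2, theta_b = 3)
    tighter_r <- classify_positions(sc, theta_r = 0.05, theta_b = 3)
    higher_b <- classify_positions(sc, theta_r = 0.2, theta_b = 10)
    # lowering theta_r never adds contact positions
    expect_true(all(
      positions_with_label(tighter_r, "contact") %in%
        positions_with_label(base, "contact")
    ))
    # raising theta_b never adds anchors
    expect_true(all(
      positions_with_label(higher_b, "anchor") %in%
        positions_with_label(base, "anchor")
    ))
  }
})

test_that("the motif constrains contact positions to wild-type residues", {
  cl <- classify_positions(fixture_scan())
  m <- build_motif(cl)
  expect_equal(m$allowed[[3]], "S")
  expect_equal(m$allowed[[4]], "N")
  expect_equal(m$allowed[[5]], "D")
  expect_equal(m$allowed[[8]], "Q")
  for (p in c(1, 2, 6, 7, 9)) expect_equal(m$allowed[[p]], AA_STANDARD)
  expect_true(matches_motif("ALSNDTVQL", m))
  expect_false(matches_motif("ALTNDTVQL", m))
})

test_that("a fully constrained motif matches only the wild type", {
  labels <- rep("contact", 9)
  cl <- structure(
    list(
      labels = labels, theta_r = 0.1, theta_b = 5,
      wild_type = validate_peptide("FLSNDTVQL")
    ),
    class = "position_classification"
  )
  m <- build_motif(cl)
  expect_true(matches_motif("FLSNDTVQL", m))
  set.seed(77)
  others <- replicate(50, random_peptide())
  expect_false(any(matches_motif(setdiff(others, "FLSNDTVQL"), m)))
})

test_that("a single-contact motif agrees with a brute-force regex scan", {
  labels <- rep("tolerant", 9)
  labels[3] <- "contact"
  cl <- structure(
    list(
      labels = labels, theta_r = 0.1, theta_b = 5,
      wild_type = validate_peptide("FLSNDTVQL")
    ),
    class = "position_classification"
  )
  m <- build_motif(cl)
  sim <- generate_proteome(
    n_proteins = 5, length_range = c(200, 300),
    planted = default_plants(0)[0, ], seed = 91
  )
  got <- scan_proteome(sim$proteome, m)
  expect_equal(plain_windows(got), plain_windows(oracle_motif_scan(sim$proteome, m)))
})

test_that("an uninformative scan (no contacts) cannot yield a motif", {
  sc <- scan_table(
    wild_type = "FLSNDTVQL", wt_response = 500, wt_predicted_binding = 10,
    variants = data.frame(
      position = 1:9, substituted_residue = "A",
      response = 500, predicted_binding = 10
    )
  )
  expect_error(build_motif(classify_positions(sc)), "no contact positions")
})

test_that("scan tables round-trip through TSV", {
  sc <- generate_scan_table(noise_sd = 0.3, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_scan_table(sc, path)
  back <- read_scan_table(path)
  expect_equal(as.character(back$wild_type), as.character(sc$wild_type))
  expect_equal(back$wt_response, sc$wt_response)
  expect_equal(back$orientation, sc$orientation)
  expect_equal(back$variants$response, sc$variants$response, tolerance = 1e-12)
  expect_equal(back$variants$predicted_binding, sc$variants$predicted_binding,
    tolerance = 1e-12
  )
})
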