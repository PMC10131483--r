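test_that("genes without significant regulatory-domain hits stay candidates", {
  cat3 <- tibble::tibble(gene_id = c("g1", "g2", "g3"))
  empty <- tibble::tibble(gene_id = character(),
                          domain_accession = character(),
                          e_value = numeric())
  res <- classify_regulatory(cat3, empty)
  expect_equal(res$gene_id, cat3$gene_id)
  expect_false(any(res$regulatory))
  expect_true(all(res$reason == "none"))
})

test_that("a significant TF-domain hit makes a gene regulatory with reason tf", {
  cat1 <- tibble::tibble(gene_id = "g1")
  hit <- tibble::tibble(gene_id = "g1", domain_accession = "PF00046.25",
                        e_value = 1e-12)
  res <- classify_regulatory(cat1, hit)
  expect_true(res$regulatory)
  expect_equal(res$reason, "tf")
})

test_that("mixed tf/signaling/off-list hits match the brute-force partition", {
  ids <- sprintf("g%02d", 1:10)
  doms <- regulatory_domain_list()
  set.seed(42)
  hits <- tibble::tibble(
    gene_id = sample(ids, 25, replace = TRUE),
    domain_accession = sample(c("PF00046", "PF00110", "PF00019",
                                "PF99901", "PF00320"), 25, replace = TRUE),
    e_value = sample(c(1e-30, 1e-8, 1e-3, 0.5), 25, replace = TRUE)
  )
  got <- classify_regulatory(ids, hits, doms, evalue_max = 1e-5)
  want <- oracle_classify_regulatory(ids, hits, doms$tf_accessions,
                                     doms$signaling_accessions, 1e-5)
  expect_equal(got$regulatory, want$regulatory)
  expect_equal(got$reason, want$reason)
})

test_that("hits naming unknown genes are rejected with the offenders listed", {
  hit <- tibble::tibble(gene_id = "ghost", domain_accession = "PF00046",
                        e_value = 1e-12)
  expect_error(classify_regulatory(c("g1"), hit), "ghost")
})

test_that("enlarging the e-value cutoff never shrinks the regulatory set", {
  set.seed(7)
  ids <- sprintf("g%02d", 1:20)
  hits <- tibble::tibble(
    gene_id = sample(ids, 60, replace = TRUE),
    domain_accession = sample(c("PF00046", "PF00110", "PF99901"), 60,
                              replace = TRUE),
    e_value = 10^runif(60, -40, 0)
  )
  cuts <- c(1e-20, 1e-10, 1e-5, 1e-2, 1)
  sets <- lapply(cuts, function(cc) {
    r <- classify_regulatory(ids, hits, evalue_max = cc)
    r$gene_id[r$regulatory]
  })
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("a mutual top-hit pair is a reciprocal best hit", {
  ab <- tibble::tibble(query_id = "a1", subject_id = "b1", bitscore = 100,
                       e_value = 1e-30)
  ba <- tibble::tibble(query_id = "b1", subject_id = "a1", bitscore = 95,
                       e_value = 1e-28)
  expect_equal(reciprocal_best_hits(ab, ba),
               tibble::tibble(species_a_id = "a1", species_b_id = "b1"))
})

test_that("a one-directional top hit is not an ortholog pair", {
  # a1's top is b1, but b1's top is a2
  ab <- tibble::tibble(query_id = "a1", subject_id = "b1", bitscore = 90,
                       e_value = 1e-20)
  ba <- tibble::tibble(query_id = c("b1", "b1"),
                       subject_id = c("a1", "a2"),
                       bitscore = c(90, 120), e_value = c(1e-20, 1e-40))
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 0)
})

test_that("bitscore ties resolve by e-value then subject id, matching the oracle", {
  ab <- tibble::tibble(
    query_id = c("a1", "a1", "a1", "a2", "a2"),
    subject_id = c("b1", "b2", "b3", "b1", "b2"),
    bitscore = c(200, 200, 200, 150, 150),
    e_value = c(1e-30, 1e-30, 1e-40, 1e-10, 1e-10)
  )
  ba <- tibble::tibble(
    query_id = c("b3", "b1", "b1"),
    subject_id = c("a1", "a2", "a1"),
    bitscore = c(180, 140, 140),
    e_value = c(1e-35, 1e-9, 1e-9)
  )
  got <- reciprocal_best_hits(ab, ba)
  want <- oracle_rbh(as.data.frame(ab), as.data.frame(ba))
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  # a1's tie at 200 resolves to b3 by smaller e-value; b3 points back
  expect_true("a1" %in% got$species_a_id)
  expect_equal(got$species_b_id[got$species_a_id == "a1"], "b3")
})

test_that("RBH equals the exhaustive oracle on random tables and is a symmetric matching", {
  for (s in 1:10) {
    set.seed(s)
    tabs <- random_hit_tables()
    got <- reciprocal_best_hits(tabs$ab, tabs$ba)
    want <- oracle_rbh(as.data.frame(tabs$ab), as.data.frame(tabs$ba))
    expect_equal(as.data.frame(got), want, info = paste("seed", s),
                 ignore_attr = TRUE)
    # matching: no id twice
    expect_false(anyDuplicated(got$species_a_id) > 0)
    expect_false(anyDuplicated(got$species_b_id) > 0)
    # symmetry under swapping the two directions
    swapped <- reciprocal_best_hits(tabs$ba, tabs$ab)
    expect_equal(
      got[order(got$species_a_id), ],
      tibble::tibble(species_a_id = swapped$species_b_id,
                     species_b_id = swapped$species_a_id)[
                       order(swapped$species_b_id), ]
    )
    # invariance under row permutation of the inputs
    perm <- reciprocal_best_hits(tabs$ab[sample(nrow(tabs$ab)), ],
                                 tabs$ba[sample(nrow(tabs$ba)), ])
    expect_equal(got, perm)
  }
})

test_that("restricting to orthologs keeps mapped candidates in input order", {
  map <- tibble::tibble(species_a_id = c("a2", "a5", "a9"),
                        species_b_id = c("b2", "b5", "b9"))
  cands <- sprintf("a%d", 1:10)
  expect_equal(restrict_to_orthologs(cands, map), c("a2", "a5", "a9"))
  expect_equal(restrict_to_orthologs(character(0), map), character(0))
  empty_map <- tibble::tibble(species_a_id = character(),
                              species_b_id = character())
  expect_equal(restrict_to_orthologs(cands, empty_map), character(0))
  full_map <- tibble::tibble(species_a_id = cands, species_b_id = cands)
  expect_equal(restrict_to_orthologs(cands, full_map), cands)
})
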