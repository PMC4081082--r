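model <- energy_model()

test_that("a strand with no complementary pairs folds to the empty structure", {
  f <- mfe_complex(c(a = "AAAAAA"), model)
  expect_equal(f$dg, 0)
  expect_equal(nrow(f$pairs), 0)
  expect_equal(f$dot_bracket, "......")
})

test_that("GGGGG/CCCCC forms a full helix scored by four G.C/G.C stacks", {
  f <- mfe_complex(c(g = "GGGGG", c = "CCCCC"), model)
  expect_equal(f$dot_bracket, "(((((&)))))")
  stack_gc <- model$stack_cc["GC", "GC"] / 100
  expect_equal(f$dg, 4 * stack_gc)
})

test_that("input contracts: strand count, empty strands, alphabet", {
  expect_error(mfe_complex(c(a = "GC", b = "GC", c = "GC", d = "GC")), "3 strands")
  expect_error(mfe_complex(c(a = "")), "empty")
  expect_error(mfe_complex(c(a = "ACGX")), "X")
})

test_that("enumeration of a 3-mer yields only the empty structure", {
  en <- enumerate_structures(c(a = "ACG"), model)
  expect_equal(nrow(en), 1)
  expect_equal(en$n_pairs, 0L)
  expect_equal(en$energy, 0)
})

test_that("enumeration of GC/GC lists the intermolecular matchings", {
  en <- enumerate_structures(c(a = "GC", b = "GC"), model)
  # empty, two single intermolecular pairs, and the two-pair helix
  expect_equal(nrow(en), 4)
  expect_equal(sort(en$n_pairs), c(0L, 1L, 1L, 2L))
  expect_equal(min(en$energy), model$stack_cc["GC", "CG"] / 100)
  expect_error(enumerate_structures(c(a = strrep("ACGU", 10))), "cap")
})

test_that("DP energies equal the enumeration minimum on random instances", {
  set.seed(20240917)
  for (i in 1:120) {
    strands <- random_instance(6, 15)
    dp <- mfe_complex(strands, model)
    en <- enumerate_structures(strands, model)
    expect_equal(dp$dg, min(en$energy), info = paste(strands, collapse = "&"))
  }
})

test_that("dot-bracket and pair map convert back and forth exactly", {
  set.seed(5)
  for (i in 1:40) {
    strands <- random_instance(8, 16)
    f <- mfe_complex(strands, model)
    back <- dotbracket_to_pairs(f$dot_bracket)
    expect_equal(back$lengths, unname(nchar(f$strands)))
    expect_equal(unname(back$pairs), unname(f$pairs))
    expect_equal(pairs_to_dotbracket(back$pairs, back$lengths), f$dot_bracket)
  }
  expect_error(dotbracket_to_pairs("(()"), "unbalanced")
})

test_that("the traceback is deterministic", {
  set.seed(9)
  for (i in 1:15) {
    strands <- random_instance(10, 18)
    f1 <- mfe_complex(strands, model)
    f2 <- mfe_complex(strands, model)
    expect_identical(f1$dot_bracket, f2$dot_bracket)
  }
})

test_that("adding a third strand never raises the complex MFE", {
  set.seed(13)
  for (i in 1:25) {
    w <- random_strand(sample(12:20, 1))
    m1 <- random_strand(sample(8:12, 1))
    m2 <- random_strand(sample(8:12, 1))
    d1 <- mfe_complex(c(w = w, m1 = m1), model)$dg
    d2 <- mfe_complex(c(w = w, m2 = m2), model)$dg
    t1 <- mfe_complex(c(w = w, m1 = m1, m2 = m2), model)$dg
    t2 <- mfe_complex(c(w = w, m2 = m2, m1 = m1), model)$dg
    tri <- min(t1, t2)
    expect_lte(tri, min(d1, d2) + 1e-9)
  }
})

test_that("conformation classes follow the inter-strand pairing pattern", {
  strands <- c(mrna = "GGGGAAAAGGGG", mirA = "CCCC", mirB = "CCCC")
  canonical <- structure_from_db(strands, "((((....((((&))))&))))")
  expect_equal(classify_conformation(canonical), "canonical_triplex")

  free_mir <- structure_from_db(strands, "((((........&))))&....")
  expect_equal(classify_conformation(free_mir), "duplex_plus_free_mirna")

  # mirA pairs both the mRNA and mirB: a miRNA-miRNA hybrid
  strands2 <- c(mrna = "GGGG", mirA = "CCGG", mirB = "CC")
  hybrid <- triplexr:::new_complex_structure(
    strands2, rbind(c(1, 6), c(2, 5), c(7, 10), c(8, 9)), -4)
  expect_equal(classify_conformation(hybrid), "mirna_mirna_hybrid")

  expect_error(classify_conformation(mfe_complex(c(a = "GC", b = "GC"))),
               "3 strands")
})

test_that("seed preservation demands pairing into the designated interval", {
  # window: two 7-nt seed-match boxes separated by 13 nt; both boxes are
  # the reverse complement of miRNA positions 2-8 ("GGGGGGG" -> "CCCCCCC")
  window <- paste0("AA", strrep("C", 7), strrep("A", 13), strrep("C", 7), "AA")
  mir <- paste0("A", strrep("G", 7), strrep("A", 14)) # 22 nt
  cand <- make_candidate(window, window_offset = 1,
                         seed1_start = 3, seed1_end = 9,
                         seed2_start = 23, seed2_end = 29,
                         mirna1_id = "mirA", mirna2_id = "mirB")
  strands <- c(mrna = window, mirA = mir, mirB = mir)
  n <- nchar(window)
  # pair miRNA A nts 2-8 onto window 3..9 (antiparallel), miRNA B onto 23..29
  pairs_a <- cbind(3:9, n + (8:2))
  pairs_b <- cbind(23:29, n + 22 + (8:2))
  st <- triplexr:::new_complex_structure(strands, rbind(pairs_a, pairs_b), -10)
  expect_true(seed_preserved(st, cand, 1))
  expect_true(seed_preserved(st, cand, 2))

  # miRNA A's seed paired to the *other* site's interval does not count
  st_swap <- triplexr:::new_complex_structure(strands, cbind(23:29, n + (8:2)), -5)
  expect_false(seed_preserved(st_swap, cand, 1))

  # threshold semantics: 6 of 7 paired passes only with min_paired = 6
  st_six <- triplexr:::new_complex_structure(strands, pairs_a[1:6, ], -5)
  expect_false(seed_preserved(st_six, cand, 1))
  expect_true(seed_preserved(st_six, cand, 1, min_paired = 6))

  bad <- make_candidate(window, window_offset = 200,
                        seed1_start = 3, seed1_end = 9,
                        seed2_start = 23, seed2_end = 29)
  expect_error(seed_preserved(st, bad, 1), "outside")
})

test_that("the population cutoff is mean minus z standard deviations", {
  # two-point population with mean -20 and sample sd 7.08
  half <- 7.08 / sqrt(2)
  pop <- c(-20 - half, -20 + half)
  expect_equal(sd(pop), 7.08)
  expect_equal(tfe_cutoff(pop, z = 3), -41.24)
  expect_equal(tfe_cutoff(pop, z = 0), -20)
  expect_equal(tfe_cutoff(rep(-12.5, 5), z = 3), -12.5)
  expect_error(tfe_cutoff(numeric(0)), "empty")
  expect_error(tfe_cutoff(-1, z = 3), ">= 2")
})

test_that("structure filters apply TFE, conformation and seed rules in order", {
  energ <- tibble::tibble(
    dg_triplex = c(-41.24, -50, -45, -30),
    conformation = c("canonical_triplex", "duplex_plus_free_mirna",
                     "canonical_triplex", "canonical_triplex"),
    seed1_preserved = c(TRUE, TRUE, FALSE, TRUE),
    seed2_preserved = TRUE
  )
  out <- apply_structure_filters(energ, cutoff = -41.24)
  expect_equal(out$kept$dg_triplex, -41.24) # boundary kept (<= semantics)
  expect_equal(out$dropped$reason, c("conformation", "seed", "tfe"))
  expect_equal(out$funnel$n_removed, c(1L, 1L, 1L))

  ident <- apply_structure_filters(energ, cutoff = Inf,
                                   require_seed = FALSE,
                                   drop_classes = character(0))
  expect_equal(nrow(ident$kept), nrow(energ))
})
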