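test_that("a planted triplex is recovered as exactly one candidate", {
  toy <- generate_toy_dataset(n_genes = 2, planted = list(
    list(seed_distance = 20)), rng_seed = 1)
  cand <- pair_sites(filter_sites(toy$sites, mirnas = toy$mirnas),
                     utrs = toy$utrs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$seed_dist, 20L)
  expect_equal(cand$gene_id, toy$truth$gene_id)
})

test_that("planted distances straddling the window recover 13 and 35 only", {
  toy <- generate_toy_dataset(n_genes = 4, planted = list(
    list(seed_distance = 12), list(seed_distance = 13),
    list(seed_distance = 35), list(seed_distance = 36)), rng_seed = 2)
  cand <- pair_sites(filter_sites(toy$sites, mirnas = toy$mirnas),
                     utrs = toy$utrs)
  expect_setequal(cand$seed_dist, c(13L, 35L))
  expect_equal(nrow(cand), 2)
})

test_that("identical seeds give byte-identical datasets", {
  a <- generate_toy_dataset(n_genes = 3, planted = list(
    list(seed_distance = 18), list(seed_distance = 25)), rng_seed = 42)
  b <- generate_toy_dataset(n_genes = 3, planted = list(
    list(seed_distance = 18), list(seed_distance = 25)), rng_seed = 42)
  expect_identical(a, b)
  c <- generate_toy_dataset(n_genes = 3, planted = list(
    list(seed_distance = 18), list(seed_distance = 25)), rng_seed = 43)
  expect_false(identical(a$utrs$seq, c$utrs$seq))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(1))
  invisible(generate_toy_dataset(n_genes = 1, planted = list(
    list(seed_distance = 20)), rng_seed = 99))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("planted UTRs carry the seed complements at the stated coordinates", {
  toy <- generate_toy_dataset(n_genes = 1, planted = list(
    list(seed_distance = 17)), rng_seed = 5)
  utr <- toy$utrs$seq[1]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (r in seq_len(nrow(toy$sites))) {
    site <- toy$sites[r, ]
    mir <- toy$mirnas$seq[match(site$mirna_id, toy$mirnas$id)]
    # miRNA nt k pairs UTR position site_end - k + 1
    for (k in 2:8) {
      utr_base <- substr(utr, site$site_end - k + 1, site$site_end - k + 1)
      mir_base <- substr(mir, k, k)
      expect_equal(utr_base, unname(comp[mir_base]))
    }
  }
})

test_that("generator contracts: capacity and coordinates", {
  expect_error(generate_toy_dataset(n_genes = 0, planted = list(
    list(seed_distance = 20))), "n_genes")
  expect_error(generate_toy_dataset(n_genes = 1, utr_len = 60, planted = list(
    list(seed_distance = 35))), "utr_len")
  toy <- generate_toy_dataset(n_genes = 2, planted = list(
    list(seed_distance = 20)), rng_seed = 3)
  s <- toy$sites
  expect_true(all(s$site_start <= s$seed_start &
                    s$seed_start <= s$seed_end & s$seed_end <= s$site_end))
  expect_equal(unique(s$seed_end - s$seed_start + 1L), 7L)
})
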