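test_that("mirSVR filter keeps the boundary value and drops weaker scores", {
  sites <- dplyr::bind_rows(
    site_at(100, mirsvr = -0.1),
    site_at(150, mirsvr = -0.05),
    site_at(200, mirsvr = -0.8)
  )
  kept <- filter_sites(sites, mirsvr_max = -0.1, conserved_only = FALSE)
  expect_equal(kept$mirsvr, c(-0.1, -0.8))
})

test_that("disabled thresholds make the site filter the identity", {
  sites <- dplyr::bind_rows(site_at(100, mirsvr = 5), site_at(150, mirsvr = -3))
  expect_equal(filter_sites(sites, mirsvr_max = Inf, conserved_only = FALSE),
               sites)
})

test_that("conservation gating uses the miRNA table", {
  sites <- dplyr::bind_rows(site_at(100, mirna = "miR-a"),
                            site_at(150, mirna = "miR-b"))
  mirnas <- tibble::tibble(id = c("miR-a", "miR-b"),
                           conserved = c(TRUE, FALSE))
  expect_equal(filter_sites(sites, mirnas = mirnas)$mirna_id, "miR-a")
})

test_that("seed distance follows the gap metric and its alternative", {
  a <- list(seed_start = 94, seed_end = 100)
  b <- list(seed_start = 114, seed_end = 120)
  expect_equal(seed_distance(a, b), 13L)
  adj <- list(seed_start = 101, seed_end = 107)
  expect_equal(seed_distance(a, adj), 0L)
  a2 <- list(seed_start = 50, seed_end = 56)
  b2 <- list(seed_start = 80, seed_end = 86)
  expect_equal(seed_distance(a2, b2, metric = "start_to_start"), 30L)
  expect_error(seed_distance(b, a), "mis-ordered")
})

test_that("pairing respects both inclusive distance bounds", {
  base <- site_at(100, mirna = "miR-a")
  for (d in c(12L, 13L, 35L, 36L)) {
    partner <- site_at(100 + d + 7L, mirna = "miR-b")
    got <- pair_sites(dplyr::bind_rows(base, partner))
    expect_equal(nrow(got), as.integer(d >= 13 && d <= 35),
                 info = paste("distance", d))
    if (nrow(got)) expect_equal(got$seed_dist, d)
  }
})

test_that("homotypic pairs (same miRNA at both sites) are kept", {
  sites <- dplyr::bind_rows(site_at(100, mirna = "miR-20a"),
                            site_at(120, mirna = "miR-20a"))
  got <- pair_sites(sites)
  expect_equal(nrow(got), 1)
  expect_equal(got$mirna1_id, got$mirna2_id)
})

test_that("pair counting matches a brute-force double loop", {
  # four mutually in-range sites give all choose(4,2) = 6 ordered pairs
  # (pairwise gaps 13/33/53 nt, so the window is widened to hold them all)
  seeds <- c(100L, 120L, 140L, 160L) # successive gaps of 13 nt
  sites <- dplyr::bind_rows(lapply(seq_along(seeds), function(i) {
    site_at(seeds[i], mirna = paste0("miR-", i))
  }))
  expect_equal(nrow(pair_sites(sites, d_min = 13, d_max = 60)), 6)
  # under the default 13-35 nt window the two outermost pairs fall out
  expect_equal(nrow(pair_sites(sites)), 5)

  # randomized fixtures against an independent predicate loop
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:7, 1)
    seed_ends <- sort(sample(seq(30L, 400L, by = 9L), k))
    sites <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      site_at(seed_ends[i], mirna = paste0("miR-", i))
    }))
    d_min <- sample(0:20, 1); d_max <- d_min + sample(0:30, 1)
    brute <- 0L
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        a <- sites[i, ]; b <- sites[j, ]
        if (a$seed_end >= b$seed_start) next
        d <- b$seed_start - a$seed_end - 1L
        if (d >= d_min && d <= d_max) brute <- brute + 1L
      }
    }
    expect_equal(nrow(pair_sites(sites, d_min = d_min, d_max = d_max)), brute)
  }
})

test_that("widening the distance interval never removes candidates", {
  set.seed(8)
  seed_ends <- sort(sample(seq(30L, 500L, by = 8L), 8))
  sites <- dplyr::bind_rows(lapply(seq_along(seed_ends), function(i) {
    site_at(seed_ends[i], mirna = paste0("miR-", i))
  }))
  narrow <- pair_sites(sites, d_min = 13, d_max = 35)
  wide <- pair_sites(sites, d_min = 5, d_max = 60)
  key <- function(x) paste(x$mirna1_id, x$mirna2_id, x$seed_dist)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("candidate windows always contain both seed intervals", {
  toy <- generate_toy_dataset(n_genes = 2, planted = list(
    list(seed_distance = 15), list(seed_distance = 30)), rng_seed = 3)
  cand <- pair_sites(toy$sites, utrs = toy$utrs)
  expect_gt(nrow(cand), 0)
  for (r in seq_len(nrow(cand))) {
    win_end <- cand$window_offset[r] + nchar(cand$window_seq[r]) - 1L
    expect_lte(cand$window_offset[r], cand$seed1_start[r])
    expect_gte(win_end, cand$seed2_end[r])
  }
})

test_that("window extraction spans, clips and round-trips coordinates", {
  utr <- strrep("ACGU", 30) # 120 nt
  w <- extract_window(utr, 10, 70)
  expect_equal(nchar(w$seq), 61)
  expect_equal(w$offset, 10L)
  # UTR position = window index + offset - 1
  idx <- 5
  expect_equal(substr(w$seq, idx, idx), substr(utr, idx + w$offset - 1, idx + w$offset - 1))

  clipped <- extract_window(utr, 3, 20, flank = 5)
  expect_equal(clipped$offset, 1L)
  expect_equal(nchar(clipped$seq), 25)

  expect_error(extract_window(utr, 100, 130), "outside")
})
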