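test_that("disabling all binding leaves monomers at their totals", {
  st <- equilibrium_concentrations(
    c(MA = Inf, MB = Inf, AB = Inf, MAB = Inf),
    totals = c(M = 100, A = 100, B = 100))
  expect_equal(st$concentrations[["M"]], 100, tolerance = 1e-9)
  expect_equal(st$concentrations[["A"]], 100, tolerance = 1e-9)
  expect_equal(st$concentrations[["MAB"]], 0)
  expect_false(triplex_filter(st))
})

test_that("the dimer solution matches the closed-form quadratic across Kd", {
  # x^2 - (A0 + B0 + Kd) x + A0 B0 = 0, smaller root
  for (kd in 10^seq(0, 4, by = 0.5)) { # 1 nM .. 10 uM
    a0 <- 100; b0 <- 100
    dg <- RT_BODY * log(kd / 1e9)
    st <- equilibrium_concentrations(c(AB = dg), totals = c(A = a0, B = b0))
    s <- a0 + b0 + kd
    x <- (s - sqrt(s^2 - 4 * a0 * b0)) / 2
    expect_equal(st$concentrations[["AB"]], x, tolerance = 1e-6)
  }
})

test_that("the worked 100 nM dissociation example gives 38.197 nM dimer", {
  dg <- RT_BODY * log(100 / 1e9)
  st <- equilibrium_concentrations(c(AB = dg), totals = c(A = 100, B = 100))
  expect_equal(st$concentrations[["AB"]], 38.19660113, tolerance = 1e-7)
})

test_that("a symmetric system yields identical duplex concentrations", {
  st <- equilibrium_concentrations(
    c(MA = -12, MB = -12, AB = -3, MAB = -26),
    totals = c(M = 100, A = 100, B = 100))
  expect_equal(st$concentrations[["MA"]], st$concentrations[["MB"]],
               tolerance = 1e-9)
})

test_that("strand mass is conserved on random systems", {
  set.seed(31)
  for (i in 1:40) {
    dg <- c(MA = -runif(1, 1, 30), MB = -runif(1, 1, 30),
            AB = -runif(1, 1, 15), MAB = -runif(1, 5, 60))
    tot <- c(M = runif(1, 10, 500), A = runif(1, 10, 500), B = runif(1, 10, 500))
    st <- equilibrium_concentrations(dg, totals = tot)
    cc <- st$concentrations
    expect_equal(cc[["M"]] + cc[["MA"]] + cc[["MB"]] + cc[["MAB"]],
                 unname(tot["M"]), tolerance = 1e-6)
    expect_equal(cc[["A"]] + cc[["MA"]] + cc[["AB"]] + cc[["MAB"]],
                 unname(tot["A"]), tolerance = 1e-6)
    expect_equal(cc[["B"]] + cc[["MB"]] + cc[["AB"]] + cc[["MAB"]],
                 unname(tot["B"]), tolerance = 1e-6)
    expect_true(all(cc >= 0))
  }
})

test_that("stabilising the triplex never decreases its concentration", {
  prev <- -Inf
  for (dg_t in seq(-10, -60, by = -5)) {
    st <- equilibrium_concentrations(
      c(MA = -15, MB = -14, AB = -4, MAB = dg_t),
      totals = c(M = 100, A = 100, B = 100))
    tec <- triplex_concentration(st)
    expect_gte(tec, prev - 1e-9)
    prev <- tec
  }
})

test_that("adding a disabled complex leaves the solution unchanged", {
  dg <- c(MA = -16, MB = -13, MAB = -35)
  base <- equilibrium_concentrations(dg, totals = c(M = 100, A = 100, B = 100))
  plus <- equilibrium_concentrations(c(dg, AB = Inf),
                                     totals = c(M = 100, A = 100, B = 100))
  for (nm in names(base$concentrations)) {
    expect_equal(base$concentrations[[nm]], plus$concentrations[[nm]],
                 tolerance = 1e-8)
  }
})

test_that("the triplex concentration filter is strictly greater-than", {
  st <- equilibrium_concentrations(c(MA = -10, MB = -10, MAB = -40),
                                   totals = c(M = 100, A = 100, B = 100))
  st$concentrations[["MAB"]] <- 50.0
  expect_false(triplex_filter(st))
  st$concentrations[["MAB"]] <- 50.1
  expect_true(triplex_filter(st))
  dimer_only <- equilibrium_concentrations(c(AB = -10), totals = c(A = 1, B = 1))
  expect_error(triplex_filter(dimer_only), "three-strand")
})

test_that("equilibrium tidiers expose concentrations and the TEC", {
  st <- equilibrium_concentrations(c(MA = -18, MB = -16, AB = -3, MAB = -40),
                                   totals = c(M = 100, A = 100, B = 100))
  td <- tidy(st)
  expect_setequal(td$complex, c("M", "A", "B", "MA", "MB", "AB", "MAB"))
  expect_equal(glance(st)$triplex_nM, st$concentrations[["MAB"]])
})
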