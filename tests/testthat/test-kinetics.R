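test_that("dissociation rates follow the free energies", {
  cfg <- kinetic_config()
  m <- model_from_dg(0, -10, -10)
  expect_equal(m$rates$d1, cfg$k_on * 1e9) # dG = 0: Kd = 1 M
  # additive energies: the second-binding Kd equals the first duplex Kd
  m2 <- model_from_dg(-8, -6, -14)
  expect_equal(m2$rates$d12 / m2$rates$a12, m2$rates$d1 / m2$rates$a1,
               tolerance = 1e-12)
  # 1.42 kcal/mol at 310.15 K shifts a stepwise Kd about tenfold
  m3a <- model_from_dg(-8, -6, -14)
  m3b <- model_from_dg(-8, -6, -15.42)
  expect_equal(m3a$rates$d12 / m3b$rates$d12, 10, tolerance = 0.01)
})

test_that("the miRNA-free steady state is exactly one", {
  m <- model_from_dg(-12, -10, -28)
  expect_identical(steady_state(m, 0, 0), 1)
  expect_identical(steady_state(m, 0, 0, method = "ode"), 1)
})

test_that("without binding the target is never repressed", {
  m <- model_from_dg(-12, -10, -28, config = kinetic_config(k_on = 0))
  for (tf in c(0.1, 1, 100)) {
    expect_equal(steady_state(m, tf, tf), 1)
  }
  rg <- repression_gain(m)
  expect_equal(c(rg$RG1, rg$RG2, rg$RG3), c(0, 0, 0))
})

test_that("a symmetric model gives a symmetric steady-state surface", {
  m <- model_from_dg(-9, -9, -24)
  for (tf in list(c(0.5, 7), c(1, 10), c(3, 80))) {
    expect_equal(steady_state(m, tf[1], tf[2]), steady_state(m, tf[2], tf[1]),
                 tolerance = 1e-10)
  }
})

test_that("Newton and ODE integration agree on random parameterizations", {
  set.seed(77)
  for (i in 1:8) {
    d1 <- -runif(1, 4, 16)
    d2 <- -runif(1, 4, 16)
    dt <- min(d1, d2) - runif(1, 0, 15)
    m <- model_from_dg(d1, d2, dt)
    tf <- 10^stats::runif(2, -1, 2)
    sn <- steady_state(m, tf[1], tf[2], method = "newton")
    so <- steady_state(m, tf[1], tf[2], method = "ode")
    expect_equal(sn, so, tolerance = 1e-6)
  }
})

test_that("steady states stay in [0,1] and decrease with miRNA expression", {
  set.seed(101)
  for (i in 1:6) {
    d1 <- -runif(1, 3, 14)
    d2 <- -runif(1, 3, 14)
    dt <- min(d1, d2) - runif(1, 0, 18)
    m <- model_from_dg(d1, d2, dt)
    tf <- 10^seq(-1, 2, length.out = 7)
    ss_row <- vapply(tf, function(x) steady_state(m, x, 1), numeric(1))
    ss_col <- vapply(tf, function(x) steady_state(m, 1, x), numeric(1))
    expect_true(all(ss_row >= 0 & ss_row <= 1))
    expect_true(all(diff(ss_row) <= 1e-8))
    expect_true(all(diff(ss_col) <= 1e-8))
  }
})

test_that("mRNA mass balances at steady state", {
  m <- model_from_dg(-11, -9, -26)
  cfg <- m$config
  ss <- steady_state(m, 5, 5, full = TRUE)
  y <- attr(ss, "state")
  influx <- cfg$k_m
  outflux <- cfg$delta_m * y[1] + cfg$delta_C * (y[4] + y[5]) +
    cfg$delta_T * y[6]
  expect_equal(outflux / influx, 1, tolerance = 1e-9)
})

test_that("only one binding-competent miRNA yields one-sided gains", {
  # miRNA 2 binds negligibly: its duplex is unstable and the triplex
  # carries no gain over duplex 1
  m <- model_from_dg(-12, +3, -9)
  rg <- repression_gain(m)
  expect_gt(rg$RG1, 1e-4)
  expect_lt(abs(rg$RG2), 1e-6)
})

test_that("repression gains match the steady-state differences and sign flag", {
  m <- model_from_dg(-8, -8, -30)
  rg <- repression_gain(m)
  expect_equal(rg$RG1, rg$ss_11 - rg$ss_10_1)
  expect_equal(rg$RG3, rg$ss_11 - rg$ss_5_5)
  lit <- repression_gain(m, convention = "literal")
  expect_equal(lit$RG1, -rg$RG1)
  expect_equal(lit$synergy_class, rg$synergy_class)
})

test_that("stable triplexes synergise, unstable ones merely add up", {
  # matched baseline kinetics; only the complex energies differ
  strong <- repression_gain(model_from_dg(-8, -8, -30))
  expect_gt(strong$RG3, max(strong$RG1, strong$RG2))
  expect_equal(strong$synergy_class, "synergistic")

  weak <- repression_gain(model_from_dg(-8, -8, -10))
  expect_lte(weak$RG3, max(weak$RG1, weak$RG2))
  expect_equal(weak$synergy_class, "additive")
})

test_that("the repression surface is monotone with its worst corner", {
  m <- model_from_dg(-7, -9, -28)
  surf <- repression_surface(m, tf_points = 7)
  expect_true(all(surf$ss >= 0 & surf$ss <= 1))
  expect_true(all(apply(surf$ss, 1, function(r) all(diff(r) <= 1e-8))))
  expect_true(all(apply(surf$ss, 2, function(r) all(diff(r) <= 1e-8))))
  expect_equal(min(surf$ss), surf$ss[7, 7])
  td <- tidy(surf)
  expect_equal(nrow(td), 49)
  expect_equal(td$ss[td$tf1 == surf$tf1[3] & td$tf2 == surf$tf2[5]],
               surf$ss[3, 5])
})

test_that("the no-binding surface is identically one", {
  m <- model_from_dg(-12, -10, -28, config = kinetic_config(k_on = 0))
  surf <- repression_surface(m, tf_points = 5)
  expect_true(all(surf$ss == 1))
  expect_equal(surf$synergy_class, "additive")
})

test_that("the reaction list reflects recycling and expression factors", {
  m <- model_from_dg(-10, -10, -24)
  rl <- reaction_list(m, tf1 = 5, tf2 = 1)
  expect_true("T -> R1 + R2" %in% rl$reaction)
  expect_equal(rl$value[rl$rate_constant == "TF1*k_1"], 5 * m$config$k_1)
  m_nr <- model_from_dg(-10, -10, -24,
                        config = kinetic_config(recycle = FALSE))
  expect_true("T -> 0" %in% reaction_list(m_nr)$reaction)
})
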