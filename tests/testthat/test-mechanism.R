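ddg_tab <- function(variant, ddg, conformation,
                    unit = "kcal_per_mol") {
  data.frame(variant = variant, conformation = conformation, ddg = ddg,
             unit = unit, stringsAsFactors = FALSE)
}

test_that("internal-energy conversion is linear through 2.9", {
  expect_equal(reu_to_kcal(2.9), 1.0)
  expect_equal(reu_to_kcal(0), 0)
  expect_equal(reu_to_kcal(5.8), 2.0)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50); a <- runif(1, -3, 3)
  expect_equal(reu_to_kcal(x + y), reu_to_kcal(x) + reu_to_kcal(y))
  expect_equal(reu_to_kcal(a * x), a * reu_to_kcal(x))
  expect_error(reu_to_kcal(NaN), "non-finite")
})

test_that("equilibrium-shift score subtracts closed from super-open", {
  cl <- ddg_tab(c("p.A2V", "p.A3V", "p.F160S"), c(0.5, 1.2, 0.3), "closed")
  so <- ddg_tab(c("p.A2V", "p.A3V"), c(1.0, 1.2), "super-open")
  out <- delta_ddg(cl, so)
  expect_equal(out$delta_ddg[1], 0.5)        # toward closed
  expect_equal(out$delta_ddg[2], 0)
  expect_equal(out$verdict[3], "no-data")    # disordered-loop position
  expect_true(is.na(out$delta_ddg[3]))
  expect_error(delta_ddg(cl, ddg_tab("p.A2V", 1, "closed")),
               "same conformation")

  # declared units are converted before subtraction
  so_reu <- ddg_tab(c("p.A2V", "p.A3V"), c(2.9, 3.48), "super-open",
                    unit = "internal_energy_units")
  out <- delta_ddg(cl, so_reu)
  expect_equal(out$delta_ddg[1:2], c(0.5, 0))
  expect_error(delta_ddg(transform(cl, unit = "rosetta"), so),
               "undeclared")
})

test_that("equilibrium-shift score is antisymmetric", {
  set.seed(8)
  v <- sprintf("p.A%dV", 2:41)
  a <- ddg_tab(v, rnorm(40), "closed")
  b <- ddg_tab(v, rnorm(40), "super-open")
  ab <- delta_ddg(a, b)
  b2 <- b; b2$conformation <- "closed"
  a2 <- a; a2$conformation <- "super-open"
  ba <- delta_ddg(b2, a2)
  expect_equal(ab$delta_ddg, -ba$delta_ddg)
})

test_that("the hyperactive shift filter applies strict thresholds", {
  calls <- data.frame(
    variant = c("a", "b", "c", "d", "e"),
    ddg_closed = c(1.0, 1.0, 2.5, 1.0, 1.0),
    ddg_superopen = c(1.5, 1.5, 3.0, 1.2, NA),
    delta_ddg = c(0.5, 0.5, 0.5, 0.2, NA))
  scores <- data.frame(variant = c("a", "b", "c", "d", "e"),
                       score = c(1.30, 1.18, 1.30, 1.30, 1.30))
  out <- hyperactive_shift_filter(scores, calls)
  expect_equal(out$variant, "a")   # b: boundary score; c: unstable;
                                   # d: small shift; e: no data
})

test_that("loosening any filter threshold never removes candidates", {
  set.seed(12)
  calls <- data.frame(variant = sprintf("v%d", 1:300),
                      ddg_closed = rnorm(300, 1, 1.5),
                      ddg_superopen = rnorm(300, 1, 1.5))
  calls$delta_ddg <- calls$ddg_superopen - calls$ddg_closed
  scores <- data.frame(variant = calls$variant,
                       score = rnorm(300, 1, 0.4))
  base <- hyperactive_shift_filter(scores, calls)$variant
  for (looser in list(c(1.0, 2, 0.25), c(1.18, 3, 0.25),
                      c(1.18, 2, 0.1))) {
    got <- hyperactive_shift_filter(scores, calls, looser[1], looser[2],
                                    looser[3])$variant
    expect_true(all(base %in% got))
  }
})

test_that("planted equilibrium-shift variants are recovered from noisy ddg", {
  truth <- generate_truth(seed = 17)
  tabs <- simulate_ddg_tables(truth, noise_sd = 0.25, seed = 18)
  calls <- delta_ddg(tabs$closed, tabs$superopen)
  scores <- data.frame(variant = truth$variant,
                       score = truth$true_activity)
  hits <- hyperactive_shift_filter(scores, calls)$variant

  mis <- truth[truth$consequence == "missense", ]
  planted <- mis$variant[!is.na(mis$ddg_superopen) &
                         (mis$ddg_superopen - mis$ddg_closed) > 0.5 &
                         mis$ddg_closed < 1 & mis$true_activity > 1.18 &
                         !(mis$position %in% 157:179)]
  sens <- mean(planted %in% hits)
  expect_gte(sens, 0.9)
  # enrichment over variants with no true shift toward the closed state
  unshifted <- mis$variant[!is.na(mis$ddg_superopen) &
                           (mis$ddg_superopen - mis$ddg_closed) <= 0.25 &
                           !(mis$position %in% 157:179)]
  fp <- mean(unshifted %in% hits)
  expect_gte(sens / max(fp, 1e-6), 10)
})

test_that("per-position medians use available missense values", {
  d <- data.frame(position = rep(5L, 19), value = 1:19)
  expect_equal(position_median(d$position, d$value)$median, 10)
  d <- data.frame(position = rep(6L, 18), value = 1:18)
  expect_equal(position_median(d$position, d$value)$median, 9.5)
  out <- position_median(c(7L, 7L), c(NA, NA), positions = 7L)
  expect_true(out$all_missing)
  expect_true(is.na(out$median))
  # nonsense values are excluded when consequences are supplied
  out <- position_median(rep(8L, 3), c(1, 2, 100),
                         consequence = c("missense", "missense",
                                         "nonsense"))
  expect_equal(out$median, 1.5)
})
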