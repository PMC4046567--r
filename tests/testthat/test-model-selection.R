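test_that("F statistic and p value match the textbook definition", {
  # equal fits: nothing gained
  ft0 <- f_test(1.0, 4, 1.0, 7, 200)
  expect_identical(ft0$f_stat, 0)
  expect_identical(ft0$p_value, 1)

  # worked example, p value checked against numeric integration of the
  # F(3, 193) density
  ft <- f_test(1.0, 4, 0.9, 7, 200)
  expect_equal(ft$f_stat, (0.1 / 3) / (0.9 / 193), tolerance = 1e-12)
  expect_equal(ft$f_stat, 7.148645, tolerance = 1e-4)
  p_oracle <- integrate(function(x) df(x, 3, 193), ft$f_stat, Inf,
                        rel.tol = 1e-12)$value
  expect_lt(abs(ft$p_value - p_oracle), 1e-6)

  # a richer model that fits worse is clamped with a warning
  expect_warning(ft_bad <- f_test(1.0, 4, 1.0 + 1e-12, 7, 200), "clamped")
  expect_identical(ft_bad$f_stat, 0)
  expect_identical(ft_bad$p_value, 1)

  expect_error(f_test(1, 5, 0.9, 5, 100), "more parameters")
  expect_error(f_test(1, 4, 0.9, 7, 7), "exceed")
})

test_that("one-extra-parameter F test equals the squared t statistic", {
  set.seed(9)
  x <- seq(0, 1, length.out = 40)
  y <- 1 + 0.4 * x + rnorm(40, 0, 0.1)
  m0 <- lm(y ~ 1)
  m1 <- lm(y ~ x)
  ft <- f_test(sum(resid(m0)^2), 1, sum(resid(m1)^2), 2, 40)
  tval <- summary(m1)$coefficients["x", "t value"]
  expect_equal(ft$f_stat, tval^2, tolerance = 1e-10)
  expect_equal(ft$p_value,
               summary(m1)$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("noiseless single-Gaussian groups keep one component", {
  sc <- synthetic_scenario("p",
    list(a = single_gaussian_model(3.2, 0.3, 0.3, 0.06),
         b = single_gaussian_model(4.3, 0.35, 0.25, 0.06)),
    t_max = 3, n_points = 200, snr = Inf, seed = 2)
  sel <- select_components(generate_traces(sc), max_components = 3,
                           n_starts = 3, seed = 0)
  expect_identical(unname(sel$n_components_final), c(1L, 1L))
  expect_length(sel$ladder, 1L)
  expect_gte(sel$ladder[[1L]]$p_value, 0.05)
})

test_that("a well-separated bimodal truth is resolved into two components", {
  sc <- synthetic_scenario("p",
    list(mix = bimodal_model(3.0, 4.5, p1 = 0.5, depth = 0.3, rate = 0.08)),
    t_max = 3, n_points = 250, snr = 50, seed = 77)
  sel <- select_components(generate_traces(sc), max_components = 3,
                           n_starts = 5, seed = 0)
  expect_identical(unname(sel$n_components_final), 2L)
  pops <- vapply(sel$chosen$per_trace$mix$distribution$components,
                 `[[`, numeric(1), "weight")
  expect_lt(max(abs(pops - 0.5)), 0.05)
})

test_that("condition summaries report populations and mean distance in A", {
  fake <- structure(list(
    per_trace = list(x = list(
      distribution = distance_distribution(
        gaussian_component(3.5, 0.1)),
      depth = 0.3)),
    rates = c(x = 0.05), conditions = "x"), class = "global_fit_result")
  sm <- summarize_condition(fake, "x")
  expect_equal(sm$mean_distance_A, 35.0, tolerance = 1e-3)
  expect_equal(sm$components$population, 1)

  fake2 <- structure(list(
    per_trace = list(x = list(
      distribution = distance_distribution(
        gaussian_component(2.5, 0.1, 0.25),
        gaussian_component(4.5, 0.1, 0.75)),
      depth = 0.3)),
    rates = c(x = 0.05), conditions = "x"), class = "global_fit_result")
  sm2 <- summarize_condition(fake2, "x")
  expect_equal(sm2$mean_distance_A, 40.0, tolerance = 1e-3)
  expect_equal(sum(sm2$components$population), 1, tolerance = 1e-6)

  expect_error(summarize_condition(fake, "missing"), "not present")
})

test_that("grid truncation shifts the mean exactly as a dense grid says", {
  fake <- structure(list(
    per_trace = list(x = list(
      distribution = distance_distribution(gaussian_component(1.2, 0.3)),
      depth = 0.3)),
    rates = c(x = 0.05), conditions = "x"), class = "global_fit_result")
  coarse <- summarize_condition(fake, "x", default_r_grid())
  dense <- summarize_condition(fake, "x", seq(1, 10, by = 0.002))
  # truncation shifts the mean well above the bare centre ...
  expect_gt(coarse$mean_distance_A, 12.0)
  # ... and the coarse grid agrees with the dense oracle to 0.01 A
  expect_lt(abs(coarse$mean_distance_A - dense$mean_distance_A), 0.01)
})

test_that("population shifts across conditions are tabulated per state", {
  mk <- function(id, p_short) structure(list(
    condition_id = id, mean_distance_A = 25 * p_short + 45 * (1 - p_short),
    depth = 0.3, background_rate = 0.05,
    components = data.frame(center_A = c(25.5, 44.6),
                            width_A = c(3, 3.5),
                            population = c(p_short, 1 - p_short))),
    class = "condition_summary")
  ref <- c(nucleotide_bound = 25, HES_like = 45)

  same <- compare_conditions(list(mk("t0", 0.8), mk("t1", 0.8)), ref)
  expect_equal(unlist(same$shifts[2, -1]), c(nucleotide_bound = 0,
                                             HES_like = 0, unassigned = 0))

  turn <- compare_conditions(list(mk("A", 0.8), mk("B", 0.3)), ref)
  expect_equal(turn$shifts$nucleotide_bound[2], -0.5, tolerance = 1e-6)
  expect_equal(turn$shifts$HES_like[2], 0.5, tolerance = 1e-6)
  expect_true(all(abs(rowSums(turn$populations[, -1]) - 1) < 1e-6))

  # a component far from every reference is unassigned
  lost <- mk("far", 0.5)
  lost$components$center_A <- c(35, 44.6)
  cc <- compare_conditions(list(lost), ref)
  expect_equal(cc$populations$unassigned[1], 0.5, tolerance = 1e-9)

  # two components competing for one state warn and are pooled
  amb <- mk("amb", 0.5)
  amb$components$center_A <- c(24.5, 26.0)
  expect_warning(compare_conditions(list(amb), ref), "pooled")
})

test_that("detection of a second component grows with signal-to-noise", {
  detect_rate <- function(snr, n_rep = 100) {
    hits <- logical(n_rep)
    for (s in seq_len(n_rep)) {
      sc <- synthetic_scenario("p",
        list(mix = bimodal_model(3.0, 4.5, p1 = 0.5, depth = 0.3,
                                 rate = 0.08)),
        t_max = 2.5, n_points = 150, snr = snr, seed = 4000 + s)
      sel <- select_components(generate_traces(sc), max_components = 2,
                               n_starts = 3, seed = 0)
      hits[s] <- sel$n_components_final[[1L]] == 2L
    }
    mean(hits)
  }
  rates <- vapply(c(10, 30, 100), detect_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
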