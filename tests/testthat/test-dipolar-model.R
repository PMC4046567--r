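test_that("dipolar kernel has the right limits and bounds", {
  rr <- c(2, 3.5, 5, 8)
  expect_equal(dipolar_kernel(0, rr), rep(1, 4))
  expect_equal(dipolar_kernel(seq(0.5, 4, by = 0.5), 1e3),
               rep(1, 8), tolerance = 1e-9)
  K <- dipolar_kernel(seq(0, 8, length.out = 60), seq(1.5, 8, length.out = 60))
  expect_true(all(K >= -1 & K <= 1))
  expect_error(dipolar_kernel(1, -2), "> 0")
})

test_that("Fresnel closed form matches independent angular quadrature", {
  # adaptive-quadrature oracle at a single point
  om <- 2 * pi * 52.04 / 27
  oracle <- integrate(function(x) cos((1 - 3 * x^2) * om * 1.0), 0, 1,
                      rel.tol = 1e-12)$value
  expect_lt(abs(dipolar_kernel(1.0, 3.0) - oracle), 1e-8)
  expect_lt(abs(dipolar_kernel(1.0, 3.0,
                               method = "quadrature", nodes = 1e4) - oracle),
            1e-10)

  # closed form vs the package's Gauss-Legendre route on a grid
  tg <- seq(0, 8, length.out = 40)
  rg <- seq(1.5, 8, length.out = 40)
  dev <- abs(dipolar_kernel(tg, rg) -
               dipolar_kernel(tg, rg, method = "quadrature", nodes = 4000))
  expect_lt(max(dev), 1e-6)
})

test_that("kernel oscillation period scales as r cubed", {
  first_min_time <- function(r) {
    period <- r^3 / 52.04
    tt <- seq(0, 1.2 * period, length.out = 2000)
    K <- dipolar_kernel(tt, r)
    i <- which(diff(sign(diff(K))) > 0)[1L] + 1L
    tt[i]
  }
  tm <- vapply(c(2, 3, 4), first_min_time, numeric(1))
  ratio <- tm / c(2, 3, 4)^3
  expect_lt(max(ratio) - min(ratio), 0.01 * mean(ratio))
})

test_that("kernel matrix cache returns bit-identical results", {
  tt <- seq(0, 2.7, length.out = 111)
  rg <- seq(1, 10, by = 0.05)
  K1 <- kernel_matrix(tt, rg, use_cache = FALSE)
  K2 <- kernel_matrix(tt, rg, use_cache = TRUE)
  K3 <- kernel_matrix(tt, rg, use_cache = TRUE)
  expect_identical(K1, K2)
  expect_identical(K2, K3)
})

test_that("distance distributions integrate to one on the grid", {
  rg <- default_r_grid()
  wr <- c(diff(rg)[1] / 2,
          (head(diff(rg), -1) + tail(diff(rg), -1)) / 2,
          tail(diff(rg), 1) / 2)

  d1 <- distance_distribution(gaussian_component(3.5, 0.3))
  expect_equal(sum(wr * evaluate_distribution(d1, rg)), 1, tolerance = 1e-6)

  # separated components put their weights where they belong
  d2 <- distance_distribution(gaussian_component(2.5, 0.2, 0.3),
                              gaussian_component(4.5, 0.2, 0.7))
  P <- evaluate_distribution(d2, rg)
  below <- rg < 3.5
  expect_equal(sum((wr * P)[below]), 0.3, tolerance = 1e-4)

  # truncation at the lower edge is renormalized away
  d3 <- distance_distribution(gaussian_component(1.1, 0.3))
  expect_equal(sum(wr * evaluate_distribution(d3, rg)), 1, tolerance = 1e-6)

  # a grid coarser than half the narrowest width warns
  expect_warning(evaluate_distribution(d1, seq(1, 10, by = 0.2)),
                 "under-resolved")
})

test_that("form factor starts at one and respects narrow/mixture limits", {
  tt <- seq(0, 3, length.out = 200)
  d <- distance_distribution(gaussian_component(3.0, 0.25, 0.4),
                             gaussian_component(4.2, 0.4, 0.6))
  Fv <- form_factor(d, tt)
  expect_equal(Fv[1L], 1, tolerance = 1e-6)
  expect_true(all(abs(Fv) <= 1 + 1e-9))

  # a width at the narrow limit approaches the bare kernel; the residual
  # difference is real dephasing, ~ (3 sigma omega t / r)^2 / 2 of the
  # oscillation amplitude (about 7e-3 by 3 us for sigma = 0.02 nm at
  # 3.5 nm), not quadrature error (identical on a 4x finer grid)
  dn <- distance_distribution(gaussian_component(3.5, 0.02))
  rg_fine <- seq(1, 10, by = 0.005)
  d_coarse <- max(abs(suppressWarnings(form_factor(dn, tt)) -
                        dipolar_kernel(tt, 3.5)))
  d_fine <- max(abs(form_factor(dn, tt, rg_fine) - dipolar_kernel(tt, 3.5)))
  expect_lt(d_fine, 0.01)
  expect_lt(abs(d_coarse - d_fine), 1e-3)
  # and the limit tightens as the width shrinks
  d_wide <- max(abs(form_factor(
    distance_distribution(gaussian_component(3.5, 0.1)), tt, rg_fine) -
      dipolar_kernel(tt, 3.5)))
  expect_lt(d_fine, d_wide / 5)

  # equal narrow mixture = mean of the single-component form factors
  da <- distance_distribution(gaussian_component(2.8, 0.05))
  db <- distance_distribution(gaussian_component(4.4, 0.05))
  dab <- distance_distribution(gaussian_component(2.8, 0.05, 0.5),
                               gaussian_component(4.4, 0.05, 0.5))
  expect_lt(max(abs(form_factor(dab, tt) -
                      (form_factor(da, tt) + form_factor(db, tt)) / 2)),
            1e-3)
})

test_that("background is exponential with the stated slope", {
  tt <- seq(0, 4, length.out = 100)
  expect_equal(background(background_model(0), tt), rep(1, 100))
  expect_equal(background(background_model(0.1), 2), exp(-0.2))
  B <- background(background_model(0.37), tt)
  fitl <- lm(log(B) ~ tt)
  expect_equal(unname(coef(fitl)[2L]), -0.37, tolerance = 1e-10)
  # lm warns that the fit is essentially perfect, which is the point here
  expect_gt(suppressWarnings(summary(fitl))$r.squared, 1 - 1e-12)
  expect_error(background_model(-0.1), ">= 0")
})

test_that("composite signal matches its building blocks and an oracle", {
  tt <- seq(0, 3, length.out = 150)
  dist <- distance_distribution(gaussian_component(3.5, 0.3))
  bg <- background_model(0.05)

  expect_equal(simulate_signal(signal_model(dist, 0, bg), tt),
               background(bg, tt))
  expect_equal(simulate_signal(signal_model(dist, 1, background_model(0)), tt),
               form_factor(dist, tt))

  # independent double quadrature (adaptive angular integral on a dense
  # 0.001 nm distance grid) at t = 1.5 us
  oracle <- local({
    rg <- seq(1, 10, by = 0.001)
    d <- diff(rg)
    wr <- c(d[1] / 2, (head(d, -1) + tail(d, -1)) / 2, tail(d, 1) / 2)
    P <- dnorm(rg, 3.5, 0.3)
    P <- P / sum(wr * P)
    K <- vapply(rg, function(r)
      integrate(function(x) cos((1 - 3 * x^2) * 2 * pi * 52.04 / r^3 * 1.5),
                0, 1, rel.tol = 1e-12, abs.tol = 1e-14,
                subdivisions = 2000L)$value, numeric(1))
    ((1 - 0.3) + 0.3 * sum(wr * P * K)) * exp(-0.05 * 1.5)
  })
  expect_lt(abs(simulate_signal(signal_model(dist, 0.3, bg), 1.5) - oracle),
            1e-6)
})

test_that("deeper modulation gives a deeper decay wherever F < 1", {
  tt <- seq(0, 3, length.out = 120)
  dist <- distance_distribution(gaussian_component(3.2, 0.3))
  bg <- background_model(0.08)
  Fv <- form_factor(dist, tt)
  sel <- Fv < 1 - 1e-6
  for (dep in list(c(0.1, 0.2), c(0.2, 0.4), c(0.45, 0.6))) {
    V_lo <- simulate_signal(signal_model(dist, dep[1L], bg), tt)
    V_hi <- simulate_signal(signal_model(dist, dep[2L], bg), tt)
    expect_true(all(V_hi[sel] < V_lo[sel]))
  }
})

test_that("fitted mean distance is stable under grid refinement", {
  tr <- make_trace(single_gaussian_model(3.7, 0.35, 0.3, 0.06))
  mean_on <- function(step) {
    rg <- seq(1, 10, by = step)
    f <- global_fit(fit_spec(list(tr), 1, n_starts = 3, seed = 0,
                             r_grid = rg))
    summarize_condition(f, "c1", rg)$mean_distance_A
  }
  expect_lt(abs(mean_on(0.02) - mean_on(0.01)), 0.05)
})
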