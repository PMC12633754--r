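test_that("inner-filter correction follows the absorbance half-sum rule", {
  expect_equal(inner_filter_correct(123.4, 0, 0), 123.4)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * 10^0.1)
  expect_warning(w <- inner_filter_correct(100, 0.4, 0.4),
                 class = "high_absorbance")
  expect_equal(w, 100 * 10^0.4)
  expect_error(inner_filter_correct(100, -0.1, 0),
               class = "malformed_input")
})

test_that("titration-level correction uses per-point absorbances", {
  ts <- titration_series(298, 2e-6, c(0, 1e-5, 3e-5, 5e-5),
                         c(1000, 800, 600, 400),
                         a_ex = c(0, 0.05, 0.1, 0.15),
                         a_em = c(0, 0.01, 0.02, 0.03))
  cc <- correct_titration(ts)
  expect_equal(cc$points$fluorescence,
               ts$points$fluorescence *
                 10^((ts$points$a_ex + ts$points$a_em) / 2))
})

test_that("Stern-Volmer fit is exact on collinear data", {
  ts <- make_linear_titration(1e4)
  fit <- stern_volmer_fit(ts)
  expect_equal(fit$ksv, 1e4)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$fit_r, 1)
  expect_equal(fit$kq, fit$ksv / fit$tau0)
})

test_that("unquenched series yields zero slope with a non-quenching warning", {
  ts <- titration_series(298, 2e-6, c(0, 1e-5, 3e-5, 5e-5),
                         rep(1000, 4))
  expect_warning(fit <- stern_volmer_fit(ts), class = "non_quenching")
  expect_equal(fit$ksv, 0)
  expect_true("non_quenching" %in% fit$flags)
})

test_that("Stern-Volmer slope tracks generator Ka despite 1:1 curvature", {
  # exact-equilibrium data over 10-80 uM: slight curvature tolerated (5%)
  truth <- binding_truth(dH = 0, dS = 8.314 * log(5.47e4))
  ts <- gen_titration(truth, temperatures = 298, noise = noise_model(0),
                      mode = "exact")[[1]]
  fit <- stern_volmer_fit(ts)
  expect_lt(abs(fit$ksv / 5.47e4 - 1), 0.05)

  # in the near-linear regime Ka[Q] <= 0.2 recovery is within 1%
  weak <- binding_truth(dH = 0, dS = 8.314 * log(2.5e3))
  small <- gen_titration(weak, temperatures = 298,
                         noise = noise_model(0), mode = "exact")[[1]]
  expect_lt(abs(stern_volmer_fit(small)$ksv / 2.5e3 - 1), 0.01)
})

test_that("Stern-Volmer fit is invariant to rescaling fluorescence", {
  ts <- gen_titration(noise = noise_model(cv = 0.01, seed = 5))[[1]]
  scaled <- titration_series(ts$temperature, ts$protein_conc,
                             ts$points$ligand_conc,
                             ts$points$fluorescence * 37.5)
  expect_equal(stern_volmer_fit(scaled)$ksv, stern_volmer_fit(ts)$ksv)
})

test_that("kq/ksv equals 1/tau0 to machine precision", {
  expect_identical(quenching_rate_constant(5.47e4, 1e-8), 5.47e12)
  expect_identical(quenching_rate_constant(1.15e4, 1e-8), 1.15e12)
  expect_identical(quenching_rate_constant(0), 0)
  for (seed in 1:5) {
    ts <- gen_titration(noise = noise_model(0.02, seed))[[1]]
    fit <- stern_volmer_fit(ts, tau0 = 1e-8)
    expect_identical(fit$kq * fit$tau0, fit$ksv)
  }
})

test_that("quenching classification follows the rule table", {
  # decreasing Ksv with Kq above the diffusion limit: static
  for (sys in names(ref_ksv)) {
    d <- data.frame(temperature = as.numeric(names(ref_ksv[[sys]])),
                    ksv = unname(ref_ksv[[sys]]),
                    kq = unname(ref_ksv[[sys]]) / 1e-8)
    expect_equal(classify_quenching(d)$verdict, "static", label = sys)
  }
  # increasing Ksv but Kq still above the limit: ambiguous
  amb <- data.frame(temperature = study_temps, ksv = c(1, 2, 3) * 1e3,
                    kq = c(1, 2, 3) * 1e3 / 1e-8)
  expect_equal(classify_quenching(amb)$verdict, "ambiguous")
  # increasing Ksv with small Kq: dynamic
  dyn <- data.frame(temperature = study_temps, ksv = c(1, 1.5, 2) * 1e2,
                    kq = c(1, 1.5, 2) * 1e2 / 1e-8)
  expect_equal(classify_quenching(dyn)$verdict, "dynamic")
})

test_that("classification accepts sv_fit lists from the dynamic generator", {
  sims <- gen_titration(mode = "dynamic", ksv_dyn_298 = 150,
                        noise = noise_model(0))
  fits <- lapply(sims, stern_volmer_fit)
  expect_equal(classify_quenching(fits)$verdict, "dynamic")
})

test_that("double-log fit recovers exact-equilibrium ground truth", {
  truth <- binding_truth(dH = 0, dS = 8.314 * log(1.91e4))
  ts <- gen_titration(truth, temperatures = 298, noise = noise_model(0),
                      mode = "exact")[[1]]
  fit <- double_log_binding_fit(ts)
  expect_lt(abs(fit$n_sites - 1), 0.05)
  expect_lt(abs(fit$ka / 1.91e4 - 1), 0.05)
  expect_equal(fit$fit_r, 1, tolerance = 1e-9)
})

test_that("double-log fit returns a constructed slope exactly", {
  # points lying exactly on y = 1.58 * x + 1.58 * log10(4.07e4)
  n_true <- 1.58
  ka_true <- 4.07e4
  q <- c(1, 2, 4, 6, 8) * 1e-5
  p0 <- 2e-6
  # invert the plot transform: choose F so that both coordinates are exact
  f0 <- 1000
  solve_f <- function(qi) {
    g <- function(f) log10((f0 - f) / f) -
      (n_true * log10(qi - p0 * (f0 - f) / f0) + n_true * log10(ka_true))
    stats::uniroot(g, c(1e-6 * f0, f0 * (1 - 1e-12)), tol = 1e-14)$root
  }
  f <- vapply(q, solve_f, 1)
  ts <- titration_series(298, p0, c(0, q), c(f0, f))
  fit <- double_log_binding_fit(ts)
  expect_equal(fit$n_sites, n_true, tolerance = 1e-6)
  expect_equal(fit$ka, ka_true, tolerance = 1e-4)
})

test_that("interior points with F >= F0 are excluded and reported", {
  truth <- binding_truth()
  ts <- gen_titration(truth, temperatures = 298, noise = noise_model(0),
                      mode = "exact")[[1]]
  pts <- ts$points
  pts$fluorescence[4] <- titration_f0(ts)   # undo quenching at one point
  broken <- titration_series(298, ts$protein_conc, pts$ligand_conc,
                             pts$fluorescence)
  fit <- double_log_binding_fit(broken)
  expect_equal(fit$excluded, 4L)
  expect_lt(abs(fit$ka / ka_at(truth, 298) - 1), 0.01)
})

test_that("double-log fit agrees with a brute-force grid search", {
  # independent oracle: direct minimisation over (log10 Ka, n) of the
  # squared residuals of the double-log relation
  for (seed in 1:5) {
    ts <- gen_titration(binding_truth(), temperatures = 298,
                        noise = noise_model(0.01, seed),
                        mode = "exact")[[1]]
    fit <- double_log_binding_fit(ts)
    f0 <- titration_f0(ts)
    pts <- ts$points[ts$points$ligand_conc > 0, ]
    y <- log10((f0 - pts$fluorescence) / pts$fluorescence)
    x <- log10(pts$ligand_conc -
                 ts$protein_conc * (f0 - pts$fluorescence) / f0)
    # residuals y - n*(x + lka); SSE expanded in precomputed sums so the
    # whole grid evaluates vectorised
    grid <- expand.grid(lka = seq(3, 6, 0.002), n = seq(0.5, 1.5, 0.002))
    sy2 <- sum(y^2); sxy <- sum(x * y); sy <- sum(y)
    sx2 <- sum(x^2); sx <- sum(x); m <- length(y)
    sse <- sy2 - 2 * grid$n * (sxy + grid$lka * sy) +
      grid$n^2 * (sx2 + 2 * grid$lka * sx + m * grid$lka^2)
    best <- grid[which.min(sse), ]
    expect_lt(abs(fit$ka / 10^best$lka - 1), 0.005)
    expect_lt(abs(fit$n_sites / best$n - 1), 0.005)
  }
})
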