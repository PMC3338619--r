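test_that("bound-fraction kernel honours its limits", {
  expect_equal(bound_fraction_model(0, 270, 500), 0)
  # stoichiometric limit kd = 0: fb = min(L, P0)/P0
  for (L in c(0, 100, 270, 500)) {
    expect_equal(bound_fraction_model(L, 270, 0), min(L, 270) / 270,
                 tolerance = 1e-12)
  }
  # hyperbolic limit P0 -> 0: fb = L/(kd + L)
  expect_equal(bound_fraction_model(100, 0.001, 100), 0.5, tolerance = 1e-4)
  expect_error(bound_fraction_model(10, 0, 100), "positive")
  # mass conservation: bound ligand never exceeds min(P0, L)
  set.seed(3)
  for (i in 1:50) {
    L <- runif(1, 0, 5000); P0 <- runif(1, 1, 500); kd <- runif(1, 0, 2000)
    fb <- bound_fraction_model(L, P0, kd)
    expect_gte(fb, 0); expect_lte(fb, 1)
    expect_lte(fb * P0, min(P0, L) + 1e-9)
  }
})

test_that("CSP isotherm and bound fraction share one kernel", {
  grid <- expand.grid(L = c(0, 10, 100, 1000, 10000),
                      P0 = c(1, 18, 270),
                      kd = c(0.1, 45, 669, 5000))
  expect_equal(mapply(function(L, P0, kd)
                 quadratic_csp_model(L, P0, kd, csp_max = 1),
                 grid$L, grid$P0, grid$kd),
               mapply(bound_fraction_model, grid$L, grid$P0, grid$kd),
               tolerance = 1e-12)
  # evaluation at the reported MS incubation point
  expect_equal(bound_fraction_model(67.6, 18, 45), 0.561, tolerance = 1e-2)
})

test_that("model is monotone in L and anti-monotone in kd", {
  set.seed(4)
  for (i in 1:20) {
    P0 <- runif(1, 1, 400)
    kd <- runif(1, 1, 2000)
    L <- sort(runif(8, 0, 8000))
    fb <- bound_fraction_model(L, P0, kd)
    expect_true(all(diff(fb) >= -1e-12))
    kds <- sort(runif(6, 0.1, 5000))
    at_L <- vapply(kds, function(k) bound_fraction_model(1000, P0, k),
                   numeric(1))
    expect_true(all(diff(at_L) <= 1e-12))
  }
})

test_that("noiseless per-residue fits recover generator truth to 1e-6", {
  L <- c(0, 270, 540, 1000, 2000, 4000)
  for (kd_true in c(45, 500, 669, 3425)) {
    csp <- quadratic_csp_model(L, 270, kd_true, 0.1)
    fit <- fit_residue_kd(L, csp, P0 = 270, residue_id = 184L)
    expect_equal(fit$kd, kd_true, tolerance = 1e-6)
    expect_equal(fit$csp_max, 0.1, tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("fit preconditions: too few points and non-binders are errors", {
  expect_error(fit_residue_kd(c(0, 100, 200), c(0, 0.02, 0.04), 270),
               "4 titration points")
  expect_error(fit_residue_kd(c(0, 1, 2, 3), rep(0, 4), 270, 7L),
               "non-binder")
})

test_that("median K_D recovery under shift noise stays within 15%", {
  kd_true <- 500
  L <- c(0, 270, 540, 1000, 2000, 4000)
  truth <- quadratic_csp_model(L, 270, kd_true, 0.1)
  est <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- pmax(truth + rnorm(length(L), 0, 0.003), 0)
    noisy[1] <- 0
    fit_residue_kd(L, noisy, 270)$kd
  }, numeric(1))
  expect_lt(abs(median(est) - kd_true) / kd_true, 0.15)
})

test_that("aggregation averages survivors and ledgers exclusions", {
  mk <- function(id, kd, r2 = 0.99) {
    structure(list(residue_id = id, kd = kd, csp_max = 0.1, rss = 0,
                   r_squared = r2, converged = TRUE, included = TRUE,
                   exclusion_reason = "none",
                   data = data.frame(L = 0:4, csp = 0:4), P0 = 270),
              class = "kd_fit")
  }
  # degenerate: 30 identical values
  agg <- aggregate_kd(lapply(1:30, function(i) mk(i, 669)))
  expect_equal(agg$mean_kd, 669)
  expect_equal(agg$sd_kd, 0)
  expect_equal(agg$n_used, 30L)
  expect_equal(nrow(agg$excluded), 0L)

  # one wild outlier among 30
  set.seed(8)
  fits <- c(lapply(1:29, function(i) mk(i, 100 * runif(1, 0.9, 1.1))),
            list(mk(30L, 10000)))
  agg <- aggregate_kd(fits)
  expect_equal(agg$excluded$residue_id, 30)
  expect_equal(agg$excluded$reason, "outlier_kd")
  expect_equal(agg$n_used, 29L)

  # order invariance
  agg_perm <- aggregate_kd(fits[sample(30)])
  expect_equal(agg_perm$mean_kd, agg$mean_kd)
  expect_setequal(agg_perm$excluded$residue_id, agg$excluded$residue_id)

  # poor fits and surface labels excluded before the outlier rule
  fits2 <- c(lapply(1:6, function(i) mk(i, 100)),
             list(mk(7L, 100, r2 = 0.5)))
  labels <- c("1" = "fast", "2" = "buried", "3" = "isolated",
              "4" = "fast", "5" = "fast", "6" = "fast", "7" = "fast")
  agg2 <- aggregate_kd(fits2, surface = labels)
  expect_setequal(agg2$excluded$reason, c("poor_fit", "buried", "isolated"))
  expect_equal(agg2$n_used, 4L)

  # single fit: its kd, sd 0, with a warning
  expect_warning(one <- aggregate_kd(list(mk(1L, 42))), "single")
  expect_equal(one$mean_kd, 42)
  expect_equal(one$sd_kd, 0)

  expect_error(aggregate_kd(list(mk(1L, 42, r2 = 0.1))), "excluded")
})

test_that("noiseless MS fits recover truth; degenerate inputs error", {
  L <- c(0, 5, 10, 25, 50, 100, 200, 300)
  for (kd_true in c(5, 11, 45, 89)) {
    dat <- gen_ms_titration(kd_true, 18, L, noise = 0)
    fit <- fit_ms_kd(dat, P0 = 18, n_boot = 0)
    expect_equal(fit$kd, kd_true, tolerance = 1e-5)
  }
  expect_error(fit_ms_kd(data.frame(ligand_total = L,
                                    bound_fraction = rep(0, 8)), 18),
               "no binding signal")
  expect_error(fit_ms_kd(data.frame(ligand_total = c(0, 1, 2),
                                    bound_fraction = c(0, 0.1, 0.2)), 18),
               "4 MS titration points")
})

test_that("narrow dynamic range flags the MS fit low-confidence", {
  dat <- gen_ms_titration(45, 18, c(0, 2, 4, 6, 8, 10), noise = 0)
  expect_warning(fit <- fit_ms_kd(dat, 18, n_boot = 0), "does not span")
  expect_true(fit$low_confidence)
})

test_that("median MS K_D recovery under fb noise stays within 20%", {
  L <- c(0, 5, 10, 25, 50, 100, 200, 300)
  est <- vapply(1:50, function(s) {
    dat <- gen_ms_titration(45, 18, L, noise = 0.03, seed = s)
    fit_ms_kd(dat, 18, n_boot = 0)$kd
  }, numeric(1))
  expect_lt(abs(median(est) - 45) / 45, 0.20)
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
  dat <- gen_ms_titration(45, 18, c(0, 5, 10, 25, 50, 100, 200, 300),
                          noise = 0.02, seed = 4)
  f1 <- fit_ms_kd(dat, 18, n_boot = 200, seed = 99)
  f2 <- fit_ms_kd(dat, 18, n_boot = 200, seed = 99)
  expect_equal(f1$ci, f2$ci)
  expect_lte(f1$ci[1], f1$kd)
  expect_gte(f1$ci[2], f1$kd)
})

test_that("kd_fit methods are coherent", {
  L <- c(0, 270, 540, 1000, 2000, 4000)
  csp <- quadratic_csp_model(L, 270, 669, 0.1)
  fit <- fit_residue_kd(L, csp, 270, 5L)
  expect_equal(unname(coef(fit)), c(fit$kd, fit$csp_max))
  expect_equal(predict(fit), csp, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})
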