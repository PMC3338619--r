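test_that("combined CSP matches hand arithmetic and is symmetric and nonnegative", {
  expect_equal(combined_csp(8, 8, 110, 110), 0)
  expect_equal(combined_csp(8, 8.03, 110, 110.2, alpha = 0.2), 0.05)
  expect_equal(combined_csp(8, 8.05, 110, 110), 0.05)
  # symmetry under sign flips of either shift difference
  expect_equal(combined_csp(8, 8.03, 110, 109.8), combined_csp(8, 7.97, 110, 110.2))
  set.seed(42)
  for (i in 1:20) {
    dh <- rnorm(1); dn <- rnorm(1)
    expect_gte(combined_csp(8, 8 + dh, 110, 110 + dn), 0)
  }
  expect_error(combined_csp(8, 8, 110, 110, alpha = 0), "alpha")
})

test_that("iterative threshold reproduces hand-iterated cases", {
  # all equal: sd 0, strict removal stops immediately
  r <- iterative_threshold(rep(0.05, 10), "upper")
  expect_equal(r$threshold, 0.05)
  expect_length(r$flagged, 0)
  expect_equal(r$n_iterations, 1L)

  # {0 x9, 1}: pass 1 cut ~0.732 removes 1.0; pass 2 converges at 0
  v <- c(rep(0, 9), 1)
  names(v) <- paste0("r", 1:10)
  r <- iterative_threshold(v, "upper")
  expect_equal(r$threshold, 0)
  expect_equal(r$flagged, "r10")

  # {1,1,1,1,10}: cut 2.8 + 2*4.0249... = 10.85 > 10, nothing removed
  r <- iterative_threshold(c(1, 1, 1, 1, 10), "upper")
  expect_equal(r$threshold, 2.8 + 2 * sd(c(1, 1, 1, 1, 10)), tolerance = 1e-12)
  expect_length(r$flagged, 0)

  # lower direction mirrors the upper one
  v <- c(rep(1, 9), 0.1)
  names(v) <- paste0("r", 1:10)
  r <- iterative_threshold(v, "lower")
  expect_equal(r$threshold, 1)
  expect_equal(r$flagged, "r10")

  expect_error(iterative_threshold(0.5), "at least 2")
})

test_that("iterative threshold agrees with the prefix fixed-point oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    v <- abs(rnorm(n, mean = 0.05, sd = 0.05)) +
      ifelse(runif(n) < 0.25, runif(n, 0.2, 1), 0)
    names(v) <- paste0("r", seq_len(n))
    got <- iterative_threshold(v, "upper")
    ora <- threshold_oracle_upper(v)
    if (is.null(ora) || got$degenerate) next
    expect_equal(length(got$flagged), ora$k)
    expect_setequal(unname(v[got$flagged]), unname(ora$flagged))
    expect_equal(got$threshold, ora$threshold, tolerance = 1e-12)
  }
})

test_that("iterative threshold is permutation-invariant and scale-equivariant", {
  set.seed(7)
  v <- abs(rnorm(12, 0.05, 0.04))
  names(v) <- paste0("r", 1:12)
  base <- iterative_threshold(v, "upper")
  perm <- sample(12)
  shuffled <- iterative_threshold(v[perm], "upper")
  expect_equal(shuffled$threshold, base$threshold)
  expect_setequal(shuffled$flagged, base$flagged)
  for (c_ in c(0.1, 3, 100)) {
    scaled <- iterative_threshold(c_ * v, "upper")
    expect_equal(scaled$threshold, c_ * base$threshold, tolerance = 1e-12)
    expect_setequal(scaled$flagged, base$flagged)
  }
})

test_that("trimming always terminates with a usable retained set", {
  # a removal needs a standardized deviation above 2, which no set of
  # five or fewer values can produce, so trimming can never exhaust them
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    v <- rlnorm(n, sdlog = 2)
    names(v) <- paste0("r", seq_len(n))
    r <- iterative_threshold(v, sample(c("upper", "lower"), 1))
    expect_gte(length(r$retained), min(n, 5))
    expect_false(r$degenerate)
  }
})

test_that("exchange classification applies the regime rules", {
  expect_equal(classify_exchange(0.12, 0.95, 0.087, 0.6), "fast")
  expect_equal(classify_exchange(0.01, 0, 0.087, 0.6, disappeared = TRUE),
               "slow")
  expect_equal(classify_exchange(0.12, 0.3, 0.087, 0.6), "intermediate")
  expect_equal(classify_exchange(0.01, 0.95, 0.087, 0.6), "unperturbed")
  expect_warning(cls <- classify_exchange(0.12, NA, 0.087, NA),
                 "restricted")
  expect_equal(cls, "fast")
})

test_that("trajectory linearity: collinear 1, hand-computed 0.75, degenerate NA", {
  line <- cbind(0:3, 2 * (0:3) + 1)
  expect_equal(trajectory_linearity(line), 1.0)
  expect_equal(trajectory_linearity(rbind(c(0, 0), c(1, 0), c(1, 1))), 0.75)
  expect_true(is.na(trajectory_linearity(rbind(c(1, 1), c(1, 1), c(1, 1)))))
  expect_true(is.na(trajectory_linearity(rbind(c(0, 0), c(1, 1)))))
})

test_that("trajectory linearity is invariant under rotation and translation", {
  set.seed(9)
  pts <- cbind(rnorm(6), rnorm(6))
  base <- trajectory_linearity(pts)
  for (theta in c(0.3, 1.2, 2.9)) {
    Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    moved <- pts %*% Rm + matrix(c(5, -3), 6, 2, byrow = TRUE)
    expect_equal(trajectory_linearity(moved), base, tolerance = 1e-10)
  }
})

test_that("saturation check compares the last increment to the final CSP", {
  expect_true(saturation_check(c(0, 0.04, 0.048, 0.050), rel_tol = 0.15))
  expect_false(saturation_check(c(0, 0.02, 0.04, 0.06), rel_tol = 0.15))
  expect_false(saturation_check(c(0, 0, 0, 0)))
  expect_error(saturation_check(c(0, 0.1)), "3")
})

test_that("csp_titration computes profiles with reference invariants", {
  ser <- gen_titration(regime_scenario(seed = 5))
  ct <- csp_titration(ser)
  expect_true(all(ct$csp[, 1] == 0, na.rm = TRUE))
  expect_true(all(ct$intensity_ratio[, 1] == 1, na.rm = TRUE))
  expect_true(all(ct$csp >= 0, na.rm = TRUE))
  # fast-exchange trajectories are linear for a single binding event
  fast <- ct$profiles$exchange_class == "fast"
  expect_true(all(ct$profiles$linearity[fast] > 0.999))
})

test_that("noiseless regimes are recovered exactly by classification", {
  ser <- gen_titration(regime_scenario(seed = 11, true_kd = 50))
  # fb at the last point exceeds 0.9 so slow peaks disappear/saturate
  expect_gt(bound_fraction_model(5000, 100, 50), 0.9)
  ct <- csp_titration(ser)
  got <- setNames(ct$profiles$exchange_class, ct$profiles$residue_id)
  expect_true(all(got[as.character(1:4)] == "fast"))
  expect_true(all(got[as.character(11:13)] == "intermediate"))
  expect_true(all(got[as.character(21:22)] == "slow"))
  expect_true(all(got[as.character(31:70)] == "unperturbed"))
})

test_that("csp reports are written as TSV", {
  ser <- gen_titration(nucleotide_scenario(seed = 2, n_binders = 3,
                                           n_background = 6))
  ct <- csp_titration(ser)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_csp_report(ct, p1, p2)
  prof <- read.delim(p1)
  expect_equal(nrow(prof), nrow(ct$profiles))
  thr <- read.delim(p2)
  expect_equal(thr$quantity, c("csp", "intensity_ratio"))
})
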