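test_that("design matrix uses event-type contrasts with aGvHD as reference", {
  d <- mar_fixture(n = 200, fraction = 0.3)
  des <- build_design(d, include_aux = FALSE)
  expect_equal(colnames(des$Z), c("(Intercept)", "event2", "event3"))
  desa <- build_design(d, include_aux = TRUE)
  expect_equal(ncol(desa$Z), 4L)
  # outcome rows: observed event times only, censored records excluded
  expect_true(all(d$event[des$obs_idx] %in% 1:3))
  expect_false(anyNA(des$y))

  d1 <- d[d$event %in% c(0L, 1L), ]
  expect_warning(des1 <- build_design(d1, include_aux = FALSE),
                 "dropping")
  expect_equal(colnames(des1$Z), "(Intercept)")
})

test_that("posterior draws centre on the OLS fit", {
  set.seed(31)
  Z <- cbind(1, rnorm(50), rbinom(50, 1, 0.5))
  colnames(Z) <- c("i", "x", "g")
  beta <- c(2, 1, -1)
  y <- drop(Z %*% beta) + rnorm(50, sd = 0.5)
  bh <- qr.solve(Z, y)
  draws <- replicate(4000, unlist(draw_posterior(y, Z)[c("beta_star",
                                                         "sigma_star")]))
  mc_se <- apply(draws[1:3, ], 1, sd) / sqrt(4000)
  expect_true(all(abs(rowMeans(draws[1:3, ]) - bh) < 3 * mc_se))

  # zero residuals: the posterior collapses on the fit
  y0 <- drop(Z %*% beta)
  dr0 <- draw_posterior(y0, Z)
  expect_equal(dr0$sigma_star, 0, tolerance = 1e-8)
  expect_equal(dr0$beta_star, unname(bh0 <- qr.solve(Z, y0)),
               tolerance = 1e-6)

  expect_error(draw_posterior(y, cbind(Z, Z[, 2])), "singular")
  expect_error(draw_posterior(y[1:3], Z[1:3, ]), "observed rows")
})

test_that("predictive distances distinguish the three PMM types", {
  draw <- list(beta_hat = c(1, 2), beta_star = c(1.5, 1))
  zi <- c(1, 1); zh <- c(1, 0.5)
  # type 0: |3 - 2|; type 1: |2.5 - 2|; type 2: |2.5 - 2|
  expect_equal(drop(pmm_distance(zi, zh, draw, 0L)), 1)
  expect_equal(drop(pmm_distance(zi, zh, draw, 1L)), 0.5)
  expect_equal(drop(pmm_distance(zi, zh, draw, 2L)), 0.5)
  expect_equal(drop(pmm_distance(zi, zi, draw, 0L)), 0)
  # type 1 with beta* != beta_hat is positive even for identical rows
  expect_gt(drop(pmm_distance(zi, zi, draw, 1L)), 0)
  # with beta* = beta_hat all three coincide
  dr2 <- list(beta_hat = c(1, 2), beta_star = c(1, 2))
  for (ty in 0:2)
    expect_equal(drop(pmm_distance(zi, zh, dr2, ty)), 1)
})

test_that("normal-family engines honour their range contracts", {
  d <- mar_fixture(n = 400, fraction = 0.5)
  set.seed(41)
  mn <- impute_times(d, imp_spec("norm"))
  expect_equal(dim(mn$imp), c(sum(d$time_missing), 5L))
  # imputations are distinct stochastic draws
  expect_gt(min(apply(mn$imp, 1, function(r) length(unique(r)))), 0)
  expect_false(all(mn$imp[, 1] == mn$imp[, 2]))
  # unrestricted: no bound respected in general
  expect_gt(max(mn$imp), 100)

  ml <- impute_times(d, imp_spec("lognorm"))
  expect_true(all(ml$imp > 0))

  mr <- impute_times(d, imp_spec("resnorm", rejection_cap = 500))
  expect_true(all(mr$imp > 0 & mr$imp <= 100))
  expect_equal(mr$out_of_bounds, 0L)

  # forced exhaustion: every observed time far above the bound
  dfar <- d
  dfar$time[!dfar$time_missing] <- dfar$time[!dfar$time_missing] + 400
  set.seed(42)
  mf <- impute_times(dfar, imp_spec("resnorm", rejection_cap = 50))
  expect_equal(mf$out_of_bounds, 5L * sum(dfar$time_missing))
})

test_that("PMM copies observed donor times", {
  d <- mar_fixture(n = 400, fraction = 0.5)
  obs_times <- d$time[!d$time_missing & d$event != 0L]
  obs1_times <- d$time[!d$time_missing & d$event == 1L]
  set.seed(43)
  mp <- impute_times(d, imp_spec("pmm"))
  expect_true(all(mp$imp %in% obs_times))
  # event type dominates the predictive mean, so donors are cause-1 records
  expect_true(all(mp$imp %in% obs1_times))

  # identical donors with a pool of one: the value is forced
  dd <- d[c(which(!d$time_missing & d$event == 1L)[1:3],
            which(d$time_missing)[1]), ]
  dd$time[!dd$time_missing] <- 55
  set.seed(44)
  m1 <- suppressWarnings(
    impute_times(dd, imp_spec("pmm", donor_pool_size = 1,
                              include_aux = FALSE)))
  expect_true(all(m1$imp == 55))
})

test_that("MICI samples observed cause-1 days inside the bounds", {
  d <- mar_fixture(n = 400, fraction = 0.5)
  obs1 <- d$time[!d$time_missing & d$event == 1L]
  set.seed(45)
  mm <- impute_times(d, imp_spec("mici"))
  expect_true(all(mm$imp %in% obs1))
  expect_true(all(mm$imp > 0 & mm$imp <= 100))

  # a single in-bounds candidate forces a degenerate imputation
  keep1 <- which(!d$time_missing & d$event == 1L & d$time <= 100)[1]
  drop1 <- setdiff(which(!d$time_missing & d$event == 1L & d$time <= 100),
                   keep1)
  d1 <- d[-drop1, ]
  set.seed(46)
  m1 <- impute_times(d1, imp_spec("mici"))
  expect_true(all(m1$imp == d$time[keep1]))
})

test_that("imputation is reproducible and completion restores integrity", {
  d <- mar_fixture(n = 300, fraction = 0.3)
  for (meth in c("norm", "lognorm", "resnorm", "pmm", "mici")) {
    set.seed(47); a <- impute_times(d, imp_spec(meth))
    set.seed(47); b <- impute_times(d, imp_spec(meth))
    expect_identical(a$imp, b$imp, label = meth)

    cd <- complete(a, 2)
    expect_equal(nrow(cd), nrow(d))
    expect_false(any(cd$time_missing))
    expect_false(anyNA(cd$time))
    expect_true(all(cd$event[d$time_missing] == 1L), label = meth)
    # untouched records keep their values
    expect_identical(cd$time[!d$time_missing], d$time[!d$time_missing])
  }

  # no flags: completion is the identity on times and events
  d0 <- generate_dataset(sim_config(n_subjects = 50))
  set.seed(48)
  m0 <- impute_times(d0, imp_spec("norm"))
  c0 <- complete(m0, 1)
  expect_identical(c0$time, d0$time)
  expect_identical(c0$event, d0$event)

  expect_error(impute_times(transform(d, interval_left = NA_real_),
                            imp_spec("norm")), "bounds")
})
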