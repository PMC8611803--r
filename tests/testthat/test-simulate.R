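test_that("event types follow the cause distribution", {
  cfg1 <- sim_config(event_probs = c(1, 0, 0))
  expect_true(all(draw_event_type(100, cfg1) == 1L))
  cfg3 <- sim_config(event_probs = c(0, 0, 1))
  expect_true(all(draw_event_type(100, cfg3) == 3L))

  set.seed(5)
  e <- draw_event_type(1e5, sim_config())
  expect_equal(mean(e == 1L), 0.65, tolerance = 0.005)
  gof <- chisq.test(tabulate(e, 3L), p = c(0.65, 0.25, 0.10))
  expect_gt(gof$p.value, 0.001)
})

test_that("inverse-transform times are ceiled log-normal quantiles", {
  cfg <- sim_config()
  expect_equal(inverse_transform_time(1L, 0.5, cfg), 26)
  expect_equal(inverse_transform_time(3L, 0.5, cfg), 77)
  expect_equal(inverse_transform_time(1L, 0.975, cfg), 102)
  expect_error(inverse_transform_time(1L, 0, cfg), "inside")
  expect_error(inverse_transform_time(1L, 1, cfg), "inside")

  # empirical quantiles match the ceiled quantile function, per cause
  set.seed(8)
  for (cause in 1:3) {
    tm <- inverse_transform_time(rep(cause, 1e5), runif(1e5), cfg)
    probs <- seq(0.05, 0.95, by = 0.05)
    qs <- quantile(tm, probs, type = 1)
    ref <- ceiling(qlnorm(probs, cfg$lognormal_mu[cause],
                          cfg$lognormal_sigma[cause]))
    expect_true(all(abs(qs - ref) <= pmax(1, 0.02 * ref)),
                label = sprintf("cause %d quantiles", cause))
  }
})

test_that("generated datasets respect the censoring horizon and are seeded", {
  set.seed(3)
  d <- generate_dataset(sim_config())
  expect_equal(nrow(d), 500L)
  expect_true(all(d$time >= 1))
  expect_true(all(d$time[d$event == 0L] == 365))
  expect_true(all(d$time <= 365))
  expect_false(any(d$time_missing))

  set.seed(99); d1 <- generate_dataset(sim_config())
  set.seed(99); d2 <- generate_dataset(sim_config())
  expect_identical(d1, d2)

  # horizon below any feasible event day censors everyone
  set.seed(4)
  d0 <- generate_dataset(sim_config(admin_censor_day = 1, bounds = c(0, 1)))
  expect_true(all(d0$event == 0L))
  expect_true(all(d0$time == 1))
})

test_that("MNAR flags the extreme order statistics deterministically", {
  d <- data.frame(id = 1:12,
                  time = c(seq(10, 100, by = 10), 365, 50),
                  event = c(rep(1L, 10), 0L, 2L),
                  aux = 0L, time_missing = FALSE,
                  interval_left = NA_real_, interval_right = NA_real_,
                  true_time = c(seq(10, 100, by = 10), 365, 50))
  class(d) <- c("crd_data", "data.frame")

  sm <- apply_mdm(d, mdm_spec("MNAR", 0.3))
  expect_equal(sort(sm$true_time[sm$time_missing]), c(10, 20, 30))
  lg <- apply_mdm(d, mdm_spec("MNAR", 0.3, mnar_direction = "largest"))
  expect_equal(sort(lg$true_time[lg$time_missing]), c(80, 90, 100))

  # competing / censored records are never flagged, times are blanked,
  # bounds attached
  expect_true(all(sm$event[sm$time_missing] == 1L))
  expect_true(all(is.na(sm$time[sm$time_missing])))
  expect_equal(unique(sm$interval_right[sm$time_missing]), 100)

  # deterministic and RNG-free
  set.seed(1); r0 <- .Random.seed
  sm2 <- apply_mdm(d, mdm_spec("MNAR", 0.3))
  expect_identical(r0, .Random.seed)
  expect_identical(sm, sm2)

  expect_warning(apply_mdm(d, mdm_spec("MNAR", 0.05)), "no records flagged")
  expect_error(apply_mdm(sm, mdm_spec("MAR", 0.3)), "already")
})

test_that("MAR flags only aGvHD records at the nominal rate", {
  n <- 8e4
  set.seed(21)
  ev <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  d <- data.frame(id = seq_len(n), time = 50, event = ev, aux = 0L,
                  time_missing = FALSE, interval_left = NA_real_,
                  interval_right = NA_real_, true_time = 50)
  class(d) <- c("crd_data", "data.frame")
  m <- apply_mdm(d, mdm_spec("MAR", 0.5))
  expect_lt(abs(mean(m$time_missing[m$event == 1L]) - 0.5), 0.01)
  expect_equal(sum(m$time_missing[m$event != 1L]), 0L)

  # MCAR flags irrespective of event type
  mc <- apply_mdm(d, mdm_spec("MCAR", 0.3))
  for (e in 1:3)
    expect_equal(mean(mc$time_missing[mc$event == e]), 0.3,
                 tolerance = 0.03)
})

test_that("analytic truth matches an independent numerical oracle", {
  cfg <- sim_config()
  tr <- true_estimands(cfg)
  # oracle: integrate the cause-1 log-normal density over (0, 100]
  num <- cfg$event_probs[1] *
    integrate(dlnorm, 0, 100, meanlog = cfg$lognormal_mu[1],
              sdlog = cfg$lognormal_sigma[1])$value
  expect_equal(tr$cif, num, tolerance = 1e-6)
  expect_equal(round(tr$cif, 4), 0.6331)

  # oracle: brute-force scan over integer days
  cifs <- cfg$event_probs[1] *
    pnorm((log(1:365) - cfg$lognormal_mu[1]) / cfg$lognormal_sigma[1])
  expect_equal(tr$median, which(cifs >= 0.5)[1])
  expect_equal(tr$median, 44)
  cont <- true_estimands(cfg, median_convention = "continuous")$median
  expect_lt(abs(cfg$event_probs[1] *
                plnorm(cont, cfg$lognormal_mu[1], cfg$lognormal_sigma[1]) -
              0.5), 1e-10)

  expect_true(is.na(true_estimands(sim_config(
    event_probs = c(0.45, 0.45, 0.10)))$median))
  expect_error(true_estimands(cfg, horizon = 400), "horizon")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(event_probs = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(sim_config(lognormal_sigma = c(0, 1, 1)), "sigma")
  expect_error(sim_config(bounds = c(100, 50)), "bounds")
  expect_error(sim_config(bounds = c(0, 400)), "bounds")
  expect_error(mdm_spec("MAR", 0), "fraction")
})
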