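test_that("design scenarios construct and apply trap rules", {
  traps <- build_grid(10, 10, 9.43)
  expect_equal(nrow(scenario_traps(traps, design_scenario("full", "full"))), 100)
  expect_equal(nrow(scenario_traps(traps, design_scenario("9x9", "n_by_n", n = 9))), 81)
  expect_equal(nrow(scenario_traps(traps, design_scenario("half", "checkerboard_half"))), 50)

  wide <- scenario_traps(traps, design_scenario("15m", "respaced", spacing = 15))
  expect_equal(nrow(wide), 100)
  expect_equal(mean_nearest_trap_distance(wide), 15)

  thin <- scenario_traps(traps, design_scenario("15m-extent", "respaced",
                                                spacing = 15, preserve = "extent"))
  expect_lt(nrow(thin), 100)
  expect_lte(max(thin$x), max(traps$x))

  expect_error(design_scenario("bad", "n_by_n"), "positive integer")
  expect_error(design_scenario("bad", "respaced"), "positive")
  expect_error(design_scenario("bad", "full", occasions = c(1, 1)), "distinct")
})

test_that("subsampling deletes records at removed traps and occasions", {
  traps <- build_grid(10, 10, 9.43)
  mask <- build_mask(traps, 50, 10)
  pop <- simulate_population(30, mask, seed = 11)
  ch <- simulate_capthist(pop, traps, 4, study_params(), seed = 12)

  # identity
  full <- subsample_capthist(ch, traps, design_scenario("full", "full"))
  expect_equal(as.data.frame(full$capthist), as.data.frame(ch))

  # 3-night: the dropped occasion's records vanish, S becomes 3
  d3 <- subsample_capthist(ch, traps, design_scenario("3day", "full",
                                                      occasions = 1:3))
  expect_equal(n_occasions(d3$capthist), 3L)
  expect_equal(nrow(d3$capthist), sum(ch$occasion <= 3))

  # trap subsets: only retained traps, individuals re-pruned
  s7 <- subsample_capthist(ch, traps, design_scenario("7x7", "n_by_n", n = 7))
  expect_true(all(s7$capthist$trap_id %in% s7$traps$trap_id))
  expect_lte(nrow(s7$capthist), nrow(ch))
  expect_true(all(table(s7$capthist$individual) >= 1))

  expect_error(subsample_capthist(ch, traps,
                                  design_scenario("x", "full", occasions = 1:5)),
               "absent")
  expect_error(subsample_capthist(ch, traps,
                                  design_scenario("x", "respaced", spacing = 15)),
               "Monte Carlo")
})

test_that("nested trap subsets yield nested capture records", {
  traps <- build_grid(10, 10, 9.43)
  mask <- build_mask(traps, 50, 10)
  for (s in 1:4) {
    pop <- simulate_population(35, mask, seed = 40 + s)
    ch <- simulate_capthist(pop, traps, 4, study_params(), seed = 50 + s)
    last <- NULL
    for (n in c(9, 8, 7, 6)) {
      red <- subsample_capthist(ch, traps,
                                design_scenario(paste0(n), "n_by_n", n = n))
      key <- paste(red$capthist$individual, red$capthist$occasion,
                   red$capthist$trap_id)
      if (!is.null(last)) expect_true(all(key %in% last))
      expect_gte(length(last %||% key), length(key))
      last <- key
    }
  }
})

test_that("comparison records follow the published sign convention", {
  rec <- compare_to_full(list(D_hat = 26.11, SE_D = 3.0, session = "2000"),
                         list(D_hat = 29.43, SE_D = 3.4, session = "2000"))
  expect_equal(rec$difference, 26.11 - 29.43)
  expect_equal(rec$pct_abs_difference, 100 * 3.32 / 26.11)
  expect_false(rec$within_SE)

  rec2 <- compare_to_full(list(D_hat = 9.13, SE_D = 2.7, session = "2017"),
                          list(D_hat = 8.58, SE_D = 2.5, session = "2017"))
  expect_equal(rec2$difference, 0.55)
  expect_true(rec2$within_SE)

  same <- compare_to_full(list(D_hat = 20, SE_D = 2, session = "x"),
                          list(D_hat = 20, SE_D = 2.2, session = "x"))
  expect_equal(same$difference, 0)
  expect_true(same$within_SE)

  expect_error(compare_to_full(list(D_hat = 1, SE_D = 1, session = "a"),
                               list(D_hat = 1, SE_D = 1, session = "b")),
               "different sessions")
})

test_that("comparison summaries aggregate mean, absolute mean, max and rate", {
  recs <- dplyr::bind_rows(
    compare_to_full(list(D_hat = 30, SE_D = 2, session = "1"),
                    list(D_hat = 28, SE_D = 2, session = "1")),
    compare_to_full(list(D_hat = 20, SE_D = 1, session = "2"),
                    list(D_hat = 23, SE_D = 1, session = "2"))
  )
  s <- summarize_comparisons(recs)
  expect_equal(s$mean_difference, mean(c(2, -3)))
  expect_equal(s$mean_abs_difference, 2.5)
  expect_equal(s$max_abs_difference, 3)
  expect_equal(s$replication_rate, 50)

  one <- summarize_comparisons(recs[1, ])
  expect_equal(one$mean_abs_difference, 2)
  expect_error(summarize_comparisons(recs[0, ]), "no comparison")
})

test_that("relative bias and RMSE are the standard estimator summaries", {
  expect_equal(relative_bias(33, 30), 0.1)
  expect_equal(relative_bias(30, 30), 0)
  expect_equal(relative_bias(27, 30), -0.1)
  expect_error(relative_bias(10, 0), "positive")

  expect_equal(rmse(c(28, 32), 30), 2)
  expect_equal(rmse(rep(25, 7), 30), 5)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(rmse(1:3, 1:2), "equal positive length")

  # decomposition: RMSE^2 = var + bias^2 (population variance)
  set.seed(2)
  est <- rnorm(40, 32, 4)
  r <- rmse(est, 30)
  pvar <- mean((est - mean(est))^2)
  expect_equal(r^2, pvar + (mean(est) - 30)^2, tolerance = 1e-10)
})

test_that("trap-night accounting and capture efficiency are simple products", {
  traps <- build_grid(10, 10, 9.43)
  expect_equal(trap_nights(traps, 4, 1), 400)
  expect_equal(trap_nights(traps, 4, 18), 7200)
  expect_equal(trap_nights(1, 1, 1), 1)

  ch <- capture_history(tibble::tibble(
    individual = paste0("i", 1:34), occasion = 1L,
    trap_id = traps$trap_id[1:34], sex = "F"
  ), 4, traps = traps)
  expect_equal(capture_efficiency(ch, 400), 8.5)
  expect_equal(capture_efficiency(ch, 800), 4.25)
  empty <- capture_history(tibble::tibble(individual = character(),
                                          occasion = integer(),
                                          trap_id = character(),
                                          sex = character()), 4)
  expect_equal(capture_efficiency(empty, 400), 0)
})

test_that("Monte Carlo evaluation is reproducible and reports exclusions", {
  truth <- tibble::tibble(session = "t", D = 30, g0_F = 0.32, g0_M = 0.16,
                          sigma_F = 7, sigma_M = 9, pmix = 0.5)
  sc <- design_scenario("full", "full")
  mc1 <- monte_carlo_eval(truth, sc, n_reps = 3, seed = 5)
  mc2 <- monte_carlo_eval(truth, sc, n_reps = 3, seed = 5)
  expect_identical(as.data.frame(mc1$replicates), as.data.frame(mc2$replicates))
  expect_equal(mc1$summary$n_used + mc1$summary$n_excluded, 3)
  expect_s3_class(glance(mc1), "tbl_df")
  expect_equal(nrow(tidy(mc1)), 3)

  # n_reps = 1: RMSE reduces to the absolute error of the single replicate
  mc3 <- monte_carlo_eval(truth, sc, n_reps = 1, seed = 7)
  if (mc3$summary$n_used == 1) {
    expect_equal(mc3$summary$RMSE, abs(mc3$replicates$D_hat[1] - 30))
  }
})
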