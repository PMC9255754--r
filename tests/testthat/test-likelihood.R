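test_that("negative log-likelihood equals brute-force enumeration on small instances", {
  spec <- secr_model("EX", g0_effects = "sex", sigma_effects = "sex")
  for (seed in 1:12) {
    inst <- make_small_instance(seed)
    theta <- c(log(40), stats::qlogis(0.3), 0.4, log(9), 0.3, stats::qlogis(0.45))
    v <- negloglik(inst$ch, inst$traps, inst$mask, spec, theta)

    mats <- gridsecr:::capthist_matrices(inst$ch, inst$traps)
    pmix <- stats::plogis(theta[6])
    classes <- list(
      F = detection_params(stats::plogis(theta[2]), exp(theta[4]), "EX"),
      M = detection_params(stats::plogis(theta[2] + theta[3]),
                           exp(theta[4] + theta[5]), "EX")
    )
    sex_of <- mats$ids
    sex_chr <- vapply(mats$ids, function(id) {
      inst$ch$sex[match(id, inst$ch$individual)]
    }, "")
    oracle <- brute_nll(inst$traps, inst$mask, mats$caps,
                        ifelse(sex_chr == "unknown", NA, sex_chr),
                        classes, c(F = pmix, M = 1 - pmix), D = 40)
    expect_equal(v, oracle, tolerance = 1e-10)
  }
})

test_that("empty histories reduce the likelihood to the Poisson exposure term", {
  traps <- tiny_traps(cbind(c(0, 10), c(0, 0)))
  mask <- tiny_mask(cbind(c(-3, 5, 13), c(1, -2, 0)))
  ch0 <- capture_history(tibble::tibble(individual = character(),
                                        occasion = integer(),
                                        trap_id = character(),
                                        sex = character()),
                         3, traps = traps)
  spec <- secr_model("EX")
  theta <- c(log(25), stats::qlogis(0.2), log(8))
  p <- detection_params(0.2, 8, "EX")
  Lambda <- 25 * 0.01 * sum(vapply(seq_len(nrow(mask)), function(m) {
    p_dot(c(mask$x[m], mask$y[m]), traps, 3, p)
  }, 0))
  expect_equal(negloglik(ch0, traps, mask, spec, theta), Lambda, tolerance = 1e-12)
})

test_that("likelihood is invariant to mask point order", {
  inst <- make_small_instance(99)
  spec <- secr_model("HN", g0_effects = "sex")
  theta <- c(log(30), stats::qlogis(0.25), -0.3, log(10), stats::qlogis(0.5))
  v1 <- negloglik(inst$ch, inst$traps, inst$mask, spec, theta)
  perm <- sample(nrow(inst$mask))
  mask2 <- tiny_mask(cbind(inst$mask$x[perm], inst$mask$y[perm]))
  v2 <- negloglik(inst$ch, inst$traps, mask2, spec, theta)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("effect terms at zero collapse to the null model likelihood", {
  traps <- build_grid(4, 4, 9.43)
  mask <- build_mask(traps, 30, 15)
  pop <- simulate_population(25, mask, seed = 3)
  ch <- simulate_capthist(pop, traps, 3, detection_params(0.3, 10, "EX"), seed = 4)
  base <- c(log(25), stats::qlogis(0.3), log(10))
  v_null <- negloglik(ch, traps, mask, secr_model("EX"), base)

  # time effect with all occasion contrasts zero
  v_time <- negloglik(ch, traps, mask, secr_model("EX", g0_effects = "time"),
                      c(base[1:2], 0, 0, base[3]))
  expect_equal(v_time, v_null, tolerance = 1e-10)

  # behaviour effect with zero shift
  v_b <- negloglik(ch, traps, mask, secr_model("EX", g0_effects = "behavior"),
                   c(base[1:2], 0, base[3]))
  expect_equal(v_b, v_null, tolerance = 1e-10)

  # mixture with identical classes: adds only the label binomial, n log 2
  # at pmix = 1/2
  v_mix <- negloglik(ch, traps, mask,
                     secr_model("EX", mixture = TRUE),
                     c(base, stats::qlogis(0.5)))
  expect_equal(v_mix, v_null + n_individuals(ch) * log(2), tolerance = 1e-9)
})

test_that("a behavioural response in the data is picked up with the right sign", {
  traps <- build_grid(8, 8, 9.43)
  mask <- build_mask(traps, 40, 10)
  pop <- simulate_population(60, mask, seed = 21)
  # trap-happy animals: g0 doubles after first capture
  ch <- simulate_capthist(pop, traps, 4, detection_params(0.12, 10, "EX"),
                          behavior_effect = list(g0_mult = 2.5), seed = 22)
  fit <- fit_secr(ch, traps, mask, secr_model("EX", g0_effects = "behavior"))
  b <- fit$coefficients$estimate[fit$coefficients$term == "g0.b"]
  expect_true(fit$convergence)
  expect_gt(b, 0)
})

test_that("fitting recovers truth on one simulated dataset and restarts stably", {
  traps <- build_grid(10, 10, 9.43)
  mask <- build_mask(traps, 50, 10)
  pop <- simulate_population(30, mask, seed = 1)
  ch <- simulate_capthist(pop, traps, 4, study_params(), seed = 2)
  fit <- fit_secr(ch, traps, mask, study_spec())
  expect_true(fit$convergence)
  expect_gt(fit$D_hat, 0)
  expect_true(is.finite(fit$SE_D) && fit$SE_D > 0)
  # truth D = 30: a single replicate should land within a few SEs
  expect_lt(abs(fit$D_hat - 30), 4 * fit$SE_D)
  expect_equal(fit$AIC, -2 * fit$log_likelihood + 2 * fit$n_parameters)

  # restart from perturbed starting values reaches the same optimum
  starts <- gridsecr:::default_starts(ch, traps, mask, study_spec())
  fit2 <- fit_secr(ch, traps, mask, study_spec(),
                   starts = starts + c(0.4, -0.5, 0.3, 0.25, -0.2, 0.3))
  expect_equal(fit2$D_hat, fit$D_hat, tolerance = 1e-4)
  expect_equal(fit2$log_likelihood, fit$log_likelihood, tolerance = 1e-6)
})

test_that("sparse and degenerate data are flagged rather than trusted", {
  traps <- build_grid(4, 4, 9.43)
  mask <- build_mask(traps, 50, 15)
  pop <- simulate_population(20, mask, seed = 8)
  ch <- simulate_capthist(pop, traps, 4,
                          detection_params(0.01, 10, "EX"), seed = 9)
  # with g0 near zero and 16 traps almost nothing is caught
  expect_lt(n_individuals(ch), 15)
  fit <- fit_secr(ch, traps, mask, secr_model("EX"))
  expect_true("unstable" %in% fit$flags ||
                "non_identifiable" %in% fit$flags ||
                !fit$convergence)
})

test_that("AIC ranking orders models with weights summing to one", {
  traps <- build_grid(6, 6, 9.43)
  mask <- build_mask(traps, 40, 12)
  pop <- simulate_population(35, mask, seed = 31)
  ch <- simulate_capthist(pop, traps, 4, detection_params(0.25, 10, "EX"),
                          seed = 32)
  f1 <- fit_secr(ch, traps, mask, secr_model("EX"))
  f2 <- fit_secr(ch, traps, mask, secr_model("HN"))

  one <- aic_rank(list(f1))
  expect_equal(one$dAIC, 0)
  expect_equal(one$weight, 1)

  two <- aic_rank(list(f1, f2), labels = c("EX", "HN"))
  expect_equal(sum(two$weight), 1)
  expect_true(all(diff(two$AIC) >= 0))
  expect_equal(two$dAIC[1], 0)

  # equal-AIC fits split the weight evenly
  f1b <- f1
  tie <- aic_rank(list(f1, f1b), labels = c("a", "b"))
  expect_equal(tie$weight, c(0.5, 0.5))

  fmix <- fit_secr(ch, traps, mask, secr_model("EX", mixture = TRUE))
  expect_error(aic_rank(list(f1, fmix)), "cannot be AIC-ranked")
})

test_that("tidy and glance expose coefficient and summary tables", {
  traps <- build_grid(6, 6, 9.43)
  mask <- build_mask(traps, 40, 12)
  pop <- simulate_population(35, mask, seed = 51)
  ch <- simulate_capthist(pop, traps, 4, detection_params(0.25, 10, "EX"),
                          seed = 52)
  fit <- fit_secr(ch, traps, mask, secr_model("EX"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("D_hat", "SE_D", "AIC", "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("period summaries of annual densities use plain arithmetic", {
  d <- tibble::tibble(year = 2001:2005, density = c(10, 20, 30, 40, 50))
  s <- summarize_densities(d, list(c(2001, 2005), c(2002, 2003)))
  expect_equal(s$mean_D, c(30, 25))
  expect_equal(s$year_max, c(2005, 2003))
  one <- summarize_densities(d[3, ])
  expect_equal(one$mean_D, 30)
  expect_error(summarize_densities(d, list(c(2010, 2011))), "no years")
})
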