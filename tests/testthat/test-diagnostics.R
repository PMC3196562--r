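test_that("CWRES reduces to a z-score under additive-only error", {
  st <- small_mtl3_study(n = 2, seed = 51)
  g <- graph_preset("mtl3")
  fit <- make_pointmass_fit(st$data, g, mtl3_truth(), lag = 10,
                            sa = 0.004, sp = 0)
  cw <- compute_cwres(fit)
  expect_equal(nrow(cw), sum(st$data$EVID == 0))
  expect_equal(cw$cwres, cw$residual / 0.004, tolerance = 1e-10)
})

test_that("systematic underprediction drives a tissue's CWRES positive", {
  st <- small_mtl3_study(n = 3, seed = 52)
  g <- graph_preset("mtl3")
  low <- mtl3_truth()
  low["k_L1T2"] <- low[["k_L1T2"]] / 3   # starves the tumor chain
  fit <- make_pointmass_fit(st$data, g, low, lag = 10, sa = 0.005,
                            sp = 0.05)
  cw <- compute_cwres(fit)
  expect_gt(mean(cw$cwres[cw$tissue == "tumor"]), 0.5)
})

test_that("CWRES of a self-simulated fit is approximately standard normal", {
  fit <- shared_mtl3_fit()$fit
  cw <- compute_cwres(fit)
  expect_lt(abs(mean(cw$cwres)), 0.1)
  expect_gt(sd(cw$cwres), 0.9)
  expect_lt(sd(cw$cwres), 1.1)
})

test_that("chain stability: calibrated on white noise, fires on trends", {
  withr::local_seed(53)
  wn <- matrix(rnorm(500 * 300), 500, 300)
  tbl <- chain_stability(wn)
  expect_gte(mean(tbl$stable), 0.92)
  # injected linear trend of 3 posterior SDs across the chain
  trended <- wn[, 1:20] + outer(seq(0, 3, length.out = 500), rep(1, 20))
  tbl2 <- chain_stability(trended)
  expect_true(all(!tbl2$stable))
  expect_false(attr(tbl2, "model_stable"))
  # constant chain: z = 0, stable
  tbl3 <- chain_stability(matrix(1, 500, 1))
  expect_equal(tbl3$z, 0)
  expect_true(tbl3$stable)
  expect_error(chain_stability(wn[1:50, ]), class = "dcepop_state_error")
})

test_that("DIC: zero effective parameters at a point mass, consistent parts", {
  st <- small_mtl3_study(n = 2, seed = 54)
  pm <- make_pointmass_fit(st$data, graph_preset("mtl3"), mtl3_truth(),
                           lag = 10, sa = 0.005, sp = 0.05)
  d <- compute_dic(pm)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, compute_ofv(pm, type = "joint")$total,
               tolerance = 1e-8)
  # a real posterior spends effective parameters and DIC = Dbar + pD
  fit <- shared_mtl3_fit()$fit
  dr <- compute_dic(fit)
  expect_gt(dr$pd, 0)
  expect_equal(dr$dic, dr$dbar + dr$pd)
  expect_equal(dr$dbar, mean(rowSums(fit$ofv)))
})

test_that("model comparison tabulates OFV deltas and prefers low DIC", {
  sf <- shared_mtl3_fit()
  cfg <- sampler_config("custom", saem_iterations = 30, burn_in = 150,
                        samples = 150, seed = 12)
  fit_red <- fit_population(sf$study$data, graph_preset("no_t3"),
                            config = cfg)
  cmp <- compare_models(list(mtl3 = sf$fit, no_t3 = fit_red))
  expect_equal(cmp$delta_ofv[cmp$model == "mtl3"], 0)
  expect_equal(cmp$ofv - cmp$ofv[cmp$model == "mtl3"], cmp$delta_ofv)
  expect_equal(cmp$model[cmp$preferred], cmp$model[which.min(cmp$dic)])
  # self-comparison is exactly zero
  cmp_self <- compare_models(list(a = sf$fit, b = sf$fit))
  expect_equal(cmp_self$delta_ofv, c(0, 0))
  # refusing to compare fits of different data
  other <- make_pointmass_fit(small_mtl3_study(n = 2, seed = 55)$data,
                              graph_preset("mtl3"), mtl3_truth(), 10,
                              0.005, 0.05)
  expect_error(compare_models(list(a = sf$fit, b = other)),
               class = "dcepop_comparison_error")
})

test_that("flattening factors map correlation to ellipse shape", {
  r <- matrix(c(1, 0.25, 0, 0.25, 1, -0.5, 0, -0.5, 1), 3, 3)
  f <- correlation_flattening(r)
  expect_equal(diag(f), rep(0, 3))   # perfect self-correlation: a line
  expect_equal(f[1, 2], 0.75)
  expect_equal(f[1, 3], 1)           # uncorrelated: a circle
  expect_equal(f[2, 3], 1.5)
  expect_true(all(f >= 0 & f <= 2))
  bad <- r; bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(correlation_flattening(bad), class = "dcepop_data_error")
  fit <- shared_mtl3_fit()$fit
  ff <- correlation_flattening(fit_correlation(fit))
  expect_equal(diag(ff), setNames(rep(0, 17), colnames(ff)))
})

test_that("covariate scan applies the SE% retention rule", {
  sp <- covariate_spec("anest", "k_M1C", beta = -0.5)
  des <- study_design(
    n_datasets = 8, vti_sizes = c(8, 0, 0, 0),
    anest = rep(c(0, 1), 4),
    truth = population_model(graph_preset("mtl3"), covariates = list(sp))
  )
  st <- degrade_schedule(generate_study(des, seed = 56), keep_every = 2)
  cfg <- sampler_config("custom", saem_iterations = 20, burn_in = 100,
                        samples = 100, seed = 57)
  base <- fit_population(st$data, graph_preset("mtl3"), config = cfg)
  scan <- covariate_scan(st$data, graph_preset("mtl3"), config = cfg,
                         pairs = data.frame(covariate = "anest",
                                            target = "k_M1C"),
                         base_fit = base)
  expect_equal(nrow(scan), 1)
  expect_true(is.finite(scan$delta_ofv))
  expect_equal(scan$retained, scan$se_pct <= 55)
  expect_lt(scan$beta, 0)   # the simulated effect has the right sign
})

test_that("covariates sprayed across many rates destabilize the fit", {
  des <- study_design(n_datasets = 6, vti_sizes = c(6, 0, 0, 0),
                      anest = rep(c(0, 1), 3))
  st <- degrade_schedule(generate_study(des, seed = 58), keep_every = 3)
  pop <- population_model(
    graph_preset("mtl3"),
    covariates = list(covariate_spec("anest", "k_M1C"),
                      covariate_spec("anest", "k_L1C"),
                      covariate_spec("anest", "k_M3M2"))
  )
  cfg <- sampler_config("custom", saem_iterations = 10, burn_in = 100,
                        samples = 100, seed = 59)
  fit <- suppressWarnings(fit_population(st$data, graph_preset("mtl3"),
                                         pop = pop, config = cfg))
  s <- summarize_posterior(fit)
  betas <- s[grepl("^beta_", s$parameter), ]
  stab <- chain_stability(fit)
  blown <- any(betas$se_pct > 55) || any(!stab$stable)
  expect_true(blown)
})
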