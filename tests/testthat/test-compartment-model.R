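test_that("rate matrix encodes transfers, outflows and the Metzler property", {
  g <- graph_preset("mtl3")
  K <- build_rate_matrix(g, kinetic_params(mtl3_truth()))
  expect_equal(K["M1", "C"], 0.3)
  # central column: elimination + the two central-to-peripheral transfers
  expect_equal(K["C", "C"], -(0.013 + 0.3 + 2.9))
  offdiag <- K[row(K) != col(K)]
  expect_true(all(offdiag >= 0))
  expect_true(all(colSums(K) <= 1e-12))
  # single compartment, no edges, no elimination: the zero matrix
  g0 <- compartment_graph("C", "C", data.frame(from = character(0),
                                               to = character(0),
                                               rate = character(0)), "C")
  expect_equal(unname(build_rate_matrix(g0, c(k = 1))), matrix(0, 1, 1))
  # missing rate is a configuration error naming the rate
  expect_error(build_rate_matrix(g, c(k_CM1 = 0.3)),
               class = "dcepop_config_error", regexp = "k_M1C")
})

test_that("graph invariants are enforced at construction", {
  expect_error(compartment_graph(c("A", "B"), "Z",
                                 data.frame(from = "A", to = "B", rate = "k"),
                                 "A"),
               class = "dcepop_graph_error")
  expect_error(compartment_graph(c("A", "B", "X"), "B",
                                 data.frame(from = "A", to = "B", rate = "k"),
                                 "A"),
               class = "dcepop_graph_error", regexp = "connected")
  expect_error(compartment_graph(c("A", "B"), "B",
                                 data.frame(from = c("A", "A"),
                                            to = c("B", "B"),
                                            rate = c("k", "k")), "A"),
               class = "dcepop_graph_error", regexp = "unique")
  # the tumor chain of the full preset hangs off the first liver compartment
  g <- graph_preset("mtl3")
  e <- g$edges
  expect_equal(e$from[e$rate == "k_L1T2"], "L1")
})

test_that("bolus solution: initial condition and monoexponential closed form", {
  g1 <- compartment_graph("C", "C",
                          data.frame(from = character(0), to = character(0),
                                     rate = character(0)),
                          "C", c(compartment = "C", rate = "k_C0"))
  tr <- solve_amounts(g1, c(k_C0 = 0.013), dose_amount = 60, lag = 5,
                      times = c(0, 5, 105))
  expect_equal(unname(tr$amounts[1, "C"]), 0)          # before the lag
  expect_equal(unname(tr$amounts[2, "C"]), 60)         # all mass at t = lag
  expect_equal(unname(tr$amounts[3, "C"]), 60 * exp(-1.3), tolerance = 1e-12)
})

test_that("matrix-exponential solution matches an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  g <- graph_preset("mtl3")
  K <- build_rate_matrix(g, kinetic_params(mtl3_truth()))
  times <- c(0, seq(6, 900, by = 15))
  tr <- solve_amounts(g, mtl3_truth(), dose_amount = 60, lag = 0,
                      times = times)
  ode <- deSolve::ode(
    y = setNames(c(60, rep(0, 8)), colnames(K)), times = times,
    func = function(t, y, p) list(as.vector(K %*% y)), parms = NULL,
    method = "lsoda", rtol = 1e-12, atol = 1e-14
  )
  relerr <- max(abs(ode[, -1] - tr$amounts)) / max(abs(tr$amounts))
  expect_lt(relerr, 1e-8)
})

test_that("solver matches the ODE oracle across random rates and topologies", {
  skip_if_not_installed("deSolve")
  withr::local_seed(101)
  for (preset in c("mtl3", "minimal", "no_t3")) {
    g <- graph_preset(preset)
    for (trial in 1:8) {
      rates <- setNames(10^runif(length(rate_names(g)), -4, 1.5),
                        rate_names(g))
      K <- build_rate_matrix(g, kinetic_params(rates))
      expect_lte(max(Re(eigen(K)$values)), 1e-10)
      times <- c(0, sort(runif(25, 1, 900)))
      tr <- solve_amounts(g, rates, dose_amount = 60, times = times)
      ode <- deSolve::ode(
        y = setNames(c(60, rep(0, nrow(K) - 1)), colnames(K)),
        times = times,
        func = function(t, y, p) list(as.vector(K %*% y)), parms = NULL,
        method = "lsoda", rtol = 1e-12, atol = 1e-14
      )
      expect_lt(max(abs(ode[, -1] - tr$amounts)) / max(abs(tr$amounts)),
                1e-8)
    }
  }
})

test_that("mass is conserved once the elimination sink is made explicit", {
  # augment the full model with an explicit sink compartment in place of
  # the elimination pathway: total mass must then be constant, and the
  # body total (dose minus sink) non-increasing after the dose instant
  g <- graph_preset("mtl3")
  e <- rbind(g$edges, data.frame(from = "C", to = "SINK", rate = "k_C0"))
  g_aug <- compartment_graph(c(g$compartments, "SINK"), g$observed, e, "C")
  times <- seq(0, 900, by = 30)
  tr <- solve_amounts(g_aug, mtl3_truth(), dose_amount = 60, lag = 0,
                      times = times)
  total <- rowSums(tr$amounts)
  expect_true(all(abs(total - 60) / 60 < 1e-8))
  body <- rowSums(tr$amounts[, setdiff(colnames(tr$amounts), "SINK")])
  expect_true(all(diff(body) <= 1e-10))
  expect_true(all(tr$amounts > -1e-10))
})

test_that("volume derivation: central anchor, symmetry, chain ratios", {
  g <- graph_preset("mtl3")
  vs <- derive_volumes(g, kinetic_params(mtl3_truth(), Cl = 0.04))
  expect_equal(unname(vs$volumes["C"]), 0.04 / 0.013, tolerance = 1e-12)
  # distal liver blow-up: V_L3 / V_L2 = k_L2L3 / k_L3L2
  expect_equal(unname(vs$volumes["L3"] / vs$volumes["L2"]),
               0.027 / 2.3e-5, tolerance = 1e-12)
  expect_equal(sum(vs$fractions), 1)
  # equal forward/backward rates give equal volumes
  tg <- toy_graph()
  vs2 <- derive_volumes(tg, kinetic_params(c(k_CM2 = 0.1, k_M2C = 0.1,
                                             k_C0 = 0.013)))
  expect_equal(unname(vs2$volumes["M2"]), unname(vs2$volumes["C"]))
  # a unidirectional edge cannot be inverted into a volume
  g_uni <- compartment_graph(c("C", "P"), "P",
                             data.frame(from = "C", to = "P", rate = "k_CP"),
                             "C", c(compartment = "C", rate = "k_C0"))
  expect_error(derive_volumes(g_uni, c(k_CP = 0.1, k_C0 = 0.013)),
               class = "dcepop_derivation_error")
})

test_that("rebuilding rates from derived flows and volumes is the identity", {
  withr::local_seed(7)
  g <- graph_preset("mtl3")
  rates <- setNames(10^runif(length(rate_names(g)), -4, 1),
                    rate_names(g))
  vs <- derive_volumes(g, kinetic_params(rates, Cl = 0.04))
  for (i in seq_len(nrow(vs$flows))) {
    from <- vs$flows$from[i]; to <- vs$flows$to[i]; Q <- vs$flows$Q[i]
    e <- g$edges
    fwd <- e$rate[e$from == from & e$to == to]
    back <- e$rate[e$from == to & e$to == from]
    expect_equal(Q / vs$volumes[[from]], rates[[fwd]], tolerance = 1e-12)
    expect_equal(Q / vs$volumes[[to]], rates[[back]], tolerance = 1e-12)
  }
  # and the elimination anchor round-trips too: k_C0 = Cl / V_c
  expect_equal(0.04 / vs$volumes[["C"]], rates[["k_C0"]], tolerance = 1e-12)
})

test_that("concentration prediction is amount over volume with scaling laws", {
  g <- graph_preset("mtl3")
  tr <- solve_amounts(g, mtl3_truth(), dose_amount = 60,
                      times = seq(0, 300, 30))
  vs <- derive_volumes(g, kinetic_params(mtl3_truth()))
  cc <- predict_concentrations(tr, vs, compartments = g$observed)
  expect_setequal(unique(cc$compartment), c("M2", "T2", "L2"))
  # direct arithmetic: C = A / V
  a <- tr$amounts[3, "M2"]
  expect_equal(cc$conc[cc$compartment == "M2"][3],
               unname(a / vs$volumes["M2"]))
  # zero amounts give zero concentrations
  expect_equal(cc$conc[cc$time == 0], rep(0, 3))
  # doubling all volumes halves all concentrations
  v2 <- vs; v2$volumes <- vs$volumes * 2
  cc2 <- predict_concentrations(tr, v2, compartments = g$observed)
  expect_equal(cc2$conc, cc$conc / 2)
  # arithmetic anchor at the derived central volume
  expect_equal(30.77 / (0.04 / 0.013), 10.0, tolerance = 1e-3)
  v0 <- vs; v0$volumes["M2"] <- 0
  expect_error(predict_concentrations(tr, v0, "M2"),
               class = "dcepop_numeric_error")
})

test_that("posterior central curve collapses to the forward solution for a point mass", {
  st <- small_mtl3_study(n = 3, seed = 5)
  fit <- make_pointmass_fit(st$data, graph_preset("mtl3"), mtl3_truth(),
                            lag = 10, sa = 0.005, sp = 0.05)
  times <- seq(0, 900, by = 50)
  cur <- central_curve(fit, times)
  dose <- mean(vapply(fit$prep$dsets, `[[`, numeric(1), "dose"))
  tr <- solve_amounts(graph_preset("mtl3"), mtl3_truth(), dose, lag = 10,
                      times = times)
  vc <- 0.04 / mtl3_truth()[["k_C0"]]
  expect_equal(cur$median, unname(tr$amounts[, "C"]) / vc, tolerance = 1e-10)
  expect_equal(cur$lower, cur$upper)
  # shortly after the lag the curve is near dose / V_c, then decays
  expect_true(all(cur$median >= 0))
  late <- cur$median[times > 300]
  expect_true(all(diff(late) < 0))
  just_after <- central_curve(fit, times = 10.001)
  expect_equal(just_after$median, dose / vc, tolerance = 0.05)
})
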