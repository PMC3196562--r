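# Shared fixtures: small study designs, a two-compartment toy model, a
# point-mass pseudo-fit, and a memoised moderate-size fit reused by the
# diagnostic tests. Everything is generated in code at test time.

mtl3_truth <- function() default_rates(graph_preset("mtl3"))

# two-compartment toy: central C (eliminating) exchanging with observed M2
toy_graph <- function() {
  compartment_graph(
    compartments = c("C", "M2"), observed = "M2",
    edges = data.frame(from = c("C", "M2"), to = c("M2", "C"),
                       rate = c("k_CM2", "k_M2C")),
    dose_compartment = "C",
    elimination = c(compartment = "C", rate = "k_C0")
  )
}

toy_rates <- function() c(k_CM2 = 0.05, k_M2C = 0.02, k_C0 = 0.013)

toy_population <- function(theta = toy_rates(), ...) {
  population_model(toy_graph(), theta = theta, ...)
}

# deterministic single-tissue toy study (muscle only)
toy_study <- function(n = 20, seed = 1, omega2 = 0.04,
                      sigma_add = 0.005, sigma_prop = 0.05, ...) {
  des <- study_design(
    n_datasets = n, vti_sizes = c(n, 0, 0, 0),
    truth = toy_population(omega2 = omega2, sigma_add = sigma_add,
                           sigma_prop = sigma_prop, ...)
  )
  st <- generate_study(des, seed = seed)
  # keep the muscle curves only: the toy graph has no tumor/liver
  st$data <- st$data[st$data$EVID == 1 | st$data$TISSUE == "muscle", ]
  st
}

small_mtl3_study <- function(n = 6, seed = 1, ...) {
  des <- study_design(n_datasets = n, vti_sizes = c(n, 0, 0, 0),
                      truth = population_model(graph_preset("mtl3"), ...))
  generate_study(des, seed = seed)
}

# a pop_fit whose posterior is a point mass at given individual parameters:
# lets diagnostics be checked against closed forms
make_pointmass_fit <- function(data, graph, rates, lag, sa, sp,
                               n_samples = 5) {
  pop <- population_model(graph, theta = rates, omega2 = 1e-4,
                          sigma_add = sa, sigma_prop = max(sp, 1e-12))
  prep <- dcepop:::.fit_prep(data, pop)
  R <- length(prep$rn)
  D <- prep$D
  lpsi <- log(unname(rates[prep$rn]))
  psi <- aperm(array(lpsi, c(R, n_samples, D)), c(2, 3, 1))
  dimnames(psi) <- list(NULL, as.character(prep$ids), prep$rn)
  par_names <- c(paste0("theta_", prep$rn), paste0("omega2_", prep$rn),
                 "sigma_add", "sigma_prop", paste0("lag_", prep$ids))
  one_row <- c(unname(rates[prep$rn]), rep(1e-4, R), sa, sp, rep(lag, D))
  chains <- matrix(rep(one_row, each = n_samples), n_samples,
                   dimnames = list(NULL, par_names))
  # joint per-dataset deviance: conditional likelihood plus the prior
  # terms of the individual parameters (zero etas here, lag at `lag`)
  prior_m2 <- -2 * (R * dnorm(0, 0, sqrt(1e-4), log = TRUE) +
                      dnorm(lag, 10, 5, log = TRUE) -
                      pnorm(10 / 5, log.p = TRUE))
  ofv_row <- vapply(prep$dsets, function(ds) {
    obs <- data[data$EVID == 0 & data$ID == ds$id, ]
    dataset_loglik(list(rates = rates, lag = lag), obs, graph,
                   dose = ds$dose, sigma_add = sa, sigma_prop = sp) +
      prior_m2
  }, numeric(1))
  ofv <- matrix(rep(ofv_row, each = n_samples), n_samples,
                dimnames = list(NULL, as.character(prep$ids)))
  structure(
    list(chains = chains, ofv = ofv, psi = psi,
         lag = matrix(lag, n_samples, D),
         rate_names = prep$rn, ids = prep$ids, graph = graph, pop = pop,
         config = sampler_config("custom", 1, 1, n_samples),
         prep = prep, acceptance = c(psi = NA, lag = NA, omega2 = NA,
                                     sigma = NA),
         data_hash = prep$hash),
    class = "pop_fit"
  )
}

# moderate self-simulated fit shared across diagnostic tests (memoised)
.shared <- new.env(parent = emptyenv())

shared_mtl3_fit <- function() {
  if (is.null(.shared$fit)) {
    st <- small_mtl3_study(n = 8, seed = 11)
    cfg <- sampler_config("custom", saem_iterations = 30, burn_in = 150,
                          samples = 150, seed = 12)
    .shared$study <- st
    .shared$fit <- fit_population(st$data, graph_preset("mtl3"),
                                  config = cfg)
  }
  list(study = .shared$study, fit = .shared$fit)
}
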