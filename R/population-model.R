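#' Covariate effect specification
#'
#' Declares a multiplicative log-linear covariate effect on one transfer
#' constant. Two covariates are supported: `anest`, a binary anesthesia
#' protocol indicator (0 = injection anesthesia, the reference; 1 = gaseous),
#' and `vti`, an ordered 4-level grouping by residual vital tumor tissue
#' (level 1 = pre-treatment, the reference; levels 2-4 = treated groups).
#' The adjusted typical value is `theta * exp(beta * x)` for `anest` and
#' `theta * exp(beta[level - 1])` for `vti` (reference level: factor 1).
#'
#' @param covariate `"anest"` or `"vti"`.
#' @param target Name of the transfer constant the effect applies to.
#' @param beta Numeric coefficient(s): length 1 for `anest`, length 3 for
#'   `vti` (levels 2, 3, 4 versus the reference).
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("anest", "k_M1C", beta = -0.3)
#' @export
covariate_spec <- function(covariate = c("anest", "vti"), target, beta = NULL) {
  covariate <- arg_match(covariate)
  p <- if (covariate == "anest") 1L else 3L
  if (is.null(beta)) beta <- rep(0, p)
  if (length(beta) != p || any(!is.finite(beta))) {
    abort(paste0("`", covariate, "` takes ", p, " finite coefficient(s)."),
          class = "dcepop_config_error")
  }
  structure(list(covariate = covariate, target = target, beta = beta),
            class = "covariate_spec")
}

#' Hierarchical population model
#'
#' The population layer on top of a compartment topology: typical transfer
#' constants (THETA), diagonal log-normal inter-individual variability
#' (one ETA variance per rate), a mixed additive + proportional residual
#' error model, a zero-truncated normal injection-lag model (the lag is a
#' nuisance parameter, uncorrelated with the kinetic parameters), and
#' optional covariate effects. Individual rates are
#' `k_i = theta * exp(covariate term + eta_i)` with
#' `eta_i ~ N(0, omega^2)`.
#'
#' @param graph A [compartment_graph()].
#' @param theta Named typical rate values [1/s]; default the graph preset's
#'   default rates.
#' @param omega2 Inter-individual variance on the log scale; scalar
#'   (recycled over rates) or named vector. Default 0.09 (about 30% CV).
#' @param sigma_add Additive residual SD [mM]; default 0.005.
#' @param sigma_prop Proportional residual SD (fraction); default 0.05.
#' @param lag_mean,lag_sd Injection-lag model [s]: normal truncated at zero.
#' @param covariates List of [covariate_spec()] objects.
#' @param Cl Fixed clearance [ml/s]; never estimated.
#' @return An object of class `population_model`.
#' @export
population_model <- function(graph, theta = NULL, omega2 = 0.09,
                             sigma_add = 0.005, sigma_prop = 0.05,
                             lag_mean = 10, lag_sd = 5,
                             covariates = list(), Cl = 0.04) {
  stopifnot(inherits(graph, "compartment_graph"))
  rn <- rate_names(graph)
  if (is.null(theta)) theta <- default_rates(graph)
  theta <- unlist(theta)
  if (!setequal(names(theta), rn)) {
    abort("`theta` names must match the graph's rate names.",
          class = "dcepop_config_error")
  }
  theta <- theta[rn]
  if (any(theta <= 0)) {
    abort("Typical rates must be > 0.", class = "dcepop_config_error")
  }
  if (length(omega2) == 1 && is.null(names(omega2))) {
    omega2 <- setNames(rep(omega2, length(rn)), rn)
  }
  if (!setequal(names(omega2), rn) || any(omega2 < 0)) {
    abort("`omega2` must be a non-negative scalar or named per-rate vector.",
          class = "dcepop_config_error")
  }
  omega2 <- omega2[rn]
  if (sigma_add <= 0 && sigma_prop <= 0) {
    abort("At least one residual-error component must be positive.",
          class = "dcepop_config_error")
  }
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  for (cv in covariates) {
    stopifnot(inherits(cv, "covariate_spec"))
    if (!cv$target %in% rn) {
      abort(paste0("Covariate target `", cv$target,
                   "` is not a rate of this graph."),
            class = "dcepop_config_error")
    }
  }
  structure(
    list(graph = graph, theta = theta, omega2 = omega2,
         sigma_add = sigma_add, sigma_prop = sigma_prop,
         lag_mean = lag_mean, lag_sd = lag_sd,
         covariates = covariates, Cl = Cl),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> on ", length(x$graph$compartments),
      "-compartment graph; ", length(x$theta), " typical rates\n", sep = "")
  cat("  sigma_add ", x$sigma_add, " mM, sigma_prop ", x$sigma_prop,
      "; lag ~ N(", x$lag_mean, ", ", x$lag_sd, "^2) truncated at 0\n",
      sep = "")
  if (length(x$covariates) > 0) {
    cat("  covariates:",
        paste(vapply(x$covariates, function(cv)
          paste0(cv$covariate, " -> ", cv$target), character(1)),
          collapse = ", "), "\n")
  }
  invisible(x)
}

# Additive log-scale covariate contribution per rate for one dataset.
.cov_terms <- function(covariates, anest, vti, rn) {
  term <- setNames(rep(0, length(rn)), rn)
  for (cv in covariates) {
    if (cv$covariate == "anest") {
      if (!anest %in% c(0, 1)) {
        abort("`anest` must be 0 or 1.", class = "dcepop_data_error")
      }
      term[cv$target] <- term[cv$target] + cv$beta * anest
    } else {
      if (!vti %in% 1:4) {
        abort(paste0("Unknown vti level: ", vti),
              class = "dcepop_data_error")
      }
      if (vti > 1) {
        term[cv$target] <- term[cv$target] + cv$beta[vti - 1]
      }
    }
  }
  term
}

#' Apply covariate effects to typical values
#'
#' Adjusts typical transfer constants for one dataset's covariate values by
#' the multiplicative log-linear model `theta * exp(beta x)`; reference
#' levels (anest = 0, vti = 1) leave the rates unchanged. Positivity is
#' preserved by construction.
#'
#' @param theta Named typical rate values.
#' @param covariates List of [covariate_spec()] objects.
#' @param anest Binary anesthesia value (0/1).
#' @param vti Vital-tumor-tissue group (1-4; 1 = reference).
#' @return Adjusted named rate vector.
#' @examples
#' th <- c(k_M1C = 0.012)
#' sp <- covariate_spec("anest", "k_M1C", beta = -0.3)
#' apply_covariates(th, list(sp), anest = 1)
#' @export
apply_covariates <- function(theta, covariates, anest = 0, vti = 1) {
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  term <- .cov_terms(covariates, anest, vti, names(theta))
  theta * exp(term)
}

#' Draw one individual's parameters
#'
#' Samples per-rate random effects `eta ~ N(0, omega^2)` independently,
#' forms individual rates `k_i = theta_adj * exp(eta)` about the
#' covariate-adjusted typical values, and draws the injection lag from the
#' zero-truncated normal lag model. Uses R's RNG stream: seed the session
#' (or wrap in `withr::with_seed()`) for reproducibility.
#'
#' @param pop A [population_model()].
#' @param anest,vti Covariate values of the dataset.
#' @return An object of class `individual_parameters`: `rates`, `eta`,
#'   `lag`.
#' @export
draw_individual <- function(pop, anest = 0, vti = 1) {
  stopifnot(inherits(pop, "population_model"))
  rn <- names(pop$theta)
  eta <- rnorm(length(rn), 0, sqrt(pop$omega2))
  names(eta) <- rn
  term <- .cov_terms(pop$covariates, anest, vti, rn)
  rates <- pop$theta * exp(term + eta)
  repeat {
    lag <- rnorm(1, pop$lag_mean, pop$lag_sd)
    if (lag >= 0) break
  }
  structure(list(rates = rates, eta = eta, lag = lag,
                 anest = anest, vti = vti),
            class = "individual_parameters")
}

.tissue_compartments <- c(muscle = "M2", tumor = "T2", liver = "L2")

# f(psi) for one dataset: observation-level predicted concentrations [mM].
# utimes: unique observation times; comp_id/time_id index obs into the
# compartment x time grid. Returns NULL if volumes are unavailable.
.predict_obs <- function(tmpl, kvec, Cl, dose, lag, utimes, comp_id, time_id) {
  K <- .rate_matrix(tmpl, kvec)
  a0 <- rep(0, tmpl$n)
  a0[tmpl$root] <- dose
  A <- matrix(0, tmpl$n, length(utimes))
  post <- utimes >= lag
  if (any(post)) A[, post] <- .amounts_at(K, a0, utimes[post] - lag)
  V <- .volume_vector(tmpl, kvec, Cl)
  if (is.null(V)) return(NULL)
  A[cbind(comp_id, time_id)] / V[comp_id]
}

# -2 log N(y; f, sa^2 + (sp f)^2), summed
.m2ll <- function(y, f, sa, sp) {
  v <- sa^2 + (sp * f)^2
  sum(log(2 * pi * v) + (y - f)^2 / v)
}

#' Conditional -2 log-likelihood of one dataset
#'
#' Evaluates the mixed additive + proportional residual error model for one
#' dataset's observations given fixed individual parameters: with predicted
#' concentration f, the observation model is `y = f (1 + eps_prop) +
#' eps_add`, i.e. `y ~ N(f, sigma_add^2 + (sigma_prop f)^2)`. Returns
#' \eqn{-2 \sum \log \phi(y; f, v)} — the dataset's objective-function-value
#' (OFV) contribution at those parameters.
#'
#' @param individual An [draw_individual()] result (or list with `rates` and
#'   `lag`).
#' @param data Data frame of the dataset's observation rows: columns `TIME`
#'   \[s\], `TISSUE` (muscle/tumor/liver), `DV` \[mM\].
#' @param graph A [compartment_graph()].
#' @param dose Bolus amount [µmol].
#' @param sigma_add,sigma_prop Residual error components.
#' @param Cl Fixed clearance [ml/s].
#' @return Scalar -2 log-likelihood.
#' @export
dataset_loglik <- function(individual, data, graph, dose,
                           sigma_add, sigma_prop, Cl = 0.04) {
  tmpl <- .graph_template(graph)
  kvec <- .as_rate_vector(tmpl, individual$rates)
  tiss <- as.character(data$TISSUE)
  bad <- setdiff(unique(tiss), names(.tissue_compartments))
  if (length(bad) > 0) {
    abort(paste0("Unknown tissue label(s): ", paste(bad, collapse = ", ")),
          class = "dcepop_data_error")
  }
  comp_id <- match(.tissue_compartments[tiss], tmpl$comps)
  utimes <- sort(unique(data$TIME))
  time_id <- match(data$TIME, utimes)
  f <- .predict_obs(tmpl, kvec, Cl, dose, individual$lag,
                    utimes, comp_id, time_id)
  if (is.null(f) || any(!is.finite(f))) {
    abort("Non-finite prediction while evaluating the likelihood.",
          class = "dcepop_numeric_error")
  }
  .m2ll(data$DV, f, sigma_add, sigma_prop)
}
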