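#' Conditional weighted residuals
#'
#' Residuals standardized by the model-implied observation variance,
#' conditioned on the empirical-Bayes individual estimates (posterior-mean
#' individual log-rates and lag per dataset). With the mixed error model the
#' conditional observation covariance is diagonal, so
#' `CWRES = (y - f) / sqrt(sigma_add^2 + (sigma_prop f)^2)` at the
#' posterior-mean individual parameters. For data simulated from the fitted
#' model, CWRES are approximately standard normal; systematic offsets in one
#' tissue flag structural misfit.
#'
#' @param fit A `pop_fit`.
#' @return Tibble with one row per observation: `ID`, `tissue`, `time`,
#'   `dv`, `pred`, `residual`, `cwres`.
#' @export
compute_cwres <- function(fit) {
  stopifnot(inherits(fit, "pop_fit"))
  prep <- fit$prep
  psi_bar <- apply(fit$psi, c(2, 3), mean)
  lag_bar <- colMeans(fit$lag)
  sa <- mean(fit$chains[, "sigma_add"])
  sp <- mean(fit$chains[, "sigma_prop"])
  out <- vector("list", prep$D)
  for (d in seq_len(prep$D)) {
    ds <- prep$dsets[[d]]
    ev <- .state_eval(prep, d, psi_bar[d, ], lag_bar[d], sa, sp,
                      fit$pop$Cl)
    if (is.null(ev)) {
      abort(paste0("Singular/non-finite conditional prediction in dataset ",
                   ds$id, "."),
            class = "dcepop_numeric_error")
    }
    v <- sa^2 + (sp * ev$f)^2
    out[[d]] <- tibble(ID = ds$id, tissue = ds$tissue, time = ds$time,
                       dv = ds$y, pred = ev$f, residual = ds$y - ev$f,
                       cwres = (ds$y - ev$f) / sqrt(v))
  }
  bind_rows(out)
}

#' Chain stability diagnostics
#'
#' Geweke-style stationarity check per parameter chain: compares the mean
#' of the first 10% of the chain against the mean of the last 50% with a
#' two-sample z statistic (|z| > 2 flags the parameter unstable), and
#' reports the standardized running-mean trend (least-squares slope over
#' the chain, expressed in posterior-SD units across the whole chain).
#' Degenerate (constant) chains are stable with z = 0.
#'
#' @param x A `pop_fit` (its parameter chains are checked) or a numeric
#'   matrix with one chain per column.
#' @param z_crit Instability threshold on |z| (default 2).
#' @return Tibble with `parameter`, `z`, `trend_sd`, `stable`; attribute
#'   `model_stable` is `TRUE` when every parameter is stable.
#' @export
chain_stability <- function(x, z_crit = 2) {
  ch <- if (inherits(x, "pop_fit")) x$chains else as.matrix(x)
  n <- nrow(ch)
  if (n < 100) {
    abort("Chain length must be >= 100 for stability assessment.",
          class = "dcepop_state_error")
  }
  ia <- seq_len(max(1, floor(0.1 * n)))
  ib <- seq.int(floor(0.5 * n) + 1, n)
  idx <- seq_len(n)
  res <- lapply(seq_len(ncol(ch)), function(j) {
    v <- ch[, j]
    va <- var(v[ia]); vb <- var(v[ib])
    se <- sqrt(va / length(ia) + vb / length(ib))
    z <- if (!is.finite(se) || se == 0) 0 else
      (mean(v[ia]) - mean(v[ib])) / se
    s <- sd(v)
    trend <- if (!is.finite(s) || s == 0) 0 else
      unname(coef(lm(v ~ idx))[2]) * n / s
    tibble(parameter = colnames(ch)[j] %||% paste0("par", j),
           z = z, trend_sd = trend, stable = abs(z) <= z_crit)
  })
  out <- bind_rows(res)
  attr(out, "model_stable") <- all(out$stable)
  out
}

#' Deviance information criterion
#'
#' Spiegelhalter's DIC from the per-sample total deviance trace:
#' `Dbar` is the posterior mean of the total conditional -2 log-likelihood,
#' `Dhat` the deviance at the posterior-mean parameters (individual
#' log-rates, lags and residual SDs), `pD = Dbar - Dhat` the effective
#' number of parameters, and `DIC = Dbar + pD`.
#'
#' @param fit A `pop_fit`.
#' @return List with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "pop_fit"))
  if (nrow(fit$ofv) == 0) {
    abort("Fit has no retained samples.", class = "dcepop_state_error")
  }
  dbar <- mean(rowSums(fit$ofv))
  prep <- fit$prep
  psi_bar <- apply(fit$psi, c(2, 3), mean)
  lag_bar <- colMeans(fit$lag)
  sa <- mean(fit$chains[, "sigma_add"])
  sp <- mean(fit$chains[, "sigma_prop"])
  ltheta_bar <- log(colMeans(fit$chains[, paste0("theta_", prep$rn),
                                        drop = FALSE]))
  omega2_bar <- colMeans(fit$chains[, paste0("omega2_", prep$rn),
                                    drop = FALSE])
  beta_bar <- if (length(prep$beta_labels) > 0) {
    colMeans(fit$chains[, prep$beta_labels, drop = FALSE])
  } else numeric(0)
  mu_bar <- .mu_matrix(prep, unname(ltheta_bar), unname(beta_bar))
  dhat <- 0
  for (d in seq_len(prep$D)) {
    ev <- .state_eval(prep, d, psi_bar[d, ], lag_bar[d], sa, sp,
                      fit$pop$Cl)
    if (is.null(ev)) {
      abort("Non-finite deviance at the posterior mean.",
            class = "dcepop_numeric_error")
    }
    dhat <- dhat + ev$m2ll +
      .prior_m2(psi_bar[d, ], mu_bar[d, ], unname(omega2_bar),
                lag_bar[d], fit$pop$lag_mean, fit$pop$lag_sd)
  }
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Compare fitted models on identical data
#'
#' Tabulates total OFV, \eqn{\Delta}OFV against a reference model, DIC and
#' effective parameter count for a family of fits of the same data; the
#' preferred model is the one with the lowest DIC.
#'
#' @param fits Named list of `pop_fit` objects fitted to the same datasets.
#' @param reference Name of the reference model (default: first).
#' @return Tibble with `model`, `ofv`, `delta_ofv`, `dic`, `pd`,
#'   `preferred`.
#' @export
compare_models <- function(fits, reference = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    abort("`fits` must be a named list.", class = "dcepop_comparison_error")
  }
  reference <- reference %||% names(fits)[1]
  if (!reference %in% names(fits)) {
    abort("`reference` is not among the fitted models.",
          class = "dcepop_comparison_error")
  }
  h <- vapply(fits, function(f) f$data_hash, character(1))
  idsets <- lapply(fits, function(f) f$ids)
  if (length(unique(h)) != 1 ||
      !all(vapply(idsets, identical, logical(1), idsets[[1]]))) {
    abort("All fits must be on the identical dataset collection.",
          class = "dcepop_comparison_error")
  }
  ofvs <- vapply(fits, function(f) compute_ofv(f)$total, numeric(1))
  dics <- lapply(fits, compute_dic)
  out <- tibble(
    model = names(fits),
    ofv = unname(ofvs),
    delta_ofv = unname(ofvs - ofvs[reference]),
    dic = vapply(dics, `[[`, numeric(1), "dic"),
    pd = vapply(dics, `[[`, numeric(1), "pd")
  )
  out$preferred <- out$dic == min(out$dic)
  out
}

#' Correlation flattening factors
#'
#' Converts a parameter correlation matrix into per-pair flattening factors
#' `f = 1 - r`, the ratio of minor to major axis of the correlation
#' ellipse: `f = 0` for perfect correlation (a line), `f = 1` for no
#' correlation (a circle).
#'
#' @param r Symmetric correlation matrix with unit diagonal.
#' @return Matrix of flattening factors (zero diagonal), same dimnames.
#' @export
correlation_flattening <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8 ||
      max(abs(diag(r) - 1)) > 1e-8) {
    abort("`r` must be symmetric with unit diagonal.",
          class = "dcepop_data_error")
  }
  if (max(abs(r)) > 1 + 1e-8) {
    abort("Correlations must lie in [-1, 1].", class = "dcepop_data_error")
  }
  1 - r
}

#' Parameter correlation matrix of a fit
#'
#' Posterior correlation of the typical-rate chains, the usual input to
#' [correlation_flattening()].
#'
#' @param fit A `pop_fit`.
#' @return Correlation matrix over `theta_*` chains.
#' @export
fit_correlation <- function(fit) {
  stopifnot(inherits(fit, "pop_fit"))
  stats::cor(fit$chains[, paste0("theta_", fit$rate_names), drop = FALSE])
}

#' Single-covariate scan
#'
#' Exhaustively fits one-covariate extensions of a base model over the
#' admissible (covariate, rate) pairs — `anest` on muscle or liver transfer
#' constants, `vti` on the tumor exchange constants — and tabulates
#' \eqn{\Delta}OFV, DIC and the coefficient's SE%. A covariate model is
#' retained only when its coefficient is estimated with SE% at or below 55
#' (`anest`) / 30 (`vti`, worst coefficient).
#'
#' @param data Event-record data.
#' @param graph A [compartment_graph()] (default the full preset).
#' @param config A [sampler_config()].
#' @param pairs Optional data frame with columns `covariate`, `target`
#'   restricting the scan; default: the full admissible set.
#' @param base_fit Optional pre-computed base-model fit on `data`.
#' @param se_limits Named retention limits, default
#'   `c(anest = 55, vti = 30)`.
#' @return Tibble with `covariate`, `target`, `ofv`, `delta_ofv`, `dic`,
#'   `beta`, `se_pct`, `retained`.
#' @export
covariate_scan <- function(data, graph = graph_preset("mtl3"),
                           config = sampler_config("fast"),
                           pairs = NULL, base_fit = NULL,
                           se_limits = c(anest = 55, vti = 30)) {
  if (is.null(pairs)) {
    rn <- rate_names(graph)
    musc_liver <- rn[grepl("M|L", rn) & !grepl("T", rn)]
    tumor <- intersect(c("k_T2T3", "k_T3T2"), rn)
    pairs <- bind_rows(
      tibble(covariate = "anest", target = musc_liver),
      tibble(covariate = "vti", target = tumor)
    )
  }
  if (is.null(base_fit)) {
    base_fit <- fit_population(data, graph, config = config)
  }
  base_ofv <- compute_ofv(base_fit)$total
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cv <- covariate_spec(pairs$covariate[i], pairs$target[i])
    pop <- population_model(graph, covariates = list(cv))
    fit <- fit_population(data, graph, pop = pop, config = config)
    sm <- summarize_posterior(fit)
    bcols <- grepl(paste0("^beta_", pairs$covariate[i]),
                   sm$parameter) &
      grepl(pairs$target[i], sm$parameter, fixed = TRUE)
    se <- max(sm$se_pct[bcols])
    rows[[i]] <- tibble(
      covariate = pairs$covariate[i], target = pairs$target[i],
      ofv = compute_ofv(fit)$total,
      delta_ofv = compute_ofv(fit)$total - base_ofv,
      dic = compute_dic(fit)$dic,
      beta = sm$estimate[which(bcols)[1]],
      se_pct = se,
      retained = se <= se_limits[[pairs$covariate[i]]]
    )
  }
  bind_rows(rows)
}
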