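#' Kinetic parameter set
#'
#' Couples a named vector of first-order transfer constants [1/s] with the
#' plasma clearance Cl [ml/s], which is fixed (taken from literature, not
#' estimated) and anchors the absolute volume scale through
#' `V_c = Cl / k_C0`.
#'
#' @param rates Named numeric vector, one positive value per rate name of the
#'   graph the parameters will be used with.
#' @param Cl Clearance in ml/s; default 0.04.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(rates, Cl = 0.04) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(names(rates) == "")) {
    abort("`rates` must be a fully named vector.",
          class = "dcepop_config_error")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("All transfer constants must be finite and > 0.",
          class = "dcepop_config_error")
  }
  if (!is.finite(Cl) || Cl <= 0) {
    abort("`Cl` must be finite and > 0.", class = "dcepop_config_error")
  }
  structure(list(rates = rates, Cl = Cl), class = "kinetic_params")
}

.as_rate_vector <- function(tmpl, params) {
  rates <- if (inherits(params, "kinetic_params")) params$rates else unlist(params)
  missing <- setdiff(tmpl$rate_names, names(rates))
  if (length(missing) > 0) {
    abort(paste0("Missing rate value(s): ", paste(missing, collapse = ", ")),
          class = "dcepop_config_error")
  }
  unname(rates[tmpl$rate_names])
}

#' Build the compartmental rate matrix
#'
#' Assembles the square matrix K of the linear system dA/dt = K A: the
#' off-diagonal entry (to, from) is the transfer constant from `from` to
#' `to`, and each diagonal entry is minus the total outflow of its
#' compartment (transfers out plus elimination, if that compartment
#' eliminates). K is a compartmental (Metzler) matrix: non-negative
#' off-diagonal, column sums \eqn{\le 0}.
#'
#' @param graph A [compartment_graph()].
#' @param params A [kinetic_params()] object or named rate vector covering
#'   every rate of `graph`.
#' @return Square numeric matrix with compartment dimnames.
#' @examples
#' g <- graph_preset("mtl3")
#' K <- build_rate_matrix(g, kinetic_params(default_rates(g)))
#' K["M1", "C"]   # k_CM1
#' @export
build_rate_matrix <- function(graph, params) {
  tmpl <- .graph_template(graph)
  K <- .rate_matrix(tmpl, .as_rate_vector(tmpl, params))
  dimnames(K) <- list(tmpl$comps, tmpl$comps)
  K
}

# Amounts [µmol] at offsets tau >= 0 for initial condition a0: columns are
# times. Eigendecomposition of K (generically diagonalizable for positive
# rates); falls back to scaling-and-squaring expm when the eigenbasis is
# ill-conditioned. The rate spread in these models (1e-5 .. 3e2 1/s) makes
# the system stiff, so fixed-step integration is not an option.
.amounts_at <- function(K, a0, tau) {
  n <- nrow(K)
  e <- tryCatch(eigen(K), error = function(err) NULL)
  if (!is.null(e)) {
    w <- tryCatch(solve(e$vectors, a0), error = function(err) NULL)
    if (!is.null(w)) {
      # residual check of the eigenbasis; scale-free
      res <- max(Mod(K %*% e$vectors - e$vectors %*% diag(e$values, n)))
      sc <- max(abs(K), 1)
      if (is.finite(res) && res <= 1e-9 * sc) {
        E <- exp(outer(e$values, tau))      # n x length(tau), complex-safe
        A <- Re(e$vectors %*% (w * E))
        return(A)
      }
    }
  }
  # fallback: Pade scaling-and-squaring per unique offset
  vapply(tau, function(t1) {
    as.vector(as.matrix(Matrix::expm(K * t1)) %*% a0)
  }, numeric(n))
}

#' Solve bolus-dose kinetics analytically
#'
#' Computes the amount in every compartment over time for an instantaneous
#' bolus of `dose_amount` placed in the dose compartment at time `lag`:
#' A(t) = expm(K (t - lag)) A0 for t >= lag, zero before. The solution uses
#' the matrix exponential (eigendecomposition with an expm fallback), never
#' step-wise integration.
#'
#' @param graph A [compartment_graph()].
#' @param params A [kinetic_params()] or named rate vector.
#' @param dose_amount Bolus amount in µmol (> 0).
#' @param lag Injection lag in seconds (>= 0).
#' @param times Sorted non-negative observation times in seconds.
#' @return An object of class `amount_trajectory`: list with `times` and an
#'   `amounts` matrix (time x compartment, µmol). `as_tibble()` pivots it to
#'   long form.
#' @examples
#' g <- graph_preset("mtl3")
#' tr <- solve_amounts(g, default_rates(g), dose_amount = 60, lag = 10,
#'                     times = seq(0, 900, by = 6))
#' head(as_tibble(tr))
#' @export
solve_amounts <- function(graph, params, dose_amount, lag = 0, times) {
  stopifnot(dose_amount > 0, lag >= 0)
  if (is.unsorted(times)) {
    abort("`times` must be sorted ascending.", class = "dcepop_data_error")
  }
  tmpl <- .graph_template(graph)
  kvec <- .as_rate_vector(tmpl, params)
  K <- .rate_matrix(tmpl, kvec)
  if (any(!is.finite(K))) {
    abort("Rate matrix has non-finite entries.", class = "dcepop_numeric_error")
  }
  a0 <- rep(0, tmpl$n)
  a0[tmpl$root] <- dose_amount
  A <- matrix(0, tmpl$n, length(times))
  post <- times >= lag
  if (any(post)) A[, post] <- .amounts_at(K, a0, times[post] - lag)
  A <- t(A)
  dimnames(A) <- list(NULL, tmpl$comps)
  structure(list(times = times, amounts = A, dose_amount = dose_amount,
                 lag = lag),
            class = "amount_trajectory")
}

#' @exportS3Method tibble::as_tibble
as_tibble.amount_trajectory <- function(x, ...) {
  tibble(time = rep(x$times, times = ncol(x$amounts)),
         compartment = rep(colnames(x$amounts), each = length(x$times)),
         amount = as.vector(x$amounts))
}

#' @export
print.amount_trajectory <- function(x, ...) {
  cat("<amount_trajectory> ", length(x$times), " times x ",
      ncol(x$amounts), " compartments; dose ", x$dose_amount,
      " µmol, lag ", x$lag, " s\n", sep = "")
  invisible(x)
}

#' Derive distribution volumes and inter-compartmental flows
#'
#' With clearance fixed, the central volume follows from the elimination
#' rate, `V_c = Cl / k_C0`, and every peripheral volume follows by walking
#' the tree of bidirectional exchange pairs outward from the dose
#' compartment using k = Q/V: for a pair i->j / j->i, the flow is
#' Q = k_ij V_i and the far volume V_j = Q / k_ji (flow balance,
#' Q_forward = Q_backward).
#'
#' @param graph A [compartment_graph()] whose exchange edges form a
#'   bidirectional tree rooted at the dose compartment (true for all
#'   presets).
#' @param params A [kinetic_params()] or named rate vector.
#' @return An object of class `volume_set`: `volumes` (named, ml),
#'   `fractions` (volumes normalized to sum 1), and `flows` (tibble with
#'   `from`, `to`, `Q` in ml/s, one row per pair).
#' @examples
#' g <- graph_preset("mtl3")
#' vs <- derive_volumes(g, kinetic_params(default_rates(g)))
#' vs$volumes["C"]   # Cl / k_C0
#' @export
derive_volumes <- function(graph, params) {
  tmpl <- .graph_template(graph)
  kvec <- .as_rate_vector(tmpl, params)
  Cl <- if (inherits(params, "kinetic_params")) params$Cl else 0.04
  if (is.na(tmpl$elim_rate)) {
    abort("Volume derivation needs an elimination pathway (to anchor V_c).",
          class = "dcepop_derivation_error")
  }
  V <- .volume_vector(tmpl, kvec, Cl)
  if (is.null(V)) {
    abort("Volume derivation requires bidirectional exchange pairs.",
          class = "dcepop_derivation_error")
  }
  names(V) <- tmpl$comps
  pr <- tmpl$pairs
  flows <- if (is.null(pr)) {
    tibble(from = character(0), to = character(0), Q = numeric(0))
  } else {
    tibble(from = tmpl$comps[pr[, "parent"]],
           to = tmpl$comps[pr[, "child"]],
           Q = unname(kvec[pr[, "fwd"]] * V[pr[, "parent"]]))
  }
  structure(list(volumes = V, fractions = V / sum(V), flows = flows,
                 Cl = Cl),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat("<volume_set> total ", format(sum(x$volumes), digits = 4), " ml\n",
      sep = "")
  print(round(x$volumes, 4))
  invisible(x)
}

#' Convert amounts to tissue concentrations
#'
#' Concentration is amount over apparent distribution volume,
#' C = A / V (µmol / ml = mM).
#'
#' @param traj An [solve_amounts()] trajectory.
#' @param volumes A [derive_volumes()] result (or named volume vector in
#'   ml covering the requested compartments).
#' @param compartments Compartments to return; default the trajectory's
#'   full set. Typically the graph's observed set.
#' @return Tibble with `time` \[s\], `compartment`, `conc` \[mM\].
#' @export
predict_concentrations <- function(traj, volumes, compartments = NULL) {
  stopifnot(inherits(traj, "amount_trajectory"))
  V <- if (inherits(volumes, "volume_set")) volumes$volumes else unlist(volumes)
  if (is.null(compartments)) compartments <- colnames(traj$amounts)
  missing <- setdiff(compartments, names(V))
  if (length(missing) > 0) {
    abort(paste0("No volume for compartment(s): ",
                 paste(missing, collapse = ", ")),
          class = "dcepop_config_error")
  }
  if (any(!is.finite(V[compartments])) || any(V[compartments] <= 0)) {
    abort("Volumes must be finite and > 0.", class = "dcepop_numeric_error")
  }
  tibble(
    time = rep(traj$times, times = length(compartments)),
    compartment = rep(compartments, each = length(traj$times)),
    conc = as.vector(traj$amounts[, compartments, drop = FALSE] /
                       rep(V[compartments], each = length(traj$times)))
  )
}
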