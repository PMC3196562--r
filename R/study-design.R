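#' Synthetic multi-tissue study design
#'
#' Describes a bolus DCE-MRI population study to simulate: number of
#' datasets, vital-tumor-tissue (vti) group sizes, anesthesia-protocol
#' assignment, the two-phase sampling schedule (dense early, sparse late),
#' per-kg dose and body-weight distribution, and the generating truth (a
#' [population_model()]). The default reproduces the design of the rat
#' hepatocellular-carcinoma study this package emulates: 33 datasets — 17
#' pre-treatment (vti level 1) and 16 post-treatment split 5/6/5 over vti
#' levels 2-4 — sampled every 6 s to 3 min then every 24 s to 15 min after
#' a 0.2 mmol/kg gadolinium bolus, with the gaseous-anesthesia protocol
#' (anest = 1) applied to half of the post-treatment datasets.
#'
#' @param n_datasets Number of datasets (default 33).
#' @param vti_sizes Integer vector of length 4: datasets per vti level
#'   (level 1 = pre-treatment reference). Must sum to `n_datasets`.
#' @param anest Optional 0/1 vector of length `n_datasets`; default assigns
#'   anest = 1 to every other post-treatment dataset.
#' @param fine_step,fine_end,coarse_step,total_end Sampling schedule [s]:
#'   `fine_step` spacing up to `fine_end`, then `coarse_step` spacing up to
#'   `total_end`. Defaults 6, 180, 24, 900.
#' @param dose_per_kg Dose in µmol/kg (default 200, i.e. 0.2 mmol/kg).
#' @param weight_mean,weight_sd Body-weight distribution [kg]; default
#'   0.3 ± 0.025 (normal truncated at 0.1).
#' @param truth Generating [population_model()]; default the full
#'   nine-compartment preset with its published typical rates.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_datasets = 33, vti_sizes = c(17, 5, 6, 5),
                         anest = NULL,
                         fine_step = 6, fine_end = 180,
                         coarse_step = 24, total_end = 900,
                         dose_per_kg = 200,
                         weight_mean = 0.3, weight_sd = 0.025,
                         truth = NULL) {
  if (length(vti_sizes) != 4 || sum(vti_sizes) != n_datasets) {
    abort("`vti_sizes` must have 4 levels summing to `n_datasets`.",
          class = "dcepop_config_error")
  }
  vti <- rep(1:4, times = vti_sizes)
  if (is.null(anest)) {
    anest <- integer(n_datasets)
    post <- which(vti > 1)
    if (length(post) > 0) anest[post[seq_along(post) %% 2 == 1]] <- 1L
  }
  if (length(anest) != n_datasets || !all(anest %in% c(0, 1))) {
    abort("`anest` must be a 0/1 vector of length `n_datasets`.",
          class = "dcepop_config_error")
  }
  if (is.null(truth)) truth <- population_model(graph_preset("mtl3"))
  stopifnot(inherits(truth, "population_model"))
  structure(
    list(n_datasets = n_datasets, vti = vti, anest = as.integer(anest),
         fine_step = fine_step, fine_end = fine_end,
         coarse_step = coarse_step, total_end = total_end,
         dose_per_kg = dose_per_kg, weight_mean = weight_mean,
         weight_sd = weight_sd, truth = truth),
    class = "study_design"
  )
}

#' Observation schedule of a study design
#'
#' Two temporal resolutions: `fine_step` spacing from the first sample after
#' the dose to `fine_end`, then `coarse_step` spacing to `total_end`. The
#' default gives \{6, 12, ..., 180\} and \{204, 228, ..., 900\} seconds —
#' identical for every tissue.
#'
#' @param design A [study_design()].
#' @return Strictly increasing numeric vector of times [s].
#' @export
make_schedule <- function(design) {
  stopifnot(inherits(design, "study_design"))
  c(seq(design$fine_step, design$fine_end, by = design$fine_step),
    seq(design$fine_end + design$coarse_step, design$total_end,
        by = design$coarse_step))
}

#' Simulate a multi-tissue population study
#'
#' For each dataset: draws body weight (hence dose), individual transfer
#' constants (log-normal inter-individual variability about the
#' covariate-adjusted typical values) and an injection lag; solves the
#' kinetics analytically; converts amounts to tissue concentrations through
#' the derived volumes; and adds mixed proportional + additive measurement
#' noise. Returns the event-record table together with a truth ledger
#' (individual rates, random effects, lag, dose) for recovery scoring.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; same seed, same study.
#' @return A list of class `study_data`: `data` (event-record tibble with
#'   columns ID, OCC, TIME, TISSUE, DV, AMT, EVID, ANEST, VTI), `truth`
#'   (long tibble ID/parameter/value), and `individuals` (list of
#'   per-dataset [draw_individual()] results).
#' @examples
#' des <- study_design(n_datasets = 4, vti_sizes = c(4, 0, 0, 0))
#' st <- generate_study(des, seed = 1)
#' dplyr::count(st$data, TISSUE)
#' @export
generate_study <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  pop <- design$truth
  tmpl <- .graph_template(pop$graph)
  sched <- make_schedule(design)
  tiss <- names(.tissue_compartments)[.tissue_compartments %in%
                                        pop$graph$observed]
  comp_id <- match(.tissue_compartments[rep(tiss, each = length(sched))],
                   tmpl$comps)
  time_id <- rep(seq_along(sched), times = length(tiss))

  rows <- vector("list", design$n_datasets)
  inds <- vector("list", design$n_datasets)
  truth <- vector("list", design$n_datasets)
  for (d in seq_len(design$n_datasets)) {
    repeat {
      wt <- rnorm(1, design$weight_mean, design$weight_sd)
      if (wt > 0.1) break
    }
    dose <- design$dose_per_kg * wt
    ind <- draw_individual(pop, anest = design$anest[d],
                           vti = design$vti[d])
    kvec <- .as_rate_vector(tmpl, ind$rates)
    f <- .predict_obs(tmpl, kvec, pop$Cl, dose, ind$lag,
                      sched, comp_id, time_id)
    dv <- f * (1 + rnorm(length(f), 0, pop$sigma_prop)) +
      rnorm(length(f), 0, pop$sigma_add)
    occ <- if (design$vti[d] == 1) 1L else 2L
    rows[[d]] <- tibble(
      ID = d,
      OCC = occ,
      TIME = c(0, rep(sched, times = length(tiss))),
      TISSUE = c(NA_character_, rep(tiss, each = length(sched))),
      DV = c(NA_real_, dv),
      AMT = c(dose, rep(NA_real_, length(f))),
      EVID = c(1L, rep(0L, length(f))),
      ANEST = design$anest[d],
      VTI = design$vti[d]
    )
    inds[[d]] <- ind
    truth[[d]] <- tibble(
      ID = d,
      parameter = c(names(ind$rates),
                    paste0("eta_", names(ind$eta)),
                    "lag", "dose", "weight"),
      value = c(unname(ind$rates), unname(ind$eta), ind$lag, dose, wt)
    )
  }
  structure(
    list(data = bind_rows(rows), truth = bind_rows(truth),
         individuals = inds, design = design, seed = seed),
    class = "study_data"
  )
}

#' @export
print.study_data <- function(x, ...) {
  cat("<study_data> ", x$design$n_datasets, " datasets, ",
      sum(x$data$EVID == 0), " observations\n", sep = "")
  invisible(x)
}

#' Thin the observation schedule of a study
#'
#' Keeps every k-th observation of each concentration curve (dose records
#' untouched), for robustness checks against coarser temporal sampling.
#'
#' @param study A `study_data` object or an event-record tibble.
#' @param keep_every Positive integer k; `1` is the identity.
#' @return Same type as `study`, with thinned observation rows.
#' @export
degrade_schedule <- function(study, keep_every = 1) {
  stopifnot(keep_every >= 1)
  data <- if (inherits(study, "study_data")) study$data else study
  obs_idx <- which(data$EVID == 0)
  curves <- split(obs_idx, list(data$ID[obs_idx], data$TISSUE[obs_idx]),
                  drop = TRUE)
  keep <- unlist(lapply(curves, function(idx) {
    if (keep_every > length(idx)) {
      abort("`keep_every` exceeds a curve's length.",
            class = "dcepop_data_error")
    }
    idx[seq(1, length(idx), by = keep_every)]
  }))
  out <- data[sort(c(which(data$EVID == 1), keep)), ]
  if (inherits(study, "study_data")) {
    study$data <- out
    study
  } else {
    out
  }
}
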