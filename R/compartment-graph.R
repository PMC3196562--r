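#' Define a linear compartment topology
#'
#' A compartment graph is the structural skeleton of a kinetic model: an
#' ordered set of compartments (some observed, the rest latent), directed
#' first-order transfer edges named after their rate constants, a dose
#' compartment receiving the bolus, and a single linear elimination pathway.
#' Topologies are data, not code: the nine-compartment muscle/tumor/liver
#' model, the four-compartment minimal model and the reduced variants used in
#' structural model selection are all instances (see [graph_preset()]), and
#' arbitrary variants can be written to / read from YAML with
#' [write_graph_yaml()].
#'
#' @param compartments Character vector of compartment labels, in order.
#' @param observed Character vector, subset of `compartments`, giving the
#'   measured compartments.
#' @param edges Data frame with columns `from`, `to`, `rate`: one row per
#'   directed transfer, `rate` being the (unique) transfer-constant name.
#' @param dose_compartment Label of the compartment receiving the bolus.
#' @param elimination Named character vector or list with elements
#'   `compartment` and `rate`: the single first-order elimination pathway.
#'   May be `NULL` for closed systems (useful in toy examples).
#'
#' @return An object of class `compartment_graph`.
#' @examples
#' g <- compartment_graph(
#'   compartments = c("C", "P"), observed = "P",
#'   edges = data.frame(from = c("C", "P"), to = c("P", "C"),
#'                      rate = c("k_CP", "k_PC")),
#'   dose_compartment = "C",
#'   elimination = c(compartment = "C", rate = "k_C0")
#' )
#' @export
compartment_graph <- function(compartments, observed, edges, dose_compartment,
                              elimination = NULL) {
  compartments <- as.character(compartments)
  observed <- as.character(observed)
  edges <- as_tibble(edges)[, c("from", "to", "rate")]
  stopifnot(!anyDuplicated(compartments))
  if (!all(observed %in% compartments)) {
    abort("`observed` must be a subset of `compartments`.",
          class = "dcepop_graph_error")
  }
  if (nrow(edges) > 0 &&
      !all(c(edges$from, edges$to) %in% compartments)) {
    abort("Edge endpoints must be declared compartments.",
          class = "dcepop_graph_error")
  }
  if (anyDuplicated(edges$rate)) {
    abort("Transfer-constant names must be unique.",
          class = "dcepop_graph_error")
  }
  if (!dose_compartment %in% compartments) {
    abort("`dose_compartment` is not a declared compartment.",
          class = "dcepop_graph_error")
  }
  if (!is.null(elimination)) {
    elimination <- as.list(elimination)
    if (!identical(sort(names(elimination)), c("compartment", "rate")) ||
        !elimination$compartment %in% compartments) {
      abort("`elimination` needs a valid `compartment` and a `rate` name.",
            class = "dcepop_graph_error")
    }
    if (elimination$rate %in% edges$rate) {
      abort("Elimination rate name collides with an edge rate.",
            class = "dcepop_graph_error")
    }
  }
  # connectivity (undirected sense); single compartments are trivially fine
  if (length(compartments) > 1) {
    reach <- compartments[1]
    repeat {
      nxt <- unique(c(edges$to[edges$from %in% reach],
                      edges$from[edges$to %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    if (length(reach) < length(compartments)) {
      abort(paste0("Graph is not connected; unreachable: ",
                   paste(setdiff(compartments, reach), collapse = ", ")),
            class = "dcepop_graph_error")
    }
  }
  structure(
    list(compartments = compartments, observed = observed, edges = edges,
         dose_compartment = dose_compartment, elimination = elimination),
    class = "compartment_graph"
  )
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat("<compartment_graph> ", length(x$compartments), " compartments (",
      paste(x$compartments, collapse = ", "), ")\n", sep = "")
  cat("  observed: ", paste(x$observed, collapse = ", "), "\n", sep = "")
  cat("  edges: ", nrow(x$edges), "; dose in ", x$dose_compartment, sep = "")
  if (!is.null(x$elimination)) {
    cat("; elimination ", x$elimination$rate, " from ",
        x$elimination$compartment, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Rate-constant names of a compartment graph
#'
#' Edge rates in declaration order, followed by the elimination rate.
#' This is the canonical parameter order used throughout fitting.
#'
#' @param graph A [compartment_graph()].
#' @return Character vector of rate names.
#' @export
rate_names <- function(graph) {
  stopifnot(inherits(graph, "compartment_graph"))
  c(graph$edges$rate,
    if (!is.null(graph$elimination)) graph$elimination$rate)
}

# Helper for bidirectional-pair construction: two directed edges per pair.
.pair_edges <- function(...) {
  p <- list(...)
  tibble(
    from = unlist(lapply(p, function(e) e[c(1, 2)]))[c(TRUE, FALSE)],
    to = unlist(lapply(p, function(e) e[c(1, 2)]))[c(FALSE, TRUE)],
    rate = vapply(p, function(e) e[[3]], character(1))
  )
}

.mtl3_edges <- function() {
  tibble(
    from = c("C", "M1", "M1", "M2", "M2", "M3",
             "C", "L1", "L1", "T2", "T2", "T3",
             "L1", "L2", "L2", "L3"),
    to   = c("M1", "C", "M2", "M1", "M3", "M2",
             "L1", "C", "T2", "L1", "T3", "T2",
             "L2", "L1", "L3", "L2"),
    rate = c("k_CM1", "k_M1C", "k_M1M2", "k_M2M1", "k_M2M3", "k_M3M2",
             "k_CL1", "k_L1C", "k_L1T2", "k_T2L1", "k_T2T3", "k_T3T2",
             "k_L1L2", "k_L2L1", "k_L2L3", "k_L3L2")
  )
}

# Published population estimates for the full nine-compartment model [1/s].
.mtl3_rates <- c(
  k_CM1 = 0.3, k_M1C = 0.012, k_M1M2 = 3.6, k_M2M1 = 300,
  k_M2M3 = 0.24, k_M3M2 = 0.0024,
  k_CL1 = 2.9, k_L1C = 0.59, k_L1T2 = 0.03, k_T2L1 = 0.38,
  k_T2T3 = 3.7, k_T3T2 = 0.33,
  k_L1L2 = 0.0045, k_L2L1 = 0.021, k_L2L3 = 0.027, k_L3L2 = 2.3e-5,
  k_C0 = 0.013
)

#' Preset compartment topologies
#'
#' Ships the structural-model family used in multi-tissue DCE-MRI population
#' modelling:
#' \describe{
#'   \item{`mtl3`}{Nine compartments: latent central `C` with a three-deep
#'     muscle chain (`M1`-`M2`-`M3`, `M2` observed), a three-deep liver chain
#'     (`L1`-`L2`-`L3`, `L2` observed) and a two-deep tumor chain
#'     (`T2`-`T3`, `T2` observed) attached to the first liver compartment
#'     `L1` — the hepatic supply of the tumor, not the central compartment.}
#'   \item{`minimal`}{Four compartments: the three observed tissues each
#'     exchanging directly with latent `C`.}
#'   \item{`no_t3`, `no_l3`, `muscle_two`, `muscle_direct`,
#'     `tumor_on_c`}{Reduced variants: latent `T3` removed, latent `L3`
#'     removed, muscle chain shortened to two compartments, muscle observed
#'     compartment attached directly to `C`, and tumor chain moved from `L1`
#'     to `C`.}
#' }
#' Each preset carries default typical rate values (attribute
#' `default_rates`), the full model's being the published population
#' estimates; reduced/renamed edges inherit the matching full-model value.
#'
#' @param name Preset name.
#' @return A [compartment_graph()] with a `default_rates` attribute.
#' @examples
#' g <- graph_preset("mtl3")
#' rate_names(g)
#' @export
graph_preset <- function(name = c("mtl3", "minimal", "no_t3", "no_l3",
                                  "muscle_two", "muscle_direct",
                                  "tumor_on_c")) {
  name <- arg_match(name)
  elim <- c(compartment = "C", rate = "k_C0")
  obs <- c("M2", "T2", "L2")
  g <- switch(
    name,
    mtl3 = compartment_graph(
      c("C", "M1", "M2", "M3", "L1", "L2", "L3", "T2", "T3"),
      obs, .mtl3_edges(), "C", elim
    ),
    minimal = compartment_graph(
      c("C", "M2", "T2", "L2"), obs,
      tibble(from = c("C", "M2", "C", "T2", "C", "L2"),
             to = c("M2", "C", "T2", "C", "L2", "C"),
             rate = c("k_CM2", "k_M2C", "k_CT2", "k_T2C",
                      "k_CL2", "k_L2C")),
      "C", elim
    ),
    no_t3 = {
      e <- .mtl3_edges()
      compartment_graph(
        c("C", "M1", "M2", "M3", "L1", "L2", "L3", "T2"), obs,
        e[!(e$rate %in% c("k_T2T3", "k_T3T2")), ], "C", elim
      )
    },
    no_l3 = {
      e <- .mtl3_edges()
      compartment_graph(
        c("C", "M1", "M2", "M3", "L1", "L2", "T2", "T3"), obs,
        e[!(e$rate %in% c("k_L2L3", "k_L3L2")), ], "C", elim
      )
    },
    muscle_two = {
      e <- .mtl3_edges()
      compartment_graph(
        c("C", "M1", "M2", "L1", "L2", "L3", "T2", "T3"), obs,
        e[!(e$rate %in% c("k_M2M3", "k_M3M2")), ], "C", elim
      )
    },
    muscle_direct = {
      e <- .mtl3_edges()
      e <- e[!(e$rate %in% c("k_CM1", "k_M1C", "k_M1M2", "k_M2M1",
                             "k_M2M3", "k_M3M2")), ]
      e <- bind_rows(tibble(from = c("C", "M2"), to = c("M2", "C"),
                            rate = c("k_CM2", "k_M2C")), e)
      compartment_graph(
        c("C", "M2", "L1", "L2", "L3", "T2", "T3"), obs, e, "C", elim
      )
    },
    tumor_on_c = {
      e <- .mtl3_edges()
      e$from[e$rate == "k_L1T2"] <- "C"
      e$to[e$rate == "k_T2L1"] <- "C"
      e$rate[e$rate == "k_L1T2"] <- "k_CT2"
      e$rate[e$rate == "k_T2L1"] <- "k_T2C"
      compartment_graph(
        c("C", "M1", "M2", "M3", "L1", "L2", "L3", "T2", "T3"), obs,
        e, "C", elim
      )
    }
  )
  # default typical rates: published estimates, renamed edges inherit
  alias <- c(k_CM2 = "k_CM1", k_M2C = "k_M1C", k_CT2 = "k_L1T2",
             k_T2C = "k_T2L1", k_CL2 = "k_CL1", k_L2C = "k_L1C")
  rn <- rate_names(g)
  src <- ifelse(rn %in% names(.mtl3_rates), rn, alias[rn])
  attr(g, "default_rates") <- setNames(.mtl3_rates[src], rn)
  attr(g, "preset") <- name
  g
}

#' Default typical rate values for a graph
#'
#' Returns the `default_rates` attribute of a preset graph, or errors for a
#' custom graph without defaults.
#'
#' @param graph A [compartment_graph()].
#' @return Named numeric vector of rates, ordered as [rate_names()].
#' @export
default_rates <- function(graph) {
  dr <- attr(graph, "default_rates")
  if (is.null(dr)) {
    abort("Graph carries no default rates; supply typical values explicitly.",
          class = "dcepop_config_error")
  }
  dr
}

#' Write / read a topology configuration file
#'
#' Serializes a compartment graph to YAML (compartments, observed set, edge
#' list with rate names, dose and elimination compartments) and reads it
#' back. Round-trips exactly.
#'
#' @param graph A [compartment_graph()].
#' @param path File path.
#' @return `write_graph_yaml()` returns `path` invisibly;
#'   `read_graph_yaml()` returns a [compartment_graph()].
#' @export
write_graph_yaml <- function(graph, path) {
  stopifnot(inherits(graph, "compartment_graph"))
  obj <- list(
    compartments = as.list(graph$compartments),
    observed = as.list(graph$observed),
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      as.list(graph$edges[i, ])
    }),
    dose_compartment = graph$dose_compartment,
    elimination = graph$elimination
  )
  dr <- attr(graph, "default_rates")
  if (!is.null(dr)) obj$default_rates <- as.list(dr)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_graph_yaml
#' @export
read_graph_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("compartments", "observed", "edges", "dose_compartment")
  if (!all(need %in% names(obj))) {
    abort(paste0("Topology config is missing field(s): ",
                 paste(setdiff(need, names(obj)), collapse = ", ")),
          class = "dcepop_config_error")
  }
  edges <- bind_rows(lapply(obj$edges, as_tibble))
  g <- compartment_graph(unlist(obj$compartments), unlist(obj$observed),
                         edges, obj$dose_compartment,
                         obj$elimination)
  if (!is.null(obj$default_rates)) {
    attr(g, "default_rates") <- unlist(obj$default_rates)[rate_names(g)]
  }
  g
}

# ---- internal fitting template ---------------------------------------------
# Precomputes index maps so the rate matrix and forward solution can be
# rebuilt from a bare rate vector with no name lookups in the hot path.
.graph_template <- function(graph) {
  comps <- graph$compartments
  n <- length(comps)
  rn <- rate_names(graph)
  nr <- length(rn)
  ei <- match(graph$edges$from, comps)
  ej <- match(graph$edges$to, comps)
  # linear indices into an n x n matrix: entry (to, from) holds k_from,to
  off_lin <- (ei - 1L) * n + ej
  off_rate <- match(graph$edges$rate, rn)
  # outflow map: column j of K loses the sum of rates leaving compartment j
  out <- matrix(0, n, nr)
  for (i in seq_along(ei)) out[ei[i], off_rate[i]] <- 1
  if (!is.null(graph$elimination)) {
    out[match(graph$elimination$compartment, comps),
        match(graph$elimination$rate, rn)] <- 1
  }
  diag_lin <- (seq_len(n) - 1L) * n + seq_len(n)

  # BFS over bidirectional pairs from the dose compartment, for the
  # flow-balance volume chain V_child = k_fwd * V_parent / k_back.
  root <- match(graph$dose_compartment, comps)
  pairs <- NULL
  visited <- root
  frontier <- root
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (p in frontier) {
      kids <- unique(ej[ei == p])
      for (ch in kids) {
        if (ch %in% visited) next
        fwd <- which(ei == p & ej == ch)
        back <- which(ei == ch & ej == p)
        pairs <- rbind(pairs, c(parent = p, child = ch,
                                fwd = if (length(fwd)) off_rate[fwd[1]] else NA_integer_,
                                back = if (length(back)) off_rate[back[1]] else NA_integer_))
        visited <- c(visited, ch)
        nxt <- c(nxt, ch)
      }
    }
    frontier <- nxt
  }
  elim_rate <- if (!is.null(graph$elimination)) {
    match(graph$elimination$rate, rn)
  } else NA_integer_
  list(
    graph = graph, comps = comps, n = n, rate_names = rn, nr = nr,
    off_lin = off_lin, off_rate = off_rate, out = out, diag_lin = diag_lin,
    root = root, pairs = pairs, elim_rate = elim_rate,
    obs_idx = match(graph$observed, comps)
  )
}

# K from a bare rate vector (ordered as tmpl$rate_names)
.rate_matrix <- function(tmpl, kvec) {
  K <- matrix(0, tmpl$n, tmpl$n)
  K[tmpl$off_lin] <- kvec[tmpl$off_rate]
  K[tmpl$diag_lin] <- -as.vector(tmpl$out %*% kvec)
  K
}

# Volumes [ml] from the flow-balance chain rooted at the dose compartment.
# Returns NULL if the walk hits a unidirectional edge.
.volume_vector <- function(tmpl, kvec, Cl) {
  if (is.na(tmpl$elim_rate)) return(NULL)
  V <- rep(NA_real_, tmpl$n)
  V[tmpl$root] <- Cl / kvec[tmpl$elim_rate]
  pr <- tmpl$pairs
  if (!is.null(pr)) {
    for (i in seq_len(nrow(pr))) {
      if (is.na(pr[i, "fwd"]) || is.na(pr[i, "back"])) return(NULL)
      V[pr[i, "child"]] <- kvec[pr[i, "fwd"]] * V[pr[i, "parent"]] /
        kvec[pr[i, "back"]]
    }
  }
  V
}
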