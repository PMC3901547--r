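#' Stage-structured mosquito population model
#'
#' A Lefkovitch stage model for the aquatic-to-adult mosquito life cycle
#' (egg, larva, pupa, adult by default) with per-stage duration in days,
#' daily survival probability, and per-capita daily fecundity from adults
#' into eggs.  The projection step is `step_hours` long (48 h by default);
#' the daily matrix is compounded to the step length.  Carrying capacity is
#' a vector: the adult entry is the target Ne and the other entries are
#' scaled by the stable stage distribution.
#'
#' Default stage parameters are representative values for *An. gambiae*
#' (egg ~2 d, larva ~8 d, pupa ~1 d development; see
#' `inst/extdata/stage_defaults.yaml`, an editable file clearly labelled as
#' representative rather than a published life table).
#'
#' @param durations named numeric vector of stage durations in days
#'   (last stage = adult; its duration only sets residence, adults do not
#'   advance out).
#' @param survivals daily survival probability per stage, in `[0, 1]`.
#' @param fecundity effective eggs per adult per day (recruitment into the
#'   egg class net of density-independent early losses).
#' @param step_hours projection step length in hours (multiple of 24).
#' @param K_adult adult carrying capacity (the target Ne).
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(durations = c(egg = 2, larva = 8, pupa = 1, adult = 14),
                        survivals = c(egg = 0.8, larva = 0.86, pupa = 0.9,
                                      adult = 0.93),
                        fecundity = 2, step_hours = 48, K_adult = 5692) {
  stopifnot(length(durations) == length(survivals), length(durations) >= 2,
            all(durations > 0), all(survivals >= 0), all(survivals <= 1),
            fecundity >= 0, step_hours > 0, step_hours %% 24 == 0,
            K_adult > 0)
  if (is.null(names(durations)))
    names(durations) <- paste0("stage", seq_along(durations))
  structure(list(durations = durations,
                 survivals = setNames(survivals, names(durations)),
                 fecundity = fecundity, step_hours = step_hours,
                 K_adult = K_adult),
            class = "stage_model")
}

#' Load stage parameters from a YAML file
#'
#' Reads `durations`, `survivals`, `fecundity`, `step_hours`, `K_adult`.
#' Use this to supply literature life-table values in place of the shipped
#' representative defaults.
#'
#' @param path YAML file; defaults to the packaged
#'   `stage_defaults.yaml`.
#' @return A [stage_model()].
#' @export
stage_model_from_yaml <- function(path = system.file("extdata",
                                                     "stage_defaults.yaml",
                                                     package = "irsabc")) {
  y <- yaml::read_yaml(path)
  st <- y$stages
  stage_model(durations = setNames(vapply(st, `[[`, numeric(1),
                                          "duration_days"),
                                   vapply(st, `[[`, character(1), "name")),
              survivals = vapply(st, `[[`, numeric(1), "daily_survival"),
              fecundity = y$fecundity_eggs_per_adult_per_day,
              step_hours = y$step_hours, K_adult = y$K_adult)
}

#' Build the per-step stage transition matrix
#'
#' Standard stage-classified (Lefkovitch) construction from daily rates:
#' within-stage persistence `P_i = s_i (1 - 1/d_i)`, stage advance
#' `G_i = s_i / d_i`, adult persistence `s_adult`, fecundity on the adult
#' column into the egg row; the daily matrix is raised to the number of
#' days per step.
#'
#' @param model a [stage_model()].
#' @return Non-negative square matrix, one row/column per stage.
#' @export
build_transition_matrix <- function(model) {
  stopifnot(inherits(model, "stage_model"))
  k <- length(model$durations)
  M <- matrix(0, k, k, dimnames = list(names(model$durations),
                                       names(model$durations)))
  for (i in seq_len(k - 1)) {
    M[i, i] <- model$survivals[i] * (1 - 1 / model$durations[i])
    M[i + 1, i] <- model$survivals[i] / model$durations[i]
  }
  M[k, k] <- model$survivals[k]
  M[1, k] <- M[1, k] + model$fecundity
  days <- model$step_hours / 24
  out <- diag(k)
  for (d in seq_len(days)) out <- out %*% M
  dimnames(out) <- dimnames(M)
  out
}

#' Stable stage distribution
#'
#' Normalized dominant right eigenvector by power iteration (on `I + M`,
#' which shares eigenvectors with `M` and converges for any irreducible
#' non-negative matrix).  Errors if the matrix is reducible (e.g. the
#' identity), for which no unique stable distribution exists.
#'
#' @param M non-negative square matrix.
#' @param tol convergence tolerance (default `1e-10`).
#' @param max_iter iteration cap.
#' @return Proportions vector summing to 1.
#' @export
stable_stage_distribution <- function(M, tol = 1e-10, max_iter = 1e5) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(M >= 0))
  k <- nrow(M)
  B <- diag(k) + M
  P <- diag(k)
  for (i in seq_len(k - 1)) P <- P %*% B
  if (any(P == 0))
    stop("matrix is reducible: no unique stable stage distribution")
  w <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    w2 <- as.numeric(B %*% w)
    w2 <- w2 / sum(w2)
    if (max(abs(w2 - w)) < tol) return(setNames(w2, rownames(M)))
    w <- w2
  }
  stop("power iteration did not converge")
}

#' Carrying-capacity vector of a stage model
#'
#' Adult entry equals `K_adult`; other stages are scaled by the stable
#' stage distribution of the per-step matrix.
#'
#' @param model a [stage_model()].
#' @return Named positive vector.
#' @export
stage_K <- function(model) {
  M <- build_transition_matrix(model)
  w <- stable_stage_distribution(M)
  k <- length(w)
  model$K_adult * w / w[k]
}

#' A one-day mortality perturbation event
#'
#' @param step projection step index (1-based) at which the shock applies.
#' @param mortality per-stage one-day mortality fractions in `[0, 1]`
#'   (named or in stage order).
#' @return An object of class `perturbation_event`.
#' @export
perturbation_event <- function(step, mortality) {
  stopifnot(step >= 1, all(mortality >= 0), all(mortality <= 1))
  structure(list(step = as.integer(step), mortality = mortality),
            class = "perturbation_event")
}

#' Aquatic-stage mortality shock
#'
#' Convenience constructor for the deluge what-if: the given mortality on
#' every stage except the last (adult), zero on adults.
#'
#' @param step projection step index.
#' @param mortality aquatic mortality fraction (e.g. 0.99 or 0.75).
#' @param n_stages number of stages (default 4).
#' @return A [perturbation_event()].
#' @export
aquatic_shock <- function(step, mortality, n_stages = 4) {
  perturbation_event(step, c(rep(mortality, n_stages - 1), 0))
}

#' Project the stage model through time
#'
#' Density-dependent logistic matrix update in the tradition of simple
#' logistic stage models: the growth increment `(M - I) N[t]` is scaled by
#' the logistic factor in total abundance,
#' `N[t+1] = N[t] + ((sum(K) - sum(N[t])) / sum(K)) * ((M - I) N[t])`.
#' Under this update `N = K` is an exact fixed point and the low-density
#' limit recovers the linear model `N[t+1] = M N[t]`.  Two alternative
#' readings are switchable: `literal = TRUE` uses `M` instead of `M - I`
#' in the increment (the printed form, which double-counts standing
#' abundance), and `elementwise = TRUE` applies a per-stage factor
#' `(K_i - N_i)/K_i` instead of the total-abundance factor (that variant
#' freezes any stage that starts at its carrying capacity, so it cannot
#' produce the adult dip the perturbation analysis is about; it is kept
#' for comparison only).  Perturbation events multiply the listed stages
#' by `1 - mortality` at their step.  Negative abundances are clipped to
#' zero with a warning.
#'
#' @param model a [stage_model()].
#' @param steps number of projection steps (default 100, i.e. 200 days at
#'   the 48-h default step).
#' @param perturbations list of [perturbation_event()]s.
#' @param start initial stage vector (default: the carrying capacity, an
#'   equilibrium start).
#' @param literal use the literal update without `- I`.
#' @param elementwise use per-stage logistic factors instead of the
#'   total-abundance factor (degenerate at equilibrium starts; see above).
#' @return An object of class `stage_trajectory`: matrix `N` of
#'   `(steps + 1) x n_stages` abundances, plus `K`, `adult` series and
#'   `step_hours`.
#' @export
project <- function(model, steps = 100, perturbations = list(),
                    start = NULL, literal = FALSE, elementwise = FALSE) {
  stopifnot(inherits(model, "stage_model"), steps >= 1)
  if (inherits(perturbations, "perturbation_event"))
    perturbations <- list(perturbations)
  M <- build_transition_matrix(model)
  K <- stage_K(model)
  k <- length(K)
  G <- if (literal) M else M - diag(k)
  N <- matrix(NA_real_, steps + 1, k,
              dimnames = list(NULL, names(model$durations)))
  N[1, ] <- if (is.null(start)) K else start
  shock_at <- vapply(perturbations, `[[`, integer(1), "step")
  clipped <- FALSE
  for (t in seq_len(steps)) {
    n <- N[t, ]
    hit <- which(shock_at == t)
    for (h in hit) n <- n * (1 - perturbations[[h]]$mortality)
    phi <- if (elementwise) (K - n) / K else (sum(K) - sum(n)) / sum(K)
    n2 <- n + phi * as.numeric(G %*% n)
    if (any(n2 < 0)) { clipped <- TRUE; n2[n2 < 0] <- 0 }
    N[t + 1, ] <- n2
  }
  if (clipped) warning("negative abundances clipped to zero")
  structure(list(N = N, K = K, adult = N[, k], step_hours = model$step_hours),
            class = "stage_trajectory")
}

#' Summarize a perturbation trajectory
#'
#' @param traj a [project()] result.
#' @return List: `min_adult`, `percent_reduction`
#'   (`100 (1 - min adult / K_adult)`), `recovery_step` (first step after
#'   the minimum with adult `>= 0.99 K_adult`; 0 when the series never
#'   leaves that band; `NA` when it never recovers), `recovery_days`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "stage_trajectory"))
  adult <- traj$adult
  K <- traj$K[length(traj$K)]
  min_adult <- min(adult)
  reduction <- 100 * (1 - min_adult / K)
  if (all(adult >= 0.99 * K)) {
    rec <- 0L
  } else {
    i_min <- which.min(adult)
    after <- which(adult >= 0.99 * K & seq_along(adult) > i_min)
    rec <- if (length(after)) after[1] - 1L else NA_integer_
  }
  days_per_step <- traj$step_hours / 24
  rec_days <- if (is.na(rec) || rec == 0) rec else {
    i_min <- which.min(adult)
    (rec - (i_min - 1L)) * days_per_step
  }
  list(min_adult = unname(min_adult), percent_reduction = unname(reduction),
       recovery_step = unname(rec), recovery_days = as.numeric(rec_days))
}

#' Percent changes along an interval Ne trajectory
#'
#' Arithmetic on the five interval estimates: percent decline around the
#' first in-study spray round (interval 1 -> 2), percent decline around the
#' second round (interval 4 -> 5), and the rebound of interval 4 relative
#' to interval 2, expressed as a percentage ratio.
#'
#' @param ne numeric vector of five interval Ne values, oldest first.
#' @return Named list `decline_round1_pct`, `decline_round2_pct`,
#'   `rebound_pct`.
#' @examples
#' interval_changes(c(5692, 428, 1782, 12060, 4204))
#' @export
interval_changes <- function(ne) {
  stopifnot(length(ne) == 5, all(ne > 0))
  ne <- unname(ne)
  list(decline_round1_pct = 100 * (1 - ne[2] / ne[1]),
       decline_round2_pct = 100 * (1 - ne[5] / ne[4]),
       rebound_pct = 100 * ne[4] / ne[2])
}
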