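#' Build one of the six competing demographic scenarios
#'
#' The six scenarios are alternative stories for how Ne moved across the
#' study window: (1) constant; (2) reduced by each IRS round, recovering
#' until the next round; (3) reduced by each round with no recovery;
#' (4) rank-concordant with interval rainfall; (5) rank-discordant with
#' interval rainfall; (6) reduced by the first round and declining for three
#' months before recovering by month four.
#'
#' All scenarios except (1) share the same epoch template: one free Ne per
#' interval between consecutive sampling dates, plus a shared ancestral Ne
#' (`N_anc`) for all time older than the first sample, needed so that
#' coalescence completes.  The scenarios differ only in their inequality
#' constraints among these parameters.  Scenario 6 splits the interval
#' containing the three-month post-spray mark into a declining part (`N4a`)
#' and a recovering part (`N4b`).  With `anchor = "spray"`, epoch change
#' points that bracket a spray round are moved to the spray date itself
#' rather than the sampling date.
#'
#' Rainfall scenarios are encoded as rank-order constraints: the ranks of
#' the interval Ne values must equal the ranks of interval mean rainfall
#' (scenario 4) or their reverse (scenario 5); no functional form of the
#' rainfall response is imposed.
#'
#' @param scenario_id integer 1-6.
#' @param design a [sampling_design()]; must carry spray dates for scenarios
#'   2, 3, 6 and rainfall for 4, 5.
#' @param clock a [generation_clock()]; defaults to 18 generations/year
#'   referenced at the last sampling date.
#' @param ne_bounds log-uniform prior bounds on every Ne parameter
#'   (default `c(10, 1e5)`).
#' @param anchor `"sampling"` (epoch changes at sampling dates; the default,
#'   matching the reported inference intervals) or `"spray"` (changes at
#'   spray dates where a round falls inside an interval).
#' @return An object of class `scenario_spec`.
#' @export
build_scenario <- function(scenario_id, design = default_design(),
                           clock = generation_clock(18, max(design$dates)),
                           ne_bounds = c(10, 1e5),
                           anchor = c("sampling", "spray")) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(clock, "generation_clock"),
            scenario_id %in% 1:6,
            length(ne_bounds) == 2, all(ne_bounds >= 2),
            ne_bounds[1] <= ne_bounds[2])
  anchor <- match.arg(anchor)
  scenario_id <- as.integer(scenario_id)
  if (scenario_id %in% c(2L, 3L, 6L) && is.null(design$spray_dates))
    stop("scenario ", scenario_id, " needs spray dates in the design")
  if (scenario_id %in% c(4L, 5L) && is.null(design$rainfall))
    stop("scenario ", scenario_id, " needs a rainfall series in the design")

  S <- length(design$dates)
  t_sample <- calendar_to_generations(design$dates, clock)  # decreasing
  rank_target <- NULL
  constraints <- list()

  if (scenario_id == 1L) {
    breaks <- numeric(0)
    params <- "N"
    epoch_param <- "N"
  } else {
    n_ivl <- S - 1L
    # change points at the S-1 older sampling dates (recent -> old)
    bnd_dates <- design$dates[-S]
    if (anchor == "spray") {
      # move a change point to the spray date when a round falls inside the
      # interval that the change point opens
      spr <- design$spray_dates[design$spray_dates >= min(design$dates)]
      for (sd in as.list(spr)) {
        i <- findInterval(as.numeric(sd), as.numeric(design$dates))
        if (i >= 1 && i < S) bnd_dates[i] <- sd
      }
    }
    breaks <- sort(calendar_to_generations(bnd_dates, clock))
    params <- c("N_anc", paste0("N", seq_len(n_ivl)))
    # epochs recent -> old: interval n_ivl, ..., interval 1, ancestral
    epoch_param <- c(paste0("N", rev(seq_len(n_ivl))), "N_anc")

    if (scenario_id == 6L) {
      # extra change point three months after the first in-study round
      r1 <- design$spray_dates[design$spray_dates >= min(design$dates)][1]
      split_date <- r1 + 91
      i <- findInterval(as.numeric(split_date), as.numeric(design$dates))
      if (i < 1 || i >= S)
        stop("three-month post-spray mark falls outside the sampling window")
      split_gen <- calendar_to_generations(split_date, clock)
      breaks <- sort(c(breaks, split_gen))
      nm <- paste0("N", i)
      params <- c("N_anc",
                  vapply(seq_len(n_ivl), function(j) {
                    if (j < i) paste0("N", j) else if (j == i) paste0("N", i, "a")
                    else paste0("N", j)
                  }, character(1)))
      params <- append(params, paste0("N", i, "b"), after = i + 1L)
      ivl_names <- setdiff(params, "N_anc")
      epoch_param <- c(rev(ivl_names), "N_anc")
      # drop at round 1 then continued decline to the split, then recovery,
      # then drop at round 2
      chain <- ivl_names
      constraints <- list(c("N_anc", "<=", "N1"))
      decl_end <- which(chain == paste0("N", i, "a"))
      for (j in 2:decl_end)
        constraints <- c(constraints, list(c(chain[j], "<=", chain[j - 1])))
      constraints <- c(constraints,
                       list(c(paste0("N", i, "a"), "<=", paste0("N", i, "b"))))
      last <- chain[length(chain)]
      constraints <- c(constraints,
                       list(c(last, "<=", paste0("N", i, "b"))))
    } else if (scenario_id == 2L) {
      # drop in each interval containing an in-study round, recovery between
      in_study <- design$spray_dates[design$spray_dates > min(design$dates) &
                                       design$spray_dates < max(design$dates)]
      if (!length(in_study)) stop("scenario 2 needs an in-study spray round")
      drop_ivl <- findInterval(as.numeric(in_study), as.numeric(design$dates))
      constraints <- list(c("N_anc", "<=", "N1"))
      for (i in drop_ivl) {
        prev <- if (i >= 2) paste0("N", i - 1) else "N_anc"
        constraints <- c(constraints, list(c(paste0("N", i), "<=", prev)))
      }
      seg_ends <- c(drop_ivl[-1], n_ivl + 1L)
      for (k in seq_along(drop_ivl)) {
        j <- drop_ivl[k]
        while (j + 1L < seg_ends[k]) {
          constraints <- c(constraints,
                           list(c(paste0("N", j), "<=", paste0("N", j + 1))))
          j <- j + 1L
        }
      }
    } else if (scenario_id == 3L) {
      prev <- "N_anc"
      for (j in seq_len(n_ivl)) {
        constraints <- c(constraints, list(c(paste0("N", j), "<=", prev)))
        prev <- paste0("N", j)
      }
    } else if (scenario_id %in% c(4L, 5L)) {
      rain <- interval_rainfall_means(design)
      rank_target <- if (scenario_id == 4L) rank(rain) else rank(-rain)
    }
  }

  structure(list(scenario_id = scenario_id, params = params,
                 breaks = breaks, epoch_param = epoch_param,
                 constraints = constraints, rank_target = rank_target,
                 ne_bounds = as.numeric(ne_bounds),
                 anchor = anchor, design = design, clock = clock),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> scenario %d: %d parameter(s) [%s], %d epochs\n",
              x$scenario_id, length(x$params),
              paste(x$params, collapse = ", "), length(x$epoch_param)))
  if (length(x$constraints))
    cat("  constraints:",
        paste(vapply(x$constraints, paste, character(1), collapse = " "),
              collapse = "; "), "\n")
  if (!is.null(x$rank_target))
    cat("  rank constraint on interval Ne, target ranks:",
        paste(x$rank_target, collapse = " "), "\n")
  invisible(x)
}

#' Check scenario constraints on a matrix of parameter draws
#'
#' @param spec a [build_scenario()] spec.
#' @param par numeric matrix, one column per `spec$params`, one row per draw.
#' @return Logical vector, `TRUE` where all constraints hold.
#' @export
check_constraints <- function(spec, par) {
  stopifnot(inherits(spec, "scenario_spec"))
  par <- rbind(par)
  colnames(par) <- spec$params
  ok <- rep(TRUE, nrow(par))
  for (cn in spec$constraints)
    ok <- ok & (par[, cn[1]] <= par[, cn[3]])
  if (!is.null(spec$rank_target)) {
    ivl <- setdiff(spec$params, "N_anc")
    tgt <- spec$rank_target
    ok <- ok & apply(par[, ivl, drop = FALSE], 1,
                     function(v) all(rank(v) == tgt))
  }
  ok
}

#' Draw scenario parameters from the constrained prior
#'
#' Samples each Ne parameter log-uniformly on `spec$ne_bounds` and keeps
#' draws satisfying all scenario constraints (rejection sampling), so every
#' returned row satisfies the constraint set.  Mutation-model
#' hyperparameters are drawn by [mutation_model()] machinery, not here.
#'
#' @param spec a [build_scenario()] spec.
#' @param n number of accepted draws required.
#' @param accept_floor abort with a diagnostic if the empirical acceptance
#'   rate falls below this floor (default `1e-4`).
#' @return Matrix `n x length(spec$params)` of accepted draws (an attribute
#'   `acceptance_rate` records the empirical rate).
#' @export
draw_scenario_params <- function(spec, n, accept_floor = 1e-4) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 1)
  p <- length(spec$params)
  lo <- log10(spec$ne_bounds[1]); hi <- log10(spec$ne_bounds[2])
  out <- matrix(NA_real_, 0, p)
  tries <- 0
  block <- max(2L * n, 1000L)
  while (nrow(out) < n) {
    cand <- matrix(10^runif(block * p, lo, hi), block, p,
                   dimnames = list(NULL, spec$params))
    keep <- check_constraints(spec, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
    tries <- tries + block
    if (tries >= 1e5 && nrow(out) / tries < accept_floor)
      stop(sprintf(
        "constraint acceptance rate %.2g below floor %.2g for scenario %d",
        nrow(out) / tries, accept_floor, spec$scenario_id))
  }
  acc <- nrow(out) / tries
  out <- out[seq_len(n), , drop = FALSE]
  attr(out, "acceptance_rate") <- acc
  out
}

#' Realize the epoch trajectory implied by one parameter draw
#'
#' @param spec a [build_scenario()] spec.
#' @param par named vector (or 1-row matrix) of parameter values.
#' @return An [epoch_trajectory()].
#' @export
realize_trajectory <- function(spec, par) {
  stopifnot(inherits(spec, "scenario_spec"))
  par <- drop(rbind(par))
  if (is.null(names(par)) || !all(spec$params %in% names(par)))
    names(par) <- spec$params
  epoch_trajectory(spec$breaks, unname(par[spec$epoch_param]))
}
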