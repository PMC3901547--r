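#' Simulate an ABC reference table
#'
#' For each candidate model (a [build_scenario()] spec, or any named list of
#' specs — e.g. the same scenario under different generation clocks), draws
#' parameters from the constrained prior, simulates a full temporal dataset
#' of the spec's design, and records its summary-statistic vector.  Loci are
#' independent; per-locus mutation rates are redrawn for every simulated
#' dataset.  Deterministic under a fixed RNG seed.
#'
#' @param specs a single `scenario_spec` or a named list of them.
#' @param n_per_model number of simulations per model (>= 100 is sensible;
#'   scaled-down tables are legitimate for method checks).
#' @param model a [mutation_model()].
#' @param progress print a note every `progress` simulations (0 = quiet).
#' @return An object of class `ref_table`: `model` (factor), `stats`
#'   (matrix), `params` (data.frame over the union of parameter names, `NA`
#'   where a model lacks a parameter), `specs`, `mutation`, `n_per_model`.
#' @export
simulate_reference_table <- function(specs, n_per_model,
                                     model = mutation_model(),
                                     progress = 0) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- paste0("scenario_",
                           vapply(specs, `[[`, integer(1), "scenario_id"))
  stopifnot(n_per_model >= 1, inherits(model, "mutation_model"))
  all_params <- unique(unlist(lapply(specs, `[[`, "params")))
  n_tot <- n_per_model * length(specs)
  S <- length(specs[[1]]$design$dates)
  stats <- matrix(NA_real_, n_tot, 4 * S + 4 * (S - 1),
                  dimnames = list(NULL, stat_names(S)))
  params <- matrix(NA_real_, n_tot, length(all_params),
                   dimnames = list(NULL, all_params))
  labels <- rep(names(specs), each = n_per_model)
  row <- 0
  for (m in names(specs)) {
    spec <- specs[[m]]
    design <- spec$design
    times <- calendar_to_generations(design$dates, spec$clock)
    par <- draw_scenario_params(spec, n_per_model)
    for (i in seq_len(n_per_model)) {
      row <- row + 1
      traj <- realize_trajectory(spec, par[i, ])
      mu <- draw_locus_rates(model, design$n_loci)
      geno <- cpp_sim_dataset(design$sizes, times, traj$breaks, traj$sizes,
                              mu, model$p_gsm, model$n_states,
                              model$root_state)
      stats[row, ] <- cpp_stat_vector(geno, design$sizes, design$n_loci)
      params[row, spec$params] <- par[i, ]
      if (progress > 0 && row %% progress == 0)
        message("simulated ", row, "/", n_tot)
    }
  }
  structure(list(model = factor(labels, levels = names(specs)),
                 stats = stats, params = as.data.frame(params),
                 specs = specs, mutation = model,
                 n_per_model = n_per_model),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat(sprintf("<ref_table> %d rows (%d models x %d), %d statistics\n",
              nrow(x$stats), nlevels(x$model), x$n_per_model,
              ncol(x$stats)))
  invisible(x)
}

#' Retain the simulations nearest to the observed data
#'
#' Each statistic column is normalized by its robust SD (1.4826 x MAD,
#' computed over the whole table); columns with zero robust spread are
#' excluded from the distance with a warning.  Euclidean distance to the
#' observed vector is computed on the normalized scale and the
#' `ceiling(fraction * n)` nearest rows are kept, ties broken by row index.
#'
#' @param table a [simulate_reference_table()] result.
#' @param observed named statistic vector from [stat_vector()]; all finite.
#' @param fraction tolerance fraction in `(0, 1]` (default 0.01, the "top
#'   1%" rule).
#' @param use_stats optional character vector restricting which statistic
#'   columns enter the distance (used by the sensitivity analysis).
#' @param use_rows optional logical/integer subset of table rows.
#' @param robust use MAD-based scaling (default) or plain SD.
#' @return An object of class `retained_set`: row `index` into the table,
#'   sorted `distance`, `model`, `params`, `stats_centered` (normalized,
#'   observed at the origin), `scale`, `excluded_cols`.
#' @export
retain_nearest <- function(table, observed, fraction = 0.01,
                           use_stats = NULL, use_rows = NULL,
                           robust = TRUE) {
  stopifnot(inherits(table, "ref_table"), fraction > 0, fraction <= 1)
  cols <- colnames(table$stats)
  if (!is.null(use_stats)) cols <- intersect(cols, use_stats)
  if (!length(cols)) stop("no statistic columns selected")
  obs <- observed[cols]
  if (any(!is.finite(obs))) stop("observed statistics must all be finite")
  rows <- seq_len(nrow(table$stats))
  if (!is.null(use_rows)) rows <- rows[use_rows]
  X <- table$stats[rows, cols, drop = FALSE]
  sc <- apply(table$stats[, cols, drop = FALSE], 2, function(x) {
    if (robust) mad(x, na.rm = TRUE) else sd_(x)
  })
  bad <- !is.finite(sc) | sc == 0
  if (any(bad)) {
    warning("excluding zero-spread statistic column(s): ",
            paste(cols[bad], collapse = ", "))
    cols <- cols[!bad]; X <- X[, cols, drop = FALSE]
    obs <- obs[cols]; sc <- sc[!bad]
  }
  Z <- sweep(sweep(X, 2, obs, "-"), 2, sc, "/")
  d <- sqrt(rowSums(Z^2))
  m <- ceiling(fraction * length(rows))
  ord <- order(d, seq_along(d))[seq_len(m)]
  structure(list(index = rows[ord], distance = d[ord],
                 model = table$model[rows[ord]],
                 params = table$params[rows[ord], , drop = FALSE],
                 stats_centered = Z[ord, , drop = FALSE],
                 scale = sc, excluded_cols = if (any(bad)) cols[bad]
                 else character(0)),
            class = "retained_set")
}

sd_ <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

#' Posterior probabilities of the candidate models
#'
#' Fits a weighted multinomial logistic regression of model label on the
#' retained summary statistics, centered at the observed vector, and
#' evaluates it at the observed point; weights are Epanechnikov in the
#' retained distances.  By default the statistics are first projected onto
#' their linear discriminant axes (at most `n_models - 1` of them), the
#' standard preprocessing for this regression: it concentrates the
#' between-model signal and stabilizes the fit when many statistics are
#' noisy or collinear.  The direct-count (rejection) estimator - the
#' retained-set model proportions - is always reported alongside, and is
#' the fallback if the regression fails.
#'
#' @param retained a [retain_nearest()] result.
#' @param lda project the statistics onto linear discriminant axes before
#'   the regression (default `TRUE`); set `FALSE` to regress on the raw
#'   normalized statistics.
#' @return List with `logistic` and `rejection` named probability vectors
#'   (each summing to 1), `n_retained`, and `method` actually used.
#' @export
scenario_posteriors <- function(retained, lda = TRUE) {
  stopifnot(inherits(retained, "retained_set"))
  lev <- levels(retained$model)
  counts <- table(retained$model)
  rejection <- as.numeric(counts) / sum(counts)
  names(rejection) <- lev
  present <- lev[counts > 0]
  if (length(present) < 2) {
    logistic <- rejection
    method <- "counts (single model retained)"
  } else {
    dmax <- max(retained$distance)
    w <- 1 - (retained$distance / (dmax * (1 + 1e-9)))^2
    X <- retained$stats_centered
    x0 <- matrix(0, 1, ncol(X), dimnames = list(NULL, colnames(X)))
    method <- "logistic"
    if (lda) {
      proj <- tryCatch(suppressWarnings(
        MASS::lda(X, grouping = droplevels(retained$model))),
        error = function(e) NULL)
      if (!is.null(proj)) {
        x0 <- predict(proj, x0)$x
        X <- predict(proj, X)$x
        method <- "logistic on discriminant axes"
      }
    }
    dat <- data.frame(y = droplevels(retained$model), X, check.names = FALSE)
    fit <- tryCatch(
      nnet::multinom(y ~ ., data = dat, weights = w, trace = FALSE,
                     maxit = 1000, MaxNWts = 20000),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("multinomial regression failed; falling back to counts")
      logistic <- rejection
      method <- "counts (regression failure)"
    } else {
      new0 <- as.data.frame(as.list(setNames(as.numeric(x0),
                                             colnames(X))),
                            check.names = FALSE)
      pr <- predict(fit, newdata = new0, type = "probs")
      if (length(present) == 2) pr <- c(1 - pr, pr)
      logistic <- setNames(rep(0, length(lev)), lev)
      logistic[present] <- as.numeric(pr)
    }
  }
  list(logistic = logistic, rejection = rejection,
       n_retained = sum(counts), method = method)
}

#' Posterior summary for one parameter
#'
#' Point estimate is the median of the retained draws.  The primary 95%
#' interval is the 2.5%-97.5% quantile range; the alternative
#' density-threshold interval drops values where a kernel density estimate
#' falls below 5% of its maximum (the "excluding values below 5% frequency"
#' reading) and both are reported side by side.
#'
#' @param values retained draws of the parameter (>= 50 required).
#' @param level credibility level (default 0.95).
#' @param min_draws minimum number of draws.
#' @return List `median`, `ci_quantile`, `ci_density`, `n`.
#' @export
parameter_posterior <- function(values, level = 0.95, min_draws = 50) {
  values <- values[is.finite(values)]
  if (length(values) < min_draws)
    stop("too few retained draws (", length(values), " < ", min_draws, ")")
  alpha <- (1 - level) / 2
  med <- median(values)
  ci_q <- unname(quantile(values, c(alpha, 1 - alpha)))
  if (diff(range(values)) == 0) {
    ci_d <- range(values)
  } else {
    dens <- density(values)
    keep <- approx(dens$x, dens$y, xout = values)$y >= 0.05 * max(dens$y)
    keep[is.na(keep)] <- FALSE
    ci_d <- if (any(keep)) range(values[keep]) else range(values)
  }
  list(median = med, ci_quantile = ci_q, ci_density = ci_d,
       n = length(values))
}

#' Parameter posteriors for a chosen model
#'
#' Retains the `fraction` of the chosen model's own simulations nearest to
#' the observed vector and summarizes each of its parameters with
#' [parameter_posterior()].  Optionally applies the local-linear
#' (Beaumont-style) regression adjustment on log10(Ne) with Epanechnikov
#' weights before summarizing.
#'
#' @param table a [simulate_reference_table()] result.
#' @param observed observed statistic vector.
#' @param model_name which model's rows to use (default: the first level).
#' @param fraction retention fraction within the model's rows.
#' @param adjust apply the local-linear regression adjustment.
#' @param use_stats optional statistic subset (see [retain_nearest()]).
#' @return Named list of [parameter_posterior()] summaries, with attributes
#'   `model` and `adjusted`.
#' @export
parameter_posteriors <- function(table, observed,
                                 model_name = levels(table$model)[1],
                                 fraction = 0.01, adjust = FALSE,
                                 use_stats = NULL) {
  stopifnot(inherits(table, "ref_table"),
            model_name %in% levels(table$model))
  ret <- retain_nearest(table, observed, fraction = fraction,
                        use_stats = use_stats,
                        use_rows = table$model == model_name)
  pars <- table$specs[[model_name]]$params
  draws <- ret$params[, pars, drop = FALSE]
  if (adjust) {
    dmax <- max(ret$distance)
    w <- 1 - (ret$distance / (dmax * (1 + 1e-9)))^2
    X <- ret$stats_centered
    for (p in pars) {
      y <- log10(draws[[p]])
      fit <- tryCatch(lm(y ~ X, weights = w), error = function(e) NULL)
      if (!is.null(fit))
        draws[[p]] <- 10^(unname(coef(fit)[1]) + stats::residuals(fit))
    }
  }
  out <- lapply(pars, function(p) parameter_posterior(draws[[p]]))
  names(out) <- pars
  attr(out, "model") <- model_name
  attr(out, "adjusted") <- adjust
  out
}

#' Summary-statistic sensitivity analysis
#'
#' Re-runs retention and model choice with each summary-statistic category
#' removed in turn (the four one-sample and four pairwise categories),
#' restricted to a pair (or any subset) of competing models; the full-set
#' baseline is included as the first row.
#'
#' @param table a [simulate_reference_table()] result.
#' @param observed observed statistic vector.
#' @param models character vector of model names to compare (default: all).
#' @param fraction retention fraction.
#' @return Data frame: one row per removed category (plus baseline), one
#'   posterior-probability column per model (logistic estimator), plus the
#'   rejection estimator columns suffixed `.rej`.
#' @export
sensitivity_drop_stats <- function(table, observed, models = NULL,
                                   fraction = 0.01) {
  stopifnot(inherits(table, "ref_table"))
  if (is.null(models)) models <- levels(table$model)
  stopifnot(all(models %in% levels(table$model)), length(models) >= 2)
  all_names <- colnames(table$stats)
  cats <- unique(stat_categories(all_names))
  rows_use <- table$model %in% models
  run1 <- function(drop_cat) {
    keep <- if (is.na(drop_cat)) all_names
    else all_names[stat_categories(all_names) != drop_cat]
    if (!length(keep)) stop("cannot remove every statistic category")
    ret <- retain_nearest(table, observed, fraction = fraction,
                          use_stats = keep, use_rows = rows_use)
    ret$model <- droplevels(factor(ret$model, levels = models))
    sp <- scenario_posteriors(ret)
    c(sp$logistic[models], setNames(sp$rejection[models],
                                    paste0(models, ".rej")))
  }
  res <- t(vapply(c(NA, cats), run1,
                  numeric(2 * length(models))))
  data.frame(removed = c("none", cats), res, check.names = FALSE,
             row.names = NULL)
}

#' Compare generation clocks as competing models
#'
#' Replicates one demographic scenario under each candidate clock
#' (generations/year) and treats each clock as a competing model in the
#' scenario-choice machinery.
#'
#' @param observed observed statistic vector.
#' @param scenario_id scenario to hold fixed across clocks.
#' @param design a [sampling_design()].
#' @param clocks numeric vector of generations/year values (default the
#'   candidate set 12, 15, 18, 20, 24).
#' @param n_per_clock simulations per clock.
#' @param fraction retention fraction.
#' @param ... passed to [build_scenario()] / [simulate_reference_table()].
#' @return List as from [scenario_posteriors()], with models named
#'   `gpy_<clock>`, plus the reference `table`.
#' @export
compare_generation_clocks <- function(observed, scenario_id = 2,
                                      design = default_design(),
                                      clocks = c(12, 15, 18, 20, 24),
                                      n_per_clock = 1000, fraction = 0.01,
                                      ...) {
  stopifnot(length(clocks) >= 1, all(clocks > 0))
  specs <- lapply(clocks, function(g)
    build_scenario(scenario_id, design,
                   clock = generation_clock(g, max(design$dates)), ...))
  names(specs) <- paste0("gpy_", clocks)
  tab <- simulate_reference_table(specs, n_per_clock)
  if (length(clocks) == 1) {
    post <- list(logistic = setNames(1, names(specs)),
                 rejection = setNames(1, names(specs)),
                 n_retained = NA_integer_, method = "single model")
  } else {
    post <- scenario_posteriors(retain_nearest(tab, observed,
                                               fraction = fraction))
  }
  c(post, list(table = tab))
}
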