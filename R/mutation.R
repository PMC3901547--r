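#' Generalized stepwise microsatellite mutation model
#'
#' Mutations arrive on branches as a Poisson process and change the repeat
#' number by +/- k, where `k - 1` is geometric with parameter `p_gsm`
#' (`p_gsm = 0` recovers the strict single-step SMM; larger values add the
#' multi-step, infinite-allele-like component of the generalized model).
#' Allele states live on `n_states` contiguous repeat classes with
#' reflecting boundaries; genealogies are rooted at the range midpoint.
#'
#' Per-locus rates are drawn from a Gamma distribution whose *median* is
#' `mu_median` (the shape controls between-locus rate dispersion;
#' `rate_shape = Inf` fixes all loci to `mu_median` exactly).
#'
#' @param mu_median median mutation rate per locus per generation
#'   (default `6.34e-4`).
#' @param rate_shape Gamma shape of the between-locus rate distribution
#'   (default 1; `Inf` = no dispersion).
#' @param p_gsm geometric parameter of the step-size distribution in
#'   `[0, 1)`; default 0.35.
#' @param n_states number of contiguous allele states (default 40).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu_median = 6.34e-4, rate_shape = 1,
                           p_gsm = 0.35, n_states = 40) {
  stopifnot(mu_median >= 0, rate_shape > 0, p_gsm >= 0, p_gsm < 1,
            n_states >= 2)
  structure(list(mu_median = mu_median, rate_shape = rate_shape,
                 p_gsm = p_gsm, n_states = as.integer(n_states),
                 root_state = as.integer(ceiling(n_states / 2))),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf(paste0("<mutation_model> median rate %.3g/locus/generation ",
                     "(Gamma shape %s), GSM P = %.2f, %d allele states\n"),
              x$mu_median, format(x$rate_shape), x$p_gsm, x$n_states))
  invisible(x)
}

#' Draw per-locus mutation rates
#'
#' @param model a [mutation_model()].
#' @param n_loci number of rates to draw.
#' @return Numeric vector of rates with median `mu_median` (exactly
#'   `mu_median` when `rate_shape = Inf`).
#' @export
draw_locus_rates <- function(model, n_loci) {
  stopifnot(inherits(model, "mutation_model"), n_loci >= 1)
  if (is.infinite(model$rate_shape)) return(rep(model$mu_median, n_loci))
  scale <- model$mu_median / qgamma(0.5, shape = model$rate_shape)
  rgamma(n_loci, shape = model$rate_shape, scale = scale)
}
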