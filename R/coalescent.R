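#' Simulate a genealogy of heterochronously sampled gene copies
#'
#' Backwards-in-time coalescent under a piecewise-constant diploid Ne.
#' Lineages enter the active set at their sampling times; within an epoch of
#' size `N`, the waiting time to the next coalescence among `k` lineages is
#' exponential with rate `k(k-1)/(4N)` per generation; epoch boundaries and
#' lineage-entry events truncate waits (valid by the memorylessness of the
#' exponential).  The run ends when a single lineage remains, so exactly
#' `n - 1` coalescences occur.
#'
#' @param trajectory an [epoch_trajectory()] (final epoch unbounded).
#' @param tip_times sampling times of the gene copies in generations before
#'   reference (e.g. from [calendar_to_generations()]); length >= 2.
#' @return An object of class `genealogy`: `parent` (1-based parent index,
#'   0 for the root), `time` (node times, tips first in input order),
#'   `n_tips`.
#' @export
simulate_genealogy <- function(trajectory, tip_times) {
  stopifnot(inherits(trajectory, "epoch_trajectory"),
            length(tip_times) >= 2, all(is.finite(tip_times)),
            all(tip_times >= 0))
  g <- cpp_sim_genealogy(as.numeric(tip_times), trajectory$breaks,
                         trajectory$sizes)
  structure(g, class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA %.2f generations before reference\n",
              x$n_tips, tmrca(x)))
  invisible(x)
}

#' Time to the most recent common ancestor
#' @param genealogy a [simulate_genealogy()] result.
#' @return Root node time in generations before reference.
#' @export
tmrca <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  genealogy$time[length(genealogy$time)]
}

#' Total branch length of a genealogy
#' @param genealogy a [simulate_genealogy()] result.
#' @return Sum of all branch lengths in generations.
#' @export
tree_length <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  has_parent <- genealogy$parent > 0
  sum(genealogy$time[genealogy$parent[has_parent]] -
        genealogy$time[has_parent])
}

#' Drop microsatellite mutations on a genealogy
#'
#' The mutation count on each branch is Poisson(`mu` x branch length); each
#' mutation steps the allele by +/- k with `k - 1` geometric (`p_gsm`;
#' `p_gsm = 0` gives the strict stepwise model).  Steps that would leave the
#' allowed state range are reflected.  The root allele starts at the range
#' midpoint.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param model a [mutation_model()].
#' @param mu per-generation mutation rate for this locus; defaults to the
#'   model's median rate.
#' @return Integer vector of tip allele states in repeat units.
#' @export
apply_mutations <- function(genealogy, model = mutation_model(),
                            mu = model$mu_median) {
  stopifnot(inherits(genealogy, "genealogy"),
            inherits(model, "mutation_model"), mu >= 0)
  cpp_drop_mutations(genealogy$parent, genealogy$time, genealogy$n_tips,
                     mu, model$p_gsm, model$n_states, model$root_state)
}

#' Simulate a temporal microsatellite dataset
#'
#' One independent genealogy per locus, two gene copies per individual
#' entering at the individual's sampling time; per-locus mutation rates are
#' drawn from the model's rate distribution unless supplied.  Deterministic
#' under a fixed RNG seed.
#'
#' @param trajectory an [epoch_trajectory()].
#' @param design a [sampling_design()].
#' @param clock a [generation_clock()]; defaults to 18 generations/year
#'   referenced at the design's last sampling date.
#' @param model a [mutation_model()].
#' @param mu_locus optional fixed per-locus rates (length `design$n_loci`).
#' @return A [temporal_dataset()] with groups dated from the design.
#' @export
simulate_dataset <- function(trajectory, design,
                             clock = generation_clock(18, max(design$dates)),
                             model = mutation_model(), mu_locus = NULL) {
  stopifnot(inherits(trajectory, "epoch_trajectory"),
            inherits(design, "sampling_design"),
            inherits(clock, "generation_clock"),
            inherits(model, "mutation_model"))
  if (is.null(mu_locus)) mu_locus <- draw_locus_rates(model, design$n_loci)
  stopifnot(length(mu_locus) == design$n_loci, all(mu_locus >= 0))
  times <- calendar_to_generations(design$dates, clock)
  geno <- cpp_sim_dataset(design$sizes, times, trajectory$breaks,
                          trajectory$sizes, mu_locus, model$p_gsm,
                          model$n_states, model$root_state)
  split_at <- rep(seq_along(design$sizes), design$sizes)
  groups <- lapply(seq_along(design$sizes), function(g) {
    list(label = paste0("sample_", format(design$dates[g])),
         date = design$dates[g],
         geno = geno[split_at == g, , drop = FALSE])
  })
  temporal_dataset(groups, loci = paste0("locus_", seq_len(design$n_loci)))
}
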