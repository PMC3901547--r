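#' Piecewise-constant effective-size trajectory
#'
#' An epoch trajectory gives the diploid effective size Ne as a step
#' function of time measured in generations before the clock reference.
#' `breaks` are the epoch change points; epoch `i` covers
#' `[breaks[i-1], breaks[i])` (with an implicit lower bound of 0) and the
#' final epoch is unbounded into the past, so coalescence always completes.
#'
#' @param breaks strictly monotone change points in generations before
#'   reference (accepted in either order; stored increasing).  May be empty
#'   for a constant trajectory.
#' @param sizes diploid Ne per epoch, most recent first; one more entry than
#'   `breaks`; all `>= 2`.
#' @return An object of class `epoch_trajectory`.
#' @examples
#' epoch_trajectory(c(7.6, 16.3), c(4204, 1000, 5692))
#' @export
epoch_trajectory <- function(breaks, sizes) {
  breaks <- as.numeric(breaks)
  if (length(breaks) && is.unsorted(breaks)) breaks <- rev(breaks)
  stopifnot(length(sizes) == length(breaks) + 1L,
            all(is.finite(sizes)), all(sizes >= 2),
            all(breaks > 0), !is.unsorted(breaks, strictly = TRUE))
  structure(list(breaks = breaks, sizes = as.numeric(sizes)),
            class = "epoch_trajectory")
}

#' @export
print.epoch_trajectory <- function(x, ...) {
  lo <- c(0, x$breaks); hi <- c(x$breaks, Inf)
  cat("<epoch_trajectory> generations before reference -> Ne\n")
  for (i in seq_along(x$sizes))
    cat(sprintf("  [%6.2f, %6.2f): %s\n", lo[i], hi[i],
                format(x$sizes[i], big.mark = ",")))
  invisible(x)
}

#' Evaluate a trajectory at given times
#'
#' @param trajectory an [epoch_trajectory()].
#' @param t non-negative times in generations before reference.
#' @return Ne at each time.
#' @export
trajectory_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "epoch_trajectory"), all(t >= 0))
  idx <- findInterval(t, trajectory$breaks) + 1L
  trajectory$sizes[idx]
}
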