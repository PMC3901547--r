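#' Temporal microsatellite genotype dataset
#'
#' Diploid allele-size genotypes (repeat units) for `L` loci in `S` dated
#' sample groups.  Each group holds an `n x 2L` integer matrix: columns
#' `2l - 1` and `2l` are the two allele copies at locus `l`; `NA` marks a
#' missing allele.
#'
#' @param groups list of groups, each a list with elements `label`
#'   (character), `date` (`Date` or `NA`), and `geno` (integer matrix).
#' @param loci character vector of locus names.
#' @return An object of class `temporal_dataset`.
#' @export
temporal_dataset <- function(groups, loci) {
  stopifnot(length(groups) >= 1, length(loci) >= 1)
  for (g in groups) {
    stopifnot(is.matrix(g$geno), ncol(g$geno) == 2L * length(loci),
              nrow(g$geno) >= 1)
    if (any(g$geno <= 0, na.rm = TRUE))
      stop("allele sizes must be positive integers")
  }
  dates <- as.Date(vapply(groups, function(g) {
    if (is.null(g$date) || all(is.na(g$date))) NA_character_
    else as.character(as.Date(g$date))
  }, character(1)))
  if (!any(is.na(dates)) && is.unsorted(dates))
    stop("group dates must be non-decreasing")
  structure(list(groups = groups, loci = as.character(loci)),
            class = "temporal_dataset")
}

#' @export
print.temporal_dataset <- function(x, ...) {
  cat(sprintf("<temporal_dataset> %d groups, %d loci, %d individuals\n",
              length(x$groups), length(x$loci), sum(group_sizes(x))))
  for (g in x$groups)
    cat(sprintf("  %s (%s): n = %d\n", g$label,
                if (is.na(g$date)) "undated" else format(as.Date(g$date)),
                nrow(g$geno)))
  invisible(x)
}

#' Number of individuals per group
#' @param dataset a [temporal_dataset()].
#' @return Integer vector.
#' @export
group_sizes <- function(dataset) {
  stopifnot(inherits(dataset, "temporal_dataset"))
  vapply(dataset$groups, function(g) nrow(g$geno), integer(1))
}

#' Stack all groups into one genotype matrix
#' @param dataset a [temporal_dataset()].
#' @return Integer matrix with `sum(group_sizes)` rows and `2 * n_loci`
#'   columns, groups stacked in order.
#' @export
stack_genotypes <- function(dataset) {
  stopifnot(inherits(dataset, "temporal_dataset"))
  do.call(rbind, lapply(dataset$groups, `[[`, "geno"))
}
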