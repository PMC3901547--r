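#' One-sample microsatellite summary statistics
#'
#' Per locus: `A` = number of distinct alleles; `He` = Nei's unbiased
#' expected heterozygosity `c/(c-1) * (1 - sum p_i^2)` over the `c` typed
#' gene copies; `V` = unbiased variance of allele size; `M` =
#' Garza-Williamson index `A / (allele range in repeat units + 1)`.  A locus
#' contributes only where it has at least two typed copies; loci with fewer
#' are dropped with a warning.
#'
#' @param geno integer matrix `n x 2L` of diploid genotypes (`NA` missing).
#' @param per_locus return the per-locus matrix instead of locus means.
#' @return Named vector `c(A, He, V, M)` of locus means, or an `L x 4`
#'   matrix when `per_locus = TRUE`.
#' @examples
#' g <- rbind(c(1L, 1L), c(1L, 2L))
#' one_sample_stats(g)["He"]  # 4/3 * (1 - 0.625) = 0.5
#' @export
one_sample_stats <- function(geno, per_locus = FALSE) {
  stopifnot(is.matrix(geno), ncol(geno) %% 2 == 0, nrow(geno) >= 1)
  L <- ncol(geno) / 2
  out <- matrix(NA_real_, L, 4, dimnames = list(NULL, c("A", "He", "V", "M")))
  for (l in seq_len(L)) {
    x <- c(geno[, 2 * l - 1], geno[, 2 * l])
    x <- x[!is.na(x)]
    cc <- length(x)
    if (cc < 2) next
    tab <- table(x)
    p <- tab / cc
    out[l, "A"] <- length(tab)
    out[l, "He"] <- cc / (cc - 1) * (1 - sum(p^2))
    out[l, "V"] <- stats::var(x)
    out[l, "M"] <- length(tab) / (diff(range(x)) + 1)
  }
  if (per_locus) return(out)
  used <- !is.na(out[, "A"])
  if (!any(used)) stop("no locus with at least two typed gene copies")
  if (!all(used))
    warning(sum(!used), " locus/loci dropped (fewer than 2 typed copies)")
  colMeans(out[used, , drop = FALSE])
}

#' Two-sample summary statistics for a temporal pair
#'
#' `A2`, `He2`, `V2` are the one-sample statistics computed on the pooled
#' pair of groups; `FST` is the Weir-Cockerham estimator (theta) for two
#' populations, combined over loci and alleles as a ratio of sums, using
#' individuals with complete genotypes at the locus.
#'
#' @param geno1,geno2 integer matrices `n x 2L` with the same loci.
#' @return Named vector `c(A2, He2, V2, FST)`.
#' @export
two_sample_stats <- function(geno1, geno2) {
  stopifnot(is.matrix(geno1), is.matrix(geno2), ncol(geno1) == ncol(geno2))
  pooled <- one_sample_stats(rbind(geno1, geno2))
  c(A2 = unname(pooled["A"]), He2 = unname(pooled["He"]),
    V2 = unname(pooled["V"]), FST = wc_fst_pair(geno1, geno2))
}

# Weir-Cockerham theta for two groups, ratio of sums over loci and alleles
wc_fst_pair <- function(geno1, geno2) {
  L <- ncol(geno1) / 2
  num <- den <- 0
  for (l in seq_len(L)) {
    g1 <- geno1[, c(2 * l - 1, 2 * l), drop = FALSE]
    g2 <- geno2[, c(2 * l - 1, 2 * l), drop = FALSE]
    g1 <- g1[complete.cases(g1), , drop = FALSE]
    g2 <- g2[complete.cases(g2), , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    alleles <- sort(unique(c(g1, g2)))
    for (al in alleles) {
      p1 <- mean(g1 == al); p2 <- mean(g2 == al)
      h1 <- mean(xor(g1[, 1] == al, g1[, 2] == al))
      h2 <- mean(xor(g2[, 1] == al, g2[, 2] == al))
      pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
      hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) 0 else num / den
}

#' Names of the temporal summary-statistic vector
#' @param n_groups number of temporal sample groups.
#' @return Character vector of length `4 * S + 4 * (S - 1)`.
#' @export
stat_names <- function(n_groups) {
  S <- n_groups
  pairs <- paste0(seq_len(S - 1), "_", seq_len(S - 1) + 1)
  c(paste0("A_", seq_len(S)), paste0("He_", seq_len(S)),
    paste0("V_", seq_len(S)), paste0("M_", seq_len(S)),
    paste0("A2_", pairs), paste0("He2_", pairs),
    paste0("V2_", pairs), paste0("FST_", pairs))
}

#' The temporal summary-statistic vector
#'
#' Concatenates, in a fixed named order, the four one-sample statistics per
#' group (each averaged over loci) and the four two-sample statistics for
#' each adjacent-in-time pair of groups: `4S + 4(S-1)` values for `S`
#' groups (44 for the six-sample study design).  `engine = "cpp"` (default)
#' and `engine = "r"` are independent code paths that agree to numerical
#' precision; the C++ path is the one the ABC reference-table simulator
#' uses.
#'
#' @param dataset a [temporal_dataset()].
#' @param engine `"cpp"` or `"r"`.
#' @return Named numeric vector.
#' @export
stat_vector <- function(dataset, engine = c("cpp", "r")) {
  stopifnot(inherits(dataset, "temporal_dataset"))
  engine <- match.arg(engine)
  S <- length(dataset$groups)
  nm <- stat_names(S)
  if (engine == "cpp") {
    v <- cpp_stat_vector(stack_genotypes(dataset), group_sizes(dataset),
                         length(dataset$loci))
    return(setNames(v, nm))
  }
  ones <- vapply(dataset$groups,
                 function(g) suppressWarnings(one_sample_stats(g$geno)),
                 numeric(4))
  twos <- vapply(seq_len(S - 1), function(p) {
    suppressWarnings(two_sample_stats(dataset$groups[[p]]$geno,
                                      dataset$groups[[p + 1]]$geno))
  }, numeric(4))
  setNames(c(ones["A", ], ones["He", ], ones["V", ], ones["M", ],
             twos["A2", ], twos["He2", ], twos["V2", ], twos["FST", ]), nm)
}

#' Category of each summary statistic
#'
#' Maps statistic names to the eight removable categories used by the
#' sensitivity analysis: `A`, `He`, `V`, `M` (one-sample) and `A2`, `He2`,
#' `V2`, `FST` (pairwise).
#'
#' @param names statistic names as produced by [stat_names()].
#' @return Character vector of category labels.
#' @export
stat_categories <- function(names) sub("_.*$", "", names)
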