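# Independent brute-force implementations used as oracles.  Deliberately
# written with different code structure (explicit loops, no shared helpers)
# than the package paths they check.

# one-sample stats for a single locus from raw allele copies
oracle_locus_one <- function(copies) {
  copies <- copies[!is.na(copies)]
  cc <- length(copies)
  if (cc < 2) return(NULL)
  freq <- numeric(0)
  for (a in sort(unique(copies))) freq <- c(freq, sum(copies == a) / cc)
  A <- length(freq)
  He <- (cc / (cc - 1)) * (1 - sum(freq * freq))
  mu <- sum(copies) / cc
  V <- sum((copies - mu)^2) / (cc - 1)
  M <- A / (max(copies) - min(copies) + 1)
  c(A = A, He = He, V = V, M = M)
}

oracle_one_sample <- function(geno) {
  L <- ncol(geno) / 2
  acc <- NULL
  for (l in seq_len(L)) {
    st <- oracle_locus_one(c(geno[, 2 * l - 1], geno[, 2 * l]))
    if (!is.null(st)) acc <- rbind(acc, st)
  }
  colMeans(acc)
}

# Weir-Cockerham theta for two groups at one locus, summed components
oracle_wc_locus <- function(g1, g2) {
  keep1 <- !is.na(g1[, 1]) & !is.na(g1[, 2])
  keep2 <- !is.na(g2[, 1]) & !is.na(g2[, 2])
  g1 <- g1[keep1, , drop = FALSE]; g2 <- g2[keep2, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) return(c(0, 0))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (al in sort(unique(c(g1, g2)))) {
    p1 <- sum(g1 == al) / (2 * n1)
    p2 <- sum(g2 == al) / (2 * n2)
    h1 <- sum((g1[, 1] == al) != (g1[, 2] == al)) / n1
    h2 <- sum((g2[, 1] == al) != (g2[, 2] == al)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  c(num, den)
}

oracle_stat_vector <- function(ds) {
  S <- length(ds$groups)
  A <- He <- V <- M <- numeric(S)
  for (g in seq_len(S)) {
    st <- oracle_one_sample(ds$groups[[g]]$geno)
    A[g] <- st["A"]; He[g] <- st["He"]; V[g] <- st["V"]; M[g] <- st["M"]
  }
  A2 <- He2 <- V2 <- FST <- numeric(S - 1)
  for (p in seq_len(S - 1)) {
    pooled <- oracle_one_sample(rbind(ds$groups[[p]]$geno,
                                      ds$groups[[p + 1]]$geno))
    A2[p] <- pooled["A"]; He2[p] <- pooled["He"]; V2[p] <- pooled["V"]
    num <- den <- 0
    L <- length(ds$loci)
    for (l in seq_len(L)) {
      nd <- oracle_wc_locus(ds$groups[[p]]$geno[, c(2 * l - 1, 2 * l), drop = FALSE],
                            ds$groups[[p + 1]]$geno[, c(2 * l - 1, 2 * l), drop = FALSE])
      num <- num + nd[1]; den <- den + nd[2]
    }
    FST[p] <- if (den == 0) 0 else num / den
  }
  stats::setNames(c(A, He, V, M, A2, He2, V2, FST), stat_names(S))
}

# random small dataset with occasional missing genotypes
random_small_dataset <- function(n_groups = NULL) {
  if (is.null(n_groups)) n_groups <- sample(2:4, 1)
  L <- sample(1:4, 1)
  groups <- lapply(seq_len(n_groups), function(g) {
    n <- sample(3:10, 1)
    geno <- matrix(sample(1:12, n * 2 * L, replace = TRUE), n, 2 * L)
    # knock out some whole genotypes
    drop <- matrix(stats::runif(n * L) < 0.1, n, L)
    for (l in seq_len(L)) {
      geno[drop[, l], 2 * l - 1] <- NA_integer_
      geno[drop[, l], 2 * l] <- NA_integer_
    }
    # guarantee at least 2 typed copies per locus per group
    for (l in seq_len(L)) {
      if (sum(!is.na(geno[, 2 * l - 1])) < 2) {
        geno[1:2, 2 * l - 1] <- sample(1:12, 2, replace = TRUE)
        geno[1:2, 2 * l] <- sample(1:12, 2, replace = TRUE)
      }
    }
    list(label = paste0("g", g), date = as.Date("2009-01-01") + 30 * g,
         geno = geno)
  })
  temporal_dataset(groups, loci = paste0("L", seq_len(L)))
}
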