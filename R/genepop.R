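#' Write a temporal dataset to GenePop format
#'
#' One `POP` block per temporal sample group, in chronological order; allele
#' states written with 3-digit (default) or 2-digit coding; missing alleles
#' coded as zeros.  Allele states are written as repeat units directly.
#'
#' @param dataset a [temporal_dataset()].
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @param digits 2 or 3 digit allele coding.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path,
                          title = "irsabc temporal microsatellite dataset",
                          digits = 3) {
  stopifnot(inherits(dataset, "temporal_dataset"), digits %in% c(2, 3))
  mx <- suppressWarnings(max(stack_genotypes(dataset), na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele state ", mx, " does not fit ", digits, "-digit coding")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$loci, con)
  fmt <- paste0("%0", digits, "d")
  for (g in dataset$groups) {
    writeLines("POP", con)
    geno <- g$geno
    for (i in seq_len(nrow(geno))) {
      a <- geno[i, ]
      a[is.na(a)] <- 0L
      gt <- paste0(sprintf(fmt, a[c(TRUE, FALSE)]),
                   sprintf(fmt, a[c(FALSE, TRUE)]))
      writeLines(paste0(g$label, "_", i, " ,  ", paste(gt, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a GenePop file
#'
#' Accepts 2- or 3-digit allele coding (detected from genotype width);
#' `POP` blocks map to temporal groups in file order; zero-coded alleles
#' become `NA`; locus names are retained (one per line, or comma-separated
#' on a single line).  Malformed lines are reported with their line number.
#'
#' @param path GenePop file.
#' @param dates optional vector of collection `Date`s, one per POP block.
#' @return A [temporal_dataset()].
#' @export
read_genepop <- function(path, dates = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("not a GenePop file: fewer than 3 lines")
  lines_trim <- trimws(lines)
  is_pop <- toupper(lines_trim) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP block found in ", path)
  if (first_pop < 3) stop("no locus names before first POP (line ",
                          first_pop, ")")
  loci_lines <- lines_trim[2:(first_pop - 1)]
  loci <- unlist(strsplit(loci_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L < 1) stop("no locus names parsed")

  groups <- list()
  cur <- NULL
  cur_rows <- list()
  flush_group <- function() {
    if (is.null(cur)) return()
    if (!length(cur_rows))
      stop("empty POP block ending before line ", cur)
    geno <- do.call(rbind, cur_rows)
    groups[[length(groups) + 1]] <<- list(
      label = paste0("pop", length(groups) + 1), date = NA, geno = geno)
  }
  for (i in seq(first_pop, length(lines))) {
    ln <- lines_trim[i]
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") {
      flush_group()
      cur <- i
      cur_rows <- list()
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i, ": expected '<id> , <genotypes>'")
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != L)
      stop("line ", i, ": ", length(gts), " genotypes for ", L, " loci")
    w <- unique(nchar(gts))
    if (length(w) != 1 || !w %in% c(4, 6))
      stop("line ", i, ": genotype fields must be 4 or 6 digits wide")
    d <- w / 2
    a1 <- suppressWarnings(as.integer(substr(gts, 1, d)))
    a2 <- suppressWarnings(as.integer(substr(gts, d + 1, w)))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop("line ", i, ": non-numeric allele code")
    a1[a1 == 0] <- NA_integer_
    a2[a2 == 0] <- NA_integer_
    row <- integer(2 * L)
    row[c(TRUE, FALSE)] <- a1
    row[c(FALSE, TRUE)] <- a2
    cur_rows[[length(cur_rows) + 1]] <- row
  }
  flush_group()
  if (!length(groups)) stop("no individuals parsed from ", path)
  if (!is.null(dates)) {
    stopifnot(length(dates) == length(groups))
    for (g in seq_along(groups)) groups[[g]]$date <- as.Date(dates[g])
  }
  temporal_dataset(groups, loci)
}

#' Exclude individuals with too many failed loci
#'
#' Applies the study's missingness rule: an individual missing genotypes at
#' `max_failed_loci` or more loci is excluded.  Groups emptied by the
#' filter are dropped with a warning.
#'
#' @param dataset a [temporal_dataset()].
#' @param max_failed_loci exclusion threshold (default 2: missing two or
#'   more loci removes the individual; missing one is tolerated).
#' @return The filtered dataset, with attribute `report`: a data frame of
#'   per-group kept/removed counts.
#' @export
filter_missingness <- function(dataset, max_failed_loci = 2) {
  stopifnot(inherits(dataset, "temporal_dataset"), max_failed_loci >= 1)
  L <- length(dataset$loci)
  report <- data.frame(group = character(0), kept = integer(0),
                       removed = integer(0))
  keep_groups <- list()
  for (g in dataset$groups) {
    odd <- g$geno[, c(TRUE, FALSE), drop = FALSE]
    even <- g$geno[, c(FALSE, TRUE), drop = FALSE]
    failed <- rowSums(is.na(odd) | is.na(even))
    keep <- failed < max_failed_loci
    report <- rbind(report, data.frame(group = g$label,
                                       kept = sum(keep),
                                       removed = sum(!keep)))
    if (!any(keep)) {
      warning("group ", g$label, " emptied by missingness filter; dropped")
      next
    }
    g$geno <- g$geno[keep, , drop = FALSE]
    keep_groups[[length(keep_groups) + 1]] <- g
  }
  if (!length(keep_groups)) stop("all groups emptied by missingness filter")
  out <- temporal_dataset(keep_groups, dataset$loci)
  attr(out, "report") <- report
  out
}
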