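#' Round half away from zero at a fixed number of decimals
#'
#' Percentages are reported with half-up rounding (0.005 -> 0.01), not R's
#' banker's rounding. A relative epsilon guards against binary
#' representation of exact halves (e.g. 2.675 stored as 2.67499...).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

format_rate <- function(n_positive, n) {
  ifelse(n < 5, "ND",
         sprintf("%.2f%%", round_half_up(100 * n_positive / pmax(n, 1), 2)))
}

#' Per-taxon SAC positive rates with the minimum-count rule
#'
#' One row per taxon at the requested rank plus a Total row. The rate is the
#' percentage of strains (or of type strains, when `type_strains_only`) with
#' a positive SAC call, rounded half-up to two decimals; taxa with fewer
#' than `min_count` members get the literal rate `"ND"` (no data) while
#' their counts are still reported.
#'
#' @param calls SacCall table (`genome_id`, `sac_positive`).
#' @param meta Metadata table with taxonomy columns and `is_type_strain`.
#' @param rank One of class, order, family, genus, species.
#' @param type_strains_only Restrict to type strains (the species-level
#'   unit; one type strain represents one species).
#' @param min_count Minimum taxon size for a rate to be computed (default 5).
#' @return data.frame: `taxon`, `rank`, `n_strains`, `n_positive`, `rate`.
#' @export
positive_rates <- function(calls, meta, rank = "order",
                           type_strains_only = FALSE, min_count = 5) {
  if (!rank %in% c("class", "order", "family", "genus", "species")) {
    stop("unknown rank: ", rank)
  }
  df <- merge(calls[, c("genome_id", "sac_positive")], meta, by = "genome_id")
  if (nrow(df) < nrow(calls)) {
    stop("metadata missing for ", nrow(calls) - nrow(df), " genome(s)")
  }
  if (type_strains_only) df <- df[df$is_type_strain, , drop = FALSE]
  n <- tapply(df$sac_positive, df[[rank]], length)
  np <- tapply(df$sac_positive, df[[rank]], sum)
  out <- data.frame(taxon = names(n), rank = rank,
                    n_strains = as.integer(n), n_positive = as.integer(np),
                    stringsAsFactors = FALSE)
  out <- out[order(out$taxon), , drop = FALSE]
  out <- rbind(out, data.frame(taxon = "Total", rank = rank,
                               n_strains = nrow(df),
                               n_positive = sum(df$sac_positive)))
  out$rate <- ifelse(out$n_strains < min_count, "ND",
                     format_rate(out$n_positive, out$n_strains))
  rownames(out) <- NULL
  out
}

#' Presence rate of a single gene role over type-strain species
#'
#' Unlike the cluster verdict, presence counts the role anywhere in the
#' genome (copy number >= 1), clustered or not.
#'
#' @param role Role column name in the copy-number part of `calls`.
#' @param calls SacCall table carrying per-role copy-number columns.
#' @param meta Metadata table.
#' @param type_strains_only Restrict to type strains (default TRUE).
#' @return One-row data.frame: `role`, `n`, `n_present`, `rate`.
#' @export
gene_presence_rates <- function(role, calls, meta, type_strains_only = TRUE) {
  if (!role %in% names(calls)) stop("unknown role: ", role)
  df <- merge(calls[, c("genome_id", role)], meta, by = "genome_id")
  if (type_strains_only) df <- df[df$is_type_strain, , drop = FALSE]
  n <- nrow(df)
  np <- sum(df[[role]] >= 1)
  data.frame(role = role, n = n, n_present = np,
             rate = format_rate(np, n), stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability ("minimum-likelihood") two-sided p: with margins fixed,
#' the p-value is the sum of hypergeometric point probabilities not
#' exceeding the observed table's probability, with a relative tolerance of
#' 1e-7 on the comparison to absorb floating-point noise. Probabilities are
#' computed in log space, so counts up to 1e5 are safe.
#'
#' @param a,b,c,d Cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("cell counts must be non-negative integers")
  }
  m <- a + b       # row 1 total
  n2 <- c + d      # row 2 total
  k <- a + c       # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  logp <- stats::dhyper(x, m, n2, k, log = TRUE)
  obs <- logp[x == a]
  p <- sum(exp(logp[logp <= obs + log1p(1e-7)]))
  min(p, 1)
}

#' Habitat association of SAC across species
#'
#' Builds the 2x2 contingency table of habitat (animal host-associated vs
#' non-animal-associated) against SAC status, reports per-group positive
#' rates, and tests association with the two-sided Fisher exact test.
#' Genomes of unknown habitat are excluded and their count reported.
#'
#' @param calls SacCall table.
#' @param meta Metadata table with `habitat`.
#' @param type_strains_only Restrict to type strains (default TRUE).
#' @return list: `table` (2x2 matrix), `rates` (named, percent,
#'   half-up 2 dp), `p_value`, `n_unknown`.
#' @export
habitat_association <- function(calls, meta, type_strains_only = TRUE) {
  df <- merge(calls[, c("genome_id", "sac_positive")], meta, by = "genome_id")
  if (type_strains_only) df <- df[df$is_type_strain, , drop = FALSE]
  n_unknown <- sum(df$habitat == "unknown")
  df <- df[df$habitat != "unknown", , drop = FALSE]
  tab <- matrix(c(sum(df$habitat == "animal" & df$sac_positive),
                  sum(df$habitat == "animal" & !df$sac_positive),
                  sum(df$habitat == "non_animal" & df$sac_positive),
                  sum(df$habitat == "non_animal" & !df$sac_positive)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("animal", "non_animal"),
                                c("positive", "negative")))
  contingency_result(tab, n_unknown = n_unknown)
}

#' Contingency analysis of a prebuilt 2x2 habitat-by-status table
#'
#' @param tab 2x2 matrix, rows = groups, columns = (positive, negative).
#' @param n_unknown Count of excluded unknown-habitat genomes.
#' @return list as in [habitat_association()].
#' @export
contingency_result <- function(tab, n_unknown = 0L) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  margins_zero <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (margins_zero) {
    warning("a margin of the 2x2 table is zero; p reported as 1")
    1
  } else {
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  rates <- round_half_up(100 * tab[, 1] / pmax(rowSums(tab), 1), 2)
  list(table = tab, rates = rates, p_value = p, n_unknown = n_unknown)
}

#' Fraction of one subset within another, as a rounded percentage
#'
#' @param numerator Logical vector (or count) selecting the numerator.
#' @param denominator Logical vector (or count) selecting the denominator;
#'   the numerator must be contained in it.
#' @return Percent rounded half-up to 2 decimals, or `"ND"` on an empty
#'   denominator.
#' @export
subset_fraction <- function(numerator, denominator) {
  if (is.logical(numerator) && is.logical(denominator)) {
    if (any(numerator & !denominator)) {
      stop("numerator must be a subset of the denominator")
    }
    num <- sum(numerator)
    den <- sum(denominator)
  } else {
    num <- numerator
    den <- denominator
    if (num > den) stop("numerator must be a subset of the denominator")
  }
  if (den == 0) return("ND")
  sprintf("%.2f%%", round_half_up(100 * num / den, 2))
}
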