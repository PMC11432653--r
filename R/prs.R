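# Additive and weighted 8-SNP LDLC polygenic scores, standardization and
# percentile/decile binning.

# counted-allele count for one SNP row of the definition given minor-allele
# dosage (vectorised over individuals)
counted_allele_count <- function(dosage, counted) {
  if (counted == "minor") dosage else 2L - dosage
}

score_components <- function(genotypes, definition, value_col) {
  snps <- definition$snps
  snp_col <- paste0(value_col, "_per_allele")
  miss <- setdiff(c(snps$rsid, "rs429358", "rs7412"), names(genotypes))
  if (length(miss)) stop("genotype table lacks required loci: ",
                         paste(miss, collapse = ", "))
  apoe <- call_apoe_genotype(genotypes[["rs429358"]], genotypes[["rs7412"]])
  apoe_val <- definition$apoe[[value_col]][match(apoe, definition$apoe$genotype)]
  snp_sum <- rep(0, nrow(genotypes))
  for (i in seq_len(nrow(snps))) {
    cnt <- counted_allele_count(genotypes[[snps$rsid[i]]],
                                snps$counted_allele[i])
    snp_sum <- snp_sum + snps[[snp_col]][i] * cnt
  }
  list(total = snp_sum + apoe_val, apoe = apoe)
}

#' Compute the additive polygenic score (aPRS)
#'
#' Sum over the scored SNPs of the counted-allele count, plus the APOE
#' genotype's additive contribution (-2 to +2). Under the default
#' definition the attainable range is \[-2, 14\]. Individuals missing any
#' scored locus receive NA.
#'
#' @param genotypes A genotype table (see [genotype_table()]) containing the
#'   scored SNPs and the two APOE SNPs.
#' @param definition A score definition; default [default_score_definition()].
#' @return Integer vector of additive scores (NA where any locus missing).
#' @export
compute_aprs <- function(genotypes, definition = default_score_definition()) {
  as.integer(round(score_components(genotypes, definition, "aprs")$total))
}

#' Compute the weighted polygenic score (wPRS)
#'
#' Sum over the scored SNPs of weight (mmol/L of LDLC per allele) times the
#' counted-allele count, plus the APOE genotype weight. Under the default
#' definition the attainable range is \[-0.800, 1.482\] mmol/L.
#'
#' @inheritParams compute_aprs
#' @return Numeric vector of weighted scores (NA where any locus missing).
#' @export
compute_wprs <- function(genotypes, definition = default_score_definition()) {
  score_components(genotypes, definition, "weight")$total
}

#' Standardize scores to Z scores
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation, computed
#' over the supplied standardization cohort (by default the full vector).
#'
#' @param x Numeric vector.
#' @param center,scale Optional externally supplied mean and SD (e.g. to
#'   standardize a subgroup against the combined cohort).
#' @return Numeric vector of Z scores with attributes `center` and `scale`.
#' @export
standardize_scores <- function(x, center = NULL, scale = NULL) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing scores to standardize")
  center <- center %||% mean(x[ok])
  scale <- scale %||% stats::sd(x[ok])
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate score distribution: zero standard deviation")
  }
  structure((x - center) / scale, center = center, scale = scale)
}

#' Empirical percentile ranks
#'
#' Percentile rank of each value against the empirical distribution of the
#' whole vector, using the mid-rank convention
#' `(count strictly below + half the ties) / n * 100`, so ranks lie in
#' (0, 100).
#'
#' @param x Numeric vector (NAs propagate).
#' @return Numeric vector of percentile ranks.
#' @export
percentile_rank <- function(x) {
  ok <- !is.na(x)
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- 100 * (r - 0.5) / sum(ok)
  out
}

#' Assign decile bins from percentile ranks
#'
#' `decile = ceiling(rank / 10)` clipped to 1..10. Ties share a mid-rank and
#' therefore always land in the same (left-closed) bin; if every value is
#' tied all individuals fall in one bin and a warning is emitted.
#'
#' @param x Numeric vector of scores.
#' @return Integer vector of decile labels 1-10.
#' @export
assign_deciles <- function(x) {
  pr <- percentile_rank(x)
  if (length(unique(x[!is.na(x)])) == 1) {
    warning("all scores tied: every individual assigned to a single decile bin")
  }
  as.integer(pmin(10, pmax(1, ceiling(pr / 10))))
}

#' Empirical quantile threshold for percentile queries
#'
#' Resolves queries such as "above the 90th percentile" against the
#' empirical quantile function with linear interpolation.
#'
#' @param x Numeric vector.
#' @param pct Percentile in \[0, 100\].
#' @return The score threshold.
#' @export
percentile_threshold <- function(x, pct) {
  stats::quantile(x, probs = pct / 100, na.rm = TRUE, names = FALSE, type = 7)
}

#' Score a cohort
#'
#' Computes aPRS, wPRS, the wPRS Z score (standardized over the full
#' cohort), percentile ranks and decile bins for every individual in a
#' genotype table. Individuals missing any scored locus are flagged and get
#' NA scores.
#'
#' @inheritParams compute_aprs
#' @return A data.frame with columns `id`, `apoe`, `aprs`, `wprs`, `wprs_z`,
#'   `percentile`, `decile`, `excluded` (TRUE when a scored locus was
#'   missing).
#' @export
score_cohort <- function(genotypes, definition = default_score_definition()) {
  comp <- score_components(genotypes, definition, "weight")
  wprs <- comp$total
  aprs <- compute_aprs(genotypes, definition)
  excluded <- is.na(wprs)
  if (any(excluded)) {
    message(sum(excluded), " individual(s) excluded from scoring (missing genotype)")
  }
  data.frame(
    id = genotypes$id,
    apoe = comp$apoe,
    aprs = aprs,
    wprs = wprs,
    wprs_z = as.numeric(standardize_scores(wprs)),
    percentile = percentile_rank(wprs),
    decile = assign_deciles(wprs),
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

#' Enumerate all genotype combinations under a score definition
#'
#' Exhaustively enumerates the 3^k x 6 combinations of SNP dosages and APOE
#' genotypes and returns the aPRS and wPRS of each; used to verify score
#' bounds and monotonicity.
#'
#' @param definition A score definition.
#' @return A data.frame with one row per combination, the dosage columns,
#'   `apoe`, `aprs` and `wprs`.
#' @export
enumerate_score_space <- function(definition = default_score_definition()) {
  snps <- definition$snps
  grids <- c(stats::setNames(rep(list(0:2), nrow(snps)), snps$rsid),
             list(apoe = definition$apoe$genotype))
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  apoe_dos <- apoe_to_dosages(grid$apoe)
  g <- genotype_table(seq_len(nrow(grid)),
                      cbind(grid[snps$rsid], as.data.frame(apoe_dos)))
  grid$aprs <- compute_aprs(g, definition)
  grid$wprs <- compute_wprs(g, definition)
  grid
}
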