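# Genotype QC: Hardy-Weinberg equilibrium chi-squared test and pairwise
# linkage disequilibrium from unphased genotypes via EM haplotype estimation.

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Asymptotic 1-df chi-squared goodness-of-fit test of observed genotype
#' counts against expectations under random mating, without continuity
#' correction. The allele frequency is estimated from the counts
#' themselves.
#'
#' @param counts Integer vector `c(n_MM, n_Mm, n_mm)` of common-homozygote,
#'   heterozygote and minor-homozygote counts, or a dosage vector (values
#'   0/1/2/NA) from which counts are tabulated.
#' @return A list of class `ldlprs_hwe` with `chi2`, `df`, `p`, `observed`,
#'   `expected`, `maf` and `degenerate` (TRUE for a monomorphic locus,
#'   where the test is vacuous and `chi2 = 0`).
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3) {
    check_dosage(counts)
    d <- counts[!is.na(counts)]
    counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no genotypes observed: HWE test undefined")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)  # minor-allele frequency
  p <- 1 - q
  degenerate <- q == 0 || q == 1
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (degenerate) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  out <- list(chi2 = chi2, df = 1L,
              p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              observed = counts, expected = expected, maf = q,
              degenerate = degenerate)
  class(out) <- "ldlprs_hwe"
  out
}

#' @export
print.ldlprs_hwe <- function(x, ...) {
  cat(sprintf("HWE chi-squared = %.4f (df = 1), p = %.4g, MAF = %.4f%s\n",
              x$chi2, x$p, x$maf,
              if (x$degenerate) " [monomorphic: test vacuous]" else ""))
  invisible(x)
}

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by
#' expectation-maximisation over unphased diploid genotypes (the only
#' ambiguous configuration being the double heterozygote), then reports the
#' classical disequilibrium coefficients. Alleles are oriented to the minor
#' allele at each locus, so `D > 0` means minor alleles co-occur in excess.
#'
#' `D = pAB - pA * pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA * (1 - pB), (1 - pA) * pB)` for `D > 0` and
#' `min(pA * pB, (1 - pA) * (1 - pB))` for `D < 0`;
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))`. A chi-squared LD p-value is
#' computed as `2n * r2` on 1 df.
#'
#' @param dosA,dosB Equal-length minor-allele dosage vectors (0/1/2/NA).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Iteration cap for EM.
#' @return A list of class `ldlprs_ld` with `D`, `D_prime`, `r2`,
#'   `haplotype_freqs` (AB, Ab, aB, ab where A/B denote minor alleles),
#'   `chi2`, `p`, `n`, `converged`.
#' @export
ld_pairwise <- function(dosA, dosB, tol = 1e-10, max_iter = 1000L) {
  check_dosage(dosA, "locus A"); check_dosage(dosB, "locus B")
  stopifnot(length(dosA) == length(dosB))
  keep <- !is.na(dosA) & !is.na(dosB)
  a <- dosA[keep]; b <- dosB[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete genotype pairs")
  pA <- mean(a) / 2; pB <- mean(b) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("LD undefined for a monomorphic locus")
  }
  # 3x3 genotype count table; cell [i+1, j+1] = count of (dosA = i, dosB = j)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(a == i & b == j)

  # EM on haplotype frequencies h = (AB, Ab, aB, ab); A/B = minor alleles.
  # Start from linkage equilibrium.
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  loglik <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # Expected haplotype counts given current h. Every genotype except the
    # double heterozygote has a unique phase.
    # Phase-known contributions (haplotype counts per individual):
    # dosA/dosB: 2,2 -> 2 AB ; 2,1 -> AB + Ab ; 2,0 -> 2 Ab ; etc.
    cnt <- c(
      AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
      Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
      aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
      ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
    )
    # Double heterozygote: AB/ab with prob q, Ab/aB with prob 1 - q
    dh <- tab[2, 2]
    denom <- h[1] * h[4] + h[2] * h[3]
    qq <- if (denom > 0) h[1] * h[4] / denom else 0.5
    cnt <- cnt + dh * c(qq, 1 - qq, 1 - qq, qq)
    h_new <- cnt / (2 * n)
    ll <- em_loglik(tab, h_new)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      h <- h_new; loglik <- ll; converged <- TRUE
      break
    }
    h <- h_new; loglik <- ll
  }
  h <- unname(h)
  pA_hat <- h[1] + h[2]; pB_hat <- h[1] + h[3]
  D <- h[1] - pA_hat * pB_hat
  Dmax <- if (D >= 0) {
    min(pA_hat * (1 - pB_hat), (1 - pA_hat) * pB_hat)
  } else {
    min(pA_hat * pB_hat, (1 - pA_hat) * (1 - pB_hat))
  }
  D_prime <- if (Dmax > 0) abs(D) / Dmax else 0
  denomr <- pA_hat * (1 - pA_hat) * pB_hat * (1 - pB_hat)
  r2 <- if (denomr > 0) D^2 / denomr else 0
  chi2 <- 2 * n * r2
  out <- list(D = D, D_prime = min(D_prime, 1), r2 = min(r2, 1),
              haplotype_freqs = stats::setNames(h, c("AB", "Ab", "aB", "ab")),
              chi2 = chi2,
              p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              n = n, converged = converged)
  class(out) <- "ldlprs_ld"
  out
}

em_loglik <- function(tab, h) {
  # genotype probabilities implied by haplotype frequencies under
  # random union of gametes
  gp <- matrix(0, 3, 3)
  pAB <- h[1]; pAb <- h[2]; paB <- h[3]; pab <- h[4]
  gp[3, 3] <- pAB^2
  gp[3, 2] <- 2 * pAB * pAb
  gp[3, 1] <- pAb^2
  gp[2, 3] <- 2 * pAB * paB
  gp[2, 2] <- 2 * (pAB * pab + pAb * paB)
  gp[2, 1] <- 2 * pAb * pab
  gp[1, 3] <- paB^2
  gp[1, 2] <- 2 * paB * pab
  gp[1, 1] <- pab^2
  keep <- tab > 0
  sum(tab[keep] * log(pmax(gp[keep], .Machine$double.xmin)))
}

#' @export
print.ldlprs_ld <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.4f, r2 = %.4f, chi2 p = %.3g (n = %d)%s\n",
              x$D, x$D_prime, x$r2, x$p, x$n,
              if (!x$converged) " [EM did not converge]" else ""))
  invisible(x)
}
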