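# Shared fixtures and independent oracles used across test files.

# genotype table for a single individual given per-locus dosages
one_ind_genotypes <- function(...) {
  genotype_table("i1", as.data.frame(list(...)))
}

# genotype table where every scored SNP has the given minor-allele dosage
# trio1 = rs6511720/rs629301/rs1800562 (counted allele = common),
# trio2 = rs1367117/rs4299376/rs2479409 (counted allele = minor)
trio_genotypes <- function(trio1, trio2, apoe) {
  ad <- ldlprs:::apoe_to_dosages(apoe)
  one_ind_genotypes(
    rs6511720 = trio1, rs629301 = trio1, rs1800562 = trio1,
    rs1367117 = trio2, rs4299376 = trio2, rs2479409 = trio2,
    rs429358 = ad[1, "rs429358"], rs7412 = ad[1, "rs7412"])
}

# dosage vectors built from explicit two-locus haplotype counts, pairing
# haplotypes in a fixed deterministic order (phase-known construction)
genotypes_from_haplotypes <- function(n_AB, n_Ab, n_aB, n_ab) {
  mk <- function(a, b, n) cbind(rep(a, n), rep(b, n))
  haps <- rbind(mk(1, 1, n_AB), mk(1, 0, n_Ab), mk(0, 1, n_aB), mk(0, 0, n_ab))
  stopifnot(nrow(haps) %% 2 == 0)
  i1 <- seq(1, nrow(haps), by = 2); i2 <- i1 + 1
  list(dosA = haps[i1, 1] + haps[i2, 1], dosB = haps[i1, 2] + haps[i2, 2])
}

# exhaustive Jonckheere-Terpstra enumeration over all distinct assignments
# of values to ordered groups of the given sizes; returns the one-sided
# (increasing) p-value for the observed statistic
jt_exact_p <- function(values, sizes) {
  n <- length(values)
  stopifnot(sum(sizes) == n)
  obs <- ldlprs:::jt_statistic(values, rep(seq_along(sizes), sizes))
  idx <- seq_len(n)
  stats <- c()
  g1 <- utils::combn(idx, sizes[1], simplify = FALSE)
  for (a in g1) {
    rest <- setdiff(idx, a)
    g2 <- utils::combn(rest, sizes[2], simplify = FALSE)
    for (b in g2) {
      cc <- setdiff(rest, b)
      gi <- integer(n); gi[a] <- 1L; gi[b] <- 2L; gi[cc] <- 3L
      stats <- c(stats, ldlprs:::jt_statistic(values, gi))
    }
  }
  mean(stats >= obs - 1e-9)
}

# default test cohort spec kept small for speed
test_spec <- function(seed = 7, n_cases = 125, n_controls = 97, ...) {
  cohort_spec(n_cases = n_cases, n_controls = n_controls, seed = seed, ...)
}
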