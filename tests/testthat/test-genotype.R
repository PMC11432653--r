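test_that("APOE epsilon genotypes are called from the two-SNP haplotype table", {
  # e2 = (T,T), e3 = (T,C), e4 = (C,C) over (rs429358, rs7412)
  expect_equal(call_apoe_genotype(0, 0), "e3e3")
  expect_equal(call_apoe_genotype(2, 0), "e4e4")
  expect_equal(call_apoe_genotype(0, 2), "e2e2")
  expect_equal(call_apoe_genotype(0, 1), "e2e3")
  expect_equal(call_apoe_genotype(1, 0), "e3e4")
  # the ambiguous double heterozygote resolves to e2e4 by convention
  expect_equal(call_apoe_genotype(1, 1), "e2e4")
  expect_true(is.na(call_apoe_genotype(NA, 1)))
  # combinations needing an epsilon-1 haplotype are rejected
  expect_warning(out <- call_apoe_genotype(2, 1), "epsilon-1")
  expect_true(is.na(out))
})

test_that("APOE calling inverts the genotype-to-dosage map for all six genotypes", {
  genos <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
  d <- ldlprs:::apoe_to_dosages(genos)
  expect_equal(call_apoe_genotype(d[, "rs429358"], d[, "rs7412"]), genos)
})

test_that("unambiguous dosage pairs agree with exhaustive haplotype-pair enumeration", {
  # enumerate all unordered pairs of the three haplotypes and check that
  # the dosage pair they imply is called back to the same genotype
  haps <- list(e2 = c(0, 1), e3 = c(0, 0), e4 = c(1, 0))  # (C count, T count)
  for (i in names(haps)) for (j in names(haps)) {
    d429 <- haps[[i]][1] + haps[[j]][1]
    d7412 <- haps[[i]][2] + haps[[j]][2]
    label <- paste0(sort(c(i, j))[1], sort(c(i, j))[2])
    expect_equal(call_apoe_genotype(d429, d7412), label,
                 info = paste(i, j))
  }
})

test_that("HWE chi-squared matches hand arithmetic and handles degenerate loci", {
  h0 <- hwe_chisq(c(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p, 1)
  h1 <- hwe_chisq(c(30, 40, 30))  # expected (25, 50, 25): 1 + 2 + 1
  expect_equal(h1$chi2, 4)
  expect_equal(h1$df, 1L)
  expect_equal(h1$p, pchisq(4, 1, lower.tail = FALSE))
  hm <- hwe_chisq(c(100, 0, 0))
  expect_equal(hm$chi2, 0)
  expect_true(hm$degenerate)
  expect_error(hwe_chisq(c(0, 0, 0)), "undefined")
  # dosage-vector input tabulates to the same result
  dos <- c(rep(0, 30), rep(1, 40), rep(2, 30))
  expect_equal(hwe_chisq(dos)$chi2, 4)
})

test_that("HWE statistic is invariant to swapping homozygote labels", {
  set.seed(11)
  for (k in 1:25) {
    cnt <- as.vector(rmultinom(1, 200, c(runif(1), runif(1), runif(1))))
    if (sum(cnt) == 0) next
    expect_equal(hwe_chisq(cnt)$chi2, hwe_chisq(rev(cnt))$chi2, tolerance = 1e-12)
  }
})

test_that("LD estimation recovers hand-computable configurations", {
  # complete LD: only AB and ab haplotypes, pA = pB = 0.3
  g <- genotypes_from_haplotypes(60, 0, 0, 140)
  ld <- ld_pairwise(g$dosA, g$dosB)
  expect_equal(ld$D, 0.21, tolerance = 1e-6)
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_true(ld$converged)
  # linkage equilibrium: haplotype counts exactly at independence
  g0 <- genotypes_from_haplotypes(15, 35, 15, 35)  # pA = 0.5, pB = 0.3, pAB = pA*pB
  ld0 <- ld_pairwise(g0$dosA, g0$dosB)
  expect_equal(ld0$D, 0, tolerance = 1e-6)
  expect_equal(ld0$D_prime, 0, tolerance = 1e-6)
})

test_that("EM haplotype frequencies are a proper distribution and match counting when phase is known", {
  set.seed(21)
  for (k in 1:20) {
    nAB <- sample(5:40, 1); nAb <- sample(5:40, 1)
    naB <- sample(5:40, 1); nab <- sample(5:40, 1)
    if ((nAB + nAb + naB + nab) %% 2 == 1) nab <- nab + 1
    g <- genotypes_from_haplotypes(nAB, nAb, naB, nab)
    # only keep datasets without double heterozygotes (phase unambiguous)
    if (any(g$dosA == 1 & g$dosB == 1)) next
    ld <- ld_pairwise(g$dosA, g$dosB)
    expect_equal(sum(ld$haplotype_freqs), 1, tolerance = 1e-9)
    expect_true(all(ld$haplotype_freqs >= 0))
    tot <- 2 * length(g$dosA)
    expect_equal(unname(ld$haplotype_freqs),
                 c(nAB, nAb, naB, nab) / tot, tolerance = 1e-6)
  }
})

test_that("LD errors on monomorphic input", {
  expect_error(ld_pairwise(rep(0, 10), c(0, 1, 2, rep(1, 7))), "monomorphic")
})

test_that("genotype CSV round-trips including missing values", {
  g <- genotype_table(c("a", "b"), data.frame(rs1 = c(0L, NA), rs2 = c(2L, 1L)))
  tf <- tempfile(fileext = ".csv")
  write_genotypes_csv(g, tf)
  g2 <- read_genotypes_csv(tf)
  expect_equal(as.data.frame(g2), as.data.frame(g))
})

test_that("VCF reader reconciles REF/ALT orientation against the score definition", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    # ALT is the definition's minor allele: direct orientation
    "19\t11202306\trs6511720\tG\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    # REF/ALT swapped relative to the definition: must be flipped
    "1\t109818306\trs629301\tG\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    # missing genotype
    "2\t21263900\trs1367117\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1"
  ), tf)
  expect_warning(g <- read_genotypes_vcf(tf), "flipping")
  expect_equal(g$rs6511720, c(1L, 2L))
  # rs629301 minor is G, common is T; VCF REF=G ALT=T, so ALT counts the
  # common allele and the minor dosage is 2 - ALT count
  expect_equal(g$rs629301, c(2L, 1L))
  expect_equal(g$rs1367117, c(NA_integer_, 1L))
})
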