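test_that("the cohort spec validates its invariants", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(seed = 1, apoe_freq = c(e3e3 = 0.5)), "sum to 1")
  expect_error(cohort_spec(seed = 1, trait_effects = c(eldlc = 1.2, hdlc = 0,
                                                       bmi = 0, lpa = 0)),
               "beta")
  expect_error(cohort_spec(seed = 1, nonsense = 2), "unknown")
  expect_error(
    sample_genotypes(cohort_spec(seed = 1,
                                 ld_pairs = list(list(a = "rs1367117",
                                                      b = "rs676210",
                                                      dprime = 1.4))), 10),
    "D'")
})

test_that("genotype sampling is seed-deterministic and matches configured frequencies", {
  spec <- test_spec(seed = 17)
  g1 <- sample_genotypes(spec, 5000)
  g2 <- sample_genotypes(spec, 5000)
  expect_identical(g1, g2)
  g3 <- sample_genotypes(spec, 10000, seed = 999)
  for (rs in c("rs6511720", "rs629301", "rs2479409")) {
    p <- spec$maf[[rs]]
    tol <- 3 * sqrt(p * (1 - p) / (2 * 10000))
    expect_lt(abs(mean(g3[[rs]]) / 2 - p), tol)
  }
  # APOE genotype distribution is drawn directly
  apoe <- call_apoe_genotype(g3$rs429358, g3$rs7412)
  expect_equal(mean(apoe == "e3e3"), 0.660, tolerance = 0.03)
})

test_that("independent loci sampled under HWE pass the equilibrium test", {
  indep <- c("rs6511720", "rs629301", "rs4299376", "rs1800562", "rs2479409")
  fails <- 0L; total <- 0L
  for (s in 1:100) {
    g <- sample_genotypes(test_spec(seed = s), 400)
    for (rs in indep) {
      h <- hwe_chisq(g[[rs]])
      if (h$degenerate) next
      total <- total + 1L
      if (h$p < 0.001) fails <- fails + 1L
    }
  }
  expect_gte(1 - fails / total, 0.99)
})

test_that("the LD pair reproduces its configured D-prime and independence when D' = 0", {
  spec <- test_spec(seed = 23)
  g <- sample_genotypes(spec, 5000)
  ld <- ld_pairwise(g$rs1367117, g$rs676210)
  expect_equal(ld$D_prime, 0.99, tolerance = 0.02)
  spec0 <- test_spec(seed = 23,
                     ld_pairs = list(list(a = "rs1367117", b = "rs676210",
                                          dprime = 0)))
  g0 <- sample_genotypes(spec0, 5000)
  ld0 <- ld_pairwise(g0$rs1367117, g0$rs676210)
  expect_lt(ld0$D_prime, 0.08)
})

test_that("a null trait effect yields a null sample correlation", {
  spec <- test_spec(seed = 29,
                    trait_effects = c(eldlc = 0, hdlc = -0.14, bmi = 0.15,
                                      lpa = 0.05))
  g <- sample_genotypes(spec, 4000)
  ph <- sample_phenotypes(g, spec)
  r <- cor(ph$eldlc, ph$wprs_z)
  expect_lt(abs(r), 2.5 / sqrt(4000))
})

test_that("generated trait scale matches the configured SD", {
  spec <- test_spec(seed = 31)
  g <- sample_genotypes(spec, 10000)
  ph <- sample_phenotypes(g, spec)
  expect_equal(sd(ph$eldlc), spec$trait_scales$eldlc[["sd"]], tolerance = 0.05)
  expect_equal(sd(ph$hdlc), spec$trait_scales$hdlc[["sd"]], tolerance = 0.05)
})

test_that("a zero-coefficient case model gives covariate-independent labels at the target rate", {
  spec <- test_spec(seed = 37, n_cases = 500, n_controls = 500,
                    case_model = c(alcohol = 0, hypertension = 0, famhist = 0,
                                   smoking = 0, eldlc = 0, hdlc = 0, lpa = 0))
  g <- sample_genotypes(spec, 6000)
  ph <- sample_phenotypes(g, spec)
  ph <- assign_case_control(ph, spec)
  expect_equal(mean(ph$case), 0.5, tolerance = 0.03)
  expect_lt(abs(cor(ph$case, ph$eldlc)), 2.5 / sqrt(6000))
})

test_that("simulated cohorts are reproducible and meet their quotas exactly", {
  spec <- test_spec(seed = 41)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_identical(as.data.frame(co1$genotypes), as.data.frame(co2$genotypes))
  expect_equal(sum(co1$phenotypes$case), 125)
  expect_equal(sum(!co1$phenotypes$case), 97)
})

test_that("masked on-statin LDLC back-estimates to the generated eLDLC exactly", {
  spec <- test_spec(seed = 43)
  co <- simulate_cohort(spec)
  ph <- co$phenotypes
  est <- estimate_pretreatment_ldlc(ph$ldlc, ph$statin, ph$statin_dose)
  expect_equal(est, ph$eldlc, tolerance = 1e-12)
  treated <- !is.na(ph$statin)
  expect_true(any(treated))
  expect_true(all(ph$ldlc[treated] < ph$eldlc[treated]))
})

test_that("cohort CSVs round-trip through the package readers", {
  spec <- test_spec(seed = 47, n_cases = 30, n_controls = 25)
  co <- simulate_cohort(spec)
  dir <- tempfile()
  paths <- write_cohort_csv(co, dir)
  g <- read_genotypes_csv(paths[["genotypes"]])
  expect_equal(as.data.frame(g), as.data.frame(co$genotypes))
  ph <- utils::read.csv(paths[["phenotypes"]], stringsAsFactors = FALSE)
  expect_equal(nrow(ph), 55)
  expect_equal(sum(ph$case == "TRUE" | ph$case == TRUE), 30)
})

test_that("the fitted case model recovers the configured coefficient signs", {
  signs_ok <- vapply(1000 + 1:20, function(seed) {
    spec <- test_spec(seed = seed, n_cases = 1100, n_controls = 900)
    co <- simulate_cohort(spec)
    ph <- co$phenotypes
    fit <- logistic_fit(ph$case, ph[c("alcohol", "hypertension", "famhist",
                                      "smoking", "eldlc", "hdlc", "lpa")])
    cf <- fit$coefficients
    est <- cf$beta[match(c("alcoholTRUE", "hypertensionTRUE", "famhistTRUE",
                           "smokingTRUE", "eldlc", "hdlc", "lpa"), cf$term)]
    all(sign(est) == sign(spec$case_model))
  }, logical(1))
  expect_gte(mean(signs_ok), 0.95)
})
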