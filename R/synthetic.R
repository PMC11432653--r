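# Synthetic genotype-phenotype cohort generator. Emulates the statistical
# structure the analysis pipeline assumes: HWE genotypes at configured
# allele frequencies, one LD pair at a configured D', APOE genotypes drawn
# from a genotype distribution, and phenotypes driven by the weighted score
# through a single-index model with configured per-SD effects.

#' Specification of a synthetic cohort
#'
#' Returns the default cohort specification: 125 cases and 97 controls,
#' allele frequencies and APOE genotype frequencies of a central-European
#' healthy-control population, one strong LD pair
#' (rs676210-rs1367117, D' = 0.99), trait effects per SD of the weighted
#' score (eLDLC +0.20, HDLC -0.14, BMI +0.15, Lp(a) +0.05, DLCN +0.16),
#' threshold effects (odds per SD 1.36 for eLDLC > 190 mg/dL and 1.58 for
#' DLCN >= 3), and a logistic case model with clinically realistic
#' coefficients (strong smoking and family-history effects, moderate
#' hypertension, protective alcohol, per-mg/dL lipid effects).
#'
#' Trait means and SDs are chosen to match the medians and IQRs of the
#' emulated case-control study (SDs back-converted from IQRs assuming
#' near-normality). The eLDLC residual is a two-component normal mixture
#' (a normolipidemic majority plus a hypercholesterolemic component, as
#' seen in clinically enriched lipid cohorts) and the DLCN item models
#' carry score dependence; the mixture and the item slopes are fixed by
#' one-time moment-matching so that the generator reproduces its
#' configured threshold effects and the DLCN trait effect (see the
#' methods vignette).
#'
#' @param n_cases,n_controls Group sizes.
#' @param seed Mandatory integer seed; expanded internally into per-stage
#'   substreams.
#' @param ... Named overrides for any default component.
#' @return A list of class `ldlprs_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 125, n_controls = 97, seed, ...) {
  if (missing(seed)) stop("a seed is mandatory for a cohort spec")
  spec <- list(
    n_cases = n_cases, n_controls = n_controls, seed = as.integer(seed),
    maf = c(rs6511720 = 0.118, rs629301 = 0.221, rs1367117 = 0.345,
            rs4299376 = 0.350, rs1800562 = 0.031, rs2479409 = 0.350,
            rs676210 = 0.300),
    apoe_freq = c(e2e2 = 0, e2e3 = 0.103, e2e4 = 0.041,
                  e3e3 = 0.660, e3e4 = 0.196, e4e4 = 0),
    ld_pairs = list(list(a = "rs1367117", b = "rs676210", dprime = 0.99)),
    trait_effects = c(eldlc = 0.20, hdlc = -0.14, bmi = 0.15, lpa = 0.05),
    dlcn_effect = 0.16,
    threshold_effects = c(or_eldlc190 = 1.36, or_dlcn3 = 1.58),
    trait_scales = list(eldlc = c(mean = 150, sd = 48),
                        hdlc = c(mean = 44, sd = 11),
                        bmi = c(mean = 28.5, sd = 4.3),
                        lpa = c(mean = 18, sd = 14)),
    lpa_floor = 9.7,
    eldlc_floor = 20,
    # eLDLC residual: normolipidemic majority plus a hypercholesterolemic
    # component (weight w, mean/sd in eLDLC-SD units); the majority
    # component's mean and sd are derived so the residual has mean 0, var 1
    eldlc_mix = c(w = 0.08, mean2 = 2.2, sd2 = 0.8),
    covariate_rates = c(famhist = 0.239, smoking = 0.567, alcohol = 0.297,
                        hypertension = 0.360, male = 0.783, age_over45 = 0.55),
    covariate_z_or = c(famhist = 1.27, hypertension = 1.17,
                       male = 1.05, age_over45 = 1.01),
    dlcn_item_rates = c(relative_high_ldl_or_stigmata = 0.050,
                        premature_cerebral_peripheral = 0.040,
                        tendon_xanthomata = 0.015,
                        arcus_cornealis_under_45 = 0.030),
    dlcn_item_z_slopes = c(relative_high_ldl_or_stigmata = 0.50,
                           premature_cerebral_peripheral = 0.80,
                           tendon_xanthomata = 0.25,
                           arcus_cornealis_under_45 = 0.25),
    statin_rate = c(control = 0.082, case = 0.704),
    statin_mix = data.frame(
      statin = c("atorvastatin", "atorvastatin", "rosuvastatin",
                 "rosuvastatin", "simvastatin"),
      dose = c(20, 40, 10, 20, 20),
      prob = c(0.30, 0.25, 0.20, 0.15, 0.10),
      stringsAsFactors = FALSE),
    case_model = c(alcohol = log(0.29), hypertension = log(2.42),
                   famhist = log(10.01), smoking = log(10.86),
                   eldlc = log(1.012), hdlc = log(0.949), lpa = log(1.020))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(spec)) stop("unknown cohort spec field: ", nm)
    spec[[nm]] <- dots[[nm]]
  }
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_cases >= 0, spec$n_controls >= 0,
            spec$n_cases + spec$n_controls > 0)
  if (any(spec$maf < 0 | spec$maf > 1)) stop("allele frequencies must be in [0, 1]")
  if (abs(sum(spec$apoe_freq) - 1) > 1e-8) stop("APOE genotype frequencies must sum to 1")
  for (p in spec$ld_pairs) {
    if (p$dprime < 0 || p$dprime > 1) stop("D' must be in [0, 1]")
  }
  if (any(abs(spec$trait_effects) >= 1)) {
    stop("per-SD trait effects must satisfy |beta| < 1")
  }
  sds <- vapply(spec$trait_scales, function(s) s[["sd"]], numeric(1))
  if (any(sds <= 0)) stop("trait SDs must be positive")
  class(spec) <- "ldlprs_cohort_spec"
  spec
}

# two-locus haplotype frequencies (AB, Ab, aB, ab) for minor-allele
# frequencies pA, pB and a target D'
haplotype_freqs_for_dprime <- function(pA, pB, dprime) {
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  D <- dprime * dmax
  h <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
         aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  if (any(h < -1e-12)) {
    stop(sprintf("infeasible D' = %.3f for frequencies %.3f / %.3f (max feasible %.3f)",
                 dprime, pA, pB, 1))
  }
  pmax(h, 0) / sum(pmax(h, 0))
}

#' Sample genotypes for a synthetic cohort
#'
#' Independent loci are drawn under Hardy-Weinberg equilibrium at their
#' configured minor-allele frequencies; LD-paired loci are drawn as random
#' unions of two-locus haplotypes whose frequencies solve for the
#' configured D'; APOE epsilon genotypes are drawn from the configured
#' genotype distribution and expressed as rs429358/rs7412 dosages.
#'
#' @param spec A cohort spec.
#' @param n Number of individuals.
#' @param seed Seed for this stage (default: derived from `spec$seed`).
#' @return A genotype table.
#' @export
sample_genotypes <- function(spec, n, seed = substream_seed(spec$seed, 1)) {
  set.seed(seed)
  paired <- unlist(lapply(spec$ld_pairs, function(p) c(p$a, p$b)))
  dos <- list()
  for (rs in setdiff(names(spec$maf), paired)) {
    dos[[rs]] <- stats::rbinom(n, 2, spec$maf[[rs]])
  }
  for (p in spec$ld_pairs) {
    h <- haplotype_freqs_for_dprime(spec$maf[[p$a]], spec$maf[[p$b]], p$dprime)
    hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = h), nrow = 2)
    dos[[p$a]] <- colSums(hap <= 2)          # haplotypes AB, Ab carry A
    dos[[p$b]] <- colSums(hap == 1 | hap == 3)  # AB, aB carry B
  }
  apoe <- sample(names(spec$apoe_freq), n, replace = TRUE,
                 prob = spec$apoe_freq)
  ad <- apoe_to_dosages(apoe)
  dos[["rs429358"]] <- ad[, "rs429358"]
  dos[["rs7412"]] <- ad[, "rs7412"]
  genotype_table(sprintf("S%05d", seq_len(n)), as.data.frame(dos))
}

# zero-mean unit-variance two-component normal mixture residual
rmix_resid <- function(n, mix) {
  w <- mix[["w"]]; m2 <- mix[["mean2"]]; s2 <- mix[["sd2"]]
  m1 <- -w * m2 / (1 - w)
  s1sq <- (1 - w * (s2^2 + m2^2)) / (1 - w) - m1^2
  if (s1sq <= 0) stop("infeasible eLDLC mixture: majority variance would be negative")
  hi <- stats::runif(n) < w
  ifelse(hi, stats::rnorm(n, m2, s2), stats::rnorm(n, m1, sqrt(s1sq)))
}

#' Sample phenotypes given genotypes
#'
#' Single-index model: every trait depends on the genotypes only through
#' the weighted-score Z value. Continuous traits follow
#' `trait_Z = beta * wPRS_Z + sqrt(1 - beta^2) * eps` with unit-variance
#' residuals (a bimodal normal mixture for eLDLC, normal otherwise),
#' de-standardized to
#' their configured means/SDs. Binary covariates and DLCN items are
#' Bernoulli with logit-linear score dependence. Lp(a) is floored at the
#' assay detection limit.
#'
#' @param genotypes A genotype table from [sample_genotypes()].
#' @param spec The cohort spec.
#' @param seed Stage seed (default derived from `spec$seed`).
#' @return A data.frame of phenotype records including the generator's
#'   `wprs` and `wprs_z` columns (as used during generation).
#' @export
sample_phenotypes <- function(genotypes, spec,
                              seed = substream_seed(spec$seed, 2)) {
  set.seed(seed)
  wprs <- compute_wprs(genotypes)
  z <- as.numeric(standardize_scores(wprs))
  n <- length(z)
  eff <- spec$trait_effects
  sc <- spec$trait_scales
  mk_cont <- function(beta, resid) beta * z + sqrt(1 - beta^2) * resid
  eldlc_z <- mk_cont(eff[["eldlc"]], rmix_resid(n, spec$eldlc_mix))
  hdlc_z <- mk_cont(eff[["hdlc"]], stats::rnorm(n))
  bmi_z <- mk_cont(eff[["bmi"]], stats::rnorm(n))
  lpa_z <- mk_cont(eff[["lpa"]], stats::rnorm(n))
  destd <- function(zz, s) s[["mean"]] + s[["sd"]] * zz
  eldlc <- pmax(spec$eldlc_floor, destd(eldlc_z, sc$eldlc))
  hdlc <- pmax(10, destd(hdlc_z, sc$hdlc))
  bmi <- pmax(15, destd(bmi_z, sc$bmi))
  lpa <- pmax(spec$lpa_floor, destd(lpa_z, sc$lpa))
  bern_z <- function(rate, or_per_sd) {
    stats::rbinom(n, 1, stats::plogis(stats::qlogis(rate) + log(or_per_sd) * z)) == 1
  }
  rates <- spec$covariate_rates; zor <- spec$covariate_z_or
  famhist <- bern_z(rates[["famhist"]], zor[["famhist"]])
  hypertension <- bern_z(rates[["hypertension"]], zor[["hypertension"]])
  male <- bern_z(rates[["male"]], zor[["male"]])
  age_over45 <- bern_z(rates[["age_over45"]], zor[["age_over45"]])
  smoking <- stats::rbinom(n, 1, rates[["smoking"]]) == 1
  alcohol <- stats::rbinom(n, 1, rates[["alcohol"]]) == 1
  ir <- spec$dlcn_item_rates; is_ <- spec$dlcn_item_z_slopes
  item <- function(nm) {
    stats::rbinom(n, 1, stats::plogis(stats::qlogis(ir[[nm]]) + is_[[nm]] * z)) == 1
  }
  data.frame(
    id = genotypes$id,
    wprs = wprs, wprs_z = z,
    eldlc = eldlc, hdlc = hdlc, bmi = bmi, lpa = lpa,
    famhist = famhist, smoking = smoking, alcohol = alcohol,
    hypertension = hypertension, male = male, age_over45 = age_over45,
    relative_premature_cvd = famhist,
    relative_high_ldl_or_stigmata = item("relative_high_ldl_or_stigmata"),
    premature_cerebral_peripheral = item("premature_cerebral_peripheral"),
    tendon_xanthomata = item("tendon_xanthomata"),
    arcus_cornealis_under_45 = item("arcus_cornealis_under_45"),
    stringsAsFactors = FALSE
  )
}

#' Assign case/control labels
#'
#' Case probability follows the configured logistic model on the sampled
#' covariates; the intercept is solved numerically so the expected case
#' fraction equals `n_cases / (n_cases + n_controls)`, and labels are then
#' Bernoulli draws. The personal premature-CAD history flag is set to the
#' case label afterwards (cases are defined by it), and statin exposure is
#' assigned per group with the measured LDLC back-derived from eLDLC
#' through the statin correction table.
#'
#' @param records Phenotype records from [sample_phenotypes()].
#' @param spec The cohort spec.
#' @param seed Stage seed (default derived from `spec$seed`).
#' @param statin_table Correction table used to derive measured LDLC.
#' @return The records with columns `case`, `premature_cad`, `statin`,
#'   `statin_dose`, `ldlc` (measured) added.
#' @export
assign_case_control <- function(records, spec,
                                seed = substream_seed(spec$seed, 3),
                                statin_table = default_statin_table()) {
  set.seed(seed)
  cm <- spec$case_model
  eta <- with(records,
              cm[["alcohol"]] * alcohol + cm[["hypertension"]] * hypertension +
                cm[["famhist"]] * famhist + cm[["smoking"]] * smoking +
                cm[["eldlc"]] * eldlc + cm[["hdlc"]] * hdlc +
                cm[["lpa"]] * lpa)
  frac <- spec$n_cases / (spec$n_cases + spec$n_controls)
  f <- function(a) mean(stats::plogis(a + eta)) - frac
  lo <- -50 - max(eta); hi <- 50 - min(eta)
  if (f(lo) > 0 || f(hi) < 0) stop("requested case fraction unattainable at any intercept")
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  records$case <- stats::runif(nrow(records)) < stats::plogis(alpha + eta)
  records$premature_cad <- records$case
  # statin exposure by group; measured LDLC back-derived from eLDLC
  rate <- ifelse(records$case, spec$statin_rate[["case"]],
                 spec$statin_rate[["control"]])
  treated <- stats::runif(nrow(records)) < rate
  mix <- spec$statin_mix
  pick <- sample.int(nrow(mix), nrow(records), replace = TRUE, prob = mix$prob)
  records$statin <- ifelse(treated, mix$statin[pick], NA_character_)
  records$statin_dose <- ifelse(treated, mix$dose[pick], NA_real_)
  r <- statin_table$reduction[match(paste(records$statin, records$statin_dose),
                                    paste(statin_table$statin, statin_table$dose))]
  r[!treated] <- 0
  records$ldlc <- records$eldlc * (1 - r)
  records
}

#' Simulate a complete synthetic cohort
#'
#' Runs the three generator stages and fills the requested case/control
#' quotas by rejection: a population pool is generated, labels are drawn
#' from the case model, and the first `n_cases` cases and `n_controls`
#' controls (in pool order) are retained, expanding the pool if a quota is
#' not yet met. Deterministic for a given spec (the pool expansion uses
#' further substreams of the spec seed).
#'
#' @param spec A cohort spec from [cohort_spec()].
#' @return A list with `genotypes` (genotype table), `phenotypes`
#'   (records incl. `case` and measured `ldlc`) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  n_needed <- spec$n_cases + spec$n_controls
  got <- NULL; got_g <- NULL
  batch <- 0L
  while (is.null(got) ||
         sum(got$case) < spec$n_cases ||
         sum(!got$case) < spec$n_controls) {
    if (batch > 25L) stop("case/control quotas not met after 25 pool expansions")
    n_pool <- max(200L, ceiling(1.4 * n_needed))
    g <- sample_genotypes(spec, n_pool,
                          seed = substream_seed(spec$seed, 1 + 10 * batch))
    ph <- sample_phenotypes(g, spec,
                            seed = substream_seed(spec$seed, 2 + 10 * batch))
    ph <- assign_case_control(ph, spec,
                              seed = substream_seed(spec$seed, 3 + 10 * batch))
    ph$id <- paste0("B", batch, "_", ph$id)
    g$id <- ph$id
    got <- if (is.null(got)) ph else rbind(got, ph)
    got_g <- if (is.null(got_g)) g else rbind(got_g, g)
    batch <- batch + 1L
  }
  keep <- c(which(got$case)[seq_len(spec$n_cases)],
            which(!got$case)[seq_len(spec$n_controls)])
  keep <- sort(keep)
  ph <- got[keep, , drop = FALSE]
  g <- got_g[keep, , drop = FALSE]
  rownames(ph) <- rownames(g) <- NULL
  class(g) <- c("ldlprs_genotypes", "data.frame")
  # generation-time score columns are internal; the pipeline recomputes them
  ph$wprs <- NULL; ph$wprs_z <- NULL
  list(genotypes = g, phenotypes = ph, spec = spec)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the genotype and phenotype tables in exactly the dialects the
#' package readers consume.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genotypes.csv")
  pp <- file.path(dir, "phenotypes.csv")
  write_genotypes_csv(cohort$genotypes, gp)
  utils::write.csv(cohort$phenotypes, pp, row.names = FALSE, na = "")
  invisible(c(genotypes = gp, phenotypes = pp))
}
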