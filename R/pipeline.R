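# End-to-end orchestration: ingest -> QC -> score -> phenotype-derive ->
# associate -> report.

#' Run the full analysis pipeline
#'
#' Executes, in order: genotype QC (per-group Hardy-Weinberg tests and a
#' pairwise LD screen that drops any scoreable SNP exceeding a configured
#' D' cut at chi-squared p < 0.001, keeping the higher-weight member of a
#' correlated pair), APOE
#' calling and polygenic scoring, phenotype derivation (eLDLC, DLCN,
#' group labels), and the association battery: allele-frequency and
#' median-score summaries by group, per-SD score-trait associations,
#' univariate and multivariate case-control logistic models with
#' Hosmer-Lemeshow diagnostics and a nested-model comparison, decile trend
#' tests, percentile-extreme risk comparisons, and DLCN-category ROC
#' analyses.
#'
#' @param genotypes A genotype table.
#' @param phenotypes A phenotype data.frame with at least `id`, `case`,
#'   measured `ldlc`, `hdlc`, `lpa`, `bmi`, `statin`, `statin_dose`,
#'   the binary covariates `famhist`, `smoking`, `alcohol`,
#'   `hypertension`, and any DLCN item flags.
#' @param definition Score definition (default [default_score_definition()]).
#' @param statin_table Statin correction table.
#' @param dlcn_table DLCN point table.
#' @param ld_cut D' threshold above which one member of a scored pair is
#'   excluded (default 0.90).
#' @param top_pct,bottom_pct Percentile cuts for the extreme comparison.
#' @param seed Seed recorded in the manifest (used only by permutation
#'   tests, if any run).
#' @return A list of class `ldlprs_report`: `scores`, `phenotypes` (with
#'   derived columns), `qc` (HWE + LD tables), `tables` (named list of
#'   tidy data.frames), `manifest`.
#' @export
run_full_analysis <- function(genotypes, phenotypes,
                              definition = default_score_definition(),
                              statin_table = default_statin_table(),
                              dlcn_table = default_dlcn_table(),
                              ld_cut = 0.90,
                              top_pct = 90, bottom_pct = 10,
                              seed = NA_integer_) {
  stopifnot(all(c("id", "case", "ldlc") %in% names(phenotypes)))
  ph <- phenotypes[match(genotypes$id, phenotypes$id), , drop = FALSE]
  if (any(is.na(ph$id))) stop("phenotype table lacks rows for some genotyped individuals")
  exclusions <- list()

  # --- QC: HWE per group per locus -------------------------------------
  loci <- setdiff(names(genotypes), "id")
  hwe <- do.call(rbind, lapply(loci, function(rs) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(is_case) {
      d <- genotypes[[rs]][ph$case == is_case]
      h <- hwe_chisq(d)
      data.frame(rsid = rs, group = if (is_case) "case" else "control",
                 chi2 = h$chi2, p = h$p, maf = h$maf,
                 degenerate = h$degenerate, stringsAsFactors = FALSE)
    }))
  }))

  # --- QC: LD screen over scoreable loci -------------------------------
  screen <- intersect(c(definition$snps$rsid, definition$excluded), loci)
  ld_rows <- list()
  dropped <- character(0)
  if (length(screen) >= 2) {
    pairs <- utils::combn(screen, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ld <- tryCatch(ld_pairwise(genotypes[[a]], genotypes[[b]]),
                     error = function(e) NULL)
      if (is.null(ld)) next
      ld_rows[[length(ld_rows) + 1]] <- data.frame(
        snp_a = a, snp_b = b, D = ld$D, D_prime = ld$D_prime,
        r2 = ld$r2, p = ld$p, stringsAsFactors = FALSE)
      # both conditions required: |D'| alone is unstable for rare alleles
      if (ld$D_prime > ld_cut && ld$p < 0.001) {
        w <- stats::setNames(definition$snps$weight_per_allele, definition$snps$rsid)
        wa <- w[a]; wb <- w[b]
        drop <- if (is.na(wa)) a else if (is.na(wb)) b
                else if (wa < wb) a else b
        dropped <- union(dropped, drop)
      }
    }
  }
  ld_tab <- if (length(ld_rows)) do.call(rbind, ld_rows) else NULL
  # loci excluded from scoring by default stay excluded even if under the cut
  dropped <- union(dropped, intersect(definition$excluded, loci))
  exclusions$ld_dropped <- setdiff(dropped, definition$excluded)
  def_used <- definition
  def_used$snps <- def_used$snps[!def_used$snps$rsid %in% dropped, , drop = FALSE]

  # --- scoring ----------------------------------------------------------
  scores <- score_cohort(genotypes, def_used)
  exclusions$missing_genotype <- sum(scores$excluded)

  # --- phenotype derivation --------------------------------------------
  ph$eldlc <- estimate_pretreatment_ldlc(ph$ldlc, ph$statin, ph$statin_dose,
                                         statin_table)
  exclusions$unknown_statin <- sum(is.na(ph$eldlc) & !is.na(ph$ldlc))
  dl <- dlcn_score(ph$eldlc, ph, dlcn_table)
  ph$dlcn <- dl$points
  ph$dlcn_category <- dl$category
  ph$group <- assign_groups(ph$case, ph$dlcn)
  dat <- cbind(scores, ph[setdiff(names(ph), "id")])

  # --- association battery ---------------------------------------------
  cc <- dat[!dat$excluded & !is.na(dat$eldlc), , drop = FALSE]
  tables <- list()

  # allele frequencies + median scores per group (score-table analog)
  tables$score_summary <- do.call(rbind, lapply(
    split(cc, cc$group), function(gg) {
      data.frame(group = gg$group[1], n = nrow(gg),
                 aprs_median = stats::median(gg$aprs),
                 wprs_median = stats::median(gg$wprs),
                 wprs_q1 = unname(stats::quantile(gg$wprs, 0.25)),
                 wprs_q3 = unname(stats::quantile(gg$wprs, 0.75)),
                 stringsAsFactors = FALSE)
    }))

  # per-SD score-trait associations (combined cohort)
  zz <- as.numeric(standardize_scores(cc$wprs))
  assoc <- list()
  for (tr in intersect(c("eldlc", "hdlc", "bmi", "lpa", "dlcn"), names(cc))) {
    assoc[[paste0(tr, "_per_sd")]] <- linear_fit_standardized(cc[[tr]], zz)
  }
  for (bv in intersect(c("famhist", "hypertension", "male", "age_over45"),
                       names(cc))) {
    fit <- logistic_fit(cc[[bv]], data.frame(wprs_z = zz))
    r <- fit$coefficients[fit$coefficients$term == "wprs_z", ]
    assoc[[paste0(bv, "_or_per_sd")]] <-
      association_result(r$or, r$or_low, r$or_high, r$p,
                         "logistic regression (OR per SD)", fit$n)
  }
  assoc$eldlc_gt190_or_per_sd <- or_per_sd(cc$eldlc > 190, zz)
  assoc$dlcn_ge3_or_per_sd <- or_per_sd(cc$dlcn >= 3, zz)
  tables$trait_associations <- tidy_associations(assoc)

  # univariate case-control models (risk-factor-table analog)
  uni <- list()
  for (bv in intersect(c("famhist", "smoking", "alcohol", "hypertension"),
                       names(cc))) {
    a <- sum(cc[[bv]] & cc$case); b <- sum(!cc[[bv]] & cc$case)
    c_ <- sum(cc[[bv]] & !cc$case); d <- sum(!cc[[bv]] & !cc$case)
    uni[[bv]] <- odds_ratio_2x2(a, b, c_, d)
  }
  for (cv in intersect(c("bmi", "eldlc", "hdlc", "lpa"), names(cc))) {
    fit <- logistic_fit(cc$case, cc[cv])
    r <- fit$coefficients[fit$coefficients$term == cv, ]
    uni[[cv]] <- association_result(r$or, r$or_low, r$or_high, r$p,
                                    "logistic regression (OR per unit)", fit$n)
  }
  uni$wprs_per_sd <- or_per_sd(cc$case, zz)
  uni$aprs_per_sd <- or_per_sd(cc$case, as.numeric(standardize_scores(cc$aprs)))
  tables$univariate_models <- tidy_associations(uni)

  # multivariate models: reduced (clinical/demographic) vs complete (+labs)
  red_vars <- intersect(c("alcohol", "hypertension", "bmi", "famhist", "smoking"),
                        names(cc))
  com_vars <- union(setdiff(red_vars, "bmi"),
                    intersect(c("eldlc", "hdlc", "lpa"), names(cc)))
  fit_red <- logistic_fit(cc$case, cc[red_vars])
  fit_com <- logistic_fit(cc$case, cc[com_vars])
  cmp <- nested_model_compare(
    logistic_fit(cc$case, cc[setdiff(red_vars, "bmi")]), fit_com)
  tables$multivariate_models <- rbind(
    cbind(model = "reduced", fit_red$coefficients),
    cbind(model = "complete", fit_com$coefficients))
  hl_red <- hosmer_lemeshow(stats::fitted(fit_red$fit), cc$case)
  hl_com <- hosmer_lemeshow(stats::fitted(fit_com$fit), cc$case)
  tables$model_performance <- data.frame(
    model = c("reduced", "complete"),
    cox_snell_r2 = c(fit_red$model$cox_snell_r2, fit_com$model$cox_snell_r2),
    auc = c(model_auc(fit_red$fit), model_auc(fit_com$fit)),
    accuracy = c(fit_red$model$accuracy, fit_com$model$accuracy),
    sensitivity = c(fit_red$model$sensitivity, fit_com$model$sensitivity),
    specificity = c(fit_red$model$specificity, fit_com$model$specificity),
    hosmer_lemeshow_p = c(hl_red$p, hl_com$p),
    stringsAsFactors = FALSE)
  tables$nested_comparison <- tidy_associations(list(reduced_vs_complete = cmp))

  # decile trends of eLDLC and DLCN across weighted-score deciles
  trend <- list()
  for (tr in intersect(c("eldlc", "dlcn"), names(cc))) {
    trend[[paste0(tr, "_by_decile")]] <-
      jonckheere_terpstra(cc[[tr]], cc$decile)
  }
  tables$decile_trends <- tidy_associations(trend)

  # extreme-percentile case-risk comparison
  tables$extreme_percentiles <- tidy_associations(list(
    top_vs_bottom = extreme_percentile_comparison(cc$wprs, cc$case,
                                                  top_pct, bottom_pct)))

  # DLCN-category discrimination by the weighted score
  roc_dlcn3 <- roc_analysis(cc$wprs, cc$dlcn >= 3)
  roc_dfh <- tryCatch(
    roc_analysis(cc$wprs, cc$dlcn > 8, criterion = "sensitivity",
                 target_sensitivity = 1.0),
    error = function(e) NULL)
  tables$dlcn_roc <- data.frame(
    contrast = c("dlcn_ge3_vs_lt3", if (!is.null(roc_dfh)) "definite_vs_rest"),
    auc = c(roc_dlcn3$auc, if (!is.null(roc_dfh)) roc_dfh$auc),
    auc_low = c(roc_dlcn3$auc_ci[1], if (!is.null(roc_dfh)) roc_dfh$auc_ci[1]),
    auc_high = c(roc_dlcn3$auc_ci[2], if (!is.null(roc_dfh)) roc_dfh$auc_ci[2]),
    threshold = c(roc_dlcn3$operating_point$threshold,
                  if (!is.null(roc_dfh)) roc_dfh$operating_point$threshold),
    sensitivity = c(roc_dlcn3$operating_point$sensitivity,
                    if (!is.null(roc_dfh)) roc_dfh$operating_point$sensitivity),
    specificity = c(roc_dlcn3$operating_point$specificity,
                    if (!is.null(roc_dfh)) roc_dfh$operating_point$specificity),
    stringsAsFactors = FALSE)

  tables$group_summary <- emit_group_summary(dat)

  manifest <- list(
    n = nrow(dat), n_cases = sum(dat$case), n_controls = sum(!dat$case),
    seed = seed, ld_cut = ld_cut,
    snps_scored = def_used$snps$rsid,
    exclusions = exclusions,
    config_hash = config_hash(list(definition = definition,
                                   statin_table = statin_table,
                                   dlcn_table = dlcn_table,
                                   ld_cut = ld_cut, top_pct = top_pct,
                                   bottom_pct = bottom_pct)),
    package_version = as.character(utils::packageVersion("ldlprs")),
    r_version = R.version.string
  )
  out <- list(scores = scores, phenotypes = ph, qc = list(hwe = hwe, ld = ld_tab),
              tables = tables, manifest = manifest)
  class(out) <- "ldlprs_report"
  out
}

or_per_sd <- function(outcome, z) {
  fit <- logistic_fit(outcome, data.frame(z = z))
  r <- fit$coefficients[fit$coefficients$term == "z", ]
  association_result(r$or, r$or_low, r$or_high, r$p,
                     "logistic regression (OR per SD)", fit$n)
}

config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Group summary table with between-group tests
#'
#' Median (IQR) per continuous trait and n (%) per binary trait, by group,
#' with between-group p-values: continuous traits use the independent t
#' test when both groups pass a Lilliefors normality check at alpha 0.05
#' (Welch variant when an F test rejects equal variances), otherwise the
#' Mann-Whitney test; binary traits use the chi-squared test. p-values
#' above 0.10 are suppressed in the `p_display` column (the raw value is
#' kept in `p`).
#'
#' @param dat A data.frame with a `group` column (HC/nFH/dFH) and trait
#'   columns.
#' @param traits Optional character vector of traits to summarise.
#' @return A tidy data.frame, one row per trait x group-contrast.
#' @export
emit_group_summary <- function(dat, traits = NULL) {
  stopifnot("group" %in% names(dat))
  groups <- intersect(c("HC", "nFH", "dFH"), unique(dat$group))
  if (length(groups) < 2) warning("fewer than 2 non-empty groups")
  if (is.null(traits)) {
    traits <- intersect(c("age", "bmi", "ldlc", "eldlc", "hdlc", "lpa",
                          "dlcn", "aprs", "wprs", "famhist", "smoking",
                          "alcohol", "hypertension", "male"), names(dat))
  }
  contrasts <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (tr in traits) {
    v <- dat[[tr]]
    binary <- is.logical(v) || all(stats::na.omit(v) %in% 0:1)
    for (ct in contrasts) {
      x <- v[dat$group == ct[1]]; y <- v[dat$group == ct[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      if (binary) {
        tab <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
        p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                      error = function(e) NA_real_)
        desc1 <- sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
        desc2 <- sprintf("%d (%.1f%%)", sum(y), 100 * mean(y))
        test <- "chi-squared"
      } else {
        normal_ok <- length(x) >= 5 && length(y) >= 5 &&
          lilliefors_p(x) > 0.05 && lilliefors_p(y) > 0.05
        if (normal_ok) {
          eqvar <- stats::var.test(x, y)$p.value > 0.05
          p <- stats::t.test(x, y, var.equal = eqvar)$p.value
          test <- if (eqvar) "t test" else "Welch t test"
        } else {
          p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
          test <- "Mann-Whitney"
        }
        desc1 <- med_iqr(x); desc2 <- med_iqr(y)
      }
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, group1 = ct[1], group2 = ct[2],
        summary1 = desc1, summary2 = desc2, test = test, p = p,
        p_display = ifelse(!is.na(p) & p <= 0.10, formatC(p, digits = 4, format = "g"), ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

lilliefors_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75))
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Write a report bundle to disk
#'
#' Emits every table as CSV plus a JSON manifest. Values are rounded only
#' at serialization: 2 decimals for estimates/CIs, 4 significant digits
#' for p-values; the in-memory report keeps full precision.
#'
#' @param report A report from [run_full_analysis()].
#' @param dir Output directory.
#' @param round_output Apply the serialization rounding (default TRUE).
#' @return The directory path, invisibly.
#' @export
write_report_bundle <- function(report, dir, round_output = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rnd <- function(d) {
    if (!round_output) return(d)
    for (cn in names(d)) {
      if (!is.numeric(d[[cn]])) next
      d[[cn]] <- if (grepl("^p$|_p$|^p_", cn)) signif(d[[cn]], 4)
                 else round(d[[cn]], 4)
    }
    d
  }
  for (nm in names(report$tables)) {
    utils::write.csv(rnd(report$tables[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(report$qc$hwe, file.path(dir, "qc_hwe.csv"), row.names = FALSE)
  if (!is.null(report$qc$ld)) {
    utils::write.csv(report$qc$ld, file.path(dir, "qc_ld.csv"), row.names = FALSE)
  }
  utils::write.csv(report$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ldlprs_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ldlprs analysis report: %d individuals (%d cases / %d controls)\n",
              m$n, m$n_cases, m$n_controls))
  cat("SNPs scored:", paste(m$snps_scored, collapse = ", "), "\n")
  if (length(m$exclusions$ld_dropped)) {
    cat("LD-dropped:", paste(m$exclusions$ld_dropped, collapse = ", "), "\n")
  }
  cat("Tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
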