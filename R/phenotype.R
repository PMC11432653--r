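# Phenotype derivation: estimated pre-treatment LDLC (eLDLC) from on-statin
# measurements, DLCN scoring without genetic items, and group assignment.

#' Default statin correction table
#'
#' Expected fractional LDLC reductions by statin type and daily dose (mg),
#' assembled from widely used dose-response summaries of statin trials.
#' These are population-average approximations shipped as editable data:
#' any table with columns `statin`, `dose`, `reduction` can replace it.
#'
#' @return A data.frame with columns `statin`, `dose` (mg/day) and
#'   `reduction` (fraction of LDLC removed, in \[0, 1)).
#' @export
default_statin_table <- function() {
  data.frame(
    statin = rep(c("atorvastatin", "rosuvastatin", "simvastatin"),
                 times = c(4, 4, 4)),
    dose = c(10, 20, 40, 80,
             5, 10, 20, 40,
             10, 20, 40, 80),
    reduction = c(0.37, 0.43, 0.49, 0.55,
                  0.38, 0.43, 0.48, 0.53,
                  0.27, 0.32, 0.37, 0.42),
    stringsAsFactors = FALSE
  )
}

#' Estimate pre-treatment LDL cholesterol
#'
#' Back-calculates the LDLC concentration an individual would have off
#' statins: `eLDLC = measured / (1 - r)` where `r` is the expected
#' fractional reduction for the statin type and dose; `r = 0` (identity)
#' for untreated individuals. Individuals on combination lipid-lowering
#' therapy are handled with the statin-only factor unless the table
#' provides a combination entry.
#'
#' @param ldlc Measured LDLC (mg/dL), vectorised.
#' @param statin Statin type (character; NA or `"none"` for untreated).
#' @param dose Daily dose in mg (NA for untreated).
#' @param table Correction table; default [default_statin_table()].
#' @return Numeric vector of eLDLC (mg/dL). Unknown statin/dose
#'   combinations give NA with a warning (the record should be excluded).
#' @export
estimate_pretreatment_ldlc <- function(ldlc, statin = NA, dose = NA,
                                       table = default_statin_table()) {
  stopifnot(all(is.na(ldlc) | ldlc > 0), all(table$reduction >= 0),
            all(table$reduction < 1))
  n <- length(ldlc)
  statin <- rep_len(as.character(statin), n)
  dose <- rep_len(as.numeric(dose), n)
  untreated <- is.na(statin) | statin %in% c("none", "")
  key <- paste(statin, dose)
  r <- table$reduction[match(key, paste(table$statin, table$dose))]
  r[untreated] <- 0
  unknown <- !untreated & is.na(r)
  if (any(unknown)) {
    warning(sprintf("%d record(s) with unknown statin/dose (%s): eLDLC set to NA",
                    sum(unknown),
                    paste(utils::head(unique(key[unknown]), 3), collapse = "; ")))
  }
  ldlc / (1 - r)
}

#' Default DLCN point table
#'
#' The standard Dutch Lipid Clinic Network items and points, excluding the
#' genetic (DNA) criterion. LDLC bands are on the pre-treatment (estimated)
#' concentration in mmol/L. Within the family-history, clinical-history and
#' physical-examination sections the highest applicable item counts.
#'
#' @return A list with `items` (data.frame: section, item, points) and
#'   `ldlc_bands` (data.frame: lower bound in mmol/L, points).
#' @export
default_dlcn_table <- function() {
  list(
    items = data.frame(
      section = c("family", "family",
                  "clinical", "clinical",
                  "physical", "physical"),
      item = c("relative_premature_cvd", "relative_high_ldl_or_stigmata",
               "premature_cad", "premature_cerebral_peripheral",
               "tendon_xanthomata", "arcus_cornealis_under_45"),
      points = c(1L, 2L, 2L, 1L, 6L, 4L),
      stringsAsFactors = FALSE
    ),
    ldlc_bands = data.frame(
      lower_mmol = c(8.5, 6.5, 5.0, 4.0),
      points = c(8L, 5L, 3L, 1L),
      stringsAsFactors = FALSE
    )
  )
}

#' Dutch Lipid Clinic Network score without genetic items
#'
#' Sums family-history, clinical-history, physical-examination and
#' LDLC-band points; within each non-LDL section the maximum applicable
#' item is taken (standard DLCN practice). The LDLC band is evaluated on
#' the estimated pre-treatment concentration converted to mmol/L. Genetic
#' items contribute 0 by construction. Absent item flags score 0.
#'
#' @param eldlc Estimated pre-treatment LDLC in mg/dL, vectorised.
#' @param items A data.frame (or list) of logical item flags named as in
#'   [default_dlcn_table()] `items$item`; missing columns are treated as
#'   all-FALSE.
#' @param table DLCN point table; default [default_dlcn_table()].
#' @return A data.frame with `points` (integer) and `category`
#'   (`"unlikely"` < 3, `"possible"` 3-5, `"probable"` 6-8,
#'   `"definite"` > 8).
#' @export
dlcn_score <- function(eldlc, items = NULL, table = default_dlcn_table()) {
  if (any(!is.na(eldlc) & eldlc < 0)) stop("negative eLDLC is invalid")
  n <- length(eldlc)
  it <- table$items
  flags <- matrix(FALSE, n, nrow(it),
                  dimnames = list(NULL, it$item))
  if (!is.null(items)) {
    items <- as.data.frame(items)
    for (cn in intersect(colnames(flags), names(items))) {
      v <- items[[cn]]
      flags[, cn] <- !is.na(v) & as.logical(v)
    }
  }
  section_pts <- rep(0L, n)
  for (sec in unique(it$section)) {
    rows <- which(it$section == sec)
    pts <- flags[, rows, drop = FALSE] %*% diag(it$points[rows], nrow = length(rows))
    section_pts <- section_pts + as.integer(apply(pts, 1, max))
  }
  mmol <- convert_ldl(eldlc, "mgdl")
  band <- rep(0L, n)
  bands <- table$ldlc_bands[order(-table$ldlc_bands$lower_mmol), ]
  for (i in seq_len(nrow(bands))) {
    hit <- band == 0L & !is.na(mmol) & mmol >= bands$lower_mmol[i]
    band[hit] <- bands$points[i]
  }
  points <- section_pts + band
  points[is.na(eldlc)] <- NA_integer_
  data.frame(points = points, category = dlcn_category(points),
             stringsAsFactors = FALSE)
}

#' DLCN probability category from points
#'
#' @param points Integer DLCN points.
#' @return Character: `"unlikely"` (< 3), `"possible"` (3-5),
#'   `"probable"` (6-8), `"definite"` (> 8).
#' @export
dlcn_category <- function(points) {
  cut(points, breaks = c(-Inf, 2, 5, 8, Inf),
      labels = c("unlikely", "possible", "probable", "definite")) |>
    as.character()
}

#' Assign analysis groups
#'
#' Healthy controls stay `HC`; cases are split at DLCN > 8 into `dFH`
#' (definite clinical FH) and `nFH`.
#'
#' @param case Logical vector (TRUE for a case).
#' @param dlcn_points Integer DLCN points (required for cases).
#' @return Character vector with levels `HC`, `nFH`, `dFH`.
#' @export
assign_groups <- function(case, dlcn_points) {
  stopifnot(length(case) == length(dlcn_points))
  out <- ifelse(!case, "HC", ifelse(dlcn_points > 8, "dFH", "nFH"))
  if (any(case & is.na(dlcn_points))) {
    stop("DLCN points must be available for every case")
  }
  out
}
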