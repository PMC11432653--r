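# Score definition: the per-SNP allele/contribution/weight contract for the
# 8-SNP LDLC polygenic scores, plus the APOE genotype -> weight map.

#' Default 8-SNP LDLC score definition
#'
#' Returns the default score definition used throughout the package: six
#' biallelic LDLC-affecting SNPs plus the APOE epsilon-genotype term derived
#' from rs429358 and rs7412. Each SNP carries the allele that is counted
#' towards the score ("minor" or "common"), its additive contribution
#' (+1 per counted allele) and its weight in mmol/L of LDLC per allele.
#'
#' For rs6511720, rs629301 and rs1800562 the minor allele is LDLC-lowering;
#' rather than subtracting protective alleles, the score counts the
#' corresponding COMMON allele as the risk allele, so every per-allele term
#' is non-negative and the full range of the weighted score is
#' \[-0.800, 1.482\] mmol/L (the negative bound coming from the APOE
#' epsilon2/epsilon2 weight).
#'
#' APOE weights per genotype (mmol/L): e2e2 -0.800, e2e3 -0.400,
#' e2e4 -0.270, e3e3 0, e3e4 +0.130, e4e4 +0.260; additive contributions
#' -2, -1, 0, 0, +1, +2 respectively.
#'
#' rs676210 (APOB) is listed among the assayed loci but is excluded from
#' scoring by default because of its strong linkage disequilibrium with
#' rs1367117; it can be re-enabled via `include_rs676210` (it then inherits
#' a zero weight unless one is supplied in a custom definition).
#'
#' @param include_rs676210 Logical; keep rs676210 as a scored SNP (weight 0).
#' @return A list of class `ldlprs_score_definition` with elements `snps`
#'   (data.frame), `apoe` (data.frame), `apoe_snps` (character) and
#'   `excluded` (character).
#' @export
default_score_definition <- function(include_rs676210 = FALSE) {
  snps <- data.frame(
    rsid          = c("rs6511720", "rs629301", "rs1367117",
                      "rs4299376", "rs1800562", "rs2479409"),
    gene          = c("LDLR", "CELSR2", "APOB", "ABCG8", "HFE", "PCSK9"),
    minor_allele  = c("T", "G", "A", "G", "A", "G"),
    common_allele = c("G", "T", "G", "T", "G", "A"),
    counted_allele = c("common", "common", "minor",
                       "minor", "common", "minor"),
    aprs_per_allele = c(1L, 1L, 1L, 1L, 1L, 1L),
    weight_per_allele = c(0.180, 0.146, 0.105, 0.071, 0.057, 0.052),
    stringsAsFactors = FALSE
  )
  excluded <- "rs676210"
  if (include_rs676210) {
    snps <- rbind(snps, data.frame(
      rsid = "rs676210", gene = "APOB", minor_allele = "A",
      common_allele = "G", counted_allele = "minor",
      aprs_per_allele = 1L, weight_per_allele = 0,
      stringsAsFactors = FALSE))
    excluded <- character(0)
  }
  apoe <- data.frame(
    genotype = c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4"),
    aprs     = c(-2L, -1L, 0L, 0L, 1L, 2L),
    weight   = c(-0.800, -0.400, -0.270, 0, 0.130, 0.260),
    stringsAsFactors = FALSE
  )
  def <- list(snps = snps, apoe = apoe,
              apoe_snps = c(rs429358 = "C", rs7412 = "T"),
              excluded = excluded)
  class(def) <- "ldlprs_score_definition"
  validate_score_definition(def)
}

#' Validate a score definition
#'
#' @param def A score definition as returned by [default_score_definition()]
#'   or [read_score_definition()].
#' @return The definition, invisibly checked; stops on contract violations.
#' @export
validate_score_definition <- function(def) {
  stopifnot(is.list(def), !is.null(def$snps), !is.null(def$apoe))
  snps <- def$snps
  need <- c("rsid", "minor_allele", "common_allele", "counted_allele",
            "aprs_per_allele", "weight_per_allele")
  if (!all(need %in% names(snps))) {
    stop("score definition snps table is missing columns: ",
         paste(setdiff(need, names(snps)), collapse = ", "))
  }
  if (anyDuplicated(snps$rsid)) stop("duplicated rsid in score definition")
  if (any(snps$minor_allele == snps$common_allele)) {
    stop("minor and common allele must differ for every SNP")
  }
  if (!all(snps$counted_allele %in% c("minor", "common"))) {
    stop("counted_allele must be 'minor' or 'common'")
  }
  apoe <- def$apoe
  want <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
  if (!setequal(apoe$genotype, want)) {
    stop("APOE map must cover exactly the six epsilon genotypes")
  }
  def
}

#' Read / write a score definition as YAML
#'
#' The on-disk format mirrors the definition column-for-column so that
#' alternative published score families (6- or 12-SNP variants) can be
#' expressed without touching code.
#'
#' @param path File path.
#' @return `read_score_definition()` returns the validated definition;
#'   `write_score_definition()` returns `path` invisibly.
#' @export
read_score_definition <- function(path) {
  y <- yaml::read_yaml(path)
  snps <- do.call(rbind, lapply(y$snps, function(s) {
    data.frame(rsid = s$rsid, gene = s$gene %||% NA_character_,
               minor_allele = s$minor_allele, common_allele = s$common_allele,
               counted_allele = s$counted_allele,
               aprs_per_allele = as.integer(s$aprs_per_allele),
               weight_per_allele = as.numeric(s$weight_per_allele),
               stringsAsFactors = FALSE)
  }))
  apoe <- do.call(rbind, lapply(y$apoe, function(a) {
    data.frame(genotype = a$genotype, aprs = as.integer(a$aprs),
               weight = as.numeric(a$weight), stringsAsFactors = FALSE)
  }))
  def <- list(snps = snps, apoe = apoe,
              apoe_snps = c(rs429358 = "C", rs7412 = "T"),
              excluded = as.character(y$excluded %||% character(0)))
  class(def) <- "ldlprs_score_definition"
  validate_score_definition(def)
}

#' @rdname read_score_definition
#' @param def A score definition.
#' @export
write_score_definition <- function(def, path) {
  validate_score_definition(def)
  y <- list(
    snps = lapply(seq_len(nrow(def$snps)), function(i) as.list(def$snps[i, ])),
    apoe = lapply(seq_len(nrow(def$apoe)), function(i) as.list(def$apoe[i, ])),
    excluded = def$excluded
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.ldlprs_score_definition <- function(x, ...) {
  cat("LDLC polygenic score definition:", nrow(x$snps),
      "SNPs + APOE genotype term\n")
  print(x$snps, row.names = FALSE)
  cat("APOE genotype map:\n")
  print(x$apoe, row.names = FALSE)
  if (length(x$excluded)) {
    cat("Accepted in input but excluded from scoring:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
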