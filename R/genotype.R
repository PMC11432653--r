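# Genotype containers and readers. Dosage convention: the per-locus count of
# the MINOR allele as fixed by the score definition (not the VCF ALT allele).

#' Build a genotype table
#'
#' A genotype table is a data.frame with an `id` column of individual
#' identifiers and one integer column per rsID holding the count of the
#' locus's minor allele (0, 1, 2 or NA for missing).
#'
#' @param id Character vector of individual identifiers.
#' @param dosage Data frame or matrix of minor-allele counts, one column per
#'   rsID.
#' @return A data.frame of class `ldlprs_genotypes`.
#' @export
genotype_table <- function(id, dosage) {
  dosage <- as.data.frame(dosage)
  stopifnot(length(id) == nrow(dosage))
  for (cn in names(dosage)) check_dosage(dosage[[cn]], cn)
  out <- cbind(data.frame(id = as.character(id), stringsAsFactors = FALSE),
               dosage)
  class(out) <- c("ldlprs_genotypes", "data.frame")
  out
}

#' Read genotypes from CSV
#'
#' Expects one row per individual; an `id` column (or first column) of
#' identifiers and one column per rsID with values in \{0, 1, 2\}; empty
#' cells are missing. Values are minor-allele counts.
#'
#' @param path CSV file path.
#' @return A genotype table (see [genotype_table()]).
#' @export
read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- if ("id" %in% names(d)) "id" else names(d)[1]
  dos <- d[setdiff(names(d), idcol)]
  dos[] <- lapply(dos, function(x) {
    x[x %in% c("", "NA")] <- NA
    as.integer(x)
  })
  genotype_table(d[[idcol]], dos)
}

#' Write genotypes to CSV
#'
#' @param g A genotype table.
#' @param path Output path.
#' @export
write_genotypes_csv <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads the assayed loci from a VCF (v4.x, plain or bgzipped) and converts
#' GT fields to minor-allele counts. REF/ALT orientation is reconciled
#' against the score definition: when the VCF ALT is the definition's minor
#' allele, the ALT count is used directly; when REF/ALT are swapped relative
#' to the definition the dosage is flipped with a warning. Loci whose
#' alleles match neither orientation are dropped with a warning.
#'
#' @param path VCF file path.
#' @param definition Score definition used to fix allele identity; defaults
#'   to [default_score_definition()] plus the two APOE SNPs.
#' @return A genotype table keyed by rsID.
#' @export
read_genotypes_vcf <- function(path, definition = default_score_definition()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF genotypes requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_map <- rbind(
    definition$snps[, c("rsid", "minor_allele", "common_allele")],
    data.frame(rsid = c("rs429358", "rs7412"),
               minor_allele = c("C", "T"),
               common_allele = c("T", "C"), stringsAsFactors = FALSE),
    if (length(definition$excluded))
      data.frame(rsid = definition$excluded,
                 minor_allele = "A", common_allele = "G",
                 stringsAsFactors = FALSE)
  )
  ids <- colnames(gt)
  dos <- list()
  for (i in seq_len(nrow(fix))) {
    rsid <- fix$ID[i]
    m <- allele_map[allele_map$rsid == rsid, ]
    if (nrow(m) == 0) next
    alt_count <- count_alt_alleles(gt[i, ])
    if (identical(fix$ALT[i], m$minor_allele) &&
        identical(fix$REF[i], m$common_allele)) {
      dos[[rsid]] <- alt_count
    } else if (identical(fix$REF[i], m$minor_allele) &&
               identical(fix$ALT[i], m$common_allele)) {
      warning(sprintf("%s: REF/ALT swapped relative to score definition; flipping dosage", rsid))
      dos[[rsid]] <- 2L - alt_count
    } else {
      warning(sprintf("%s: VCF alleles (%s/%s) do not match score definition; locus dropped",
                      rsid, fix$REF[i], fix$ALT[i]))
    }
  }
  genotype_table(ids, as.data.frame(dos, check.names = FALSE))
}

# "0/1", "1|1", "./." ... -> count of ALT alleles
count_alt_alleles <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }, integer(1), USE.NAMES = FALSE)
}

#' Call APOE epsilon genotype from the two APOE SNPs
#'
#' Maps unphased genotypes at rs429358 (count of C) and rs7412 (count of T)
#' to the six epsilon genotypes, using the standard haplotype table
#' e2 = (T, T), e3 = (T, C), e4 = (C, C) over (rs429358, rs7412). The
#' double heterozygote C/T + C/T is ambiguous between e2e4 and the
#' vanishingly rare e1e3 and is called `e2e4` by convention. Combinations
#' requiring an e1 (C, T) haplotype — rs429358 C/C with any rs7412 T —
#' cannot arise from the six recognised genotypes and return NA with a
#' warning.
#'
#' @param g429358 Dosage of C at rs429358 (0, 1, 2 or NA), vectorised.
#' @param g7412 Dosage of T at rs7412 (0, 1, 2 or NA), vectorised.
#' @return Character vector of epsilon genotypes
#'   (`"e2e2" ... "e4e4"`), NA where a dosage is missing or inconsistent.
#' @export
call_apoe_genotype <- function(g429358, g7412) {
  check_dosage(g429358, "rs429358"); check_dosage(g7412, "rs7412")
  stopifnot(length(g429358) == length(g7412))
  key <- paste(g429358, g7412, sep = "_")
  map <- c("0_0" = "e3e3", "0_1" = "e2e3", "0_2" = "e2e2",
           "1_0" = "e3e4", "1_1" = "e2e4", "2_0" = "e4e4")
  out <- unname(map[key])
  impossible <- !is.na(g429358) & !is.na(g7412) & is.na(out)
  if (any(impossible)) {
    warning(sprintf(
      "%d APOE genotype(s) require an epsilon-1 haplotype (rs429358 C with rs7412 T) and were set to NA",
      sum(impossible)))
  }
  out
}

# Inverse map used by the synthetic generator: epsilon genotype ->
# (rs429358 C-count, rs7412 T-count).
apoe_to_dosages <- function(genotype) {
  m <- rbind(e2e2 = c(0L, 2L), e2e3 = c(0L, 1L), e2e4 = c(1L, 1L),
             e3e3 = c(0L, 0L), e3e4 = c(1L, 0L), e4e4 = c(2L, 0L))
  bad <- !genotype %in% rownames(m)
  if (any(bad)) stop("unknown APOE genotype: ", paste(unique(genotype[bad]), collapse = ", "))
  out <- m[genotype, , drop = FALSE]
  colnames(out) <- c("rs429358", "rs7412")
  rownames(out) <- NULL
  out
}
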