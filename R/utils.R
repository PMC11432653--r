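# Shared small helpers: unit conversion, seed substreams, input checks.

#' Convert LDL cholesterol between mg/dL and mmol/L
#'
#' Uses the conventional conversion factor 38.67 mg/dL per mmol/L for
#' cholesterol. Round-trips to within 0.01 mg/dL.
#'
#' @param x Numeric vector of concentrations.
#' @param from Source unit, `"mgdl"` or `"mmol"`.
#' @return Numeric vector in the other unit.
#' @export
convert_ldl <- function(x, from = c("mgdl", "mmol")) {
  from <- match.arg(from)
  if (from == "mgdl") x / 38.67 else x * 38.67
}

# Derive a reproducible per-stage seed from a base seed. Offsets are small
# fixed integers per pipeline stage; result stays below 2^31.
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assert a dosage vector is in {0,1,2,NA}
check_dosage <- function(x, what = "dosage") {
  bad <- !is.na(x) & !(x %in% c(0, 1, 2))
  if (any(bad)) {
    stop(sprintf("%s values must be 0, 1, 2 or NA; offending values: %s",
                 what, paste(utils::head(unique(x[bad]), 5), collapse = ", ")))
  }
  invisible(x)
}
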