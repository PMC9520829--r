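#' COPD case definition for administrative claims
#'
#' A case definition holds the diagnosis code sets and minimum event counts
#' used to identify COPD from physician billing claims and hospital discharge
#' abstracts. The default follows the validated Ontario claims algorithm: a
#' patient qualifies on 1 or more billing claims and/or 1 or more hospital
#' discharges carrying a COPD diagnosis. Matching is prefix-based, so `"J44"`
#' matches `"J44.1"`; administrative codes carry sub-digits.
#'
#' The default ICD-9 set is `c("491", "492", "496")` (chronic bronchitis,
#' emphysema, chronic airway obstruction) and the ICD-10 set
#' `c("J41", "J42", "J43", "J44")`. Alternative sets (for example a
#' three-character OHIP dialect) can be supplied directly.
#'
#' @param icd9_codes Character vector of ICD-9 / OHIP diagnosis code prefixes.
#' @param icd10_codes Character vector of ICD-10 diagnosis code prefixes.
#' @param min_claims Minimum number of qualifying billing claims.
#' @param min_discharges Minimum number of qualifying hospital discharges.
#'
#' @return An object of class `case_definition`: a list with elements
#'   `icd9_codes`, `icd10_codes`, `min_claims`, `min_discharges` and
#'   `combination = "any-of"` (a patient qualifies when either threshold
#'   is met).
#' @examples
#' copd_case_definition()
#' @export
copd_case_definition <- function(icd9_codes = c("491", "492", "496"),
                                 icd10_codes = c("J41", "J42", "J43", "J44"),
                                 min_claims = 1L,
                                 min_discharges = 1L) {
  icd9_codes <- as.character(icd9_codes %||% character())
  icd10_codes <- as.character(icd10_codes %||% character())
  if (length(icd9_codes) + length(icd10_codes) == 0L) {
    abort("At least one of `icd9_codes`, `icd10_codes` must be non-empty.")
  }
  check_positive_scalar(min_claims, "min_claims", integer = TRUE)
  check_positive_scalar(min_discharges, "min_discharges", integer = TRUE)
  structure(
    list(icd9_codes = icd9_codes, icd10_codes = icd10_codes,
         min_claims = as.integer(min_claims),
         min_discharges = as.integer(min_discharges),
         combination = "any-of"),
    class = "case_definition"
  )
}

#' @export
print.case_definition <- function(x, ...) {
  cat("<case_definition>\n")
  cat("  ICD-9 prefixes: ", paste(x$icd9_codes, collapse = ", "), "\n", sep = "")
  cat("  ICD-10 prefixes:", paste(x$icd10_codes, collapse = ", "), "\n")
  cat("  qualifies on >=", x$min_claims, "claim(s) and/or >=",
      x$min_discharges, "discharge(s)\n")
  invisible(x)
}

all_code_prefixes <- function(case_def) {
  c(case_def$icd9_codes, case_def$icd10_codes)
}

#' Match diagnosis codes against a case definition (prefix match)
#'
#' @param codes Character vector of diagnosis codes.
#' @param case_def A [copd_case_definition()] object, or a character vector of
#'   prefixes.
#' @return Logical vector: does each code start with any prefix in the
#'   definition? `NA` and empty codes return `FALSE`.
#' @export
matches_case_definition <- function(codes, case_def = copd_case_definition()) {
  prefixes <- if (inherits(case_def, "case_definition")) {
    all_code_prefixes(case_def)
  } else {
    as.character(case_def)
  }
  codes <- as.character(codes)
  out <- rep(FALSE, length(codes))
  valid <- !is.na(codes) & nzchar(codes)
  for (p in prefixes) {
    out[valid] <- out[valid] | startsWith(codes[valid], p)
  }
  out
}
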