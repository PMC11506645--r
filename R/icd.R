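#' Diagnosis-code predicate configuration
#'
#' Builds the configuration object that decides which diagnosis codes count
#' as Down syndrome (DS) codes. Matching is prefix-based on normalized codes
#' (upper case, no decimal point), separately per ICD revision: the defaults
#' are the DS rubric 758.0 in ICD-9-CM and the Q90 family (Q90.0-Q90.9) in
#' ICD-10-CM. Supplying other prefixes retargets the whole pipeline at a
#' different phenotype without touching the classification logic.
#'
#' @param icd9_codes character vector of ICD-9 code prefixes (dotted or
#'   undotted; normalized internally). May be empty, in which case no ICD-9
#'   code ever matches.
#' @param icd10_codes character vector of ICD-10 code prefixes, likewise.
#' @return An object of class `ds_code_config`: a list with normalized
#'   `icd9` and `icd10` prefix vectors.
#' @examples
#' cfg <- ds_code_config()
#' is_ds_code("758.0", 9, cfg)
#' is_ds_code("Q90.1", 10, cfg)
#' @export
ds_code_config <- function(icd9_codes = "758.0", icd10_codes = "Q90") {
  norm <- function(x, what) {
    x <- as.character(x)
    if (length(x) == 0L) return(character(0))
    x <- normalize_icd(x)
    x
  }
  structure(list(icd9 = norm(icd9_codes), icd10 = norm(icd10_codes)),
            class = "ds_code_config")
}

#' @export
print.ds_code_config <- function(x, ...) {
  cat("DS code predicate\n")
  cat("  ICD-9 prefixes: ", if (length(x$icd9)) paste(x$icd9, collapse = ", ") else "(none)", "\n", sep = "")
  cat("  ICD-10 prefixes: ", if (length(x$icd10)) paste(x$icd10, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' Normalize ICD code strings
#'
#' Claims extracts carry both dotted ("758.0") and undotted ("7580") code
#' dialects, in mixed case and with stray whitespace. Normalization trims
#' whitespace, upper-cases, and removes the decimal point; nothing else is
#' altered. The operation is idempotent.
#'
#' @param codes character vector of raw code strings.
#' @return character vector of normalized codes, same length.
#' @examples
#' normalize_icd(c("758.0", "q90.9", " 486 "))
#' @export
normalize_icd <- function(codes) {
  codes <- as.character(codes)
  out <- gsub(".", "", toupper(trimws(codes)), fixed = TRUE)
  bad <- is.na(codes) | !nzchar(out)
  if (any(bad)) {
    stop("invalid ICD code: empty or blank at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Test diagnosis codes for DS-code membership
#'
#' A code matches when its normalized form starts with any configured prefix
#' for its own ICD revision; revisions are never cross-matched (ICD-9 "7580"
#' and ICD-10 "Q90" live in disjoint namespaces).
#'
#' @param codes character vector of raw code strings.
#' @param icd_version integer vector (9 or 10), recycled against `codes`.
#' @param config a [ds_code_config()] object.
#' @return logical vector, same length as `codes`.
#' @examples
#' is_ds_code(c("758.0", "758.1", "Q90.1"), c(9, 9, 10))
#' @export
is_ds_code <- function(codes, icd_version, config = ds_code_config()) {
  stopifnot(inherits(config, "ds_code_config"))
  icd_version <- as.integer(icd_version)
  if (!all(icd_version %in% c(9L, 10L))) {
    stop("icd_version must be 9 or 10", call. = FALSE)
  }
  norm <- normalize_icd(codes)
  if (length(icd_version) == 1L) icd_version <- rep(icd_version, length(norm))
  stopifnot(length(icd_version) == length(norm))
  match_prefix <- function(x, prefixes) {
    if (length(prefixes) == 0L || length(x) == 0L) return(rep(FALSE, length(x)))
    Reduce(`|`, lapply(prefixes, function(p) startsWith(x, p)))
  }
  out <- logical(length(norm))
  i9 <- icd_version == 9L
  out[i9] <- match_prefix(norm[i9], config$icd9)
  out[!i9] <- match_prefix(norm[!i9], config$icd10)
  out
}
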