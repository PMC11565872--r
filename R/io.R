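# Reading and writing GWAS summary-statistics tables.
#
# Published summary statistics come in hundreds of header dialects; the
# reader works against a canonical, GWAS-SSF-style header set and a column
# map translating the file's actual headers onto it. Fields that are absent
# but derivable (OR from beta; SE from beta and p-value) are filled in with
# provenance flags, rows that fail type coercion are collected into a
# rejects table instead of failing the read.

CANONICAL_FIELDS <- c("chromosome", "base_pair_location", "effect_allele",
                      "other_allele", "odds_ratio", "beta", "standard_error",
                      "p_value", "effect_allele_frequency")
MISSING_TOKENS <- c("NA", "", "NaN", ".")

#' Column map for a summary-statistics dialect
#'
#' Maps canonical field names to the column headers of a particular file.
#' Canonical names follow the GWAS-SSF convention: `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`, `odds_ratio`,
#' `beta`, `standard_error`, `p_value`, `effect_allele_frequency`.
#'
#' @param ... Named overrides, e.g. `odds_ratio = "OR"`, `p_value = "P"`.
#'   Set a field to `NA` to declare it absent from the file.
#' @param delim Field delimiter.
#' @return An object of class `"column_map"`.
#' @examples
#' column_map(odds_ratio = "OR", p_value = "P", delim = ",")
#' @export
column_map <- function(..., delim = "\t") {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), CANONICAL_FIELDS)
  if (length(unknown) > 0)
    stop("unknown canonical field(s): ", paste(unknown, collapse = ", "))
  map <- stats::setNames(as.list(CANONICAL_FIELDS), CANONICAL_FIELDS)
  map[names(overrides)] <- overrides
  structure(list(map = map, delim = delim), class = "column_map")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file through a [column_map()], coerces fields to
#' canonical types, derives the odds ratio from beta (`exp(beta)`) and the
#' standard error from beta and p-value ([se_from_beta_p()]) where the
#' primary fields are missing, and collects rows failing coercion into a
#' rejects table rather than failing. Recognized missing-value tokens:
#' `"NA"`, `""`, `"NaN"`, `"."`.
#'
#' @param path Path to the file.
#' @param map A [column_map()]; defaults to canonical headers, tab
#'   delimited.
#' @param required Canonical fields that must be present as columns.
#' @return A `data.frame` with canonical columns plus logical provenance
#'   columns `or_derived` and `se_derived`; the rejects table (`data.frame`
#'   with `line` and `reason`) is attached as attribute `"rejects"`.
#' @export
read_sumstats <- function(path,
                          map = column_map(),
                          required = c("chromosome", "base_pair_location",
                                       "effect_allele", "other_allele")) {
  stopifnot(inherits(map, "column_map"))
  if (!file.exists(path))
    stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = map$delim,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0)
    stop("empty summary-statistics file: ", path)

  get_col <- function(field) {
    header <- map$map[[field]]
    if (is.null(header) || is.na(header) || !header %in% names(raw))
      return(NULL)
    x <- raw[[header]]
    x[x %in% MISSING_TOKENS] <- NA
    x
  }
  for (field in required) {
    header <- map$map[[field]]
    if (is.null(get_col(field)))
      stop("required column '", header, "' (canonical '", field,
           "') not found in ", path)
  }

  n <- nrow(raw)
  out <- data.frame(row.names = seq_len(n))
  out$chromosome <- get_col("chromosome")
  pos_chr <- get_col("base_pair_location")
  pos <- suppressWarnings(as.numeric(pos_chr))
  out$base_pair_location <- as.integer(pos)
  out$effect_allele <- toupper(get_col("effect_allele"))
  out$other_allele <- toupper(get_col("other_allele"))
  num_or_na <- function(field) {
    x <- get_col(field)
    if (is.null(x)) rep(NA_real_, n) else suppressWarnings(as.numeric(x))
  }
  out$odds_ratio <- num_or_na("odds_ratio")
  out$beta <- num_or_na("beta")
  out$standard_error <- num_or_na("standard_error")
  out$p_value <- num_or_na("p_value")
  out$effect_allele_frequency <- num_or_na("effect_allele_frequency")

  # row-level validation -> rejects, not failure
  reason <- rep(NA_character_, n)
  bad_pos <- !is.na(pos_chr) & (is.na(pos) | pos <= 0 | pos != floor(pos))
  reason[bad_pos] <- "invalid position"
  bad_allele <- !grepl("^[ACGT]+$", out$effect_allele) |
    !grepl("^[ACGT]+$", out$other_allele)
  reason[is.na(reason) & bad_allele] <- "invalid allele"
  no_effect <- is.na(out$odds_ratio) & is.na(out$beta)
  reason[is.na(reason) & no_effect] <- "no odds ratio or beta"
  keep <- is.na(reason)
  rejects <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                        reason = reason[!keep])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  # derivations with provenance
  out$or_derived <- is.na(out$odds_ratio) & !is.na(out$beta)
  out$odds_ratio[out$or_derived] <- exp(out$beta[out$or_derived])
  can_derive_se <- is.na(out$standard_error) & !is.na(out$beta) &
    out$beta != 0 & !is.na(out$p_value) & out$p_value > 0 & out$p_value < 1
  out$se_derived <- can_derive_se
  if (any(can_derive_se))
    out$standard_error[can_derive_se] <-
      se_from_beta_p(out$beta[can_derive_se], out$p_value[can_derive_se])

  if (nrow(rejects) > 0)
    message(nrow(rejects), " row(s) rejected while reading ", path)
  attr(out, "rejects") <- rejects
  out
}

#' Append reconstruction estimates to a summary-statistics table and write
#'
#' Preserves the original columns and appends the estimate columns: the
#' total-AF route appends `AF_case`, `AF_control`; the SE route `MAF_case`,
#' `MAF_control`, `MAF_total`; bias-corrected estimates `MAF_case_adj`,
#' `MAF_control_adj`, `MAF_total_adj`. Missing estimates are written as
#' `"NA"`.
#'
#' @param records The original records (`data.frame`).
#' @param estimates A `data.frame` of estimate columns aligned with
#'   `records` (same row count and order).
#' @param path Output path (tab separated).
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, estimates, path) {
  if (nrow(records) != nrow(estimates))
    stop("internal consistency error: ", nrow(records), " records but ",
         nrow(estimates), " estimate rows")
  renames <- c(af_case = "AF_case", af_control = "AF_control",
               maf_case = "MAF_case", maf_control = "MAF_control",
               maf_total = "MAF_total", maf_case_adj = "MAF_case_adj",
               maf_control_adj = "MAF_control_adj",
               maf_total_adj = "MAF_total_adj")
  hit <- names(estimates) %in% names(renames)
  names(estimates)[hit] <- renames[names(estimates)[hit]]
  out <- cbind(records, estimates)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
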