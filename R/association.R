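#' @importFrom stats pnorm qnorm rnorm runif median setNames
#' @importFrom utils modifyList
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct an instrument set
#'
#' An instrument set bundles the per-SNP summary associations of one trait
#' with its metadata: trait name, measurement type and unit label. It is the
#' basic currency of the package — exposures, mediators and outcomes are all
#' represented this way.
#'
#' @param trait_name Trait label, e.g. `"BMI"`.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits are assumed
#'   to carry effects on the log-odds scale.
#' @param unit_label Unit of the per-allele effect, e.g. `"SD"` or
#'   `"log-odds"`.
#' @param records Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` (missing optional
#'   columns are filled with `NA`).
#' @param exclusions Data frame of rows rejected during validation, with
#'   columns `variant_id` and `reason`.
#'
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(trait_name, trait_type = c("continuous", "binary"),
                           unit_label = "SD", records,
                           exclusions = empty_exclusions()) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("eaf", "pvalue", "n")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("instrument_set records lack columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in instrument set for trait '", trait_name, "'")
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         unit_label = unit_label,
         records = records[, c("variant_id", "effect_allele", "other_allele",
                               "eaf", "beta", "se", "pvalue", "n")],
         exclusions = exclusions),
    class = "instrument_set")
}

empty_exclusions <- function() {
  data.frame(variant_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s (%s, %s): %d SNPs, %d excluded\n",
              x$trait_name, x$trait_type, x$unit_label,
              nrow(x$records), nrow(x$exclusions)))
  invisible(x)
}

# Validate raw rows; returns list(records, exclusions). Rows failing an
# invariant are routed to the exclusion report, never silently dropped.
validate_association_rows <- function(df) {
  df$effect_allele <- toupper(trimws(as.character(df$effect_allele)))
  df$other_allele <- toupper(trimws(as.character(df$other_allele)))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$variant_id <- as.character(df$variant_id)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    ifelse(bad & is.na(reason), why, reason)
  }
  reason <- flag(is.na(df$variant_id) | df$variant_id == "", "missing_variant_id")
  reason <- flag(!(df$effect_allele %in% VALID_ALLELES) |
                   !(df$other_allele %in% VALID_ALLELES), "malformed_allele")
  reason <- flag(df$effect_allele == df$other_allele, "identical_alleles")
  reason <- flag(is.na(df$beta), "missing_beta")
  reason <- flag(is.na(df$se) | df$se <= 0, "nonpositive_se")
  reason <- flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf_out_of_range")
  reason <- flag(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1),
                 "pvalue_out_of_range")

  bad <- !is.na(reason)
  list(records = df[!bad, , drop = FALSE],
       exclusions = data.frame(variant_id = df$variant_id[bad],
                               reason = reason[bad],
                               stringsAsFactors = FALSE))
}

#' Read a GWAS summary-association table
#'
#' Reads a tab- or comma-separated flat file of per-SNP summary statistics
#' (one row per variant) into an [instrument_set]. Separator is detected
#' automatically. Rows violating basic invariants (non-positive SE, malformed
#' alleles, allele frequency outside (0,1), ...) are routed to the exclusion
#' report rather than silently dropped.
#'
#' @param path Path to the file. Must have a header row.
#' @param column_map Named character vector remapping logical column names to
#'   the file's column names, e.g.
#'   `c(variant_id = "SNP", effect_allele = "A1", other_allele = "A2",
#'      beta = "b", se = "se")`. Logical names: `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (required); `eaf`, `pvalue`, `n` (optional).
#'   `NULL` means the file already uses the logical names.
#' @param trait_name,trait_type,unit_label Trait metadata, see
#'   [instrument_set()].
#'
#' @return An [instrument_set]; rejected rows are in `$exclusions`.
#' @export
read_association_table <- function(path, column_map = NULL,
                                   trait_name = "trait",
                                   trait_type = c("continuous", "binary"),
                                   unit_label = "SD") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("cannot read association table: ", path)
  raw <- data.table::fread(path, data.table = FALSE, colClasses = list(
    character = 1L))
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop("column_map refers to columns absent from ", path, ": ",
           paste(absent, collapse = ", "))
    }
    for (logical_name in names(column_map)) {
      names(raw)[names(raw) == column_map[[logical_name]]] <- logical_name
    }
  }
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("association table ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("eaf", "pvalue", "n")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_real_
  }
  parts <- validate_association_rows(
    raw[, c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "pvalue", "n")])
  instrument_set(trait_name, trait_type, unit_label,
                 records = parts$records, exclusions = parts$exclusions)
}

#' Write an instrument set to a TSV file
#'
#' Writes the records of an [instrument_set] in the same dialect that
#' [read_association_table()] reads, so a write-then-read round trip preserves
#' all numeric fields at full double precision.
#'
#' @param x An [instrument_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  stopifnot(inherits(x, "instrument_set"))
  df <- x$records
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
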