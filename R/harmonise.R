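is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Align one non-exposure record to the exposure orientation of a single SNP.
# Returns list(status = "aligned"|"flip"|reason-string). Palindromic SNPs
# cannot be oriented from allele labels alone (a strand flip looks like an
# allele swap), so under drop_ambiguous we fall back on allele-frequency
# concordance outside the ambiguity window.
align_record <- function(exp_ea, exp_oa, exp_eaf,
                         out_ea, out_oa, out_eaf,
                         palindrome_policy, eaf_window) {
  pal <- is_palindromic(exp_ea, exp_oa)
  same <- out_ea == exp_ea & out_oa == exp_oa
  swapped <- out_ea == exp_oa & out_oa == exp_ea
  if (!same && !swapped) return("allele_mismatch")

  if (pal) {
    if (palindrome_policy == "drop_all") return("palindromic")
    if (palindrome_policy == "drop_ambiguous") {
      ambiguous <- function(f) {
        is.na(f) || (f > eaf_window[1] && f < eaf_window[2])
      }
      if (ambiguous(exp_eaf) || ambiguous(out_eaf)) {
        return("palindromic_ambiguous")
      }
      # Label-based alignment first, then check the aligned outcome frequency
      # agrees in side-of-0.5 with the exposure; a disagreement means the two
      # files used opposite strands, which for a palindrome is a hidden swap.
      aligned_eaf <- if (same) out_eaf else 1 - out_eaf
      freq_concordant <- (exp_eaf < 0.5) == (aligned_eaf < 0.5)
      if (same) {
        return(if (freq_concordant) "aligned" else "flip")
      }
      return(if (freq_concordant) "flip" else "aligned")
    }
    # policy "keep": trust allele labels like any other SNP
  }
  if (same) "aligned" else "flip"
}

#' Harmonise exposure, outcome (and mediator) associations
#'
#' Matches SNPs across instrument sets by variant id and re-orients every
#' association to the exposure's effect allele. When the outcome record's
#' effect/other alleles are swapped relative to the exposure, the outcome beta
#' sign is flipped and its effect-allele frequency replaced by `1 - eaf`.
#' Palindromic SNPs (A/T or C/G) are handled per `palindrome_policy`. Every
#' input SNP of the exposure set appears exactly once across the retained rows
#' and the exclusion log.
#'
#' @param exposure [instrument_set] providing the instruments and the
#'   reference allele orientation.
#' @param outcome [instrument_set] (or plain association table read with
#'   [read_association_table()]) for the outcome trait.
#' @param mediators Optional named list of [instrument_set]s with the
#'   SNP-mediator associations; SNPs missing from any mediator table are
#'   excluded (the multivariable model needs complete rows).
#' @param palindrome_policy One of `"drop_ambiguous"` (default: drop a
#'   palindromic SNP iff either allele frequency is missing or falls inside
#'   `eaf_window`, otherwise orient by frequency concordance), `"drop_all"`,
#'   or `"keep"` (trust allele labels).
#' @param eaf_window Ambiguity window on the allele frequency, default
#'   `c(0.42, 0.58)`.
#'
#' @return An object of class `harmonised_set`: a list with `exposure_name`,
#'   `outcome_name`, `outcome_type`, `mediator_names`, `data` (data frame with
#'   columns `variant_id`, `E`, `E_se`, `D`, `D_se`, `eaf` and per-mediator
#'   `M_<name>`, `M_<name>_se`), and `exclusion_log` (`variant_id`, `reason`).
#' @export
harmonise <- function(exposure, outcome, mediators = list(),
                      palindrome_policy = c("drop_ambiguous", "drop_all", "keep"),
                      eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "instrument_set"),
            inherits(outcome, "instrument_set"))
  if (nrow(exposure$records) == 0) stop("exposure instrument set is empty")
  if (nrow(outcome$records) == 0) stop("outcome association set is empty")
  if (length(mediators) && is.null(names(mediators))) {
    stop("mediators must be a named list")
  }
  stopifnot(length(eaf_window) == 2, eaf_window[1] <= eaf_window[2])

  exp_rec <- exposure$records
  out_rec <- outcome$records
  med_recs <- lapply(mediators, function(m) m$records)

  n <- nrow(exp_rec)
  keep <- logical(n)
  reason <- character(n)
  D <- D_se <- rep(NA_real_, n)
  med_beta <- lapply(mediators, function(m) rep(NA_real_, n))
  med_se <- lapply(mediators, function(m) rep(NA_real_, n))

  for (i in seq_len(n)) {
    vid <- exp_rec$variant_id[i]
    j <- match(vid, out_rec$variant_id)
    if (is.na(j)) {
      reason[i] <- "absent_in_outcome"
      next
    }
    st <- align_record(exp_rec$effect_allele[i], exp_rec$other_allele[i],
                       exp_rec$eaf[i],
                       out_rec$effect_allele[j], out_rec$other_allele[j],
                       out_rec$eaf[j], palindrome_policy, eaf_window)
    if (!st %in% c("aligned", "flip")) {
      reason[i] <- st
      next
    }
    D[i] <- if (st == "flip") -out_rec$beta[j] else out_rec$beta[j]
    D_se[i] <- out_rec$se[j]

    ok <- TRUE
    for (m in seq_along(mediators)) {
      mr <- med_recs[[m]]
      jm <- match(vid, mr$variant_id)
      if (is.na(jm)) {
        reason[i] <- paste0("absent_in_", names(mediators)[m])
        ok <- FALSE
        break
      }
      stm <- align_record(exp_rec$effect_allele[i], exp_rec$other_allele[i],
                          exp_rec$eaf[i],
                          mr$effect_allele[jm], mr$other_allele[jm],
                          mr$eaf[jm], palindrome_policy, eaf_window)
      if (!stm %in% c("aligned", "flip")) {
        reason[i] <- paste0(stm, "_in_", names(mediators)[m])
        ok <- FALSE
        break
      }
      med_beta[[m]][i] <- if (stm == "flip") -mr$beta[jm] else mr$beta[jm]
      med_se[[m]][i] <- mr$se[jm]
    }
    if (!ok) next
    keep[i] <- TRUE
  }

  data <- data.frame(variant_id = exp_rec$variant_id[keep],
                     E = exp_rec$beta[keep], E_se = exp_rec$se[keep],
                     D = D[keep], D_se = D_se[keep],
                     eaf = exp_rec$eaf[keep],
                     stringsAsFactors = FALSE)
  for (m in seq_along(mediators)) {
    nm <- names(mediators)[m]
    data[[paste0("M_", nm)]] <- med_beta[[m]][keep]
    data[[paste0("M_", nm, "_se")]] <- med_se[[m]][keep]
  }
  log <- data.frame(variant_id = exp_rec$variant_id[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(data) == 0) {
    stop("harmonisation retained zero SNPs; exclusion log:\n",
         paste(sprintf("  %s: %s", log$variant_id, log$reason),
               collapse = "\n"))
  }
  structure(
    list(exposure_name = exposure$trait_name,
         outcome_name = outcome$trait_name,
         outcome_type = outcome$trait_type,
         mediator_names = names(mediators),
         palindrome_policy = palindrome_policy,
         eaf_window = eaf_window,
         data = data, exclusion_log = log),
    class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s -> %s: %d SNPs retained, %d excluded",
              x$exposure_name, x$outcome_name, nrow(x$data),
              nrow(x$exclusion_log)))
  if (length(x$mediator_names)) {
    cat(" | mediators:", paste(x$mediator_names, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Rescale an effect estimate and its standard error
#'
#' Multiplies a point estimate and its SE by a positive factor, for linear
#' unit conversions (e.g. HbA1c effects in NGSP percent to IFCC mmol/mol,
#' factor 10.929). P values are unaffected by a linear rescaling.
#'
#' @param beta Point estimate.
#' @param se Standard error.
#' @param factor Positive scalar conversion factor.
#' @return Named numeric vector `c(beta = , se = )`.
#' @export
rescale_estimate <- function(beta, se, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) ||
      factor <= 0) {
    stop("rescale factor must be a positive scalar")
  }
  c(beta = beta * factor, se = se * factor)
}

#' Conversion factor between HbA1c percentage (NGSP) and mmol/mol (IFCC)
#'
#' Effect-size differences on the NGSP percent scale multiply by this factor
#' to give differences on the IFCC mmol/mol scale.
#' @export
NGSP_TO_IFCC <- 10.929
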