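# Multivariable IVW regression, mediated-proportion arithmetic and the
# two-step triage rule for candidate mediators.

#' Multivariable IVW: direct effect adjusted for mediators
#'
#' Weighted least squares of the SNP-outcome betas on the SNP-exposure betas
#' and the SNP-mediator betas jointly, with weights `1 / se_D^2` and no
#' intercept. The coefficient on the exposure column is the direct effect of
#' the exposure on the outcome not acting through the included mediators.
#' Coefficient SEs are the fixed-effect `sqrt(diag((X'WX)^-1))`, so with zero
#' mediators the result reproduces the univariable IVW estimate exactly.
#'
#' @param h A `harmonised_set` from [harmonise()] that carries mediator
#'   columns (`M_<name>`, `M_<name>_se`).
#' @param mediators Character vector of mediator names to adjust for;
#'   defaults to all mediators present in `h`.
#' @return Object of class `mvmr_result`: `direct_beta`, `direct_se`,
#'   `direct_ci_low/high`, `direct_p`, `mediators` (data frame of conditional
#'   betas/SEs/p), `n_snps`, trait labels.
#' @export
mvmr_ivw <- function(h, mediators = NULL) {
  stopifnot(inherits(h, "harmonised_set"))
  if (is.null(mediators)) mediators <- h$mediator_names
  if (is.null(mediators)) mediators <- character()
  missing_med <- setdiff(mediators, h$mediator_names %||% character())
  if (length(missing_med)) {
    stop("harmonised set has no mediator column for: ",
         paste(missing_med, collapse = ", "))
  }
  d <- h$data
  k <- nrow(d)
  p <- 1L + length(mediators)
  if (k <= p) {
    stop("multivariable IVW needs more SNPs (", k, ") than regressors (", p, ")")
  }
  X <- cbind(exposure = d$E)
  for (m in mediators) X <- cbind(X, d[[paste0("M_", m)]])
  colnames(X) <- c("exposure", mediators)
  # a mediator with no SNP association anywhere contributes nothing and would
  # make the design singular; drop it from the regression, report NA for it
  zero_col <- colSums(X != 0) == 0 & colnames(X) != "exposure"
  Xf <- X[, !zero_col, drop = FALSE]
  qr_x <- qr(Xf)
  if (qr_x$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qr_x$pivot[seq_len(ncol(Xf))][-seq_len(qr_x$rank)]]
    stop("rank-deficient multivariable design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  w <- 1 / d$D_se^2
  XtWX <- crossprod(Xf, w * Xf)
  coefs_f <- drop(solve(XtWX, crossprod(Xf, w * d$D)))
  ses_f <- sqrt(diag(solve(XtWX)))
  coefs <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  ses <- coefs
  coefs[colnames(Xf)] <- coefs_f
  ses[colnames(Xf)] <- ses_f
  pvals <- 2 * pnorm(-abs(coefs / ses))

  med_df <- data.frame(mediator = mediators,
                       beta = unname(coefs[mediators]),
                       se = unname(ses[mediators]),
                       pvalue = unname(pvals[mediators]),
                       stringsAsFactors = FALSE)
  structure(
    list(exposure_name = h$exposure_name, outcome_name = h$outcome_name,
         outcome_type = h$outcome_type,
         mediator_names = mediators,
         direct_beta = unname(coefs["exposure"]),
         direct_se = unname(ses["exposure"]),
         direct_ci_low = unname(coefs["exposure"] - Z95 * ses["exposure"]),
         direct_ci_high = unname(coefs["exposure"] + Z95 * ses["exposure"]),
         direct_p = unname(pvals["exposure"]),
         mediators = med_df, n_snps = k),
    class = "mvmr_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %s -> %s adjusted for {%s} (%d SNPs)\n",
              x$exposure_name, x$outcome_name,
              paste(x$mediator_names, collapse = ", "), x$n_snps))
  cat(sprintf("  direct beta %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$direct_beta, x$direct_se, x$direct_ci_low, x$direct_ci_high,
              x$direct_p))
  invisible(x)
}

#' Proportion of an effect mediated
#'
#' Compares the total exposure-outcome effect with the direct effect after
#' multivariable adjustment for the mediator(s); the default formula is
#' `1 - beta_direct / beta_total`, reported as a percentage. Both effects
#' must be on the same scale (log-odds for a binary outcome). The proportion
#' can fall outside [0, 100] in finite samples and is reported as computed.
#' Refuses to run when a mediator is binary: attenuation of a log-odds
#' effect by a dichotomised mediator is not interpretable as a proportion of
#' a continuous pathway.
#'
#' @param total An `mr_result` for the unadjusted exposure-outcome effect.
#' @param direct An `mvmr_result` for the adjusted (direct) effect.
#' @param mediator_binary Logical: is any adjusted-for mediator binary?
#' @return Object of class `mediation_result` with `total_beta`,
#'   `direct_beta`, `proportion_mediated` (percent) and `formula_tag`.
#' @export
proportion_mediated <- function(total, direct, mediator_binary = FALSE) {
  stopifnot(inherits(total, "mr_result"), inherits(direct, "mvmr_result"))
  if (mediator_binary) {
    stop("proportion mediated is not computed for binary mediators: ",
         "the attenuation of a log-odds effect by a dichotomised trait has ",
         "no proportion-of-pathway interpretation")
  }
  if (!identical(total$exposure, direct$exposure_name) ||
      !identical(total$outcome, direct$outcome_name)) {
    stop("total and direct effects must be for the same exposure/outcome pair")
  }
  if (total$beta == 0) stop("proportion mediated undefined: total effect is 0")
  prop <- 100 * (1 - direct$direct_beta / total$beta)
  structure(list(exposure_name = total$exposure,
                 outcome_name = total$outcome,
                 mediator_names = direct$mediator_names,
                 total_beta = total$beta, direct_beta = direct$direct_beta,
                 proportion_mediated = prop,
                 formula_tag = "one_minus_direct_over_total_pct"),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s -> %s via {%s}: total %.4g, direct %.4g, %.1f%% mediated [%s]\n",
    x$exposure_name, x$outcome_name,
    paste(x$mediator_names, collapse = ", "),
    x$total_beta, x$direct_beta, x$proportion_mediated, x$formula_tag))
  invisible(x)
}

ci_excludes_zero <- function(r) r$ci_low > 0 || r$ci_high < 0

# One candidate's verdict from its three-method results in one step.
triage_step_pass <- function(methods) {
  needed <- c("ivw", "weighted_median", "egger")
  if (!all(needed %in% names(methods)) ||
      any(vapply(methods[needed], is.null, logical(1)))) {
    return(NA)
  }
  betas <- vapply(methods[needed], function(r) r$beta, numeric(1))
  if (any(is.na(betas))) return(NA)
  signs_concordant <- all(sign(betas) == sign(betas[1])) && all(betas != 0)
  signs_concordant &&
    ci_excludes_zero(methods$ivw) &&
    ci_excludes_zero(methods$weighted_median)
}

#' Triage candidate mediators from two-step MR results
#'
#' A candidate mediator is carried forward to mediation analysis iff, in both
#' step one (exposure to mediator) and step two (mediator to outcome), the
#' IVW, weighted-median and MR-Egger point estimates agree in sign and the
#' IVW and weighted-median 95% CIs exclude zero. The MR-Egger CI is allowed
#' to include zero (it has lower power) provided its point estimate is
#' sign-concordant with the other two. Candidates with missing method results
#' are marked not evaluable.
#'
#' @param step1 Named list (one element per candidate) of lists with
#'   components `ivw`, `weighted_median`, `egger`, each an `mr_result` for
#'   the exposure-to-mediator analysis.
#' @param step2 Same structure for the mediator-to-outcome analyses.
#' @return Data frame with columns `mediator`, `step1_pass`, `step2_pass`,
#'   `status` (`"pass"`, `"fail"` or `"not_evaluable"`).
#' @export
mediator_triage <- function(step1, step2) {
  candidates <- union(names(step1), names(step2))
  if (!length(candidates)) stop("no candidate mediators supplied")
  rows <- lapply(candidates, function(m) {
    p1 <- if (m %in% names(step1)) triage_step_pass(step1[[m]]) else NA
    p2 <- if (m %in% names(step2)) triage_step_pass(step2[[m]]) else NA
    status <- if (is.na(p1) || is.na(p2)) "not_evaluable"
      else if (p1 && p2) "pass" else "fail"
    data.frame(mediator = m, step1_pass = p1, step2_pass = p2,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
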