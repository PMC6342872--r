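# Causal estimators for two-sample MR from harmonised summary statistics:
# Wald ratio, inverse-variance weighted (IVW), weighted median, and MR-Egger
# regression, plus instrument-strength diagnostics.

Z95 <- 1.96  # fixed CI multiplier; nominal significance, no adjustment

mr_result <- function(method, beta, se, n_snps,
                      exposure = NA_character_, outcome = NA_character_,
                      outcome_binary = FALSE,
                      intercept = NA_real_, intercept_se = NA_real_) {
  pvalue <- 2 * pnorm(-abs(beta / se))
  res <- list(method = method, exposure = exposure, outcome = outcome,
              n_snps = n_snps,
              beta = beta, se = se,
              ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
              pvalue = pvalue,
              intercept = intercept, intercept_se = intercept_se,
              intercept_p = if (is.na(intercept)) NA_real_ else
                2 * pnorm(-abs(intercept / intercept_se)))
  if (outcome_binary) {
    res$or_scale <- c(or = exp(res$beta), or_ci_low = exp(res$ci_low),
                      or_ci_high = exp(res$ci_high))
  }
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %s -> %s (%d SNPs)\n", x$method,
              x$exposure, x$outcome, x$n_snps))
  cat(sprintf("  beta %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.null(x$or_scale)) {
    cat(sprintf("  OR %.3f [%.3f, %.3f]\n", x$or_scale["or"],
                x$or_scale["or_ci_low"], x$or_scale["or_ci_high"]))
  }
  invisible(x)
}

#' Single-SNP Wald ratio estimate
#'
#' The causal effect from one instrument is the ratio of the SNP-outcome to
#' the SNP-exposure association; its SE uses the first-order delta
#' approximation `se_D / |E|`, which ignores uncertainty in the exposure
#' association (adequate for strong instruments).
#'
#' @param E,E_se SNP-exposure beta and SE.
#' @param D,D_se SNP-outcome beta and SE.
#' @param exposure,outcome Optional trait labels.
#' @param outcome_binary If `TRUE`, an odds-ratio presentation is attached.
#' @return An `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(E, E_se, D, D_se,
                       exposure = NA_character_, outcome = NA_character_,
                       outcome_binary = FALSE) {
  if (E == 0) stop("Wald ratio undefined for a null exposure association")
  mr_result("wald", beta = D / E, se = D_se / abs(E), n_snps = 1L,
            exposure = exposure, outcome = outcome,
            outcome_binary = outcome_binary)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW estimate combining all instruments:
#' `beta = sum(E * D / se_D^2) / sum(E^2 / se_D^2)` with
#' `SE = sqrt(1 / sum(E^2 / se_D^2))`. Efficient when all instruments are
#' valid (or pleiotropic effects are balanced), but biased by directional
#' pleiotropy. With a single SNP this reduces exactly to the Wald ratio.
#'
#' @param h A `harmonised_set` from [harmonise()].
#' @return An `mr_result` with `method = "ivw"`.
#' @export
mr_ivw <- function(h) {
  d <- as_harmonised_data(h)
  if (nrow(d) < 1) stop("IVW requires at least one SNP")
  w <- 1 / d$D_se^2
  denom <- sum(d$E^2 * w)
  mr_result("ivw", beta = sum(d$E * d$D * w) / denom, se = sqrt(1 / denom),
            n_snps = nrow(d),
            exposure = attr(d, "exposure"), outcome = attr(d, "outcome"),
            outcome_binary = isTRUE(attr(d, "binary")))
}

# Accept a harmonised_set or a bare data frame with E/E_se/D/D_se columns
# (convenient for simulation loops and tests).
as_harmonised_data <- function(h) {
  if (inherits(h, "harmonised_set")) {
    d <- h$data
    attr(d, "exposure") <- h$exposure_name
    attr(d, "outcome") <- h$outcome_name
    attr(d, "binary") <- identical(h$outcome_type, "binary")
    return(d)
  }
  d <- as.data.frame(h)
  stopifnot(all(c("E", "D", "D_se") %in% names(d)))
  d
}

# 50th weighted percentile of ordered ratio estimates: the j-th ordered ratio
# sits at percentile 100 * (S_j - W_j / 2) where S_j is the cumulative weight;
# the estimate interpolates linearly between the two ratios bracketing 50.
weighted_median_estimate <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- 100 * (cumsum(w) - w / 2)
  k <- length(r)
  if (50 <= p[1]) return(r[1])
  if (50 >= p[k]) return(r[k])
  j <- findInterval(50, p)
  r[j] + (50 - p[j]) / (p[j + 1] - p[j]) * (r[j + 1] - r[j])
}

#' Weighted-median causal estimate
#'
#' The median of the inverse-variance-weighted distribution of per-SNP ratio
#' estimates. Consistent as long as no more than 50% of the weight comes from
#' invalid instruments. Weights are proportional to the inverse first-order
#' ratio variance `se_D^2 / E^2`; the SE comes from a parametric bootstrap
#' that resamples the SNP-exposure and SNP-outcome betas from normal
#' distributions centred at their observed values.
#'
#' @param h A `harmonised_set` from [harmonise()].
#' @param n_boot Number of bootstrap replicates for the SE (default 1000).
#' @param seed Integer seed for the bootstrap; mandatory so that results are
#'   reproducible.
#' @return An `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  if (missing(seed)) stop("mr_weighted_median requires an explicit seed")
  d <- as_harmonised_data(h)
  k <- nrow(d)
  if (k < 3) stop("weighted median requires at least 3 SNPs")
  ratios <- d$D / d$E
  weights <- d$E^2 / d$D_se^2
  est <- weighted_median_estimate(ratios, weights)

  se <- local_seed(seed, {
    E_se <- if (is.null(d$E_se)) rep(0, k) else d$E_se
    boots <- vapply(seq_len(n_boot), function(b) {
      Eb <- rnorm(k, d$E, E_se)
      Db <- rnorm(k, d$D, d$D_se)
      ok <- Eb != 0
      weighted_median_estimate(Db[ok] / Eb[ok], Eb[ok]^2 / d$D_se[ok]^2)
    }, numeric(1))
    stats::sd(boots)
  })

  mr_result("weighted_median", beta = est, se = se, n_snps = k,
            exposure = attr(d, "exposure"), outcome = attr(d, "outcome"),
            outcome_binary = isTRUE(attr(d, "binary")))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome coefficients on the
#' SNP-exposure coefficients with a free intercept and weights `1 / se_D^2`.
#' All exposure associations are first oriented positive (flipping the
#' outcome beta in tandem). A non-zero intercept indicates directional
#' horizontal pleiotropy; the slope is a pleiotropy-corrected causal estimate
#' under the InSIDE assumption (instrument strength independent of direct
#' effects). Standard errors are multiplied by the square root of the
#' residual variance when it exceeds 1 (floored at 1: under-dispersion is not
#' allowed to shrink them); p values use a normal reference.
#'
#' @param h A `harmonised_set` from [harmonise()].
#' @return An `mr_result` with `method = "egger_slope"` carrying `intercept`,
#'   `intercept_se` and `intercept_p`.
#' @export
mr_egger <- function(h) {
  d <- as_harmonised_data(h)
  k <- nrow(d)
  if (k < 3) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(d$E) < 0
  E <- abs(d$E)
  D <- ifelse(flip, -d$D, d$D)
  if (max(E) - min(E) < .Machine$double.eps^0.5 * max(abs(E), 1)) {
    stop("MR-Egger slope not identifiable: all exposure associations equal")
  }
  w <- 1 / d$D_se^2
  X <- cbind(intercept = 1, slope = E)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * D)
  coefs <- drop(solve(XtWX, XtWy))
  resid <- D - drop(X %*% coefs)
  scale2 <- max(1, sum(w * resid^2) / (k - 2))
  ses <- sqrt(scale2 * diag(solve(XtWX)))
  mr_result("egger_slope", beta = unname(coefs["slope"]),
            se = unname(ses["slope"]), n_snps = k,
            exposure = attr(d, "exposure"), outcome = attr(d, "outcome"),
            outcome_binary = isTRUE(attr(d, "binary")),
            intercept = unname(coefs["intercept"]),
            intercept_se = unname(ses["intercept"]))
}

#' Instrument strength: variance explained and F-statistic
#'
#' For a standardised trait the variance explained by SNP k with effect-allele
#' frequency p and per-allele effect beta is `2 p (1 - p) beta^2`; summing
#' over independent instruments gives R-squared, and the first-stage
#' F-statistic is `((n - k - 1) / k) * (R2 / (1 - R2))`. SNPs with missing
#' allele frequency are skipped with a warning and the reported coverage
#' fraction says how much of the set contributed.
#'
#' @param s An [instrument_set] (trait assumed standardised, or betas supplied
#'   on a standardised scale).
#' @param n_sample Sample size of the GWAS providing the betas.
#' @return List of class `instrument_strength` with `r_squared`,
#'   `f_statistic`, `n_snps`, `n_sample`, `coverage`.
#' @export
instrument_strength <- function(s, n_sample) {
  stopifnot(inherits(s, "instrument_set"), n_sample > 0)
  rec <- s$records
  usable <- !is.na(rec$eaf) & !is.na(rec$beta)
  if (!all(usable)) {
    warning(sum(!usable), " SNP(s) without eaf/beta skipped in ",
            "instrument_strength for ", s$trait_name)
  }
  k <- sum(usable)
  if (k == 0) stop("no SNP with both eaf and beta available")
  p <- rec$eaf[usable]
  b <- rec$beta[usable]
  r2 <- sum(2 * p * (1 - p) * b^2)
  f <- ((n_sample - k - 1) / k) * (r2 / (1 - r2))
  structure(list(r_squared = r2, f_statistic = f, n_snps = k,
                 n_sample = n_sample, coverage = k / nrow(rec)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf(
    "<instrument_strength> R2 = %.4f, F = %.1f (%d SNPs, n = %d, coverage %.0f%%)\n",
    x$r_squared, x$f_statistic, x$n_snps, x$n_sample, 100 * x$coverage))
  invisible(x)
}

# Run code with a temporary RNG state so package functions never clobber the
# caller's random stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
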