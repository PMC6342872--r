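# Generator for two-sample GWAS summary statistics with known causal
# structure. Each trait gets its own association table with independent
# sampling noise (the two-sample design); instrument effects, horizontal
# pleiotropy and mediation chains are all configurable, and the generating
# parameters are echoed alongside the tables so estimators can be validated
# against ground truth.

#' Specify the ground truth of a simulated summary-statistics study
#'
#' Defaults describe a study shaped like a large adiposity-to-coronary-disease
#' consortium analysis: 77 independent exposure instruments jointly explaining
#' 2.4% of a standardised exposure in a sample of 322,154, a binary outcome
#' GWAS of 184,305 (effects on the log-odds scale), and mediator GWAS of
#' 188,577. Effect alleles are oriented to the exposure-increasing allele, as
#' published instrument lists are.
#'
#' @param n_snps Number of exposure instruments.
#' @param beta_direct Direct (unmediated) exposure-outcome effect, log-odds
#'   per exposure unit for a binary outcome.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (zero-mean direct
#'   SNP-outcome effects), `"directional"` (non-zero mean, independent of
#'   instrument strength: InSIDE holds) or `"inside_violating"` (direct
#'   effects correlated with instrument strength, correlation 0.8).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-SNP direct
#'   effect `alpha_k` on the outcome.
#' @param mediators List of mediator specifications; each element a list with
#'   `theta_xm` (exposure effect on the mediator), `beta_my` (mediator effect
#'   on the outcome), and optionally `n_snps` (mediator-specific instruments,
#'   default 50), `r2` (variance they explain, default 0.02), `n_sample`
#'   (mediator GWAS size, default `n_mediator`). Elements may be named; unnamed
#'   mediators are called `M1`, `M2`, ...
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param r2_exposure Variance of the (standardised) exposure explained by
#'   its instruments; effect sizes are scaled to hit this exactly.
#' @param maf_range Range for the uniform minor/effect-allele frequency draw.
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G alleles to
#'   exercise strand-ambiguity handling.
#' @param swap_fraction Fraction of rows in non-exposure tables stored with
#'   effect/other alleles exchanged (beta negated, eaf complemented) to
#'   exercise harmonisation.
#' @param exposure_name,outcome_name,outcome_type Trait labels; the outcome
#'   is binary by default.
#' @param seed Integer seed; mandatory, every draw flows from it.
#'
#' @return Object of class `simulation_truth`. Field `beta_causal` echoes the
#'   implied total effect `beta_direct + sum(theta_xm * beta_my)`.
#' @export
simulation_truth <- function(n_snps = 77,
                             beta_direct = 0.37,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional",
                                                 "inside_violating"),
                             pleiotropy_mean = 0, pleiotropy_sd = 0,
                             mediators = list(),
                             n_exposure = 322154, n_outcome = 184305,
                             n_mediator = 188577,
                             r2_exposure = 0.024,
                             maf_range = c(0.05, 0.5),
                             palindromic_fraction = 0.15,
                             swap_fraction = 0.3,
                             exposure_name = "exposure",
                             outcome_name = "outcome",
                             outcome_type = c("binary", "continuous"),
                             seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop("simulation_truth requires an explicit seed")
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            swap_fraction >= 0, swap_fraction <= 1,
            r2_exposure > 0, r2_exposure < 1)
  if (pleiotropy_mode == "none" && pleiotropy_sd != 0) {
    stop("pleiotropy_mode 'none' requires pleiotropy_sd = 0")
  }
  if (pleiotropy_mode == "none" && pleiotropy_mean != 0) {
    stop("pleiotropy_mode 'none' requires pleiotropy_mean = 0")
  }
  if (pleiotropy_sd < 0) stop("pleiotropy_sd must be nonnegative")

  meds <- list()
  if (length(mediators)) {
    nms <- names(mediators) %||% rep("", length(mediators))
    for (i in seq_along(mediators)) {
      m <- mediators[[i]]
      stopifnot(is.list(m), !is.null(m$theta_xm), !is.null(m$beta_my))
      nm <- if (nzchar(nms[i])) nms[i] else paste0("M", i)
      meds[[nm]] <- list(theta_xm = m$theta_xm, beta_my = m$beta_my,
                         n_snps = m$n_snps %||% 50L,
                         r2 = m$r2 %||% 0.02,
                         n_sample = m$n_sample %||% n_mediator)
    }
  }
  theta_beta <- if (length(meds)) {
    sum(vapply(meds, function(m) m$theta_xm * m$beta_my, numeric(1)))
  } else 0
  structure(
    list(n_snps = as.integer(n_snps), beta_direct = beta_direct,
         beta_causal = beta_direct + theta_beta,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         mediators = meds,
         n_exposure = n_exposure, n_outcome = n_outcome,
         n_mediator = n_mediator,
         r2_exposure = r2_exposure, maf_range = maf_range,
         palindromic_fraction = palindromic_fraction,
         swap_fraction = swap_fraction,
         exposure_name = exposure_name, outcome_name = outcome_name,
         outcome_type = outcome_type, seed = as.integer(seed)),
    class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth> %d instruments, direct effect %.3g (total %.3g), pleiotropy %s, %d mediator(s), seed %d\n",
    x$n_snps, x$beta_direct, x$beta_causal, x$pleiotropy_mode,
    length(x$mediators), x$seed))
  invisible(x)
}

draw_alleles <- function(n, palindromic_fraction) {
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  all_pairs <- expand.grid(ea = VALID_ALLELES, oa = VALID_ALLELES,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$ea != all_pairs$oa, ]
  nonpal <- all_pairs[!is_palindromic(all_pairs$ea, all_pairs$oa), ]
  is_pal <- runif(n) < palindromic_fraction
  ea <- oa <- character(n)
  pick_pal <- sample.int(nrow(pal_pairs), sum(is_pal), replace = TRUE)
  ea[is_pal] <- pal_pairs[pick_pal, 1]
  oa[is_pal] <- pal_pairs[pick_pal, 2]
  pick <- sample.int(nrow(nonpal), sum(!is_pal), replace = TRUE)
  ea[!is_pal] <- nonpal$ea[pick]
  oa[!is_pal] <- nonpal$oa[pick]
  data.frame(effect_allele = ea, other_allele = oa, stringsAsFactors = FALSE)
}

# Scale raw effect sizes so that sum(2 p (1-p) beta^2) equals r2 exactly.
scale_to_r2 <- function(raw, p, r2) {
  raw * sqrt(r2 / sum(2 * p * (1 - p) * raw^2))
}

# Instrument effect sizes: half-normal truncated below at 0.45 (before
# rescaling to the target R2). Published instruments are genome-wide
# significant, so their true effects are bounded away from zero; without the
# truncation, near-null instruments whose observed exposure beta flips sign
# make MR-Egger's positive-orientation step co-flip pure noise, biasing the
# slope up and the intercept down even when InSIDE holds.
TRUNC_HALF_NORMAL <- 0.45
draw_instrument_effects <- function(n) {
  t0 <- 2 * pnorm(TRUNC_HALF_NORMAL) - 1
  q <- t0 + runif(n) * (1 - t0)
  qnorm((1 + q) / 2)
}

# One trait's observed association table over the SNP universe.
observe_trait <- function(universe, true_beta, n_sample, swap_fraction,
                          trait_name, trait_type, unit_label) {
  k <- nrow(universe)
  se <- 1 / sqrt(2 * universe$maf * (1 - universe$maf) * n_sample)
  beta <- true_beta + rnorm(k, 0, se)
  rec <- data.frame(variant_id = universe$variant_id,
                    effect_allele = universe$effect_allele,
                    other_allele = universe$other_allele,
                    eaf = universe$maf, beta = beta, se = se,
                    stringsAsFactors = FALSE)
  swap <- runif(k) < swap_fraction
  rec[swap, c("effect_allele", "other_allele")] <-
    rec[swap, c("other_allele", "effect_allele")]
  rec$beta[swap] <- -rec$beta[swap]
  rec$eaf[swap] <- 1 - rec$eaf[swap]
  rec$pvalue <- 2 * pnorm(-abs(rec$beta / rec$se))
  rec$n <- n_sample
  instrument_set(trait_name, trait_type, unit_label, rec)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates, per SNP: an allele frequency from `maf_range`; a true exposure
#' effect (half-normal, scaled so the instrument set explains exactly
#' `r2_exposure`); mediator effects `theta_xm * gamma_k` plus mediator-specific
#' instrument effects; a true outcome effect
#' `beta_direct * gamma_k + sum(beta_my * delta_k) + alpha_k` with the
#' pleiotropic effect `alpha_k` drawn per `pleiotropy_mode`; and per-trait
#' sampling SEs `1 / sqrt(2 p (1 - p) n)`. Observed betas add independent
#' normal noise per dataset, honouring the two-sample design.
#'
#' @param truth A [simulation_truth()].
#' @return List of class `simulated_study`: `traits` — a named list with one
#'   element per trait (exposure, each mediator, outcome), each carrying
#'   `instruments` (that trait's own instrument set, `NULL` for the outcome)
#'   and `associations` (the trait's associations at every SNP in the study);
#'   `truth` — the input echoed with the per-SNP true effects attached
#'   (`truth$snp_effects`).
#' @export
simulate_summary_stats <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  local_seed(truth$seed, {
    meds <- truth$mediators
    n_extra <- if (length(meds)) {
      vapply(meds, function(m) as.integer(m$n_snps), integer(1))
    } else integer()
    k_total <- truth$n_snps + sum(n_extra)

    owner <- c(rep("exposure", truth$n_snps),
               rep(names(meds), times = n_extra))
    maf <- runif(k_total, truth$maf_range[1], truth$maf_range[2])
    alleles <- draw_alleles(k_total, truth$palindromic_fraction)
    universe <- data.frame(
      variant_id = sprintf("rs%06d", seq_len(k_total)),
      effect_allele = alleles$effect_allele,
      other_allele = alleles$other_allele,
      maf = maf, owner = owner, stringsAsFactors = FALSE)

    # True per-allele effects. gamma: exposure; eta/delta: mediators;
    # Gamma: outcome. Effect alleles are exposure-increasing, so gamma >= 0.
    gamma <- numeric(k_total)
    is_exp <- owner == "exposure"
    gamma[is_exp] <- scale_to_r2(draw_instrument_effects(truth$n_snps),
                                 maf[is_exp],
                                 truth$r2_exposure)

    delta <- list()
    for (nm in names(meds)) {
      m <- meds[[nm]]
      eta <- numeric(k_total)
      own <- owner == nm
      eta[own] <- scale_to_r2(draw_instrument_effects(sum(own)), maf[own],
                              m$r2)
      delta[[nm]] <- m$theta_xm * gamma + eta
    }

    alpha <- numeric(k_total)
    if (truth$pleiotropy_mode != "none") {
      z <- rnorm(truth$n_snps)
      base <- switch(truth$pleiotropy_mode,
        balanced = truth$pleiotropy_sd * z,
        directional = truth$pleiotropy_mean + truth$pleiotropy_sd * z,
        inside_violating = {
          g <- gamma[is_exp]
          zg <- (g - mean(g)) / stats::sd(g)
          rho <- 0.8
          truth$pleiotropy_mean +
            truth$pleiotropy_sd * (rho * zg + sqrt(1 - rho^2) * z)
        })
      alpha[is_exp] <- base
    }

    Gamma <- truth$beta_direct * gamma + alpha
    for (nm in names(meds)) Gamma <- Gamma + meds[[nm]]$beta_my * delta[[nm]]

    traits <- list()
    exp_assoc <- observe_trait(universe, gamma, truth$n_exposure, 0,
                               truth$exposure_name, "continuous", "SD")
    traits[[truth$exposure_name]] <- list(
      instruments = instrument_set(
        truth$exposure_name, "continuous", "SD",
        exp_assoc$records[is_exp, , drop = FALSE]),
      associations = local({
        r <- exp_assoc$records
        swap <- runif(k_total) < truth$swap_fraction & !is_exp
        r[swap, c("effect_allele", "other_allele")] <-
          r[swap, c("other_allele", "effect_allele")]
        r$beta[swap] <- -r$beta[swap]
        r$eaf[swap] <- 1 - r$eaf[swap]
        instrument_set(truth$exposure_name, "continuous", "SD", r)
      }))

    for (nm in names(meds)) {
      m <- meds[[nm]]
      assoc <- observe_trait(universe, delta[[nm]], m$n_sample,
                             truth$swap_fraction, nm, "continuous", "SD")
      own <- owner == nm
      traits[[nm]] <- list(
        instruments = instrument_set(nm, "continuous", "SD",
                                     assoc$records[own, , drop = FALSE]),
        associations = assoc)
    }

    out_unit <- if (truth$outcome_type == "binary") "log-odds" else "SD"
    traits[[truth$outcome_name]] <- list(
      instruments = NULL,
      associations = observe_trait(universe, Gamma, truth$n_outcome,
                                   truth$swap_fraction, truth$outcome_name,
                                   truth$outcome_type, out_unit))

    truth$snp_effects <- data.frame(
      variant_id = universe$variant_id, owner = owner, maf = maf,
      gamma = gamma, alpha = alpha, Gamma = Gamma,
      stringsAsFactors = FALSE)
    for (nm in names(meds)) truth$snp_effects[[paste0("delta_", nm)]] <- delta[[nm]]

    structure(list(traits = traits, truth = truth),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> traits: %s (%d SNPs in universe)\n",
              paste(names(x$traits), collapse = ", "),
              nrow(x$truth$snp_effects)))
  invisible(x)
}

fixture_truth <- function(profile, seed, ...) {
  base <- switch(profile,
    null_mediator = list(
      beta_direct = 0.3,
      mediators = list(M1 = list(theta_xm = 0, beta_my = 0))),
    single_mediator = list(
      beta_direct = 0.1,
      mediators = list(M1 = list(theta_xm = 0.2, beta_my = 1.0))),
    dual_mediator = list(
      beta_direct = 0.1,
      mediators = list(M1 = list(theta_xm = 0.2, beta_my = 0.8),
                       M2 = list(theta_xm = 0.15, beta_my = 0.6))),
    stop("unknown fixture profile: ", profile))
  do.call(simulation_truth, modifyList(base, list(seed = seed, ...)))
}

#' Write a ready-to-run simulated study to disk
#'
#' Materialises a simulated study as consortium-style TSV files plus a study
#' configuration and a plain-text echo of the generating truth, so the full
#' pipeline (and its command-line interface) can be exercised end to end.
#' Profiles: `"null_mediator"` (one candidate mediator with no causal role),
#' `"single_mediator"` (direct effect 0.1, exposure-to-mediator 0.2,
#' mediator-to-outcome 1.0, so 2/3 of the total effect is mediated),
#' `"dual_mediator"` (two independent mediators).
#'
#' @param profile Fixture profile name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_truth()] (e.g. `n_snps`).
#' @return The [study_config] describing the files written, invisibly the
#'   same object that `read_study_config(file.path(dir, "config.json"))`
#'   returns.
#' @export
make_fixture_study <- function(profile = c("single_mediator", "null_mediator",
                                           "dual_mediator"),
                               dir, seed, ...) {
  profile <- match.arg(profile)
  truth <- fixture_truth(profile, seed, ...)
  sim <- simulate_summary_stats(truth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  trait_cfg <- list()
  for (nm in names(sim$traits)) {
    t <- sim$traits[[nm]]
    assoc_path <- file.path(dir, paste0(nm, "_associations.tsv"))
    write_association_table(t$associations, assoc_path)
    inst_path <- NULL
    if (!is.null(t$instruments)) {
      inst_path <- file.path(dir, paste0(nm, "_instruments.tsv"))
      write_association_table(t$instruments, inst_path)
    }
    trait_cfg[[nm]] <- list(
      type = t$associations$trait_type,
      unit = t$associations$unit_label,
      sample_size = t$associations$records$n[1],
      instrument_file = inst_path,
      association_file = assoc_path)
  }

  truth_echo <- truth
  truth_echo$snp_effects <- NULL
  jsonlite::write_json(unclass(truth_echo), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "Synthetic two-sample MR study (simulated data, no real cohort).",
    sprintf("Profile: %s; seed %d.", profile, truth$seed),
    sprintf("Direct effect %.4g; implied total effect %.4g.",
            truth$beta_direct, truth$beta_causal),
    if (length(truth$mediators)) sprintf(
      "Mediator %s: exposure->mediator %.4g, mediator->outcome %.4g.",
      names(truth$mediators),
      vapply(truth$mediators, `[[`, numeric(1), "theta_xm"),
      vapply(truth$mediators, `[[`, numeric(1), "beta_my")) else character(),
    "Full generating parameters: truth.json."),
    file.path(dir, "README.txt"))

  cfg <- study_config(
    exposure = truth$exposure_name, outcome = truth$outcome_name,
    mediators = names(truth$mediators),
    traits = trait_cfg,
    settings = list(seed = truth$seed, n_boot = 1000,
                    palindrome_policy = "drop_ambiguous",
                    eaf_window = c(0.42, 0.58)),
    output_dir = file.path(dir, "results"))
  write_study_config(cfg, file.path(dir, "config.json"))
  invisible(cfg)
}
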