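# Study orchestration: configuration, the bidirectional IVW screen, and the
# full two-step mediation pipeline with its report bundle.

#' Define a two-step MR study
#'
#' @param exposure,outcome Names of the exposure and outcome traits; both
#'   must appear in `traits`.
#' @param mediators Character vector of candidate mediator trait names.
#' @param traits Named list; each element a list with `type`
#'   (`"continuous"`/`"binary"`), `unit`, `sample_size`, `instrument_file`
#'   (TSV of the trait's own instruments; may be `NULL` for traits never used
#'   as an exposure) and `association_file` (TSV of the trait's associations
#'   at every study SNP).
#' @param settings List: `seed` (mandatory: all stochastic steps derive from
#'   it), `n_boot` (weighted-median bootstrap size, default 1000),
#'   `palindrome_policy`, `eaf_window` (see [harmonise()]).
#' @param output_dir Directory where [run_two_step()] writes its report.
#' @return Object of class `study_config`.
#' @export
study_config <- function(exposure, outcome, mediators = character(),
                         traits, settings = list(), output_dir = ".") {
  stopifnot(is.list(traits), length(names(traits)) == length(traits))
  for (nm in c(exposure, outcome, mediators)) {
    if (!nm %in% names(traits)) stop("trait '", nm, "' not described in traits")
  }
  defaults <- list(seed = NULL, n_boot = 1000,
                   palindrome_policy = "drop_ambiguous",
                   eaf_window = c(0.42, 0.58))
  settings <- modifyList(defaults, settings)
  if (is.null(settings$seed)) {
    stop("settings$seed is mandatory: the weighted-median bootstrap is stochastic")
  }
  structure(list(exposure = exposure, outcome = outcome,
                 mediators = as.character(mediators), traits = traits,
                 settings = settings, output_dir = output_dir),
            class = "study_config")
}

#' Write / read a study configuration as JSON
#' @param cfg A [study_config].
#' @param path File path.
#' @return `write_study_config`: `path` invisibly; `read_study_config`: the
#'   [study_config].
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  study_config(exposure = raw$exposure, outcome = raw$outcome,
               mediators = unlist(raw$mediators) %||% character(),
               traits = raw$traits, settings = raw$settings,
               output_dir = raw$output_dir %||% ".")
}

# Deterministic 31-bit sub-seed for a labelled stochastic step.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

load_trait <- function(cfg, name) {
  t <- cfg$traits[[name]]
  inst <- NULL
  if (!is.null(t$instrument_file)) {
    if (!file.exists(t$instrument_file)) return(NULL)
    inst <- read_association_table(t$instrument_file, trait_name = name,
                                   trait_type = t$type, unit_label = t$unit)
  }
  assoc <- read_association_table(t$association_file, trait_name = name,
                                  trait_type = t$type, unit_label = t$unit)
  list(instruments = inst, associations = assoc,
       sample_size = t$sample_size, type = t$type, unit = t$unit)
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# Flatten an mr_result into one report row.
result_row <- function(r, extra = list()) {
  row <- data.frame(
    method = r$method, exposure = r$exposure, outcome = r$outcome,
    n_snps = r$n_snps, beta = r$beta, se = r$se,
    ci_low = r$ci_low, ci_high = r$ci_high, pvalue = r$pvalue,
    intercept = r$intercept, intercept_se = r$intercept_se,
    intercept_p = r$intercept_p,
    or = if (is.null(r$or_scale)) NA_real_ else unname(r$or_scale["or"]),
    or_ci_low = if (is.null(r$or_scale)) NA_real_ else
      unname(r$or_scale["or_ci_low"]),
    or_ci_high = if (is.null(r$or_scale)) NA_real_ else
      unname(r$or_scale["or_ci_high"]),
    stringsAsFactors = FALSE)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

# All three estimators of one exposure on one outcome.
estimate_pair <- function(exp_trait, out_trait, cfg, label) {
  h <- harmonise(exp_trait$instruments, out_trait$associations,
                 palindrome_policy = cfg$settings$palindrome_policy,
                 eaf_window = cfg$settings$eaf_window)
  list(harmonised = h,
       ivw = mr_ivw(h),
       weighted_median = mr_weighted_median(
         h, n_boot = cfg$settings$n_boot,
         seed = derive_seed(cfg$settings$seed, label)),
       egger = mr_egger(h))
}

#' Bidirectional IVW screen among all study traits
#'
#' Estimates, by IVW, the effect of every trait that has its own instrument
#' set on every other trait, flagging nominal significance. Reverse effects
#' (e.g. outcome on exposure, outcome on mediators) warn about reverse
#' causation that would bias mediation estimates; effects among candidate
#' mediators warn about mediator-mediator causality that the joint model
#' assumes away. Traits without an instrument file get an unavailable row
#' and the screen continues.
#'
#' @param cfg A [study_config].
#' @param study Optional pre-loaded traits (internal use).
#' @return Data frame with one row per ordered trait pair: `exposure`,
#'   `outcome`, `n_snps`, `beta`, `se`, `pvalue`, `stars`, `status`.
#' @export
bidirectional_screen <- function(cfg, study = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  trait_names <- names(cfg$traits)
  if (is.null(study)) {
    study <- lapply(setNames(trait_names, trait_names),
                    function(nm) load_trait(cfg, nm))
  }
  rows <- list()
  for (ex in trait_names) {
    for (out in setdiff(trait_names, ex)) {
      if (is.null(study[[ex]]) || is.null(study[[ex]]$instruments)) {
        rows[[length(rows) + 1L]] <- data.frame(
          exposure = ex, outcome = out, n_snps = NA_integer_,
          beta = NA_real_, se = NA_real_, pvalue = NA_real_, stars = "",
          status = "no_instruments", stringsAsFactors = FALSE)
        next
      }
      r <- tryCatch({
        h <- harmonise(study[[ex]]$instruments, study[[out]]$associations,
                       palindrome_policy = cfg$settings$palindrome_policy,
                       eaf_window = cfg$settings$eaf_window)
        iv <- mr_ivw(h)
        data.frame(exposure = ex, outcome = out, n_snps = iv$n_snps,
                   beta = iv$beta, se = iv$se, pvalue = iv$pvalue,
                   stars = p_stars(iv$pvalue), status = "ok",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(exposure = ex, outcome = out, n_snps = NA_integer_,
                   beta = NA_real_, se = NA_real_, pvalue = NA_real_,
                   stars = "", status = paste0("error: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Run the full two-step MR mediation analysis
#'
#' Orchestrates, in order: instrument-strength diagnostics for every trait
#' with instruments; the bidirectional IVW screen; step one (exposure on
#' outcome and on each candidate mediator, three estimators each); step two
#' (each candidate mediator on the outcome, three estimators); mediator
#' triage; and, for triaged mediators, multivariable IVW models (each
#' mediator singly and all jointly) with the mediated proportion for
#' continuous mediators. Everything is written to `cfg$output_dir` as TSV
#' tables, a machine-readable JSON bundle carrying the identical numbers, and
#' a run log recording seeds, policies and exclusion counts. Re-running with
#' the same config and seed reproduces every number bit-identically.
#'
#' @param cfg A [study_config].
#' @return The report bundle (a list mirroring `bundle.json`), invisibly.
#' @export
run_two_step <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  trait_names <- names(cfg$traits)
  study <- lapply(setNames(trait_names, trait_names),
                  function(nm) load_trait(cfg, nm))
  log_lines <- c(
    sprintf("two-step MR run: exposure=%s outcome=%s mediators=[%s]",
            cfg$exposure, cfg$outcome, paste(cfg$mediators, collapse = ", ")),
    sprintf("seed=%d n_boot=%d palindrome_policy=%s eaf_window=(%g,%g)",
            cfg$settings$seed, cfg$settings$n_boot,
            cfg$settings$palindrome_policy,
            cfg$settings$eaf_window[1], cfg$settings$eaf_window[2]))

  # Instrument strength.
  strength <- list()
  for (nm in trait_names) {
    tr <- study[[nm]]
    if (is.null(tr) || is.null(tr$instruments)) next
    s <- instrument_strength(tr$instruments, tr$sample_size)
    strength[[length(strength) + 1L]] <- data.frame(
      trait = nm, n_snps = s$n_snps, n_sample = s$n_sample,
      r_squared = s$r_squared, f_statistic = s$f_statistic,
      coverage = s$coverage, stringsAsFactors = FALSE)
  }
  strength <- if (length(strength)) do.call(rbind, strength) else NULL

  screen <- bidirectional_screen(cfg, study = study)

  run_block <- function(pairs, step_label) {
    rows <- list()
    results <- list()
    for (p in pairs) {
      label <- paste(step_label, p$exposure, p$outcome, sep = ":")
      fit <- tryCatch(
        estimate_pair(study[[p$exposure]], study[[p$outcome]], cfg, label),
        error = function(e) e)
      if (inherits(fit, "error")) {
        log_lines <<- c(log_lines, sprintf("%s %s->%s FAILED: %s", step_label,
                                           p$exposure, p$outcome,
                                           conditionMessage(fit)))
        next
      }
      log_lines <<- c(log_lines, sprintf(
        "%s %s->%s: %d SNPs retained, %d excluded", step_label, p$exposure,
        p$outcome, nrow(fit$harmonised$data), nrow(fit$harmonised$exclusion_log)))
      results[[paste(p$exposure, p$outcome, sep = "->")]] <-
        fit[c("ivw", "weighted_median", "egger")]
      for (m in c("ivw", "weighted_median", "egger")) {
        rows[[length(rows) + 1L]] <- result_row(fit[[m]])
      }
    }
    list(table = if (length(rows)) do.call(rbind, rows) else NULL,
         results = results)
  }

  # Step one: exposure on outcome and on each mediator.
  step1_pairs <- c(
    list(list(exposure = cfg$exposure, outcome = cfg$outcome)),
    lapply(cfg$mediators, function(m) list(exposure = cfg$exposure, outcome = m)))
  step1 <- run_block(step1_pairs, "step1")

  # Step two: each mediator on the outcome.
  step2_pairs <- lapply(cfg$mediators,
                        function(m) list(exposure = m, outcome = cfg$outcome))
  step2 <- run_block(step2_pairs, "step2")

  pair_key <- function(a, b) paste(a, b, sep = "->")
  total_key <- pair_key(cfg$exposure, cfg$outcome)
  total <- if (!is.null(step1$results[[total_key]]))
    step1$results[[total_key]]$ivw else NULL

  triage <- NULL
  mediation_rows <- list()
  bundle_mediation <- NULL
  if (length(cfg$mediators)) {
    s1 <- s2 <- list()
    for (m in cfg$mediators) {
      s1[[m]] <- step1$results[[pair_key(cfg$exposure, m)]] %||% list()
      s2[[m]] <- step2$results[[pair_key(m, cfg$outcome)]] %||% list()
    }
    triage <- mediator_triage(s1, s2)
    passing <- triage$mediator[triage$status == "pass"]
    log_lines <- c(log_lines, sprintf("triage: %s",
      paste(sprintf("%s=%s", triage$mediator, triage$status), collapse = " ")))

    if (length(passing) && !is.null(total)) {
      model_sets <- c(lapply(passing, function(m) m),
                      if (length(passing) > 1) list(passing) else NULL)
      model_id <- 0L
      for (med_set in model_sets) {
        model_id <- model_id + 1L
        med_set <- as.character(med_set)
        fit <- tryCatch({
          med_assoc <- lapply(setNames(med_set, med_set),
                              function(m) study[[m]]$associations)
          # The multivariable design needs SNPs that separate the exposure
          # and mediator pathways: use the union of the exposure's and the
          # included mediators' instruments, with every SNP's exposure
          # association taken from the exposure's genome-wide table.
          inst_ids <- study[[cfg$exposure]]$instruments$records$variant_id
          for (m in med_set) {
            mi <- study[[m]]$instruments
            if (!is.null(mi)) inst_ids <- union(inst_ids, mi$records$variant_id)
          }
          exp_assoc <- study[[cfg$exposure]]$associations
          combined <- instrument_set(
            cfg$exposure, exp_assoc$trait_type, exp_assoc$unit_label,
            exp_assoc$records[exp_assoc$records$variant_id %in% inst_ids, ,
                              drop = FALSE])
          h <- harmonise(combined, study[[cfg$outcome]]$associations,
                         mediators = med_assoc,
                         palindrome_policy = cfg$settings$palindrome_policy,
                         eaf_window = cfg$settings$eaf_window)
          mvmr_ivw(h)
        }, error = function(e) e)
        if (inherits(fit, "error")) {
          log_lines <- c(log_lines, sprintf("mediation model [%s] FAILED: %s",
                                            paste(med_set, collapse = "+"),
                                            conditionMessage(fit)))
          next
        }
        any_binary <- any(vapply(med_set, function(m)
          identical(cfg$traits[[m]]$type, "binary"), logical(1)))
        prop <- NA_real_
        tag <- NA_character_
        if (!any_binary) {
          pm <- proportion_mediated(total, fit, mediator_binary = FALSE)
          prop <- pm$proportion_mediated
          tag <- pm$formula_tag
        } else {
          log_lines <- c(log_lines, sprintf(
            "mediation model [%s]: proportion not computed (binary mediator)",
            paste(med_set, collapse = "+")))
        }
        binary_out <- identical(cfg$traits[[cfg$outcome]]$type, "binary")
        mediation_rows[[length(mediation_rows) + 1L]] <- data.frame(
          model = sprintf("adjusted_for_%s", paste(med_set, collapse = "+")),
          mediators = paste(med_set, collapse = "+"),
          n_snps = fit$n_snps,
          direct_beta = fit$direct_beta, direct_se = fit$direct_se,
          ci_low = fit$direct_ci_low, ci_high = fit$direct_ci_high,
          pvalue = fit$direct_p,
          or = if (binary_out) exp(fit$direct_beta) else NA_real_,
          or_ci_low = if (binary_out) exp(fit$direct_ci_low) else NA_real_,
          or_ci_high = if (binary_out) exp(fit$direct_ci_high) else NA_real_,
          proportion_mediated = prop, formula_tag = tag,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(total)) {
      crude <- data.frame(
        model = "crude", mediators = "", n_snps = total$n_snps,
        direct_beta = total$beta, direct_se = total$se,
        ci_low = total$ci_low, ci_high = total$ci_high, pvalue = total$pvalue,
        or = if (is.null(total$or_scale)) NA_real_ else
          unname(total$or_scale["or"]),
        or_ci_low = if (is.null(total$or_scale)) NA_real_ else
          unname(total$or_scale["or_ci_low"]),
        or_ci_high = if (is.null(total$or_scale)) NA_real_ else
          unname(total$or_scale["or_ci_high"]),
        proportion_mediated = NA_real_, formula_tag = NA_character_,
        stringsAsFactors = FALSE)
      bundle_mediation <- do.call(rbind, c(list(crude), mediation_rows))
    }
  }

  bundle <- list(
    config = list(exposure = cfg$exposure, outcome = cfg$outcome,
                  mediators = cfg$mediators, settings = cfg$settings),
    instrument_strength = strength,
    screen = screen,
    step1 = step1$table,
    step2 = step2$table,
    triage = triage,
    mediation = bundle_mediation)

  write_report_bundle(bundle, log_lines, cfg$output_dir)
  invisible(bundle)
}

# Serialise the bundle: TSV per table (numbers formatted %.17g so the TSVs
# and the JSON round-trip to identical doubles), one JSON with everything,
# and the run log.
write_report_bundle <- function(bundle, log_lines, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("instrument_strength", "screen", "step1", "step2", "triage",
              "mediation")
  for (nm in tables) {
    df <- bundle[[nm]]
    if (is.null(df)) next
    out <- df
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v)
      ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
    data.table::fwrite(out, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, na = "NA")
  }
  # digits = I(17): shortest-exact is not available, but 17 significant
  # digits round-trip IEEE doubles exactly, keeping JSON == TSV
  jsonlite::write_json(bundle, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = I(17), dataframe = "rows",
                       na = "null", null = "null", pretty = TRUE)
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
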