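# Tests of association between each derived variable and the trait of
# interest. The phenotype is the dependent variable and the trait the
# independent variable, adjusted for confounders: age at recruitment and sex
# by default (plus a genotype-chip indicator when the trait is genetic), or
# exactly the columns of a supplied confounder file. Model by data type:
# linear (continuous), binomial (binary), proportional-odds ordinal logistic
# (ordered), multinomial logistic with a likelihood-ratio model p-value
# (unordered). Complete-case per variable; variables with fewer than 500
# complete cases, and unordered variables with more than 1000 categories, are
# removed and counted, never tested.

MIN_SAMPLE_SIZE <- 500L
MAX_UNORDERED_CATEGORIES <- 1000L

#' Define the regression adjustment for a scan
#'
#' @param trait_name Name of the trait of interest.
#' @param confounder_names Confounders entering every regression. `NULL`
#'   selects the defaults: age and sex, plus `genotype_chip` when
#'   `genetic = TRUE` (the chip indicator is derived from the genotype
#'   measurement batch by the user; see [chip_from_batch()]). When a
#'   confounder file is supplied to [assemble_dataset()], pass its column
#'   names here — they are used exactly.
#' @param genetic Is the trait of interest a genetic variant or score?
#' @return A `phs_model_spec`.
#' @export
model_spec <- function(trait_name, confounder_names = NULL, genetic = FALSE) {
  if (is.null(confounder_names)) {
    confounder_names <- c("age", "sex", if (isTRUE(genetic)) "genotype_chip")
  }
  phs_assert(!(trait_name %in% confounder_names), "schema_error",
             "trait of interest may not appear among the confounders")
  structure(list(trait_name = trait_name, confounder_names = confounder_names,
                 genetic = isTRUE(genetic)),
            class = "phs_model_spec")
}

#' Derive a binary genotype-chip indicator from batch labels
#'
#' Genotyping batches map many-to-one onto the chip used; this helper turns a
#' batch label column into the 0/1 chip covariate used when the trait of
#' interest is genetic.
#'
#' @param batch Character or factor vector of batch labels.
#' @param chip_levels Batch labels belonging to the second chip (coded 1).
#' @return Integer 0/1 vector.
#' @export
chip_from_batch <- function(batch, chip_levels) {
  as.integer(as.character(batch) %in% chip_levels)
}

# Build the complete-case model frame for one derived variable. Confounders
# constant on the complete cases (e.g. sex for a sex-specific field) are
# dropped, logged.
model_frame <- function(dv, dataset, spec) {
  conf <- dataset$confounders
  use_conf <- intersect(spec$confounder_names, names(conf))
  absent <- setdiff(spec$confounder_names, names(conf))
  if (length(absent) > 0L) {
    phs_log("variable %s: confounder(s) %s not in dataset; omitted",
            dv$name, paste(absent, collapse = ", "))
  }
  df <- data.frame(outcome = dv$values, trait = dataset$trait)
  for (cn in use_conf) df[[cn]] <- conf[[cn]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  dropped <- character(0)
  for (cn in use_conf) {
    if (length(unique(df[[cn]])) < 2L) {
      df[[cn]] <- NULL
      dropped <- c(dropped, cn)
    }
  }
  if (length(dropped) > 0L) {
    phs_log("variable %s: confounder(s) %s constant on complete cases; dropped",
            dv$name, paste(dropped, collapse = ", "))
  }
  df
}

rhs_formula <- function(df, with_trait = TRUE) {
  terms <- c(if (with_trait) "trait", setdiff(names(df), c("outcome", "trait")))
  if (length(terms) == 0L) terms <- "1"
  stats::as.formula(paste("outcome ~", paste(terms, collapse = " + ")))
}

check_trait_varies <- function(df, name) {
  phs_assert(length(unique(df$trait)) >= 2L, "degenerate_exposure",
             sprintf("variable %s: trait constant on complete cases", name))
}

new_result <- function(dv, n, estimate = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, p_value = NA_real_,
                       converged = TRUE) {
  data.table::data.table(
    varName = dv$name, field_id = dv$field_id, data_type = dv$data_type,
    n = as.integer(n), estimate = estimate, ci_lower = ci_lower,
    ci_upper = ci_upper, p_value = p_value, converged = converged,
    validation_only = dv$validation_only)
}

#' Linear regression of a continuous derived variable on the trait
#'
#' The (already rank-normalised) phenotype is regressed on the trait plus
#' confounders; the result carries the trait coefficient, its Wald 95% CI and
#' two-sided p-value. The coefficient reads as SDs of phenotype per unit
#' trait.
#'
#' @param dv A CONTINUOUS `phs_derived`.
#' @param dataset A `phs_dataset`.
#' @param spec A `phs_model_spec`.
#' @return One-row result `data.table`.
#' @export
test_linear <- function(dv, dataset, spec) {
  df <- model_frame(dv, dataset, spec)
  check_trait_varies(df, dv$name)
  fit <- stats::lm(rhs_formula(df), data = df)
  co <- summary(fit)$coefficients
  if (!("trait" %in% rownames(co)) || anyNA(coef(fit))) {
    phs_log("variable %s: rank-deficient linear fit", dv$name)
    return(new_result(dv, nrow(df), converged = FALSE))
  }
  est <- co["trait", "Estimate"]
  se <- co["trait", "Std. Error"]
  new_result(dv, nrow(df), estimate = est,
             ci_lower = est - stats::qnorm(0.975) * se,
             ci_upper = est + stats::qnorm(0.975) * se,
             p_value = co["trait", "Pr(>|t|)"])
}

#' Binomial regression of a binary derived variable on the trait
#'
#' Logistic regression; the estimate is the odds ratio per unit trait with a
#' Wald 95% CI and two-sided p-value. Complete separation is reported as a
#' non-converged result (retained, p absent) rather than dropped.
#'
#' @inheritParams test_linear
#' @param dv A BINARY `phs_derived`.
#' @return One-row result `data.table`.
#' @export
test_logistic <- function(dv, dataset, spec) {
  df <- model_frame(dv, dataset, spec)
  check_trait_varies(df, dv$name)
  phs_assert(length(unique(df$outcome)) == 2L, "degenerate_outcome",
             sprintf("variable %s: a single outcome class on complete cases", dv$name))
  df$outcome <- as.integer(df$outcome == max(df$outcome))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(rhs_formula(df), data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || !fit$converged) {
    phs_log("variable %s: logistic fit did not converge (separation?)", dv$name)
    return(new_result(dv, nrow(df), converged = FALSE))
  }
  co <- summary(fit)$coefficients
  if (!("trait" %in% rownames(co))) return(new_result(dv, nrow(df), converged = FALSE))
  b <- co["trait", "Estimate"]
  se <- co["trait", "Std. Error"]
  new_result(dv, nrow(df), estimate = exp(b),
             ci_lower = exp(b - stats::qnorm(0.975) * se),
             ci_upper = exp(b + stats::qnorm(0.975) * se),
             p_value = co["trait", "Pr(>|z|)"])
}

#' Ordinal (proportional-odds) logistic regression of an ordered variable
#'
#' Fits a proportional-odds model ([MASS::polr]); the estimate is the odds
#' ratio per unit trait with a Wald 95% CI. The p-value comes, by default,
#' from a likelihood-ratio test of the trait term against the
#' confounders-only model (`p_method = "wald"` gives the Wald z-test
#' instead). Outcome levels empty on the complete cases are dropped (logged);
#' a variable left with 2 levels is tested with [test_logistic()].
#'
#' @inheritParams test_linear
#' @param dv An ORDERED `phs_derived`.
#' @param p_method `"lrt"` (default) or `"wald"`.
#' @return One-row result `data.table`.
#' @export
test_ordered <- function(dv, dataset, spec, p_method = c("lrt", "wald")) {
  p_method <- match.arg(p_method)
  df <- model_frame(dv, dataset, spec)
  check_trait_varies(df, dv$name)
  lev <- sort(unique(df$outcome))
  if (length(lev) < length(unique(dv$values[!is.na(dv$values)]))) {
    phs_log("variable %s: empty outcome level(s) dropped on complete cases", dv$name)
  }
  if (length(lev) == 2L) {
    return(test_logistic(dv, dataset, spec))
  }
  phs_assert(length(lev) >= 3L, "degenerate_outcome",
             sprintf("variable %s: <2 outcome levels", dv$name))
  df$outcome <- factor(df$outcome, levels = lev, ordered = TRUE)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(rhs_formula(df), data = df, Hess = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) || !("trait" %in% names(coef(fit)))) {
    phs_log("variable %s: ordinal fit failed", dv$name)
    return(new_result(dv, nrow(df), converged = FALSE))
  }
  b <- coef(fit)[["trait"]]
  se <- sqrt(diag(stats::vcov(fit)))[["trait"]]
  if (p_method == "lrt") {
    fit0 <- tryCatch(
      suppressWarnings(MASS::polr(rhs_formula(df, with_trait = FALSE), data = df)),
      error = function(e) NULL)
    if (is.null(fit0)) return(new_result(dv, nrow(df), converged = FALSE))
    lr <- 2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(fit0)))
    p <- stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE)
  } else {
    p <- 2 * stats::pnorm(-abs(b / se))
  }
  new_result(dv, nrow(df), estimate = exp(b),
             ci_lower = exp(b - stats::qnorm(0.975) * se),
             ci_upper = exp(b + stats::qnorm(0.975) * se),
             p_value = p)
}

#' Multinomial logistic regression of an unordered variable (LRT p-value)
#'
#' Fits the full multinomial model (trait + confounders) and the null model
#' (confounders only) with [nnet::multinom]; the model p-value is the
#' likelihood-ratio statistic \eqn{2(\ell_{full} - \ell_{null})} referred to a
#' chi-square with K-1 degrees of freedom (K outcome categories). No overall
#' estimate or CI exists for these models.
#'
#' @inheritParams test_linear
#' @param dv An UNORDERED `phs_derived`.
#' @return One-row result `data.table` with `estimate`, `ci_lower`, `ci_upper`
#'   absent (`NA`).
#' @export
test_unordered_lrt <- function(dv, dataset, spec) {
  df <- model_frame(dv, dataset, spec)
  check_trait_varies(df, dv$name)
  k <- length(unique(df$outcome))
  phs_assert(k <= MAX_UNORDERED_CATEGORIES, "category_limit",
             sprintf("variable %s: %d categories exceeds the %d-category limit",
                     dv$name, k, MAX_UNORDERED_CATEGORIES))
  phs_assert(k >= 3L, "degenerate_outcome",
             sprintf("variable %s: %d outcome categories", dv$name, k))
  df$outcome <- factor(df$outcome)
  quiet_multinom <- function(formula) {
    fit <- nnet::multinom(formula, data = df, trace = FALSE,
                          maxit = 500L, MaxNWts = 100000L)
    fit
  }
  fit1 <- tryCatch(quiet_multinom(rhs_formula(df)), error = function(e) NULL)
  fit0 <- tryCatch(quiet_multinom(rhs_formula(df, with_trait = FALSE)),
                   error = function(e) NULL)
  if (is.null(fit1) || is.null(fit0)) {
    phs_log("variable %s: multinomial fit failed", dv$name)
    return(new_result(dv, nrow(df), converged = FALSE))
  }
  lr <- 2 * (as.numeric(stats::logLik(fit1)) - as.numeric(stats::logLik(fit0)))
  p <- stats::pchisq(max(lr, 0), df = k - 1L, lower.tail = FALSE)
  res <- new_result(dv, nrow(df), p_value = p,
                    converged = fit1$convergence == 0L && fit0$convergence == 0L)
  res
}

#' Run the association scan over a set of derived variables
#'
#' Dispatches each derived variable to the regression matching its data type.
#' Variables with fewer than 500 complete cases (outcome, trait and all
#' confounders non-missing) are removed and counted, as are unordered
#' variables with more than 1000 categories and degenerate variables (single
#' outcome class, constant trait). Model failures yield flagged, retained
#' results; the scan never aborts on a single variable.
#'
#' @param derived List of `phs_derived` variables.
#' @param dataset A `phs_dataset`.
#' @param spec A `phs_model_spec`.
#' @param ordered_p_method p-value method for ordered models (see
#'   [test_ordered()]).
#' @return List with `results` (one row per tested variable) and `counters`
#'   (`data.table` of scan-level removals).
#' @export
run_scan <- function(derived, dataset, spec,
                     ordered_p_method = c("lrt", "wald")) {
  ordered_p_method <- match.arg(ordered_p_method)
  scan_counters <- data.table::data.table(
    variables_entered = length(derived), removed_small_n = 0L,
    removed_too_many_categories = 0L, removed_degenerate = 0L,
    tested = 0L)
  rows <- vector("list", length(derived))
  conf_present <- intersect(spec$confounder_names, names(dataset$confounders))
  for (i in seq_along(derived)) {
    dv <- derived[[i]]
    cc <- !is.na(dv$values) & !is.na(dataset$trait)
    for (cn in conf_present) cc <- cc & !is.na(dataset$confounders[[cn]])
    n_cc <- sum(cc)
    if (n_cc < MIN_SAMPLE_SIZE) {
      bump(scan_counters, "removed_small_n")
      phs_log("variable %s: removed, %d complete cases < %d",
              dv$name, n_cc, MIN_SAMPLE_SIZE)
      next
    }
    if (dv$data_type == "UNORDERED" &&
        length(unique(dv$values[cc])) > MAX_UNORDERED_CATEGORIES) {
      bump(scan_counters, "removed_too_many_categories")
      phs_log("variable %s: removed, >%d categories", dv$name,
              MAX_UNORDERED_CATEGORIES)
      next
    }
    res <- tryCatch({
      switch(dv$data_type,
             CONTINUOUS = test_linear(dv, dataset, spec),
             BINARY = test_logistic(dv, dataset, spec),
             ORDERED = test_ordered(dv, dataset, spec, p_method = ordered_p_method),
             UNORDERED = test_unordered_lrt(dv, dataset, spec))
    },
    phs_category_limit = function(e) {
      bump(scan_counters, "removed_too_many_categories")
      phs_log("%s", conditionMessage(e)); NULL
    },
    phenomescan_error = function(e) {
      bump(scan_counters, "removed_degenerate")
      phs_log("variable %s: removed (%s)", dv$name, conditionMessage(e)); NULL
    })
    if (is.null(res)) next
    bump(scan_counters, "tested")
    rows[[i]] <- res
  }
  results <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  phs_log("scan: %d variables entered, %d tested, %d removed (n<%d), %d removed (>%d categories), %d removed degenerate",
          scan_counters$variables_entered, scan_counters$tested,
          scan_counters$removed_small_n, MIN_SAMPLE_SIZE,
          scan_counters$removed_too_many_categories, MAX_UNORDERED_CATEGORIES,
          scan_counters$removed_degenerate)
  list(results = results, counters = scan_counters)
}
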