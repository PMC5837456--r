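# Synthetic cohort generator. Emits complete, self-consistent scan inputs —
# phenotype CSV, trait of interest, confounders, variable-information and
# data-coding files, category hierarchy — with known ground truth per field,
# so the whole engine is testable without any restricted data.
#
# The trait of interest emulates a weighted allele score: a sum over simulated
# biallelic variant dosages weighted by their effect sizes, standardised to
# unit SD. Effects on phenotypes are injected on the natural link scale of the
# regression that will test them: linear shift for continuous fields,
# log-odds for binary fields, proportional-odds log-OR for ordered fields,
# category-specific log-odds for unordered fields.

#' Build a simulation configuration
#'
#' @param n_participants Cohort size (default 5000: small enough for routine
#'   runs, large enough that fields clear the 500-complete-case filter).
#' @param seed Integer seed; fully determines every generated file.
#' @param field_plan List of field plans (default [default_field_plan()]),
#'   each a list with `field_id`, `field_type`, `shape` and shape-specific
#'   parameters, a link-scale `effect`, `missing_rate`, and optional flags
#'   (`excluded`, `trait_equivalent`, `n_arrays`, `extra_instance`, ...).
#' @param n_variants Number of variants in the allele score (default 96).
#' @param trait_age_loading Optional loading of (standardised) age on the
#'   trait, creating a confounded cohort for adjustment tests (default 0: a
#'   genetic score is independent of age and sex).
#' @param conf_effects Link-scale effects of the confounders on every
#'   phenotype: `age` per year (age is centred at 57) and `sex` (0/1).
#' @return A `phs_sim_config`.
#' @export
simulation_config <- function(n_participants = 5000L, seed = 2026L,
                              field_plan = default_field_plan(),
                              n_variants = 96L, trait_age_loading = 0,
                              conf_effects = c(age = 0.02, sex = 0.2)) {
  phs_assert(n_participants >= 1L, "config_error", "n_participants must be >= 1")
  phs_assert(all(c("age", "sex") %in% names(conf_effects)), "config_error",
             "conf_effects must name age and sex")
  ids <- vapply(field_plan, function(f) as.integer(f$field_id), 1L)
  dup <- ids[duplicated(ids)]
  phs_assert(length(dup) == 0L, "config_error",
             sprintf("duplicate field id(s) in plan: %s", paste(dup, collapse = ", ")))
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), field_plan = field_plan,
                 n_variants = as.integer(n_variants),
                 trait_age_loading = trait_age_loading,
                 conf_effects = conf_effects),
            class = "phs_sim_config")
}

#' Plan one simulated field
#'
#' @param field_id Field id (unique within a plan).
#' @param field_type Declared biobank field type (`"CONTINUOUS"`, `"INTEGER"`,
#'   `"CAT_SINGLE"`, `"CAT_MULTIPLE"`).
#' @param shape Generator shape: `"normal"`, `"zero_inflated"` (`p_zero`),
#'   `"quantile_levels"` (`n_levels`), `"ordered_levels"` (`n_levels`),
#'   `"unordered_levels"` (`n_levels`), `"binary"`, `"cases_only"`
#'   (`prevalence`), `"multi_select"` (`n_values`, `cat_mult_option`).
#' @param effect Link-scale effect of the trait on this field (0 = null).
#' @param ... Shape-specific parameters (see `shape`), plus `n_arrays` and
#'   `extra_instance` for continuous fields.
#' @param missing_rate Missing-completely-at-random rate.
#' @param excluded,trait_equivalent Per-scan flags copied into the generated
#'   variable-information file.
#' @return A plan entry for [simulation_config()].
#' @export
plan_field <- function(field_id, field_type, shape, effect = 0, ...,
                       missing_rate = 0.02, excluded = FALSE,
                       trait_equivalent = FALSE) {
  c(list(field_id = as.integer(field_id), field_type = field_type,
         shape = shape, effect = effect, missing_rate = missing_rate,
         excluded = excluded, trait_equivalent = trait_equivalent),
    list(...))
}

#' Default field plan
#'
#' Roughly sixty fields spanning every branch of the decision flow: plain and
#' repeat-measured continuous fields, zero-inflated continuous fields routed
#' to binning, integer fields at the 2 / 20 / 21 distinct-value boundaries,
#' ordered and unordered categorical (single) fields, a default-value field,
#' categorical (multiple) fields with negative missingness codes, a
#' high-missingness field below the sample-size filter, a trait-equivalent
#' field and an a-priori excluded field. Null fields (effect 0) dominate, as
#' in a real phenome.
#'
#' @return List of field plans for [simulation_config()].
#' @export
default_field_plan <- function() {
  plan <- list()
  add <- function(...) plan[[length(plan) + 1L]] <<- plan_field(...)

  # continuous, normal errors; 1010 averages 3 array repeats, 1011 carries a
  # second (ignored) instance
  for (i in 0:7) add(1001 + i, "CONTINUOUS", "normal", effect = 0)
  add(1010, "CONTINUOUS", "normal", effect = 0.10, n_arrays = 3L)
  add(1011, "CONTINUOUS", "normal", effect = 0.08, extra_instance = TRUE)
  add(1012, "CONTINUOUS", "normal", effect = -0.10)
  add(1013, "CONTINUOUS", "normal", effect = 0.15)
  # zero-inflated (most participants at zero), routed to 3 ordered bins
  add(1020, "CONTINUOUS", "zero_inflated", effect = 0, p_zero = 0.6)
  add(1021, "CONTINUOUS", "zero_inflated", effect = 0.20, p_zero = 0.6)
  add(1022, "CONTINUOUS", "zero_inflated", effect = -0.20, p_zero = 0.5)
  # sample-size filter: almost entirely missing
  add(1030, "CONTINUOUS", "normal", effect = 0, missing_rate = 0.95)
  # trait-equivalent phenotype (essentially the trait itself, e.g. weight
  # when the trait proxies adiposity): validation only
  add(1040, "CONTINUOUS", "normal", effect = 1.0, trait_equivalent = TRUE)
  # excluded a priori
  add(1041, "CONTINUOUS", "normal", effect = 0, excluded = TRUE)

  # integers across the distinct-value boundaries
  for (i in 0:3) add(2001 + i, "INTEGER", "quantile_levels", effect = 0,
                     n_levels = c(2L, 3L, 5L, 20L)[i + 1])
  add(2005, "INTEGER", "quantile_levels", effect = 0, n_levels = 21L)
  add(2006, "INTEGER", "quantile_levels", effect = 0, n_levels = 50L)
  add(2010, "INTEGER", "quantile_levels", effect = 0.20, n_levels = 2L)
  add(2011, "INTEGER", "quantile_levels", effect = 0.15, n_levels = 5L)
  add(2012, "INTEGER", "quantile_levels", effect = 0.12, n_levels = 20L)
  add(2013, "INTEGER", "quantile_levels", effect = 0.10, n_levels = 30L)
  add(2014, "INTEGER", "quantile_levels", effect = 0, n_levels = 3L)
  add(2015, "INTEGER", "quantile_levels", effect = 0, n_levels = 12L)

  # categorical (single), ordered; data codes shared per level count
  for (i in 0:4) add(3001 + i, "CAT_SINGLE", "ordered_levels", effect = 0,
                     n_levels = c(3L, 3L, 4L, 5L, 5L)[i + 1])
  add(3010, "CAT_SINGLE", "ordered_levels", effect = 0.15, n_levels = 3L)
  add(3011, "CAT_SINGLE", "ordered_levels", effect = -0.15, n_levels = 4L)
  add(3012, "CAT_SINGLE", "ordered_levels", effect = 0.12, n_levels = 5L)
  # categorical (single), unordered
  for (i in 0:3) add(3020 + i, "CAT_SINGLE", "unordered_levels", effect = 0,
                     n_levels = c(3L, 3L, 4L, 6L)[i + 1])
  add(3030, "CAT_SINGLE", "unordered_levels", effect = 0.25, n_levels = 3L)
  add(3031, "CAT_SINGLE", "unordered_levels", effect = 0.25, n_levels = 4L)
  # categorical (single), binary
  for (i in 0:3) add(3040 + i, "CAT_SINGLE", "binary", effect = 0)
  add(3050, "CAT_SINGLE", "binary", effect = 0.10)
  add(3051, "CAT_SINGLE", "binary", effect = -0.10)
  add(3052, "CAT_SINGLE", "binary", effect = 0.20)
  # recorded-cases-only field: value 1 recorded, the data code's default value
  # 0 fills everyone else (hospital-diagnosis style)
  add(3060, "CAT_SINGLE", "cases_only", effect = 0.10, prevalence = 0.15)

  # categorical (multiple): several values per participant, some unknown
  # (negative) codes
  add(4001, "CAT_MULTIPLE", "multi_select", effect = 0, n_values = 5L,
      cat_mult_option = "RESPONDERS")
  add(4002, "CAT_MULTIPLE", "multi_select", effect = 0.20, n_values = 5L,
      cat_mult_option = "RESPONDERS")
  add(4003, "CAT_MULTIPLE", "multi_select", effect = 0, n_values = 3L,
      cat_mult_option = "OTHER_VALUE_HOLDERS")
  add(4004, "CAT_MULTIPLE", "multi_select", effect = 0.15, n_values = 3L,
      cat_mult_option = "ALL")

  # padding nulls so the phenome is dominated by nulls (~60 fields total)
  for (i in 0:9) add(1101 + i, "CONTINUOUS", "normal", effect = 0)
  plan
}

#' Inject (or zero) associations in a configuration
#'
#' @param config A `phs_sim_config`.
#' @param field_ids Fields to modify; must exist in the plan.
#' @param effects Link-scale effect sizes, recycled against `field_ids`.
#' @return The updated `phs_sim_config` (ground truth follows automatically).
#' @export
inject_associations <- function(config, field_ids, effects) {
  effects <- rep_len(effects, length(field_ids))
  plan_ids <- vapply(config$field_plan, function(f) f$field_id, 1L)
  for (i in seq_along(field_ids)) {
    j <- match(field_ids[i], plan_ids)
    phs_assert(!is.na(j), "config_error",
               sprintf("field %d not in the simulation plan", field_ids[i]))
    config$field_plan[[j]]$effect <- effects[i]
  }
  config
}

# expected decision-flow routing of a plan entry (for ground truth / coverage)
expected_route <- function(f) {
  switch(f$shape,
    normal = "CONTINUOUS",
    zero_inflated = "ORDERED",
    quantile_levels = if (f$n_levels == 2L) "BINARY"
                      else if (f$n_levels <= 20L) "ORDERED" else "CONTINUOUS",
    ordered_levels = "ORDERED",
    unordered_levels = "UNORDERED",
    binary = "BINARY",
    cases_only = "BINARY",
    multi_select = "BINARY")
}

#' Generate a synthetic cohort
#'
#' @param config A `phs_sim_config`.
#' @return List with `pheno` (participant id + raw field columns), `trait`
#'   (`userId`, `score`), `confounders` (`userId`, `age`, `sex`,
#'   `genotype_chip`), and `ground_truth` (per field: shape, link-scale
#'   effect, expected data-type routing).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phs_sim_config"))
  n <- config$n_participants
  with_local_seed(config$seed, {
    # confounders: recruitment-age range, balanced sex, two genotyping chips
    age <- round(runif(n, 40, 70))
    sex <- rbinom(n, 1L, 0.5)
    chip <- rbinom(n, 1L, 0.5)
    # weighted allele score over simulated biallelic dosages
    maf <- runif(config$n_variants, 0.1, 0.5)
    w <- abs(rnorm(config$n_variants, 0.05, 0.02))
    dosage <- matrix(rbinom(n * config$n_variants, 2L, rep(maf, each = n)), nrow = n)
    score <- as.vector(dosage %*% w)
    score <- score + config$trait_age_loading * (age - 57) / 8
    score <- (score - mean(score)) / stats::sd(score)

    linpred <- function(f) {
      f$effect * score +
        config$conf_effects[["age"]] * (age - 57) +
        config$conf_effects[["sex"]] * sex
    }
    apply_missing <- function(x, rate) {
      x[runif(length(x)) < rate] <- NA
      x
    }

    cols <- list(userId = sprintf("P%06d", seq_len(n)))
    gt <- list()
    for (f in config$field_plan) {
      lp <- linpred(f)
      cn <- function(instance, array) sprintf("x%d_%d_%d", f$field_id, instance, array)
      if (f$shape == "normal") {
        y <- lp + rnorm(n)
        n_arrays <- f$n_arrays %||% 1L
        if (n_arrays > 1L) {
          for (a in seq_len(n_arrays) - 1L) {
            cols[[cn(0L, a)]] <- apply_missing(round(y + rnorm(n, 0, 0.15), 4),
                                               f$missing_rate)
          }
        } else {
          cols[[cn(0L, 0L)]] <- apply_missing(round(y, 4), f$missing_rate)
        }
        if (isTRUE(f$extra_instance)) {
          cols[[cn(2L, 0L)]] <- apply_missing(round(y + rnorm(n, 0, 0.3), 4),
                                              f$missing_rate)
        }
      } else if (f$shape == "zero_inflated") {
        latent <- lp + rnorm(n)
        cut0 <- stats::quantile(latent, f$p_zero)
        y <- round(pmax(0, latent - cut0), 2)
        cols[[cn(0L, 0L)]] <- apply_missing(y, f$missing_rate)
      } else if (f$shape == "quantile_levels") {
        # equal-mass levels 0..L-1, monotone in the latent scale
        latent <- lp + stats::rlogis(n)
        br <- unique(stats::quantile(latent, seq(0, 1, length.out = f$n_levels + 1L)))
        y <- as.integer(cut(latent, br, include.lowest = TRUE)) - 1L
        cols[[cn(0L, 0L)]] <- apply_missing(y, f$missing_rate)
      } else if (f$shape == "ordered_levels") {
        # proportional-odds data: logistic latent cut into L levels 1..L,
        # with a sprinkling of negative do-not-know codes
        latent <- lp + stats::rlogis(n)
        br <- unique(stats::quantile(latent, seq(0, 1, length.out = f$n_levels + 1L)))
        y <- as.numeric(cut(latent, br, include.lowest = TRUE))
        y[runif(n) < 0.02] <- -1
        cols[[cn(0L, 0L)]] <- apply_missing(y, f$missing_rate)
      } else if (f$shape == "unordered_levels") {
        # multinomial logit; the effect loads on category 2's utility
        K <- f$n_levels
        util <- matrix(rnorm(n * K, 0, 1), n, K)
        util[, 2] <- util[, 2] + f$effect * score
        util[, 1] <- util[, 1] + config$conf_effects[["age"]] * (age - 57) / 2
        y <- max.col(util)
        y[runif(n) < 0.02] <- -1
        cols[[cn(0L, 0L)]] <- apply_missing(as.numeric(y), f$missing_rate)
      } else if (f$shape == "binary") {
        y <- rbinom(n, 1L, plogis(lp)) + 1  # category codes 1/2
        y[runif(n) < 0.02] <- -1
        cols[[cn(0L, 0L)]] <- apply_missing(as.numeric(y), f$missing_rate)
      } else if (f$shape == "cases_only") {
        # only cases carry a record; the data code's default value 0 fills the rest
        a <- stats::qlogis(f$prevalence)
        case <- rbinom(n, 1L, plogis(a + lp)) == 1L
        y <- rep(NA_real_, n)
        y[case] <- 1
        cols[[cn(0L, 0L)]] <- y
      } else if (f$shape == "multi_select") {
        M <- f$n_values
        hold <- matrix(0L, n, M)
        for (v in seq_len(M)) {
          b <- if (v == 1L) f$effect else 0
          hold[, v] <- rbinom(n, 1L, plogis(-0.8 + b * score))
        }
        responded <- rowSums(hold) > 0L
        unknown <- responded & (runif(n) < 0.03)  # extra 'not known' code
        nonresp <- runif(n) < f$missing_rate
        arr <- matrix(NA_real_, n, M + 1L)
        for (i in seq_len(n)) {
          if (nonresp[i] || !responded[i]) next
          vals <- which(hold[i, ] == 1L)
          if (unknown[i]) vals <- c(vals, -1)
          arr[i, seq_along(vals)] <- vals
        }
        for (a in seq_len(M + 1L) - 1L) cols[[cn(0L, a)]] <- arr[, a + 1L]
      } else {
        phs_error("config_error", sprintf("unknown field shape '%s'", f$shape))
      }
      gt[[length(gt) + 1L]] <- data.table::data.table(
        field_id = f$field_id, field_type = f$field_type, shape = f$shape,
        effect = f$effect, expected_type = expected_route(f),
        excluded = isTRUE(f$excluded),
        trait_equivalent = isTRUE(f$trait_equivalent))
    }

    list(pheno = data.table::as.data.table(cols),
         trait = data.table::data.table(userId = cols$userId, score = score),
         confounders = data.table::data.table(userId = cols$userId, age = age,
                                              sex = sex, genotype_chip = chip),
         ground_truth = data.table::rbindlist(gt))
  })
}

# data-code id shared by fields of the same categorical structure
plan_data_code <- function(f) {
  switch(f$shape,
    ordered_levels = 500L + f$n_levels,
    unordered_levels = 600L + f$n_levels,
    binary = 700L,
    cases_only = 710L,
    multi_select = 800L,
    NA_integer_)
}

#' Generate the metadata files matching a configuration
#'
#' Variable information, data codings and a small category hierarchy, all
#' consistent with the cohort [generate_cohort()] emits from the same
#' configuration: every field has a metadata row, every categorical field's
#' coding covers its values.
#'
#' @param config A `phs_sim_config`.
#' @return List with `variable_info` (`data.table`), `codings` (list of
#'   `phs_data_coding`), `categories` and `field_map` (hierarchy tables).
#' @export
generate_metadata_files <- function(config) {
  vi <- data.table::rbindlist(lapply(config$field_plan, function(f) {
    data.table::data.table(
      field_id = f$field_id, field_type = f$field_type,
      data_code = plan_data_code(f),
      excluded = isTRUE(f$excluded),
      trait_equivalent = isTRUE(f$trait_equivalent),
      cat_mult_missingness = if (f$field_type == "CAT_MULTIPLE")
        (f$cat_mult_option %||% "RESPONDERS") else NA_character_)
  }))
  codings <- list()
  for (f in config$field_plan) {
    code <- plan_data_code(f)
    if (is.na(code) || !is.null(codings[[as.character(code)]])) next
    codings[[as.character(code)]] <- switch(f$shape,
      ordered_levels = data_coding(code, TRUE, ordering = seq_len(f$n_levels),
                                   reassignments = list(from = -3, to = NA_real_)),
      unordered_levels = data_coding(code, FALSE),
      binary = data_coding(code, FALSE),
      cases_only = data_coding(code, FALSE, default_value = 0),
      multi_select = data_coding(code, FALSE))
  }
  # two-level hierarchy: root plus one category per field-id block
  categories <- data.table::data.table(
    category_id = c(0L, 1L, 2L, 3L, 4L),
    parent_id = c(NA_integer_, 0L, 0L, 0L, 0L),
    title = c("Phenome", "Continuous measures", "Integer measures",
              "Questionnaire", "Multi-select questionnaire"))
  field_map <- data.table::data.table(field_id = vi$field_id,
                                      category_id = pmin(vi$field_id %/% 1000L, 4L))
  list(variable_info = vi, codings = codings, categories = categories,
       field_map = field_map)
}

#' Write a generated cohort and its metadata as scan input files
#'
#' Emits exactly the dialects the readers consume: `pheno.csv`, `trait.csv`,
#' `confounders.csv`, `variable-info.tsv`, `data-codings.tsv`,
#' `categories.tsv`, `field-categories.tsv`.
#'
#' @param config A `phs_sim_config`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_files <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  meta <- generate_metadata_files(config)
  paths <- list(
    pheno = file.path(dir, "pheno.csv"),
    trait = file.path(dir, "trait.csv"),
    confounders = file.path(dir, "confounders.csv"),
    variable_info = file.path(dir, "variable-info.tsv"),
    data_codings = file.path(dir, "data-codings.tsv"),
    categories = file.path(dir, "categories.tsv"),
    field_map = file.path(dir, "field-categories.tsv"))
  data.table::fwrite(cohort$pheno, paths$pheno, na = "", quote = FALSE)
  data.table::fwrite(cohort$trait, paths$trait, na = "", quote = FALSE)
  data.table::fwrite(cohort$confounders, paths$confounders, na = "", quote = FALSE)
  write_variable_info(meta$variable_info, paths$variable_info)
  write_data_coding(meta$codings, paths$data_codings)
  data.table::fwrite(meta$categories, paths$categories, sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(meta$field_map, paths$field_map, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(paths)
}
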