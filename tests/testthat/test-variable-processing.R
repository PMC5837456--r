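# The decision flow: collapsing, recoding, transforms, routing, expansion.

test_that("array repeats at the first time point are averaged", {
  cols <- data.table::data.table(
    x3062_0_0 = c(3.1, 1, NA), x3062_0_1 = c(2.9, NA, NA), x3062_0_2 = c(NA, 3, NA))
  out <- collapse_field_columns(cols, "CONTINUOUS")
  expect_equal(out$values, c(3.0, 2.0, NA))

  # later instances are ignored entirely
  cols2 <- data.table::data.table(x10_0_0 = c(1, 2), x10_2_0 = c(100, 100))
  expect_equal(collapse_field_columns(cols2, "CONTINUOUS")$values, c(1, 2))

  # single column passes through unchanged
  one <- data.table::data.table(x10_0_0 = c(5, NA, 7))
  expect_equal(collapse_field_columns(one, "INTEGER")$values, c(5, NA, 7))

  # no instance-0 columns: the smallest instance present is used
  late <- data.table::data.table(x10_1_0 = c(1, 2), x10_3_0 = c(9, 9))
  expect_equal(collapse_field_columns(late, "CONTINUOUS")$values, c(1, 2))

  # a categorical (single) field may not present several array columns
  amb <- data.table::data.table(x10_0_0 = 1:2, x10_0_1 = 1:2)
  expect_error(collapse_field_columns(amb, "CAT_SINGLE"),
               class = "phs_ambiguous_single")
})

test_that("recoding: reassignments, negative-to-missing, defaults", {
  # categorical negatives (prefer-not-to-answer style codes) become missing
  expect_equal(recode_values(c(1, -1, 3), NULL, "CAT_SINGLE"), c(1, NA, 3))
  # negatives are legitimate measurements on continuous fields
  expect_equal(recode_values(c(-2.5, 1.0), NULL, "CONTINUOUS"), c(-2.5, 1.0))
  # declared default fills missing after reassignment
  cod <- data_coding(1L, FALSE, default_value = 0)
  expect_equal(recode_values(c(7, NA), cod, "CAT_SINGLE"), c(7, 0))
  # reassignments run before the negative rule and can send values to missing
  cod2 <- data_coding(2L, TRUE, reassignments = list(from = c(555, 4), to = c(0.5, NA)))
  expect_equal(recode_values(c(555, 4, -3, 2), cod2, "CAT_SINGLE"),
               c(0.5, NA, NA, 2))
})

test_that("inverse rank-normal matches direct quantile evaluation", {
  # (1,2,3): middle element exactly 0, antisymmetric outputs
  out <- inverse_rank_normal(c(1, 2, 3))
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])

  # untied vector: equals the oracle at the known ranks, to 1e-12
  out <- inverse_rank_normal(c(5, 1, 3))
  expect_equal(out, irnt_oracle(c(3, 1, 2), 3), tolerance = 1e-12)

  set.seed(99)
  x <- rnorm(500)
  x[sample(500, 30)] <- NA
  out <- inverse_rank_normal(x, seed = 7)
  expect_equal(is.na(out), is.na(x))
  expect_equal(out[!is.na(x)], irnt_oracle(rank(x[!is.na(x)]), 470),
               tolerance = 1e-12)
  # order-isomorphic on untied values
  expect_identical(order(out[!is.na(out)]), order(x[!is.na(x)]))

  # ties: permuted ranks across seeds, identical output multiset
  x <- c(0, 0, 0, 1)
  o1 <- inverse_rank_normal(x, seed = 1)
  o2 <- inverse_rank_normal(x, seed = 2)
  expect_equal(sort(o1), sort(o2))
  expect_equal(o1[4], irnt_oracle(4, 4))
  expect_identical(o1, inverse_rank_normal(x, seed = 1))  # deterministic

  expect_error(inverse_rank_normal(rep(2, 5)), class = "phs_degenerate_distribution")
})

test_that("inverse rank-normal output is marginally standard normal", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(100:2000, 1)
    x <- rexp(n)  # heavily skewed input
    out <- inverse_rank_normal(x, seed = rep)
    expect_lt(abs(mean(out)), 3 / sqrt(n))
    expect_gt(var(out), 0.8)
    expect_lt(var(out), 1.2)
  }
})

test_that("dominance check routes heavily tied variables to binning", {
  expect_true(needs_binning(c(rep(0, 60), runif(40))))
  expect_false(needs_binning(1:100))            # max share 1/n
  expect_false(needs_binning(rep(1:5, each = 2))) # exactly 0.2: strict inequality
  expect_true(needs_binning(c(1, 1, 1, 2, 3)))  # 0.6 > 0.2
  expect_true(needs_binning(c(1, 1, 2, 3, 4), threshold = 0.1))
})

test_that("equal-mass binning matches exhaustive split enumeration", {
  # worked zero-inflated case: no split pair beats {0},{1},{2}
  x <- c(rep(0, 60), rep(1, 20), rep(2, 20))
  b <- bin_to_ordered(x)
  expect_equal(b$counts, c(60, 20, 20))
  expect_equal(sort(unique(b$labels)), 1:3)
  expect_equal(b$labels[x == 0], rep(1L, 60))

  # three distinct values at equal frequency: one category each, counts n/3
  x <- rep(c(10, 20, 30), each = 50)
  expect_equal(bin_to_ordered(x)$counts, c(50, 50, 50))

  # exhaustive oracle comparison over random vectors with <= 12 distinct values
  set.seed(2024)
  for (rep in 1:60) {
    d <- sample(4:12, 1)
    vals <- sort(sample(-5:30, d))
    x <- sample(vals, sample(30:200, 1), replace = TRUE,
                prob = runif(d)^2 + 0.05)
    if (length(unique(x)) < 4) next
    got <- bin_to_ordered(x)
    want <- bin3_oracle(x)
    expect_equal(max(abs(got$counts - length(x) / 3)), want$score)
    expect_equal(got$splits, want$splits)  # tie-break: lowest split values
  }

  # labels are monotone in value and missing is preserved
  x <- c(NA, rep(0, 50), runif(50, 1, 2))
  b <- bin_to_ordered(x)
  expect_true(is.na(b$labels[1]))
  expect_true(all(diff(b$labels[order(x, na.last = NA)]) >= 0, na.rm = TRUE))
})

test_that("integer routing boundaries: 2 binary, 3-20 ordered, >20 continuous", {
  expect_equal(classify_integer(rep(c(0, 1), 50)), "BINARY")
  expect_equal(classify_integer(rep(1:3, 20)), "ORDERED")
  expect_equal(classify_integer(rep(1:20, 5)), "ORDERED")
  expect_equal(classify_integer(rep(1:21, 5)), "CONTINUOUS_PATH")
  expect_error(classify_integer(rep(7, 10)), class = "phs_degenerate_distribution")
})

test_that("categorical (multiple) expansion: one binary child per value", {
  # bread-style field: 5 options, both white and wholemeal selectable at once
  cols <- data.table::data.table(
    x20091_0_0 = c(1, 3, 2, NA, 5),
    x20091_0_1 = c(3, NA, NA, NA, 4),
    x20091_0_2 = rep(NA_real_, 5))
  kids <- expand_cat_multiple(cols, "RESPONDERS", field_id = 20091L)
  expect_length(kids, 5L)
  expect_equal(vapply(kids, `[[`, "", "name"),
               paste0("20091#", 1:5))
  expect_true(all(vapply(kids, function(k) k$data_type, "") == "BINARY"))
  # participant 1 holds {1,3}: TRUE in children 1 and 3, FALSE in 2/4/5
  first <- vapply(kids, function(k) k$values[1], 0)
  expect_equal(first, c(1, 0, 1, 0, 0))
  # participant 4 did not respond: missing everywhere under RESPONDERS
  expect_true(all(is.na(vapply(kids, function(k) k$values[4], 0))))
})

test_that("an unknown (negative) value blocks FALSE but not TRUE", {
  # delivery-professional field: participant 1 has {midwife=2, not-known=-1}
  cols <- data.table::data.table(
    x41228_0_0 = c(2, 1, 1),
    x41228_0_1 = c(-1, NA, 2))
  kids <- expand_cat_multiple(cols, "RESPONDERS", field_id = 41228L)
  names(kids) <- vapply(kids, `[[`, "", "name")
  # TRUE for midwife: a midwife conducted at least one delivery
  expect_equal(kids[["41228#2"]]$values[1], 1)
  # but hospital_doctor = FALSE cannot be asserted: missing, not 0
  expect_true(is.na(kids[["41228#1"]]$values[1]))
  # participants without unknown codes get ordinary FALSE
  expect_equal(kids[["41228#2"]]$values[2], 0)
})

test_that("expansion options coincide when everyone responded, and children are
          invariant to array order and duplicates", {
  cols <- data.table::data.table(
    x50_0_0 = c(1, 2, 1, 3), x50_0_1 = c(2, NA, NA, 1))
  for (opt in c("OTHER_VALUE_HOLDERS", "RESPONDERS", "ALL")) {
    kids <- expand_cat_multiple(cols, opt, field_id = 50L)
    base <- expand_cat_multiple(cols, "ALL", field_id = 50L)
    expect_equal(lapply(kids, `[[`, "values"), lapply(base, `[[`, "values"),
                 info = opt)
  }
  # permuted arrays and duplicated values change nothing
  perm <- data.table::data.table(
    x50_0_0 = c(2, NA, NA, 1), x50_0_1 = c(1, 2, 1, 3), x50_0_2 = c(2, 2, NA, 3))
  k1 <- expand_cat_multiple(cols, "RESPONDERS", field_id = 50L)
  k2 <- expand_cat_multiple(perm, "RESPONDERS", field_id = 50L)
  expect_equal(lapply(k1, `[[`, "values"), lapply(k2, `[[`, "values"))

  # nothing to expand
  none <- data.table::data.table(x51_0_0 = c(NA_real_, -1))
  expect_error(expand_cat_multiple(none, "ALL", field_id = 51L),
               class = "phs_empty_expansion")
})

test_that("missingness options differ when non-responders exist", {
  # 4 participants: holds value 2; holds value 1; responded empty-handed is not
  # representable here, so the distinction is holders vs responders vs all
  cols <- data.table::data.table(x60_0_0 = c(2, 1, -1, NA))
  kids <- function(opt) {
    k <- expand_cat_multiple(cols, opt, field_id = 60L)
    stats::setNames(lapply(k, `[[`, "values"), vapply(k, `[[`, "", "name"))
  }
  # value-1 child, participant 3 (only an unknown code): never FALSE
  expect_true(is.na(kids("ALL")[["60#1"]][3]))
  # participant 4 (no response): FALSE only under ALL
  expect_equal(kids("ALL")[["60#1"]][4], 0)
  expect_true(is.na(kids("RESPONDERS")[["60#1"]][4]))
  expect_true(is.na(kids("OTHER_VALUE_HOLDERS")[["60#1"]][4]))
})

test_that("process_field routes each field type as declared", {
  n <- 300
  set.seed(5)
  # walking-pace style ordinal field: slow < steady < brisk via its data code
  pace <- data.table::data.table(x924_0_0 = sample(c(1, 2, 3, -1), n, TRUE,
                                                   prob = c(.3, .4, .28, .02)))
  cods <- list("100" = data_coding(100L, TRUE, ordering = c(1, 2, 3)))
  meta <- list(field_id = 924L, field_type = "CAT_SINGLE", data_code = 100L,
               trait_equivalent = FALSE)
  out <- process_field(meta, pace, cods)
  expect_length(out, 1L)
  expect_equal(out[[1]]$data_type, "ORDERED")
  expect_equal(sort(unique(out[[1]]$values[!is.na(out[[1]]$values)])), 1:3)

  # a declared ordering reverses the rank assignment
  cods_rev <- list("100" = data_coding(100L, TRUE, ordering = c(3, 2, 1)))
  out_rev <- process_field(meta, pace, cods_rev)
  keep <- !is.na(out[[1]]$values) & !is.na(out_rev[[1]]$values)
  expect_equal(out_rev[[1]]$values[keep], 4 - out[[1]]$values[keep])

  # zero-inflated continuous field: binned to 3 ordered categories
  alco <- data.table::data.table(
    x100022_0_0 = c(rep(0, 200), round(rexp(100, 0.5), 2)))
  meta2 <- list(field_id = 100022L, field_type = "CONTINUOUS", data_code = NA,
                trait_equivalent = FALSE)
  out2 <- process_field(meta2, alco, list())
  expect_equal(out2[[1]]$data_type, "ORDERED")
  expect_equal(sort(unique(out2[[1]]$values)), 1:3)
  expect_true(any(grepl("binned", out2[[1]]$provenance)))

  # categorical (single) collapsing to two values becomes binary
  yn <- data.table::data.table(x2443_0_0 = sample(c(0, 1, -3), n, TRUE))
  meta3 <- list(field_id = 2443L, field_type = "CAT_SINGLE", data_code = 101L,
                trait_equivalent = FALSE)
  out3 <- process_field(meta3, yn, list("101" = data_coding(101L, FALSE)))
  expect_equal(out3[[1]]$data_type, "BINARY")

  # unordered coding yields an unordered variable
  job <- data.table::data.table(x132_0_0 = sample(1:6, n, TRUE))
  meta4 <- list(field_id = 132L, field_type = "CAT_SINGLE", data_code = 102L,
                trait_equivalent = FALSE)
  out4 <- process_field(meta4, job, list("102" = data_coding(102L, FALSE)))
  expect_equal(out4[[1]]$data_type, "UNORDERED")

  # a categorical (single) field without a data code is an error
  meta5 <- list(field_id = 7L, field_type = "CAT_SINGLE", data_code = NA,
                trait_equivalent = FALSE)
  expect_error(process_field(meta5, yn, list()), class = "phs_missing_data_code")
})

test_that("flow counters conserve: entered = emitted + removed", {
  fx <- tiny_fixture_dir(n = 600)
  ds <- assemble_dataset(fx$paths$pheno, fx$paths$trait,
                         confounders = fx$paths$confounders)
  vi <- load_variable_info(fx$paths$variable_info)
  cods <- load_data_coding(fx$paths$data_codings)
  pr <- process_fields(ds, vi, cods)
  ct <- pr$counters
  expect_equal(ct$fields_entered,
               ct$fields_emitted + ct$excluded_a_priori + ct$removed_degenerate +
                 ct$removed_empty_expansion + ct$removed_error)
  expect_equal(length(pr$derived),
               ct$emitted_CONTINUOUS + ct$emitted_ORDERED +
                 ct$emitted_UNORDERED + ct$emitted_BINARY)

  # determinism: identical inputs and seed give identical derived variables
  pr2 <- process_fields(ds, vi, cods)
  expect_identical(lapply(pr$derived, `[[`, "values"),
                   lapply(pr2$derived, `[[`, "values"))
})
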