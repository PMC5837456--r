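# Shared builders and independent oracles. Oracles are deliberately naive
# (direct quantile evaluation, exhaustive enumeration, hand-written
# likelihoods) and never call the code paths they check.

# --- dataset builders -------------------------------------------------------

# minimal dataset wrapper around explicit vectors (bypasses file IO)
make_dataset <- function(trait, confounders = NULL, pheno_cols = NULL,
                         ids = NULL) {
  n <- length(trait)
  ids <- ids %||% sprintf("P%06d", seq_len(n))
  pheno <- data.table::data.table(userId = ids)
  if (!is.null(pheno_cols)) for (nm in names(pheno_cols)) pheno[[nm]] <- pheno_cols[[nm]]
  tr <- data.table::data.table(userId = ids, trait = trait)
  cf <- if (is.null(confounders)) NULL else
    cbind(data.table::data.table(userId = ids), data.table::as.data.table(confounders))
  assemble_dataset(pheno, tr, confounders = cf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived variable shortcut
dv <- function(values, data_type, name = "1", field_id = 1L, ...) {
  derived_variable(name, field_id, data_type, values, ...)
}

no_conf_spec <- function() model_spec("trait", confounder_names = character(0))

# --- independent oracles ----------------------------------------------------

# inverse-normal oracle: direct quantile evaluation given known ranks
irnt_oracle <- function(ranks, n) qnorm((ranks - 0.5) / n)

# exhaustive split-pair enumeration for 3-way equal-mass binning
bin3_oracle <- function(x) {
  x <- x[!is.na(x)]
  dvs <- sort(unique(x))
  n <- length(x)
  best <- NULL
  for (i in seq_len(length(dvs) - 1)) {
    for (j in seq_len(length(dvs) - 1)) {
      if (j <= i) next
      s1 <- (dvs[i] + dvs[i + 1]) / 2
      s2 <- (dvs[j] + dvs[j + 1]) / 2
      c1 <- sum(x < s1); c2 <- sum(x >= s1 & x < s2); c3 <- sum(x >= s2)
      score <- max(abs(c(c1, c2, c3) - n / 3))
      if (is.null(best) || score < best$score) {
        best <- list(score = score, splits = c(s1, s2), counts = c(c1, c2, c3))
      }
    }
  }
  best
}

# closed-form least squares via the normal equations
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# proportional-odds log-likelihood (3 levels: params cut1, cut2, beta)
polr3_loglik <- function(par, y, x) {
  cuts <- c(par[1], par[2])
  if (diff(cuts) <= 0) return(-Inf)
  eta <- par[3] * x
  p1 <- plogis(cuts[1] - eta)
  p2 <- plogis(cuts[2] - eta) - p1
  p3 <- 1 - plogis(cuts[2] - eta)
  pr <- cbind(p1, p2, p3)[cbind(seq_along(y), y)]
  sum(log(pmax(pr, 1e-300)))
}

# coarse-to-fine grid search for the proportional-odds trait coefficient,
# profiling the cutpoints at each candidate beta
polr3_grid_oracle <- function(y, x) {
  profile_ll <- function(beta) {
    fit <- optim(c(-0.5, 0.5), function(cuts) -polr3_loglik(c(cuts, beta), y, x),
                 method = "Nelder-Mead")
    -fit$value
  }
  lo <- -2; hi <- 2
  for (step in c(0.1, 0.01, 1e-3, 1e-4)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, profile_ll, 0)
    b <- grid[which.max(ll)]
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

# multinomial log-likelihood evaluated directly from fitted class probabilities
multinom_loglik_oracle <- function(fit, y) {
  pr <- predict(fit, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
  sum(log(pmax(pr[cbind(seq_along(y), as.integer(y))], 1e-300)))
}

# tiny two-field scan fixture written to a temp dir
tiny_fixture_dir <- function(n = 800, seed = 11,
                             plan = NULL) {
  cfg <- simulation_config(
    n_participants = n, seed = seed,
    field_plan = plan %||% list(
      plan_field(1001, "CONTINUOUS", "normal", effect = 0.2),
      plan_field(3040, "CAT_SINGLE", "binary", effect = 0.3),
      plan_field(3001, "CAT_SINGLE", "ordered_levels",
                               effect = 0, n_levels = 3L),
      plan_field(3020, "CAT_SINGLE", "unordered_levels",
                               effect = 0, n_levels = 4L)))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_fixture_files(cfg, dir)
  list(cfg = cfg, paths = paths, dir = dir)
}
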