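# Base risk of the default planted mechanism.  The three figure-derived rules
# (low BMI -> 0.05; WHR > 0.9 & ALT > 17.5 -> 0.8; TG > 247.5 -> 0.6) leave a
# residual stratum whose risk is calibrated analytically so that the implied
# cohort prevalence equals the study's 359/1600 = 0.2244 (see the methods
# vignette for the calibration).
.default_base_risk <- 0.336

#' Scenario: sample size, prevalence and planted outcome mechanism
#'
#' A scenario fixes how a synthetic cohort is drawn: the number of subjects,
#' the target disease prevalence (which weights the two outcome-group
#' mixture components the predictors are drawn from), an ordered list of
#' first-match rules mapping predictor conditions to disease risk, and an
#' outcome label-flip probability.  The default rules plant a tree-shaped
#' mechanism — BMI at the root, then waist-hip ratio with ALT, then
#' triglycerides — mimicking the structure recovered in the screening study.
#'
#' @param n_subjects cohort size (at least 50).
#' @param outcome_prevalence target prevalence; default 359/1600, the study's
#'   group split.
#' @param planted_rules ordered list of `list(when = <R expression string on
#'   the predictor columns>, risk = <probability>)`; rules are applied
#'   first-match, and the last rule must catch every remaining subject.
#' @param noise_flip_prob probability of flipping the drawn outcome label.
#' @param seed integer seed governing every random draw of the scenario.
#' @return An object of class `cohort_scenario`.
#' @export
default_scenario <- function(n_subjects = 1600,
                             outcome_prevalence = 359 / 1600,
                             planted_rules = NULL,
                             noise_flip_prob = 0,
                             seed = 1) {
  if (is.null(planted_rules)) {
    planted_rules <- list(
      list(when = 'BMI %in% c("UW", "N")',   risk = 0.05),
      list(when = 'WHR > 0.9 & ALT > 17.5',  risk = 0.80),
      list(when = 'TG > 247.5',              risk = 0.60),
      list(when = 'TRUE',                    risk = .default_base_risk)
    )
  }
  sc <- structure(list(n_subjects = n_subjects,
                       outcome_prevalence = outcome_prevalence,
                       planted_rules = planted_rules,
                       noise_flip_prob = noise_flip_prob,
                       seed = seed),
                  class = "cohort_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "cohort_scenario"))
  if (sc$n_subjects < 50) stop("n_subjects must be >= 50", call. = FALSE)
  if (sc$outcome_prevalence <= 0 || sc$outcome_prevalence >= 1)
    stop("outcome_prevalence must be in (0,1)", call. = FALSE)
  if (sc$noise_flip_prob < 0 || sc$noise_flip_prob > 1)
    stop("noise_flip_prob must be in [0,1]", call. = FALSE)
  risks <- vapply(sc$planted_rules, `[[`, 0, "risk")
  if (any(risks < 0) || any(risks > 1))
    stop("planted rule risks must be in [0,1]", call. = FALSE)
  last <- sc$planted_rules[[length(sc$planted_rules)]]$when
  if (!identical(trimws(last), "TRUE"))
    stop("last planted rule must be a catch-all ('TRUE') so the rules ",
         "partition the predictor space", call. = FALSE)
  invisible(sc)
}

# mean of a normal(mu, sd) truncated below at `lower`
.tnorm_mean <- function(mu, sd, lower) {
  a <- (lower - mu) / sd
  mu + sd * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE,
                                             log.p = TRUE))
}

# location parameter whose lower-truncated normal has the target mean, so
# cohort means match the schema despite the physiologic truncation
.tnorm_location <- function(target, sd, lower) {
  if (.tnorm_mean(target, sd, lower) - target < 1e-9 * sd) return(target)
  uniroot(function(mu) .tnorm_mean(mu, sd, lower) - target,
          lower = target - 6 * sd, upper = target, tol = 1e-10)$root
}

# truncated-normal draw via inverse CDF (exact, vectorised, seed-stable),
# mean-corrected for the truncation
.rtnorm <- function(n, mean, sd, lower) {
  mu <- .tnorm_location(mean, sd, lower)
  plo <- pnorm(lower, mu, sd)
  qnorm(runif(n, plo, 1), mu, sd)
}

#' Generate a synthetic cohort
#'
#' Subjects are drawn in three stages: (i) a latent outcome-group indicator
#' with probability `outcome_prevalence`; (ii) predictors from their
#' group-conditional marginals (categorical variables from per-group category
#' probabilities, continuous variables from truncated normals with per-group
#' mean and SD); (iii) the observed outcome as Bernoulli draws from the risk
#' of the first matching planted rule, optionally label-flipped with
#' probability `noise_flip_prob`.  The latent group and per-row planted risk
#' are attached as attributes for downstream diagnostics.
#'
#' @param schema a [cohort_schema()]; defaults to [nafld_schema()].
#' @param scenario a [default_scenario()].
#' @return A `data.frame` with one predictor column per schema variable
#'   (factors for categorical kinds, ordered for ordinal) and a 0/1 outcome
#'   column; attributes `latent_group` and `planted_risk` hold the generating
#'   state per row.
#' @export
generate_cohort <- function(schema = nafld_schema(),
                            scenario = default_scenario()) {
  validate_schema(schema)
  validate_scenario(scenario)
  n <- scenario$n_subjects
  set.seed(scenario$seed)
  g <- rbinom(n, 1, scenario$outcome_prevalence)
  cols <- lapply(schema$vars, function(v) {
    if (v$kind == "continuous") {
      x <- numeric(n)
      for (grp in 0:1) {
        idx <- which(g == grp)
        m <- if (grp == 0) v$mean0 else v$mean1
        s <- if (grp == 0) v$sd0 else v$sd1
        x[idx] <- .rtnorm(length(idx), m, s, v$lower)
      }
      x
    } else {
      lab <- character(n)
      for (grp in 0:1) {
        idx <- which(g == grp)
        p <- if (grp == 0) v$p0 else v$p1
        if (length(idx))
          lab[idx] <- sample(v$levels, length(idx), replace = TRUE, prob = p)
      }
      factor(lab, levels = v$levels, ordered = v$kind == "ordinal")
    }
  })
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  names(df) <- vapply(schema$vars, `[[`, "", "name")

  risk <- rep(NA_real_, n)
  for (rule in scenario$planted_rules) {
    hit <- eval(parse(text = rule$when), envir = df)
    if (length(hit) == 1) hit <- rep(hit, n)
    risk[is.na(risk) & hit] <- rule$risk
  }
  if (anyNA(risk))
    stop("planted rules do not cover every subject", call. = FALSE)
  y <- rbinom(n, 1, risk)
  if (scenario$noise_flip_prob > 0) {
    flip <- rbinom(n, 1, scenario$noise_flip_prob) == 1
    y[flip] <- 1 - y[flip]
  }
  df[[schema$outcome]] <- y
  rownames(df) <- seq_len(n)
  attr(df, "latent_group") <- g
  attr(df, "planted_risk") <- risk
  df
}

#' Planted per-row risk of a synthetic cohort
#'
#' @param cohort a cohort from [generate_cohort()] (or a subset from
#'   [split_train_test()]).
#' @return Numeric vector of generating risks, one per row.
#' @export
planted_risk <- function(cohort) attr(cohort, "planted_risk")

#' Split a cohort into training and test sets
#'
#' The training set receives `round(n * train_fraction)` rows and the test
#' set the remainder.  By default the split is stratified by outcome (the
#' class-specific allocations are rounded so the total is exact), which
#' stabilises small-node counts; set `stratify = FALSE` for a simple random
#' split.
#'
#' @param table a cohort `data.frame`.
#' @param train_fraction proportion of rows for training, in (0,1).
#' @param seed integer seed.
#' @param outcome outcome column name (used for stratification).
#' @param stratify stratify the split by outcome?
#' @return `list(train = , test = )`; generator attributes (`latent_group`,
#'   `planted_risk`) are subset alongside the rows.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1,
                             outcome = "NAFLD", stratify = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)", call. = FALSE)
  n <- nrow(table)
  n_train <- round(n * train_fraction)
  set.seed(seed)
  if (stratify && outcome %in% names(table)) {
    y <- table[[outcome]]
    i1 <- which(y == 1); i0 <- which(y != 1)
    n1 <- round(length(i1) * train_fraction)
    n1 <- max(0, min(n1, n_train, length(i1)))
    n0 <- n_train - n1
    if (n0 > length(i0)) { n1 <- n1 + (n0 - length(i0)); n0 <- length(i0) }
    tr <- c(sample(i1, n1), sample(i0, n0))
  } else {
    tr <- sample(n, n_train)
  }
  tr <- sort(tr)
  list(train = .subset_cohort(table, tr),
       test  = .subset_cohort(table, setdiff(seq_len(n), tr)))
}

.subset_cohort <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  for (a in c("latent_group", "planted_risk")) {
    if (!is.null(attr(table, a))) attr(out, a) <- attr(table, a)[idx]
  }
  out
}

#' Read / write a cohort as CSV
#'
#' The CSV has a header row; on reading, column types are restored from the
#' schema (factor levels, ordinal ordering, 0/1 outcome).
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @param schema a `cohort_schema` used to restore column types.
#' @return `read_cohort` returns the typed `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema = nafld_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in schema$vars) {
    if (!v$name %in% names(df))
      stop("cohort CSV lacks schema column '", v$name, "'", call. = FALSE)
    if (v$kind != "continuous")
      df[[v$name]] <- factor(df[[v$name]], levels = v$levels,
                             ordered = v$kind == "ordinal")
  }
  if (!schema$outcome %in% names(df))
    stop("cohort CSV lacks outcome column '", schema$outcome, "'",
         call. = FALSE)
  df
}
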