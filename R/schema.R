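#' Variable schema for a synthetic screening cohort
#'
#' A schema describes each predictor of a cohort: its name, kind
#' (`"continuous"`, `"ordinal"` or `"nominal"`), and the parameters of its
#' outcome-group-conditional generator — per-group category probabilities for
#' categorical variables, per-group mean and SD (with a lower truncation
#' bound) for continuous ones.  Group 0 is "without disease", group 1 "with".
#'
#' @param vars list of variable descriptors (see [schema_variable()]).
#' @param outcome name of the binary outcome column.
#' @return An object of class `cohort_schema`.
#' @seealso [nafld_schema()] for the built-in 30-predictor fatty-liver schema.
#' @export
cohort_schema <- function(vars, outcome = "NAFLD") {
  stopifnot(is.list(vars), length(vars) >= 1)
  names(vars) <- vapply(vars, `[[`, "", "name")
  obj <- structure(list(vars = vars, outcome = outcome),
                   class = "cohort_schema")
  validate_schema(obj)
  obj
}

#' Describe one schema variable
#'
#' @param name column name (short clinical abbreviation, e.g. `"WHR"`).
#' @param kind one of `"continuous"`, `"ordinal"`, `"nominal"`.
#' @param levels character vector of category labels (categorical kinds only);
#'   for ordinal variables the order of `levels` is the variable's order.
#' @param p0,p1 per-group category probabilities (categorical kinds).
#' @param mean0,sd0,mean1,sd1 per-group normal parameters (continuous kind).
#' @param lower lower truncation bound for continuous draws (default 0,
#'   keeping clinical measurements non-negative).
#' @return A variable descriptor list.
#' @export
schema_variable <- function(name, kind, levels = NULL, p0 = NULL, p1 = NULL,
                            mean0 = NULL, sd0 = NULL, mean1 = NULL, sd1 = NULL,
                            lower = 0) {
  kind <- match.arg(kind, c("continuous", "ordinal", "nominal"))
  list(name = name, kind = kind, levels = levels, p0 = p0, p1 = p1,
       mean0 = mean0, sd0 = sd0, mean1 = mean1, sd1 = sd1, lower = lower)
}

#' Validate a cohort schema
#'
#' Checks that category probabilities are valid distributions (non-negative,
#' summing to 1 within 1e-6) and that SDs are positive.
#'
#' @param schema a `cohort_schema`.
#' @return `schema`, invisibly; signals an error on violation.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  for (v in schema$vars) {
    if (v$kind == "continuous") {
      if (is.null(v$sd0) || is.null(v$sd1) || v$sd0 <= 0 || v$sd1 <= 0)
        stop("variable '", v$name, "': SDs must be positive", call. = FALSE)
    } else {
      for (p in list(v$p0, v$p1)) {
        if (is.null(p) || length(p) != length(v$levels))
          stop("variable '", v$name, "': probabilities must match levels",
               call. = FALSE)
        if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6)
          stop("variable '", v$name,
               "': category probabilities must be in [0,1] and sum to 1",
               call. = FALSE)
      }
    }
  }
  invisible(schema)
}

# Per-group count pair -> normalised probability pair helper
.pp <- function(...) { x <- c(...); x / sum(x) }

#' Built-in fatty-liver cohort schema
#'
#' Thirty predictors of mixed kind matching the demographic and clinical
#' profile of a population fatty-liver screening study: 18 nominal variables
#' (sex, marital status, hepatitis-B vaccination, transfusion and surgical
#' history, tattooing, smoking, HBs serology, ...), a 4-level ordinal body
#' mass index category (UW < N < OW < OB) and 11 continuous measurements
#' (waist-hip ratio, blood pressures, lipids, transaminases, glucose,
#' albumin, age), each parameterised by its outcome-group-conditional
#' marginal (category counts or mean ± SD).
#'
#' @return A `cohort_schema` with 30 predictors and outcome `"NAFLD"`.
#' @export
nafld_schema <- function() {
  yn <- c("yes", "no")
  v <- list(
    schema_variable("SEX", "nominal", c("male", "female"),
                    .pp(361, 880), .pp(110, 249)),
    schema_variable("MS", "nominal", c("single", "married", "other"),
                    .pp(447, 726, 68), .pp(27, 297, 35)),
    schema_variable("HEP",  "nominal", yn, .pp(538, 703),  .pp(70, 289)),
    schema_variable("BT",   "nominal", yn, .pp(22, 1219),  .pp(11, 348)),
    schema_variable("THAL", "nominal", yn, .pp(2, 1239),   .pp(1, 358)),
    schema_variable("HEMO", "nominal", yn, .pp(3, 1238),   .pp(0, 359)),
    schema_variable("DI",   "nominal", yn, .pp(3, 1238),   .pp(1, 358)),
    schema_variable("SU",   "nominal", yn, .pp(3, 1238),   .pp(1, 358)),
    schema_variable("HS",   "nominal", yn, .pp(356, 885),  .pp(141, 218)),
    schema_variable("DE",   "nominal", yn, .pp(1002, 239), .pp(303, 56)),
    schema_variable("PH",   "nominal", yn, .pp(94, 1147),  .pp(35, 324)),
    schema_variable("TA",   "nominal", yn, .pp(38, 1203),  .pp(19, 340)),
    schema_variable("UPE",  "nominal", yn, .pp(541, 700),  .pp(141, 218)),
    schema_variable("HOO",  "nominal", yn, .pp(83, 1158),  .pp(28, 331)),
    schema_variable("SMOK", "nominal", yn, .pp(39, 1202),  .pp(19, 340)),
    schema_variable("HDU",  "nominal", yn, .pp(28, 1213),  .pp(6, 353)),
    schema_variable("HBSAG", "nominal", c("negative", "positive"),
                    .pp(1215, 26), .pp(353, 6)),
    schema_variable("HBSAB", "nominal", c("negative", "positive"),
                    .pp(1079, 162), .pp(307, 52)),
    schema_variable("BMI", "ordinal", c("UW", "N", "OW", "OB"),
                    .pp(197, 633, 320, 87), .pp(1, 62, 186, 110)),
    schema_variable("WHR", "continuous", mean0 = 0.83,  sd0 = 0.09,
                    mean1 = 0.92,  sd1 = 0.09),
    schema_variable("SBP", "continuous", mean0 = 100.05, sd0 = 26.1,
                    mean1 = 108.42, sd1 = 31.86),
    schema_variable("DBP", "continuous", mean0 = 82.14, sd0 = 20.01,
                    mean1 = 93.37, sd1 = 23.85),
    schema_variable("HDL", "continuous", mean0 = 50.95, sd0 = 11.5,
                    mean1 = 48.9,  sd1 = 9.73),
    schema_variable("TG",  "continuous", mean0 = 120.3, sd0 = 68.52,
                    mean1 = 193.89, sd1 = 113.5),
    schema_variable("ALT", "continuous", mean0 = 15.56, sd0 = 10.92,
                    mean1 = 19.11, sd1 = 12.5),
    schema_variable("CHO", "continuous", mean0 = 184.94, sd0 = 42.58,
                    mean1 = 207.62, sd1 = 41.79),
    schema_variable("AST", "continuous", mean0 = 24.84, sd0 = 11.66,
                    mean1 = 28.06, sd1 = 17.84),
    schema_variable("GLU", "continuous", mean0 = 96.68, sd0 = 26.86,
                    mean1 = 108.45, sd1 = 39.56),
    schema_variable("AL",  "continuous", mean0 = 4.32,  sd0 = 0.37,
                    mean1 = 4.23,  sd1 = 0.4),
    schema_variable("AGE", "continuous", mean0 = 34.85, sd0 = 17.45,
                    mean1 = 45.9,  sd1 = 13.34)
  )
  cohort_schema(v, outcome = "NAFLD")
}

#' @export
print.cohort_schema <- function(x, ...) {
  kinds <- vapply(x$vars, `[[`, "", "kind")
  cat("Cohort schema:", length(x$vars), "predictors (",
      sum(kinds == "continuous"), "continuous,",
      sum(kinds == "ordinal"), "ordinal,",
      sum(kinds == "nominal"), "nominal ), outcome '", x$outcome, "'\n")
  invisible(x)
}

#' Serialise / restore a schema as JSON
#'
#' @param schema a `cohort_schema`.
#' @param path file path.
#' @return `schema_from_json` returns the restored `cohort_schema`.
#' @export
schema_to_json <- function(schema, path) {
  validate_schema(schema)
  jsonlite::write_json(list(outcome = schema$outcome, vars = schema$vars),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  vars <- lapply(raw$vars, function(v) {
    schema_variable(v$name, v$kind, levels = unlist(v$levels),
                    p0 = unlist(v$p0), p1 = unlist(v$p1),
                    mean0 = v$mean0, sd0 = v$sd0,
                    mean1 = v$mean1, sd1 = v$sd1,
                    lower = if (is.null(v$lower)) 0 else v$lower)
  })
  cohort_schema(vars, outcome = raw$outcome)
}
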