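#' Assign a BMI group label
#'
#' Standard BMI categorization: normoweight (NW) below 25 kg/m2,
#' overweight (OW) for 25 <= BMI < 30, obese (OB) for BMI >= 30.  Both
#' boundaries are closed on the left.
#'
#' @param bmi body mass index in kg/m2; finite and positive.
#' @return `"NW"`, `"OW"` or `"OB"`.
#' @examples
#' assign_bmi_group(21.33)
#' assign_bmi_group(25)
#' @export
assign_bmi_group <- function(bmi) {
  if (!is.numeric(bmi) || length(bmi) != 1 || !is.finite(bmi) || bmi <= 0)
    stop("bmi must be a single positive finite number")
  if (bmi < 25) "NW" else if (bmi < 30) "OW" else "OB"
}

#' Fit the age-and-gender adjustment model
#'
#' For each requested variable, fits an ordinary least-squares model of the
#' (optionally log-transformed) variable on continuous age and a gender
#' indicator (M vs F).  The adjusted value of a variable is its residual
#' from this model, so on the fitting cohort adjusted values are exactly
#' uncorrelated with age and gender.  Skewed power-like proxies (RR TP,
#' RR LFa, RR HFa, SAP LFa) are log-transformed before fitting by default.
#'
#' @param cohort data.frame with `age`, `gender` and the variables in
#'   `vars`.
#' @param vars variables to adjust; defaults to the 16 proxies plus `bmi`.
#' @param log_vars variables log-transformed before adjustment.
#' @return An object of class `carproc_adjustment`: per-variable intercept,
#'   age and gender coefficients, residual scale, log flag, and the
#'   fitting-cohort age mean.
#' @examples
#' sim <- generate_cohort(default_config(n_total = 120, seed = 3))
#' mod <- fit_adjustment(sim$cohort)
#' mod$coefficients["alpha_index", ]
#' @export
fit_adjustment <- function(cohort, vars = c(proxy_names(), "bmi"),
                           log_vars = default_log_vars()) {
  if (nrow(cohort) < 30) stop("adjustment requires at least 30 subjects")
  if (length(unique(cohort$gender)) < 2)
    stop("adjustment requires both genders in the fitting cohort")
  if (stats::sd(cohort$age) == 0) stop("age is constant in the fitting cohort")
  missing <- setdiff(vars, names(cohort))
  if (length(missing))
    stop("cohort lacks variable(s): ", paste(missing, collapse = ", "))

  male <- as.numeric(cohort$gender == "M")
  X <- cbind(1, age = cohort$age, male = male)
  coefs <- matrix(NA_real_, length(vars), 3,
                  dimnames = list(vars, c("intercept", "age", "male")))
  scale <- setNames(numeric(length(vars)), vars)
  for (v in vars) {
    y <- cohort[[v]]
    if (v %in% log_vars) {
      if (any(y <= 0)) stop("cannot log-transform non-positive values in ", v)
      y <- log(y)
    }
    if (stats::sd(y) == 0) stop("variable ", v, " is constant")
    fit <- stats::lm.fit(X, y)
    coefs[v, ] <- fit$coefficients
    scale[v] <- sqrt(sum(fit$residuals^2) / max(1, fit$df.residual))
  }
  structure(list(coefficients = coefs, residual_scale = scale,
                 log_vars = intersect(log_vars, vars),
                 age_mean = mean(cohort$age), vars = vars,
                 n_fit = nrow(cohort)),
            class = "carproc_adjustment")
}

#' Apply an adjustment model
#'
#' Computes age-and-gender-adjusted values (residuals from the fitted
#' additive model, after any log pre-transform) for each modelled variable
#' present in `cohort`.
#'
#' @param cohort data.frame with `age`, `gender` and the modelled variables.
#' @param model a [fit_adjustment()] model.
#' @param vars subset of modelled variables to adjust (default: all that
#'   are present in `cohort`).
#' @return A numeric matrix of adjusted values, rows aligned with `cohort`.
#' @export
adjust <- function(cohort, model, vars = NULL) {
  stopifnot(inherits(model, "carproc_adjustment"))
  if (is.null(vars)) vars <- intersect(model$vars, names(cohort))
  missing <- setdiff(vars, model$vars)
  if (length(missing))
    stop("variable(s) not in adjustment model: ", paste(missing, collapse = ", "))
  male <- as.numeric(cohort$gender == "M")
  out <- matrix(NA_real_, nrow(cohort), length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) {
    y <- cohort[[v]]
    if (v %in% model$log_vars) y <- log(y)
    b <- model$coefficients[v, ]
    out[, v] <- y - (b["intercept"] + b["age"] * cohort$age + b["male"] * male)
  }
  out
}

#' Percentile rank transformation
#'
#' Maps values to percentiles `100 * (r - 0.5) / n`, where `r` is the
#' midrank (ties receive the average of the tied ranks).  The output lies
#' strictly inside (0, 100), is order-isomorphic to the input, and has mean
#' 50 when there are no ties.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @return Percentile vector of the same length.
#' @examples
#' percentile_rank(c(10, 20, 30, 40))
#' @export
percentile_rank <- function(x) {
  if (length(x) < 2) stop("percentile_rank needs at least 2 values")
  if (!all(is.finite(x))) stop("percentile_rank requires finite input")
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Adjusted percentile rank transformation (aPRT)
#'
#' Applies the age-and-gender adjustment followed by the percentile rank
#' transformation: the workhorse used to build the percentile-ranked
#' baroreflex index (alpha aPRT) and BMI (BMI aPRT).
#'
#' @param cohort data.frame with `age`, `gender` and `var`.
#' @param var name of the variable to transform.
#' @param model a [fit_adjustment()] model containing `var`.
#' @return Percentile vector in (0, 100), one value per row of `cohort`.
#' @examples
#' sim <- generate_cohort(default_config(n_total = 120, seed = 3))
#' mod <- fit_adjustment(sim$cohort)
#' bmi_aprt <- aprt(sim$cohort, "bmi", mod)
#' range(bmi_aprt)
#' @export
aprt <- function(cohort, var, model) {
  percentile_rank(adjust(cohort, model, vars = var)[, var])
}

#' Serialize / restore an adjustment model as JSON
#'
#' @param model a [fit_adjustment()] model.
#' @param path file path.
#' @return `read_adjustment()` returns the restored model.
#' @export
write_adjustment <- function(model, path) {
  stopifnot(inherits(model, "carproc_adjustment"))
  obj <- list(coefficients = as.data.frame(model$coefficients),
              variables = model$vars,
              residual_scale = unname(model$residual_scale),
              log_vars = model$log_vars, age_mean = model$age_mean,
              n_fit = model$n_fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adjustment
#' @export
read_adjustment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.matrix(obj$coefficients)
  rownames(coefs) <- obj$variables
  structure(list(coefficients = coefs,
                 residual_scale = setNames(obj$residual_scale, obj$variables),
                 log_vars = as.character(obj$log_vars),
                 age_mean = obj$age_mean, vars = obj$variables,
                 n_fit = obj$n_fit),
            class = "carproc_adjustment")
}
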