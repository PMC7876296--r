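#' Reference sign pattern of the four autonomic domains
#'
#' The expected clustering of the 16 adjusted proxies on the four latent
#' domains: oscillatory (+RR LFnu, +RR LF/HF, -RR HFnu, -dRR LFnu),
#' amplitude (+RR TP, +RR LFa, +RR HFa, +alpha index), pressure (+SAP,
#' +DAP, +SAP Mean), and pulse (+HR, -RR Mean).  Used for factor labelling
#' and sign alignment.
#'
#' @return A 16 x 4 sign matrix (entries -1, 0, +1) with proxy row names
#'   and domain column names.
#' @export
reference_pattern <- function() {
  p <- proxy_names()
  ref <- matrix(0, 16, 4,
                dimnames = list(p, c("oscillatory", "amplitude",
                                     "pressure", "pulse")))
  ref[c("RR_LFnu", "RR_LFHF"), "oscillatory"] <- 1
  ref[c("RR_HFnu", "dRR_LFnu"), "oscillatory"] <- -1
  ref[c("RR_TP", "RR_LFa", "RR_HFa", "alpha_index"), "amplitude"] <- 1
  ref[c("SAP", "DAP", "SAP_Mean"), "pressure"] <- 1
  ref["HR", "pulse"] <- 1
  ref["RR_Mean", "pulse"] <- -1
  ref
}

#' Maximum-likelihood exploratory factor analysis with varimax rotation
#'
#' Fits an orthogonal common-factor model to the adjusted proxy matrix by
#' maximum likelihood and rotates the solution with (Kaiser-normalized)
#' varimax.  Loadings are reported in the correlation metric; factors are
#' ordered by percentage of total variance reproduced.  The fit is
#' deterministic for a given input.
#'
#' @param adjusted numeric matrix of adjusted proxies (rows = subjects).
#' @param max_factors number of factors to extract before retention.
#' @return An object of class `carproc_efa` with `loadings` (p x q),
#'   `uniquenesses`, `communalities`, `pct_total_variance`,
#'   `pct_total_communality`, `q_retained` (set by [retain_factors()]),
#'   `rotation = "varimax"`, the proxy correlation matrix `R`, and
#'   `converged`.
#' @examples
#' sim <- generate_cohort(default_config(n_total = 400, seed = 2))
#' adj <- adjust(sim$cohort, fit_adjustment(sim$cohort), vars = proxy_names())
#' efa <- fit_efa(adj)
#' efa$pct_total_variance
#' @export
fit_efa <- function(adjusted, max_factors = 4) {
  adjusted <- as.matrix(adjusted)
  p <- ncol(adjusted)
  if (nrow(adjusted) < 5 * p)
    stop("EFA requires at least ", 5 * p, " rows (5 per variable)")
  R <- stats::cor(adjusted)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("proxy correlation matrix is not positive definite")
  fit <- stats::factanal(factors = max_factors, covmat = R,
                         n.obs = nrow(adjusted), rotation = "varimax")
  if (fit$converged == FALSE)
    stop("maximum-likelihood factor extraction did not converge")
  L <- unclass(fit$loadings)
  # order factors by variance reproduced; resolve rotation sign later
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  uniq <- fit$uniquenesses
  heywood <- names(uniq)[uniq <= 0]
  if (length(heywood))
    stop("Heywood case (non-positive uniqueness) for: ",
         paste(heywood, collapse = ", "))
  comm <- 1 - uniq
  model <- structure(list(
    loadings = L, uniquenesses = uniq, communalities = comm,
    pct_total_variance = 100 * colSums(L^2) / p,
    pct_total_communality = 100 * colSums(L^2) / sum(comm),
    q_retained = ncol(L), rotation = "varimax",
    score_method = "regression", R = R, converged = fit$converged,
    n_obs = nrow(adjusted)), class = "carproc_efa")
  model
}

#' Apply the factor retention rule
#'
#' Keeps exactly the factors that reproduce at least `min_variance` percent
#' of the total variance AND at least `min_communality` percent of the
#' total communality, preserving the variance ordering.
#'
#' @param model a [fit_efa()] model.
#' @param min_variance retention threshold on percent total variance.
#' @param min_communality retention threshold on percent total communality.
#' @return The model restricted to the retained factors, with `q_retained`
#'   updated.  Signals an error if no factor survives.
#' @export
retain_factors <- function(model, min_variance = 10, min_communality = 15) {
  stopifnot(inherits(model, "carproc_efa"))
  keep <- model$pct_total_variance >= min_variance &
    model$pct_total_communality >= min_communality
  if (!any(keep)) stop("no factor meets both retention thresholds")
  model$loadings <- model$loadings[, keep, drop = FALSE]
  model$pct_total_variance <- model$pct_total_variance[keep]
  model$pct_total_communality <- model$pct_total_communality[keep]
  model$q_retained <- sum(keep)
  model
}

#' Label retained factors by domain
#'
#' Matches each retained factor to one of the four reference autonomic
#' domains by its cluster of salient loadings (absolute value at or above
#' `threshold`).  The assignment maximizes total pattern agreement over all
#' factor-to-domain matchings (exhaustive bipartite search); each factor's
#' sign is set so that its salient loadings agree with the reference signs.
#' A factor with no salient loading, or no overlap with any reference
#' cluster, is labelled `"unassigned"`.  Ties between two equally good
#' assignments are an error, not a guess.
#'
#' @param model a retained [fit_efa()] model.
#' @param threshold salient-loading cutoff (default 0.5 in absolute value).
#' @return A data.frame with one row per factor: `factor`, `domain`,
#'   `sign` (+1/-1 flip applied for alignment), and the contributing
#'   proxies with signs as a comma-separated string.
#' @export
label_factors <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "carproc_efa"))
  L <- model$loadings
  ref <- reference_pattern()
  q <- ncol(L)
  # agreement score of factor f with domain d under optimal sign
  score <- matrix(0, q, ncol(ref), dimnames = list(colnames(L), colnames(ref)))
  for (f in seq_len(q)) {
    sal <- abs(L[, f]) >= threshold
    if (!any(sal)) next
    score[f, ] <- abs(crossprod(L[, f] * sal, ref))
  }
  # exhaustive assignment of factors to distinct domains (q <= 4)
  doms <- seq_len(ncol(ref))
  perms <- all_assignments(doms, q)
  totals <- vapply(perms, function(a) sum(score[cbind(seq_len(q), a)]),
                   numeric(1))
  best <- which(totals == max(totals))
  if (length(best) > 1 && max(totals) > 0)
    stop("ambiguous factor-to-domain assignment (tied matchings)")
  a <- perms[[best[1]]]
  out <- data.frame(factor = colnames(L), domain = NA_character_,
                    sign = 1, proxies = NA_character_,
                    stringsAsFactors = FALSE)
  for (f in seq_len(q)) {
    sal <- which(abs(L[, f]) >= threshold)
    if (length(sal) == 0 || score[f, a[f]] == 0) {
      out$domain[f] <- "unassigned"
      next
    }
    d <- a[f]
    out$domain[f] <- colnames(ref)[d]
    s <- sign(sum(L[sal, f] * ref[sal, d]))
    if (s == 0) s <- 1
    out$sign[f] <- s
    lab <- paste0(ifelse(s * L[sal, f] > 0, "+", "-"), rownames(L)[sal])
    out$proxies[f] <- paste(lab, collapse = ",")
  }
  out
}

# all injective maps of q factors into the domain indices
all_assignments <- function(doms, q) {
  if (q == 1) return(lapply(doms, identity))
  res <- list()
  for (d in doms) {
    sub <- all_assignments(setdiff(doms, d), q - 1)
    res <- c(res, lapply(sub, function(s) c(d, s)))
  }
  res
}

#' Factor scores (regression / Thomson estimator)
#'
#' Per-subject scores for the retained factors, computed from the
#' standardized adjusted proxies as `Z R^{-1} L` (regression scores;
#' Bartlett weighting available as an option).  Column means are zero on
#' the fitting sample.
#'
#' @param model a retained [fit_efa()] model.
#' @param adjusted the adjusted proxy matrix the model was fitted to (or a
#'   compatible new matrix scored against the same correlation structure).
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return An n x q matrix of factor scores.
#' @export
factor_scores <- function(model, adjusted, method = c("regression", "bartlett")) {
  stopifnot(inherits(model, "carproc_efa"))
  method <- match.arg(method)
  adjusted <- as.matrix(adjusted)
  if (!all(rownames(model$loadings) %in% colnames(adjusted)))
    stop("adjusted matrix does not contain the modelled proxies")
  adjusted <- adjusted[, rownames(model$loadings), drop = FALSE]
  Z <- scale(adjusted)
  L <- model$loadings
  if (method == "regression") {
    W <- solve(model$R, L)
  } else {
    Psi_inv <- diag(1 / model$uniquenesses)
    W <- Psi_inv %*% L %*% solve(crossprod(L, Psi_inv %*% L))
  }
  S <- Z %*% W
  colnames(S) <- colnames(L)
  S
}

#' Percentile-ranked domain indicators from factor scores
#'
#' Orients each labelled factor-score column by its alignment sign (so
#' that, e.g., the pressure indicator increases with adjusted SAP) and
#' applies the percentile rank transformation, yielding the OSC, AMP,
#' PRESS and PUL indicators on (0, 100).  Unassigned factors are dropped
#' with a warning.
#'
#' @param scores n x q matrix from [factor_scores()].
#' @param labels data.frame from [label_factors()].
#' @return A data.frame of percentile indicator columns named
#'   `OSC_ind`, `AMP_ind`, `PRESS_ind`, `PUL_ind` (those present).
#' @export
indicators_from_scores <- function(scores, labels) {
  short <- c(oscillatory = "OSC_ind", amplitude = "AMP_ind",
             pressure = "PRESS_ind", pulse = "PUL_ind")
  out <- list()
  for (f in seq_len(nrow(labels))) {
    d <- labels$domain[f]
    if (d == "unassigned") {
      warning("factor ", labels$factor[f], " is unassigned; excluded")
      next
    }
    out[[short[[d]]]] <- percentile_rank(labels$sign[f] *
                                           scores[, labels$factor[f]])
  }
  as.data.frame(out)[, intersect(unname(short), names(out)), drop = FALSE]
}

#' Composite autonomic nervous system index (ANSI)
#'
#' ANSI summarizes overall cardiac autonomic regulation from three selected
#' proxies, one per key domain: RR Mean (pulse), RR TP (amplitude) and the
#' stand-rest shift dRR LFnu (oscillatory).  Each component is
#' age-and-gender adjusted and percentile-ranked (aPRT), oriented so that
#' higher is better (longer RR, larger total power, larger orthostatic LFnu
#' increase), averaged with equal weights, and the average is
#' percentile-ranked again so ANSI spans (0, 100), higher = better.
#'
#' @param cohort data.frame with `age`, `gender` and the three component
#'   proxies.
#' @param model a [fit_adjustment()] model covering the components.
#' @param orientation named vector of +1/-1 component orientations;
#'   the default treats all three as higher-is-better.
#' @return ANSI percentile vector, one value per row of `cohort`.
#' @export
compute_ansi <- function(cohort, model,
                         orientation = c(RR_Mean = 1, RR_TP = 1, dRR_LFnu = 1)) {
  comp <- c("RR_Mean", "RR_TP", "dRR_LFnu")
  missing <- setdiff(comp, names(cohort))
  if (length(missing))
    stop("cohort lacks ANSI component(s): ", paste(missing, collapse = ", "))
  pr <- vapply(comp, function(v) {
    p <- aprt(cohort, v, model)
    if (orientation[[v]] < 0) 100 - p else p
  }, numeric(nrow(cohort)))
  percentile_rank(rowMeans(pr))
}

#' Build the full indicator table for a cohort
#'
#' Convenience wrapper running adjustment, EFA (fit, retain, label,
#' score), the four domain indicators, the percentile-ranked baroreflex
#' index and BMI, and ANSI.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param model optional pre-fitted [fit_adjustment()] model; fitted on
#'   `cohort` when `NULL`.
#' @param max_factors factors to extract before retention.
#' @return A list with `indicators` (data.frame: OSC_ind, AMP_ind,
#'   PRESS_ind, PUL_ind, alpha_aPRT, BMI_aPRT, ANSI), `efa`, `labels`,
#'   `scores`, and the adjustment `model`.
#' @examples
#' sim <- generate_cohort(default_config(n_total = 400, seed = 2))
#' res <- build_indicators(sim$cohort)
#' head(res$indicators)
#' @export
build_indicators <- function(cohort, model = NULL, max_factors = 4) {
  if (is.null(model)) model <- fit_adjustment(cohort)
  adj <- adjust(cohort, model, vars = proxy_names())
  efa <- retain_factors(fit_efa(adj, max_factors = max_factors))
  labels <- label_factors(efa)
  scores <- factor_scores(efa, adj)
  ind <- indicators_from_scores(scores, labels)
  ind$alpha_aPRT <- aprt(cohort, "alpha_index", model)
  ind$BMI_aPRT <- aprt(cohort, "bmi", model)
  ind$ANSI <- compute_ansi(cohort, model)
  list(indicators = ind, efa = efa, labels = labels, scores = scores,
       model = model)
}

#' Serialize a factor model to JSON
#'
#' @param model a `carproc_efa` model.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_efa <- function(model, path) {
  stopifnot(inherits(model, "carproc_efa"))
  obj <- list(loadings = as.data.frame(model$loadings),
              proxies = rownames(model$loadings),
              uniquenesses = unname(model$uniquenesses),
              pct_total_variance = unname(model$pct_total_variance),
              pct_total_communality = unname(model$pct_total_communality),
              q_retained = model$q_retained, rotation = model$rotation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
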