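# Clinical regression stage: Box-Cox transformation of (cognitive) scores,
# backward stepwise linear model selection over MLV-per-combination
# predictors plus covariates, Bonferroni correction over the family of
# models, and leave-one-out cross-validation summarized by the adjusted R^2
# and p of the predicted-versus-observed fit.

#' Box-Cox transformation with maximum-likelihood lambda
#'
#' y(lambda) = (y^lambda - 1) / lambda for lambda != 0, log(y) for
#' lambda = 0. Lambda maximizes the profile log-likelihood of the
#' intercept-only normal model over a bounded grid. Non-positive inputs are
#' shifted by (1 - min(y)) first when `shift = TRUE`.
#'
#' @param y Numeric scores.
#' @param lambda Fixed lambda; `NULL` (default) selects by ML.
#' @param grid Candidate lambdas (default `seq(-3, 3, by = 0.01)`).
#' @param shift Apply the positivity shift when needed (default TRUE).
#' @return List with `y` (transformed), `lambda`, `shift` (amount added).
#' @export
boxcox_transform <- function(y, lambda = NULL, grid = seq(-3, 3, by = 0.01),
                             shift = TRUE) {
  if (any(!is.finite(y))) input_error("scores must be finite")
  delta <- 0
  if (any(y <= 0)) {
    if (!shift) input_error("non-positive values and shift = FALSE")
    delta <- 1 - min(y)
    y <- y + delta
  }
  if (any(y <= 0)) input_error("non-positive values after shift")
  bc <- function(l) if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
  if (is.null(lambda)) {
    n <- length(y)
    slog <- sum(log(y))
    ll <- vapply(grid, function(l) {
      z <- bc(l)
      -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
    }, double(1L))
    lambda <- grid[which.max(ll)]
  }
  list(y = bc(lambda), lambda = lambda, shift = delta)
}

#' Bonferroni correction
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of tests (default 7).
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = 7L) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    input_error("p must be in [0, 1]")
  }
  if (m < 1L) input_error("m must be >= 1")
  pmin(1, p * m)
}

# Overall model F-test p-value of an lm fit (NA for intercept-only).
model_pvalue <- function(fit) {
  fs <- summary(fit)$fstatistic
  if (is.null(fs)) return(NA_real_)
  unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
}

#' Backward stepwise linear model selection
#'
#' Starts from the full predictor set and iteratively removes the predictor
#' whose removal most improves the selection criterion until no removal
#' improves it. `criterion = "AIC"` (default) removes while AIC decreases;
#' `criterion = "pvalue"` removes the least significant predictor while its
#' p-value exceeds `alpha`. Zero-variance predictors are dropped up front;
#' when p >= n - 2 the candidate set is pre-screened to the floor(n / 2)
#' predictors with the largest absolute marginal correlation to the response.
#' Aliased (rank-deficient) columns in the final fit are dropped with a
#' warning and the model refit.
#'
#' @param design Data frame of candidate predictors (MLV columns +
#'   covariates), numeric.
#' @param response Numeric response (already transformed if desired).
#' @param criterion `"AIC"` or `"pvalue"`.
#' @param alpha Removal threshold for `criterion = "pvalue"` (default 0.05).
#' @return Object of class `stepwise_fit`: list with `selected` (predictor
#'   names), `fit` (the final `lm`), `coefficients` (coefficient table),
#'   `p_value` (model F-test), `adj_r_squared`, `r_squared`, `criterion`,
#'   `dropped_constant`, `prescreened`.
#' @export
backward_stepwise <- function(design, response,
                              criterion = c("AIC", "pvalue"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  design <- as.data.frame(design)
  if (nrow(design) != length(response)) {
    input_error("design and response sizes differ")
  }
  keep_names <- names(design)
  sds <- vapply(design, stats::sd, double(1L))
  dropped_constant <- keep_names[!is.finite(sds) | sds == 0]
  keep_names <- setdiff(keep_names, dropped_constant)
  n <- length(response)
  prescreened <- character(0)
  if (length(keep_names) >= n - 2L) {
    r <- vapply(keep_names, function(nm) {
      abs(stats::cor(design[[nm]], response))
    }, double(1L))
    top <- names(sort(r, decreasing = TRUE))[seq_len(max(1L, floor(n / 2)))]
    prescreened <- setdiff(keep_names, top)
    keep_names <- intersect(keep_names, top)
  }

  dat <- cbind(.y = response, design[keep_names])
  fit_with <- function(vars) {
    f <- if (length(vars)) {
      stats::reformulate(sprintf("`%s`", vars), response = ".y")
    } else {
      .y ~ 1
    }
    stats::lm(f, data = dat)
  }

  current <- keep_names
  fit <- fit_with(current)
  repeat {
    if (!length(current)) break
    if (criterion == "AIC") {
      aic0 <- stats::AIC(fit)
      cand <- vapply(current, function(v) {
        stats::AIC(fit_with(setdiff(current, v)))
      }, double(1L))
      if (min(cand) < aic0) {
        current <- setdiff(current, names(which.min(cand)))
        fit <- fit_with(current)
      } else {
        break
      }
    } else {
      ct <- summary(fit)$coefficients
      pv <- ct[setdiff(rownames(ct), "(Intercept)"), 4L]
      pv[is.na(pv)] <- 1 # aliased -> remove first
      if (!length(pv) || max(pv) <= alpha) break
      worst <- names(which.max(pv))
      worst <- gsub("^`|`$", "", worst)
      current <- setdiff(current, worst)
      fit <- fit_with(current)
    }
  }
  # drop aliased columns if the final design is rank deficient
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    aliased <- gsub("^`|`$", "", aliased)
    warning(sprintf("dropping aliased predictors: %s",
                    paste(aliased, collapse = ", ")))
    current <- setdiff(current, aliased)
    fit <- fit_with(current)
  }
  sm <- summary(fit)
  rownames(sm$coefficients) <- gsub("^`|`$", "", rownames(sm$coefficients))
  structure(
    list(selected = current, fit = fit, coefficients = sm$coefficients,
         p_value = model_pvalue(fit), adj_r_squared = sm$adj.r.squared,
         r_squared = sm$r.squared, criterion = criterion,
         dropped_constant = dropped_constant, prescreened = prescreened,
         data = dat),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %d predictor(s) retained (%s)\n",
              length(x$selected), x$criterion))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  model p = %.3g, adj R^2 = %.3f\n", x$p_value,
              x$adj_r_squared))
  invisible(x)
}

#' Leave-one-out cross-validation of a selected model
#'
#' For each subject, the selected predictor set is refit on the remaining
#' n - 1 subjects and the held-out score predicted; prediction quality is
#' summarized by regressing observed on predicted scores and reporting that
#' fit's adjusted R^2 and p-value. Singular leave-one-out fits yield NA
#' predictions, excluded from the summary fit with a warning.
#'
#' @param selected Character vector of predictor names (possibly empty).
#' @param design Data frame holding those predictors.
#' @param response Numeric response.
#' @return List with `predicted` (per-subject), `adj_r_squared`, `p_value`.
#' @export
loo_cv <- function(selected, design, response) {
  design <- as.data.frame(design)
  n <- length(response)
  if (n < length(selected) + 2L) {
    input_error("too few subjects for leave-one-out refits")
  }
  dat <- cbind(.y = response, design[selected])
  f <- if (length(selected)) {
    stats::reformulate(sprintf("`%s`", selected), response = ".y")
  } else {
    .y ~ 1
  }
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- stats::lm(f, data = dat[-i, , drop = FALSE])
    if (any(is.na(stats::coef(fit)))) next
    pred[i] <- stats::predict(fit, newdata = dat[i, , drop = FALSE])
  }
  ok <- is.finite(pred)
  if (!all(ok)) {
    warning(sprintf("%d singular leave-one-out fit(s) excluded", sum(!ok)))
  }
  # An intercept-only model carries no predictive signal, and its LOO
  # prediction (sum - y_i)/(n - 1) is an exact affine function of y_i, which
  # would make the predicted-vs-observed fit spuriously perfect; report NA.
  if (!length(selected) || sum(ok) < 3L || stats::sd(pred[ok]) == 0) {
    return(list(predicted = pred, adj_r_squared = NA_real_,
                p_value = NA_real_))
  }
  sfit <- stats::lm(response[ok] ~ pred[ok])
  list(predicted = pred,
       adj_r_squared = summary(sfit)$adj.r.squared,
       p_value = model_pvalue(sfit))
}

#' Run the full clinical regression stage
#'
#' For each response: optional Box-Cox transformation, backward stepwise
#' selection over the MLV predictors and covariates, Bonferroni correction of
#' the model p-value over `m` tests, and leave-one-out cross-validation.
#'
#' @param predictors Data frame of per-subject MLV columns (see
#'   [mlv_predictor_matrix()]); a `subject` column is ignored.
#' @param covariates Data frame of per-subject covariates (age, gender 0/1,
#'   education, HAD anxiety/depression); a `subject` column is ignored.
#' @param scores Data frame of per-subject clinical scores, one column per
#'   response; a `subject` column is ignored.
#' @param responses Response columns to model (default: all score columns).
#' @param boxcox_responses Which responses get Box-Cox transformed (default:
#'   all but `MSFC`, the composite left on its native scale).
#' @param m Bonferroni family size (default 7).
#' @param criterion,alpha Passed to [backward_stepwise()].
#' @return Object of class `clinical_regression`: list with `models` (a
#'   summary data frame: response, lambda, p, corrected p, adjusted R^2, LOO
#'   adjusted R^2 and p, retained predictors) and `fits` (per-response
#'   detail: the `stepwise_fit`, LOO output, transform).
#' @export
regress_clinical <- function(predictors, covariates, scores,
                             responses = NULL, boxcox_responses = NULL,
                             m = 7L, criterion = "AIC", alpha = 0.05) {
  drop_subject <- function(d) d[setdiff(names(d), "subject")]
  predictors <- drop_subject(as.data.frame(predictors))
  covariates <- drop_subject(as.data.frame(covariates))
  scores <- drop_subject(as.data.frame(scores))
  responses <- responses %||% names(scores)
  boxcox_responses <- boxcox_responses %||% setdiff(responses, "MSFC")
  design <- cbind(predictors, covariates)
  if (anyNA(design) || anyNA(scores[responses])) {
    input_error("missing values among modelled variables")
  }
  fits <- list()
  rows <- list()
  for (resp in responses) {
    y <- scores[[resp]]
    tr <- if (resp %in% boxcox_responses) {
      boxcox_transform(y)
    } else {
      list(y = y, lambda = NA_real_, shift = 0)
    }
    sw <- backward_stepwise(design, tr$y, criterion = criterion, alpha = alpha)
    cv <- loo_cv(sw$selected, design, tr$y)
    fits[[resp]] <- list(stepwise = sw, loo = cv, transform = tr)
    rows[[resp]] <- data.frame(
      response = resp, lambda = tr$lambda, n_predictors = length(sw$selected),
      p_value = sw$p_value,
      p_corrected = if (is.na(sw$p_value)) NA_real_ else
        bonferroni(sw$p_value, m),
      adj_r_squared = sw$adj_r_squared,
      loo_adj_r_squared = cv$adj_r_squared,
      loo_p_value = cv$p_value,
      predictors = paste(sw$selected, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  structure(list(models = do.call(rbind, rows), fits = fits, m = m),
            class = "clinical_regression")
}

# Significance symbols at the printed thresholds.
significance_symbol <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "*", ifelse(p < 0.01, "#",
                                                     ifelse(p < 0.05, "+", "ns"))))
}

#' Per-predictor p-value matrix of a clinical regression
#'
#' Rows are predictors ever retained, columns are responses; cells hold the
#' retained predictor's p-value (blank when not retained), formatted with the
#' significance symbols `*` (p < 0.001), `#` (p < 0.01), `+` (p < 0.05),
#' `ns` otherwise.
#'
#' @param x A `clinical_regression` object.
#' @return Character data frame.
#' @export
predictor_pvalue_table <- function(x) {
  all_pred <- unique(unlist(lapply(x$fits, function(f) f$stepwise$selected)))
  out <- data.frame(predictor = all_pred, stringsAsFactors = FALSE)
  for (resp in names(x$fits)) {
    ct <- x$fits[[resp]]$stepwise$coefficients
    rn <- gsub("^`|`$", "", rownames(ct))
    pv <- stats::setNames(ct[, 4L], rn)[all_pred]
    out[[resp]] <- ifelse(is.na(pv), "",
                          sprintf("%.4f%s", pv, significance_symbol(pv)))
  }
  out
}

#' @export
print.clinical_regression <- function(x, ...) {
  cat(sprintf("<clinical_regression> %d model(s), Bonferroni m = %d\n",
              nrow(x$models), x$m))
  print(x$models[c("response", "p_value", "p_corrected", "adj_r_squared",
                   "loo_adj_r_squared")], row.names = FALSE)
  invisible(x)
}
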