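# Synthetic clinical scores: the inverse of the regression stage. Each score
# is a known linear combination of MLV-per-combination predictors and
# covariates plus Gaussian noise, with the generating coefficients recorded
# so downstream selection and estimation can be checked against truth.

#' Default synthetic score model
#'
#' A linear model for each clinical score on `predictor_names` (typically
#' `MLV_<signature>` columns) and covariates. Each response gets three true
#' MLV predictors with coefficients sized so that, at the default predictor
#' scale, the standardized effect is about 0.4 residual SDs per predictor SD
#' (comfortably detectable at n of order 100), plus an age covariate effect
#' for some scores and unit noise.
#'
#' @param predictor_names Names of available MLV predictor columns; the
#'   first three are used as true predictors.
#' @param predictor_sd Typical SD of an MLV predictor (normalized-volume
#'   units); defaults to 1e-4, the scale of TIV-normalized lesion volumes.
#' @param noise_sd Residual SD of every score (default 1).
#' @return Named list (one element per response) of lists with `intercept`,
#'   `coefficients` (named numeric) and `noise_sd`.
#' @export
default_score_model <- function(predictor_names, predictor_sd = 1e-4,
                                noise_sd = 1) {
  if (length(predictor_names) < 3L) {
    config_error("need at least 3 predictor names for the default score model")
  }
  truth <- predictor_names[1:3]
  beta <- 0.4 * noise_sd / predictor_sd # standardized effect ~0.4 per predictor
  responses <- c("MSFC", "FV", "SRT", "SDMT", "Tot1036", "FSMCcog", "FSMCmot")
  signs <- c(-1, -1, -1, -1, -1, 1, 1) # worse scores with more lesion load
  out <- lapply(seq_along(responses), function(i) {
    list(intercept = c(MSFC = 0, FV = 25, SRT = 50, SDMT = 55, Tot1036 = 25,
                       FSMCcog = 20, FSMCmot = 23)[[responses[i]]],
         coefficients = stats::setNames(rep(signs[i] * beta, 3L), truth),
         noise_sd = noise_sd)
  })
  names(out) <- responses
  out
}

#' Generate synthetic clinical scores from a known linear model
#'
#' @param design Data frame of per-subject predictors (MLV columns and/or
#'   covariates); a `subject` column is carried through.
#' @param score_model As returned by [default_score_model()]: per response an
#'   intercept, named coefficients over `design` columns, and a noise SD.
#' @param seed Integer seed.
#' @return Data frame of scores (one column per response, plus `subject` if
#'   present in `design`), with the generating model attached as attribute
#'   `"truth"`.
#' @export
generate_clinical_scores <- function(design, score_model, seed = 1L) {
  design <- as.data.frame(design)
  set.seed(as.integer(seed))
  n <- nrow(design)
  out <- if ("subject" %in% names(design)) {
    data.frame(subject = design$subject)
  } else {
    data.frame(row.names = seq_len(n))
  }
  for (resp in names(score_model)) {
    m <- score_model[[resp]]
    vars <- names(m$coefficients)
    missing <- setdiff(vars, names(design))
    if (length(missing)) {
      config_error(sprintf("score model for %s references unknown columns: %s",
                           resp, paste(missing, collapse = ", ")))
    }
    lp <- m$intercept
    if (length(vars)) {
      lp <- lp + as.matrix(design[vars]) %*% m$coefficients
    }
    out[[resp]] <- as.vector(lp) + stats::rnorm(n, sd = m$noise_sd)
  }
  attr(out, "truth") <- score_model
  out
}

#' Generate synthetic covariates
#'
#' Age in years, gender 0/1, education years, HAD anxiety/depression scores;
#' marginals loosely matching an adult relapsing-remitting cohort.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return Data frame with columns age, gender, education, HADA, HADD.
#' @export
generate_covariates <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    age = round(stats::rnorm(n, 35, 9), 1),
    gender = stats::rbinom(n, 1L, 2 / 3),
    education = pmax(9L, round(stats::rnorm(n, 15, 3))),
    HADA = pmax(0L, round(stats::rnorm(n, 6, 3))),
    HADD = pmax(0L, round(stats::rnorm(n, 4, 3)))
  )
}
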