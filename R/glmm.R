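#' Effect-size interpretation labels
#'
#' Shared cut-points for generalized eta-squared and marginal R-squared:
#' small for values \eqn{\le} 0.1, medium strictly between 0.1 and 0.25,
#' large for values \eqn{\ge} 0.25.
#'
#' @param x Numeric vector of effect sizes in \[0, 1\].
#' @return Character vector: `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_label <- function(x) {
  dplyr::case_when(
    x <= 0.1 ~ "small",
    x < 0.25 ~ "medium",
    TRUE ~ "large"
  )
}

#' Repeated-measures ANOVA over choice conditions
#'
#' One-way repeated-measures ANOVA of a (z-scored) feature across choice
#' conditions with subject as the repeated unit, delegated to
#' `stats::aov` with an `Error(subject/...)` stratum. Post-hoc
#' paired t-tests between all condition pairs use Holm-adjusted p-values.
#' Generalized eta-squared is computed from the sums of squares as
#' `SS_effect / (SS_effect + SS_subject + SS_error)` and labeled with
#' [effect_size_label()]. Subjects missing a condition level are dropped
#' listwise (counted in `n_dropped_subjects`).
#'
#' @param features Data frame with columns named by `subject`, `condition`
#'   and `value` arguments.
#' @param value,condition,subject Column names (strings).
#' @return List with `anova` (tibble: term, df, statistic, p.value),
#'   `eta2_gen`, `eta2_label`, `posthoc` (tibble of pairwise contrasts with
#'   raw and Holm-adjusted p), `n_dropped_subjects`.
#' @export
rm_anova_stage <- function(features, value = "z", condition = "choice",
                           subject = "subject") {
  assert_that(all(c(value, condition, subject) %in% names(features)),
              "missing value/condition/subject columns")
  df <- tibble::tibble(
    value = features[[value]],
    condition = factor(features[[condition]]),
    subject = factor(features[[subject]])
  )
  df <- df[complete.cases(df), ]
  # subject x condition cell means; listwise-drop incomplete subjects
  cells <- df |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  nlev <- nlevels(df$condition)
  counts <- table(cells$subject)
  keep <- names(counts)[counts == nlev]
  dropped <- sum(counts != nlev)
  cells <- cells[cells$subject %in% keep, ]
  assert_that(length(keep) >= 2, "need >= 2 subjects with all condition levels")
  fit <- aov(value ~ condition + Error(subject / condition), data = cells)
  sm <- summary(fit)
  ss_cond <- NA_real_; ss_subj <- 0; ss_err <- 0
  cond_row <- NULL
  for (stratum in names(sm)) {
    tab <- as.data.frame(sm[[stratum]][[1]])
    rn <- trimws(rownames(tab))
    if ("condition" %in% rn) {
      cond_row <- tab[rn == "condition", , drop = FALSE]
      ss_cond <- cond_row[["Sum Sq"]]
      ss_err <- ss_err + sum(tab[rn == "Residuals", "Sum Sq"])
    } else {
      # subject stratum: between-subject variability
      ss_subj <- ss_subj + sum(tab[["Sum Sq"]])
    }
  }
  assert_that(!is.null(cond_row), "could not locate the condition stratum")
  anova_tbl <- tibble::tibble(
    term = "condition",
    df = cond_row[["Df"]],
    statistic = cond_row[["F value"]],
    p.value = cond_row[["Pr(>F)"]]
  )
  eta2 <- ss_cond / (ss_cond + ss_subj + ss_err)

  wide <- tidyr::pivot_wider(cells, names_from = "condition",
                             values_from = "value")
  levs <- levels(df$condition)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  ph <- dplyr::bind_rows(lapply(pairs, function(pr) {
    tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble::tibble(contrast = paste(pr, collapse = " vs "),
                   estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   p.value = tt$p.value)
  }))
  ph$p.adj <- p.adjust(ph$p.value, method = "holm")
  list(anova = anova_tbl, eta2_gen = eta2,
       eta2_label = effect_size_label(eta2), posthoc = ph,
       n_dropped_subjects = dropped)
}

#' Marginal and conditional R-squared of a mixed logistic model
#'
#' Variance-partition coefficients of determination:
#' `R2m = var_f / (var_f + var_r + var_d)` and
#' `R2c = (var_f + var_r) / (var_f + var_r + var_d)`, where `var_f` is the
#' variance of the fixed-effect linear predictor, `var_r` the summed
#' random-effect variance and `var_d` the link-distribution variance,
#' `pi^2 / 3` for the logistic link.
#'
#' @param fixed_var,random_var Non-negative variance components.
#' @param link_variance Residual distribution variance (default logistic).
#' @return Tibble with `r2m`, `r2c` and their interpretation labels.
#' @export
#' @examples
#' r2_mixed(1, 1)  # r2m ~0.1891, r2c ~0.3782
r2_mixed <- function(fixed_var, random_var, link_variance = pi^2 / 3) {
  assert_that(all(c(fixed_var, random_var, link_variance) >= 0),
              "variances must be >= 0")
  denom <- fixed_var + random_var + link_variance
  assert_that(denom > 0, "all variance components are zero")
  r2m <- fixed_var / denom
  r2c <- (fixed_var + random_var) / denom
  tibble::tibble(r2m = r2m, r2c = r2c,
                 r2m_label = effect_size_label(r2m),
                 r2c_label = effect_size_label(r2c))
}

# Mean per-observation random-effect variance of a glmer fit
# (Nakagawa/Johnson: mean of diag(Z Sigma Z') summed over grouping factors).
ranef_variance <- function(fit) {
  vc <- lme4::VarCorr(fit)
  fr <- stats::model.frame(fit)
  total <- 0
  for (g in names(vc)) {
    Sigma <- as.matrix(vc[[g]])
    terms <- rownames(Sigma)
    M <- matrix(1, nrow(fr), length(terms),
                dimnames = list(NULL, terms))
    for (j in seq_along(terms)) {
      if (terms[j] != "(Intercept)") {
        M[, j] <- fr[[terms[j]]]
      }
    }
    total <- total + mean(rowSums((M %*% Sigma) * M))
  }
  total
}

#' Fit a mixed-effects logistic model of a binary choice contrast
#'
#' Thin wrapper around `lme4::glmer` with a binomial(logit) family: the
#' outcome is a binary contrast between two choice labels and the
#' predictors are z-scored RMS features; subject enters through random
#' intercepts (and slopes, per the formula). Non-convergence and complete
#' separation are flagged rather than raised so callers can exclude the fit
#' from downstream series.
#'
#' @param data Data frame containing the outcome, predictors and subject.
#' @param formula Mixed-model formula, default
#'   `outcome ~ z + (1 + z | subject)`.
#' @param outcome_pair Optional length-2 character: the `choice` labels
#'   coded 1 and 0; when given, `data$choice` is filtered to these labels
#'   and an `outcome` column is built.
#' @return A `lam_glmm`: list with `fit`, `converged`, `singular`,
#'   `beta` (fixed effects), `r2` (tibble from [r2_mixed()]), `p_fixed`
#'   (Wald p of the first non-intercept fixed effect), `n`, `formula`.
#' @export
fit_choice_glmm <- function(data, formula = outcome ~ z + (1 + z | subject),
                            outcome_pair = NULL) {
  if (!is.null(outcome_pair)) {
    assert_that(length(outcome_pair) == 2, "`outcome_pair` must have 2 labels")
    data <- data[data$choice %in% outcome_pair, , drop = FALSE]
    data$outcome <- as.integer(data$choice == outcome_pair[1])
  }
  ovar <- all.vars(formula)[1]
  assert_that(ovar %in% names(data), paste0("outcome column `", ovar, "` missing"))
  y <- data[[ovar]]
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome has a single class; cannot fit a logistic contrast")
  }
  conv <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(formula, data = data, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) e),
    warning = function(w) {
      conv <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  if (inherits(fit, "error")) {
    return(structure(list(fit = NULL, converged = FALSE, singular = NA,
                          beta = NULL, r2 = NULL, p_fixed = NA_real_,
                          n = nrow(data), formula = formula,
                          error = conditionMessage(fit)),
                     class = "lam_glmm"))
  }
  beta <- lme4::fixef(fit)
  eta_fixed <- as.numeric(model.matrix(fit) %*% beta)
  r2 <- r2_mixed(var(eta_fixed), ranef_variance(fit))
  coefs <- summary(fit)$coefficients
  slope_rows <- setdiff(rownames(coefs), "(Intercept)")
  p_fixed <- if (length(slope_rows)) coefs[slope_rows[1], "Pr(>|z|)"] else NA_real_
  structure(
    list(fit = fit, converged = conv,
         singular = lme4::isSingular(fit),
         beta = beta, r2 = r2, p_fixed = p_fixed,
         n = nrow(data), formula = formula),
    class = "lam_glmm")
}

#' @export
print.lam_glmm <- function(x, ...) {
  cat("<lam_glmm>", if (x$converged) "converged" else "NOT converged",
      sprintf("n=%d", x$n), "\n")
  if (!is.null(x$r2)) {
    cat(sprintf("  R2m=%.4f (%s), R2c=%.4f\n",
                x$r2$r2m, x$r2$r2m_label, x$r2$r2c))
  }
  invisible(x)
}

#' Time-resolved effect-size series across stimulus positions
#'
#' For each cortical layer and each stimulus position (number of CS before
#' the final decision), fits the mixed logistic contrast of two choice
#' labels on the z-scored layer RMS feature and records the marginal
#' R-squared with a significance flag (Wald p of the fixed slope < 0.05).
#' Positions with fewer than 2 trials per class, or non-converging fits,
#' appear as gaps (`r2m = NA`) with the reason recorded.
#'
#' @param features Feature tibble with columns `layer`, `cs_position`,
#'   `choice`, `z` and a subject column.
#' @param outcome_pair Length-2 character vector of choice labels.
#' @param subject Subject column name (default `"subject"`).
#' @param layers Layers to fit (default: all in `features`, AVREC
#'   excluded).
#' @param random Random-terms string appended to the fixed part, default
#'   `"(1 + z | subject)"`.
#' @return Tibble: layer, cs_position, r2m, r2c, p, significant, n, status.
#' @export
effect_size_series <- function(features, outcome_pair, subject = "subject",
                               layers = NULL, random = "(1 + z | subject)") {
  assert_that(all(c("layer", "cs_position", "choice", "z") %in% names(features)),
              "`features` needs layer, cs_position, choice, z")
  assert_that(subject %in% names(features),
              paste0("subject column `", subject, "` missing"))
  layers <- layers %||% setdiff(unique(features$layer), "AVREC")
  positions <- sort(unique(features$cs_position))
  fml <- stats::as.formula(paste0("outcome ~ z + ", random))
  rows <- list()
  for (lay in layers) {
    for (pos in positions) {
      sub <- features[features$layer == lay & features$cs_position == pos &
                        features$choice %in% outcome_pair, , drop = FALSE]
      sub <- tibble::tibble(choice = sub$choice, z = sub$z,
                            subject = sub[[subject]])
      ncls <- table(factor(sub$choice, levels = outcome_pair))
      if (any(ncls < 2)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = lay, cs_position = pos, r2m = NA_real_, r2c = NA_real_,
          p = NA_real_, significant = NA, n = nrow(sub),
          status = "too_few_trials")
        next
      }
      fit <- fit_choice_glmm(sub, fml, outcome_pair = outcome_pair)
      if (is.null(fit$fit)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = lay, cs_position = pos, r2m = NA_real_, r2c = NA_real_,
          p = NA_real_, significant = NA, n = fit$n, status = "fit_error")
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        layer = lay, cs_position = pos,
        r2m = fit$r2$r2m, r2c = fit$r2$r2c, p = fit$p_fixed,
        significant = !is.na(fit$p_fixed) && fit$p_fixed < 0.05,
        n = fit$n,
        status = if (fit$converged) "ok" else "not_converged")
    }
  }
  dplyr::bind_rows(rows)
}
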