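# Confound-adjusted linear mixed model for the time-of-day effect.

#' Multi-variable adjusted linear mixed model
#'
#' Fits, by REML, a linear mixed model for a repeatedly measured response
#' (e.g. visual-cortex cluster BOLD SD) with time of day and scanning day
#' as repeated-measures fixed effects, the supplied covariates as fixed
#' effects, a random intercept per subject, and an AR(1) residual
#' correlation over the ordered sessions (day-major: the 6 times of day
#' within day 1, then day 2) within subject. Requested interactions with
#' time of day test whether a covariate explains part of the time-of-day
#' modulation. Type III (marginal) F-tests are computed under sum-to-zero
#' contrasts; denominator degrees of freedom follow nlme's containment
#' method, recorded in the output as `df_method`.
#'
#' Rows with missing covariates are dropped listwise and the count is
#' reported; numeric covariates are mean-centered after deletion, so the
#' marginal time-of-day test is evaluated at the covariate means. If the AR(1) fit fails to converge the model is refitted with
#' a compound-symmetry residual structure and a warning records the
#' downgrade.
#'
#' @param table long-format data.frame: subject, tod, day, the response and
#'   covariate columns. tod is treated as an ordered 6-level factor, day as
#'   a factor.
#' @param response name of the response column.
#' @param fixed character vector of covariate column names entering as
#'   fixed effects (may be empty).
#' @param interactions character vector of covariate names to interact
#'   with tod (e.g. chronotype, wake-up time, sleep debt, day).
#' @return list of class `confound_lmm`: `model` (the nlme fit), `anova`
#'   (type III F table: term, numDF, denDF, F, p), `correlation_structure`
#'   ("AR1" or "compound symmetry"), `n_used`, `n_dropped`, `df_method`,
#'   `sigma`, `random_intercept_sd`, `ar1_phi`.
#' @export
fit_confound_lmm <- function(table, response, fixed = character(0),
                             interactions = character(0)) {
  stopifnot(all(c("subject", "tod", "day", response) %in% names(table)),
            all(fixed %in% names(table)))
  tods <- unique(as.character(table$tod))
  dat <- data.frame(subject = factor(table$subject),
                    tod = factor(table$tod, levels = sort(tods)),
                    day = factor(table$day))
  dat$..y <- table[[response]]
  for (v in fixed) dat[[v]] <- table[[v]]
  # AR(1) position: session order within subject, day-major
  dat$..pos <- (as.integer(dat$day) - 1L) * nlevels(dat$tod) + as.integer(dat$tod)
  n0 <- nrow(dat)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_dropped <- n0 - nrow(dat)
  if (n_dropped > 0)
    message("listwise deletion: dropped ", n_dropped, " row(s) with missing values")
  # center numeric covariates so that, with tod x covariate interactions in
  # the model, the marginal (type III) tod test is evaluated at the sample
  # mean of each covariate rather than at covariate = 0
  for (v in fixed) if (is.numeric(dat[[v]])) dat[[v]] <- dat[[v]] - mean(dat[[v]])

  terms <- c("tod", if (nlevels(dat$day) > 1) "day", fixed,
             vapply(interactions, function(v)
               paste0("tod:", if (v == "day") "day" else v), character(1)))
  fml <- stats::as.formula(paste("..y ~", paste(terms, collapse = " + ")))
  opts <- list(contrasts = c(unordered = "contr.sum", ordered = "contr.poly"))
  old <- options(contrasts = opts$contrasts); on.exit(options(old), add = TRUE)

  fit_with <- function(corstr) {
    nlme::lme(fml, random = ~ 1 | subject, data = dat,
              correlation = corstr, method = "REML",
              na.action = stats::na.fail,
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100))
  }
  structure_used <- "AR1"
  fit <- tryCatch(fit_with(nlme::corAR1(form = ~ ..pos | subject)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    warning("AR(1) fit did not converge (", conditionMessage(fit),
            "); downgrading to compound symmetry")
    structure_used <- "compound symmetry"
    fit <- tryCatch(fit_with(nlme::corCompSymm(form = ~ 1 | subject)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("compound-symmetry fit failed too; fitting independent residuals")
      structure_used <- "independent"
      fit <- fit_with(NULL)
    }
  }
  an <- stats::anova(fit, type = "marginal")
  an_df <- data.frame(term = rownames(an), numDF = an$numDF, denDF = an$denDF,
                      F = an$`F-value`, p = an$`p-value`)
  vc <- nlme::VarCorr(fit)
  phi <- tryCatch({
    cs <- fit$modelStruct$corStruct
    if (is.null(cs)) NA_real_ else unname(stats::coef(cs, unconstrained = FALSE)[1])
  }, error = function(e) NA_real_)
  structure(list(model = fit, anova = an_df,
                 correlation_structure = structure_used,
                 n_used = nrow(dat), n_dropped = n_dropped,
                 df_method = "nlme containment",
                 sigma = fit$sigma,
                 random_intercept_sd = suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"])),
                 ar1_phi = phi),
            class = "confound_lmm")
}

#' @export
print.confound_lmm <- function(x, ...) {
  cat(sprintf("<confound_lmm> %s residual correlation | %d rows used (%d dropped) | df: %s\n",
              x$correlation_structure, x$n_used, x$n_dropped, x$df_method))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' JSON-ready summary of a confound-adjusted mixed model
#' @param x a `confound_lmm`.
#' @export
lmm_summary <- function(x) {
  list(terms = x$anova, correlation_structure = x$correlation_structure,
       n_used = x$n_used, n_dropped = x$n_dropped, df_method = x$df_method,
       sigma = x$sigma, random_intercept_sd = x$random_intercept_sd,
       ar1_phi = x$ar1_phi)
}
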