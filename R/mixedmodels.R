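#' Fit one linear mixed-effects model of the analysis ladder
#'
#' Fits a Gaussian linear mixed model by maximum likelihood (ML, not REML,
#' so AIC values are comparable across fixed-effect structures) with
#' sum-to-zero factor coding, as required for type-III tests.  Convergence
#' failures and singular fits are flagged on the returned object instead of
#' raising errors, so a model-selection ladder can step over them.
#'
#' A fit is flagged singular when any random-effect standard deviation
#' falls below `1e-4` of the outcome standard deviation or any
#' random-effect correlation exceeds 0.999 in magnitude.
#'
#' @param formula model formula (or string) in `lme4` notation, e.g.
#'   `hu_asin ~ condition * age_group + (condition | participant)`.
#' @param data data frame; character columns are converted to factors.
#' @return an `av_fit` object: list with `model` (the `merMod`), `formula`,
#'   `aic`, `loglik`, `npar`, `converged`, `singular`, `messages`.
#' @export
fit_mixed_model <- function(formula, data) {
  formula <- stats::as.formula(formula)
  data <- as.data.frame(data)
  for (v in names(data))
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  fac <- names(data)[vapply(data, is.factor, logical(1))]
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  used <- intersect(fac, all.vars(formula))
  contr <- contr[used]
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(formula, data = data, REML = FALSE,
                 contrasts = contr),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(structure(list(model = NULL, formula = formula, aic = Inf,
                          loglik = NA_real_, npar = NA_integer_,
                          converged = FALSE, singular = NA,
                          messages = conditionMessage(fit)),
                     class = "av_fit"))
  }
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  outcome_sd <- stats::sd(stats::model.frame(fit)[[1]])
  vc <- lme4::VarCorr(fit)
  re_sd <- unlist(lapply(vc, function(v) attr(v, "stddev")))
  re_cor <- unlist(lapply(vc, function(v) {
    cc <- attr(v, "correlation")
    if (is.null(cc) || length(cc) < 2) numeric(0) else cc[lower.tri(cc)]
  }))
  singular <- lme4::isSingular(fit, tol = 1e-4) ||
    any(re_sd < 1e-4 * outcome_sd) ||
    (length(re_cor) > 0 && any(abs(re_cor) > 0.999))
  ll <- stats::logLik(fit)
  structure(list(model = fit, formula = formula,
                 aic = stats::AIC(fit), loglik = as.numeric(ll),
                 npar = attr(ll, "df"), converged = converged,
                 singular = singular, messages = msgs),
            class = "av_fit")
}

#' @export
print.av_fit <- function(x, ...) {
  cat(sprintf("<av_fit> %s\n  AIC %.2f | logLik %.2f | npar %s | %s%s\n",
              deparse(x$formula), x$aic, x$loglik, x$npar,
              if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$singular)) " | singular" else ""))
  invisible(x)
}

#' Select a model by walking an AIC ladder
#'
#' Walks an ordered list of candidate formulas from simple to complex,
#' accepting a more complex model only if it converged, is not a singular
#' fit, and lowers the AIC of the currently accepted model by at least
#' `delta` (default 2).  A candidate failing any of the three checks is
#' skipped and the walk continues from the last accepted model.
#'
#' @param candidates list of formulas (or strings), ordered simple to
#'   complex.
#' @param data data frame passed to every fit.
#' @param delta required AIC decrease (default 2).
#' @return the selected `av_fit`, with attribute `"ladder"`: a data frame
#'   tracing every candidate (`formula`, `aic`, `converged`, `singular`,
#'   `accepted`).
#' @export
aic_ladder <- function(candidates, data, delta = 2) {
  if (length(candidates) == 0) stop("no candidate models")
  fits <- lapply(candidates, fit_mixed_model, data = data)
  if (!fits[[1]]$converged)
    stop("the first (simplest) candidate failed to fit: ",
         paste(fits[[1]]$messages, collapse = "; "))
  accepted <- logical(length(fits))
  accepted[1] <- TRUE
  current <- 1
  for (i in seq_along(fits)[-1]) {
    if (ladder_accept(fits[[current]]$aic, fits[[i]], delta)) {
      accepted[i] <- TRUE
      current <- i
    }
  }
  trace <- data.frame(
    formula = vapply(fits, function(f) deparse1(f$formula), character(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    singular = vapply(fits, function(f) isTRUE(f$singular), logical(1)),
    accepted = accepted)
  out <- fits[[current]]
  attr(out, "ladder") <- trace
  out
}

# the ladder's acceptance rule: a more complex model must have converged,
# be non-singular, and lower the AIC by at least delta
ladder_accept <- function(aic_current, fit, delta = 2) {
  isTRUE(fit$converged) && !isTRUE(fit$singular) &&
    (aic_current - fit$aic) >= delta
}

#' Type-III Wald chi-square deviance table
#'
#' Analysis-of-deviance table for the fixed effects of a fitted model:
#' per-term Wald chi-square statistic, degrees of freedom, and p-value,
#' with type-III contrasts (the model is fitted with sum-to-zero coding by
#' [fit_mixed_model()], as type III requires).
#'
#' @param fit an `av_fit` from [fit_mixed_model()].
#' @return data frame with `term`, `chisq`, `df`, `p`.
#' @export
wald_anova <- function(fit) {
  stopifnot(inherits(fit, "av_fit"))
  if (!fit$converged) stop("cannot test an unconverged fit")
  cf <- lme4::fixef(fit$model)
  if (any(is.na(cf)))
    stop("aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  tab <- car::Anova(fit$model, type = 3)
  keep <- rownames(tab) != "(Intercept)"
  data.frame(term = rownames(tab)[keep],
             chisq = tab$Chisq[keep], df = tab$Df[keep],
             p = tab$`Pr(>Chisq)`[keep])
}

#' Corrected pairwise post-hoc contrasts
#'
#' Pairwise differences of estimated marginal means over the given
#' factor(s), with Bonferroni or false-discovery-rate corrected p-values.
#' Degrees of freedom are asymptotic (z treated as t with large df), as
#' appropriate for ML fits.
#'
#' @param fit an `av_fit`.
#' @param specs factor name, or `A | B` style specification string, passed
#'   to [emmeans::emmeans()].
#' @param correction `"bonferroni"` or `"fdr"`.
#' @return data frame with `contrast`, (grouping columns if any,)
#'   `estimate`, `se`, `t`, `p`.
#' @export
posthoc_contrasts <- function(fit, specs,
                              correction = c("bonferroni", "fdr")) {
  stopifnot(inherits(fit, "av_fit"))
  correction <- match.arg(correction)
  if (is.character(specs)) specs <- stats::as.formula(paste("~", specs))
  vars <- all.vars(specs)
  miss <- setdiff(vars, all.vars(fit$formula))
  if (length(miss) > 0)
    stop("factor(s) not in the model: ", paste(miss, collapse = ", "))
  emm <- emmeans::emmeans(fit$model, specs, lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = correction))
  out <- as.data.frame(prs)
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) %in% c("t.ratio", "z.ratio")] <- "t"
  names(out)[names(out) == "p.value"] <- "p"
  out
}
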