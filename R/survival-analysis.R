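# Kaplan-Meier / log-rank / Cox machinery and the driver-gene contrast
# battery that dissects confounded prognostic associations.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()].  The median is the
#' first observed time at which the survival estimate drops to 0.5 or
#' below, `NA` when the curve never reaches 0.5 (e.g. censored-only input).
#'
#' @param time positive follow-up times.
#' @param event event indicators, 0 (censored) or 1 (event).
#' @return a list of class `km_curve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `median`, `n`.
#' @export
km_estimate <- function(time, event) {
  .check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(
    time = fit$time,
    surv = fit$surv,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    median = .km_median(fit$time, fit$surv),
    n = length(time)
  ), class = "km_curve")
}

.km_median <- function(time, surv) {
  i <- which(surv <= 0.5)
  if (length(i)) time[min(i)] else NA_real_
}

.check_surv_input <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all survival times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicators must be 0 or 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Chi-square statistic on 1 df via [survival::survdiff()], with the
#' standard hypergeometric variance at tied event times.  Two identical
#' groups give statistic 0 and P = 1.
#'
#' @param time,event pooled survival data.
#' @param group a two-level grouping vector aligned with `time`.
#' @param name label carried into the result.
#' @return a one-row data frame: `contrast`, `n1`, `n2`, `chisq`,
#'   `p_value`, `median1`, `median2`.
#' @export
logrank_test <- function(time, event, group, name = "contrast") {
  .check_surv_input(time, event)
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stop("`group` must have exactly two nonempty levels", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  lev <- levels(group)
  med <- vapply(lev, function(l) {
    km <- km_estimate(time[group == l], event[group == l])
    km$median
  }, numeric(1))
  data.frame(
    contrast = name,
    n1 = sum(group == lev[1]), n2 = sum(group == lev[2]),
    chisq = chisq,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    median1 = med[1], median2 = med[2],
    evaluable = TRUE,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()].  Per-covariate hazard
#' ratios with Wald 95% CIs and P values, plus per-variable sequential
#' significance from the likelihood-ratio analysis-of-deviance table
#' (`anova()` on the fitted model), mirroring how variable-level
#' significance is usually assessed alongside a multivariate fit.
#'
#' @param data data frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @return a list of class `cox_result`: `coefficients` (data frame with
#'   `term`, `hr`, `ci_lower`, `ci_upper`, `wald_p`), `anova` (data frame
#'   with `variable`, `seq_p`), `converged`, `fit`.
#' @export
cox_fit <- function(data, covariates) {
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    stop("covariate(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in covariates) {
    if (length(unique(data[[v]])) < 2L) {
      stop("covariate `", v, "` is constant", call. = FALSE)
    }
  }
  .check_surv_input(data$time, data$event)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data)
  converged <- is.null(fit$info) &&
    all(is.finite(stats::coef(fit))) && all(is.finite(sqrt(diag(fit$var))))
  if (!converged) {
    warning("Cox fit did not converge cleanly (possible separation)",
            call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    hr = unname(sm$conf.int[, "exp(coef)"]),
    ci_lower = unname(sm$conf.int[, "lower .95"]),
    ci_upper = unname(sm$conf.int[, "upper .95"]),
    wald_p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  an <- stats::anova(fit)
  an_df <- data.frame(
    variable = rownames(an)[-1L],
    seq_p = an[["Pr(>|Chi|)"]][-1L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(coefficients = coefs, anova = an_df,
                 converged = converged, fit = fit),
            class = "cox_result")
}

# Run one battery contrast; empty or degenerate arms give a
# "not evaluable" row rather than an error.
.battery_contrast <- function(name, sel1, sel2, profiles) {
  n1 <- sum(sel1); n2 <- sum(sel2)
  na_row <- data.frame(
    contrast = name, n1 = n1, n2 = n2, chisq = NA_real_,
    p_value = NA_real_, median1 = NA_real_, median2 = NA_real_,
    evaluable = FALSE, stringsAsFactors = FALSE
  )
  if (n1 == 0L || n2 == 0L) return(na_row)
  sel <- sel1 | sel2
  grp <- ifelse(sel1[sel], "g1", "g2")
  res <- tryCatch(
    logrank_test(profiles$time[sel], profiles$event[sel], grp, name = name),
    error = function(e) na_row
  )
  res
}

#' Driver-gene prognostic contrast battery
#'
#' Runs, in order, the full set of overall-survival contrasts used to
#' dissect which of the four PDAC driver genes actually carries the
#' prognostic signal once co-occurring mutations are held fixed:
#' \describe{
#'   \item{A}{KRAS-only mutants vs patients without any driver mutation.}
#'   \item{B}{each exact two-gene combination KRAS+X (X = TP53, SMAD4,
#'     CDKN2A; all other drivers wildtype) vs KRAS-only.}
#'   \item{C}{each exact co-mutation combination on a KRAS-mutant
#'     background (three or more drivers) vs KRAS-only.}
#'   \item{D/E}{CDKN2A (resp. SMAD4) mutant vs wildtype, computed on all
#'     patients and again after excluding TP53-mutant patients.}
#'   \item{F}{TP53 mutant vs TP53 wildtype.}
#' }
#' Contrasts with an empty arm are returned as not evaluable rather than
#' dropped, so the battery shape is stable.
#'
#' @param profiles profiles from [build_profiles()] with all four driver
#'   flags plus `time` and `event`.
#' @return a data frame with one row per contrast: `contrast`, `n1`, `n2`,
#'   `chisq`, `p_value`, `median1`, `median2`, `evaluable`.
#' @export
driver_battery <- function(profiles) {
  k <- profiles$kras_mut; t <- profiles$tp53_mut
  s <- profiles$smad4_mut; c2 <- profiles$cdkn2a_mut
  kras_only <- k & !t & !s & !c2
  no_driver <- !k & !t & !s & !c2

  rows <- list()
  add <- function(name, sel1, sel2) {
    rows[[length(rows) + 1L]] <<- .battery_contrast(name, sel1, sel2, profiles)
  }

  add("A: KRAS-only vs no-driver", kras_only, no_driver)

  add("B: KRAS+TP53-only vs KRAS-only",  k &  t & !s & !c2, kras_only)
  add("B: KRAS+SMAD4-only vs KRAS-only", k & !t &  s & !c2, kras_only)
  add("B: KRAS+CDKN2A-only vs KRAS-only", k & !t & !s &  c2, kras_only)

  add("C: KRAS+TP53+SMAD4-only vs KRAS-only",   k &  t &  s & !c2, kras_only)
  add("C: KRAS+TP53+CDKN2A-only vs KRAS-only",  k &  t & !s &  c2, kras_only)
  add("C: KRAS+SMAD4+CDKN2A-only vs KRAS-only", k & !t &  s &  c2, kras_only)
  add("C: KRAS+TP53+SMAD4+CDKN2A vs KRAS-only", k &  t &  s &  c2, kras_only)

  add("D: CDKN2A-mut vs CDKN2A-wt (all)", c2, !c2)
  add("D: CDKN2A-mut vs CDKN2A-wt (TP53-wt only)", c2 & !t, !c2 & !t)
  add("E: SMAD4-mut vs SMAD4-wt (all)", s, !s)
  add("E: SMAD4-mut vs SMAD4-wt (TP53-wt only)", s & !t, !s & !t)

  add("F: TP53-mut vs TP53-wt", t, !t)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
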