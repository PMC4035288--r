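#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` over the distinct event times,
#' computed with [survival::survfit()]. Censored observations tied with an
#' event time are considered still at risk at that time (the standard
#' convention).
#'
#' @param times non-negative follow-up times (months).
#' @param events 0 = censored, 1 = event.
#' @return object of class `km_curve`: data.frame `curve` (time, n_risk,
#'   n_event, survival, restricted to event times) plus the full survfit
#'   step function in `fit`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (length(times) != length(events)) stop("times and events must align")
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  sm <- summary(fit, censored = FALSE)
  curve <- data.frame(time = sm$time, n_risk = sm$n.risk,
                      n_event = sm$n.event, survival = sm$surv)
  structure(list(curve = curve, fit = fit, n = length(times),
                 n_events = sum(events)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d events\n", x$n, x$n_events))
  print(utils::head(x$curve, 10))
  if (nrow(x$curve) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "Months", ylab = "Relapse-free survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic
#' `chi2 = (sum_t (O_At - E_At))^2 / sum_t V_t`, with p from a chi-square
#' distribution on 1 df, via [survival::survdiff()]. If neither group has
#' any event the test is degenerate: chi2 = 0, p = 1, flagged.
#'
#' @param times_a,events_a,times_b,events_b per-group survival data.
#' @return list(chi2, p, degenerate).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Univariate Cox hazard ratio
#'
#' Proportional-hazards fit of a single binary group indicator by partial
#' likelihood with Breslow tie handling (Efron available via `ties`),
#' through [survival::coxph()]. Reports `HR = exp(beta)`, the Wald 95% CI
#' `exp(beta +/- 1.96 SE)` and the Wald p-value. The hazard ratio is for
#' the second group level relative to the first.
#'
#' @param times,events aligned survival data.
#' @param group two-level vector (factor order defines the HR direction).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list(hr, ci_low, ci_high, p, beta, se).
#' @export
cox_hazard_ratio <- function(times, events, group, ties = "breslow") {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  fit <- survival::coxph(survival::Surv(times, events) ~ group, ties = ties)
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta) || abs(beta) > 15) {
    stop("monotone partial likelihood (complete separation of events); ",
         "use an exact or penalized method")
  }
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se)
}

#' Survival comparison of reclassified G2 groups
#'
#' Validates a G1*/G3* reclassification against relapse-free survival:
#' log-rank tests and Cox hazard ratios for G1* vs G3*, G1 vs G1* and
#' G3 vs G3*, plus Kaplan-Meier curves for all four groups. A comparison
#' with an empty group is marked degenerate.
#'
#' @param samples a sample table with survival columns.
#' @param reclass a [reclassify_g2()] result (names = G2 sample ids), or a
#'   named character vector of `"G1*"`/`"G3*"`.
#' @return object of class `reclass_survival`: `comparisons` (named list
#'   of comparison records), `km` (named list of `km_curve` for G1, G3,
#'   G1*, G3*).
#' @export
compare_reclassified_groups <- function(samples, reclass) {
  assigned <- if (inherits(reclass, "reclassification")) reclass$assigned
              else reclass
  if (is.null(names(assigned))) stop("reclassification must be named by sample")
  missing <- setdiff(names(assigned), samples$sample_id)
  if (length(missing)) {
    stop("reclassified sample(s) missing survival data: ",
         paste(missing, collapse = ", "))
  }
  pick <- function(ids) samples[match(ids, samples$sample_id), , drop = FALSE]
  groups <- list(
    "G1" = pick(samples$sample_id[samples$grade == "G1"]),
    "G3" = pick(samples$sample_id[samples$grade == "G3"]),
    "G1*" = pick(names(assigned)[assigned == "G1*"]),
    "G3*" = pick(names(assigned)[assigned == "G3*"]))
  km <- lapply(groups, function(g) {
    if (nrow(g)) km_estimate(g$time, g$event) else NULL
  })
  compare <- function(a, b) {
    ga <- groups[[a]]; gb <- groups[[b]]
    if (!nrow(ga) || !nrow(gb)) {
      return(list(group_a = a, group_b = b, degenerate = TRUE))
    }
    lr <- logrank_test(ga$time, ga$event, gb$time, gb$event)
    hr <- tryCatch({
      cox_hazard_ratio(c(ga$time, gb$time), c(ga$event, gb$event),
                       factor(rep(c(a, b), c(nrow(ga), nrow(gb))),
                              levels = c(a, b)))
    }, error = function(e) NULL)
    list(group_a = a, group_b = b, degenerate = FALSE,
         logrank_chi2 = lr$chi2, logrank_p = lr$p,
         logrank_degenerate = lr$degenerate,
         hr = if (is.null(hr)) NA_real_ else hr$hr,
         hr_ci = if (is.null(hr)) c(NA_real_, NA_real_)
                 else c(hr$ci_low, hr$ci_high),
         hr_p = if (is.null(hr)) NA_real_ else hr$p)
  }
  comparisons <- list(
    "G1*_vs_G3*" = compare("G1*", "G3*"),
    "G1_vs_G1*" = compare("G1", "G1*"),
    "G3_vs_G3*" = compare("G3", "G3*"))
  structure(list(comparisons = comparisons, km = km),
            class = "reclass_survival")
}

#' @export
print.reclass_survival <- function(x, ...) {
  cat("<reclass_survival>\n")
  for (nm in names(x$comparisons)) {
    cm <- x$comparisons[[nm]]
    if (cm$degenerate) {
      cat(sprintf("  %-12s degenerate (empty group)\n", nm))
    } else {
      cat(sprintf("  %-12s log-rank chi2 = %.3f (p = %.4g), HR = %.2f [%.2f-%.2f]\n",
                  nm, cm$logrank_chi2, cm$logrank_p, cm$hr,
                  cm$hr_ci[1], cm$hr_ci[2]))
    }
  }
  invisible(x)
}

#' @export
plot.reclass_survival <- function(x, ...) {
  cols <- c("G1" = "#1b7837", "G3" = "#762a83",
            "G1*" = "#5aae61", "G3*" = "#9970ab")
  keep <- !vapply(x$km, is.null, logical(1))
  fits <- x$km[keep]
  plot(NULL, xlim = c(0, max(vapply(fits, function(k) max(k$fit$time), 1))),
       ylim = c(0, 1), xlab = "Months", ylab = "Relapse-free survival", ...)
  for (nm in names(fits)) {
    graphics::lines(fits[[nm]]$fit, col = cols[[nm]], conf.int = FALSE,
                    mark.time = TRUE)
  }
  graphics::legend("bottomleft", legend = names(fits),
                   col = cols[names(fits)], lty = 1, bty = "n")
  invisible(x)
}
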