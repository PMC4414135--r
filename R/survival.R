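#' @include AllClasses.R AllGenerics.R
#' @importFrom survival Surv survfit survdiff
NULL

#' Median split on mean microRNA expression
#'
#' Scores each patient by the arithmetic mean of the listed microRNA
#' expression values and assigns `"high"` to patients whose score is
#' strictly greater than the cohort median, `"low"` otherwise (ties at
#' the median go to low, reading "greater than the group median"
#' literally).
#'
#' @param records survival data.frame with one `expr_<mir>` column per
#'   microRNA (see [readSurvival()]).
#' @param mirs microRNA names defining the score.
#' @return named character vector (`"high"`/`"low"`) indexed by patient
#'   id.
#' @export
medianSplit <- function(records, mirs) {
  cols <- paste0("expr_", mirs)
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("missing expression column(s): ", paste(miss, collapse = ", "))
  em <- as.matrix(records[, cols, drop = FALSE])
  if (anyNA(em)) {
    bad <- records$id[apply(is.na(em), 1L, any)]
    stop("missing expression value for patient(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  score <- rowMeans(em)
  grp <- ifelse(score > stats::median(score), "high", "low")
  stats::setNames(grp, records$id)
}

#' Kaplan-Meier product-limit curve
#'
#' Fits the product-limit estimator via [survival::survfit()]; subjects
#' censored at an event time are counted at risk for that event
#' (censoring ordered after events at equal times, the standard
#' convention).
#'
#' @param records data.frame with `time_months` and `event` columns.
#' @return a [KMCurve-class].
#' @export
kmCurve <- function(records) {
  if (nrow(records) < 1L) stop("need at least one record")
  if (any(records$time_months < 0)) stop("negative survival times")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records)
  ev <- fit$n.event > 0
  new("KMCurve",
      time = fit$time[ev], surv = fit$surv[ev],
      nRisk = as.integer(fit$n.risk[ev]),
      nEvent = as.integer(fit$n.event[ev]),
      censorTimes = rep(fit$time[fit$n.censor > 0],
                        fit$n.censor[fit$n.censor > 0]),
      nSubjects = nrow(records))
}

#' @rdname kmCurve
#' @param curve a [KMCurve-class]
#' @param t time (months)
#' @export
setMethod("survivalAt", "KMCurve", function(curve, t) {
  stopifnot(t >= 0)
  if (length(curve@time) == 0L || t < curve@time[1]) return(1)
  curve@surv[findInterval(t, curve@time)]
})

setMethod("show", "KMCurve", function(object) {
  cat("KMCurve:", object@nSubjects, "subjects,", sum(object@nEvent),
      "events,", length(object@censorTimes), "censored\n")
  if (length(object@time))
    cat("  S at last event time", max(object@time), "=",
        format(min(object@surv), digits = 4), "\n")
})

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival cohorts over the pooled
#' event times, via [survival::survdiff()] (chi-squared statistic, 1
#' degree of freedom, upper-tail p). At least one event overall is
#' required; with none the statistic is undefined.
#'
#' @param recordsA,recordsB data.frames with `time_months` and `event`.
#' @return a [LogRankResult-class].
#' @export
logrankTest <- function(recordsA, recordsB) {
  if (nrow(recordsA) == 0L || nrow(recordsB) == 0L)
    stop("both groups must be non-empty")
  dat <- data.frame(
    time_months = c(recordsA$time_months, recordsB$time_months),
    event = c(recordsA$event, recordsB$event),
    grp = rep(c("A", "B"), c(nrow(recordsA), nrow(recordsB))))
  if (sum(dat$event) == 0L)
    stop("no events in either group; the log-rank statistic is undefined")
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ grp, data = dat)
  stat <- unname(sd$chisq)
  new("LogRankResult", statistic = stat, df = 1L,
      p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              object@statistic, object@df, object@p))
})

#' Stratified recurrence-free survival analysis
#'
#' Convenience wrapper: median-splits the cohort on mean expression of
#' the given microRNAs, fits a Kaplan-Meier curve per group, and runs the
#' two-group log-rank test.
#'
#' @param records survival data.frame (see [readSurvival()]).
#' @param mirs microRNAs defining the expression score.
#' @return list with `groups`, `curves` (named list high/low of
#'   [KMCurve-class]) and `logrank` ([LogRankResult-class]).
#' @export
survivalStratified <- function(records, mirs) {
  grp <- medianSplit(records, mirs)
  hi <- records[grp[records$id] == "high", , drop = FALSE]
  lo <- records[grp[records$id] == "low", , drop = FALSE]
  list(groups = grp,
       curves = list(high = kmCurve(hi), low = kmCurve(lo)),
       logrank = logrankTest(hi, lo))
}
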