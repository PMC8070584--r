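#' Median split of a regulon activity profile
#'
#' Samples strictly above the median activity are labelled `"high"`,
#' samples at or below it `"low"` (ties at the median go low).
#'
#' @param activity_row named numeric vector of per-sample activity (at
#'   least 4 samples, not all equal).
#' @return A named factor with levels `low`, `high`.
#' @export
median_split <- function(activity_row) {
  if (length(activity_row) < 4) stop("need at least 4 samples to split")
  if (max(activity_row) == min(activity_row))
    stop("all activities are equal; no median split possible")
  med <- median(activity_row)
  factor(ifelse(activity_row > med, "high", "low"),
         levels = c("low", "high"))
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample", "time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (!all(records$event %in% c(0, 1)))
    stop("event flags must be 0 (censored) or 1 (death)")
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct event times; censored times reduce the risk set without a
#' drop in the curve.
#'
#' @param records data.frame with columns `sample`, `time` (> 0), `event`
#'   (0/1); at least one record.
#' @return An object of class `km_curve`: a data.frame with columns `time`,
#'   `n_risk`, `n_event`, `surv` (one row per distinct event time).
#' @export
km_estimate <- function(records) {
  validate_records(records)
  if (nrow(records) == 0) stop("at least one record is required")
  et <- sort(unique(records$time[records$event == 1]))
  if (length(et) == 0) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    class(out) <- c("km_curve", class(out))
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(records$time >= t), integer(1))
  n_event <- vapply(et, function(t)
    sum(records$time == t & records$event == 1), integer(1))
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    surv = cumprod(1 - n_event / n_risk))
  class(out) <- c("km_curve", class(out))
  out
}

#' Median survival time of a Kaplan-Meier curve
#'
#' First event time at which the survival estimate drops to 0.5 or below;
#' `Inf` when the curve never reaches 0.5.
#'
#' @param km a [km_estimate()] result.
#' @return A single number (possibly `Inf`).
#' @export
km_median <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  hit <- which(km$surv <= 0.5)
  if (length(hit) == 0) Inf else km$time[hit[1]]
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic: at each distinct event time
#' the observed events in group A are compared with the hypergeometric
#' expectation given the risk sets, and
#' `chi-square = (O_A - E_A)^2 / V` is referred to chi-square with 1 df.
#'
#' @param groupA,groupB record data.frames (both non-empty, at least one
#'   event overall).
#' @return An object of class `logrank_result`: `observed`, `expected`
#'   (per-group event totals), `var`, `chisq`, `p`. Zero total variance
#'   yields `NA` statistics with a warning.
#' @export
logrank_test <- function(groupA, groupB) {
  validate_records(groupA); validate_records(groupB)
  if (nrow(groupA) == 0 || nrow(groupB) == 0)
    stop("both groups must be non-empty")
  if (sum(groupA$event) + sum(groupB$event) == 0)
    stop("at least one event is required")
  all_t <- sort(unique(c(groupA$time[groupA$event == 1],
                         groupB$time[groupB$event == 1])))
  oA <- sum(groupA$event); oB <- sum(groupB$event)
  eA <- v <- 0
  for (t in all_t) {
    nA <- sum(groupA$time >= t); nB <- sum(groupB$time >= t)
    n <- nA + nB
    d <- sum(groupA$time == t & groupA$event == 1) +
      sum(groupB$time == t & groupB$event == 1)
    eA <- eA + d * nA / n
    if (n > 1)
      v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  if (v == 0) {
    warning("zero log-rank variance; test undefined")
    return(structure(list(observed = c(A = oA, B = oB),
                          expected = c(A = eA, B = oA + oB - eA),
                          var = 0, chisq = NA_real_, p = NA_real_),
                     class = "logrank_result"))
  }
  chisq <- (oA - eA)^2 / v
  structure(list(observed = c(A = oA, B = oB),
                 expected = c(A = eA, B = oA + oB - eA),
                 var = v, chisq = chisq,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.4f (1 df), p = %.4g\n", x$chisq, x$p))
  cat(sprintf("  observed A/B = %d/%d, expected A = %.3f, var = %.4f\n",
              x$observed["A"], x$observed["B"], x$expected["A"], x$var))
  invisible(x)
}

# Restricted mean survival (area under the KM curve up to the largest
# observed time); used as a direction fall-back when a KM median is
# undefined in both groups.
km_rmean <- function(records) {
  km <- km_estimate(records)
  t_max <- max(records$time)
  if (nrow(km) == 0) return(t_max)
  times <- c(0, km$time, t_max)
  surv <- c(1, km$surv, km$surv[nrow(km)])
  sum(diff(times) * surv[-length(surv)])
}

#' Screen every regulon for survival stratification
#'
#' For each regulon the cohort is median-split on its activity and the two
#' groups are compared with the log-rank test. The prognosis direction is
#' `"good"` when the high-activity group survives longer (by KM median,
#' falling back to restricted mean survival when both medians are
#' undefined), `"bad"` otherwise. Raw and BH-adjusted p-values are both
#' reported; the raw value matches per-regulon reporting, the adjusted one
#' accounts for screening several regulons.
#'
#' @param activity a [regulon_activity_matrix()] result.
#' @param records survival data.frame (`sample`, `time`, `event`); only
#'   samples shared with `activity` are used.
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05, on the raw p).
#' @return A data.frame with one row per regulon: `regulon`, `chisq`, `p`,
#'   `p_adj`, `n_high`, `n_low`, `direction`, `significant`.
#' @export
survival_screen <- function(activity, records, alpha = 0.05) {
  validate_records(records)
  shared <- intersect(colnames(activity), records$sample)
  if (length(shared) < 4) stop("fewer than 4 samples shared with 'records'")
  records <- records[match(shared, records$sample), , drop = FALSE]
  rows <- list()
  for (tf in rownames(activity)) {
    act <- setNames(unclass(activity)[tf, shared], shared)
    if (anyNA(act) || max(act) == min(act)) {
      warning(sprintf("regulon %s skipped: no valid median split", tf))
      next
    }
    grp <- median_split(act)
    high <- records[grp == "high", , drop = FALSE]
    low <- records[grp == "low", , drop = FALSE]
    lr <- if (sum(high$event) + sum(low$event) == 0) NULL else
      suppressWarnings(logrank_test(high, low))
    med_h <- km_median(km_estimate(high))
    med_l <- km_median(km_estimate(low))
    direction <- if (med_h != med_l) {
      if (med_h > med_l) "good" else "bad"
    } else if (is.infinite(med_h)) {
      if (km_rmean(high) >= km_rmean(low)) "good" else "bad"
    } else {
      if (km_rmean(high) >= km_rmean(low)) "good" else "bad"
    }
    rows[[tf]] <- data.frame(
      regulon = tf,
      chisq = if (is.null(lr)) NA_real_ else lr$chisq,
      p = if (is.null(lr)) NA_real_ else lr$p,
      n_high = nrow(high), n_low = nrow(low), direction = direction,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no regulon could be screened")
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- adjust_pvalues(out$p[ok], "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out <- out[, c("regulon", "chisq", "p", "p_adj", "n_high", "n_low",
                 "direction", "significant")]
  rownames(out) <- NULL
  out
}
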