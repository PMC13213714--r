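#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` over distinct event times, with
#' the standard convention that subjects censored at an event time are still
#' at risk at that time. The median is the smallest event time with
#' `S(t) <= 0.5`, NA if never reached.
#'
#' @param time follow-up times (nonnegative; rows with NA dropped pairwise
#'   with `event`).
#' @param event event indicator (1 = death/event, 0 = censored).
#' @return list of class `kmCurve`: `curve` (data.frame time, nRisk, nEvent,
#'   survival over distinct event times) and `median`.
#' @export
kmEstimate <- function(time, event) {
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]
  if (!length(time)) stop("no subjects with observed survival data")
  et <- sort(unique(time[event == 1]))
  if (!length(et)) {
    out <- list(curve = data.frame(time = numeric(), nRisk = integer(),
                                   nEvent = integer(), survival = numeric()),
                median = NA_real_, n = length(time))
    class(out) <- "kmCurve"
    return(out)
  }
  nRisk <- vapply(et, function(t) sum(time >= t), integer(1))
  nEvent <- vapply(et, function(t) sum(time == t & event == 1), integer(1))
  surv <- cumprod(1 - nEvent / nRisk)
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  out <- list(curve = data.frame(time = et, nRisk = nRisk, nEvent = nEvent,
                                 survival = surv),
              median = med, n = length(time))
  class(out) <- "kmCurve"
  out
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$curve$nEvent),
      "events; median", if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time t with d events among n at risk (n1 in group
#' A): `E1 = n1 d / n`, `V = d (n1/n)(1 - n1/n)(n - d)/(n - 1)`; the statistic
#' is `(sum O1 - sum E1)^2 / sum V` on 1 df.
#'
#' @param timeA,eventA follow-up and event indicator for group A.
#' @param timeB,eventB same for group B.
#' @return list of class `logrankResult`: chiSquare, df, p, observed and
#'   expected event counts per group.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  ka <- !is.na(timeA) & !is.na(eventA); kb <- !is.na(timeB) & !is.na(eventB)
  timeA <- timeA[ka]; eventA <- eventA[ka]
  timeB <- timeB[kb]; eventB <- eventB[kb]
  if (!length(timeA) || !length(timeB))
    stop("both groups need at least one subject with survival data")
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  g1 <- c(rep(TRUE, length(timeA)), rep(FALSE, length(timeB)))
  if (sum(event) == 0) stop("log-rank undefined: no events in either group")
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- numeric(length(et))
  for (j in seq_along(et)) {
    t <- et[j]
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1[j] <- d1
    E1[j] <- n1 * d / n
    V[j] <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
  }
  chi <- (sum(O1) - sum(E1))^2 / sum(V)
  D <- sum(event)
  out <- list(chiSquare = chi, df = 1L,
              p = stats::pchisq(chi, 1, lower.tail = FALSE),
              observed = c(A = sum(O1), B = D - sum(O1)),
              expected = c(A = sum(E1), B = D - sum(E1)))
  class(out) <- "logrankResult"
  out
}

#' @export
print.logrankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chiSquare, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit for subtype survival comparisons
#'
#' Partial-likelihood maximization is delegated to [survival::coxph()] (Efron
#' tie handling by default). The subtype covariate is coded with MUT1 as the
#' reference, so a hazard ratio above 1 means excess mortality in MUT2. Sex is
#' coded male vs female reference; smoking as former/current dummies vs never.
#' Rows with missing time/event are dropped per the complete-case rule, as are
#' rows missing any requested covariate (count reported via message).
#'
#' @param data data.frame with survival and covariate columns.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("subtype", "age", "sex", "smoking")`).
#' @param timeCol,eventCol survival column names (months; 1 = event).
#' @param tieMethod passed to coxph (default "efron").
#' @return list of class `coxResult`: `table` (data.frame term, hr, lo, hi, p),
#'   `n`, `events`, `tieMethod`, and the underlying `model`.
#' @export
coxFit <- function(data, covariates, timeCol = "os_months",
                   eventCol = "os_event", tieMethod = "efron") {
  d <- data[, c(timeCol, eventCol, covariates), drop = FALSE]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message("dropping ", sum(!cc), " incomplete row(s) (complete-case)")
  d <- d[cc, , drop = FALSE]
  if ("subtype" %in% names(d))
    d$subtype <- factor(d$subtype, levels = c("MUT1", "MUT2"))
  if ("sex" %in% names(d))
    d$sex <- factor(d$sex, levels = c("female", "male"))
  if ("smoking" %in% names(d))
    d$smoking <- factor(d$smoking, levels = c("never", "former", "current"))
  for (v in covariates)
    if (length(unique(d[[v]])) < 2)
      stop("covariate '", v, "' is constant after complete-case filtering")
  if (sum(d[[eventCol]]) < length(covariates) + 1)
    stop("too few events (", sum(d[[eventCol]]), ") for ",
         length(covariates), " covariate(s)")
  fml <- stats::as.formula(paste0("survival::Surv(", timeCol, ", ", eventCol,
                                  ") ~ ", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = tieMethod)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox model failed to converge")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    lo = s$conf.int[, "lower .95"],
                    hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  out <- list(table = tab, n = s$n, events = s$nevent, tieMethod = tieMethod,
              model = fit)
  class(out) <- "coxResult"
  out
}

#' @export
print.coxResult <- function(x, ...) {
  cat("Cox proportional hazards (", x$tieMethod, " ties): n = ", x$n,
      ", events = ", x$events, "\n", sep = "")
  print(transform(x$table, hr = signif(hr, 3), lo = signif(lo, 3),
                  hi = signif(hi, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction by
#' default (Yates available via `correct = TRUE`).
#'
#' @param tab matrix of nonnegative integer counts with positive margins.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list: statistic, df, p.
#' @export
chiSquareTest <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero margin in the table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Wilcoxon rank-sum comparison (thin delegation)
#' @param x,y numeric samples.
#' @return list: statistic, p.
#' @export
wilcoxonTest <- function(x, y) {
  w <- stats::wilcox.test(x, y, exact = FALSE)
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Round half away from zero
#'
#' Table-style rounding (0.05 -> 0.1 at one decimal), unlike base R's
#' round-half-even.
#' @param x numeric.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Pool per-cohort demographic counts into a Table-1-style summary
#'
#' Pools category counts across cohorts and reports the pooled count with its
#' percentage of the pooled total (one decimal, rounded half-up), plus
#' per-cohort percentages of each cohort's n.
#'
#' @param counts long-format data.frame: cohort, characteristic, category,
#'   count.
#' @param cohortSizes named numeric vector of per-cohort sample sizes.
#' @return list: `pooled` (characteristic, category, count, percent),
#'   `perCohort` (cohort, characteristic, category, count, percent),
#'   `totalN`.
#' @export
cohortSummary <- function(counts, cohortSizes) {
  need <- c("cohort", "characteristic", "category", "count")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(counts$cohort), names(cohortSizes))
  if (length(unknown))
    stop("cohort(s) without a size: ", paste(unknown, collapse = ", "))
  totalN <- sum(cohortSizes[unique(counts$cohort)])
  agg <- stats::aggregate(count ~ characteristic + category, counts, sum)
  agg <- agg[order(match(paste(agg$characteristic, agg$category),
                         paste(counts$characteristic, counts$category))), ]
  pooled <- data.frame(characteristic = agg$characteristic,
                       category = agg$category, count = agg$count,
                       percent = roundHalfUp(100 * agg$count / totalN, 1),
                       row.names = NULL)
  per <- counts
  per$percent <- roundHalfUp(100 * per$count /
                               as.numeric(cohortSizes[per$cohort]), 1)
  list(pooled = pooled, perCohort = per, totalN = totalN)
}

#' Tabulate raw clinical records into cohortSummary input
#'
#' Convenience for raw per-sample tables: counts sex, smoking, OS event and
#' subtype categories per cohort (NA becomes category "NA").
#'
#' @param clinical data.frame with columns cohort, sex, smoking, os_event,
#'   subtype (any subset).
#' @return long-format counts data.frame as expected by [cohortSummary()].
#' @export
tabulateClinical <- function(clinical) {
  vars <- intersect(c("sex", "smoking", "os_event", "subtype"),
                    names(clinical))
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- as.character(clinical[[v]])
    x[is.na(x)] <- "NA"
    if (v == "os_event")
      x <- c(`1` = "Event", `0` = "Censored", `NA` = "NA")[x]
    t <- as.data.frame(table(cohort = clinical$cohort, category = x),
                       stringsAsFactors = FALSE)
    data.frame(cohort = t$cohort, characteristic = v, category = t$category,
               count = t$Freq)
  }))
  rownames(out) <- NULL
  out
}
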