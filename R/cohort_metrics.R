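#' Classify a variant for the weighted mutation-burden score
#'
#' Truncating: nonsense, frame-shift deletion/insertion, splice-site.
#' Non-truncating: missense, in-frame deletion/insertion, nonstop. Anything
#' else (silent, UTR, intronic, ...) is excluded. Strings are matched
#' case-insensitively against MAF-convention names plus common synonyms;
#' additional synonyms can be supplied.
#'
#' @param classification character vector of variant classification strings.
#' @param synonyms optional named character vector mapping extra
#'   (lower-cased) strings to \code{"truncating"} or \code{"non_truncating"}.
#' @return character vector in \{"truncating", "non_truncating", "excluded"\}.
#' @export
classifyMutation <- function(classification, synonyms = NULL) {
    truncating <- c("nonsense_mutation", "nonsense",
                    "frame_shift_del", "frame_shift_ins",
                    "frameshift_deletion", "frameshift_insertion",
                    "splice_site", "splice_site_mutation")
    non_truncating <- c("missense_mutation", "missense",
                        "in_frame_del", "in_frame_ins",
                        "inframe_deletion", "inframe_insertion",
                        "nonstop_mutation", "nonstop")
    x <- tolower(trimws(as.character(classification)))
    out <- rep("excluded", length(x))
    out[x %in% truncating] <- "truncating"
    out[x %in% non_truncating] <- "non_truncating"
    if (!is.null(synonyms)) {
        hit <- x %in% names(synonyms)
        out[hit] <- unname(synonyms[x[hit]])
    }
    out
}

#' Weighted tumor mutational burden score
#'
#' TMB = (number of truncating mutations) x 2.0 + (number of non-truncating
#' mutations) x 1.0; excluded classes contribute 0. Reported as the raw
#' weighted count (no per-megabase normalization).
#'
#' @param mutations data.frame with columns \code{sample} and
#'   \code{variant_classification} (a MAF-like table).
#' @param sample sample identifier to score.
#' @param synonyms passed to \code{\link{classifyMutation}}.
#' @return numeric score.
#' @export
tmbScore <- function(mutations, sample, synonyms = NULL) {
    if (!sample %in% mutations$sample)
        stop("unknown sample: ", sample)
    cls <- classifyMutation(
        mutations$variant_classification[mutations$sample == sample],
        synonyms)
    2.0 * sum(cls == "truncating") + 1.0 * sum(cls == "non_truncating")
}

#' Median split of samples by an expression value
#'
#' Samples at or above the median are \code{"high"}, below it \code{"low"}
#' (median ties go high, deterministically). A constant vector is a
#' degenerate stratification and errors.
#'
#' @param values named numeric vector of per-sample values.
#' @return list(groups = named character vector sample -> "high"/"low",
#'   median, n_high, n_low).
#' @export
stratifyByExpression <- function(values) {
    if (length(values) < 2) stop("need >= 2 samples to stratify")
    if (max(values) == min(values))
        stop("constant expression vector: degenerate stratification")
    med <- stats::median(values)
    grp <- ifelse(values >= med, "high", "low")
    names(grp) <- names(values)
    list(groups = grp, median = med,
         n_high = sum(grp == "high"), n_low = sum(grp == "low"))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Right-continuous nonincreasing step function with S(0) = 1, dropping by
#' the product-limit factor (1 - d/n) at each event time. With no censoring
#' it reduces to one minus the empirical CDF of event times.
#'
#' @param survival_table data.frame(subject, group, time, event) with
#'   \code{time >= 0} and \code{event} in \{0, 1\}.
#' @param group group label to estimate within (NULL = all records).
#' @return object of class \code{"km_fit"}: list with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv} and \code{fun}, a
#'   right-continuous step function time -> survival probability.
#' @export
kmEstimate <- function(survival_table, group = NULL) {
    tab <- if (is.null(group)) survival_table
           else survival_table[survival_table$group == group, , drop = FALSE]
    if (!nrow(tab)) stop("group is empty: ", group)
    if (any(tab$time < 0)) stop("negative survival times")
    if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = tab)
    out <- list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                surv = fit$surv,
                fun = stats::stepfun(fit$time, c(1, fit$surv), right = FALSE))
    class(out) <- "km_fit"
    out
}

#' @export
print.km_fit <- function(x, ...) {
    cat("Kaplan-Meier fit:", length(x$time), "time point(s); S(max t) =",
        signif(utils::tail(x$surv, 1), 4), "\n")
    invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom, comparing two
#' groups of a survival table.
#'
#' @inheritParams kmEstimate
#' @param group_a,group_b group labels.
#' @return list(chisq, p).
#' @export
logrankTest <- function(survival_table, group_a, group_b) {
    tab <- survival_table[survival_table$group %in% c(group_a, group_b), ,
                          drop = FALSE]
    if (!sum(tab$group == group_a) || !sum(tab$group == group_b))
        stop("both groups must be nonempty")
    if (sum(tab$event) < 1) stop("log-rank requires at least one event")
    fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = tab)
    chisq <- as.numeric(fit$chisq)
    list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Threshold growth curves into survival records
#'
#' Converts longitudinal tumor volumes into time-to-endpoint records: the
#' event time is the first day the animal's volume exceeds
#' \code{endpoint_volume} (default 2000 mm^3); animals never reaching it are
#' censored at their last measurement.
#'
#' @param curves growth-curve data.frame (animal, arm, day, volume or
#'   a_mm/b_mm).
#' @param endpoint_volume endpoint threshold in mm^3.
#' @return data.frame(subject, group, time, event).
#' @export
survivalFromGrowth <- function(curves, endpoint_volume = 2000) {
    v <- curveVolumes(curves)
    rows <- lapply(split(v, v$animal), function(d) {
        d <- d[order(d$day), , drop = FALSE]
        hit <- which(d$volume > endpoint_volume)
        if (length(hit))
            data.frame(subject = d$animal[1], group = d$arm[1],
                       time = d$day[hit[1]], event = 1L)
        else
            data.frame(subject = d$animal[1], group = d$arm[1],
                       time = max(d$day), event = 0L)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}
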