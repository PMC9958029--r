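#' Stratify bulk samples at a percentile of a focal cluster's proportion
#'
#' The high group holds samples whose focal-cluster proportion lies strictly
#' above the percentile value (linear-interpolation / type-7 percentile;
#' boundary ties go to the low group). When the percentile value is zero the
#' stratification is skipped with a warning, since a "high" group defined
#' above zero abundance is not meaningful for an absent cluster.
#'
#' @param proportions a [estimate_proportions()] result or a samples x
#'   clusters matrix.
#' @param focal_cluster cluster (column) to stratify on.
#' @param survival data.frame of survival records (`sample_id`, `time`,
#'   `event`); every survival sample must have a proportion.
#' @param percentile percentile in (0, 100), default 70.
#' @return list of class `stratified_cohort`: `table` (sample_id,
#'   proportion, group, time, event), `cutoff`, `focal_cluster`,
#'   `percentile`, `skipped`.
#' @export
stratify <- function(proportions, focal_cluster, survival,
                     percentile = 70) {
  props <- if (inherits(proportions, "proportion_table"))
    proportions$proportions else as.matrix(proportions)
  if (!focal_cluster %in% colnames(props)) {
    stop("unknown focal cluster '", focal_cluster, "'", call. = FALSE)
  }
  missing <- setdiff(survival$sample_id, rownames(props))
  if (length(missing) > 0) {
    stop("no proportions for survival sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  p <- props[survival$sample_id, focal_cluster]
  cutoff <- quantile(p, percentile / 100, type = 7, names = FALSE)
  if (cutoff == 0) {
    warning("stratification skipped: the ", percentile,
            "th percentile of '", focal_cluster, "' is zero")
    return(structure(list(table = NULL, cutoff = 0,
                          focal_cluster = focal_cluster,
                          percentile = percentile, skipped = TRUE),
                     class = "stratified_cohort"))
  }
  group <- ifelse(p > cutoff, "high", "low")
  if (!any(group == "high")) {
    warning("high group is empty at the ", percentile, "th percentile")
  }
  tab <- data.frame(sample_id = survival$sample_id, proportion = p,
                    group = group, time = survival$time,
                    event = survival$event, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, cutoff = cutoff,
                 focal_cluster = focal_cluster, percentile = percentile,
                 skipped = FALSE),
            class = "stratified_cohort")
}

#' Log-rank survival comparison of a stratified cohort
#'
#' Standard 1-df log-rank test between the high and low groups (via
#' `survival::survdiff`), a hazard-ratio estimate from the
#' observed/expected ratios `(O_high/E_high)/(O_low/E_low)`, and the
#' Kaplan-Meier step curves per group. Follow-up can be truncated at a
#' horizon (times beyond it are censored there).
#'
#' @param cohort a [stratify()] result (not skipped), or a data.frame with
#'   `group`, `time`, `event`.
#' @param horizon optional follow-up truncation in the time unit of the
#'   records (e.g. 60 for 5 years of monthly follow-up); `NULL` for none.
#' @return list: `chi_sq`, `p`, `hr_estimate` (high vs low), `n`
#'   (per-group sizes), `km` (data.frame group, time, surv).
#' @export
logrank_survival <- function(cohort, horizon = NULL) {
  tab <- if (inherits(cohort, "stratified_cohort")) {
    if (isTRUE(cohort$skipped)) {
      stop("cohort stratification was skipped; nothing to test",
           call. = FALSE)
    }
    cohort$table
  } else {
    cohort
  }
  stopifnot(all(c("group", "time", "event") %in% names(tab)))
  if (!is.null(horizon)) {
    over <- tab$time > horizon
    tab$event[over] <- 0L
    tab$time[over] <- horizon
  }
  if (length(unique(tab$group)) < 2) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(tab$event) < 1) {
    stop("no events observed; log-rank test undefined", call. = FALSE)
  }
  tab$group <- factor(tab$group, levels = c("low", "high"))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = tab)
  chi_sq <- sd_fit$chisq
  p <- stats::pchisq(chi_sq, df = 1, lower.tail = FALSE)
  o <- sd_fit$obs
  e <- sd_fit$exp
  hr <- (o[2] / e[2]) / (o[1] / e[1])
  km_fit <- survival::survfit(survival::Surv(time, event) ~ group,
                              data = tab)
  strata <- rep(names(km_fit$strata), km_fit$strata)
  km <- data.frame(group = sub("^group=", "", strata),
                   time = km_fit$time, surv = km_fit$surv,
                   stringsAsFactors = FALSE)
  list(chi_sq = unname(chi_sq), p = unname(p), hr_estimate = unname(hr),
       n = table(tab$group), km = km)
}

#' Correlation between a cluster's proportion and a gene's bulk expression
#'
#' @param proportions a [estimate_proportions()] result or samples x
#'   clusters matrix.
#' @param bulk genes x samples bulk matrix.
#' @param cluster cluster name.
#' @param gene gene id.
#' @param min_samples minimum shared samples (default 10).
#' @return list with `r`, `p`, `n`, and `reason` (`NA` unless undefined).
#' @export
proportion_gene_correlation <- function(proportions, bulk, cluster, gene,
                                        min_samples = 10) {
  props <- if (inherits(proportions, "proportion_table"))
    proportions$proportions else as.matrix(proportions)
  samples <- intersect(rownames(props), colnames(bulk))
  if (length(samples) < min_samples) {
    stop("need >= ", min_samples, " samples; got ", length(samples),
         call. = FALSE)
  }
  x <- props[samples, cluster]
  y <- as.numeric(bulk[gene, samples])
  if (sd(y) == 0 || sd(x) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(samples),
                reason = "zero variance"))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(samples),
       reason = NA_character_)
}
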