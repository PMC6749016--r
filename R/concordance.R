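#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, from the beta
#' quantile form: the lower bound is `qbeta(alpha/2, x, n - x + 1)` (0 when
#' `x = 0`) and the upper bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when
#' `x = n`). At `x = 0` the upper bound reduces to the closed form
#' `1 - (alpha/2)^(1/n)`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `n > 0`.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' exact_binomial_ci(134, 181)  # approximately 0.670, 0.803
#' @export
exact_binomial_ci <- function(x, n, conf_level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    stop("exact binomial CI requires n > 0", call. = FALSE)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > n)
    stop("exact binomial CI requires 0 <= x <= n", call. = FALSE)
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - conf_level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Proportion with exact confidence interval
#'
#' @param x Numerator (successes).
#' @param n Denominator (trials).
#' @param conf_level Confidence level.
#' @param label Optional label carried in printing.
#' @return Object of class `"prop_ci"`: list with `point`, `ci_low`,
#'   `ci_high`, `conf_level`, `numerator`, `denominator`, `label`.
#' @export
prop_ci <- function(x, n, conf_level = 0.95, label = NULL) {
  ci <- exact_binomial_ci(x, n, conf_level)
  structure(list(point = x / n, ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), conf_level = conf_level,
                 numerator = x, denominator = n, label = label),
            class = "prop_ci")
}

#' @export
print.prop_ci <- function(x, digits = 1, ...) {
  cat(if (!is.null(x$label)) paste0(x$label, ": "),
      format_pct(x$point, digits), "% [",
      format_pct(x$ci_low, digits), "-", format_pct(x$ci_high, digits),
      "] (", x$numerator, "/", x$denominator, ", ",
      format(100 * x$conf_level), "% CI)\n", sep = "")
  invisible(x)
}

#' Round half away from zero
#'
#' Report tables round percentages half away from zero (so 74.5 prints as
#' 75), unlike base `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pct <- function(p, digits = 1) {
  format(round_half_up(100 * p, digits), nsmall = 0, trim = TRUE)
}

#' Cross-tabulate two platforms' calls
#'
#' Classifies each alteration event (sample x canonical key) in the shared
#' sample scope as detected by both platforms, by the reference only, or by
#' the test only. When a target panel (the set of assayable keys) is
#' supplied, double-negative (sample, key) pairs are counted as
#' `n_neither`, which defines the NPA denominator.
#'
#' @param test,reference `callset` objects.
#' @param sample_ids Character vector: the shared sample scope.
#' @param unit `"variant_event"` or `"fusion_event"`.
#' @param panel Optional character vector of assayable canonical keys
#'   (variant `"GENE:p.X"` ids or fusion `"P5:P3"` ids).
#' @param unordered_fusions Match fusions ignoring 5'/3' orientation
#'   (default `FALSE`: reverse-orientation calls do not match).
#' @return Object of class `"concordance_counts"`: `n_both`, `n_ref_only`,
#'   `n_test_only`, `n_neither` (`NA` without a panel), `unit`, `n_samples`,
#'   and an `events` data frame with one row per discordant or concordant
#'   positive event.
#' @export
cross_tabulate <- function(test, reference, sample_ids,
                           unit = c("variant_event", "fusion_event"),
                           panel = NULL, unordered_fusions = FALSE) {
  stopifnot(inherits(test, "callset"), inherits(reference, "callset"))
  unit <- match.arg(unit)
  sample_ids <- unique(as.character(sample_ids))
  if (length(sample_ids) == 0L)
    stop("empty sample scope", call. = FALSE)
  ev <- function(x) event_ids(x, unit, sample_ids, unordered_fusions)
  test_ev <- ev(test)
  ref_ev <- ev(reference)
  both <- intersect(test_ev, ref_ev)
  ref_only <- setdiff(ref_ev, test_ev)
  test_only <- setdiff(test_ev, ref_ev)
  n_neither <- NA_integer_
  if (!is.null(panel)) {
    panel <- unique(as.character(panel))
    if (unordered_fusions && unit == "fusion_event")
      panel <- vapply(strsplit(panel, ":", fixed = TRUE),
                      function(p) paste(sort(p), collapse = ":"), "")
    universe <- as.vector(outer(sample_ids, panel, paste, sep = "\r"))
    n_neither <- length(setdiff(universe, union(test_ev, ref_ev)))
  }
  events <- data.frame(
    event = c(both, ref_only, test_only),
    status = rep(c("both", "ref_only", "test_only"),
                 c(length(both), length(ref_only), length(test_only))),
    stringsAsFactors = FALSE)
  if (nrow(events)) {
    parts <- strsplit(events$event, "\r", fixed = TRUE)
    events$sample_id <- vapply(parts, `[`, "", 1)
    events$key <- vapply(parts, `[`, "", 2)
    events$event <- NULL
    events <- events[order(events$sample_id, events$key), c("sample_id",
                     "key", "status")]
    rownames(events) <- NULL
  } else {
    events <- data.frame(sample_id = character(), key = character(),
                         status = character(), stringsAsFactors = FALSE)
  }
  structure(list(n_both = length(both), n_ref_only = length(ref_only),
                 n_test_only = length(test_only), n_neither = n_neither,
                 unit = unit, n_samples = length(sample_ids),
                 events = events),
            class = "concordance_counts")
}

event_ids <- function(x, unit, sample_ids, unordered_fusions) {
  if (unit == "variant_event") {
    df <- x$variants[x$variants$sample_id %in% sample_ids, , drop = FALSE]
    keys <- df$key
  } else {
    df <- x$fusions[x$fusions$sample_id %in% sample_ids, , drop = FALSE]
    keys <- df$fusion_id
    if (unordered_fusions && nrow(df))
      keys <- vapply(strsplit(keys, ":", fixed = TRUE),
                     function(p) paste(sort(p), collapse = ":"), "")
  }
  unique(paste(df$sample_id, keys, sep = "\r"))
}

#' Manually specified concordance counts
#'
#' Constructs a `concordance_counts` object directly from tallies, e.g.
#' when reproducing a published cross-tabulation.
#'
#' @param n_both,n_ref_only,n_test_only,n_neither Non-negative counts
#'   (`n_neither` may be `NA` when no target panel defines negatives).
#' @param unit `"variant_event"` or `"fusion_event"`.
#' @param n_samples Optional number of samples in scope.
#' @export
concordance_counts <- function(n_both, n_ref_only, n_test_only,
                               n_neither = NA_integer_,
                               unit = c("variant_event", "fusion_event"),
                               n_samples = NA_integer_) {
  unit <- match.arg(unit)
  counts <- c(n_both, n_ref_only, n_test_only)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (!is.na(n_neither) && n_neither < 0)
    stop("n_neither must be non-negative", call. = FALSE)
  structure(list(n_both = as.integer(n_both),
                 n_ref_only = as.integer(n_ref_only),
                 n_test_only = as.integer(n_test_only),
                 n_neither = as.integer(n_neither), unit = unit,
                 n_samples = as.integer(n_samples), events = NULL),
            class = "concordance_counts")
}

#' @export
print.concordance_counts <- function(x, ...) {
  cat("Concordance (", x$unit, "): both=", x$n_both,
      ", reference-only=", x$n_ref_only, ", test-only=", x$n_test_only,
      if (!is.na(x$n_neither)) paste0(", neither=", x$n_neither),
      "\n", sep = "")
  invisible(x)
}

#' Positive percent agreement
#'
#' PPA is the share of reference-positive events also detected by the test
#' method: `n_both / (n_both + n_ref_only)`, with an exact binomial CI.
#'
#' @param counts A `concordance_counts`.
#' @param conf_level Confidence level.
#' @return A [prop_ci()].
#' @export
ppa <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "concordance_counts"))
  n <- counts$n_both + counts$n_ref_only
  if (n == 0)
    stop("PPA undefined: no reference-positive events", call. = FALSE)
  prop_ci(counts$n_both, n, conf_level, label = "PPA")
}

#' Confirmation rate
#'
#' The share of test-positive events corroborated by the reference method:
#' `n_both / (n_both + n_test_only)`. Equivalent to PPA with the platform
#' roles swapped.
#'
#' @inheritParams ppa
#' @return A [prop_ci()].
#' @export
confirmation <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "concordance_counts"))
  n <- counts$n_both + counts$n_test_only
  if (n == 0)
    stop("confirmation undefined: no test-positive events", call. = FALSE)
  prop_ci(counts$n_both, n, conf_level, label = "Confirmation")
}

#' Negative percent agreement
#'
#' NPA is the share of reference-negative (sample, panel-target) pairs
#' also negative in the test method: `n_neither / (n_neither +
#' n_test_only)`. Defined only when the cross-tabulation was given a
#' target panel, which fixes the negative denominator.
#'
#' @inheritParams ppa
#' @return A [prop_ci()].
#' @export
npa <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "concordance_counts"))
  if (is.na(counts$n_neither))
    stop("NPA requires a target panel: cross-tabulate with 'panel=' so ",
         "that double negatives are defined", call. = FALSE)
  n <- counts$n_neither + counts$n_test_only
  if (n == 0)
    stop("NPA undefined: no reference-negative pairs", call. = FALSE)
  prop_ci(counts$n_neither, n, conf_level, label = "NPA")
}

#' Adjudicate discordant events with a third method
#'
#' Each event called by exactly one of the two compared platforms is looked
#' up in an arbiter call set (typically qPCR). If the arbiter detects the
#' event, the platform that called it was correct; if the arbiter assayed
#' the sample but not the event, the platform that did not call it was
#' correct; events the arbiter never assayed are `unresolved`.
#'
#' @param counts A `concordance_counts` from [cross_tabulate()] (must carry
#'   its `events` table).
#' @param truth A `callset` from the arbiter platform.
#' @param truth_samples Optional character vector of samples the arbiter
#'   assayed; defaults to the samples present in `truth`. A discordant
#'   event in a sample outside this set is `unresolved`.
#' @return Data frame with one row per discordant event: `sample_id`,
#'   `key`, `status` (`ref_only`/`test_only`), `verdict`
#'   (`test_correct`/`reference_correct`/`unresolved`).
#' @export
adjudicate_discordants <- function(counts, truth, truth_samples = NULL) {
  stopifnot(inherits(counts, "concordance_counts"),
            inherits(truth, "callset"))
  if (is.null(counts$events))
    stop("adjudication needs per-event records; use cross_tabulate()",
         call. = FALSE)
  disc <- counts$events[counts$events$status != "both", , drop = FALSE]
  if (nrow(disc) == 0L)
    return(data.frame(sample_id = character(), key = character(),
                      status = character(), verdict = character(),
                      stringsAsFactors = FALSE))
  truth_ev <- unique(c(
    paste(truth$variants$sample_id, truth$variants$key, sep = "\r"),
    paste(truth$fusions$sample_id, truth$fusions$fusion_id, sep = "\r")))
  if (is.null(truth_samples))
    truth_samples <- unique(c(truth$variants$sample_id,
                              truth$fusions$sample_id))
  ev <- paste(disc$sample_id, disc$key, sep = "\r")
  in_truth <- ev %in% truth_ev
  assayed <- disc$sample_id %in% truth_samples
  disc$verdict <- ifelse(!assayed, "unresolved",
    ifelse(disc$status == "test_only",
           ifelse(in_truth, "test_correct", "reference_correct"),
           ifelse(in_truth, "reference_correct", "test_correct")))
  if (any(!assayed))
    warning(sum(!assayed), " discordant event(s) not covered by the ",
            "arbiter; labeled unresolved", call. = FALSE)
  rownames(disc) <- NULL
  disc
}

#' Agreement summary for one platform comparison
#'
#' Convenience wrapper bundling PPA, confirmation and (when a panel was
#' supplied) NPA for one cross-tabulation, in report shape.
#'
#' @param counts A `concordance_counts`.
#' @param conf_level Confidence level.
#' @param method Label for the comparison (e.g. `"DNA variants"`).
#' @return Object of class `"agreement_summary"`; a list with the
#'   `prop_ci` components and a one-row `table` data frame formatted the
#'   way validation reports print it (agreement to whole percent,
#'   confirmation to one decimal).
#' @export
agreement_summary <- function(counts, conf_level = 0.95, method = "") {
  stopifnot(inherits(counts, "concordance_counts"))
  p <- ppa(counts, conf_level)
  cf <- confirmation(counts, conf_level)
  np <- if (!is.na(counts$n_neither)) npa(counts, conf_level) else NULL
  # one decimal, trailing ".0" dropped (so 74.0 prints "74", 88.9 "88.9");
  # CI bounds to whole percent
  fmt <- function(pc) sprintf(
    "%s%%[%s-%s]",
    sub("\\.0$", "", sprintf("%.1f", round_half_up(100 * pc$point, 1))),
    format_pct(pc$ci_low, 0), format_pct(pc$ci_high, 0))
  table <- data.frame(
    method = method,
    n_samples = counts$n_samples,
    ppa = fmt(p),
    npa = if (is.null(np)) NA_character_ else fmt(np),
    confirmation = fmt(cf),
    test_only = counts$n_test_only,
    ref_only = counts$n_ref_only,
    both = counts$n_both,
    stringsAsFactors = FALSE)
  structure(list(ppa = p, npa = np, confirmation = cf, counts = counts,
                 table = table),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
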