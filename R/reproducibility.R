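#' Replicate plating design
#'
#' Describes which samples were plated where: one row per physical
#' replicate, plus the set of expected positive calls that each replicate
#' should reproduce.
#'
#' @param layout Data frame with columns `sample_id`, `replicate_index`,
#'   `plate_id` and optionally `reagent_lot`, `lab_id`, `operator_id`.
#'   `(sample_id, replicate_index, plate_id)` must be unique.
#' @param expected_positive Data frame with columns `sample_id`, `key`
#'   (canonical variant or fusion id): the calls every replicate of that
#'   sample is expected to make. Every row must reference a designed
#'   sample.
#' @return Object of class `"replicate_design"`.
#' @export
replicate_design <- function(layout, expected_positive) {
  req <- c("sample_id", "replicate_index", "plate_id")
  if (!all(req %in% names(layout)))
    stop("layout needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  for (col in c("reagent_lot", "lab_id", "operator_id"))
    if (!col %in% names(layout)) layout[[col]] <- NA_character_
  id <- paste(layout$sample_id, layout$replicate_index, layout$plate_id)
  if (anyDuplicated(id))
    stop("(sample_id, replicate_index, plate_id) must be unique",
         call. = FALSE)
  if (!all(c("sample_id", "key") %in% names(expected_positive)))
    stop("expected_positive needs columns sample_id, key", call. = FALSE)
  orphan <- setdiff(expected_positive$sample_id, layout$sample_id)
  if (length(orphan))
    stop("expected positives reference undesigned sample(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  structure(list(layout = layout, expected_positive = expected_positive),
            class = "replicate_design")
}

#' @export
print.replicate_design <- function(x, ...) {
  cat("Replicate design: ", length(unique(x$layout$sample_id)),
      " sample(s) x ", length(unique(x$layout$plate_id)), " plate(s), ",
      nrow(x$layout), " replicate wells; ", nrow(x$expected_positive),
      " expected positive call(s)\n", sep = "")
  invisible(x)
}

#' Between-laboratory accuracy of positive calls
#'
#' Fraction of expected positive events detected identically (i.e. by
#' both) in two laboratories' runs of the same samples. Under independent
#' per-call miss probability m in each lab, the expectation is (1 - m)^2.
#'
#' @param calls_lab1,calls_lab2 `callset` objects, one per lab.
#' @param expected Data frame with columns `sample_id`, `key` listing the
#'   expected positive events.
#' @param conf_level Confidence level for the exact binomial CI.
#' @return A [prop_ci()]; also carries `per_sample`, the sample-level
#'   tally (a sample agrees when all its expected events do), as an
#'   attribute `"per_sample"`.
#' @export
between_lab_accuracy <- function(calls_lab1, calls_lab2, expected,
                                 conf_level = 0.95) {
  stopifnot(inherits(calls_lab1, "callset"), inherits(calls_lab2, "callset"))
  if (is.null(expected) || nrow(expected) == 0L)
    stop("empty expected-positive set", call. = FALSE)
  ev <- paste(expected$sample_id, expected$key, sep = "\r")
  hit1 <- ev %in% all_event_ids(calls_lab1)
  hit2 <- ev %in% all_event_ids(calls_lab2)
  both <- hit1 & hit2
  out <- prop_ci(sum(both), length(ev), conf_level,
                 label = "Between-lab accuracy")
  per_sample <- tapply(both, expected$sample_id, all)
  attr(out, "per_sample") <- prop_ci(sum(per_sample), length(per_sample),
                                     conf_level,
                                     label = "Between-lab accuracy (samples)")
  out
}

all_event_ids <- function(x) {
  unique(c(paste(x$variants$sample_id, x$variants$key, sep = "\r"),
           paste(x$fusions$sample_id, x$fusions$fusion_id, sep = "\r")))
}

#' Replicate pair-agreement concordance
#'
#' Qualitative reproducibility of positive calls over a replicate design.
#' For every expected positive event and every eligible replicate pair
#' (within one plate for `intra_plate`, across two plates for
#' `inter_plate`), the pair agrees when both replicates detect the event or
#' both miss it. The statistic pools agreement over all such pairs; under
#' independent per-replicate miss probability m its expectation is
#' m^2 + (1 - m)^2.
#'
#' @param calls Data frame of per-replicate positive calls with columns
#'   `sample_id`, `replicate_index`, `plate_id`, `key` (one row per
#'   detected expected-positive event per replicate), e.g. from
#'   [simulate_replicates()].
#' @param design A [replicate_design()].
#' @param mode `"intra_plate"` or `"inter_plate"`.
#' @param conf_level Confidence level.
#' @return A [prop_ci()] over replicate pairs.
#' @export
replicate_concordance <- function(calls, design,
                                  mode = c("intra_plate", "inter_plate"),
                                  conf_level = 0.95) {
  stopifnot(inherits(design, "replicate_design"))
  mode <- match.arg(mode)
  lay <- design$layout
  called <- paste(calls$sample_id, calls$replicate_index, calls$plate_id,
                  calls$key, sep = "\r")
  agree <- 0L
  total <- 0L
  for (i in seq_len(nrow(design$expected_positive))) {
    s <- design$expected_positive$sample_id[i]
    k <- design$expected_positive$key[i]
    wells <- lay[lay$sample_id == s, , drop = FALSE]
    if (nrow(wells) < 2L) next
    det <- paste(wells$sample_id, wells$replicate_index, wells$plate_id,
                 k, sep = "\r") %in% called
    pairs <- utils::combn(nrow(wells), 2L)
    same_plate <- wells$plate_id[pairs[1, ]] == wells$plate_id[pairs[2, ]]
    use <- if (mode == "intra_plate") same_plate else !same_plate
    if (!any(use)) next
    agree <- agree + sum(det[pairs[1, use]] == det[pairs[2, use]])
    total <- total + sum(use)
  }
  if (total == 0L)
    stop("no eligible replicate pairs for mode '", mode, "'",
         call. = FALSE)
  prop_ci(agree, total, conf_level,
          label = paste0(sub("_", "-", mode), " reproducibility"))
}
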