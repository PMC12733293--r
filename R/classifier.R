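# The betweenness-sum cut-off classifier and descriptor-separability
# analytics over hapten record tables.

.cr_levels <- c("cross_reactive", "non_cross_reactive")

#' Classify a hapten by its ring betweenness sum
#'
#' A hapten is called cross-reactive when its quinolone-ring betweenness sum
#' reaches the threshold (inclusive `>=`; default cut-off 4000).
#'
#' @param ring_sum Non-negative betweenness sum(s); vectorized.
#' @param threshold Decision threshold (default 4000).
#' @return Character vector, `"cross_reactive"` or `"non_cross_reactive"`.
#' @export
classify_score <- function(ring_sum, threshold = 4000) {
  fq_assert(is.numeric(ring_sum) && !anyNA(ring_sum),
            "ring_sum must be numeric and non-missing", "domain")
  if (any(ring_sum < 0)) {
    fq_abort("ring_sum must be non-negative", "domain")
  }
  fq_assert(is_scalar_number(threshold), "threshold must be a number", "config")
  ifelse(ring_sum >= threshold, .cr_levels[1], .cr_levels[2])
}

#' Classify a table of haptens and score against experimental labels
#'
#' @param data Data frame with columns `name`, `ring_sum` and `label`
#'   (experimental class, `"cross_reactive"`/`"non_cross_reactive"`).
#' @param threshold Decision threshold (default 4000).
#' @return An `fq_classification`: list with `predictions` (tibble `name`,
#'   `ring_sum`, `label`, `predicted`), confusion counts `tp`/`tn`/`fp`/`fn`,
#'   `false_positive_names`, `false_negative_names` and `threshold`.
#'   `tidy()` returns the per-hapten predictions, `glance()` the counts.
#' @export
classify_haptens <- function(data, threshold = 4000) {
  need <- c("name", "ring_sum", "label")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    fq_abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "input")
  }
  fq_assert(nrow(data) >= 1L, "need at least one record", "input")
  if (anyDuplicated(data$name)) {
    fq_abort(paste0("duplicate hapten name: ",
                    data$name[duplicated(data$name)][1]), "input")
  }
  fq_assert(all(data$label %in% .cr_levels),
            "label must be cross_reactive or non_cross_reactive", "input")
  pred <- as_tibble(data[, need])
  pred$predicted <- classify_score(pred$ring_sum, threshold)
  pos <- pred$label == .cr_levels[1]
  hat <- pred$predicted == .cr_levels[1]
  structure(list(
    predictions = pred,
    threshold = threshold,
    tp = sum(pos & hat), tn = sum(!pos & !hat),
    fp = sum(!pos & hat), fn = sum(pos & !hat),
    false_positive_names = pred$name[!pos & hat],
    false_negative_names = pred$name[pos & !hat]
  ), class = "fq_classification")
}

#' @export
print.fq_classification <- function(x, ...) {
  cat("<fq_classification> threshold ", x$threshold, ": TP ", x$tp, ", TN ",
      x$tn, ", FP ", x$fp, ", FN ", x$fn, "\n", sep = "")
  if (length(x$false_positive_names)) {
    cat("  false positives: ", paste(x$false_positive_names, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.fq_classification <- function(x, ...) x$predictions

#' @export
glance.fq_classification <- function(x, ...) {
  tibble(threshold = x$threshold, tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         accuracy = (x$tp + x$tn) / nrow(x$predictions))
}

#' Histogram of betweenness scores per experimental class
#'
#' Left-closed bins `[k * bin_width, (k + 1) * bin_width)`.
#'
#' @param data Data frame with `ring_sum` and `label` columns.
#' @param bin_width Bin width (default 1000).
#' @return Tibble with `bin_lower`, `bin_upper`, `label`, `n`.
#' @export
score_histogram <- function(data, bin_width = 1000) {
  fq_assert(is_scalar_number(bin_width) && bin_width > 0,
            "bin_width must be positive", "config")
  fq_assert(all(data$ring_sum >= 0), "ring_sum must be non-negative", "domain")
  out <- tibble(bin = floor(data$ring_sum / bin_width), label = data$label)
  out <- count(out, .data$bin, .data$label, name = "n")
  tibble(bin_lower = out$bin * bin_width,
         bin_upper = (out$bin + 1) * bin_width,
         label = out$label, n = out$n)
}

#' Per-class descriptor ranges and their overlap
#'
#' Reports `[min, max]` of a descriptor for each experimental class and
#' whether the two class ranges overlap. An overlapping range means the
#' descriptor cannot separate the classes by any single threshold (the
#' situation observed for docking binding energies).
#'
#' @param data Data frame with a `label` column and the descriptor column.
#' @param descriptor Name of the descriptor column (string), e.g. `"ring_sum"`
#'   or `"docking_energy_low"`.
#' @return A list with `ranges` (tibble `label`, `min`, `max`, `n`) and
#'   `overlap` (logical).
#' @export
descriptor_overlap <- function(data, descriptor) {
  fq_assert(descriptor %in% names(data),
            paste0("descriptor column '", descriptor, "' not found"), "input")
  v <- data[[descriptor]]
  fq_assert(is.numeric(v) && !anyNA(v),
            paste0("descriptor '", descriptor, "' must be numeric and ",
                   "present on all records"), "input")
  fq_assert(all(data$label %in% .cr_levels),
            "label must be cross_reactive or non_cross_reactive", "input")
  ranges <- summarise(group_by(tibble(label = data$label, value = v),
                               .data$label),
                      min = min(.data$value), max = max(.data$value),
                      n = dplyr::n(), .groups = "drop")
  overlap <- if (nrow(ranges) == 2L) {
    ranges$min[1] <= ranges$max[2] && ranges$min[2] <= ranges$max[1]
  } else {
    FALSE
  }
  list(ranges = ranges, overlap = overlap)
}
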