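## CIAF classification: z-scores -> failure flags -> groups A-H -> binary
## outcome, plus prevalence estimation.

# Group lookup indexed by stunted*4 + wasted*2 + underweight + 1.
# (TRUE,TRUE,FALSE) has no slot in the standard seven-group table; it is
# labelled "H" and still counts as failure (CIAF is *any* failure).
.ciaf_groups <- c("A", "G", "F", "E", "B", "C", "H", "D")

#' Validate anthropometric z-scores against plausibility windows
#'
#' Flags biologically implausible z-score triplets using the WHO flag
#' ranges routinely applied to DHS anthropometry: HAZ in \[-6, 6\],
#' WHZ in \[-5, 5\], WAZ in \[-6, 5\].  Records outside any window should
#' be excluded before CIAF classification.
#'
#' @param haz,whz,waz Numeric vectors of height-for-age, weight-for-height
#'   and weight-for-age z-scores (SD units).  Recycled to common length.
#' @return Logical vector: `TRUE` where all three z-scores are plausible.
#' @examples
#' validate_zscores(haz = c(0, 7), whz = c(0, 0), waz = c(0, 0))
#' @export
validate_zscores <- function(haz, whz, waz) {
  n <- max(length(haz), length(whz), length(waz))
  haz <- rep_len(as.numeric(haz), n)
  whz <- rep_len(as.numeric(whz), n)
  waz <- rep_len(as.numeric(waz), n)
  if (any(!is.finite(haz)) || any(!is.finite(whz)) || any(!is.finite(waz)))
    stop("non-finite z-score: malformed record", call. = FALSE)
  haz >= -6 & haz <= 6 & whz >= -5 & whz <= 5 & waz >= -6 & waz <= 5
}

#' Flag stunting, wasting and underweight from z-scores
#'
#' A child is stunted / wasted / underweight when the corresponding
#' z-score falls strictly below the cut-off (default -2 SD); a z-score
#' exactly at the cut-off is not a failure.
#'
#' @inheritParams validate_zscores
#' @param cutoff Failure cut-off in SD units (default `-2`).
#' @return A data frame with logical columns `stunted`, `wasted`,
#'   `underweight`.
#' @examples
#' flag_failures(haz = -2.5, whz = -0.4, waz = -1.0)
#' @export
flag_failures <- function(haz, whz, waz, cutoff = -2) {
  n <- max(length(haz), length(whz), length(waz))
  data.frame(
    stunted     = rep_len(as.numeric(haz), n) < cutoff,
    wasted      = rep_len(as.numeric(whz), n) < cutoff,
    underweight = rep_len(as.numeric(waz), n) < cutoff
  )
}

#' Classify failure flags into CIAF groups A-H
#'
#' Maps each (stunted, wasted, underweight) combination to its CIAF group:
#' A no failure; B stunting only; C stunting + underweight; D wasting +
#' underweight + stunting; E wasting + underweight; F wasting only;
#' G underweight only.  The combination stunted + wasted without
#' underweight is absent from the standard table; it is assigned the extra
#' label H (with a warning) and is treated as failure.
#'
#' @param stunted,wasted,underweight Logical vectors (recycled).
#' @return Factor with levels `A`-`H`.
#' @examples
#' classify_group(stunted = TRUE, wasted = FALSE, underweight = TRUE)  # "C"
#' @export
classify_group <- function(stunted, wasted, underweight) {
  n <- max(length(stunted), length(wasted), length(underweight))
  s <- rep_len(as.logical(stunted), n)
  w <- rep_len(as.logical(wasted), n)
  u <- rep_len(as.logical(underweight), n)
  if (any(is.na(s) | is.na(w) | is.na(u)))
    stop("missing failure flag", call. = FALSE)
  g <- .ciaf_groups[s * 4L + w * 2L + u + 1L]
  if (any(g == "H"))
    warning(sum(g == "H"), " record(s) stunted + wasted without underweight: ",
            "assigned extra group 'H' (counted as failure)", call. = FALSE)
  factor(g, levels = LETTERS[1:8])
}

#' Binary CIAF indicator from the group label
#'
#' @param group Factor or character vector of group labels `A`-`H`.
#' @return Integer vector: 0 for group A (no failure), 1 otherwise.
#' @examples
#' ciaf_indicator(c("A", "D"))
#' @export
ciaf_indicator <- function(group) {
  group <- as.character(group)
  bad <- !group %in% LETTERS[1:8]
  if (any(bad))
    stop("unknown CIAF group label: ", paste(unique(group[bad]), collapse = ", "),
         call. = FALSE)
  as.integer(group != "A")
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' \[0, 1\].  This is the unweighted interval used for the prevalence
#' tables.
#'
#' @param p Estimated proportion.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' wald_ci(0.413, 10962)
#' @export
wald_ci <- function(p, n, level = 0.95) {
  stopifnot(n >= 1, p >= 0, p <= 1, level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

#' Prevalence of a binary indicator with a Wald interval
#'
#' @param indicator Binary (0/1 or logical) vector.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame: `proportion`, `ci_low`, `ci_high`, `n`.
#' @examples
#' prevalence_ci(rbinom(200, 1, 0.4))
#' @export
prevalence_ci <- function(indicator, level = 0.95) {
  indicator <- as.integer(indicator)
  if (length(indicator) == 0) stop("no data: empty indicator", call. = FALSE)
  if (any(is.na(indicator)) || any(!indicator %in% 0:1))
    stop("indicator must be binary", call. = FALSE)
  n <- length(indicator)
  p <- mean(indicator)
  ci <- wald_ci(p, n, level)
  data.frame(proportion = p, ci_low = ci[["low"]], ci_high = ci[["high"]], n = n)
}

#' Classify a child table into CIAF columns
#'
#' Convenience wrapper running validation, failure flagging, group
#' classification and the binary indicator over a data frame holding
#' `haz`, `whz`, `waz` columns.  Implausible records (outside the WHO flag
#' windows) are dropped with a message, mirroring the usual exclusion of
#' invalid anthropometric measurements from analytic samples.
#'
#' @param data Data frame with numeric columns `haz`, `whz`, `waz`.
#' @param cutoff Failure cut-off in SD units (default -2).
#' @param drop_invalid Drop implausible rows (default `TRUE`); if `FALSE`
#'   an error is raised when implausible rows are present.
#' @return `data` (valid rows) with added columns `stunted`, `wasted`,
#'   `underweight`, `group`, `ciaf`.
#' @export
ciaf_classify <- function(data, cutoff = -2, drop_invalid = TRUE) {
  stopifnot(all(c("haz", "whz", "waz") %in% names(data)))
  ok <- validate_zscores(data$haz, data$whz, data$waz)
  if (any(!ok)) {
    if (!drop_invalid)
      stop(sum(!ok), " implausible z-score record(s)", call. = FALSE)
    message("dropped ", sum(!ok), " record(s) with implausible z-scores")
    data <- data[ok, , drop = FALSE]
  }
  fl <- flag_failures(data$haz, data$whz, data$waz, cutoff = cutoff)
  data$stunted <- fl$stunted
  data$wasted <- fl$wasted
  data$underweight <- fl$underweight
  data$group <- classify_group(fl$stunted, fl$wasted, fl$underweight)
  data$ciaf <- ciaf_indicator(data$group)
  data
}

# Display labels for the exclusive CIAF groups, in customary table order.
.group_labels <- c(
  CIAF = NA, "No failure" = "A", "Wasting Only" = "F", "Stunting Only" = "B",
  "Underweight only" = "G", "Wasting + Underweight" = "E",
  "Stunting + Underweight" = "C", "Wasting + Stunting + Underweight" = "D",
  "Wasting + Stunting (no underweight)" = "H"
)

#' Prevalence table of anthropometric failure forms
#'
#' Tabulates the overall CIAF prevalence and the prevalence of each
#' exclusive failure group (Table-1 groups A-G, plus H when present), each
#' with an unweighted Wald confidence interval.  Group proportions are
#' exclusive and sum to 1 across `No failure` and the failure groups.
#'
#' @param data Data frame already carrying `group` and `ciaf` columns
#'   (e.g. output of [ciaf_classify()]), or raw z-score columns, in which
#'   case [ciaf_classify()] is applied first.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `status`, `prevalence`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
ciaf_prevalence_table <- function(data, level = 0.95) {
  if (!all(c("group", "ciaf") %in% names(data)))
    data <- ciaf_classify(data)
  n <- nrow(data)
  if (n == 0) stop("no data", call. = FALSE)
  rows <- lapply(names(.group_labels), function(lab) {
    g <- .group_labels[[lab]]
    ind <- if (lab == "CIAF") data$ciaf else as.integer(data$group == g)
    if (!is.na(g) && g == "H" && sum(ind) == 0) return(NULL)
    est <- prevalence_ci(ind, level)
    data.frame(status = lab, prevalence = est$proportion,
               ci_low = est$ci_low, ci_high = est$ci_high, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
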