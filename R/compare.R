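#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test with the conventional zero-difference
#' handling: pairs with zero difference are dropped. The exact null
#' distribution is used for n <= 25 remaining pairs without ties in the
#' absolute differences; otherwise the normal approximation with tie and
#' continuity correction. When every difference is zero the test is
#' degenerate and p = 1 is returned with a warning.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list(statistic = V, p = two-sided p, n = pairs used,
#'   exact = logical).
#' @export
pairedSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE))
  }
  use_exact <- n <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p = min(1, unname(ht$p.value)),
       n = n, exact = use_exact)
}

#' Build a cohort metric table
#'
#' Long-format table of evaluation metrics across phantoms and plan
#' variants, the input of [summarizeCohort()].
#'
#' @param evaluations named list (variant -> list over phantoms of
#'   [PlanEvaluation-class]); each inner list is named by phantom id.
#' @return data.frame(phantom_id, variant, structure, metric, basis,
#'   value) including NTCP rows (structure "ntcp").
#' @export
cohortMetricTable <- function(evaluations) {
  rows <- list()
  for (variant in names(evaluations)) {
    evs <- evaluations[[variant]]
    for (pid in names(evs)) {
      ev <- evs[[pid]]
      m <- metricTable(ev)
      m$phantom_id <- pid; m$variant <- variant
      rows[[length(rows) + 1L]] <-
        m[, c("phantom_id", "variant", "structure", "metric", "basis", "value")]
      nt <- ntcpTable(ev)
      if (nrow(nt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          phantom_id = pid, variant = variant, structure = "ntcp",
          metric = paste0(nt$endpoint, nt$grade), basis = "nominal",
          value = nt$value_pct, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a cohort metric table
#'
#' Per metric and plan variant: median and (min-max) across phantoms, plus
#' two-sided paired signed-rank p-values for every variant pair. With a
#' single phantom the median equals the value, the range is degenerate and
#' p-values are NA (flagged in the `note` column).
#'
#' @param cohort data.frame from [cohortMetricTable()].
#' @return data.frame with one row per (structure, metric, basis):
#'   median/min/max per variant and p_<a>_vs_<b> columns.
#' @export
summarizeCohort <- function(cohort) {
  need <- c("phantom_id", "variant", "structure", "metric", "basis", "value")
  if (!all(need %in% names(cohort))) .stopf("cohort table lacks required columns")
  variants <- sort(unique(cohort$variant))
  phantoms <- sort(unique(cohort$phantom_id))
  key <- unique(cohort[, c("structure", "metric", "basis")])
  rownames(key) <- NULL
  # complete-crossing check
  cnt <- table(cohort$variant, cohort$phantom_id)
  if (any(cnt == 0)) .stopf("incomplete phantom x variant crossing")
  out <- key
  for (v in variants) {
    med <- mn <- mx <- numeric(nrow(key))
    for (i in seq_len(nrow(key))) {
      sel <- cohort$variant == v & cohort$structure == key$structure[i] &
        cohort$metric == key$metric[i] & cohort$basis == key$basis[i]
      vals <- cohort$value[sel]
      if (length(vals) != length(phantoms)) .stopf("incomplete crossing for %s %s",
                                                   key$structure[i], key$metric[i])
      med[i] <- stats::median(vals); mn[i] <- min(vals); mx[i] <- max(vals)
    }
    out[[paste0("median_", v)]] <- med
    out[[paste0("min_", v)]] <- mn
    out[[paste0("max_", v)]] <- mx
  }
  if (length(phantoms) >= 2) {
    for (ab in utils::combn(variants, 2, simplify = FALSE)) {
      p <- numeric(nrow(key))
      for (i in seq_len(nrow(key))) {
        get_vals <- function(v) {
          sel <- cohort$variant == v & cohort$structure == key$structure[i] &
            cohort$metric == key$metric[i] & cohort$basis == key$basis[i]
          x <- cohort[sel, c("phantom_id", "value")]
          x$value[order(x$phantom_id)]
        }
        p[i] <- suppressWarnings(pairedSignedRank(get_vals(ab[1]), get_vals(ab[2]))$p)
      }
      out[[paste0("p_", ab[1], "_vs_", ab[2])]] <- p
    }
    out$note <- ""
  } else {
    out$note <- "single phantom: range degenerate, p undefined"
  }
  out
}
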