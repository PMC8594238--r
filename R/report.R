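#' Group-comparison report table
#'
#' Builds a clinical-style comparison table: per metric, the group means
#' +/- SD, the omnibus one-way ANOVA F and P across all groups, and
#' named pairwise P columns (uncorrected two-sided pooled t contrasts by
#' default).  Displayed p-values use 3-decimal formatting, so values
#' below 0.0005 print as `"0.000"`; full-precision values are kept in
#' the `raw` attribute and in the returned `details`.
#'
#' @param cohort data.frame with a `group` column and metric columns
#'   (see [generate_cohort()]); groups are compared in their order of
#'   first appearance unless `group` is a factor
#' @param metrics character vector of metric column names; default: all
#'   of [metric_columns()] present in `cohort`
#' @param correction pairwise p adjustment, see [one_way_anova()]
#' @return A list of class `group_comparison_report`:
#'   \describe{
#'     \item{table}{formatted data.frame (one row per metric)}
#'     \item{raw}{same shape with numeric full-precision F and p}
#'     \item{details}{named list of [stat_result()] per metric}
#'   }
#' @export
group_comparison_report <- function(cohort, metrics = NULL,
                                    correction = c("none", "bonferroni",
                                                   "holm")) {
  correction <- match.arg(correction)
  if (!is.data.frame(cohort) || !"group" %in% names(cohort))
    stop("`cohort` must be a data.frame with a `group` column",
         call. = FALSE)
  groups <- if (is.factor(cohort$group)) levels(cohort$group)
            else unique(cohort$group)
  groups <- groups[groups %in% cohort$group]
  if (length(groups) < 2L)
    stop("need at least 2 groups to compare", call. = FALSE)
  if (is.null(metrics))
    metrics <- intersect(metric_columns(), names(cohort))
  if (length(metrics) == 0L)
    stop("no metric columns found in `cohort`", call. = FALSE)
  missing_any <- unlist(lapply(metrics, function(m) {
    if (!m %in% names(cohort)) return(sprintf("%s (absent)", m))
    bad <- vapply(groups, function(g)
      all(!is.finite(cohort[[m]][cohort$group == g])), logical(1))
    if (any(bad))
      sprintf("%s (no data for: %s)", m,
              paste(groups[bad], collapse = ", "))
    else character(0)
  }))
  if (length(missing_any))
    stop("metrics missing for some groups: ",
         paste(missing_any, collapse = "; "), call. = FALSE)

  details <- list()
  fmt_rows <- list(); raw_rows <- list()
  for (m in metrics) {
    gs <- lapply(groups, function(g)
      cohort[[m]][cohort$group == g & is.finite(cohort[[m]])])
    names(gs) <- groups
    res <- one_way_anova(gs, pairwise = TRUE, correction = correction)
    details[[m]] <- res
    msd <- vapply(gs, function(v)
      sprintf("%.2f ± %.2f", mean(v), sd(v)), "")
    pw <- setNames(res$pairwise$p_value, res$pairwise$contrast)
    fmt <- c(list(metric = m), as.list(msd),
             list(F = sprintf("%.3f", res$statistic),
                  P = format_p3(res$p_value)),
             as.list(setNames(format_p3(pw),
                              paste0("P_", gsub(" vs ", "_", names(pw))))))
    raw <- c(list(metric = m),
             as.list(setNames(vapply(gs, mean, 0), paste0("mean_", groups))),
             as.list(setNames(vapply(gs, sd, 0), paste0("sd_", groups))),
             list(F = res$statistic, P = res$p_value),
             as.list(setNames(pw, paste0("P_", gsub(" vs ", "_",
                                                    names(pw))))))
    fmt_rows[[m]] <- as.data.frame(fmt, check.names = FALSE,
                                   stringsAsFactors = FALSE)
    raw_rows[[m]] <- as.data.frame(raw, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  }
  out <- list(table = do.call(rbind, fmt_rows),
              raw = do.call(rbind, raw_rows),
              details = details, groups = groups)
  rownames(out$table) <- rownames(out$raw) <- NULL
  class(out) <- "group_comparison_report"
  out
}

#' @export
print.group_comparison_report <- function(x, ...) {
  cat(sprintf("<group_comparison_report> groups: %s\n",
              paste(x$groups, collapse = ", ")))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Render a group-comparison report as a markdown table
#'
#' @param report a [group_comparison_report()]
#' @return character vector of markdown lines
#' @export
report_markdown <- function(report) {
  tb <- report$table
  header <- paste0("| ", paste(names(tb), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|")
  rows <- apply(tb, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, unname(rows))
}

#' Per-segment mean and deviation summary
#'
#' Means and SDs of iris VAD and VSD per segment across all eyes of a
#' cohort, the summary behind segment-trend figures: the innermost (1/3)
#' segment shows the highest average density and the largest deviation.
#'
#' @param cohort data.frame with the six iris metric columns
#' @return data.frame with columns `metric` (`vad`/`vsd`), `segment`,
#'   `mean`, `sd`.
#' @export
segment_deviation_summary <- function(cohort) {
  segs <- c("one_third", "two_thirds", "full")
  need <- c(paste0("iris_vad_", segs), paste0("iris_vsd_", segs))
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stop("missing iris segment metrics: ",
         paste(absent, collapse = ", "), call. = FALSE)
  rows <- list()
  for (metric in c("vad", "vsd")) for (s in segs) {
    v <- cohort[[paste0("iris_", metric, "_", s)]]
    v <- v[is.finite(v)]
    rows[[paste(metric, s)]] <- data.frame(
      metric = metric, segment = s, mean = mean(v), sd = sd(v),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot per-segment density trends
#'
#' Base-graphics rendering of a [segment_deviation_summary()]: mean
#' +/- SD per segment for VAD and VSD.
#'
#' @param summary data.frame from [segment_deviation_summary()]
#' @param ... passed to [graphics::plot()]
#' @return The summary, invisibly.
#' @export
plot_segment_trends <- function(summary, ...) {
  segs <- c("one_third", "two_thirds", "full")
  xs <- seq_along(segs)
  ylim <- range(summary$mean - summary$sd, summary$mean + summary$sd)
  graphics::plot(NA, xlim = c(0.5, 3.5), ylim = ylim, xaxt = "n",
                 xlab = "iris segment", ylab = "density (fraction)", ...)
  axis(1, at = xs, labels = c("1/3", "2/3", "full"))
  cols <- c(vad = "black", vsd = "gray50")
  for (metric in c("vad", "vsd")) {
    d <- summary[summary$metric == metric, ]
    d <- d[match(segs, d$segment), ]
    lines(xs, d$mean, col = cols[[metric]])
    points(xs, d$mean, pch = 19, col = cols[[metric]])
    arrows(xs, d$mean - d$sd, xs, d$mean + d$sd, angle = 90, code = 3,
           length = 0.04, col = cols[[metric]])
  }
  legend("topright", legend = c("VAD", "VSD"), col = cols, lty = 1,
         pch = 19, bty = "n")
  invisible(summary)
}
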