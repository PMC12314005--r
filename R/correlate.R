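# Correlation layer: Pearson r with Fisher-z 95% confidence intervals,
# Spearman cross-check, weekly weight gains, and the full group x daypart
# correlation suite with forest plots.

#' Fisher-z confidence interval for a correlation coefficient
#'
#' `tanh(atanh(r) +/- 1.96/sqrt(n - 3))`, the standard closed-form 95%
#' interval used in forest plots.
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs.
#' @return Numeric vector `c(low, high)` (matrix for vector input).
#' @export
fisher_ci <- function(r, n) {
  if (any(n < 4)) {
    # n = 3 leaves zero degrees of freedom for the z variance: the interval
    # spans the whole admissible range
    lo <- rep(-1, length(r)); hi <- rep(1, length(r))
    ok <- n >= 4
    z <- atanh(r[ok]); h <- 1.96 / sqrt(n[ok] - 3)
    lo[ok] <- tanh(z - h); hi[ok] <- tanh(z + h)
  } else {
    z <- atanh(r); h <- 1.96 / sqrt(n - 3)
    lo <- tanh(z - h); hi <- tanh(z + h)
  }
  if (length(r) == 1) c(lo, hi) else cbind(low = lo, high = hi)
}

.cor_result <- function(x, y, method) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop("fewer than 3 complete pairs (n = ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cor(x, y, method = method)
  ci <- fisher_ci(r, n)
  data.frame(r = r, ci_low = ci[1], ci_high = ci[2], n = n, method = method)
}

#' Pearson correlation with 95% confidence interval
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' Fisher-z interval of [fisher_ci()]. Zero variance in either variable is an
#' error (reported upstream as a missing cell, never as 0).
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row data frame with `r`, `ci_low`, `ci_high`, `n`, `method`.
#' @export
pearson_with_ci <- function(x, y) .cor_result(x, y, "pearson")

#' Spearman rank correlation (consistency check)
#'
#' Pearson correlation of tie-averaged ranks, reported alongside the Pearson
#' results to verify that conclusions do not hinge on linearity.
#' @inheritParams pearson_with_ci
#' @export
spearman_check <- function(x, y) .cor_result(x, y, "spearman")

#' Weekly weight gains from Monday weighings
#'
#' Differences between consecutive weigh dates per animal; a gain is
#' attributed to the week ending at the later weigh date. Gaps other than
#' exactly 7 days are flagged `nonweekly` and excluded from weekly
#' correlations.
#'
#' @param animals Long-format animal table (see [read_animals()]).
#' @param week_map Optional [make_week_map()] output used to attach
#'   `week_index` (the week containing the gain interval).
#' @return Data frame with `animal_id`, `week_start`, `week_index` (if
#'   mapped), `gain`, `nonweekly`.
#' @export
weekly_weight_gain <- function(animals, week_map = NULL) {
  stopifnot(all(c("animal_id", "weigh_date", "weight") %in% names(animals)))
  a <- animals[order(animals$animal_id, animals$weigh_date), ]
  n <- nrow(a)
  if (n < 2)
    return(data.frame(animal_id = character(), week_start = as.Date(character()),
                      gain = numeric(), nonweekly = logical()))
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  same <- a$animal_id[i1] == a$animal_id[i2]
  out <- data.frame(animal_id = a$animal_id[i1][same],
                    week_start = a$weigh_date[i1][same],
                    gain = (a$weight[i2] - a$weight[i1])[same],
                    gap_days = as.integer(a$weigh_date[i2] -
                                            a$weigh_date[i1])[same])
  out$nonweekly <- out$gap_days != 7L
  out$gap_days <- NULL
  if (!is.null(week_map)) {
    wk <- unique(week_map[c("date", "week_index")])
    names(wk) <- c("week_start", "week_index")
    out <- merge(out, wk, by = "week_start", all.x = TRUE, sort = FALSE)
  }
  out[order(out$animal_id, out$week_start), , drop = FALSE]
}

# variable sets of the correlation suite
.behavior_vars <- function(daypart) {
  v <- c(behavior_classes, "distance")
  if (daypart == "day") v <- c(v, "time_in_open")
  v
}
.anchor_vars <- c("max_cci", "bos_indicus", "initial_weight", "weekly_gain")

#' Group- and daypart-stratified correlation suite
#'
#' Within each exposure group and daypart (`full`, `day`, `night`), computes
#' the correlation of each anchor variable -- daily maximum CCI, Bos indicus
#' proportion, initial weight, and weekly weight gain -- with each behavioural
#' variable (six class-hours and distance; time in the open appears in
#' daytime analyses only, being undefined at night), plus weight gain against
#' CCI and against Bos indicus proportion. The unit of analysis is the
#' animal-day pooled over the group's two weeks (`unit = "animal_day"`), or
#' per-animal means within the group (`unit = "animal_mean"`). Cells with
#' fewer than 3 pairs or zero variance are skipped. Both Pearson (with
#' Fisher 95% CI) and Spearman rows are emitted.
#'
#' @param summaries Daily summaries from [build_daily_summaries()] with
#'   `week_index` and `max_cci`; incomplete or distance-excluded rows are
#'   dropped.
#' @param gains Weekly gains from [weekly_weight_gain()].
#' @param profiles Per-animal table with `animal_id`, `bos_indicus`,
#'   `initial_weight` (duplicated rows are collapsed).
#' @param groups A [pair_weeks()] result.
#' @param unit Unit of analysis (see above).
#' @param methods Correlation methods to emit.
#' @return Object of class `"herd_correlations"`: a data frame with
#'   `group_id`, `daypart`, `x_var`, `y_var`, `r`, `ci_low`, `ci_high`, `n`,
#'   `method`.
#' @export
correlation_suite <- function(summaries, gains, profiles, groups,
                              unit = c("animal_day", "animal_mean"),
                              methods = c("pearson", "spearman")) {
  unit <- match.arg(unit)
  stopifnot(all(c("week_index", "max_cci") %in% names(summaries)))
  prof <- unique(profiles[c("animal_id", "bos_indicus", "initial_weight")])
  use <- summaries[!summaries$incomplete %in% TRUE &
                     !(summaries$excluded %in% TRUE) &
                     !is.na(summaries$week_index), ]
  use <- merge(use, prof, by = "animal_id", all.x = TRUE, sort = FALSE)
  g_weekly <- gains[!gains$nonweekly & !is.na(gains$week_index),
                    c("animal_id", "week_index", "gain")]
  names(g_weekly)[3] <- "weekly_gain"
  use <- merge(use, g_weekly, by = c("animal_id", "week_index"),
               all.x = TRUE, sort = FALSE)
  gdf <- as.data.frame(groups)[c("week_index", "group_id")]
  use <- merge(use, gdf, by = "week_index", sort = FALSE)

  rows <- list()
  emit <- function(sub, gid, dp, xv, yv) {
    for (m in methods) {
      res <- tryCatch(.cor_result(sub[[xv]], sub[[yv]], m),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <<- cbind(
        data.frame(group_id = gid, daypart = dp, x_var = xv, y_var = yv),
        res)
    }
  }
  for (gid in sort(unique(use$group_id))) {
    for (dp in c("full", "day", "night")) {
      sub <- use[use$group_id == gid & use$daypart == dp, ]
      if (nrow(sub) < 3) {
        message("correlation_suite: group ", gid, " daypart ", dp,
                " skipped (insufficient n)")
        next
      }
      if (unit == "animal_mean") {
        num <- vapply(sub, is.numeric, TRUE)
        num[names(num) %in% c("week_index", "group_id")] <- FALSE
        sub <- stats::aggregate(sub[num], by = list(animal_id = sub$animal_id),
                                FUN = mean, na.rm = TRUE)
      }
      for (xv in .anchor_vars)
        for (yv in .behavior_vars(dp))
          emit(sub, gid, dp, xv, yv)
      emit(sub, gid, dp, "weekly_gain", "max_cci")
      emit(sub, gid, dp, "weekly_gain", "bos_indicus")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("herd_correlations", "data.frame")
  out
}

#' @export
print.herd_correlations <- function(x, ...) {
  cat(sprintf("correlation suite: %d cells over %d group(s), methods: %s\n",
              nrow(x), length(unique(x$group_id)),
              paste(unique(x$method), collapse = ", ")))
  p <- x[x$method == "pearson", ]
  excl0 <- sum(p$ci_low > 0 | p$ci_high < 0)
  cat(sprintf("  pearson cells: %d, of which %d have a 95%% CI excluding 0\n",
              nrow(p), excl0))
  invisible(x)
}

#' Forest plot of correlation results
#'
#' One panel per anchor variable; each row shows a behavioural variable's
#' correlation coefficient (point) and its 95% confidence interval
#' (whiskers), with a reference line at zero.
#'
#' @param results A [correlation_suite()] result (Pearson rows are drawn).
#' @param group_id,daypart Stratum to display (defaults: warmest group,
#'   daytime).
#' @param file Optional output path ending in `.png` or `.svg`; when `NULL`
#'   the current device is used.
#' @param anchors Anchor variables to panel.
#' @return Invisibly, the data frame of plotted rows.
#' @export
forest_plot <- function(results, group_id = max(results$group_id),
                        daypart = "day", file = NULL,
                        anchors = .anchor_vars) {
  p <- results[results$method == "pearson" &
                 results$group_id == group_id &
                 results$daypart == daypart &
                 results$x_var %in% anchors, ]
  if (nrow(p) == 0) stop("no results to plot", call. = FALSE)
  anchors <- intersect(anchors, unique(p$x_var))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 1600, height = 1200, res = 150),
           svg = grDevices::svg(file, width = 11, height = 8),
           stop("unsupported figure format: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(anchors)),
                       mar = c(4, 9, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (a in anchors) {
    sub <- p[p$x_var == a, ]
    sub <- sub[order(sub$r), ]
    k <- nrow(sub)
    graphics::plot(sub$r, seq_len(k), xlim = c(-1, 1), ylim = c(0.5, k + 0.5),
                   pch = 16, yaxt = "n", xlab = "Pearson r (95% CI)",
                   ylab = "",
                   main = sprintf("%s (group %d, %s)", a, group_id, daypart))
    graphics::segments(sub$ci_low, seq_len(k), sub$ci_high, seq_len(k))
    graphics::abline(v = 0, lty = 2, col = "grey50")
    graphics::axis(2, at = seq_len(k), labels = sub$y_var, las = 1,
                   cex.axis = 0.8)
  }
  invisible(p)
}
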