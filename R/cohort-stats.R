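#' Per-interval group summary
#'
#' Aggregates a one-group [profile_table] into per-interval statistics over
#' nuclei: the number of contributing nuclei (missing intervals are skipped,
#' not counted as zero), the mean relative intensity \eqn{I_G[x]}, the sample
#' standard deviation, and the standard error of the mean.
#'
#' @param profiles [profile_table] rows of a single group (>= 2 nuclei).
#' @param group group identifier recorded on the summary (defaults to the
#'   table's group column when unique).
#' @return data.frame of class `group_summary`: columns `group`, `x`, `n`,
#'   `mean`, `sd`, `se` (mean/sd/se are `NA` for intervals with no data).
#' @export
summarize_group <- function(profiles, group = NULL) {
  df <- as.data.frame(profiles)
  check_schema(df, c("image_id", "nucleus", "x", "value"), "profile table")
  if (is.null(group)) {
    group <- if ("group" %in% names(df)) unique(df$group) else "group"
    if (length(group) != 1L) {
      stop("profiles contain several groups; pass one group at a time",
           call. = FALSE)
    }
  }
  n_nuclei <- length(unique(paste(df$image_id, df$nucleus)))
  if (n_nuclei < 2L) {
    stop(sprintf("need at least 2 nuclei to summarise a group (got %d)",
                 n_nuclei), call. = FALSE)
  }
  xs <- sort(unique(df$x))
  out <- lapply(xs, function(x) {
    v <- df$value[df$x == x]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(group = group, x = x, n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               sd = if (n > 1) sd(v) else if (n == 1) 0 else NA_real_,
               se = if (n > 1) sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("group_summary", "data.frame"))
}

#' Mann–Whitney U test for two samples
#'
#' The U statistic is the number of pairs `(a_i, b_j)` with `a_i > b_j`,
#' counting ties as 1/2. The two-sided p-value is computed by exact
#' enumeration when `n1 + n2 <= 16` and there are no ties, and otherwise by
#' the normal approximation with tie correction and continuity correction.
#' When every value is tied across both samples there is no evidence either
#' way and p = 1.
#'
#' @param a,b numeric samples (both nonempty).
#' @return list with elements `U` and `p.value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (n1 + n2) <= 16L
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # degenerate: zero rank variance (all values tied)
  list(U = unname(U), p.value = min(p, 1))
}

#' Compare two cohorts interval by interval
#'
#' Runs a two-sided Mann–Whitney U test per 5% interval on the per-nucleus
#' values of the two groups. Intervals with fewer than two non-missing values
#' in either group are flagged `tested = FALSE` rather than silently dropped.
#' Significance is assessed at level `alpha` after the chosen multiplicity
#' correction (default none, matching per-interval testing; `"holm"` and
#' `"BH"` available).
#'
#' @param ref,test [profile_table]s for the reference and test group.
#' @param alpha significance level in (0, 1).
#' @param correction `"none"`, `"holm"`, or `"BH"`.
#' @return data.frame of class `bin_comparison`: per interval `x`, group
#'   sizes `n_ref`/`n_test`, `mean_ref`/`mean_test`, `U`, `p.value`,
#'   `p.adjusted`, `tested`, `significant`, and `direction` (`"higher"` /
#'   `"lower"`: the test group relative to the reference).
#' @export
compare_bins <- function(ref, test, alpha = 0.05,
                         correction = c("none", "holm", "BH")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must lie in (0, 1)")
  rdf <- as.data.frame(ref); tdf <- as.data.frame(test)
  check_schema(rdf, c("x", "value"), "reference table")
  check_schema(tdf, c("x", "value"), "test table")
  xs <- sort(unique(c(rdf$x, tdf$x)))
  rows <- lapply(xs, function(x) {
    va <- rdf$value[rdf$x == x]; va <- va[!is.na(va)]
    vb <- tdf$value[tdf$x == x]; vb <- vb[!is.na(vb)]
    tested <- length(va) >= 2L && length(vb) >= 2L
    if (tested) {
      mw <- mann_whitney_u(vb, va)  # U counts test-over-reference pairs
      U <- mw$U; p <- mw$p.value
    } else {
      U <- NA_real_; p <- NA_real_
    }
    data.frame(x = x, n_ref = length(va), n_test = length(vb),
               mean_ref = if (length(va)) mean(va) else NA_real_,
               mean_test = if (length(vb)) mean(vb) else NA_real_,
               U = U, p.value = p, tested = tested)
  })
  out <- do.call(rbind, rows)
  out$p.adjusted <- NA_real_
  out$p.adjusted[out$tested] <- p.adjust(out$p.value[out$tested],
                                         method = correction)
  out$significant <- !is.na(out$p.adjusted) & out$p.adjusted < alpha
  out$direction <- ifelse(is.na(out$mean_ref) | is.na(out$mean_test),
                          NA_character_,
                          ifelse(out$mean_test > out$mean_ref, "higher", "lower"))
  structure(out, alpha = alpha, correction = correction,
            class = c("bin_comparison", "data.frame"))
}

#' Interval-change statistic over a radial interval
#'
#' Quantifies the integral change (%) of the test group's relative intensity
#' compared to the reference group over a set `L` of 5% intervals:
#' \deqn{\Delta = \left(1 - \frac{\sum_{x \in L} I_{ref}[x]}
#'                              {\sum_{x \in L} I_{test}[x]}\right)
#'       \times 100\%}
#' where \eqn{I_G[x]} is the group mean per-nucleus relative intensity of
#' interval `x` ([summarize_group]). \eqn{\Delta} is 0 when the two sums are
#' equal, positive when the test group carries more intensity on `L`, and
#' always below 100.
#'
#' @param ref,test `group_summary` objects for the reference (numerator) and
#'   test (denominator) group.
#' @param L intervals (right edges, multiples of 5) to sum over.
#' @return list with `L` and `delta_percent`.
#' @export
delta_statistic <- function(ref, test, L) {
  L <- as.numeric(L)
  get_means <- function(s, who) {
    m <- s$mean[match(L, s$x)]
    bad <- L[is.na(m) | s$n[match(L, s$x)] == 0]
    if (length(bad)) {
      stop(sprintf("%s group has undefined mean(s) at interval(s): %s",
                   who, paste(bad, collapse = ", ")), call. = FALSE)
    }
    m
  }
  i_ref <- get_means(ref, "reference")
  i_test <- get_means(test, "test")
  if (sum(i_test) <= 0) {
    stop("test-group intensity sums to zero on L; delta undefined",
         call. = FALSE)
  }
  list(L = L, delta_percent = (1 - sum(i_ref) / sum(i_test)) * 100)
}

#' Default radial thirds
#'
#' Partitions the twenty 5% intervals into inner, middle and outer thirds of
#' the radial axis. Twenty intervals do not divide evenly by three, so each
#' interval is assigned to the continuous third (\[0, 100/3\], (100/3,
#' 200/3\], (200/3, 100\]) containing its midpoint `x - 2.5`:
#' inner = \{5..35\}, middle = \{40..65\}, outer = \{70..100\}.
#'
#' @return named list of three interval vectors (`inner`, `middle`, `outer`).
#' @export
default_delta_intervals <- function() {
  edges <- seq(5, 100, by = 5)
  mid <- edges - 2.5
  third <- ifelse(mid <= 100 / 3, "inner",
                  ifelse(mid <= 200 / 3, "middle", "outer"))
  split(edges, factor(third, levels = c("inner", "middle", "outer")))
}

#' Full two-group cohort comparison
#'
#' Aggregates both groups ([summarize_group]), tests every interval
#' ([compare_bins]), and computes the interval-change statistic
#' ([delta_statistic]) over the given radial intervals (default: the three
#' radial thirds).
#'
#' @param ref,test [profile_table]s for the two groups.
#' @param alpha,correction passed to [compare_bins].
#' @param intervals named list of interval sets for the change statistic.
#' @return object of class `cohort_comparison`: list with `summary_ref`,
#'   `summary_test`, `bins` (the [compare_bins] table) and `deltas`
#'   (data.frame `interval`, `bins`, `delta_percent`).
#' @export
compare_cohorts <- function(ref, test, alpha = 0.05, correction = "none",
                            intervals = default_delta_intervals()) {
  sum_ref <- summarize_group(ref, group = "reference")
  sum_test <- summarize_group(test, group = "test")
  bins <- compare_bins(ref, test, alpha = alpha, correction = correction)
  deltas <- do.call(rbind, lapply(names(intervals), function(nm) {
    d <- delta_statistic(sum_ref, sum_test, intervals[[nm]])
    data.frame(interval = nm, bins = paste(d$L, collapse = ";"),
               delta_percent = d$delta_percent, stringsAsFactors = FALSE)
  }))
  structure(list(summary_ref = sum_ref, summary_test = sum_test,
                 bins = bins, deltas = deltas),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  nsig <- sum(x$bins$significant)
  ntested <- sum(x$bins$tested)
  cat(sprintf("<cohort_comparison> %d of %d intervals significant (alpha = %g, correction = %s)\n",
              nsig, ntested, attr(x$bins, "alpha"), attr(x$bins, "correction")))
  for (i in seq_len(nrow(x$deltas))) {
    cat(sprintf("  delta[%s] = %+.1f%%\n", x$deltas$interval[i],
                x$deltas$delta_percent[i]))
  }
  invisible(x)
}

#' Plot a two-group radial intensity comparison
#'
#' Mean relative intensity per 5% interval for both groups with error bars
#' (standard deviation or standard error) and asterisks marking significant
#' intervals.
#'
#' @param comparison `cohort_comparison` from [compare_cohorts].
#' @param error `"sd"` or `"se"`.
#' @param group_labels length-2 character: labels for reference and test.
#' @return a ggplot object.
#' @export
plot_radial_comparison <- function(comparison, error = c("sd", "se"),
                                   group_labels = c("reference", "test")) {
  error <- match.arg(error)
  s <- rbind(comparison$summary_ref, comparison$summary_test)
  s$group <- factor(s$group, levels = c("reference", "test"),
                    labels = group_labels)
  s$err <- s[[error]]
  sig <- comparison$bins[comparison$bins$significant, , drop = FALSE]
  ymax <- max(s$mean + s$err, na.rm = TRUE)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = x, y = mean, colour = group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - err, ymax = mean + err),
                           width = 1.5, alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c("#2e7d32", "#c62828")) +
    ggplot2::labs(x = "relative radial position (%)",
                  y = "relative intensity (fraction of profile maximum)",
                  colour = NULL) +
    ggplot2::theme_classic()
  if (nrow(sig)) {
    p <- p + ggplot2::annotate("text", x = sig$x, y = ymax * 1.05,
                               label = "*", size = 5)
  }
  p
}
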