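#' Fold expansion at an ancestry threshold
#'
#' The cumulative fraction of a category's nonredundant folds whose
#' ancestry value is less than or equal to `a` — the empirical CDF of the
#' census ancestries, the quantity plotted by expansion curves. The
#' comparison is inclusive.
#'
#' @param census A `category_census` from [join_ancestry()].
#' @param a Ancestry threshold in \[0, 1\].
#' @return Fraction in \[0, 1\].
#' @examples
#' cen <- toy_census(c(0.1, 0.3, 0.5, 0.9))
#' expansion_at(cen, 0.4)  # 0.5
#' @export
expansion_at <- function(census, a) {
  check_census(census)
  stopifnot(is.numeric(a), length(a) >= 1, all(a >= 0 & a <= 1))
  anc <- census$folds$ancestry
  vapply(a, function(th) sum(anc <= th) / length(anc), numeric(1))
}

#' Fold-expansion step curve of a census
#'
#' Breakpoints are the sorted distinct ancestry values of the census; the
#' curve value at a breakpoint is [expansion_at()] there, and the curve is
#' right-continuous (the value holds until the next breakpoint). Ties —
#' several folds sharing one ancestry — produce a single breakpoint with a
#' multi-fold jump.
#'
#' @param census A `category_census`.
#' @return An `expansion_curve` object: list with `category`,
#'   `breakpoints`, `values`, and `n_folds`.
#' @export
expansion_curve <- function(census) {
  check_census(census)
  bp <- sort(unique(census$folds$ancestry))
  vals <- expansion_at(census, bp)
  out <- list(category = census$category, breakpoints = bp,
              values = vals, n_folds = nrow(census$folds))
  class(out) <- "expansion_curve"
  out
}

#' Evaluate an expansion curve at arbitrary thresholds
#'
#' @param curve An `expansion_curve`.
#' @param a Numeric vector of thresholds in \[0, 1\].
#' @return Numeric vector of cumulative fractions.
#' @export
eval_curve <- function(curve, a) {
  stopifnot(inherits(curve, "expansion_curve"))
  idx <- findInterval(a, curve$breakpoints)
  ifelse(idx == 0, 0, curve$values[pmax(idx, 1)])
}

#' @export
print.expansion_curve <- function(x, ...) {
  cat(sprintf("Expansion curve '%s': %d folds, %d breakpoints\n",
              x$category, x$n_folds, length(x$breakpoints)))
  invisible(x)
}

#' @export
plot.expansion_curve <- function(x, add = FALSE, col = 1, ...) {
  bx <- c(0, rep(x$breakpoints, each = 2), 1)
  by <- c(0, 0, rep(100 * x$values, each = 2))[seq_along(bx)]
  if (!add)
    graphics::plot(bx, by, type = "n", xlim = c(0, 1), ylim = c(0, 100),
                   xlab = "Ancestry value", ylab = "Fold expansion (%)", ...)
  graphics::lines(bx, by, col = col, ...)
  invisible(x)
}

#' Area under the fold-expansion curve
#'
#' The exact integral of the right-continuous step function
#' [expansion_at()] over \eqn{[0, \theta]}, expressed in percent of the
#' unit square, computed in closed form:
#' \deqn{100 \cdot \frac{1}{n}\sum_f \max(0,\ \theta - a_f)}
#' where \eqn{a_f} are the census ancestries. The maximum attainable value
#' at threshold \eqn{\theta} is \eqn{100\theta}; at \eqn{\theta = 1} the
#' statistic equals \eqn{100(1 - \bar a)}, one hundred times one minus the
#' mean fold ancestry.
#'
#' @param census A `category_census`.
#' @param theta Ancestry threshold in \[0, 1\].
#' @return Percent in \[0, 100\].
#' @examples
#' auc(toy_census(c(0, 0.5, 1)), 1)     # 50
#' auc(toy_census(c(0.1, 0.3)), 0.19)   # 4.5
#' @export
auc <- function(census, theta) {
  check_census(census)
  stopifnot(is.numeric(theta), length(theta) >= 1, all(theta >= 0 & theta <= 1))
  anc <- census$folds$ancestry
  vapply(theta, function(th) 100 * mean(pmax(0, th - anc)), numeric(1))
}

#' Threshold summaries for a set of category censuses
#'
#' Per category, final fold expansion and area under the expansion curve at
#' each threshold, both in percent. Full precision is retained in the
#' returned data frame; use `digits = 1` when printing tables at the
#' customary one-decimal report precision.
#'
#' @param censuses List of `category_census` objects.
#' @param thresholds Ancestry thresholds in \[0, 1\]; the default
#'   `c(0.19, 0.40, 1.00)` brackets the three evolutionary eras.
#' @return A data frame with columns `category`, `statistic`
#'   (`"final_expansion"` or `"auc"`) and one `thr_<value>` column per
#'   threshold, values in percent.
#' @export
summarize_categories <- function(censuses, thresholds = c(0.19, 0.40, 1.00)) {
  stopifnot(is.list(censuses), length(censuses) >= 1)
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  rows <- lapply(censuses, function(cen) {
    check_census(cen)
    exp_pct <- if (length(thresholds)) 100 * expansion_at(cen, thresholds)
               else numeric(0)
    auc_pct <- if (length(thresholds)) auc(cen, thresholds) else numeric(0)
    r <- data.frame(category = rep(cen$category, 2),
                    statistic = c("final_expansion", "auc"),
                    stringsAsFactors = FALSE)
    for (i in seq_along(thresholds))
      r[[sprintf("thr_%g", thresholds[i])]] <- c(exp_pct[i], auc_pct[i])
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write curve and summary TSVs
#'
#' `write_curve_table` emits long-format step-curve coordinates
#' (`category`, `ancestry`, `expansion` as a fraction); `write_summary_table`
#' emits the threshold summary with values in percent at full precision.
#'
#' @param curves List of `expansion_curve` objects.
#' @param path Output path.
#' @rdname expansion_tsv
#' @export
write_curve_table <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(category = cv$category, ancestry = sprintf("%.6f", cv$breakpoints),
               expansion = sprintf("%.6f", cv$values), stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param summary_df Data frame from [summarize_categories()].
#' @rdname expansion_tsv
#' @export
write_summary_table <- function(summary_df, path) {
  out <- summary_df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a census directly from ancestry values (toy/testing helper)
#'
#' Wraps a bare numeric vector of ancestries into a `category_census` with
#' generated fold identifiers, for examples and small experiments.
#'
#' @param ancestries Numeric vector in \[0, 1\].
#' @param category Category label.
#' @export
toy_census <- function(ancestries, category = "toy") {
  stopifnot(length(ancestries) >= 1, all(ancestries >= 0 & ancestries <= 1))
  out <- list(category = category,
              folds = data.frame(
                fold_id = sprintf("f%04d", seq_along(ancestries)),
                ancestry = as.numeric(ancestries), stringsAsFactors = FALSE),
              dropped = character(0))
  class(out) <- "category_census"
  out
}

check_census <- function(census) {
  if (!inherits(census, "category_census"))
    stop_data("expected a category_census object")
  if (nrow(census$folds) == 0)
    stop_data("empty census for category '%s'", census$category)
  invisible(TRUE)
}
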