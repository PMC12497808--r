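#' Mean and sample standard deviation of per-subject accuracies
#'
#' The convention of benchmark tables: arithmetic mean and the n-1
#' denominator standard deviation, both in percentage points.
#'
#' @param accs numeric vector of per-subject accuracies (length >= 2).
#' @return named numeric vector `c(mean, sd)`.
#' @export
summarize_accuracies <- function(accs) {
  if (length(accs) < 2) stop("need at least two values for a sample sd")
  c(mean = mean(accs), sd = stats::sd(accs))
}

#' Paired comparison of two models across subjects
#'
#' Two-sided paired t-test on per-subject accuracy differences `a - b`
#' (delegated to [stats::t.test()]), plus Cohen's d for paired designs
#' (mean difference over the standard deviation of the differences) and the
#' 95% confidence interval of the mean difference.
#'
#' @param a,b numeric vectors of per-subject accuracies, same subjects in
#'   the same order.
#' @param alpha significance level for the confidence interval.
#' @return a `paired_test_result` list: `mean_diff`, `t`, `p`, `d`,
#'   `ci_low`, `ci_high`, `df`.
#' @export
paired_t <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least two pairs")
  diffs <- a - b
  if (stats::sd(diffs) == 0)
    stop("zero-variance differences: the paired t statistic is undefined")
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = 1 - alpha)
  res <- list(mean_diff = mean(diffs),
              t = unname(tt$statistic),
              p = tt$p.value,
              d = mean(diffs) / stats::sd(diffs),
              ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
              df = unname(tt$parameter))
  structure(res, class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired t-test: mean diff %.2f, t(%d) = %.3f, p = %.4f, d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean_diff, x$df, x$t, x$p, x$d, x$ci_low, x$ci_high))
  invisible(x)
}

#' Published per-subject benchmark accuracies
#'
#' Within-subject classification accuracies (percent) of several published
#' motor-imagery decoders on the two BCI Competition IV benchmarks (2a:
#' 22-channel 4-class, subjects A01-A09; 2b: 3-channel 2-class, subjects
#' B01-B09), bundled for the worked statistics examples.
#'
#' @param dataset `"bcic2a"` or `"bcic2b"`.
#' @return a data frame with columns `method`, `subject`, `accuracy`.
#' @export
mi_benchmark_accuracies <- function(dataset = c("bcic2a", "bcic2b")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_subject_accuracies.csv"),
                      package = "mieeg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
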