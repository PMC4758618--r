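#' Legend-style population summary
#'
#' Sample mean and s.d. (n - 1 denominator) of a normalized population,
#' formatted \code{"mean±sd"} at two decimal places as in the figure
#' legends.
#'
#' @param values numeric normalized values (n >= 2).
#' @param label genotype label.
#' @return a \code{GenotypeSummary}: list with \code{label}, \code{n},
#'   \code{mean}, \code{sd}, \code{formatted}.
#' @examples
#' summarizeArm(c(0.9, 1.1), "wild_type")$formatted  # "1.00±0.14"
#' @export
summarizeArm <- function(values, label = "population") {
  if (length(values) < 2L)
    kqDataError("need at least two values to summarize")
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(label = label, n = length(values), mean = m, sd = s,
         formatted = sprintf("%.2f±%.2f", m, s)),
    class = "GenotypeSummary")
}

#' @export
print.GenotypeSummary <- function(x, ...) {
  cat(sprintf("%s (n = %d): %s\n", x$label, x$n, x$formatted))
  invisible(x)
}

starsForP <- function(p) if (is.finite(p) && p < 1e-4) "***" else ""

#' Compare two populations with a t test
#'
#' Two-sided two-sample t test between a test arm and its reference,
#' defaulting to the Welch unequal-variance form (the arm s.d.s of the
#' published populations differ markedly); Student's equal-variance
#' variant is available by flag. Significance is reported with the
#' published convention: \code{"***"} iff p < 0.0001. When both arms
#' have zero variance and equal means, t = 0 and p = 1.
#'
#' @param reference,test numeric values, each n >= 2.
#' @param equalVar use the pooled-variance (Student) test?
#' @return a \code{ComparisonResult}: list with \code{t}, \code{df},
#'   \code{p}, \code{stars}, \code{method}.
#' @examples
#' compareArms(rnorm(20, 1, 0.2), rnorm(20, 1.8, 0.5))
#' @export
compareArms <- function(reference, test, equalVar = FALSE) {
  if (length(reference) < 2L || length(test) < 2L)
    kqDataError("both populations need n >= 2")
  if (stats::var(reference) == 0 && stats::var(test) == 0) {
    if (mean(reference) == mean(test)) {
      res <- list(t = 0, df = length(reference) + length(test) - 2L,
                  p = 1, stars = "", method = "degenerate (zero variance)")
      class(res) <- "ComparisonResult"
      return(res)
    }
    kqDataError("zero variance in both arms with unequal means")
  }
  ht <- stats::t.test(test, reference, var.equal = equalVar,
                      alternative = "two.sided")
  res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, stars = starsForP(ht$p.value),
              method = ht$method)
  class(res) <- "ComparisonResult"
  res
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.2f, p = %.3g %s\n", x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Additional complexes implied by a relative level
#'
#' Copy-number arithmetic for a kinetochore subcomplex: given a baseline
#' number of complexes per kinetochore and a measured relative level, the
#' implied number of additional complexes is
#' \code{round(baseline * (relativeLevel - 1))}. With the 6.5-complex
#' baseline (midpoint of the 6-7 MIND complexes per anaphase
#' kinetochore), a 30% increase corresponds to 2 additional complexes.
#'
#' @param baseline complexes per kinetochore (> 0; default 6.5).
#' @param relativeLevel measured fold vs control (> 0).
#' @return integer number of additional complexes.
#' @examples
#' mindCopies(6.5, 1.30)  # 2
#' @export
mindCopies <- function(baseline = 6.5, relativeLevel) {
  if (baseline <= 0) kqConfigError("baseline must be > 0")
  if (relativeLevel <= 0) kqConfigError("relativeLevel must be > 0")
  as.integer(round(baseline * (relativeLevel - 1)))
}
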