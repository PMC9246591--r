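#' Ordinal grading table for two groups
#'
#' Holds per-grade patient counts for two groups on an ordinal scale such as
#' the Riker Sedation-Agitation Scale (SAS; grades 3-7 span calm through
#' dangerously agitated, with grade 5 and above denoting agitation).
#'
#' @param grades Strictly increasing integer grade labels.
#' @param counts Named list of non-negative integer count vectors, one per
#'   group, each the same length as `grades`.
#' @return Object of class `"grading_table"` with `grades`, `counts`,
#'   `group_sizes`.
#' @export
#' @examples
#' riker_agitation_table()
grading_table <- function(grades, counts) {
  stopifnot(is.numeric(grades), length(grades) >= 1)
  if (is.unsorted(grades, strictly = TRUE)) stop("'grades' must be strictly increasing")
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    stop("'counts' must be a named list of per-group count vectors")
  for (g in names(counts)) {
    v <- counts[[g]]
    if (length(v) != length(grades) || any(v < 0) || any(v != round(v)))
      stop("counts for group '", g, "' must be non-negative integers, one per grade")
  }
  structure(list(grades = as.integer(grades),
                 counts = lapply(counts, as.integer),
                 group_sizes = vapply(counts, sum, numeric(1))),
            class = "grading_table")
}

#' @export
print.grading_table <- function(x, ...) {
  m <- do.call(cbind, x$counts)
  rownames(m) <- x$grades
  print(m)
  invisible(x)
}

#' Riker SAS grading counts of the two anesthesia groups
#'
#' The published per-grade agitation grading of the two 30-patient groups
#' (grades 3-7): the dexmedetomidine-supplemented group A and the saline
#' control group B.
#'
#' @return A [grading_table()].
#' @export
riker_agitation_table <- function() {
  grading_table(3:7, list(A = c(5, 20, 3, 2, 0),
                          B = c(2, 5, 7, 9, 7)))
}

#' Agitation incidence from a grading table
#'
#' Percentage of patients at or above the threshold grade, truncated toward
#' zero to a whole-number percent (the printed-value convention: 5/30 and
#' 23/30 report as 16 and 76). The default threshold, Riker SAS grade 5, is
#' the standard cut for "agitated".
#'
#' @param table A [grading_table()].
#' @param group Group label.
#' @param threshold_grade Smallest grade counted as agitated; must be one of
#'   the table's grades.
#' @return Integer percent.
#' @export
#' @examples
#' agitation_incidence(riker_agitation_table(), "A")   # 16
#' agitation_incidence(riker_agitation_table(), "B")   # 76
agitation_incidence <- function(table, group, threshold_grade = 5) {
  stopifnot(inherits(table, "grading_table"))
  if (!group %in% names(table$counts))
    stop("unknown group '", group, "'; available: ",
         paste(names(table$counts), collapse = ", "))
  if (!threshold_grade %in% table$grades)
    stop("'threshold_grade' must be one of the table grades")
  k <- sum(table$counts[[group]][table$grades >= threshold_grade])
  n <- table$group_sizes[[group]]
  as.integer(trunc(100 * k / n))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Computes the chi-squared statistic from the closed form
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` (optionally with the Yates
#' continuity correction) and the p-value from the upper tail of the
#' chi-squared distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts: rows are outcomes, columns are groups, so the
#'   table is `rbind(c(a, b), c(c, d))`.
#' @param correct Apply the Yates continuity correction (default `FALSE`;
#'   the uncorrected form is appropriate when expected counts are large).
#' @return List `statistic`, `p_value`, `df` (= 1), `correct`.
#' @export
#' @examples
#' chi_square_2x2(5, 25, 23, 7)   # agitated/not in the two groups
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  N <- sum(counts)
  if (N < 1) stop("table total must be >= 1")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("chi-squared statistic undefined: a table margin is zero")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1, correct = correct)
}

#' Group summary (mean, SD, n)
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return Object of class `"group_summary"`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n))
  if (sd < 0) stop("'sd' must be >= 0")
  if (n < 2 || n != round(n)) stop("'n' must be an integer >= 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)), class = "group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (Student) or Welch t test computed from per-group mean,
#' SD and n, for published mean +/- SD data. Welch degrees of freedom follow
#' Welch-Satterthwaite.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List `t`, `df`, `p_value` (two-sided), `variant`.
#' @export
#' @examples
#' two_sample_t(group_summary(100, 5.5, 30), group_summary(112, 6.8, 30))
two_sample_t <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  if (g1$sd == 0 && g2$sd == 0)
    stop("both group variances are zero; t statistic undefined")
  v1 <- g1$sd^2; v2 <- g2$sd^2
  n1 <- g1$n; n2 <- g2$n
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (g1$mean - g2$mean) / se
  list(t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df = df),
       variant = variant)
}
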