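#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention reported alongside medians
#' in this package's summary tables.
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop("values must be nonempty and NA-free", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (wraps `stats::kruskal.test`). When every
#' observation is identical the statistic is 0 and p = 1 by convention.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each nonempty).
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L)) {
    stop("groups must be a list of >= 2 nonempty numeric vectors", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by `m` and caps at 1; never lowers a p-value.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons, `m >= length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("m must be >= number of p-values", call. = FALSE)
  pmin(pvals * m, 1)
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Probability-mass two-sided rule: p is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (the convention of
#' `stats::fisher.test`, which this wraps). Degenerate margins (an empty
#' row or column) give p = 1.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filling the table by row.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(table) || any(dim(table) != 2L) || any(table < 0) ||
      any(table != round(table))) {
    stop("table must be a 2 x 2 matrix of nonnegative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("table total must be > 0", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' ROC curve and AUC by pair counting
#'
#' AUC via the Mann-Whitney identity: the fraction of (positive, negative)
#' score pairs where the positive scores higher, plus half the tied pairs.
#' The curve is a threshold sweep over the observed values (rule: score >=
#' threshold calls positive), anchored at (0,0) and (1,1); the trapezoidal
#' area under it equals the pair-counting AUC.
#'
#' @param scores_pos,scores_neg Numeric scores for the positive (e.g. DR)
#'   and negative (control) groups; both nonempty.
#' @return List with `auc` and `roc` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), numeric(1))
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' Center-involved DME classification from CST
#'
#' Central subfield thickness strictly greater than the sex-specific
#' threshold (320 um for male, 305 um for female patients) classifies the
#' eye as having center-involved diabetic macular edema.
#'
#' @param cst_um Central subfield thickness in micrometers (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Logical.
#' @export
classify_dme <- function(cst_um, sex) {
  if (any(is.na(cst_um)) || any(cst_um <= 0)) {
    stop("cst_um must be positive", call. = FALSE)
  }
  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  cst_um > ifelse(sex == "male", 320, 305)
}

#' Decimal visual acuity to logMAR
#'
#' `logMAR = -log10(decimal VA)`.
#'
#' @param va_decimal Decimal visual acuity (> 0).
#' @return logMAR value.
#' @export
decimal_to_logmar <- function(va_decimal) {
  if (any(is.na(va_decimal)) || any(va_decimal <= 0)) {
    stop("va_decimal must be > 0", call. = FALSE)
  }
  -log10(va_decimal)
}

#' Cohort-level summary report
#'
#' For a per-eye table of sector indices and a grouping column, emits the
#' standard layout: one row per sector, per-group `median (q1-q3)` strings,
#' and a Kruskal-Wallis p-value per sector, with pairwise rank tests
#' Bonferroni-corrected by the number of group pairs when more than two
#' groups are present. Optionally adds a Fisher 2 x 2 test for a supplied
#' dichotomy and the ROC AUC of a chosen sector index for a two-level
#' grouping.
#'
#' @param df Data frame with one row per eye.
#' @param group_col Name of the grouping column in `df`.
#' @param sector_cols Names of the numeric index columns to summarize.
#'   Default: the six standard sector columns present in `df`.
#' @param auc_sector Optional sector column for a ROC AUC (needs exactly
#'   two groups; the second level sorted is treated as positive unless
#'   `positive_group` is given).
#' @param positive_group Group label treated as positive for the AUC.
#' @param alpha Significance level recorded in the output. Default 0.05.
#' @return List with `summary` (data frame), `pairwise` (data frame of
#'   Bonferroni-adjusted pairwise p-values, or NULL for two groups) and
#'   `auc` (or NULL).
#' @export
cohort_report <- function(df, group_col, sector_cols = NULL,
                          auc_sector = NULL, positive_group = NULL,
                          alpha = 0.05) {
  stopifnot(is.data.frame(df), group_col %in% names(df))
  if (is.null(sector_cols)) {
    std <- c("all_sectors", "center", "nasal", "superior", "temporal", "inferior")
    sector_cols <- intersect(std, names(df))
  }
  stopifnot(length(sector_cols) >= 1, all(sector_cols %in% names(df)))
  g <- as.character(df[[group_col]])
  lv <- unique(g)
  sizes <- table(g)[lv]
  if (any(sizes == 0)) {
    warning("empty groups omitted: ", paste(lv[sizes == 0], collapse = ", "))
    lv <- lv[sizes > 0]
  }
  if (length(lv) < 2L) stop("need >= 2 nonempty groups", call. = FALSE)

  fmt <- function(v) {
    m <- median_iqr(v)
    sprintf("%.3f (%.3f-%.3f)", m["median"], m["q1"], m["q3"])
  }
  rows <- lapply(sector_cols, function(s) {
    grp <- split(df[[s]], factor(g, levels = lv))
    kw <- kruskal_wallis(grp)
    out <- c(list(sector = s),
             stats::setNames(lapply(grp, fmt), lv),
             list(p_value = kw$p_value))
    as.data.frame(out, check.names = FALSE)
  })
  summary_tab <- do.call(rbind, rows)

  pairwise <- NULL
  if (length(lv) > 2L) {
    prs <- utils::combn(lv, 2, simplify = FALSE)
    pw <- lapply(sector_cols, function(s) {
      p_raw <- vapply(prs, function(pr) {
        kruskal_wallis(list(df[[s]][g == pr[1]], df[[s]][g == pr[2]]))$p_value
      }, numeric(1))
      data.frame(sector = s,
                 group1 = vapply(prs, `[`, character(1), 1),
                 group2 = vapply(prs, `[`, character(1), 2),
                 p_adj = bonferroni(p_raw, length(prs)))
    })
    pairwise <- do.call(rbind, pw)
  }

  auc <- NULL
  if (!is.null(auc_sector)) {
    if (length(lv) != 2L) stop("AUC needs exactly two groups", call. = FALSE)
    pos <- if (is.null(positive_group)) sort(lv)[2] else positive_group
    stopifnot(pos %in% lv)
    auc <- roc_auc(df[[auc_sector]][g == pos], df[[auc_sector]][g != pos])
  }

  list(summary = summary_tab, pairwise = pairwise, auc = auc, alpha = alpha)
}
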