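# Urinary biomarker evaluation: creatinine correction, two-group
# comparison, ROC/AUC and cutoff selection.

#' Creatinine-corrected intensity
#'
#' Divides a urinary analyte intensity by the sample's urinary creatinine to
#' normalize urine dilution. Vectorized.
#'
#' @param intensity Peak intensity (counts).
#' @param creatinine Urinary creatinine concentration, strictly positive
#'   (unit declared per cohort, e.g. mg/dL).
#' @return Corrected intensity, counts per creatinine unit.
#' @export
creatinine_correct <- function(intensity, creatinine) {
  if (any(creatinine <= 0)) stop("creatinine must be strictly positive")
  intensity / creatinine
}

# exact null distribution of U by enumeration over all assignments of the
# pooled ranks (ties handled naturally since ranks are shared)
.exact_u_pvalue <- function(u_obs, ranks_pooled, n1) {
  n <- length(ranks_pooled)
  combs <- utils::combn(n, n1)
  u_all <- colSums(matrix(ranks_pooled[combs], nrow = n1)) -
    n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_ge <- mean(u_all >= u_obs - eps)
  p_le <- mean(u_all <= u_obs + eps)
  min(1, 2 * min(p_ge, p_le))
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test of cases versus controls. U counts, over
#' all case-control pairs, the pairs where the case value exceeds the
#' control value (ties count one half). The p-value uses exact enumeration
#' of all label arrangements when both groups have at most `exact_max`
#' observations, otherwise the normal approximation with tie correction.
#' A Welch t-test is available by flag for users who prefer it; the default
#' is rank-based because intensities are non-negative and right-skewed.
#'
#' @param cases,controls Numeric vectors, each with >= 3 values.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @param exact_max Largest per-group size for exact enumeration (default 10).
#' @return List with `statistic` (U for wilcoxon, t otherwise), `p_value`,
#'   `method`.
#' @export
compare_groups <- function(cases, controls, method = c("wilcoxon", "t"),
                           exact_max = 10) {
  method <- match.arg(method)
  if (length(cases) < 3 || length(controls) < 3) {
    stop("each group needs at least 3 values")
  }
  if (method == "t") {
    tt <- stats::t.test(cases, controls)
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "welch_t"))
  }
  n1 <- length(cases); n2 <- length(controls)
  pooled <- c(cases, controls)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- .exact_u_pvalue(u, r, n1)
    return(list(statistic = u, p_value = p, method = "mann_whitney_exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                               method = "mann_whitney_normal"))
  z <- (u - mu) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "mann_whitney_normal")
}

#' Empirical ROC curve and AUC
#'
#' Orientation: a higher score indicates a case (elevated marker implies
#' disease). The AUC is computed by pair counting,
#' `(concordant + 0.5 * tied) / (n_case * n_control)`, which equals the
#' trapezoidal area under the empirical ROC curve exactly and equals
#' `U / (n1 * n2)` from the Mann-Whitney statistic.
#'
#' @param scores Numeric vector of marker values.
#' @param labels Vector of group labels, parallel to `scores`.
#' @param positive The label meaning "case" (default `"case"`).
#' @return A list of class `roc_result`: `thresholds` (decreasing),
#'   `sensitivity`, `specificity` (parallel to thresholds), `auc`,
#'   `n_case`, `n_control`.
#' @export
roc <- function(scores, labels, positive = "case") {
  stopifnot(length(scores) == length(labels))
  is_case <- labels == positive
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  cs <- scores[is_case]; ct <- scores[!is_case]

  # pair counting
  gt <- outer(cs, ct, ">"); eq <- outer(cs, ct, "==")
  auc <- (sum(gt) + 0.5 * sum(eq)) / (n1 * n2)

  # stepwise curve: thresholds between distinct score values, rule
  # "positive if score >= threshold"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(cs >= t), 0)
  spec <- vapply(thr, function(t) mean(ct < t), 0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_case = n1, n_control = n2),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d cases, %d controls)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' Trapezoidal AUC from an ROC curve
#'
#' Independent of the pair-counting route in [roc()]: integrates the
#' stepwise empirical curve over 1 - specificity. The two agree exactly.
#'
#' @param r A `roc_result`.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  fpr <- 1 - r$specificity
  ord <- order(fpr, r$sensitivity)
  x <- fpr[ord]; y <- r$sensitivity[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal cutoff
#'
#' Threshold maximizing sensitivity + specificity - 1; ties broken toward
#' higher specificity.
#'
#' @param r A `roc_result`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  j <- r$sensitivity + r$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(r$specificity[best])]
  list(threshold = r$thresholds[best],
       sensitivity = r$sensitivity[best],
       specificity = r$specificity[best],
       youden = j[best])
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap (resampling cases and controls separately), seeded.
#'
#' @param scores,labels,positive As in [roc()].
#' @param n_boot Number of resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `auc`, `lower`, `upper`, `n_boot`.
#' @export
auc_ci_boot <- function(scores, labels, positive = "case", n_boot = 2000,
                        conf = 0.95, seed = 1) {
  is_case <- labels == positive
  cs <- scores[is_case]; ct <- scores[!is_case]
  if (!length(cs) || !length(ct)) stop("both classes must be present")
  point <- roc(scores, labels, positive)$auc
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bcs <- sample(cs, replace = TRUE); bct <- sample(ct, replace = TRUE)
    gt <- outer(bcs, bct, ">"); eq <- outer(bcs, bct, "==")
    (sum(gt) + 0.5 * sum(eq)) / (length(bcs) * length(bct))
  }, 0)
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(auc = point, lower = qs[1], upper = qs[2], n_boot = n_boot)
}

#' End-to-end urinary biomarker evaluation
#'
#' Optionally creatinine-corrects the intensities, compares cases against
#' controls, and estimates screening performance by ROC analysis with a
#' Youden cutoff and a bootstrap AUC interval.
#'
#' @param cohort data.frame with columns `sample_id`, `group`, `intensity`,
#'   `creatinine` (creatinine may be omitted if
#'   `correct_creatinine = FALSE`).
#' @param positive Label meaning "case".
#' @param correct_creatinine Divide intensity by creatinine first.
#' @param n_boot Bootstrap resamples for the AUC interval.
#' @param seed Seed for the bootstrap.
#' @return List with `roc`, `auc`, `auc_ci`, `cutoff`, `test`, `corrected`
#'   (the score vector actually used).
#' @export
evaluate_biomarker <- function(cohort, positive = "case",
                               correct_creatinine = TRUE, n_boot = 2000,
                               seed = 1) {
  need <- c("group", "intensity")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  }
  score <- if (correct_creatinine) {
    if (!"creatinine" %in% names(cohort)) {
      stop("correct_creatinine = TRUE but no creatinine column")
    }
    creatinine_correct(cohort$intensity, cohort$creatinine)
  } else cohort$intensity
  is_case <- cohort$group == positive
  test <- compare_groups(score[is_case], score[!is_case])
  r <- roc(score, cohort$group, positive)
  ci <- auc_ci_boot(score, cohort$group, positive, n_boot = n_boot,
                    seed = seed)
  list(roc = r, auc = r$auc, auc_ci = ci, cutoff = youden_cutoff(r),
       test = test, corrected = score)
}

#' Read a cohort table from delimited text
#'
#' Expected tab- or comma-separated columns: `sample_id`, `group`,
#' `intensity`, `creatinine`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "intensity", "creatinine")
  if (!all(need %in% names(tbl))) {
    stop("cohort file needs columns: ", paste(need, collapse = ", "))
  }
  tbl
}
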