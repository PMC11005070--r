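# Dataset splitting, per-index ROC analysis with Hosmer grading,
# percentile normality ranges, and confusion-matrix metrics.

#' Stratified train/test split
#'
#' Splits per class at the given training fraction (`round(frac * n_c)`
#' training members per class), randomly but reproducibly from the seed.
#'
#' @param labels Class label vector.
#' @param train_fraction Training fraction (default 0.70).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_fraction = 0.70, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2L))
    stop("every class must have at least 2 members")
  train <- integer(0)
  local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Empirical AUC (Mann-Whitney estimator)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks. The
#' reported AUC is oriented to be >= 0.5, with `direction = 1` when higher
#' scores indicate the positive class and `-1` otherwise.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) positive-class indicator.
#' @return List with `auc` (oriented, in [0.5, 1]), `auc_raw` (unoriented)
#'   and `direction`.
#' @export
empirical_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc >= 0.5) list(auc = auc, auc_raw = auc, direction = 1)
  else list(auc = 1 - auc, auc_raw = auc, direction = -1)
}

#' Hosmer-Lemeshow discrimination grade of an AUC
#'
#' Bands: 0.5 no discrimination; (0.5, 0.7) poor; [0.7, 0.8) acceptable;
#' [0.8, 0.95) excellent; >= 0.95 outstanding. Boundary values belong to
#' the upper band, except 0.5 exactly, which is no discrimination.
#'
#' @param auc AUC value(s) in [0, 1].
#' @return Character vector of grades.
#' @export
hosmer_grade <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop("AUC must be in [0, 1]")
  vapply(auc, function(a) {
    if (a <= 0.5) "No discrimination"
    else if (a < 0.7) "Poor"
    else if (a < 0.8) "Acceptable"
    else if (a < 0.95) "Excellent"
    else "Outstanding"
  }, character(1))
}

#' Multiclass confusion matrix
#'
#' Counts of truth (rows) against assignment (columns) over the fixed
#' diagnostic class order, with a row-percentage view.
#'
#' @param true_labels,assigned_labels Vectors of class labels (anything
#'   coercible to factor; the five-class screening order is used when the
#'   labels are diagnostic classes).
#' @param classes Optional explicit class order.
#' @return Object of class `kc_confusion`: integer matrix `counts`, numeric
#'   matrix `row_pct`.
#' @export
confusion_matrix <- function(true_labels, assigned_labels, classes = NULL) {
  if (is.null(classes)) {
    lv <- union(levels(as.factor(true_labels)),
                levels(as.factor(assigned_labels)))
    classes <- if (all(lv %in% DIAGNOSTIC_CLASSES))
      intersect(DIAGNOSTIC_CLASSES, lv) else lv
  }
  t_f <- factor(as.character(true_labels), levels = classes)
  a_f <- factor(as.character(assigned_labels), levels = classes)
  if (anyNA(t_f) || anyNA(a_f)) stop("labels outside the class set")
  counts <- unclass(table(truth = t_f, assigned = a_f))
  rs <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(rs == 0, 1, rs)
  out <- list(counts = counts, row_pct = row_pct, classes = classes)
  class(out) <- "kc_confusion"
  out
}

#' Build a confusion object directly from a count matrix
#'
#' @param counts Square integer matrix, rows = truth, columns = assigned,
#'   with matching dimnames or with `classes` supplied.
#' @param classes Optional class order.
#' @return A `kc_confusion`.
#' @export
as_confusion <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(classes)) classes <- rownames(counts)
  if (is.null(classes)) stop("class names required")
  dimnames(counts) <- list(truth = classes, assigned = classes)
  rs <- rowSums(counts)
  out <- list(counts = counts, row_pct = 100 * counts / ifelse(rs == 0, 1, rs),
              classes = classes)
  class(out) <- "kc_confusion"
  out
}

#' @export
print.kc_confusion <- function(x, digits = 2, ...) {
  cat("Confusion matrix (rows = truth, columns = assigned)\n")
  cells <- matrix(sprintf(paste0("%d (%.", digits, "f%%)"), x$counts,
                          x$row_pct), nrow(x$counts),
                  dimnames = dimnames(x$counts))
  print(cells, quote = FALSE)
  invisible(x)
}

#' One-versus-rest metrics for one class of a confusion matrix
#'
#' Reduces the multiclass matrix to the binary problem "class c versus the
#' rest": `TP` the diagonal cell, `FP` the rest of the column, `FN` the rest
#' of the row, `TN` the remainder; then accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and the F1 harmonic mean. Undefined
#' ratios (zero denominators) yield 0 and set `degenerate = TRUE`.
#'
#' @param cm A [confusion_matrix()] / [as_confusion()] object.
#' @param class Class name.
#' @return List with `TP`, `FP`, `FN`, `TN`, `accuracy`, `precision`,
#'   `recall`, `f1`, `degenerate`.
#' @export
class_metrics <- function(cm, class) {
  stopifnot(inherits(cm, "kc_confusion"))
  counts <- cm$counts
  total <- sum(counts)
  if (total == 0L) stop("empty confusion matrix")
  if (!class %in% cm$classes) stop("unknown class: ", class)
  i <- match(class, cm$classes)
  TP <- counts[i, i]
  FP <- sum(counts[, i]) - TP
  FN <- sum(counts[i, ]) - TP
  TN <- total - TP - FP - FN
  degenerate <- (TP + FP) == 0 || (TP + FN) == 0 || TP == 0
  precision <- if ((TP + FP) == 0) 0 else TP / (TP + FP)
  recall <- if ((TP + FN) == 0) 0 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       accuracy = (TP + TN) / total, precision = precision, recall = recall,
       f1 = f1, degenerate = degenerate)
}

#' Per-class metrics table mirroring the screening report layout
#'
#' @param cm A `kc_confusion`.
#' @return Data frame: one column per class, rows TP/FP/FN/TN and the four
#'   proportions.
#' @export
metrics_table <- function(cm) {
  stopifnot(inherits(cm, "kc_confusion"))
  cols <- lapply(cm$classes, function(cl) {
    m <- class_metrics(cm, cl)
    c(TP = m$TP, FP = m$FP, FN = m$FN, TN = m$TN,
      accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1)
  })
  out <- as.data.frame(cols, col.names = cm$classes)
  out
}

#' Percentile normality model of a normal cohort
#'
#' Empirical 1st/5th/95th/99th percentiles per index (linear interpolation
#' between order statistics), plus the normative 95th-percentile
#' thickness-increase profiles used by the `pTI`/`pEpiTI` indexes.
#'
#' @param index_table Data frame of per-eye index values for the normal
#'   cohort (columns = indexes; non-numeric columns ignored).
#' @param pti_profiles,epi_pti_profiles Optional lists of
#'   [pct_thickness_increase_profile()] results for the same cohort, from
#'   which the pointwise 95th-percentile profiles are taken.
#' @param cohort_id,seed Provenance records.
#' @return Object of class `normative_model` with `percentiles` (4 x p
#'   matrix), `pti_p95`, `epi_pti_p95` and `provenance`.
#' @export
normative_percentiles <- function(index_table, pti_profiles = NULL,
                                  epi_pti_profiles = NULL,
                                  cohort_id = "normal-cohort", seed = NA) {
  num <- index_table[vapply(index_table, is.numeric, logical(1))]
  pct <- vapply(num, stats::quantile,
                probs = c(0.01, 0.05, 0.95, 0.99), names = FALSE, type = 7,
                FUN.VALUE = numeric(4))
  rownames(pct) <- c("p1", "p5", "p95", "p99")
  profile_p95 <- function(profiles) {
    if (is.null(profiles) || length(profiles) == 0L) return(NULL)
    d <- profiles[[1L]]$d
    mat <- vapply(profiles, function(p) p$pti, numeric(length(d)))
    list(d = d, pti = apply(mat, 1L, stats::quantile, probs = 0.95,
                            names = FALSE, type = 7))
  }
  out <- list(percentiles = pct,
              pti_p95 = profile_p95(pti_profiles),
              epi_pti_p95 = profile_p95(epi_pti_profiles),
              provenance = list(cohort_id = cohort_id, n = nrow(num),
                                seed = seed))
  class(out) <- "normative_model"
  out
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model: %d indexes, cohort '%s' (n = %d)\n",
              ncol(x$percentiles), x$provenance$cohort_id, x$provenance$n))
  invisible(x)
}

#' Normality flag of an index value against percentile thresholds
#'
#' Strictly inside (p5, p95) is normal; within [p1, p5] or [p95, p99] is
#' borderline; outside [p1, p99] is abnormal.
#'
#' @param value Numeric value(s).
#' @param thresholds Numeric vector with elements `p1`, `p5`, `p95`, `p99`.
#' @return Character vector in {"normal", "borderline", "abnormal"}.
#' @export
normality_flag <- function(value, thresholds) {
  p <- thresholds[c("p1", "p5", "p95", "p99")]
  if (anyNA(p) || is.unsorted(p)) stop("thresholds must be p1<=p5<=p95<=p99")
  vapply(value, function(v) {
    if (v < p["p1"] || v > p["p99"]) "abnormal"
    else if (v > p["p5"] && v < p["p95"]) "normal"
    else "borderline"
  }, character(1))
}

#' One-sample Kolmogorov-Smirnov normality check of an index
#'
#' Convenience wrapper testing an index sample against the normal
#' distribution with moment-matched parameters (the screening study uses
#' this only to decide that percentile summaries are the appropriate
#' description).
#'
#' @param x Numeric sample.
#' @return List with `statistic` and `p_value`.
#' @export
ks_normality <- function(x) {
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' ROC curve points for a score vector
#'
#' Sensitivity/specificity pairs at every distinct threshold (score >=
#' threshold calls positive), suitable for CSV export or plotting.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) positive-class indicator.
#' @return Data frame with `threshold`, `sensitivity`, `specificity`,
#'   ordered from the most to the least stringent threshold.
#' @export
roc_points <- function(scores, labels) {
  pos <- as.logical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!pos] < t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Per-index ROC/AUC table for a binary contrast
#'
#' Computes the oriented empirical AUC and its Hosmer grade for every index
#' column, for one class contrast (e.g. normal versus keratoconus).
#'
#' @param index_table Data frame containing the index columns.
#' @param labels Class labels aligned with the rows.
#' @param positive Positive class name.
#' @param negative Negative class name.
#' @return Data frame: index, auc, direction, grade.
#' @export
auc_table <- function(index_table, labels, positive = "Kcn",
                      negative = "Normal") {
  keep <- labels %in% c(positive, negative)
  num <- index_table[keep, intersect(INDEX_NAMES, names(index_table)),
                     drop = FALSE]
  pos <- labels[keep] == positive
  rows <- lapply(names(num), function(ix) {
    a <- empirical_auc(num[[ix]], pos)
    data.frame(index = ix, auc = a$auc, direction = a$direction,
               grade = hosmer_grade(a$auc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
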