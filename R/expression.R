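# Count table, reads-per-million normalization against per-sample
# genome-matched totals, and two-group differential expression with
# Student's (pooled-variance) t-test plus a strict fold-change gate.

#' Construct a miRNA-by-sample count table
#'
#' @param counts Integer matrix, miRNAs in rows (rownames are ids),
#'   samples in columns (colnames are sample ids).
#' @param groups Character vector, one of `"mid"`/`"late"` per sample.
#' @param denominators Per-sample normalization denominators: the total
#'   number of high-quality reads matched to the genome in that sample.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, groups, denominators) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("validation error: counts must have row and column names",
         call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(counts) ||
      length(denominators) != ncol(counts)) {
    stop("validation error: groups/denominators must match sample columns",
         call. = FALSE)
  }
  if (!all(groups %in% c("mid", "late"))) {
    stop("validation error: groups must be 'mid' or 'late'", call. = FALSE)
  }
  if (any(denominators <= 0)) {
    stop("validation error: denominators must all be > 0", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("validation error: counts must be non-negative", call. = FALSE)
  }
  structure(list(counts = counts, groups = groups,
                 denominators = as.numeric(denominators)),
            class = "count_table")
}

#' Normalize counts to reads per million of the sample denominator
#'
#' `value[i, j] = counts[i, j] / denominators[j] * 1e6`, where the
#' denominator is the sample's genome-matched high-quality read total.
#'
#' @param table A [count_table()].
#' @return Numeric matrix of RPM values, same dimensions as the counts.
#' @export
normalize_rpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sweep(table$counts, 2L, table$denominators, "/") * 1e6
}

#' Pooled-variance (Student's) two-sample t-test
#'
#' Two-sided, with `df = n_a + n_b - 2`. Degenerate zero-variance inputs
#' are defined rather than errors: equal means give `t = 0, p = 1`;
#' unequal means give `t = +/-Inf, p = 0` with `degenerate = TRUE`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))
student_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) {
    stop("validation error: each group needs >= 2 values", call. = FALSE)
  }
  df <- na + nb - 2L
  pooled <- ((na - 1) * stats::var(group_a) +
             (nb - 1) * stats::var(group_b)) / df
  if (pooled == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t_stat = 0, df = df, p_value = 1, degenerate = TRUE))
    }
    t <- if (mean(group_a) > mean(group_b)) Inf else -Inf
    return(list(t_stat = t, df = df, p_value = 0, degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t_stat = unname(fit$statistic), df = df,
       p_value = fit$p.value, degenerate = FALSE)
}

#' Call differential expression between mid- and late-group samples
#'
#' Per miRNA: normalize to RPM, take group means, form the late/mid
#' ratio, run the pooled t-test on the per-sample normalized values, and
#' flag. `significant` means `p < p_threshold`; `differential` means
#' significant AND the ratio strictly exceeds `fold_threshold` or falls
#' strictly below its reciprocal. A miRNA absent from the mid group but
#' present late gets ratio `Inf` and is decided by significance alone
#' (and symmetrically ratio 0 for the reverse). A Benjamini-Hochberg
#' adjusted p-value is reported as a supplementary column
#' (`padj_bh`); it plays no part in the calls.
#'
#' @param table A [count_table()] with both groups present (>= 2 samples
#'   each).
#' @param config A [pipeline_config()]; `log2_transform` tests
#'   `log2(RPM + pseudocount)` instead of plain RPM.
#' @return Data frame with one row per miRNA: `mirna_id`, `mean_mid`,
#'   `mean_late`, `ratio`, `t_stat`, `p_value`, `padj_bh`,
#'   `significant`, `differential`, `direction` (`up`/`down`/`none`).
#' @export
call_de <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "count_table"))
  mid <- table$groups == "mid"; late <- table$groups == "late"
  if (sum(mid) < 2L || sum(late) < 2L) {
    stop("validation error: each group needs >= 2 samples", call. = FALSE)
  }
  rpm <- normalize_rpm(table)
  vals <- rpm
  if (config$log2_transform) {
    if (config$pseudocount <= 0) {
      stop("configuration error: pseudocount must be > 0 with log2_transform",
           call. = FALSE)
    }
    vals <- log2(rpm + config$pseudocount)
  }
  n <- nrow(rpm)
  mean_mid <- rowMeans(rpm[, mid, drop = FALSE])
  mean_late <- rowMeans(rpm[, late, drop = FALSE])
  ratio <- ifelse(mean_mid > 0, mean_late / mean_mid,
                  ifelse(mean_late > 0, Inf, NA_real_))
  t_stat <- numeric(n); p_value <- numeric(n)
  for (i in seq_len(n)) {
    tt <- student_t_test(vals[i, late], vals[i, mid])
    t_stat[i] <- tt$t_stat; p_value[i] <- tt$p_value
  }
  significant <- p_value < config$p_threshold
  fold_pass <- !is.na(ratio) &
    (ratio > config$fold_threshold | ratio < 1 / config$fold_threshold)
  differential <- significant & (fold_pass | is.infinite(ratio))
  n_inf <- sum(is.infinite(ratio))
  if (n_inf) {
    mf_log("call_de: %d miRNA(s) with mid mean 0, ratio reported as Inf",
           n_inf)
  }
  direction <- ifelse(!differential, "none",
                      ifelse(ratio > 1 | is.infinite(ratio), "up", "down"))
  out <- data.frame(
    mirna_id = rownames(rpm), mean_mid = mean_mid, mean_late = mean_late,
    ratio = ratio, t_stat = t_stat, p_value = p_value,
    padj_bh = stats::p.adjust(p_value, method = "BH"),
    significant = significant, differential = differential,
    direction = direction, stringsAsFactors = FALSE, row.names = NULL
  )
  mf_log("call_de: %d miRNAs tested, %d significant, %d differential",
         n, sum(significant), sum(differential))
  out
}
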