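# Relative qPCR quantification by the 2^-ddCt method with a reference
# gene (U6 by default), and correlation of sequencing-derived with
# qPCR-derived expression ratios on the log2 scale.

#' Relative expression from Ct measurements by 2^-ddCt
#'
#' Replicate Ct values are averaged per (target, sample); per sample,
#' `dCt = Ct_target - Ct_reference`; per group, dCt values are averaged
#' over samples; `ddCt = dCt_late - dCt_mid` and the relative expression
#' ratio is `2^-ddCt`. A ratio strictly below 1.0 is classified `low`
#' expression in the late group, otherwise `high` (amplification
#' efficiency is fixed at the canonical base 2). The standard deviation
#' of per-sample dCt values is propagated to an uncertainty column.
#'
#' @param measurements Data frame with columns `target_id`, `sample_id`,
#'   `group` (`mid`/`late`), `replicate`, `ct` (see [read_ct_table()]).
#' @param reference Reference target id used for normalization
#'   (default `"U6"`).
#' @return Data frame with one row per non-reference target: `mirna_id`,
#'   `delta_ct_mid`, `delta_ct_late`, `sd_delta_ct_mid`,
#'   `sd_delta_ct_late`, `delta_delta_ct`, `ratio`, `classification`.
#' @export
#' @examples
#' ct <- expand.grid(target_id = c("m1", "U6"),
#'                   sample_id = paste0("s", 1:4), replicate = 1)
#' ct$group <- ifelse(ct$sample_id %in% c("s1", "s2"), "mid", "late")
#' ct$ct <- ifelse(ct$target_id == "U6", 20,
#'                 ifelse(ct$group == "mid", 25, 24))
#' ddct(ct)$ratio  # 2: one cycle earlier late means doubled expression
ddct <- function(measurements, reference = "U6") {
  required <- c("target_id", "sample_id", "group", "replicate", "ct")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols)) {
    stop("format error: Ct table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(measurements$ct <= 0)) {
    stop("validation error: Ct values must be > 0", call. = FALSE)
  }
  if (!all(measurements$group %in% c("mid", "late"))) {
    stop("validation error: group must be 'mid' or 'late'", call. = FALSE)
  }
  # mean Ct per (target, sample) over replicates
  agg <- stats::aggregate(ct ~ target_id + sample_id + group,
                          data = measurements, FUN = mean)
  ref <- agg[agg$target_id == reference, , drop = FALSE]
  targets <- setdiff(unique(agg$target_id), reference)
  if (nrow(ref) == 0L) {
    stop("validation error: no ", reference, " measurements present",
         call. = FALSE)
  }
  rows <- lapply(targets, function(tg) {
    t_agg <- agg[agg$target_id == tg, , drop = FALSE]
    ref_idx <- match(t_agg$sample_id, ref$sample_id)
    if (any(is.na(ref_idx))) {
      stop("validation error: missing ", reference, " for sample ",
           t_agg$sample_id[is.na(ref_idx)][1L], call. = FALSE)
    }
    dct <- t_agg$ct - ref$ct[ref_idx]
    mid <- t_agg$group == "mid"; late <- t_agg$group == "late"
    if (!any(mid) || !any(late)) {
      stop("validation error: target ", tg,
           " needs measurements in both groups", call. = FALSE)
    }
    dct_mid <- mean(dct[mid]); dct_late <- mean(dct[late])
    ddct_val <- dct_late - dct_mid
    ratio <- 2^(-ddct_val)
    data.frame(mirna_id = tg,
               delta_ct_mid = dct_mid, delta_ct_late = dct_late,
               sd_delta_ct_mid = stats::sd(dct[mid]),
               sd_delta_ct_late = stats::sd(dct[late]),
               delta_delta_ct = ddct_val, ratio = ratio,
               classification = if (ratio < 1.0) "low" else "high",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mf_log("ddct: %d targets quantified against %s", nrow(out), reference)
  out
}

#' Correlate sequencing-derived and qPCR-derived expression ratios
#'
#' Pearson correlation of `log2(ratio)` over the miRNAs shared by the
#' two ratio maps (Spearman on the raw ratios is available as an
#' option). Requires at least 3 shared miRNAs with finite, positive
#' ratios; the two-sided p-value comes from the t transform of r.
#'
#' @param ngs_ratios Named numeric vector of sequencing late/mid ratios.
#' @param qpcr_ratios Named numeric vector of qPCR 2^-ddCt ratios.
#' @param method `"pearson"` (default, on log2 ratios) or `"spearman"`.
#' @return List with `r`, `p_value`, `n`, and `table` (the paired,
#'   log2-transformed values).
#' @export
ngs_qpcr_correlation <- function(ngs_ratios, qpcr_ratios,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(names(ngs_ratios), names(qpcr_ratios))
  x <- ngs_ratios[shared]; y <- qpcr_ratios[shared]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3L) {
    stop("validation error: fewer than 3 shared finite positive ratios",
         call. = FALSE)
  }
  x <- x[ok]; y <- y[ok]
  tab <- data.frame(mirna_id = shared[ok],
                    log2_ngs = log2(x), log2_qpcr = log2(y),
                    stringsAsFactors = FALSE)
  fit <- if (method == "pearson") {
    stats::cor.test(tab$log2_ngs, tab$log2_qpcr, method = "pearson")
  } else {
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  }
  list(r = unname(fit$estimate), p_value = fit$p.value, n = nrow(tab),
       table = tab)
}
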