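# Two-group differential miRNA expression on normalized values ("norm
# values"): pooled-variance Student t-test on log2(value + epsilon), fold
# change from group means, DEM gate |log2FC| >= 1 and p < 0.05.

#' Two-group test for one miRNA
#'
#' log2FC = log2((mean_A + eps) / (mean_B + eps)); p from a two-sided
#' pooled-variance Student t-test on log2(value + eps) (or a z-test when
#' `variant = "z"`). Degenerate rule: both groups constant and equal gives
#' p = 1; both constant but different gives p = 0 with a degenerate flag.
#'
#' @param values_a,values_b numeric vectors (>= 2 replicates each, values >= 0).
#' @param eps pseudo-value added before log2 (default 1).
#' @param variant "t" (Student, pooled variance) or "z" (normal reference).
#' @return list: log2fc, p_value, mean_a, mean_b, degenerate.
#' @export
test_mirna <- function(values_a, values_b, eps = 1, variant = c("t", "z")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  ma <- mean(values_a); mb <- mean(values_b)
  log2fc <- log2((ma + eps) / (mb + eps))
  la <- log2(values_a + eps); lb <- log2(values_b + eps)
  va <- stats::var(la); vb <- stats::var(lb)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(la), mean(lb)))) {
      p <- 1
    } else {
      p <- 0; degenerate <- TRUE
    }
  } else {
    na <- length(la); nb <- length(lb)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- (mean(la) - mean(lb)) / se
    p <- if (variant == "t") {
      2 * stats::pt(-abs(tstat), df = na + nb - 2)
    } else {
      2 * stats::pnorm(-abs(tstat))
    }
  }
  list(log2fc = log2fc, p_value = p, mean_a = ma, mean_b = mb,
       degenerate = degenerate)
}

#' Differential expression over a normalized matrix
#'
#' Vectorized two-group testing of every row; equivalent to calling
#' [test_mirna()] per miRNA.
#'
#' @param normalized numeric matrix, miRNAs x samples.
#' @param groups named character vector sample -> group (exactly 2 groups);
#'   log2FC is group A relative to group B in `levels` order.
#' @param levels optional character(2) fixing which group is A.
#' @param eps pseudo-value (default 1).
#' @param variant "t" or "z".
#' @return data.frame: mirna, mean_a, mean_b, log2fc, p_value, bh_fdr.
#' @export
de_test <- function(normalized, groups, levels = NULL, eps = 1,
                    variant = c("t", "z")) {
  variant <- match.arg(variant)
  groups <- groups[colnames(normalized)]
  lv <- if (is.null(levels)) sort(unique(groups)) else levels
  if (length(lv) != 2) stop("need exactly 2 groups", call. = FALSE)
  A <- normalized[, groups == lv[1], drop = FALSE]
  B <- normalized[, groups == lv[2], drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop("need >= 2 replicates per group",
                                       call. = FALSE)
  ma <- rowMeans(A); mb <- rowMeans(B)
  log2fc <- log2((ma + eps) / (mb + eps))
  la <- log2(A + eps); lb <- log2(B + eps)
  na <- ncol(A); nb <- ncol(B)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- rowMeans(la) - rowMeans(lb)
  tstat <- diff / se
  p <- if (variant == "t") 2 * stats::pt(-abs(tstat), df = na + nb - 2)
       else 2 * stats::pnorm(-abs(tstat))
  # degenerate rows: zero pooled variance
  zerovar <- se == 0
  p[zerovar & abs(diff) < 1e-12] <- 1
  p[zerovar & abs(diff) >= 1e-12] <- 0
  data.frame(mirna = rownames(normalized), mean_a = ma, mean_b = mb,
             log2fc = log2fc, p_value = p,
             bh_fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag DEMs and summarize a contrast
#'
#' DEM iff |log2FC| >= 1 and p < 0.05 (the BH FDR is exported but does not
#' gate the call).
#'
#' @param results data.frame from [de_test()].
#' @param contrast label for the summary row.
#' @param fc_threshold minimum |log2FC| (inclusive).
#' @param p_threshold p-value cutoff (exclusive).
#' @return list with `results` (plus is_dem, direction) and `summary`
#'   (data.frame: contrast, n_dem, n_up, n_down).
#' @export
call_dems <- function(results, contrast = "A_vs_B", fc_threshold = 1,
                      p_threshold = 0.05) {
  is_dem <- abs(results$log2fc) >= fc_threshold & results$p_value < p_threshold
  direction <- ifelse(!is_dem, "none", ifelse(results$log2fc > 0, "up", "down"))
  results$is_dem <- is_dem
  results$direction <- direction
  summary <- data.frame(contrast = contrast, n_dem = sum(is_dem),
                        n_up = sum(direction == "up"),
                        n_down = sum(direction == "down"),
                        stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}

#' Export a volcano-plot table
#'
#' @param results data.frame from [call_dems()]`$results`.
#' @param path output TSV path.
#' @param cap ceiling for -log10(p) when p = 0 (default 300).
#' @return the exported data.frame, invisibly.
#' @export
export_volcano <- function(results, path, cap = 300) {
  neglog <- -log10(results$p_value)
  neglog[!is.finite(neglog)] <- cap
  out <- data.frame(mirna = results$mirna, log2fc = results$log2fc,
                    neg_log10_p = pmin(neglog, cap), is_dem = results$is_dem,
                    stringsAsFactors = FALSE)
  write_tsv_table(out, path)
  invisible(out)
}

#' Export a heatmap-ready matrix of row-standardized DEM values
#'
#' Rows are z-scored log2(value + eps); constant rows are emitted as zeros
#' and flagged.
#'
#' @param normalized numeric matrix, miRNAs x samples.
#' @param dem_set character vector of DEM ids (may be empty).
#' @param path output TSV path.
#' @param eps pseudo-value.
#' @return the exported data.frame, invisibly.
#' @export
export_heatmap_matrix <- function(normalized, dem_set, path, eps = 1) {
  dem_set <- intersect(dem_set, rownames(normalized))
  m <- log2(normalized[dem_set, , drop = FALSE] + eps)
  z <- t(apply(m, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  constant <- apply(m, 1, function(r) stats::sd(r) == 0)
  out <- data.frame(mirna = dem_set, constant_row = constant,
                    stringsAsFactors = FALSE)
  if (length(dem_set)) {
    for (j in seq_len(ncol(normalized))) out[[colnames(normalized)[j]]] <- z[, j]
  } else {
    for (s in colnames(normalized)) out[[s]] <- numeric(0)
  }
  write_tsv_table(out, path)
  invisible(out)
}
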