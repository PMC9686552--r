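# Two-sample comparisons of milk-composition traits from summary statistics
# (mean +- SD, n) or raw measurements, in the layout of a milk-quality
# comparison table with ** / * significance marks.

#' Two-sample t-test from group summaries
#'
#' @param mean_a,sd_a,n_a first group summary (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b second group summary.
#' @param variant "student" (pooled variance, df = n_a + n_b - 2) or
#'   "welch" (Welch-Satterthwaite df).
#' @return list: t, df, p (two-sided), degenerate flag. Both sds zero with
#'   equal means gives t = 0, p = 1; both zero with different means gives
#'   p = 0 with the degenerate flag set.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(list(t = 0, df = n_a + n_b - 2, p = 1, degenerate = FALSE))
    }
    return(list(t = Inf * sign(mean_a - mean_b), df = n_a + n_b - 2, p = 0,
                degenerate = TRUE))
  }
  if (variant == "student") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p, degenerate = FALSE)
}

significance_mark <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Compare milk-quality traits between two groups
#'
#' @param traits data.frame in summary long format with columns trait,
#'   group, mean, sd, n (every trait must appear for both groups).
#' @param variant "student" or "welch" (see [t_from_summary()]).
#' @return data.frame: trait, group_a, mean_a, sd_a, n_a, group_b, mean_b,
#'   sd_b, n_b, t, df, p_value, significance ("**" p < 0.01, "*" p < 0.05,
#'   "" otherwise).
#' @export
compare_table <- function(traits, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  groups <- sort(unique(traits$group))
  if (length(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  rows <- lapply(unique(traits$trait), function(tr) {
    d <- traits[traits$trait == tr, , drop = FALSE]
    a <- d[d$group == groups[1], , drop = FALSE]
    b <- d[d$group == groups[2], , drop = FALSE]
    if (nrow(a) != 1 || nrow(b) != 1) {
      stop("trait '", tr, "' missing a group", call. = FALSE)
    }
    ts <- t_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n, variant)
    data.frame(trait = tr, group_a = groups[1], mean_a = a$mean, sd_a = a$sd,
               n_a = a$n, group_b = groups[2], mean_b = b$mean, sd_b = b$sd,
               n_b = b$n, t = ts$t, df = ts$df, p_value = ts$p,
               significance = significance_mark(ts$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduce raw long-format measurements to group summaries
#'
#' @param raw data.frame: trait, group, value.
#' @return data.frame: trait, group, mean, sd, n.
#' @export
summarize_raw <- function(raw) {
  agg <- do.call(rbind, lapply(split(raw, list(raw$trait, raw$group),
                                     drop = TRUE), function(d) {
    data.frame(trait = d$trait[1], group = d$group[1], mean = mean(d$value),
               sd = stats::sd(d$value), n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}
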