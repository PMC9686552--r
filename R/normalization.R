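# Median-reference regression normalization of copy numbers.
#
# A common set of sequences (detected in every sample) defines a reference
# vector x = log2(median copies across samples). Per sample, sequences with
# |log2(copies) - x| < 2 (under 4-fold change from the reference) form the
# regression subset; ordinary least squares of y on x gives (a_i, b_i), the
# line is evaluated at the midpoint x_mid of the subset's x-range, and the
# arithmetic correction factor f_i = 2^(x_mid - y_i,mid) rescales the
# sample's copies.

#' Build the common set and median reference
#'
#' @param counts numeric matrix, sequences x samples (rownames required).
#' @param min_copy minimum copies in every sample for common-set membership.
#' @return list with `common` (rownames), `x` (named log2 median reference).
#' @export
build_reference <- function(counts, min_copy = 1) {
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts needs rownames", call. = FALSE)
  common <- rownames(counts)[apply(counts >= min_copy, 1, all)]
  if (length(common) < 3) {
    stop("fewer than 3 common sequences; cannot normalize", call. = FALSE)
  }
  med <- apply(counts[common, , drop = FALSE], 1, stats::median)
  list(common = common, x = stats::setNames(log2(med), common))
}

#' Fit the per-sample regression and correction factor
#'
#' @param y named numeric vector: the sample's log2 copies over the common set.
#' @param x named numeric vector: the log2 median reference (same names).
#' @param delta subset threshold on |y - x| (default 2 = under 4-fold change).
#' @param subset optional fixed regression subset (names); when given, the
#'   |y - x| < delta selection is skipped. Refitting a corrected sample over
#'   its recorded subset returns delta_y = 0 exactly.
#' @return list: subset (names), a, b, x_mid, y_mid, delta_y, f.
#' @export
fit_sample <- function(y, x, delta = 2, subset = NULL) {
  stopifnot(identical(names(y), names(x)))
  if (is.null(subset)) subset <- names(x)[abs(y - x) < delta]
  if (length(subset) < 3) {
    stop("regression subset has fewer than 3 sequences", call. = FALSE)
  }
  xs <- x[subset]; ys <- y[subset]
  if (length(unique(xs)) < 2) {
    stop("degenerate regression subset: all reference values equal", call. = FALSE)
  }
  # closed-form ordinary least squares
  xbar <- mean(xs); ybar <- mean(ys)
  a <- sum((xs - xbar) * (ys - ybar)) / sum((xs - xbar)^2)
  b <- ybar - a * xbar
  x_mid <- (max(xs) + min(xs)) / 2
  y_mid <- a * x_mid + b
  delta_y <- x_mid - y_mid
  list(subset = subset, a = a, b = b, x_mid = x_mid, y_mid = y_mid,
       delta_y = delta_y, f = 2^delta_y)
}

#' Fit the full normalization model
#'
#' @param counts numeric matrix, sequences x samples.
#' @param min_copy common-set threshold (see [build_reference()]).
#' @param delta regression-subset threshold (see [fit_sample()]).
#' @return list of class "mirexo_norm": `reference`, `fits` (per sample),
#'   `factors` (named numeric).
#' @export
fit_normalization <- function(counts, min_copy = 1, delta = 2) {
  ref <- build_reference(counts, min_copy)
  fits <- lapply(colnames(counts), function(s) {
    y <- log2(counts[ref$common, s])
    names(y) <- ref$common
    fit_sample(y, ref$x, delta)
  })
  names(fits) <- colnames(counts)
  out <- list(reference = ref, fits = fits,
              factors = vapply(fits, `[[`, numeric(1), "f"))
  class(out) <- "mirexo_norm"
  out
}

#' Apply a normalization model
#'
#' Entrywise multiplication of each sample's raw copies by its correction
#' factor; zeros stay zero.
#'
#' @param counts numeric matrix, sequences x samples.
#' @param model object from [fit_normalization()] (or a named factor vector).
#' @return numeric matrix of corrected copy numbers ("norm values").
#' @export
apply_normalization <- function(counts, model) {
  f <- if (inherits(model, "mirexo_norm")) model$factors else model
  missing <- setdiff(colnames(counts), names(f))
  if (length(missing)) {
    stop("no correction factor for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, f[colnames(counts)], `*`)
}
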