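#' Pearson product-moment correlation of paired measurements
#'
#' @param x,y paired numeric vectors (n >= 2, nonzero variance).
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) .stopf("undefined-correlation error: need n >= 2")
  if (sd(x) == 0 || sd(y) == 0)
    .stopf("undefined-correlation error: zero variance")
  stats::cor(x, y)
}

#' Intraclass correlation coefficient for two raters/scanners
#'
#' Computed from the two-way ANOVA decomposition of the n x 2 rating table.
#' The default form is ICC(A,1): two-way mixed effects, absolute agreement,
#' single measurement - the stricter cross-scanner claim, appropriate when
#' the scanners are fixed conditions. \code{"C1"} gives ICC(C,1)
#' (consistency), which ignores a systematic offset between arms.
#'
#' With mean squares for rows (subjects), columns (raters) and error,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C -
#'   MS_E)}, \quad ICC(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}}
#'
#' @param x,y measurements of the same n subjects by the two scanners.
#' @param form \code{"A1"} (absolute agreement, default) or \code{"C1"}
#'   (consistency).
#' @return list with \code{icc}, \code{form}, \code{n} and the ANOVA mean
#'   squares (\code{msr}, \code{msc}, \code{mse}).
#' @examples
#' icc(1:10, 1:10)$icc        # exact agreement -> 1
#' icc(1:10, 1:10 + 5, "C1")  # offset invisible to the consistency form
#' @export
icc <- function(x, y, form = c("A1", "C1")) {
  form <- match.arg(form)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) .stopf("ICC needs n >= 2 subjects")
  tab <- cbind(x, y)
  k <- 2L
  grand <- mean(tab)
  rowm <- rowMeans(tab)
  colm <- colMeans(tab)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((tab - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  degenerate <- msr == 0 && msc == 0 && mse == 0
  val <- if (degenerate) {
    warning("degenerate rating table (all values identical); ICC undefined")
    NA_real_
  } else if (form == "A1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(icc = val, form = form, n = n, msr = msr, msc = msc, mse = mse)
}

#' Paired t-test as a one-sample t on differences
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return list with \code{t}, \code{p}, \code{df}, \code{meanDiff} and a
#'   \code{degenerate} flag (TRUE when the differences have zero variance;
#'   then t = 0/p = 1 for identical arms and t = +/-Inf/p = 0 for a
#'   constant nonzero shift).
#' @export
pairedTTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) .stopf("paired t-test needs n >= 2")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t, p = if (md == 0) 1 else 0, df = n - 1L,
                meanDiff = md, degenerate = TRUE))
  }
  t <- md / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1L), df = n - 1L,
       meanDiff = md, degenerate = FALSE)
}

#' Two-scanner reproducibility report
#'
#' One row per measure: per-scanner mean and standard deviation, Pearson
#' correlation and ICC across the paired subjects. Subjects with a missing
#' value in either arm are dropped with a warning.
#'
#' @param lr,hr data.frames of per-subject measures (rows = subjects,
#'   columns = measures) for the low- and high-resolution scanner arms.
#' @param measures measure names to report (default: common columns).
#' @param iccForm ICC form identifier passed to \code{\link{icc}}.
#' @return data.frame with columns measure, lr_mean, lr_sd, hr_mean, hr_sd,
#'   pearson_r, icc, icc_form, n.
#' @export
reproReport <- function(lr, hr, measures = NULL, iccForm = "A1") {
  if (is.null(measures)) measures <- intersect(names(lr), names(hr))
  if (!length(measures))
    return(data.frame(measure = character(0), lr_mean = numeric(0),
                      lr_sd = numeric(0), hr_mean = numeric(0),
                      hr_sd = numeric(0), pearson_r = numeric(0),
                      icc = numeric(0), icc_form = character(0),
                      n = integer(0)))
  stopifnot(nrow(lr) == nrow(hr))
  rows <- lapply(measures, function(m) {
    x <- lr[[m]]; y <- hr[[m]]
    ok <- is.finite(x) & is.finite(y)
    if (any(!ok))
      warning(sum(!ok), " subject(s) dropped for measure '", m,
              "' (missing in one arm)")
    x <- x[ok]; y <- y[ok]
    data.frame(measure = m, lr_mean = mean(x), lr_sd = sd(x),
               hr_mean = mean(y), hr_sd = sd(y),
               pearson_r = pearsonR(x, y),
               icc = icc(x, y, iccForm)$icc, icc_form = iccForm,
               n = length(x))
  })
  do.call(rbind, rows)
}
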