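# Two-tailed statistical battery. Every p-value returned here is two-tailed;
# exact small-sample branches are documented constants (signed-rank n <= 25,
# rank-sum min(n) <= 10) and are checked against enumeration oracles in the
# test suite.

gaze_test <- function(name, statistic, p, df = NA_real_, n = NA_real_,
                      method = "") {
  structure(list(name = name, statistic = statistic,
                 p = min(1, max(0, p)), df = df, n = n, method = method),
            class = "gaze_test")
}

#' @export
print.gaze_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s%s)\n", x$name, x$statistic,
              x$p, x$method,
              if (!is.na(x$df[1])) sprintf(", df = %s", paste(x$df, collapse = ","))
              else sprintf(", n = %s", paste(x$n, collapse = ","))))
  invisible(x)
}

#' @export
as.data.frame.gaze_test <- function(x, ...) {
  data.frame(name = x$name, statistic = x$statistic,
             df = paste(x$df, collapse = ";"), n = paste(x$n, collapse = ";"),
             p = x$p, method = x$method, stringsAsFactors = FALSE)
}

# Exact null distribution of the signed-rank statistic over ranks r (average
# ranks allowed): convolution over sign patterns on the doubled-rank integer
# grid. Returns P(W = w/2) for w = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  v <- 1
  for (r in ranks2) {
    nv <- c(v, numeric(r))
    nv[(r + 1):length(nv)] <- nv[(r + 1):length(nv)] + v
    v <- nv
  }
  v / sum(v)
}

#' Wilcoxon signed-rank test (paired samples, two-tailed)
#'
#' Zero differences are dropped (Wilcoxon's convention); the statistic is
#' the sum of positive-signed ranks. For n <= 25 the two-tailed p comes from
#' the exact sign-enumeration null (computed by convolution, ties handled
#' through average ranks); beyond that, a normal approximation with tie and
#' continuity correction.
#'
#' @param diffs vector of paired differences.
#' @return a `gaze_test`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    null <- signed_rank_null(as.integer(round(2 * r)))
    w2 <- round(2 * W)
    lo <- sum(null[seq_len(w2 + 1)])           # P(W <= w)
    hi <- sum(null[(w2 + 1):length(null)])     # P(W >= w)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact (sign enumeration)"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  gaze_test("Wilcoxon signed-rank", W, p, n = n, method = method)
}

#' Wilcoxon rank-sum test (unpaired samples, two-tailed)
#'
#' Statistic is the Mann-Whitney U of the first sample. With
#' `min(n_a, n_b) <= 10` and no ties the two-tailed p is exact (null
#' distribution of U over all rank assignments); otherwise a normal
#' approximation with tie and continuity correction.
#'
#' @param a,b numeric samples.
#' @return a `gaze_test`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop_("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (min(na, nb) <= 10 && !has_ties) {
    lo <- stats::pwilcox(U, na, nb)
    hi <- 1 - if (U >= 1) stats::pwilcox(U - 1, na, nb) else 0
    p <- min(1, 2 * min(lo, hi))
    method <- "exact (rank-assignment enumeration)"
  } else {
    N <- na + nb
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  gaze_test("Wilcoxon rank-sum", U, p, n = c(na, nb), method = method)
}

#' Pearson chi-squared tests
#'
#' `chi2_proportion()` tests observed successes against a null proportion
#' (df = 1); `chi2_contingency()` tests independence in an r x k count table
#' (df = (r-1)(k-1)). No continuity correction (plain Pearson statistic);
#' the chi-squared test is two-tailed by construction. Expected counts below
#' 1 raise an error advising an exact test.
#'
#' @param successes,n,null_p observed successes, trials and null proportion.
#' @return a `gaze_test`.
#' @export
chi2_proportion <- function(successes, n, null_p = 0.5) {
  if (!is_scalar_number(n) || n <= 0) stop_("n must be positive")
  if (successes < 0 || successes > n) stop_("successes must lie in [0, n]")
  if (!is_probability(null_p)) stop_("null_p must be a probability")
  expected <- c(n * null_p, n * (1 - null_p))
  if (any(expected < 1))
    stop_("expected count below 1: use an exact binomial test instead")
  obs <- c(successes, n - successes)
  stat <- sum((obs - expected)^2 / expected)
  gaze_test("Chi-squared (proportion)", stat,
            stats::pchisq(stat, df = 1, lower.tail = FALSE),
            df = 1, n = n, method = "Pearson chi-squared")
}

#' @rdname chi2_proportion
#' @param counts matrix of counts (r x k).
#' @export
chi2_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1))
    stop_("expected count below 1: use an exact test instead")
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  gaze_test("Chi-squared (contingency)", stat,
            stats::pchisq(stat, df = df, lower.tail = FALSE),
            df = df, n = sum(counts), method = "Pearson chi-squared")
}

#' Factorial ANOVA with type-II sums of squares
#'
#' Fits a 1-3 factor linear model on (possibly unbalanced) cell data and
#' reports an F test per main effect — and per interaction when requested —
#' using type-II sums of squares (each effect adjusted for all others that
#' do not contain it), which are stable for main effects in near-balanced
#' designs.
#'
#' @param values numeric response.
#' @param factors data frame (or named list) of 1-3 factor columns.
#' @param include_interactions include all interaction terms.
#' @return object of class `gaze_anova`: data frame with `effect`,
#'   `sum_sq`, `df`, `F`, `p`, carrying the fitted model as an attribute.
#' @export
anova_factorial <- function(values, factors, include_interactions = FALSE) {
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  if (ncol(factors) < 1 || ncol(factors) > 3)
    stop_("between 1 and 3 factors are supported")
  dat <- data.frame(.y = values, lapply(factors, factor))
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  for (f in names(dat)[-1]) {
    if (nlevels(droplevels(dat[[f]])) < 2)
      stop_("factor '%s' has fewer than 2 observed levels", f)
    dat[[f]] <- droplevels(dat[[f]])
  }
  if (include_interactions && ncol(factors) > 1) {
    cells <- table(dat[names(dat)[-1]])
    if (any(cells == 0)) {
      idx <- which(cells == 0, arr.ind = TRUE)[1, , drop = TRUE]
      cell <- paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                           seq_along(idx), idx), collapse = ":")
      stop_("empty cell '%s' makes the interaction inestimable", cell)
    }
  }
  op <- if (include_interactions) " * " else " + "
  fml <- stats::as.formula(paste(".y ~", paste(names(dat)[-1], collapse = op)))
  fit <- stats::lm(fml, data = dat)
  if (stats::df.residual(fit) < 1)
    stop_("no residual degrees of freedom")
  a2 <- car::Anova(fit, type = 2)
  eff <- rownames(a2)
  resid_row <- eff == "Residuals"
  out <- data.frame(effect = eff[!resid_row],
                    sum_sq = a2$`Sum Sq`[!resid_row],
                    df = a2$Df[!resid_row],
                    F = a2$`F value`[!resid_row],
                    p = a2$`Pr(>F)`[!resid_row],
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "data") <- dat
  attr(out, "formula") <- fml
  attr(out, "df_residual") <- stats::df.residual(fit)
  attr(out, "ss_type") <- "II"
  class(out) <- c("gaze_anova", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons after an ANOVA
#'
#' Studentized-range adjusted p per level pair of one factor of a fitted
#' [anova_factorial()] model. With two groups the adjustment degenerates to
#' the unadjusted t-test p.
#'
#' @param anova_fit a `gaze_anova` object.
#' @param which factor name to compare (default: the first factor).
#' @return data frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(anova_fit, which = NULL) {
  if (!inherits(anova_fit, "gaze_anova"))
    stop_("tukey_hsd requires a fitted anova_factorial() result")
  dat <- attr(anova_fit, "data")
  fml <- attr(anova_fit, "formula")
  av <- stats::aov(fml, data = dat)
  which <- which %||% names(dat)[2]
  if (!which %in% names(dat)[-1]) stop_("unknown factor '%s'", which)
  tk <- stats::TukeyHSD(av, which = which)[[which]]
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment r; p from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return a `gaze_test` with the estimate in `statistic`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  gaze_test("Pearson correlation", unname(ct$estimate), ct$p.value,
            df = unname(ct$parameter), n = length(x),
            method = "t transform, two-tailed")
}
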