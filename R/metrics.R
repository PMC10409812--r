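#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) abort("counts must be non-negative integers")
  if (sum(v) == 0) abort("at least one count must be positive")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from two binary label vectors
#' @param pred,truth logical (or 0/1) vectors of equal length.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_labels <- function(pred, truth) {
  confusion_counts(tp = sum(pred & truth), fp = sum(pred & !truth),
                   fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Classifier performance metrics
#'
#' Sensitivity, specificity, precision and accuracy from a confusion table.
#' A metric with a zero denominator is reported as `NA` (undefined), never 0.
#'
#' @param c a [confusion_counts()].
#' @return A tibble with one row: `sensitivity`, `specificity`, `precision`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(c) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  with(c, tibble(
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    precision = rat(tp, tp + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  ))
}

#' Cohen's kappa with Landis-Koch interpretation
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed accuracy and `p_e` the chance agreement implied by the
#' marginals. The verbal label follows the Landis-Koch bands (upper edges
#' inclusive): < 0 poor, 0-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect.
#'
#' @param c a [confusion_counts()].
#' @return A list of class `kappa_result` with `kappa` and
#'   `landis_koch_label`; `kappa` is `NA` for degenerate single-class
#'   marginals (`p_e = 1`).
#' @export
cohens_kappa <- function(c) {
  n <- with(c, tp + fp + fn + tn)
  p_o <- with(c, (tp + tn) / n)
  p_e <- with(c, ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2)
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, landis_koch_label = landis_koch(kappa),
                 p_o = p_o, p_e = p_e),
            class = "kappa_result")
}

#' Landis-Koch verbal label for a kappa value
#' @param kappa agreement coefficient in `[-1, 1]`.
#' @return one of poor, slight, fair, moderate, substantial, almost_perfect.
#' @export
landis_koch <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost_perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%s)\n", x$kappa, x$landis_koch_label))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties). The
#' two-sided p-value uses the t approximation for n > 9 and exact permutation
#' enumeration for n <= 9.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A tibble with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input: Spearman correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (n <= 9) {
    # permuting x's ranks only changes the cross term; vectorise over all n!
    perms <- permutations_of(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    cross <- matrix(rxc[perms], nrow(perms), n) %*% ryc
    rs <- as.vector(cross) / denom
    p <- mean(abs(rs) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Rank-sum comparison with effect size
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test using the normal
#' approximation with tie correction, plus Cohen's d with pooled standard
#' deviation.
#'
#' @param a,b numeric samples.
#' @return A tibble with `u_statistic` (for sample `a`), `z`, `p_value`,
#'   `cohens_d`, `n_a`, `n_b`.
#' @export
ranksum_and_effect <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  z <- if (sigma > 0) (u - mu) / sigma else 0
  p <- if (sigma > 0) 2 * pnorm(-abs(z)) else 1
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) /
               max(1, n1 + n2 - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  tibble(u_statistic = u, z = z, p_value = p, cohens_d = d,
         n_a = n1, n_b = n2)
}
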