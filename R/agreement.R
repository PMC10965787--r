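#' @name agreement
#' @title Inter-rater reliability estimators
#'
#' @description
#' Two estimators validate the automated scores against human raters (and
#' the raters against each other):
#'
#' * [weighted_kappa()] — chance-corrected agreement on the ordered
#'   categories negative < neutral < positive, with unweighted, linear or
#'   quadratic disagreement weights and a large-sample (Fleiss–Cohen–
#'   Everitt) confidence interval;
#' * [icc_a1()] — the intraclass correlation ICC(A,1): two-way model,
#'   absolute agreement, single measure, estimated from ANOVA mean squares
#'   with the McGraw–Wong F-based confidence interval.
#'
#' Both return an `"agreement_estimate"` carrying the point estimate, CI,
#' and a conventional verbal interpretation (Landis–Koch bands for kappa,
#' Koo–Li bands for the ICC).
NULL

landis_koch <- function(k) {
  if (is.na(k)) NA_character_
  else if (k < 0) "none"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

koo_li <- function(r) {
  if (is.na(r)) NA_character_
  else if (r < 0.50) "poor"
  else if (r <= 0.75) "moderate"
  else if (r <= 0.90) "good"
  else "excellent"
}

agreement_estimate <- function(kind, estimate, ci_lo, ci_hi, alpha, n_pairs,
                               interpretation, se = NA_real_,
                               f_value = NA_real_, df1 = NA_integer_,
                               df2 = NA_integer_, p_value = NA_real_) {
  structure(list(kind = kind, estimate = estimate, ci_lo = ci_lo,
                 ci_hi = ci_hi, alpha = alpha, se = se, f_value = f_value,
                 df1 = df1, df2 = df2, p_value = p_value, n_pairs = n_pairs,
                 interpretation = interpretation),
            class = "agreement_estimate")
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("<agreement_estimate> %s = %.3f, %d%% CI [%.3f, %.3f], n = %d (%s)\n",
              x$kind, x$estimate, round(100 * (1 - x$alpha)), x$ci_lo, x$ci_hi,
              x$n_pairs, x$interpretation))
  if (is.finite(x$f_value))
    cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df1, x$df2, x$f_value,
                x$p_value))
  invisible(x)
}

#' Cross-tabulate two raters' categories
#'
#' Builds the 3x3 contingency table over negative/neutral/positive for the
#' record ids categorized by *both* raters (pairwise-complete). Rows are
#' rater A, columns rater B.
#'
#' @param catsA,catsB Named vectors/factors of categories (names = record
#'   ids; NAs dropped).
#' @return A matrix of class `"sentiment_xtab"` with attribute `n`.
#' @export
build_table <- function(catsA, catsB) {
  a <- stats::setNames(as.character(catsA), names(catsA))
  b <- stats::setNames(as.character(catsB), names(catsB))
  ids <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (!length(ids)) stop_data("no records categorized by both raters")
  tab <- table(factor(a[ids], levels = sentiment_levels),
               factor(b[ids], levels = sentiment_levels))
  m <- unclass(as.matrix(tab))
  dimnames(m) <- list(raterA = sentiment_levels, raterB = sentiment_levels)
  structure(m, n = sum(m), class = c("sentiment_xtab", "matrix"))
}

#' Render a contingency table with percentages
#'
#' Inner cells carry column percentages (of the column rater's category
#' total); row and column margins carry percentages of the grand total.
#' Percentages are rounded half-up to one decimal.
#'
#' @param tab A `"sentiment_xtab"` (or plain 3x3 count matrix).
#' @return A character matrix ready for printing.
#' @export
xtab_percent <- function(tab) {
  m <- unclass(tab)[seq_len(nrow(tab)), seq_len(ncol(tab)), drop = FALSE]
  n <- sum(m)
  colt <- colSums(m); rowt <- rowSums(m)
  cells <- matrix("", nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m)))
    cells[i, j] <- if (colt[j] > 0) fmt_count_pct(m[i, j], colt[j])
                   else sprintf("%d (-)", m[i, j])
  out <- rbind(cbind(cells, Total = vapply(seq_len(nrow(m)), function(i)
                 fmt_count_pct(rowt[i], n), "")),
               Total = c(vapply(seq_len(ncol(m)), function(j)
                 fmt_count_pct(colt[j], n), ""), as.character(n)))
  dimnames(out) <- list(c(rownames(tab), "Total"), c(colnames(tab), "Total"))
  out
}

#' @export
print.sentiment_xtab <- function(x, ...) {
  cat(sprintf("<sentiment_xtab> n = %d (rows rater A, cols rater B; cells = column %%)\n",
              attr(x, "n")))
  print(xtab_percent(x), quote = FALSE)
  invisible(x)
}

kappa_weight_matrix <- function(C, weights) {
  i <- 0:(C - 1)
  switch(weights,
         unweighted = diag(C) * 1,
         linear = 1 - abs(outer(i, i, "-")) / (C - 1),
         quadratic = 1 - (outer(i, i, "-") / (C - 1))^2)
}

#' Weighted Cohen's kappa with large-sample confidence interval
#'
#' Computes kappa = (Po_w - Pe_w) / (1 - Pe_w) with agreement weights
#' w_ij = 1 (unweighted, i = j), 1 - |i-j|/(C-1) (linear) or
#' 1 - ((i-j)/(C-1))^2 (quadratic) over the ordered categories. Expected
#' agreement comes from the marginal products. The default CI is the
#' asymptotic Fleiss–Cohen–Everitt standard error with a normal quantile;
#' a nonparametric bootstrap over subjects is available as an alternative.
#'
#' @param tab A square count matrix (e.g. from [build_table()]).
#' @param weights `"linear"` (default), `"unweighted"` or `"quadratic"`.
#' @param alpha CI level is `1 - alpha`.
#' @param ci `"asymptotic"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap CI only).
#' @return An `"agreement_estimate"` with Landis–Koch interpretation.
#' @examples
#' tab <- matrix(c(106, 14, 5, 14, 43, 4, 7, 13, 57), 3, byrow = TRUE)
#' weighted_kappa(tab, "linear")
#' @export
weighted_kappa <- function(tab, weights = c("linear", "unweighted", "quadratic"),
                           alpha = 0.05, ci = c("asymptotic", "bootstrap"),
                           n_boot = 1000L) {
  weights <- match.arg(weights)
  ci <- match.arg(ci)
  m <- unclass(as.matrix(tab))
  if (nrow(m) != ncol(m)) stop_data("kappa needs a square table")
  n <- sum(m)
  if (n < 2) stop_data("kappa needs at least 2 paired observations")
  C <- nrow(m)
  w <- kappa_weight_matrix(C, weights)
  p <- m / n
  pi. <- rowSums(p); p.j <- colSums(p)
  Po <- sum(w * p)
  Pe <- sum(w * outer(pi., p.j))
  if (1 - Pe < .Machine$double.eps^0.5)
    stop_data("degenerate marginals: expected agreement is 1")
  k <- (Po - Pe) / (1 - Pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance of weighted kappa
  wbar_i <- as.vector(w %*% p.j)
  wbar_j <- as.vector(t(w) %*% pi.)
  M <- outer(wbar_i, wbar_j, "+")
  v <- (sum(p * (w - M * (1 - k))^2) - (k - Pe * (1 - k))^2) / (n * (1 - Pe)^2)
  se <- sqrt(max(v, 0))
  if (ci == "asymptotic") {
    z <- stats::qnorm(1 - alpha / 2)
    lo <- max(-1, k - z * se); hi <- min(1, k + z * se)
  } else {
    # resample subjects: cells follow a multinomial over the 9 cells
    cells <- as.vector(m)
    reps <- vapply(seq_len(n_boot), function(b) {
      mb <- matrix(stats::rmultinom(1, n, cells / n), C, C)
      pb <- mb / n
      Pob <- sum(w * pb)
      Peb <- sum(w * outer(rowSums(pb), colSums(pb)))
      if (1 - Peb < 1e-12) NA_real_ else (Pob - Peb) / (1 - Peb)
    }, 0)
    qs <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
    lo <- qs[[1]]; hi <- qs[[2]]
  }
  agreement_estimate(paste0("kappa_", weights), k, lo, hi, alpha,
                     n_pairs = n, interpretation = landis_koch(k), se = se)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, absolute agreement, single measure: with n subjects and
#' k raters, from the two-way ANOVA mean squares (rows = subjects MSR,
#' columns = raters MSC, residual MSE):
#'
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#'
#' The significance test is `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of
#' freedom; the CI uses the McGraw–Wong (1996) F-based method. Rows with a
#' missing value are dropped first (pairwise deletion).
#'
#' @param x An n x k numeric matrix (k >= 2 raters; typically k = 2), or a
#'   vector paired with `y`.
#' @param y Optional second score vector (then `x` is the first).
#' @param alpha CI level is `1 - alpha`.
#' @return An `"agreement_estimate"` with Koo–Li interpretation.
#' @examples
#' icc_a1(matrix(c(1, 2, 2, 3, 3, 4, 4, 5), ncol = 2, byrow = TRUE))
#' @export
icc_a1 <- function(x, y = NULL, alpha = 0.05) {
  if (!is.null(y)) x <- cbind(x, y)
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop_data("ICC needs at least 2 raters (columns)")
  if (n < 3) stop_data("ICC needs at least 3 complete pairs")
  gm <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  SSR <- k * sum((ri - gm)^2)
  SSC <- n * sum((cj - gm)^2)
  SSE <- sum((x - gm)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- max(SSE, 0) / ((n - 1) * (k - 1))
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0)
    stop_data("ICC undefined: no variance in the scores")
  est <- (MSR - MSE) / denom
  fv <- if (MSE > 0) MSR / MSE else Inf
  pv <- if (is.finite(fv)) stats::pf(fv, df1, df2, lower.tail = FALSE) else 0
  if (MSE == 0 && MSC == 0) {
    # identical columns: exact agreement
    lo <- hi <- est
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) { # est == 1 with noise-free columns
      lo <- hi <- est
    } else {
      vv <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      if (!is.finite(vv) || vv <= 0) {
        # Satterthwaite df degenerate (negative-estimate cancellation);
        # fall back to the uninformative bounds of the parameter space
        lo <- -1; hi <- 1
      } else {
        FL <- stats::qf(1 - alpha / 2, n - 1, vv)
        FU <- stats::qf(1 - alpha / 2, vv, n - 1)
        lo <- n * (MSR - FL * MSE) /
          (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
        hi <- n * (FU * MSR - MSE) /
          (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      }
    }
  }
  # guard the degenerate corners (tiny Satterthwaite df drives qf to Inf):
  # fall back to the parameter-space bound and keep lo <= est <= hi
  if (!is.finite(lo)) lo <- -1
  if (!is.finite(hi)) hi <- 1
  lo <- min(lo, est); hi <- max(hi, est)
  out <- agreement_estimate("icc_a1", est, lo, hi, alpha, n_pairs = n,
                            interpretation = koo_li(est), f_value = fv,
                            df1 = df1, df2 = df2, p_value = pv)
  out$ms <- c(MSR = MSR, MSC = MSC, MSE = MSE)
  out
}

#' Per-patient ICC between two continuous score series
#'
#' Restricts each ICC(A,1) to one patient's jointly available records.
#' Patients with fewer than `min_pairs` complete pairs are skipped with a
#' warning (their row carries NAs).
#'
#' @param df Data.frame with columns `patient_id`, `x`, `y` (one row per
#'   record; either score may be NA).
#' @param alpha CI level is `1 - alpha`.
#' @param min_pairs Minimum complete pairs per patient (default 3).
#' @return Data.frame: patient_id, n_pairs, estimate, ci_lo, ci_hi, f_value,
#'   df1, df2, p_value, interpretation.
#' @export
per_patient_icc <- function(df, alpha = 0.05, min_pairs = 3L) {
  stopifnot(all(c("patient_id", "x", "y") %in% names(df)))
  rows <- lapply(split(df, df$patient_id), function(d) {
    ok <- stats::complete.cases(d[c("x", "y")])
    np <- sum(ok)
    if (np < min_pairs) {
      warning("patient ", d$patient_id[1], ": only ", np,
              " complete pairs, ICC skipped", call. = FALSE)
      return(data.frame(patient_id = d$patient_id[1], n_pairs = np,
                        estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        f_value = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                        p_value = NA_real_, interpretation = NA_character_))
    }
    e <- icc_a1(d$x[ok], d$y[ok], alpha = alpha)
    data.frame(patient_id = d$patient_id[1], n_pairs = np,
               estimate = e$estimate, ci_lo = e$ci_lo, ci_hi = e$ci_hi,
               f_value = e$f_value, df1 = e$df1, df2 = e$df2,
               p_value = e$p_value, interpretation = e$interpretation)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
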