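# Two-group differential protein expression: per-protein linear contrast
# (tumor minus healthy), empirical-Bayes variance moderation via a scaled
# inverse-chi-square prior fitted by method of moments on log-variances,
# moderated t-statistics and Benjamini-Hochberg FDR control.

#' Per-protein two-group fit
#'
#' @param m a complete [expression_matrix()] with tumor/healthy labels and
#'   at least two samples per group.
#' @return data.frame with columns `protein`, `lfc` (mean tumor - mean
#'   healthy, log2 units), `s2` (pooled within-group variance) and
#'   attribute `df_resid` = n_tumor + n_healthy - 2.
#' @export
fit_two_group <- function(m) {
  if (anyNA(m$values)) stop("matrix has missing values; impute first")
  tum <- samples_in_group(m, "tumor")
  hea <- samples_in_group(m, "healthy")
  n1 <- length(tum); n2 <- length(hea)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 samples per group (got ", n1, " tumor, ",
         n2, " healthy)")
  xt <- m$values[, tum, drop = FALSE]
  xh <- m$values[, hea, drop = FALSE]
  mt <- rowMeans(xt); mh <- rowMeans(xh)
  ss_t <- rowSums((xt - mt)^2)
  ss_h <- rowSums((xh - mh)^2)
  s2 <- (ss_t + ss_h) / (n1 + n2 - 2)
  out <- data.frame(protein = rownames(m$values), lfc = mt - mh, s2 = s2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_resid") <- n1 + n2 - 2
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

# Inverse of the trigamma function by Newton iteration on 1/y (monotone,
# well-conditioned); used to solve for the prior degrees of freedom.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (it in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Estimate variance-moderation hyperparameters
#'
#' Fits the prior degrees of freedom d0 and prior variance s0^2 of a
#' scaled inverse-chi-square prior on the true residual variances, by
#' method of moments on e = log(s2) - digamma(df/2) + log(df/2):
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the empirical
#' spread of log-variances does not exceed its sampling expectation, d0 is
#' infinite (all variances shrunk fully to s0^2).
#'
#' @param s2 vector of sample variances (>= 10 positive values required).
#' @param df_resid residual degrees of freedom of each `s2`.
#' @return object of class `ebayes_hyper`: list with `d0` and `s0_sq`.
#' @export
estimate_hyperparams <- function(s2, df_resid) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10)
    stop("need at least 10 positive sample variances to estimate the prior; ",
         "supply more proteins")
  e <- log(s2[ok]) - digamma(df_resid / 2) + log(df_resid / 2)
  evar <- var(e)
  excess <- evar - trigamma(df_resid / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_hyper")
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each protein's variance toward the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + df \cdot s^2)/(d_0 + df)}, and tests
#' `lfc` with \eqn{t = lfc / (\tilde s \sqrt{1/n_1 + 1/n_2})} on
#' \eqn{d_0 + df} degrees of freedom (normal when d0 is infinite).
#' Two-sided p-values.
#'
#' @param lfc,s2 per-protein effect and sample variance.
#' @param df_resid residual degrees of freedom.
#' @param hyper an `ebayes_hyper` from [estimate_hyperparams()].
#' @param n1,n2 group sizes.
#' @return data.frame with columns `t_mod` and `p`.
#' @export
moderated_t <- function(lfc, s2, df_resid, hyper, n1, n2) {
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + df_resid
  t_mod <- lfc / se
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " protein(s) with zero posterior variance; p set to 0")
    t_mod[degen] <- sign(lfc[degen]) * Inf
  }
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod))
       else 2 * pt(-abs(t_mod), df = df_total)
  p[degen] <- 0
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted q-values (monotone in the ranks of `p`, <= 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full differential-expression analysis
#'
#' Runs [fit_two_group()], [estimate_hyperparams()], [moderated_t()] and
#' [bh_adjust()] and assigns each protein an expression sign:
#' +1 (overexpressed in tumors) when `lfc >= 0` — an `lfc` of exactly 0
#' maps to +1 by convention so the label set stays binary — and -1
#' (underexpressed) otherwise.
#'
#' @param m a complete [expression_matrix()] with group labels.
#' @return data.frame of class `de_result`: `protein`, `lfc`, `s2`,
#'   `t_mod`, `p`, `q`, `sign`; hyperparameters in attribute `hyper`.
#' @export
de_analysis <- function(m) {
  fit <- fit_two_group(m)
  df_resid <- attr(fit, "df_resid")
  hyper <- estimate_hyperparams(fit$s2, df_resid)
  mt <- moderated_t(fit$lfc, fit$s2, df_resid, hyper,
                    attr(fit, "n1"), attr(fit, "n2"))
  out <- data.frame(protein = fit$protein, lfc = fit$lfc, s2 = fit$s2,
                    t_mod = mt$t_mod, p = mt$p, q = bh_adjust(mt$p),
                    sign = ifelse(fit$lfc >= 0, 1L, -1L),
                    stringsAsFactors = FALSE)
  attr(out, "hyper") <- hyper
  attr(out, "df_resid") <- df_resid
  class(out) <- c("de_result", "data.frame")
  out
}
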