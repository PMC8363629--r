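#' Liability-threshold model for score-based discrimination
#'
#' Defines the generative model used by all prediction metrics: a standard
#' normal liability `L = G + E` with `G ~ N(0, v)` the polygenic score (the
#' variance in liability it explains) and `E ~ N(0, 1 - v)`; "case" status is
#' `L > T` with `T = qnorm(1 - K)` set by the prevalence `K`. In the
#' two-disorder (differential-diagnosis) setting every subject has exactly
#' one of the disorders, so `K = K_case / (K_case + K_control)` and the
#' non-case risk at any score is one minus the case risk.
#'
#' @param K Prevalence of the "case" state, in (0, 1).
#' @param v Variance in liability explained by the score, in \[0, 1\].
#' @return An object of class `liability_model` (list with `K`, `v`, `T`).
#' @export
liability_model <- function(K, v) {
  assert_prob(K, "K")
  if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
    abort("`v` must be a single number in [0, 1]")
  }
  structure(list(K = K, v = v, T = qnorm(1 - K)), class = "liability_model")
}

# risk of the case state given score g
.risk_at <- function(model, g) {
  if (model$v >= 1) return(as.numeric(g > model$T))
  pnorm((g - model$T) / sqrt(1 - model$v))
}

# dense score grid with case/control densities (normalized by K, 1-K)
.model_grid <- function(model, n_grid = 20001L, width = 8.5) {
  v <- model$v
  s <- sqrt(max(v, 1e-12))
  g <- seq(-width * s, width * s, length.out = n_grid)
  dg <- g[2] - g[1]
  fg <- dnorm(g, 0, s)
  risk <- .risk_at(model, g)
  list(g = g, dg = dg, fg = fg, risk = risk,
       fcase = risk * fg / model$K,
       fctrl = (1 - risk) * fg / (1 - model$K))
}

trapz <- function(y, dg) dg * (sum(y) - (y[1] + y[length(y)]) / 2)

#' Maximum achievable AUC for distinguishing two disorders
#'
#' The probability that a randomly chosen subject with the first ("case")
#' disorder has a higher polygenic score than one with the second disorder,
#' when the score explains `h2_liab` of the liability of the differential
#' trait. Conditioning on having exactly one of the disorders gives the
#' prevalence `K = K_case / (K_case + K_control)`; the case and control
#' score densities are `f(g | case) = risk(g) * dnorm(g, 0, sqrt(v)) / K` and
#' its complement, and the AUC is computed by numerical integration of
#' `P(G_case > G_control)`. With `h2_liab` set to the SNP heritability of the
#' differential trait this is the maximum discrimination a genome-wide score
#' could achieve.
#'
#' @param h2_liab Liability-scale variance explained, in \[0, 1\].
#' @param K_case,K_control Lifetime prevalences of the two disorders.
#' @param method `"integrate"` (default, numerical) or `"closed_form"` (the
#'   normal approximation `pnorm((i - i') v / sqrt(v[(1 - v i (i - T)) +
#'   (1 - v i'(i' - T))]))` with `i = dnorm(T)/K`, `i' = -K i/(1 - K)`).
#' @return The AUC, in \[0.5, 1\].
#' @examples
#' max_auc(0.183, K_case = 0.005, K_control = 0.13) # ~0.76
#' @export
max_auc <- function(h2_liab, K_case, K_control, method = c("integrate", "closed_form")) {
  method <- match.arg(method)
  assert_prob(K_case, "K_case"); assert_prob(K_control, "K_control")
  if (h2_liab < 0 || h2_liab > 1) abort("`h2_liab` must lie in [0, 1]")
  if (h2_liab == 0) return(0.5)
  if (h2_liab >= 1) {
    warn("max_auc: v = 1 returns the limit 1")
    return(1)
  }
  model <- liability_model(K_case / (K_case + K_control), h2_liab)
  if (method == "closed_form") closed_form_auc(model) else auc_liability(model)
}

# numerical AUC = \int F_control(g) f_case(g) dg on a dense grid
auc_liability <- function(model) {
  if (model$v <= 0) return(0.5)
  gr <- .model_grid(model)
  # renormalize to guard against grid truncation
  fcase <- gr$fcase / trapz(gr$fcase, gr$dg)
  fctrl <- gr$fctrl / trapz(gr$fctrl, gr$dg)
  Fctrl <- cumsum(fctrl) * gr$dg - fctrl * gr$dg / 2
  min(1, max(0.5, trapz(Fctrl * fcase, gr$dg)))
}

closed_form_auc <- function(model) {
  K <- model$K; v <- model$v; T_ <- model$T
  i <- dnorm(T_) / K
  i2 <- -i * K / (1 - K)
  pnorm((i - i2) * v / sqrt(v * ((1 - v * i * (i - T_)) + (1 - v * i2 * (i2 - T_)))))
}

#' Variance explained that yields a target AUC
#'
#' Inverse of [max_auc()] at fixed prevalence: bisection on the liability
#' variance explained until the integrated AUC matches `target_auc` within
#' `tol`. Used to build risk profiles from a published polygenic-score AUC.
#'
#' @param target_auc AUC in \[0.5, 1).
#' @param K Prevalence of the case state (already conditioned, i.e.
#'   `K_case / (K_case + K_control)` in the two-disorder setting).
#' @param tol Convergence tolerance on the AUC (default 1e-6).
#' @return The liability variance explained `v`.
#' @export
invert_auc <- function(target_auc, K, tol = 1e-6) {
  if (target_auc < 0.5 || target_auc >= 1) abort("`target_auc` must lie in [0.5, 1)")
  if (target_auc == 0.5) return(0)
  lo <- 0; hi <- 1 - 1e-9
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    a <- auc_liability(liability_model(K, mid))
    if (abs(a - target_auc) < tol) return(mid)
    if (a < target_auc) lo <- mid else hi <- mid
  }
  mid
}

#' Risk profile of a liability-threshold score
#'
#' Absolute risk of each disorder along the score distribution, relative
#' risks comparing top versus bottom percentiles, the variance of predicted
#' risk, the proportion of cases among the top k% of scores, and sampled ROC
#' and predictiveness curves. At population-score percentile `q` the score is
#' `g_q = sqrt(v) * qnorm(q)` and the case-disorder risk is
#' `pnorm((g_q - T) / sqrt(1 - v))`; in the two-disorder setting the other
#' disorder's risk is its complement.
#'
#' @param model A [liability_model()].
#' @param percentiles Percentiles (in %) at which absolute risks are
#'   reported.
#' @param top_bottom_x Values of x for the top-x% versus bottom-x% relative
#'   risks.
#' @param top_k Values of k for the proportion-of-cases-in-top-k% table.
#' @param rr_mode `"point"` (default) compares risks at the two percentile
#'   points; `"bin"` compares mean risks within the top and bottom x% bins.
#' @param n_curve Number of points sampled for the ROC and predictiveness
#'   curves.
#' @return An object of class `ddx_risk_profile`: a list with `auc`,
#'   `percentile_risk`, `rr_top_bottom`, `var_predicted_risk`,
#'   `cases_in_top_k`, `roc_points`, `predictiveness_points`, and the model.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
risk_profile <- function(model, percentiles = c(1, 5, 10, 20, 30, 50, 70, 80, 90, 95, 99),
                         top_bottom_x = c(5, 10, 20, 30), top_k = c(1, 5, 10, 20),
                         rr_mode = c("point", "bin"), n_curve = 201L) {
  stopifnot(inherits(model, "liability_model"))
  rr_mode <- match.arg(rr_mode)
  v <- model$v; K <- model$K
  s <- sqrt(v) # exactly 0 when the score is uninformative

  risk_point <- function(q) .risk_at(model, s * qnorm(q))
  gr <- .model_grid(model)

  # mean risk within a score-quantile interval (for bin-mode RRs)
  risk_bin <- function(qlo, qhi) {
    glo <- s * qnorm(qlo); ghi <- s * qnorm(qhi)
    keep <- gr$g >= glo & gr$g <= ghi
    trapz((gr$risk * gr$fg)[keep], gr$dg) / trapz(gr$fg[keep], gr$dg)
  }

  perc <- tibble(
    percentile = percentiles,
    score = s * qnorm(percentiles / 100),
    risk_case = risk_point(percentiles / 100),
    risk_control = 1 - risk_point(percentiles / 100)
  )

  rr <- tibble(
    x = top_bottom_x,
    rr = vapply(top_bottom_x, function(x) {
      if (v == 0) return(1)
      if (rr_mode == "point") {
        risk_point(1 - x / 100) / risk_point(x / 100)
      } else {
        risk_bin(1 - x / 100, 1 - 1e-9) / risk_bin(1e-9, x / 100)
      }
    }, numeric(1)),
    mode = rr_mode
  )

  e_risk <- trapz(gr$risk * gr$fg, gr$dg)
  var_pred <- trapz((gr$risk - e_risk)^2 * gr$fg, gr$dg)

  topk <- tibble(
    k = top_k,
    prop_cases = vapply(top_k, function(k) {
      gk <- s * qnorm(1 - k / 100)
      keep <- gr$g >= gk
      trapz((gr$risk * gr$fg)[keep], gr$dg) / K
    }, numeric(1))
  )

  qs <- seq(1e-4, 1 - 1e-4, length.out = n_curve)
  thr <- s * qnorm(qs)
  surv_case <- vapply(thr, function(t) {
    keep <- gr$g >= t
    trapz(gr$fcase[keep], gr$dg)
  }, numeric(1))
  surv_ctrl <- vapply(thr, function(t) {
    keep <- gr$g >= t
    trapz(gr$fctrl[keep], gr$dg)
  }, numeric(1))
  roc <- tibble(fpr = c(1, pmin(1, surv_ctrl), 0),
                tpr = c(1, pmin(1, surv_case), 0))
  predictiveness <- tibble(quantile = qs, risk = risk_point(qs))

  structure(list(
    model = model,
    auc = auc_liability(model),
    percentile_risk = perc,
    rr_top_bottom = rr,
    var_predicted_risk = var_pred,
    mean_risk = e_risk,
    cases_in_top_k = topk,
    roc_points = roc,
    predictiveness_points = predictiveness
  ), class = "ddx_risk_profile")
}

#' Prevalence-based prior for the two-disorder differential diagnosis
#'
#' Before any genetic information, a subject known to have exactly one of the
#' two disorders has probability `K_case / (K_case + K_control)` of having
#' the first, and the relative risk of the second versus the first is the
#' prevalence ratio `K_control / K_case`.
#'
#' @param K_case,K_control Lifetime prevalences of the two disorders.
#' @return A one-row tibble with `prior_prob_case` and
#'   `prior_rr_control_vs_case`.
#' @examples
#' ddx_prior(0.005, 0.13) # prior RR 26
#' @export
ddx_prior <- function(K_case, K_control) {
  assert_prob(K_case, "K_case"); assert_prob(K_control, "K_control")
  tibble(prior_prob_case = K_case / (K_case + K_control),
         prior_rr_control_vs_case = K_control / K_case)
}

#' @method tidy ddx_risk_profile
#' @export
tidy.ddx_risk_profile <- function(x, ...) {
  x$percentile_risk
}

#' @method glance ddx_risk_profile
#' @export
glance.ddx_risk_profile <- function(x, ...) {
  tibble(auc = x$auc, K = x$model$K, v = x$model$v,
         var_predicted_risk = x$var_predicted_risk, mean_risk = x$mean_risk)
}

#' @export
print.ddx_risk_profile <- function(x, ...) {
  cat(sprintf("Liability-threshold risk profile (K = %.4g, v = %.4g)\n",
              x$model$K, x$model$v))
  cat(sprintf("  AUC = %.4f, var(predicted risk) = %.4g\n", x$auc, x$var_predicted_risk))
  cat("  RR top vs bottom percentiles:\n")
  print(as.data.frame(x$rr_top_bottom), row.names = FALSE)
  invisible(x)
}
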