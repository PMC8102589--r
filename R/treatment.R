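#' Colony-level comparison of removal treatments
#'
#' Tests whether a tandem performance metric differs between the four
#' targeted-removal treatments, using colony-level mixed models with a
#' random intercept for replicate.  The `success_rate` response is modelled
#' as a binomial GLMM on the per-colony success/failure counts with a logit
#' link; `mean_sld` and `mean_time` as Gaussian LMMs on the colony means
#' (maximum likelihood).  The treatment effect is assessed with a
#' likelihood-ratio chi-square against the intercept-only model, and all
#' pairwise contrasts between treatments are computed from the estimated
#' marginal means with Benjamini-Hochberg correction; compact letter
#' displays group treatments that do not differ.
#'
#' Degenerate inputs are handled by falling back: if the mixed model cannot
#' be fitted (e.g. a constant response), the fixed-effects model
#' (`glm`/`lm`) is used; if the marginal-means machinery fails on an exactly
#' singular fit, contrasts are computed directly from the fixed-effect
#' coefficients and their covariance.
#'
#' @param summaries a [summarize_performance()] data frame with `treatment`
#'   and `replicate_id` columns.
#' @param response `"success_rate"`, `"mean_sld"` or `"mean_time"`.
#' @return An object of class `treatment_analysis`: `chisq`, `df`,
#'   `p_value`, `contrasts` (estimate, SE, z/t, BH-adjusted p per pair),
#'   `letters`, `low_power` (treatments with a single colony) and the
#'   fitted model.
#' @export
colony_treatment_analysis <- function(summaries,
                                      response = c("success_rate",
                                                   "mean_sld", "mean_time")) {
  response <- match.arg(response)
  d <- as.data.frame(summaries)
  d <- d[!is.na(d$treatment), , drop = FALSE]
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  d$treatment <- factor(d$treatment)
  if (nlevels(d$treatment) < 2)
    stop("need at least 2 treatments with data")
  tab <- table(d$treatment)
  low_power <- names(tab)[tab < 2]
  if (length(low_power))
    warning("treatment(s) with a single colony: ",
            paste(low_power, collapse = ", "),
            " (contrasts computed but low-powered)")
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  try_fit <- function(mixed, fixed) {
    f <- tryCatch(quiet(mixed), error = function(e) NULL)
    if (is.null(f)) quiet(fixed) else f
  }
  if (response == "success_rate") {
    d$n_fail <- d$n_tandems - d$n_success
    full <- try_fit(
      lme4::glmer(cbind(n_success, n_fail) ~ treatment + (1 | replicate_id),
                  data = d, family = stats::binomial("logit")),
      stats::glm(cbind(n_success, n_fail) ~ treatment, data = d,
                 family = stats::binomial("logit")))
    null <- try_fit(
      lme4::glmer(cbind(n_success, n_fail) ~ 1 + (1 | replicate_id),
                  data = d, family = stats::binomial("logit")),
      stats::glm(cbind(n_success, n_fail) ~ 1, data = d,
                 family = stats::binomial("logit")))
  } else {
    f1 <- stats::as.formula(paste(response, "~ treatment + (1 | replicate_id)"))
    f0 <- stats::as.formula(paste(response, "~ 1 + (1 | replicate_id)"))
    full <- try_fit(lme4::lmer(f1, data = d, REML = FALSE),
                    stats::lm(stats::as.formula(paste(response, "~ treatment")),
                              data = d))
    null <- try_fit(lme4::lmer(f0, data = d, REML = FALSE),
                    stats::lm(stats::as.formula(paste(response, "~ 1")),
                              data = d))
  }
  ll1 <- stats::logLik(full); ll0 <- stats::logLik(null)
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  dfree <- attr(ll1, "df") - attr(ll0, "df")
  p <- stats::pchisq(chisq, dfree, lower.tail = FALSE)

  ctr <- tryCatch({
    emm <- quiet(emmeans::emmeans(full, "treatment"))
    quiet(as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "BH")))
  }, error = function(e) NULL)
  if (is.null(ctr)) ctr <- .pairwise_contrasts(full, d$treatment)
  cld <- tryCatch(
    quiet(multcomp::cld(emmeans::emmeans(full, "treatment"),
                        adjust = "BH", Letters = letters)),
    error = function(e) NULL)
  letters_df <- if (!is.null(cld)) {
    cd <- as.data.frame(cld)
    grp <- trimws(cd[[grep("group", names(cd), value = TRUE)[1]]])
    data.frame(treatment = as.character(cd$treatment), group = grp,
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(response = response, chisq = chisq, df = dfree, p_value = p,
                 contrasts = ctr, letters = letters_df,
                 low_power = low_power, fit = full),
            class = "treatment_analysis")
}

# pairwise Wald contrasts directly from the fixed-effect coefficients;
# used when the marginal-means machinery cannot handle a degenerate fit
.pairwise_contrasts <- function(fit, treatment) {
  levs <- levels(treatment)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                error = function(e) matrix(0, length(b), length(b)))
  # design rows for each treatment level (intercept + dummy coding)
  X <- matrix(0, length(levs), length(b), dimnames = list(levs, names(b)))
  X[, 1] <- 1
  for (l in levs[-1]) {
    cn <- paste0("treatment", l)
    if (cn %in% names(b)) X[l, cn] <- 1
  }
  pairs <- utils::combn(levs, 2)
  est <- se <- zv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    cvec <- X[pairs[1, j], ] - X[pairs[2, j], ]
    est[j] <- sum(cvec * b)
    se[j] <- sqrt(max(0, drop(t(cvec) %*% V %*% cvec)))
    zv[j] <- if (se[j] > 0) est[j] / se[j] else
      if (est[j] == 0) 0 else sign(est[j]) * Inf
  }
  p_raw <- 2 * stats::pnorm(-abs(zv))
  data.frame(contrast = paste(pairs[1, ], "-", pairs[2, ]),
             estimate = est, SE = se, z.ratio = zv,
             p.value = stats::p.adjust(p_raw, "BH"),
             stringsAsFactors = FALSE)
}

#' @export
print.treatment_analysis <- function(x, ...) {
  cat("Colony-level treatment comparison [", x$response, "]\n", sep = "")
  cat("  LRT: chisq = ", signif(x$chisq, 3), ", d.f. = ", x$df,
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  cat("  pairwise contrasts (BH-adjusted):\n")
  print(transform(x$contrasts, estimate = signif(estimate, 3),
                  SE = signif(SE, 3), p.value = signif(p.value, 3)))
  if (!is.null(x$letters)) {
    cat("  groups: ")
    cat(paste0(x$letters$treatment, "=", x$letters$group, collapse = ", "),
        "\n")
  }
  invisible(x)
}
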