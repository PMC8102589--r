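#' Build the per-tandem modelling table
#'
#' Joins each (filtered) tandem run with the baseline experience profile of
#' its leader (`C_L`, `A_L`) and follower (`C_F`, `A_F`), its
#' within-emigration rank, and the three responses: `success` (0/1), `sld`
#' (straight-line distance, failures only) and `time` (duration in s,
#' successes only).  Grouping identifiers for random effects are included:
#' replicate, colony (nested in replicate) and globally unique leader and
#' follower ids.
#'
#' @param events filtered `tandem_events` (see
#'   [filter_performance_events()]), typically the test emigration.
#' @param profiles baseline [experience_profiles()]; participants without a
#'   profile get zero experience.
#' @param geometry an [arena_geometry()] for the straight-line distance.
#' @return A data frame, one row per tandem run.
#' @export
model_table <- function(events, profiles, geometry = arena_geometry()) {
  key <- paste(profiles$colony_id, profiles$ant_id, sep = "\r")
  look <- function(col, k) {
    v <- setNames(as.numeric(profiles[[col]]), key)[k]
    v[is.na(v)] <- 0
    unname(v)
  }
  lk <- paste(events$colony_id, events$leader_id, sep = "\r")
  fk <- paste(events$colony_id, events$follower_id, sep = "\r")
  fail <- events$outcome == "fail"
  sld <- rep(NA_real_, nrow(events))
  if (any(fail))
    sld[fail] <- straight_line_distance(cbind(events$break_x[fail],
                                              events$break_y[fail]), geometry)
  data.frame(
    replicate = events$replicate_id,
    colony = paste(events$replicate_id, events$colony_id, sep = ":"),
    leader = lk, follower = fk,
    success = as.integer(events$outcome == "success"),
    sld = sld,
    time = ifelse(events$outcome == "success",
                  events$t_end - events$t_start, NA_real_),
    C_L = look("C_L", lk), A_L = look("A_L", lk),
    C_F = look("C_F", fk), A_F = look("A_F", fk),
    rank = as.numeric(events$rank),
    stringsAsFactors = FALSE)
}

.main_terms <- c("C_L", "A_L", "C_F", "A_F", "rank")
.int_terms <- c("C_L:C_F", "A_L:A_F")

# standardise the main-effect predictors (zero mean, unit SD) on the rows
# actually analysed; constant columns are left at zero
.standardise <- function(d) {
  for (v in .main_terms) {
    x <- d[[v]]
    s <- stats::sd(x)
    d[[v]] <- if (is.na(s) || s == 0) x * 0 else (x - mean(x)) / s
  }
  d
}

#' Enumerate marginality-respecting term subsets
#'
#' All subsets of the global fixed-effect structure
#' `C_L + A_L + C_F + A_F + rank + C_L:C_F + A_L:A_F`, where an interaction
#' may appear only in models that contain both of its main effects.
#'
#' @return A list of character vectors (the empty vector is the
#'   intercept-only model).
#' @export
enumerate_term_subsets <- function() {
  subsets <- list()
  n_main <- length(.main_terms)
  for (mask in 0:(2^n_main - 1)) {
    mains <- .main_terms[bitwAnd(mask, 2^(seq_len(n_main) - 1)) > 0]
    ints_ok <- .int_terms[vapply(.int_terms, function(it) {
      all(strsplit(it, ":", fixed = TRUE)[[1]] %in% mains)
    }, TRUE)]
    for (imask in 0:(2^length(ints_ok) - max(1, 1))) {
      if (length(ints_ok)) {
        ints <- ints_ok[bitwAnd(imask, 2^(seq_along(ints_ok) - 1)) > 0]
        if (imask >= 2^length(ints_ok)) next
      } else {
        if (imask > 0) next
        ints <- character()
      }
      subsets[[length(subsets) + 1]] <- c(mains, ints)
    }
  }
  subsets
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = IC_i - min(IC)`.
#'
#' @param ic vector of AIC/AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit one mixed model of tandem performance
#'
#' Fits a mixed-effects model of a tandem performance response on a subset
#' of the experience terms, with nested random intercepts for replicate,
#' colony-within-replicate, leader identity and follower identity.  The
#' `success` response uses a binomial GLMM with a logit link (Laplace
#' approximation); `sld` and `time` use Gaussian LMMs fitted by maximum
#' likelihood (not REML), so that models with different fixed effects are
#' comparable by information criteria.  Main-effect predictors are expected
#' to be standardised already (see [enumerate_and_rank_subsets()]).
#'
#' Random terms whose grouping factor has a single level in the analysed
#' rows are dropped; if none remain the fixed-effects model (`glm`/`lm`)
#' is fitted instead, which reproduces ordinary regression on
#' unstructured data.
#'
#' @param table modelling table (from [model_table()], standardised).
#' @param terms character vector of fixed-effect terms (subset of
#'   `C_L, A_L, C_F, A_F, rank, C_L:C_F, A_L:A_F`); empty = intercept only.
#' @param response `"success"`, `"sld"` or `"time"`.
#' @param random random-effects formula fragment.
#' @param nAGQ integration setting passed to [lme4::glmer()] for the
#'   binomial response: 1 (Laplace, default) or 0 (faster penalised
#'   quasi-likelihood-style approximation, useful for large model sets).
#' @return A list of class `tandem_fit`: `terms`, `response`, `coefs`
#'   (fixed-effect estimates and SEs), `logLik`, `k`, `n`, `AICc`,
#'   `converged`, `messages`, and `fit` (the lme4 object).
#' @export
fit_random_intercept_model <- function(table, terms, response,
                                       random = "(1 | replicate) + (1 | colony) + (1 | leader) + (1 | follower)",
                                       nAGQ = 1L) {
  d <- table[!is.na(table[[response]]), , drop = FALSE]
  # drop random terms whose grouping factor has a single level in these rows
  re_terms <- trimws(strsplit(random, "+", fixed = TRUE)[[1]])
  re_terms <- Filter(function(rt) {
    g <- trimws(sub("\\)$", "", sub(".*\\|", "", rt)))
    !(g %in% names(d)) || length(unique(d[[g]])) > 1
  }, re_terms)
  rhs <- paste(c(if (length(terms)) terms else "1", re_terms), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  msgs <- character()
  fit <- tryCatch(withCallingHandlers({
    if (!length(re_terms)) {
      if (response == "success")
        stats::glm(f, data = d, family = stats::binomial("logit"))
      else
        stats::lm(f, data = d)
    } else if (response == "success")
      lme4::glmer(f, data = d, family = stats::binomial("logit"), nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    else
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE))
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  }), error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(terms = terms, response = response, coefs = NULL,
                          logLik = NA_real_, k = NA_integer_, n = nrow(d),
                          AICc = Inf, converged = FALSE,
                          messages = conditionMessage(fit), fit = NULL),
                     class = "tandem_fit"))
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- nrow(d)
  cc <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  opt_ok <- !inherits(fit, "merMod") ||
    is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  structure(list(terms = terms, response = response, coefs = coefs,
                 logLik = as.numeric(ll), k = k, n = n,
                 AICc = aicc(as.numeric(ll), k, n),
                 converged = opt_ok, messages = msgs, fit = fit),
            class = "tandem_fit")
}

#' @export
print.tandem_fit <- function(x, ...) {
  cat("Mixed model [", x$response, "] ~ ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "\n  logLik = ", signif(x$logLik, 6), ", k = ", x$k, ", n = ", x$n,
      ", AICc = ", signif(x$AICc, 6),
      if (!x$converged) "  [did not converge]", "\n", sep = "")
  invisible(x)
}

#' All-subsets multimodel inference
#'
#' Fits every marginality-respecting subset of the global model
#' `response ~ C_L + A_L + C_F + A_F + rank + C_L:C_F + A_L:A_F` (plus the
#' random intercepts), ranks the fits by AICc, computes Akaike weights,
#' flags the 95% confidence set, and stores per-model coefficients for
#' averaging.  Main effects are standardised (zero mean, unit SD) on the
#' analysed rows before fitting so coefficients are comparable across
#' models.  Models that fail to fit are excluded and weights renormalised.
#'
#' @param table modelling table from [model_table()].
#' @param response `"success"`, `"sld"` or `"time"`.
#' @param level confidence-set level (default 0.95).
#' @param ic `"AICc"` (default) or `"AIC"`.
#' @param random,nAGQ fitting options, see
#'   [fit_random_intercept_model()].
#' @param keep_fits keep the lme4 fit objects (default `FALSE`).
#' @param progress print a dot per fitted model.
#' @return An object of class `tandem_modelset`.
#' @seealso [confidence_set_95()], [relative_importance()],
#'   [model_average()], [collinearity_report()]
#' @export
enumerate_and_rank_subsets <- function(table, response, level = 0.95,
                                       ic = c("AICc", "AIC"),
                                       random = "(1 | replicate) + (1 | colony) + (1 | leader) + (1 | follower)",
                                       nAGQ = 1L,
                                       keep_fits = FALSE, progress = FALSE) {
  ic <- match.arg(ic)
  d <- table[!is.na(table[[response]]), , drop = FALSE]
  d <- .standardise(d)
  subsets <- enumerate_term_subsets()
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- fit_random_intercept_model(d, subsets[[i]], response,
                                            random = random, nAGQ = nAGQ)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  ok <- vapply(fits, function(f) is.finite(f$logLik), TRUE)
  dropped <- lapply(fits[!ok], function(f)
    list(terms = f$terms, reason = paste(f$messages, collapse = "; ")))
  fits <- fits[ok]
  if (!length(fits)) stop("no subset model could be fitted")
  icv <- vapply(fits, function(f)
    if (ic == "AICc") f$AICc else -2 * f$logLik + 2 * f$k, 0)
  o <- order(icv)
  fits <- fits[o]; icv <- icv[o]
  w <- akaike_weights(icv)
  models <- data.frame(
    model = seq_along(fits),
    terms = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = "+") else "(intercept)", ""),
    k = vapply(fits, function(f) as.numeric(f$k), 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    IC = icv, delta = icv - icv[1], weight = w,
    cum_weight = cumsum(w),
    converged = vapply(fits, function(f) f$converged, TRUE),
    stringsAsFactors = FALSE)
  coefs <- lapply(fits, function(f) f$coefs)
  terms_list <- lapply(fits, function(f) f$terms)
  ms <- structure(list(models = models, coefs = coefs,
                       term_sets = terms_list,
                       response = response, ic = ic, level = level,
                       n = fits[[1]]$n, dropped = dropped,
                       data = d,
                       fits = if (keep_fits) fits else NULL),
                  class = "tandem_modelset")
  confidence_set_95(ms, level = level)
}

#' Flag the 95% confidence set of models
#'
#' The confidence set is the smallest prefix of the IC ranking whose
#' cumulative Akaike weight reaches the requested level.
#'
#' @param ms a `tandem_modelset`.
#' @param level cumulative-weight level (default 0.95).
#' @return The model set with an `in_set` column on `ms$models`.
#' @export
confidence_set_95 <- function(ms, level = 0.95) {
  cw <- cumsum(ms$models$weight)
  cut <- which(cw >= level - 1e-12)[1]
  ms$models$in_set <- seq_len(nrow(ms$models)) <= cut
  ms$level <- level
  ms
}

#' Relative importance of each predictor
#'
#' For every term of the global model, the sum of the Akaike weights —
#' renormalised within the confidence set — of the confidence-set models
#' that contain the term.  A term in every member model has importance 1; a
#' term in none has importance 0.
#'
#' @param ms a `tandem_modelset` with the confidence set flagged.
#' @return Named numeric vector of importances between 0 and 1, sorted
#'   decreasing.
#' @export
relative_importance <- function(ms) {
  sel <- ms$models$in_set
  w <- ms$models$weight[sel] / sum(ms$models$weight[sel])
  tsets <- ms$term_sets[sel]
  all_terms <- c(.main_terms, .int_terms)
  imp <- vapply(all_terms, function(tt)
    sum(w[vapply(tsets, function(s) tt %in% s, TRUE)]), 0)
  sort(imp, decreasing = TRUE)
}

#' Model-averaged coefficients with unconditional standard errors
#'
#' Averages each term's coefficient over the confidence-set models using
#' the renormalised Akaike weights.  With `method = "full"` (default, the
#' zero-substitution average) models that do not contain the term
#' contribute a coefficient of 0 with zero variance, so the average is
#' shrunk in proportion to the weight of models excluding the term; with
#' `method = "conditional"` the average is taken only over models
#' containing the term.  Unconditional standard errors combine within-model
#' sampling variance and between-model spread:
#' `SE = sum_i w_i * sqrt(se_i^2 + (b_i - bbar)^2)`.
#' A term is called significant when `|estimate| > 1.96 * SE`.
#'
#' @param ms a `tandem_modelset`.
#' @param method `"full"` or `"conditional"`.
#' @return Data frame with `term`, `estimate`, `se`, `z`, `significant`.
#' @export
model_average <- function(ms, method = c("full", "conditional")) {
  method <- match.arg(method)
  sel <- ms$models$in_set
  w <- ms$models$weight[sel] / sum(ms$models$weight[sel])
  coefs <- ms$coefs[sel]
  # design-column names as they appear in lme4 output
  coef_name <- function(tt) if (grepl(":", tt)) tt else tt
  all_terms <- c("(Intercept)", .main_terms, .int_terms)
  rows <- lapply(all_terms, function(tt) {
    b <- se <- numeric(length(coefs)); has <- logical(length(coefs))
    for (i in seq_along(coefs)) {
      cc <- coefs[[i]]
      j <- match(coef_name(tt), cc$term)
      if (!is.na(j)) { b[i] <- cc$estimate[j]; se[i] <- cc$se[j]; has[i] <- TRUE }
    }
    if (!any(has)) return(NULL)
    if (method == "full") {
      wt <- w
    } else {
      if (sum(w[has]) == 0) return(NULL)
      wt <- ifelse(has, w, 0) / sum(w[has])
      b[!has] <- 0; se[!has] <- 0
    }
    bbar <- sum(wt * b)
    sebar <- sum(wt * sqrt(se^2 + (b - bbar)^2))
    data.frame(term = tt, estimate = bbar, se = sebar,
               z = if (sebar > 0) bbar / sebar else NA_real_,
               significant = sebar > 0 && abs(bbar) > 1.96 * sebar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collinearity diagnostics over the confidence set
#'
#' For each confidence-set model with at least two fixed-effect predictors,
#' computes the mean absolute pairwise correlation among its predictor
#' columns (interactions entered as products of the standardised mains) and
#' the variance inflation factors `VIF_j = 1 / (1 - R2_j)` from regressing
#' each predictor on the others.  Also flags a *filtered* confidence set
#' that excludes any member model containing a predictor pair with
#' `|r| > threshold`.
#'
#' @param ms a `tandem_modelset`.
#' @param threshold pairwise-correlation cutoff for the filtered set
#'   (default 0.7).
#' @return A list of class `collinearity_report`: `per_model` (model id,
#'   `mean_abs_r`, `mean_vif`, `max_vif`, `filtered_out`), summary
#'   `mean_abs_r` and `vif` (mean and SD across models), and the filtered
#'   model ids.
#' @export
collinearity_report <- function(ms, threshold = 0.7) {
  sel <- which(ms$models$in_set)
  d <- ms$data
  rows <- list(); kept <- logical(length(sel))
  for (i in seq_along(sel)) {
    terms <- ms$term_sets[[sel[i]]]
    if (length(terms) < 2) {
      rows[[i]] <- data.frame(model = sel[i], n_predictors = length(terms),
                              mean_abs_r = NA_real_, mean_vif = NA_real_,
                              max_vif = NA_real_, filtered_out = FALSE)
      kept[i] <- TRUE
      next
    }
    X <- sapply(terms, function(tt) {
      if (grepl(":", tt)) {
        p <- strsplit(tt, ":", fixed = TRUE)[[1]]
        d[[p[1]]] * d[[p[2]]]
      } else d[[tt]]
    })
    keep_col <- apply(X, 2, stats::sd) > 0
    X <- X[, keep_col, drop = FALSE]
    if (ncol(X) < 2) {
      rows[[i]] <- data.frame(model = sel[i], n_predictors = length(terms),
                              mean_abs_r = NA_real_, mean_vif = NA_real_,
                              max_vif = NA_real_, filtered_out = FALSE)
      kept[i] <- TRUE
      next
    }
    r <- stats::cor(X)
    absr <- abs(r[upper.tri(r)])
    vifs <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      if (r2 >= 1) Inf else 1 / (1 - r2)
    }, 0)
    filtered <- any(absr > threshold)
    rows[[i]] <- data.frame(model = sel[i], n_predictors = length(terms),
                            mean_abs_r = mean(absr), mean_vif = mean(vifs),
                            max_vif = max(vifs), filtered_out = filtered)
    kept[i] <- !filtered
  }
  per_model <- do.call(rbind, rows)
  structure(list(
    per_model = per_model,
    mean_abs_r = c(mean = mean(per_model$mean_abs_r, na.rm = TRUE),
                   sd = stats::sd(per_model$mean_abs_r, na.rm = TRUE)),
    vif = c(mean = mean(per_model$mean_vif, na.rm = TRUE),
            sd = stats::sd(per_model$mean_vif, na.rm = TRUE)),
    threshold = threshold,
    filtered_models = per_model$model[!per_model$filtered_out]),
    class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity over the confidence set (",
      nrow(x$per_model), " models)\n", sep = "")
  cat("  mean |r| = ", signif(x$mean_abs_r["mean"], 3), " ± ",
      signif(x$mean_abs_r["sd"], 2), ", VIF = ",
      signif(x$vif["mean"], 3), " ± ", signif(x$vif["sd"], 2), "\n", sep = "")
  cat("  filtered set (all pairwise |r| <= ", x$threshold, "): ",
      length(x$filtered_models), " models\n", sep = "")
  invisible(x)
}

#' @export
print.tandem_modelset <- function(x, ...) {
  cat("All-subsets multimodel inference [", x$response, "], ",
      nrow(x$models), " models ranked by ", x$ic, ", n = ", x$n, "\n", sep = "")
  n_set <- sum(x$models$in_set)
  cat("  ", round(100 * x$level), "% confidence set: ", n_set, " models\n",
      sep = "")
  print(utils::head(x$models[, c("terms", "k", "IC", "delta", "weight",
                                 "in_set")], 8))
  if (nrow(x$models) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
summary.tandem_modelset <- function(object, ...) {
  imp <- relative_importance(object)
  avg <- model_average(object)
  out <- list(response = object$response, n_models = nrow(object$models),
              n_in_set = sum(object$models$in_set),
              importance = imp, averaged = avg)
  class(out) <- "summary.tandem_modelset"
  out
}

#' @export
print.summary.tandem_modelset <- function(x, ...) {
  cat("Multimodel inference summary [", x$response, "]\n", sep = "")
  cat("  models:", x$n_models, "| in 95% confidence set:", x$n_in_set, "\n")
  cat("  relative importance:\n")
  print(round(x$importance, 3))
  cat("  model-averaged coefficients:\n")
  print(transform(x$averaged, estimate = signif(estimate, 4),
                  se = signif(se, 4), z = signif(z, 3)))
  invisible(x)
}

#' @export
coef.tandem_modelset <- function(object, method = "full", ...) {
  avg <- model_average(object, method = method)
  setNames(avg$estimate, avg$term)
}

#' @export
plot.tandem_modelset <- function(x, ...) {
  imp <- relative_importance(x)
  graphics::barplot(rev(imp), horiz = TRUE, las = 1, xlim = c(0, 1),
                    xlab = "relative importance",
                    main = paste0("Predictor importance [", x$response, "]"),
                    ...)
  invisible(x)
}
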