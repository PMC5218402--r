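# Base-model fitting: explanatory variables as fixed effects plus mother as
# a random effect, fitted by REML. The conditional residuals (observed minus
# fixed effects minus predicted mother effects) are the adjusted phenotype
# used by all genome scans, and the residual variance is the denominator for
# effect standardisation.

#' Fit the base model for a trait
#'
#' REML fit of `response ~ fixed terms + (1 | mother)` via lme4. Rows with
#' missing values in the response or any used variable are dropped. A
#' rank-deficient fixed design is an error naming the aliased columns.
#'
#' @param data data.frame holding the response, covariates, and mother id.
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect term labels (may be
#'   empty for an intercept-only model).
#' @param mother Column name of the maternal grouping factor.
#' @return A `base_model_fit`: list with the lme4 `fit`, the used `data`
#'   and `ids`, `terms`, residual variance `sigma2`, `mother_var`, REML
#'   log-likelihood `reml_loglik`, and the adjusted phenotype `adjusted`
#'   (conditional residuals, named by individual).
#' @export
fit_base_model <- function(data, response, fixed_terms = character(),
                           mother = "mother") {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", mother, ")"))
  vars <- c(response, all.vars(stats::as.formula(paste("~", rhs))), mother)
  use <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  d <- data[use, , drop = FALSE]
  d[[mother]] <- factor(d[[mother]])
  if (nlevels(d[[mother]]) < 2L) stop("need at least 2 mothers")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effect design is singular; aliased: ",
         paste(aliased, collapse = ", "))
  }
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(fit = fit, data = d, ids = d$id, response = response,
              terms = fixed_terms, mother = mother,
              sigma2 = vc$vcov[vc$grp == "Residual"],
              mother_var = vc$vcov[vc$grp == mother],
              reml_loglik = as.numeric(stats::logLik(fit)),
              adjusted = stats::setNames(stats::residuals(fit), d$id),
              X = X)
  class(out) <- "base_model_fit"
  out
}

#' @export
print.base_model_fit <- function(x, ...) {
  cat("Base model:", x$response, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "+ (1 |", x$mother, ")\n")
  cat(sprintf("  n = %d, mother variance = %.4g, residual variance = %.4g\n",
              nrow(x$data), x$mother_var, x$sigma2))
  invisible(x)
}

#' Test a fixed-effect term by the chi-square approximation of d x F
#'
#' In mixed models the denominator degrees of freedom of the Wald F is
#' unclear; assuming it is large, `d * F` is compared against a chi-square
#' distribution with `d` degrees of freedom (the term's numerator df). The F
#' statistic uses the estimated residual variance as the denominator (Wald
#' form from the coefficient covariance).
#'
#' @param bm A `base_model_fit` (or any lme4 fit wrapped with `$fit`, `$X`).
#' @param term A fixed-effect term label present in the model.
#' @return list with `F`, `df`, `p`.
#' @export
test_fixed_effect <- function(bm, term) {
  asgn <- attr(bm$X, "assign")
  labs <- attr(stats::terms(stats::as.formula(
    paste("~", paste(bm$terms, collapse = " + ")))), "term.labels")
  k <- match(term, labs)
  if (is.na(k)) stop("term not in model: ", term)
  idx <- which(asgn == k)
  if (length(idx) == 0L) stop("term has 0 degrees of freedom: ", term)
  beta <- lme4::fixef(bm$fit)[idx]
  V <- as.matrix(stats::vcov(bm$fit))[idx, idx, drop = FALSE]
  d <- length(idx)
  Fstat <- as.numeric(crossprod(beta, solve(V, beta))) / d
  list(F = Fstat, df = d, p = stats::pchisq(d * Fstat, df = d,
                                            lower.tail = FALSE))
}

# REML log-likelihood of a fixed-effects-only linear model, on the same
# scale as lme4's REML logLik: -0.5 * (log|X'X| + (n-p)(1 + log(2 pi s2)))
# with s2 = RSS / (n - p).
reml_loglik_lm <- function(X, y) {
  qx <- qr(X)
  p <- qx$rank
  n <- length(y)
  rss <- sum(qr.resid(qx, y)^2)
  s2 <- rss / (n - p)
  logdet <- 2 * sum(log(abs(diag(qr.R(qx))[seq_len(p)])))
  -0.5 * (logdet + (n - p) * (1 + log(2 * pi * s2)))
}

#' REML likelihood-ratio test for the maternal random effect
#'
#' Compares the REML log-likelihood of the base model with the maternal
#' random effect against the fixed-effects-only model with the identical
#' fixed structure. The default null is chi-square with 1 df (conservative);
#' `null = "mixture"` uses the 50:50 boundary mixture of chi-square 0 and 1.
#'
#' @param bm A `base_model_fit`.
#' @param null "chisq1" (default) or "mixture".
#' @return list with `statistic` (2 x log-likelihood difference, floored at
#'   0) and `p`.
#' @export
test_mother <- function(bm, null = c("chisq1", "mixture")) {
  null <- match.arg(null)
  y <- bm$data[[bm$response]]
  ll0 <- reml_loglik_lm(bm$X, y)
  stat <- max(0, 2 * (bm$reml_loglik - ll0))
  p1 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p <- if (null == "chisq1") p1 else if (stat <= 0) 1 else 0.5 * p1
  list(statistic = stat, p = p)
}

#' Backward selection of explanatory variables
#'
#' Starting from the full candidate set, the least significant term (by the
#' chi-square approximation of d x F) with p at or above `alpha` is removed,
#' the model is refitted and the tests recomputed, until every remaining
#' term has p below `alpha`. Ties in p are broken by dropping the term
#' declared later.
#'
#' @inheritParams fit_base_model
#' @param candidates Character vector of candidate fixed-effect terms, in
#'   declaration order.
#' @param alpha Retention threshold (default 0.05).
#' @return The final `base_model_fit`, with a `dropped` attribute
#'   (data.frame of removed terms and their p at removal).
#' @export
backward_select <- function(data, response, candidates, mother = "mother",
                            alpha = 0.05) {
  terms <- candidates
  dropped <- data.frame(term = character(), p = numeric())
  repeat {
    bm <- fit_base_model(data, response, terms, mother)
    if (!length(terms)) break
    ps <- vapply(terms, function(tt) test_fixed_effect(bm, tt)$p, 0)
    worst <- max(ps)
    if (worst < alpha) break
    drop_i <- max(which(ps >= worst - 1e-12))  # later declaration on ties
    dropped <- rbind(dropped, data.frame(term = terms[drop_i], p = ps[drop_i]))
    terms <- terms[-drop_i]
  }
  attr(bm, "dropped") <- dropped
  bm
}

#' Coarsen age-at-move into a grouped factor
#'
#' Age when moved is first binned into 6-day intervals ("not moved" is its
#' own level), consecutive bins whose effect estimates differ by less than
#' `merge_tol` pooled standard errors are merged, and each remaining
#' boundary is then shifted within a +/- `shift_window` day window to the
#' day maximising the sum of squares explained by the grouping.
#'
#' @param move_age Numeric vector of move ages in days; NA = not moved.
#' @param y Response (typically the trait pre-adjusted for other terms).
#' @param bin_width Initial bin width in days (default 6).
#' @param merge_tol Merge when |difference of estimates| < merge_tol x
#'   pooled SE (default 1).
#' @param shift_window Boundary search half-width in days (default 6).
#' @return A factor (levels "not_moved" and "moved_[lo,hi)" groups) with a
#'   `boundaries` attribute (the internal cut days among moved animals).
#' @export
coarsen_move_age <- function(move_age, y, bin_width = 6, merge_tol = 1,
                             shift_window = 6) {
  moved <- !is.na(move_age)
  grouping_at <- function(bounds) {
    g <- rep("not_moved", length(move_age))
    if (length(bounds) == 0L) {
      g[moved] <- "moved"
    } else {
      cuts <- c(-Inf, bounds, Inf)
      g[moved] <- paste0("moved_g", findInterval(move_age[moved], cuts))
    }
    factor(g)
  }
  if (!any(moved)) {
    g <- grouping_at(numeric())
    attr(g, "boundaries") <- numeric()
    return(g)
  }
  ages <- move_age[moved]
  lo <- floor(min(ages)); hi <- max(ages)
  bounds <- seq(lo + bin_width, hi, by = bin_width)
  bounds <- bounds[bounds > min(ages) & bounds <= max(ages)]
  # merge adjacent bins with similar estimates until stable
  repeat {
    g <- grouping_at(bounds)
    if (nlevels(g) < 3L || length(bounds) == 0L) break
    fit <- stats::lm(y ~ g)
    sm <- summary(fit)$coefficients
    lev <- levels(g)
    mlev <- setdiff(lev, "not_moved")
    est <- se <- stats::setNames(numeric(length(mlev)), mlev)
    for (l in mlev) {
      cn <- paste0("g", l)
      if (cn %in% rownames(sm)) { est[l] <- sm[cn, 1]; se[l] <- sm[cn, 2] }
    }
    merged <- FALSE
    for (k in seq_len(length(mlev) - 1L)) {
      pooled <- sqrt(se[k]^2 + se[k + 1L]^2)
      if (abs(est[k] - est[k + 1L]) < merge_tol * pooled) {
        bounds <- bounds[-k]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # boundary refinement: shift each cut to maximise explained SS
  explained <- function(b) {
    g <- grouping_at(b)
    if (nlevels(g) < 2L) return(0)
    stats::anova(stats::lm(y ~ g))[["Sum Sq"]][1L]
  }
  if (length(bounds)) {
    for (k in seq_along(bounds)) {
      cand <- bounds[k] + seq(-shift_window, shift_window)
      lo_ok <- if (k > 1L) bounds[k - 1L] + 1 else -Inf
      hi_ok <- if (k < length(bounds)) bounds[k + 1L] - 1 else Inf
      cand <- cand[cand > lo_ok & cand < hi_ok]
      ss <- vapply(cand, function(b0) {
        b <- bounds; b[k] <- b0; explained(b)
      }, 0)
      bounds[k] <- cand[which.max(ss)]
    }
  }
  g <- grouping_at(bounds)
  attr(g, "boundaries") <- bounds
  g
}
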