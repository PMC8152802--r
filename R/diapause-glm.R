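# Logistic diapause-probability model:
#   logit p = b0 + b1 * week + b2 * width + b3 * week * width (+ year effects)
# Success is an egg in diapause (embryonated unhatched); failure a hatched
# egg. Only viable eggs with morphometry enter the design.

#' Build the diapause-model design
#'
#' Keeps viable eggs (HATCHED or EMBRYONATED_UNHATCHED) that carry
#' morphometry and assembles the per-egg Bernoulli design: response
#' `y` (1 = diapause), `x1` = ISO week of collection, `x2` = egg width in
#' micrometres, `year` = ISO week-year as a factor, and the product
#' `x1x2`.
#'
#' @param eggs a validated egg tibble.
#' @return a tibble with columns `y`, `x1`, `x2`, `year`, `x1x2`;
#'   attributes `n_viable` and `n_with_morph` record the bookkeeping.
#' @export
build_design <- function(eggs) {
  morph <- suppressMessages(summarize_reps(eggs))
  viable <- morph[morph$status %in% VIABLE_STATUSES, ]
  n_viable_all <- sum(validate_eggs(eggs)$status %in% VIABLE_STATUSES)
  if (nrow(viable) == 0) {
    abort("no viable eggs with morphometry: cannot build the design")
  }
  out <- tibble::tibble(
    y = as.integer(viable$status == "EMBRYONATED_UNHATCHED"),
    x1 = as.numeric(viable$iso_week),
    x2 = viable$width_um,
    year = factor(viable$iso_year),
    x1x2 = as.numeric(viable$iso_week) * viable$width_um
  )
  attr(out, "n_viable") <- n_viable_all
  attr(out, "n_with_morph") <- nrow(out)
  out
}

# model matrix for a term subset; enforces interaction hierarchy
.glm_model_matrix <- function(design, terms) {
  allowed <- c("x1", "x2", "year", "x1:x2")
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown term(s): %s", paste(bad, collapse = ", ")))
  }
  if ("x1:x2" %in% terms && !all(c("x1", "x2") %in% terms)) {
    abort("interaction x1:x2 requires both main effects x1 and x2")
  }
  mats <- list(`(Intercept)` = rep(1, nrow(design)))
  for (tm in terms) {
    if (tm == "x1") mats$x1 <- design$x1
    if (tm == "x2") mats$x2 <- design$x2
    if (tm == "x1:x2") mats$`x1:x2` <- design$x1x2
    if (tm == "year") {
      lev <- levels(design$year)
      for (l in lev[-1]) {
        mats[[paste0("year", l)]] <- as.numeric(design$year == l)
      }
    }
  }
  do.call(cbind, mats)
}

#' Fit the logistic diapause model by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares. Convergence is declared when the relative change in
#' log-likelihood falls below `tol` (default 1e-8) within `max_iter`
#' iterations. Complete or quasi-complete separation is detected (fitted
#' probabilities collapsing to 0/1) and flagged rather than hidden; a
#' rank-deficient design errors, naming the collinear columns.
#'
#' @param design a [build_design()] tibble (or any tibble with `y`, `x1`,
#'   `x2`, `year`, `x1x2`).
#' @param terms character subset of `c("x1", "x2", "year", "x1:x2")`;
#'   `character(0)` fits the intercept-only model. The interaction demands
#'   both main effects.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return a `diapause_glm` list: `coefficients`, `se`, `log_lik`, `aic`
#'   (2k - 2 logLik), `n`, `k`, `converged`, `separation`, `terms`,
#'   `year_levels`, `fitted`.
#' @export
fit_logistic <- function(design, terms = c("x1", "x2", "x1:x2"),
                         tol = 1e-8, max_iter = 100) {
  design <- tibble::as_tibble(design)
  y <- design$y
  if (!all(y %in% c(0L, 1L))) abort("`y` must be a 0/1 indicator")
  X <- .glm_model_matrix(design, terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("singular design: collinear column(s) %s",
                  paste(dropped, collapse = ", ")))
  }

  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    ll_new <- sum(y * log(p) + (1 - y) * log1p(-p))
    if (abs(ll_new - ll) / (abs(ll_new) + 0.1) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  separation <- any(p < 1e-8 | p > 1 - 1e-8) || any(abs(beta) > 1e4)
  w <- p * (1 - p)
  info <- crossprod(X, X * w)
  se <- tryCatch(sqrt(diag(solve(info))),
                 error = function(e) rep(NA_real_, ncol(X)))
  k <- ncol(X)
  structure(
    list(
      coefficients = setNames(as.numeric(beta), colnames(X)),
      se = setNames(as.numeric(se), colnames(X)),
      log_lik = ll,
      aic = 2 * k - 2 * ll,
      n = length(y),
      k = k,
      converged = converged,
      separation = separation,
      terms = terms,
      year_levels = levels(design$year),
      fitted = p
    ),
    class = "diapause_glm"
  )
}

#' @export
print.diapause_glm <- function(x, ...) {
  cat(sprintf(
    "logistic diapause model [%s]: n = %d, logLik = %.2f, AIC = %.2f%s%s\n",
    if (length(x$terms) == 0) "intercept only" else paste(x$terms, collapse = " + "),
    x$n, x$log_lik, x$aic,
    if (!x$converged) ", NOT CONVERGED" else "",
    if (x$separation) ", separation flagged" else ""
  ))
  print(round(rbind(estimate = x$coefficients, se = x$se), 5))
  invisible(x)
}

# hierarchical subsets of the candidate terms (interaction only with mains)
.hierarchical_subsets <- function(candidates) {
  mains <- setdiff(candidates, "x1:x2")
  subsets <- list(character(0))
  for (m in mains) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, m)))
  }
  if ("x1:x2" %in% candidates) {
    with_int <- lapply(
      Filter(function(s) all(c("x1", "x2") %in% s), subsets),
      function(s) c(s, "x1:x2")
    )
    subsets <- c(subsets, with_int)
  }
  unique(subsets)
}

#' AIC-based predictor selection
#'
#' Fits every hierarchical subset of the candidate terms (the interaction
#' is only considered together with both its main effects), ranks the
#' converged fits by AIC and returns the minimum-AIC model with the full
#' ranking table.
#'
#' @inheritParams fit_logistic
#' @param candidates candidate terms (default all four).
#' @return a list: `best` (a `diapause_glm`), `table` (tibble with
#'   `formula`, `k`, `log_lik`, `aic`, `delta_aic`, sorted by AIC).
#' @export
select_by_aic <- function(design, candidates = c("x1", "x2", "year", "x1:x2"),
                          tol = 1e-8, max_iter = 100) {
  subsets <- .hierarchical_subsets(unique(candidates))
  if (length(subsets) < 2) abort("need at least two candidate formulas")
  fits <- lapply(subsets, function(s) {
    tryCatch(fit_logistic(design, s, tol = tol, max_iter = max_iter),
             error = function(e) NULL)
  })
  labels <- vapply(subsets, function(s) {
    if (length(s) == 0) "1" else paste(s, collapse = " + ")
  }, character(1))
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) is.null(f) || f$converged, logical(1))
  if (any(!ok)) {
    warn(sprintf("excluded %d non-converged/failed candidate(s): %s",
                 sum(!ok), paste(labels[!ok], collapse = "; ")))
  }
  fits <- fits[ok]; labels <- labels[ok]
  if (length(fits) == 0) abort("no candidate model converged")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aics)
  tbl <- tibble::tibble(
    formula = labels[ord],
    k = vapply(fits[ord], function(f) f$k, numeric(1)),
    log_lik = vapply(fits[ord], function(f) f$log_lik, numeric(1)),
    aic = aics[ord],
    delta_aic = aics[ord] - min(aics)
  )
  list(best = fits[[ord[1]]], table = tbl)
}

#' Predict diapause probability
#'
#' Evaluates the fitted logistic model at new covariate values. Fitted
#' probabilities are strictly inside (0, 1) for finite covariates: the
#' model never predicts certain diapause or certain hatching.
#'
#' @param fit a converged `diapause_glm`.
#' @param week week of collection (numeric vector).
#' @param width_um egg width in micrometres.
#' @param year year level as in the training data; required when the model
#'   includes year effects. An unseen level errors.
#' @return vector of diapause probabilities.
#' @export
predict_diapause <- function(fit, week, width_um, year = NULL) {
  stopifnot(inherits(fit, "diapause_glm"))
  if (!fit$converged) abort("model did not converge; refusing to predict")
  nm <- names(fit$coefficients)
  n <- max(length(week), length(width_um))
  week <- rep_len(as.numeric(week), n)
  width_um <- rep_len(as.numeric(width_um), n)
  eta <- rep(fit$coefficients[["(Intercept)"]], n)
  if ("x1" %in% nm) eta <- eta + fit$coefficients[["x1"]] * week
  if ("x2" %in% nm) eta <- eta + fit$coefficients[["x2"]] * width_um
  if ("x1:x2" %in% nm) eta <- eta + fit$coefficients[["x1:x2"]] * week * width_um
  year_cols <- nm[startsWith(nm, "year")]
  if (length(year_cols) > 0) {
    if (is.null(year)) abort("model includes year effects: supply `year`")
    year <- rep_len(as.character(year), n)
    unseen <- setdiff(unique(year), fit$year_levels)
    if (length(unseen) > 0) {
      abort(sprintf("year level(s) unseen in training: %s",
                    paste(unseen, collapse = ", ")))
    }
    for (yc in year_cols) {
      lev <- sub("^year", "", yc)
      eta <- eta + fit$coefficients[[yc]] * (year == lev)
    }
  }
  plogis(eta)
}
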