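#' Build a candidate design matrix of mains, interactions and quadratics
#'
#' Expands a set of candidate covariates into the full candidate term set for
#' stepwise selection: every main effect, every pairwise product, and the
#' square of every continuous (non-binary) covariate. A 0/1 binary covariate
#' (such as an age-group indicator) gets no quadratic term, since its square
#' is itself. Covariates enter raw (uncentred), so fitted coefficients read
#' directly as per-unit slopes in the original units.
#'
#' @param data data frame of subject records.
#' @param candidates character vector of covariate column names.
#' @param interactions,quadratics include pairwise interaction / quadratic
#'   columns (default `TRUE`).
#' @return A list with `X` (the n x p candidate matrix, no intercept) and
#'   `terms`, a data frame registry with columns `term`, `type`
#'   (`"main"`, `"interaction"`, `"quadratic"`) and `parents`
#'   (comma-separated parent covariates).
#' @export
#' @examples
#' cohort <- generate_subject_cohort(cohort_spec(noise_sd = 0, seed = 1))
#' d <- build_design(cohort, c("e_local_task", "e_global_task",
#'                             "mean_rt", "age_group"))
#' d$terms
build_design <- function(data, candidates, interactions = TRUE,
                         quadratics = TRUE) {
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    stop("candidate covariate(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  cols <- lapply(candidates, function(nm) as.numeric(data[[nm]]))
  names(cols) <- candidates
  is_binary <- vapply(cols, function(x) all(x %in% c(0, 1)), logical(1))
  X <- do.call(cbind, cols)
  terms <- data.frame(term = candidates, type = "main", parents = candidates,
                      stringsAsFactors = FALSE)
  if (interactions && length(candidates) >= 2L) {
    pairs <- utils::combn(candidates, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      X <- cbind(X, cols[[a]] * cols[[b]])
      terms <- rbind(terms, data.frame(term = paste0(a, ":", b),
                                       type = "interaction",
                                       parents = paste(a, b, sep = ",")))
    }
  }
  if (quadratics) {
    for (a in candidates[!is_binary]) {
      X <- cbind(X, cols[[a]]^2)
      terms <- rbind(terms, data.frame(term = paste0("I(", a, "^2)"),
                                       type = "quadratic", parents = a))
    }
  }
  colnames(X) <- terms$term
  const <- apply(X, 2, function(x) max(x) - min(x) == 0)
  if (any(const)) {
    stop("constant candidate column(s): ",
         paste(terms$term[const], collapse = ", "))
  }
  rownames(terms) <- NULL
  list(X = X, terms = terms)
}

# Gaussian-likelihood AIC on the RSS scale: n*log(RSS/n) + 2*(p + 2), where
# p counts slopes (intercept and sigma are the +2). RSS is floored at
# 1e-12 * TSS so saturated (numerically zero-residual) fits keep a finite,
# stable AIC and model search remains deterministic.
rss_aic <- function(rss, tss, n, p, aicc = FALSE) {
  floor_rss <- 1e-12 * max(tss, .Machine$double.eps)
  k <- p + 2
  aic <- n * log(max(rss, floor_rss) / n) + 2 * k
  if (aicc) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  aic
}

#' Ordinary least squares fit with inference and AIC
#'
#' Fits `y` on an intercept plus the columns of `X` by QR decomposition and
#' returns coefficient standard errors, t statistics, two-sided p values and
#' 95% confidence intervals from the classical normal-theory formulas, along
#' with R-squared, adjusted R-squared, the overall F statistic, Cohen's
#' f-squared (`R2 / (1 - R2)`) and a Gaussian-likelihood AIC
#' (`n*log(RSS/n) + 2*(p+2)`; AICc adds the small-sample correction).
#'
#' @param X numeric n x p design matrix (no intercept column), possibly with
#'   zero columns for the intercept-only model.
#' @param y numeric response vector.
#' @param aicc use the small-sample corrected AICc instead of AIC.
#' @param conf_level confidence level for the coefficient intervals.
#' @return An object of class `ols_fit`: list with `coefficients` (a data
#'   frame with columns `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `aic`,
#'   `r2`, `adj_r2`, `f_stat`, `cohens_f2`, `n`, `p_terms`, `rss`, `sigma`,
#'   `fitted`, `residuals`.
#' @export
#' @examples
#' X <- cbind(a = rnorm(20), b = rnorm(20))
#' y <- 1 + 2 * X[, "a"] + rnorm(20, sd = 0.1)
#' ols_fit(X, y)
ols_fit <- function(X, y, aicc = FALSE, conf_level = 0.95) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("'X' and 'y' dimensions disagree")
  if (n <= p + 1L) stop("need n > p + 1 observations to estimate error variance")
  Xi <- cbind("(Intercept)" = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[is.na(fit$coefficients)]
    stop("singular design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p - 1L
  sigma2 <- rss / df_res
  # (X'X)^{-1} from the QR factor, columns un-pivoted
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_res else NA_real_
  f_stat <- if (p > 0 && rss > 0) ((tss - rss) / p) / (rss / df_res) else NA_real_
  structure(list(
    coefficients = data.frame(
      estimate = beta, se = se, t = tval, p = pval,
      ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
      row.names = names(beta)),
    aic = rss_aic(rss, tss, n, p, aicc),
    r2 = r2, adj_r2 = adj_r2, f_stat = f_stat,
    cohens_f2 = if (!is.na(r2) && r2 < 1) r2 / (1 - r2) else Inf,
    n = n, p_terms = p, rss = rss, sigma = sqrt(sigma2),
    fitted = as.numeric(fit$fitted.values), residuals = as.numeric(res)),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ols_fit: n = %d, %d term(s) + intercept\n", x$n, x$p_terms))
  print(round(x$coefficients, digits))
  cat(sprintf("AIC = %.3f, R2 = %.3f, adj R2 = %.3f\n", x$aic, x$r2, x$adj_r2))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
fitted.ols_fit <- function(object, ...) object$fitted

fit_subset <- function(X, y, sel, aicc) {
  ols_fit(X[, sel, drop = FALSE], y, aicc = aicc)
}

#' Bidirectional stepwise AIC model selection
#'
#' Starting from the full candidate model (every main effect, pairwise
#' interaction and quadratic expanded from the right-hand side of `formula`
#' by [build_design()]), repeatedly applies the single term addition or
#' removal that most reduces AIC, and stops when no move improves it
#' (backward-first with forward re-entry). Exact AIC ties between moves are
#' broken by higher adjusted R-squared, then by the smaller model, then by
#' candidate order, so the search is deterministic.
#'
#' @param formula model formula whose left side is the outcome and whose right
#'   side lists the candidate main effects, e.g.
#'   `dprime ~ e_local_task + e_global_task + mean_rt + n_volumes_removed +
#'   age_group`; the interaction and quadratic expansion is automatic.
#' @param data data frame of subject records.
#' @param interactions,quadratics passed to [build_design()].
#' @param aicc use small-sample corrected AICc as the selection criterion.
#' @param hierarchy if `TRUE`, a main effect may not be dropped while one of
#'   its interactions or its quadratic is in the model, and an interaction or
#'   quadratic may not enter before its parents. Default `FALSE`: the
#'   criterion alone decides.
#' @param trace print each accepted move.
#' @return An object of class `stepwise_fit`: list with `fit` (the final
#'   [ols_fit()]), `selected` (term names), `registry` (the candidate term
#'   registry), `steps` (data frame of accepted moves), plus the call,
#'   outcome name and data reference used by `predict()`.
#' @seealso [cohort_equations()] to deconstruct a fit with a group term into
#'   per-group prediction equations.
#' @export
#' @examples
#' cohort <- generate_subject_cohort(
#'   cohort_spec(n_young = 40, n_old = 40, noise_sd = 0, seed = 1))
#' fit <- stepwise_select(dprime ~ e_local_task + e_global_task + mean_rt +
#'                          n_volumes_removed + age_group, cohort)
#' coef(fit)
stepwise_select <- function(formula, data, interactions = TRUE,
                            quadratics = TRUE, aicc = FALSE,
                            hierarchy = FALSE, trace = FALSE) {
  mf <- stats::terms(formula, data = data)
  outcome <- as.character(formula[[2]])
  candidates <- attr(mf, "term.labels")
  if (any(grepl(":", candidates, fixed = TRUE))) {
    stop("list only main effects in the formula; ",
         "interactions are expanded automatically")
  }
  y <- as.numeric(data[[outcome]])
  design <- build_design(data, candidates, interactions, quadratics)
  X <- design$X
  registry <- design$terms
  all_terms <- registry$term

  allowed_drop <- function(sel, term) {
    if (!hierarchy) return(TRUE)
    if (registry$type[match(term, registry$term)] != "main") return(TRUE)
    kids <- registry$term[registry$type != "main" &
                            vapply(strsplit(registry$parents, ","),
                                   function(p) term %in% p, logical(1))]
    !any(kids %in% sel)
  }
  allowed_add <- function(sel, term) {
    if (!hierarchy) return(TRUE)
    i <- match(term, registry$term)
    if (registry$type[i] == "main") return(TRUE)
    all(strsplit(registry$parents[i], ",")[[1]] %in% sel)
  }

  current <- all_terms
  cur_fit <- fit_subset(X, y, current, aicc)
  steps <- data.frame(move = "start", term = NA_character_,
                      aic = cur_fit$aic, n_terms = length(current))
  repeat {
    moves <- list()
    for (term in current) {
      if (allowed_drop(current, term)) {
        moves[[length(moves) + 1L]] <- list(move = "drop", term = term,
                                            sel = setdiff(current, term))
      }
    }
    for (term in setdiff(all_terms, current)) {
      if (allowed_add(current, term)) {
        moves[[length(moves) + 1L]] <- list(move = "add", term = term,
                                            sel = c(current, term))
      }
    }
    if (!length(moves)) break
    evals <- lapply(moves, function(m) {
      f <- tryCatch(fit_subset(X, y, m$sel, aicc), error = function(e) NULL)
      if (is.null(f)) list(aic = Inf, adj_r2 = -Inf) else
        list(aic = f$aic, adj_r2 = f$adj_r2)
    })
    aics <- vapply(evals, `[[`, numeric(1), "aic")
    adjs <- vapply(evals, `[[`, numeric(1), "adj_r2")
    sizes <- vapply(moves, function(m) length(m$sel), numeric(1))
    best <- order(aics, -adjs, sizes)[1]
    if (!(aics[best] < cur_fit$aic - 1e-8)) break
    m <- moves[[best]]
    current <- if (m$move == "drop") setdiff(current, m$term) else
      all_terms[all_terms %in% c(current, m$term)]  # keep registry order
    cur_fit <- fit_subset(X, y, current, aicc)
    steps <- rbind(steps, data.frame(move = m$move, term = m$term,
                                     aic = cur_fit$aic,
                                     n_terms = length(current)))
    if (trace) {
      cat(sprintf("%s %-28s AIC = %.3f (%d terms)\n",
                  m$move, m$term, cur_fit$aic, length(current)))
    }
  }
  structure(list(fit = cur_fit, selected = current, registry = registry,
                 steps = steps, outcome = outcome, candidates = candidates,
                 aicc = aicc, call = match.call()),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise AIC model selection\n")
  cat("Outcome:", x$outcome, "\n")
  cat(sprintf("Candidates: %d terms; selected: %d\n",
              nrow(x$registry), length(x$selected)))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("AIC = %.3f, adj R2 = %.3f\n", x$fit$aic, x$fit$adj_r2))
  invisible(x)
}

#' @export
summary.stepwise_fit <- function(object, ...) {
  structure(list(fit = object$fit, selected = object$selected,
                 outcome = object$outcome, steps = object$steps),
            class = "summary.stepwise_fit")
}

#' @export
print.summary.stepwise_fit <- function(x, digits = 3, ...) {
  cat("Final model for", x$outcome, "\n\n")
  tab <- x$fit$coefficients
  out <- data.frame(b = round(tab$estimate, digits),
                    SE = round(tab$se, digits),
                    t = round(tab$t, digits),
                    p = signif(tab$p, 3),
                    `95% CI` = sprintf("[%.3f, %.3f]", tab$ci_lo, tab$ci_hi),
                    check.names = FALSE, row.names = rownames(tab))
  print(out)
  cat(sprintf("\nn = %d, R2 = %.3f, adj R2 = %.3f, F = %.2f, Cohen's f2 = %.3f, AIC = %.3f\n",
              x$fit$n, x$fit$r2, x$fit$adj_r2, x$fit$f_stat,
              x$fit$cohens_f2, x$fit$aic))
  invisible(x)
}

#' @export
coef.stepwise_fit <- function(object, ...) coef(object$fit)

#' @export
residuals.stepwise_fit <- function(object, ...) object$fit$residuals

#' @export
fitted.stepwise_fit <- function(object, ...) object$fit$fitted

build_columns <- function(registry, terms, newdata) {
  cols <- lapply(terms, function(tm) {
    i <- match(tm, registry$term)
    parents <- strsplit(registry$parents[i], ",")[[1]]
    missing_p <- setdiff(parents, names(newdata))
    if (length(missing_p)) {
      stop("newdata lacks covariate(s): ", paste(missing_p, collapse = ", "))
    }
    switch(registry$type[i],
           main = as.numeric(newdata[[parents]]),
           interaction = as.numeric(newdata[[parents[1]]]) *
             as.numeric(newdata[[parents[2]]]),
           quadratic = as.numeric(newdata[[parents]])^2)
  })
  do.call(cbind, stats::setNames(cols, terms))
}

#' @export
predict.stepwise_fit <- function(object, newdata, ...) {
  beta <- coef(object)
  if (!length(object$selected)) {
    return(rep(beta[["(Intercept)"]], nrow(newdata)))
  }
  Xn <- build_columns(object$registry, object$selected, newdata)
  as.numeric(beta[["(Intercept)"]] +
               Xn[, object$selected, drop = FALSE] %*% beta[object$selected])
}

#' @export
plot.stepwise_fit <- function(x, which = c("fit", "residuals"), ...) {
  which <- match.arg(which)
  if (which == "residuals") {
    graphics::plot(x$fit$fitted, x$fit$residuals,
                   xlab = "Fitted values", ylab = "Residuals",
                   main = "Residuals vs fitted", ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    obs <- x$fit$fitted + x$fit$residuals
    graphics::plot(x$fit$fitted, obs,
                   xlab = "Predicted", ylab = "Observed",
                   main = paste("Observed vs predicted", x$outcome), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Deconstruct a fitted model into per-group prediction equations
#'
#' For a model containing a 0/1 group indicator, its main effect and (only)
#' two-way interactions with that indicator, returns one linear equation per
#' group: the group-0 equation keeps the intercept and the non-group slopes;
#' the group-1 equation adds the group coefficient to the intercept and each
#' group-interaction coefficient to its partner's slope.
#'
#' @param fit a [stepwise_select()] or [ols_fit()] result (for an `ols_fit`,
#'   coefficient names must follow the `a:b` convention of [build_design()]).
#' @param group name of the binary group covariate (default `"age_group"`).
#' @return An object of class `cohort_equations`: list with named coefficient
#'   vectors `group_0` and `group_1` (intercept plus per-covariate slopes).
#' @export
#' @examples
#' cohort <- generate_subject_cohort(
#'   cohort_spec(n_young = 40, n_old = 40, noise_sd = 0, seed = 1))
#' fit <- stepwise_select(dprime ~ e_local_task + e_global_task + mean_rt +
#'                          n_volumes_removed + age_group, cohort)
#' cohort_equations(fit)
cohort_equations <- function(fit, group = "age_group") {
  beta <- coef(fit)
  nms <- names(beta)
  if (!(group %in% nms)) {
    stop("the fitted model does not contain the group main effect '",
         group, "'")
  }
  if (any(nms == paste0("I(", group, "^2)"))) {
    stop("a quadratic group term cannot be deconstructed")
  }
  split_parts <- strsplit(nms, ":", fixed = TRUE)
  is_group_int <- vapply(split_parts, function(p) {
    length(p) == 2L && group %in% p
  }, logical(1))
  too_deep <- vapply(split_parts, function(p) {
    length(p) > 2L && group %in% p
  }, logical(1))
  if (any(too_deep)) {
    stop("three-way interactions with the group term are not supported")
  }
  plain <- setdiff(nms[!is_group_int], c("(Intercept)", group))
  g0 <- c("(Intercept)" = unname(beta[["(Intercept)"]]), beta[plain])
  g1 <- g0
  g1[["(Intercept)"]] <- g1[["(Intercept)"]] + beta[[group]]
  for (nm in nms[is_group_int]) {
    partner <- setdiff(split_parts[[match(nm, nms)]], group)
    if (!partner %in% names(g1)) {
      g1[partner] <- 0
      g0[partner] <- 0
    }
    g1[[partner]] <- g1[[partner]] + beta[[nm]]
  }
  structure(list(group_0 = g0, group_1 = g1, group = group),
            class = "cohort_equations")
}

#' @export
print.cohort_equations <- function(x, digits = 4, ...) {
  show <- function(b, label) {
    terms <- sprintf("%+.*f*%s", digits, b[-1], names(b)[-1])
    cat(sprintf("  %s = %.*f %s\n", label, digits, b[[1]],
                paste(terms, collapse = " ")))
  }
  cat("Per-group prediction equations (", x$group, " = 0 / 1):\n", sep = "")
  show(x$group_0, "group 0")
  show(x$group_1, "group 1")
  invisible(x)
}

#' Serialize a model fit to JSON
#'
#' @param fit a `stepwise_fit` or `ols_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modelfit_json <- function(fit, path) {
  f <- if (inherits(fit, "stepwise_fit")) fit$fit else fit
  tab <- f$coefficients
  jsonlite::write_json(
    list(terms = rownames(tab),
         coefficients = as.list(stats::setNames(tab$estimate, rownames(tab))),
         se = as.list(stats::setNames(tab$se, rownames(tab))),
         t = as.list(stats::setNames(tab$t, rownames(tab))),
         p = as.list(stats::setNames(tab$p, rownames(tab))),
         ci_lo = as.list(stats::setNames(tab$ci_lo, rownames(tab))),
         ci_hi = as.list(stats::setNames(tab$ci_hi, rownames(tab))),
         aic = f$aic, r2 = f$r2, adj_r2 = f$adj_r2,
         f_stat = f$f_stat, cohens_f2 = f$cohens_f2, n = f$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
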