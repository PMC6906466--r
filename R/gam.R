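# Penalized-spline generalized additive models.
#
# The engine fits eta = X b + offset by penalized IRLS, with one ridge-type
# quadratic penalty lambda_s * S_s per smooth (squared second differences)
# and per random-intercept block (identity penalty: the standard
# smooth-as-random-effect identity). Smoothing parameters are chosen by
# GCV on a log-spaced grid, coordinate-wise for multiple smooths, at the
# converged working weights; the fit is then re-converged at the selected
# lambdas. Everything is deterministic.

et_family <- function(name) {
  switch(name,
    binomial = list(
      name = "binomial",
      linkinv = stats::plogis,
      mu_eta = function(mu) mu * (1 - mu),
      variance = function(mu) mu * (1 - mu),
      init_mu = function(y, w) (w * y + 0.5) / (w + 1),
      valid_y = function(y) all(y >= 0 & y <= 1),
      dev = function(y, mu, w) sum(binomial()$dev.resids(y, mu, w)),
      fixed_disp = 1,
      loglik = function(y, mu, w, disp) {
        m <- round(w)
        sum(stats::dbinom(round(y * m), m, mu, log = TRUE))
      }
    ),
    gamma = list(
      name = "gamma",
      linkinv = exp,
      mu_eta = function(mu) mu,
      variance = function(mu) mu^2,
      init_mu = function(y, w) pmax(y, mean(y) / 10),
      valid_y = function(y) all(y > 0),
      dev = function(y, mu, w) {
        2 * sum(w * (-log(y / mu) + (y - mu) / mu))
      },
      fixed_disp = NULL,
      loglik = function(y, mu, w, disp) {
        shape <- 1 / disp
        sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
      }
    ),
    beta = list(
      name = "beta",
      linkinv = stats::plogis,
      mu_eta = function(mu) mu * (1 - mu),
      variance = function(mu) mu * (1 - mu),
      init_mu = function(y, w) y,
      valid_y = function(y) all(y > 0 & y < 1),
      dev = function(y, mu, w) sum(w * (y - mu)^2 / (mu * (1 - mu))),
      fixed_disp = NULL,
      loglik = function(y, mu, w, disp) {
        phi <- max(1 / disp - 1, 1e-2)
        sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
      }
    ),
    stop("unknown family: ", name, call. = FALSE)
  )
}

# One penalized IRLS run at fixed lambdas. blocks: list of integer index
# vectors into the columns of X; penalties: list of matching matrices.
pirls <- function(X, y, fam, w0, offset, blocks, penalties, lambdas,
                  maxit = 200, tol = 1e-8, ridge = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  P <- diag(ridge, p)
  for (s in seq_along(blocks)) {
    idx <- blocks[[s]]
    P[idx, idx] <- P[idx, idx] + lambdas[s] * penalties[[s]]
  }
  mu <- fam$init_mu(y, w0)
  eta <- if (fam$name == "gamma") log(mu) else qlogis(mu)
  dev_old <- Inf
  converged <- FALSE
  beta <- NULL
  for (it in seq_len(maxit)) {
    mm <- fam$mu_eta(mu)
    w <- w0 * mm^2 / fam$variance(mu)
    z <- (eta - offset) + (y - mu) / mm
    XtW <- t(X * w)
    XtWX <- XtW %*% X
    beta <- tryCatch(
      solve(XtWX + P, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta)) {
      P <- P + diag(1e-6, p)
      next
    }
    eta <- as.numeric(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- fam$linkinv(eta)
    if (fam$name != "gamma") mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    dev <- fam$dev(y, mu, w0)
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  mm <- fam$mu_eta(mu)
  w <- w0 * mm^2 / fam$variance(mu)
  z <- (eta - offset) + (y - mu) / mm
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  A <- solve(XtWX + P)
  edf_i <- rowSums(A * t(XtWX))
  pearson <- sum(w0 * (y - mu)^2 / fam$variance(mu))
  list(beta = as.numeric(beta), mu = mu, eta = eta, w = w, z = z,
       XtWX = XtWX, A = A, edf_i = edf_i, edf = sum(edf_i),
       dev = dev_old, pearson = pearson, converged = converged,
       iterations = it)
}

# GCV (Pearson-based) of the penalized weighted LS problem at fixed working
# response/weights, for lambda selection.
gcv_at <- function(X, z, w, blocks, penalties, lambdas, ridge = 1e-9,
                   gamma = 1.4) {
  p <- ncol(X); n <- nrow(X)
  P <- diag(ridge, p)
  for (s in seq_along(blocks)) {
    idx <- blocks[[s]]
    P[idx, idx] <- P[idx, idx] + lambdas[s] * penalties[[s]]
  }
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  A <- tryCatch(solve(XtWX + P), error = function(e) NULL)
  if (is.null(A)) return(Inf)
  beta <- A %*% (XtW %*% z)
  fit <- as.numeric(X %*% beta)
  tr <- sum(rowSums(A * t(XtWX)))
  rss <- sum(w * (z - fit)^2)
  n * rss / (n - gamma * tr)^2
}

#' Fit a penalized-spline generalized additive model
#'
#' Families: binomial (logit link; binary responses or proportions with
#' `weights` as denominators), gamma (log link) and beta (logit link, with
#' the precision estimated by the method of moments at convergence).
#' Smooth terms carry squared-second-difference penalties with smoothing
#' parameters selected by GCV on a log-spaced grid (49 points,
#' 1e-4..1e4); random intercepts are realised as ridge-penalized group
#' indicators whose ridge parameter is selected on the same grid. Offsets
#' enter on the link scale.
#'
#' @param data A data frame.
#' @param response Response column name.
#' @param family `"binomial"`, `"gamma"` or `"beta"`.
#' @param smooths List of [sm()] specifications.
#' @param linear Character vector of columns entering as unpenalized
#'   linear terms.
#' @param offset Column name or numeric vector (link scale), or NULL.
#' @param weights Prior weights (column name or numeric vector);
#'   binomial-proportion denominators.
#' @param group Column name for a random-intercept grouping factor.
#' @param lambda_grid Smoothing-parameter grid.
#' @param sweeps Coordinate-descent sweeps over the smooths (default 2).
#' @param fixed_lambda Optional named numeric of fixed smoothing
#'   parameters (names = smooth variables or `"(group)"`), skipping
#'   selection for those terms.
#' @param gcv_gamma Effective-degrees-of-freedom inflation in the GCV
#'   score (default 1.4), the standard guard against GCV undersmoothing
#'   with binary responses.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return An object of class `et_gam` with coefficients, per-term edf,
#'   `aicc`, `deviance_explained`, a `terms` table with approximate Wald
#'   tests, and support for [predict.et_gam()] and [partial_effect()].
#' @export
fit_gam <- function(data, response, family = c("binomial", "gamma", "beta"),
                    smooths = list(), linear = character(), offset = NULL,
                    weights = NULL, group = NULL,
                    lambda_grid = 10^seq(-4, 4, length.out = 49),
                    sweeps = 2, fixed_lambda = NULL, gcv_gamma = 1.4,
                    maxit = 200, tol = 1e-8) {
  family <- match.arg(family)
  fam <- et_family(family)
  y <- data[[response]]
  if (is.null(y)) stop("response column not found", call. = FALSE)
  if (!fam$valid_y(y)) {
    stop("response outside the support of the ", family, " family",
         call. = FALSE)
  }
  n <- length(y)
  w0 <- if (is.null(weights)) rep(1, n)
        else if (is.character(weights)) data[[weights]] else weights
  off <- if (is.null(offset)) rep(0, n)
         else if (is.character(offset)) data[[offset]] else offset
  stopifnot(length(w0) == n, length(off) == n)

  # --- design assembly -----------------------------------------------
  Xl <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  col_terms <- "(Intercept)"
  for (v in linear) {
    Xl[[length(Xl) + 1L]] <- matrix(data[[v]], n, 1,
                                    dimnames = list(NULL, v))
    col_terms <- c(col_terms, v)
  }
  blocks <- list(); penalties <- list(); term_names <- character()
  bases <- list()
  p0 <- sum(vapply(Xl, ncol, 1L))
  for (spec in smooths) {
    b <- build_basis(spec, data[[spec$var]])
    idx <- p0 + seq_len(ncol(b$X))
    Xl[[length(Xl) + 1L]] <- b$X
    col_terms <- c(col_terms, rep(spec$var, ncol(b$X)))
    blocks[[length(blocks) + 1L]] <- idx
    penalties[[length(penalties) + 1L]] <- b$S
    term_names <- c(term_names, spec$var)
    bases[[spec$var]] <- b
    p0 <- p0 + ncol(b$X)
  }
  group_levels <- NULL
  if (!is.null(group)) {
    g <- factor(data[[group]])
    group_levels <- levels(g)
    Zg <- stats::model.matrix(~ 0 + g)
    colnames(Zg) <- group_levels
    idx <- p0 + seq_len(ncol(Zg))
    Xl[[length(Xl) + 1L]] <- Zg
    col_terms <- c(col_terms, rep("(group)", ncol(Zg)))
    blocks[[length(blocks) + 1L]] <- idx
    penalties[[length(penalties) + 1L]] <- diag(ncol(Zg))
    term_names <- c(term_names, "(group)")
    p0 <- p0 + ncol(Zg)
  }
  X <- do.call(cbind, Xl)

  # --- smoothing-parameter selection ---------------------------------
  nS <- length(blocks)
  lambdas <- rep(1, nS)
  fixed <- rep(FALSE, nS)
  if (!is.null(fixed_lambda)) {
    hit <- match(term_names, names(fixed_lambda))
    fixed <- !is.na(hit)
    lambdas[fixed] <- fixed_lambda[hit[fixed]]
  }
  fit <- pirls(X, y, fam, w0, off, blocks, penalties, lambdas,
               maxit = maxit, tol = tol)
  if (nS > 0 && !all(fixed)) {
    for (sw in seq_len(sweeps)) {
      for (s in seq_len(nS)) {
        if (fixed[s]) next
        scores <- vapply(lambda_grid, function(l) {
          lam <- lambdas; lam[s] <- l
          gcv_at(X, fit$z, fit$w, blocks, penalties, lam,
                 gamma = gcv_gamma)
        }, numeric(1))
        lambdas[s] <- lambda_grid[which.min(scores)]
      }
      fit <- pirls(X, y, fam, w0, off, blocks, penalties, lambdas,
                   maxit = maxit, tol = tol)
    }
  }
  if (!fit$converged) {
    warning("penalized IRLS did not converge in ", maxit, " iterations",
            call. = FALSE)
  }

  # --- summaries ------------------------------------------------------
  disp <- fam$fixed_disp %||% max(fit$pearson / max(n - fit$edf, 1), 1e-8)
  Vb <- disp * fit$A
  edf_term <- vapply(seq_len(nS),
                     function(s) sum(fit$edf_i[blocks[[s]]]), numeric(1))
  names(edf_term) <- term_names
  k_eff <- fit$edf + if (is.null(fam$fixed_disp)) 1 else 0
  ll <- fam$loglik(y, fit$mu, w0, disp)
  aicc_val <- aicc_value(ll, k_eff, n)
  null_fit <- pirls(X[, 1, drop = FALSE], y, fam, w0, off,
                    list(), list(), numeric(0), maxit = maxit, tol = tol)
  dev_expl <- if (null_fit$dev > 0) 1 - fit$dev / null_fit$dev else 0
  dev_expl <- min(max(dev_expl, 0), 1)

  # approximate Wald tests per term
  terms_tbl <- wald_terms(fit$beta, Vb, col_terms, linear, term_names,
                          edf_term)

  structure(list(
    family = family, response = response,
    coefficients = stats::setNames(fit$beta, colnames(X)),
    col_terms = col_terms, linear = linear, bases = bases,
    group = group, group_levels = group_levels,
    offset_name = if (is.character(offset)) offset else NULL,
    lambdas = stats::setNames(lambdas, term_names),
    edf = edf_term, edf_total = fit$edf,
    vcov = Vb, dispersion = disp, loglik = ll,
    deviance = fit$dev, null_deviance = null_fit$dev,
    deviance_explained = dev_expl,
    aicc = aicc_val, n = n, converged = fit$converged,
    terms = terms_tbl,
    fitted = fit$mu, linear_predictor = fit$eta,
    prior_weights = w0, offset_values = off
  ), class = "et_gam")
}

wald_terms <- function(beta, Vb, col_terms, linear, term_names, edf_term) {
  rows <- list()
  for (v in linear) {
    j <- which(col_terms == v)
    se <- sqrt(Vb[j, j])
    stat <- (beta[j] / se)^2
    rows[[v]] <- tibble::tibble(term = v, type = "linear", edf = 1,
                                statistic = stat,
                                p_value = stats::pchisq(stat, 1,
                                                        lower.tail = FALSE))
  }
  for (v in term_names) {
    j <- which(col_terms == v)
    b <- beta[j]
    V <- Vb[j, j, drop = FALSE]
    ev <- eigen(V, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-8
    if (!any(pos)) {
      stat <- 0
    } else {
      Vi <- ev$vectors[, pos, drop = FALSE] %*%
        diag(1 / ev$values[pos], sum(pos)) %*%
        t(ev$vectors[, pos, drop = FALSE])
      stat <- as.numeric(t(b) %*% Vi %*% b)
    }
    df <- max(min(edf_term[[v]], sum(pos)), 0.5)
    rows[[v]] <- tibble::tibble(term = v, type = "smooth",
                                edf = edf_term[[v]], statistic = stat,
                                p_value = stats::pchisq(stat, df,
                                                        lower.tail = FALSE))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.et_gam <- function(x, ...) {
  cat("<et_gam> ", x$family, " fit, n = ", x$n,
      ", total edf = ", round(x$edf_total, 2),
      ", AICc = ", round(x$aicc, 2),
      ", deviance explained = ", sprintf("%.1f%%",
                                         100 * x$deviance_explained),
      "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)`, with `k` the effective number
#' of parameters (total edf plus one for an estimated dispersion).
#'
#' @param loglik Log-likelihood.
#' @param k Effective number of parameters (> 0).
#' @param n Sample size; `n - k - 1` must be positive.
#' @return AICc value.
#' @export
aicc_value <- function(loglik, k, n) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (n - k - 1 <= 0) {
    stop("AICc undefined: n - k - 1 must be positive", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_value
#' @param fit An `et_gam` fit.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "et_gam"))
  fit$aicc
}

build_design <- function(object, newdata, exclude_group = TRUE) {
  n <- nrow(newdata)
  Xl <- list(matrix(1, n, 1))
  for (v in object$linear) {
    Xl[[length(Xl) + 1L]] <- matrix(newdata[[v]], n, 1)
  }
  for (v in names(object$bases)) {
    Xl[[length(Xl) + 1L]] <- eval_basis(object$bases[[v]], newdata[[v]])
  }
  if (!is.null(object$group)) {
    G <- length(object$group_levels)
    Zg <- matrix(0, n, G)
    if (!exclude_group && object$group %in% names(newdata)) {
      m <- match(as.character(newdata[[object$group]]),
                 object$group_levels)
      ok <- !is.na(m)
      Zg[cbind(which(ok), m[ok])] <- 1
    }
    Xl[[length(Xl) + 1L]] <- Zg
  }
  do.call(cbind, Xl)
}

#' Predict from a penalized GAM fit
#'
#' @param object An `et_gam` fit.
#' @param newdata Data frame of covariates; defaults to the training
#'   fitted values.
#' @param type `"link"`, `"response"`, or `"rate"` (response divided by
#'   the exponentiated offset — the per-offset-unit rate, invariant to
#'   rescaling the offset).
#' @param se.fit Return link-scale standard errors.
#' @param offset Offset values for `newdata` (link scale); defaults to the
#'   stored offset column when present in `newdata`, else 0.
#' @param exclude_group Predict at the population level (random intercepts
#'   zeroed; default TRUE).
#' @param ... Unused.
#' @return Numeric vector, or a list with `fit` and `se.fit`.
#' @export
predict.et_gam <- function(object, newdata = NULL,
                           type = c("link", "response", "rate"),
                           se.fit = FALSE, offset = NULL,
                           exclude_group = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear_predictor
    off <- object$offset_values
    X <- NULL
  } else {
    X <- build_design(object, newdata, exclude_group = exclude_group)
    off <- if (!is.null(offset)) {
      if (is.character(offset)) newdata[[offset]] else offset
    } else if (!is.null(object$offset_name) &&
               object$offset_name %in% names(newdata)) {
      newdata[[object$offset_name]]
    } else rep(0, nrow(newdata))
    eta <- as.numeric(X %*% object$coefficients) + off
  }
  fam <- et_family(object$family)
  out <- switch(type,
    link = eta,
    response = fam$linkinv(eta),
    rate = fam$linkinv(eta) / exp(off)
  )
  if (se.fit) {
    if (is.null(X)) {
      stop("se.fit requires newdata", call. = FALSE)
    }
    se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
    list(fit = out, se.fit = se)
  } else {
    out
  }
}

#' Partial effect of one smooth (or linear) term
#'
#' The centred contribution of a single term over a grid of its covariate,
#' with a 95% band from the Bayesian covariance of the coefficients —
#' the building block for response-curve figures.
#'
#' @param fit An `et_gam` fit.
#' @param term Term (covariate) name.
#' @param n Grid size (default 100).
#' @param xlim Optional grid range; defaults to the training range (or the
#'   period for cyclic terms).
#' @return A tibble: `x`, `fit`, `se`, `lower`, `upper` (link scale).
#' @export
partial_effect <- function(fit, term, n = 100, xlim = NULL) {
  stopifnot(inherits(fit, "et_gam"))
  if (term %in% names(fit$bases)) {
    b <- fit$bases[[term]]
    if (is.null(xlim)) {
      xlim <- if (b$spec$bs == "cyclic") c(0, b$spec$period) else b$xrange
    }
    xg <- seq(xlim[1], xlim[2], length.out = n)
    Xb <- eval_basis(b, xg)
    j <- which(fit$col_terms == term)
  } else if (term %in% fit$linear) {
    j <- which(fit$col_terms == term)
    xr <- xlim %||% c(0, 1)
    xg <- seq(xr[1], xr[2], length.out = n)
    Xb <- matrix(xg, n, 1)
  } else {
    stop("unknown term: ", term, call. = FALSE)
  }
  f <- as.numeric(Xb %*% fit$coefficients[j])
  V <- fit$vcov[j, j, drop = FALSE]
  se <- sqrt(pmax(rowSums((Xb %*% V) * Xb), 0))
  tibble::tibble(x = xg, fit = f, se = se,
                 lower = f - 1.96 * se, upper = f + 1.96 * se)
}

#' AICc model selection with a significance tie-break
#'
#' The candidate with the lowest AICc wins. Candidates within 1.0 AICc of
#' the best form a tie set; within it, candidates containing terms whose
#' approximate Wald p exceeds 0.05 are set aside in favour of candidates
#' whose every term is supported, and remaining ties go to the fewest
#' effective parameters — so a term that does not clearly earn its keep is
#' dropped.
#'
#' @param fits List of `et_gam` fits of the same response.
#' @param labels Optional candidate labels.
#' @param alpha Significance level for the tie-break (default 0.05).
#' @return A list: `best` (the chosen fit), `best_label`, and `table`
#'   (per-candidate AICc, edf, delta, tie/supported flags).
#' @export
select_model <- function(fits, labels = NULL, alpha = 0.05) {
  if (length(fits) == 0L) stop("no candidate models", call. = FALSE)
  labels <- labels %||% paste0("model", seq_along(fits))
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  edfs <- vapply(fits, function(f) f$edf_total, numeric(1))
  supported <- vapply(fits, function(f) {
    nrow(f$terms) == 0L ||
      all(f$terms$p_value[f$terms$term != "(group)"] <= alpha)
  }, logical(1))
  delta <- aiccs - min(aiccs)
  tie <- delta < 1
  pool <- if (any(tie & supported)) which(tie & supported) else which(tie)
  best_i <- pool[order(edfs[pool], aiccs[pool])][1]
  list(
    best = fits[[best_i]],
    best_label = labels[best_i],
    table = tibble::tibble(label = labels, aicc = aiccs, edf = edfs,
                           delta = delta, tie = tie,
                           all_terms_supported = supported,
                           selected = seq_along(fits) == best_i)
  )
}
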