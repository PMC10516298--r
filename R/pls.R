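# Partial least squares (PLS1, NIPALS) with cross-validated component
# selection, standardized coefficients and contribution weights.

# core NIPALS engine on matrices; returns the coefficient path so one
# decomposition serves every component count up to ncomp
pls1_engine <- function(x, y, ncomp) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  xm <- colMeans(x)
  xs <- apply(x, 2, sd)
  if (any(!is.finite(xs)) || any(xs == 0)) {
    bad <- colnames(x)[which(!is.finite(xs) | xs == 0)]
    abort(sprintf("Zero-variance feature(s): %s.", paste(bad, collapse = ", ")))
  }
  xsc <- sweep(sweep(x, 2, xm, "-"), 2, xs, "/")
  ym <- mean(y)
  ncomp <- min(ncomp, p, n - 1)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  q_vec <- numeric(ncomp)
  xd <- xsc
  yd <- y - ym
  used <- 0
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    w_mat[, h] <- w
    p_mat[, h] <- drop(crossprod(xd, tt)) / tt2
    q_vec[h] <- sum(yd * tt) / tt2
    xd <- xd - tcrossprod(tt, p_mat[, h])
    yd <- yd - q_vec[h] * tt
    used <- h
  }
  # coefficient path on the standardized scale: B_h = W_h (P_h'W_h)^-1 q_h
  path <- matrix(0, p, max(used, 1))
  if (used > 0) {
    for (h in seq_len(used)) {
      wh <- w_mat[, seq_len(h), drop = FALSE]
      ph <- p_mat[, seq_len(h), drop = FALSE]
      path[, h] <- wh %*% solve(crossprod(ph, wh), q_vec[seq_len(h)])
    }
  }
  list(path = path, ncomp = used, xm = xm, xs = xs, ym = ym,
       w = w_mat[, seq_len(max(used, 1)), drop = FALSE])
}

pls1_predict_path <- function(engine, newx) {
  newx <- as.matrix(newx)
  xsc <- sweep(sweep(newx, 2, engine$xm, "-"), 2, engine$xs, "/")
  xsc %*% engine$path + engine$ym
}

#' Fit a PLS1 regression
#'
#' NIPALS partial least squares with one response. Predictors are
#' standardized internally; with as many components as (full-rank)
#' predictors the coefficients coincide with ordinary least squares.
#'
#' @param data Data frame containing predictors and the response.
#' @param outcome Name of the response column.
#' @param features Character vector of predictor columns (default: all
#'   numeric columns except the response).
#' @param ncomp Number of latent components (1 .. number of features).
#' @return An object of class `pls_fit` with original-scale
#'   `coefficients` and `intercept`, standardized coefficients
#'   `beta_std`, `contributions` (normalized |beta_std|), `fitted`,
#'   `r_squared`, `adj_r_squared`, `ncomp` and `n`.
#' @export
#' @examples
#' d <- tibble::tibble(x1 = rnorm(30), y = 1 + 2 * x1)
#' fit <- fit_pls(d, "y", "x1", ncomp = 1)
#' glance(fit)$r.squared # 1
fit_pls <- function(data, outcome, features = NULL, ncomp = 1L) {
  if (!outcome %in% names(data)) abort(sprintf("Outcome '%s' not in data.", outcome))
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], outcome)
  }
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) abort(sprintf("Unknown feature(s): %s.", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[c(features, outcome)]), c(features, outcome)]
  x <- as.matrix(d[features])
  y <- d[[outcome]]
  n <- nrow(x)
  if (n < 3) abort("Need at least 3 complete cases.")
  if (ncomp < 1 || ncomp > length(features)) {
    abort("`ncomp` must be between 1 and the number of features.")
  }
  eng <- pls1_engine(x, y, ncomp)
  h <- eng$ncomp
  if (h < 1) abort("PLS found no usable latent direction (response may be constant).")
  b_std_scale <- eng$path[, h]
  coefs <- b_std_scale / eng$xs
  intercept <- eng$ym - sum(coefs * eng$xm)
  fitted <- drop(x %*% coefs) + intercept
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  p <- length(features)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sdy <- sd(y)
  if (sdy == 0) abort("Response has zero variance.")
  beta_std <- coefs * eng$xs / sdy
  contrib <- abs(beta_std) / sum(abs(beta_std))
  structure(list(
    outcome = outcome, features = features,
    coefficients = setNames(coefs, features), intercept = intercept,
    beta_std = setNames(beta_std, features),
    contributions = setNames(contrib, features),
    ncomp = h, n = n, fitted = fitted, observed = y,
    r_squared = r2, adj_r_squared = if (n - p - 1 > 0) adj else NA_real_,
    engine = eng
  ), class = "pls_fit")
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  drop(x %*% object$coefficients) + object$intercept
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %s ~ %d feature(s), %d component(s), n = %d, R2 = %.3f\n",
              x$outcome, length(x$features), x$ncomp, x$n, x$r_squared))
  invisible(x)
}

#' @rdname fit_pls
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pls_fit <- function(x, ...) {
  tibble(term = x$features,
         estimate = unname(x$coefficients),
         std_estimate = unname(x$beta_std),
         contribution = unname(x$contributions))
}

#' @rdname fit_pls
#' @exportS3Method generics::glance
glance.pls_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
         ncomp = x$ncomp, nobs = x$n)
}

#' Standardized PLS coefficients and contribution weights
#'
#' Standardized coefficients multiply each raw coefficient by the
#' predictor SD over the response SD; contribution weights are the
#' normalized absolute standardized coefficients (they sum to one).
#'
#' @param fit A [fit_pls()] object.
#' @return Tibble: `term`, `std_estimate`, `contribution`.
#' @export
standardized_coefficients <- function(fit) {
  if (!inherits(fit, "pls_fit")) abort("`fit` must be a pls_fit.")
  tibble(term = fit$features,
         std_estimate = unname(fit$beta_std),
         contribution = unname(fit$contributions))
}

cv_fold_ids <- function(n, folds, seed) {
  withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Select the number of PLS components by cross-validation
#'
#' Evaluates 1 .. `max_comp` latent components by k-fold cross-validated
#' mean squared error and returns the minimizer (ties broken toward
#' fewer components).
#'
#' @param x Predictor matrix or data frame (complete cases).
#' @param y Response vector.
#' @param folds Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param max_comp Largest component count to evaluate; defaults to
#'   `min(p, n - ceiling(n / folds))`.
#' @return List: `ncomp` (selected), `cv_mse` (per component count),
#'   `cv_r2` (of the selected count).
#' @export
select_components_cv <- function(x, y, folds = 5L, seed = 1L, max_comp = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) abort("Fewer observations than folds.")
  p <- ncol(x)
  max_comp <- min(max_comp %||% Inf, p, n - ceiling(n / folds))
  max_comp <- max(1L, as.integer(max_comp))
  ids <- cv_fold_ids(n, folds, seed)
  pred <- matrix(NA_real_, n, max_comp)
  for (f in seq_len(folds)) {
    test <- ids == f
    eng <- pls1_engine(x[!test, , drop = FALSE], y[!test], max_comp)
    ph <- pls1_predict_path(eng, x[test, , drop = FALSE])
    # engines may stop early; recycle the last available component
    for (h in seq_len(max_comp)) {
      pred[test, h] <- ph[, min(h, eng$ncomp)]
    }
  }
  mse <- colMeans((pred - y)^2)
  ncomp <- which.min(mse) # which.min takes the first (fewest) on ties
  cv_r2 <- 1 - mse[ncomp] / mean((y - mean(y))^2)
  list(ncomp = as.integer(ncomp), cv_mse = mse, cv_r2 = unname(cv_r2))
}

#' Search settings for PLS feature selection
#'
#' @param pool Candidate feature names (`NULL`: all oculomotor parameter
#'   columns present in the data).
#' @param min_size,max_size Subset sizes searched. An exhaustive search
#'   capped below the pool size is logged as capped.
#' @param folds,seed Cross-validation folds and fold-shuffle seed.
#' @param metric Selection metric: in-sample `"r2"` (default),
#'   `"adj_r2"` or cross-validated `"cv_r2"`.
#' @param mode `"exhaustive"` (all subsets of the allowed sizes) or
#'   `"greedy"` (forward selection).
#' @param age_col Fixed covariate appended to every candidate subset
#'   (never searched over); `NULL` to disable.
#' @return List of class `search_settings`.
#' @export
search_settings <- function(pool = NULL, min_size = 1L, max_size = 8L,
                            folds = 5L, seed = 1L,
                            metric = c("r2", "adj_r2", "cv_r2"),
                            mode = c("exhaustive", "greedy"),
                            age_col = "age") {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (folds < 2) abort("`folds` must be >= 2.")
  if (min_size < 1 || max_size < min_size) abort("Invalid subset size range.")
  structure(list(pool = pool, min_size = as.integer(min_size),
                 max_size = as.integer(max_size), folds = as.integer(folds),
                 seed = as.integer(seed), metric = metric, mode = mode,
                 age_col = age_col),
            class = c("search_settings", "list"))
}

score_subset <- function(data, outcome, vars, settings) {
  d <- data[stats::complete.cases(data[c(vars, outcome)]), c(vars, outcome), drop = FALSE]
  n <- nrow(d)
  p <- length(vars)
  if (n < p + 2 || n < settings$folds) return(NULL)
  x <- as.matrix(d[vars])
  if (any(apply(x, 2, sd) == 0)) return(NULL)
  y <- d[[outcome]]
  sel <- select_components_cv(x, y, folds = settings$folds, seed = settings$seed)
  fit <- fit_pls(d, outcome, vars, ncomp = sel$ncomp)
  metric_value <- switch(settings$metric,
                         r2 = fit$r_squared,
                         adj_r2 = fit$adj_r_squared,
                         cv_r2 = sel$cv_r2)
  list(fit = fit, sel = sel, n = n, metric = metric_value)
}

#' PLS regression with exhaustive (or greedy) feature selection
#'
#' Searches subsets of the candidate oculomotor parameters (the age
#' covariate is appended to every subset), restricting each candidate
#' model to the participants with complete data for that subset,
#' selecting the latent-component count by k-fold cross-validation, and
#' scoring by the selection metric (in-sample R-squared by default).
#' Returns the best model found with its standardized coefficients,
#' contribution weights, R-squared and adjusted R-squared.
#'
#' @param data Tibble with the outcome, the candidate parameters and the
#'   age covariate.
#' @param outcome Outcome column name (e.g. `"edss"`).
#' @param settings A [search_settings()].
#' @return Object of class `pls_selection`: `fit` (the winning
#'   [fit_pls()]), `features` (winning subset incl. the covariate),
#'   `ncomp`, `r_squared`, `adj_r_squared`, `cv_r2`, `n`, `search_log`
#'   (one row per evaluated subset) and `capped` (whether the search
#'   space was restricted).
#' @export
exhaustive_feature_selection <- function(data, outcome,
                                         settings = search_settings()) {
  if (!outcome %in% names(data)) abort(sprintf("Outcome '%s' not in data.", outcome))
  pool <- settings$pool %||%
    intersect(profile_parameter_names(TRUE), names(data))
  miss <- setdiff(pool, names(data))
  if (length(miss) > 0) {
    abort(sprintf("Candidate feature(s) not in data: %s.", paste(miss, collapse = ", ")))
  }
  covar <- settings$age_col
  if (!is.null(covar) && !covar %in% names(data)) {
    abort(sprintf("Covariate column '%s' not in data.", covar))
  }
  max_size <- min(settings$max_size, length(pool))
  capped <- settings$mode == "greedy" || max_size < length(pool)
  if (capped) {
    warn(sprintf("Feature search is not fully exhaustive (%s, sizes %d-%d of %d candidates).",
                 settings$mode, settings$min_size, max_size, length(pool)))
  }
  log_rows <- list()
  best <- NULL
  consider <- function(vars) {
    sc <- score_subset(data, outcome, c(vars, covar), settings)
    if (is.null(sc)) return(NULL)
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      subset = paste(vars, collapse = "+"), size = length(vars),
      n = sc$n, ncomp = sc$fit$ncomp, r2 = sc$fit$r_squared,
      adj_r2 = sc$fit$adj_r_squared, cv_r2 = sc$sel$cv_r2,
      metric = sc$metric
    )
    if (is.null(best) || sc$metric > best$metric) {
      best <<- c(sc, list(vars = vars))
    }
    sc
  }
  if (settings$mode == "exhaustive") {
    for (k in settings$min_size:max_size) {
      sets <- utils::combn(pool, k, simplify = FALSE)
      for (s in sets) consider(s)
    }
  } else { # greedy forward
    current <- character(0)
    remaining <- pool
    while (length(current) < max_size && length(remaining) > 0) {
      scores <- purrr::map_dbl(remaining, function(f) {
        sc <- consider(c(current, f))
        if (is.null(sc)) -Inf else sc$metric
      })
      if (all(!is.finite(scores))) break
      pick <- remaining[which.max(scores)]
      current <- c(current, pick)
      remaining <- setdiff(remaining, pick)
    }
  }
  if (is.null(best)) {
    abort("No candidate subset had enough complete cases (need n > p + 1).")
  }
  structure(list(
    outcome = outcome, features = c(best$vars, covar),
    selected_parameters = best$vars, covariate = covar,
    fit = best$fit, ncomp = best$fit$ncomp,
    r_squared = best$fit$r_squared, adj_r_squared = best$fit$adj_r_squared,
    cv_r2 = best$sel$cv_r2, n = best$n,
    search_log = bind_rows(log_rows), capped = capped, settings = settings
  ), class = "pls_selection")
}

#' @export
print.pls_selection <- function(x, ...) {
  cat(sprintf("<pls_selection> %s: %d parameter(s) + %s, ncomp = %d, n = %d\n",
              x$outcome, length(x$selected_parameters),
              x$covariate %||% "no covariate", x$ncomp, x$n))
  cat(sprintf("  R2 = %.3f (adj %.3f, CV %.3f); %d subsets evaluated%s\n",
              x$r_squared, x$adj_r_squared, x$cv_r2, nrow(x$search_log),
              if (x$capped) " [capped search]" else ""))
  cat("  selected:", paste(x$selected_parameters, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pls_selection <- function(x, ...) tidy(x$fit)

#' @exportS3Method generics::glance
glance.pls_selection <- function(x, ...) {
  tibble(outcome = x$outcome, r.squared = x$r_squared,
         adj.r.squared = x$adj_r_squared, cv.r.squared = x$cv_r2,
         ncomp = x$ncomp, nobs = x$n,
         n_features = length(x$features), capped = x$capped)
}
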