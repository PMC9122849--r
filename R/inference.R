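# Statistical stage: two-SD standardization, Gaussian OLS with multiple and
# adjusted R^2, small-sample AICc, exhaustive (dredge-style) subset selection
# with delta < 2 retention and Akaike weights, and the approach comparison
# between floral-resource and land-cover predictor pools.

#' Standardize a predictor by two standard deviations
#'
#' `z = (x - mean(x)) / (2 * sd(x))` with the sample (n-1) standard
#' deviation, so a binary 50/50 predictor and a continuous one get
#' comparable coefficients: the output has mean 0 and sd 0.5.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @param name Predictor name used in error messages.
#' @return Standardized numeric vector.
#' @export
standardize_2sd <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    stop("predictor '", name, "': need a numeric vector of length >= 2 ",
         "without missing values", call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) {
    stop("predictor '", name, "' has zero variance and cannot be standardized",
         call. = FALSE)
  }
  (x - mean(x)) / (2 * s)
}

#' Gaussian ordinary least squares fit
#'
#' Fits `y ~ X` with an intercept via [stats::lm()] and assembles the
#' quantities the selection stage needs: coefficients with standard errors,
#' t and two-sided p values (residual df `n - p`), multiple and adjusted
#' R-squared, the Gaussian maximum-likelihood log-likelihood
#' `-(n/2) * (log(2 * pi * RSS / n) + 1)`, and AICc with
#' `k = slopes + intercept + 1` (the residual variance counts as a
#' parameter).
#'
#' @param y Numeric response.
#' @param X Numeric matrix (or data.frame) of predictors; may have zero
#'   columns for the intercept-only model.
#' @param response Response name for labelling.
#' @return Object of class `fai_fit`.
#' @export
fit_ols <- function(y, X = NULL, response = "y") {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0L)
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != n) stop("X must have one row per observation", call. = FALSE)
  p <- ncol(X) + 1L
  if (n <= p) stop("need n > number of coefficients (", p, ")", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, p)] - 1L]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- if (ncol(X) == 0L) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (ncol(X) == 0L) 0 else 1 - rss / tss
  r2_adj <- if (ncol(X) == 0L) 0 else 1 - (1 - r2) * (n - 1) / (n - p)
  ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  k <- p + 1L
  ct <- stats::coef(sm)
  rownames(ct) <- sub("^`(.*)`$", "\\1", rownames(ct))
  structure(list(
    response = response,
    predictors = colnames(X),
    n = n, k = k, df_residual = n - p,
    coefficients = ct[, "Estimate"],
    standard_errors = ct[, "Std. Error"],
    t_values = ct[, "t value"],
    p_values = ct[, "Pr(>|t|)"],
    r2_mult = r2, r2_adj = r2_adj,
    rss = rss, log_likelihood = ll,
    aicc = if (n - k - 1 > 0) aicc(ll, n = n, k = k) else NA_real_,
    lm = fit
  ), class = "fai_fit")
}

#' @export
print.fai_fit <- function(x, ...) {
  cat("OLS fit:", x$response, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      "\n  n =", x$n, " R2_mult =", signif(x$r2_mult, 4),
      " R2_adj =", signif(x$r2_adj, 4), " AICc =", signif(x$aicc, 6), "\n")
  invisible(x)
}

#' Second-order (small-sample) Akaike information criterion
#'
#' `AICc = -2 * logLik + 2k + 2k(k + 1) / (n - k - 1)`, with `k` counting
#' intercept, slopes and the residual variance. Requires `n - k - 1 > 0`.
#'
#' @param object An `fai_fit`, or a log-likelihood value.
#' @param n,k Sample size and parameter count (required when `object` is a
#'   log-likelihood).
#' @return AICc value.
#' @export
aicc <- function(object, n = NULL, k = NULL) {
  if (inherits(object, "fai_fit")) {
    ll <- object$log_likelihood; n <- object$n; k <- object$k
  } else {
    ll <- as.numeric(object)
    if (is.null(n) || is.null(k)) stop("supply n and k", call. = FALSE)
  }
  if (n - k - 1 <= 0) {
    stop("AICc undefined: n - k - 1 = ", n - k - 1,
         " (model too large for the sample)", call. = FALSE)
  }
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over the candidate
#' set.
#'
#' @param delta Numeric vector of AICc differences from the best model.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Exhaustive (dredge-style) subset selection under AICc
#'
#' Fits every subset of the predictor columns (including the intercept-only
#' model) up to `max_size` terms, ranks by AICc, and reports AICc
#' differences, Akaike weights over the full candidate set, and the
#' `delta < 2` retention flag. Ties in AICc are broken by fewer predictors,
#' then lexicographic predictor names. Predictors are expected on the
#' two-SD-standardized scale.
#'
#' @param y Numeric response.
#' @param X Predictor matrix with column names.
#' @param max_size Largest subset size fitted (default: all sizes).
#' @param delta_cutoff Retention cutoff on the AICc difference (default 2).
#' @param max_predictors Combinatorial guard: more columns than this is an
#'   error unless raised explicitly (default 12).
#' @param response Response name for labelling.
#' @return Object of class `fai_selection`: `$table` (one row per candidate,
#'   AICc-ranked), `$fits` (the `fai_fit` objects in table order), `$best`,
#'   `$retained` (row indices with delta < cutoff).
#' @export
all_subsets_selection <- function(y, X, max_size = Inf, delta_cutoff = 2,
                                  max_predictors = 12L, response = "y") {
  X <- as.matrix(X)
  vars <- colnames(X)
  if (is.null(vars) || any(!nzchar(vars))) {
    stop("X must have named columns", call. = FALSE)
  }
  m <- length(vars)
  if (m > max_predictors) {
    stop(m, " predictors would require 2^", m, " model fits; raise ",
         "'max_predictors' to override the guard", call. = FALSE)
  }
  subsets <- list(character(0))
  for (size in seq_len(min(m, max_size))) {
    subsets <- c(subsets, utils::combn(sort(vars), size, simplify = FALSE))
  }
  fits <- lapply(subsets, function(s)
    fit_ols(y, X[, s, drop = FALSE], response = response))
  aiccs <- vapply(fits, `[[`, numeric(1L), "aicc")
  if (anyNA(aiccs)) {
    big <- max(lengths(subsets)[is.na(aiccs)])
    stop("AICc undefined for subsets of ", big, " predictor(s): n - k - 1 ",
         "<= 0; reduce 'max_size' or add observations", call. = FALSE)
  }
  sizes <- lengths(subsets)
  labels <- vapply(subsets, function(s)
    if (length(s) == 0L) "(intercept only)" else paste(s, collapse = " + "), "")
  ord <- order(aiccs, sizes, labels)
  fits <- fits[ord]
  tab <- data.frame(
    model = labels[ord],
    n_predictors = sizes[ord],
    df = vapply(fits, `[[`, integer(1L), "df_residual"),
    r2_mult = vapply(fits, `[[`, numeric(1L), "r2_mult"),
    r2_adj = vapply(fits, `[[`, numeric(1L), "r2_adj"),
    log_likelihood = vapply(fits, `[[`, numeric(1L), "log_likelihood"),
    aicc = aiccs[ord],
    stringsAsFactors = FALSE
  )
  tab$delta <- tab$aicc - tab$aicc[1L]
  tab$weight <- akaike_weights(tab$delta)
  tab$retained <- tab$delta < delta_cutoff
  structure(list(table = tab, fits = fits, best = fits[[1L]],
                 retained = which(tab$retained), response = response,
                 delta_cutoff = delta_cutoff),
            class = "fai_selection")
}

#' @export
print.fai_selection <- function(x, ...) {
  cat("AICc all-subsets selection for response '", x$response, "' (",
      nrow(x$table), " candidates; delta < ", x$delta_cutoff,
      " retained)\n", sep = "")
  shown <- x$table[x$table$retained, ]
  print(cbind(shown[, c("model", "df")],
              round(shown[, c("r2_mult", "r2_adj", "aicc", "delta", "weight")], 3)),
        row.names = FALSE)
  invisible(x)
}

#' Per-predictor coefficient table of the retained models
#'
#' @param selection `fai_selection`.
#' @return data.frame: `model`, `predictor`, `estimate`, `se`, `t`, `p`.
#' @export
selection_coefficients <- function(selection) {
  rows <- lapply(selection$retained, function(i) {
    f <- selection$fits[[i]]
    if (length(f$predictors) == 0L) return(NULL)
    data.frame(model = selection$table$model[i], predictor = f$predictors,
               estimate = f$coefficients[f$predictors],
               se = f$standard_errors[f$predictors],
               t = f$t_values[f$predictors], p = f$p_values[f$predictors],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model = character(0), predictor = character(0),
                      estimate = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0))
  }
  out
}

# Predictor pools for the three mapping approaches, all on the standardized
# scale. 'other' is excluded from the fine pool: it is the unit-sum
# remainder, not a mapped class.
approach_predictors <- function(fai_tab, composition, include_distances = TRUE) {
  comp <- composition[order(composition$landscape_id), ]
  ids <- comp$landscape_id
  fai_wide <- function(period) {
    sub <- fai_tab[fai_tab$period == period, ]
    sub$fai[match(ids, sub$landscape_id)]
  }
  floral <- cbind(preceding = fai_wide("preceding"),
                  synchronous = fai_wide("synchronous"))
  coarse <- cbind(
    crop = comp$arable + comp$permanent_crop,
    snh = comp$forest + comp$woody_snh + comp$herbaceous_snh,
    urban = comp$urban
  )
  fine <- cbind(
    arable = comp$arable, permanent_crop = comp$permanent_crop,
    forest = comp$forest, woody_snh = comp$woody_snh,
    herbaceous_snh = comp$herbaceous_snh, urban = comp$urban
  )
  if (include_distances) {
    fine <- cbind(fine, dist_forest = comp$dist_forest_m,
                  dist_urban = comp$dist_urban_m)
  }
  std <- function(M) {
    for (j in seq_len(ncol(M))) M[, j] <- standardize_2sd(M[, j], colnames(M)[j])
    M
  }
  list(ids = ids,
       pools = list(floral_resources = std(floral),
                    land_cover_coarse = std(coarse),
                    land_cover_fine = std(fine)))
}

#' Compare mapping approaches as predictors of seed set
#'
#' Runs [all_subsets_selection()] on the identical response for three
#' predictor pools: floral resources (preceding and synchronous fai),
#' coarse land cover (`crop = arable + permanent_crop`,
#' `snh = forest + woody_snh + herbaceous_snh`, `urban`), and fine land
#' cover (the six mapped classes, optionally plus the two distances). The
#' comparison metric is the R-squared of each approach's most parsimonious
#' (lowest-AICc) model. Landscapes lacking a response are dropped with a
#' warning.
#'
#' @param response data.frame with `landscape_id` and `seeds_per_pod`
#'   (output of [seeds_per_pod()]).
#' @param fai_tab Output of [fai_table()].
#' @param composition Output of [landscape_composition()].
#' @param include_distances Include `dist_forest` / `dist_urban` in the fine
#'   pool (default `TRUE`).
#' @param max_size Passed to [all_subsets_selection()].
#' @return Object of class `fai_comparison`: `$selections` (named list of
#'   `fai_selection`), `$comparison` (one row per approach with the best
#'   model and its R-squared values), `$n`.
#' @export
approach_comparison <- function(response, fai_tab, composition,
                                include_distances = TRUE, max_size = Inf) {
  ap <- approach_predictors(fai_tab, composition, include_distances)
  resp <- response$seeds_per_pod[match(ap$ids, response$landscape_id)]
  ok <- !is.na(resp)
  if (any(!ok)) {
    warning("dropping landscape(s) without a seed-set response: ",
            paste(ap$ids[!ok], collapse = ", "), call. = FALSE)
  }
  y <- resp[ok]
  selections <- lapply(ap$pools, function(M)
    all_subsets_selection(y, M[ok, , drop = FALSE], max_size = max_size,
                          response = "seeds_per_pod"))
  comparison <- do.call(rbind, lapply(names(selections), function(nm) {
    b <- selections[[nm]]$best
    data.frame(approach = nm,
               model = selections[[nm]]$table$model[1L],
               n_predictors = length(b$predictors),
               r2_mult = b$r2_mult, r2_adj = b$r2_adj, aicc = b$aicc,
               stringsAsFactors = FALSE)
  }))
  structure(list(selections = selections, comparison = comparison,
                 n = sum(ok), landscape_ids = ap$ids[ok]),
            class = "fai_comparison")
}

#' Single-predictor regressions of the index on landscape context
#'
#' For each period in the index table and each landscape variable (the six
#' class proportions and the two distances), fits a simple OLS of fai on the
#' variable and reports slope, t, R-squared and p. Also returns the full
#' Pearson correlation matrix of the explanatory variables.
#'
#' @param fai_tab Output of [fai_table()].
#' @param composition Output of [landscape_composition()].
#' @return List: `$regressions` (data.frame: `period`, `variable`,
#'   `estimate`, `se`, `t`, `r2_mult`, `p`), `$correlations` (matrix).
#' @export
landscape_fai_regressions <- function(fai_tab, composition) {
  comp <- composition[order(composition$landscape_id), ]
  if (nrow(comp) < 3L) stop("need at least 3 landscapes", call. = FALSE)
  vars <- c("arable", "permanent_crop", "forest", "woody_snh",
            "herbaceous_snh", "urban", "dist_forest_m", "dist_urban_m")
  rows <- list()
  for (t in unique(fai_tab$period)) {
    sub <- fai_tab[fai_tab$period == t, ]
    y <- sub$fai[match(comp$landscape_id, sub$landscape_id)]
    for (v in vars) {
      x <- comp[[v]]
      if (stats::sd(x) == 0) next
      f <- fit_ols(y, cbind(x = x), response = paste0("fai_", t))
      rows[[length(rows) + 1L]] <- data.frame(
        period = t, variable = v,
        estimate = unname(f$coefficients["x"]),
        se = unname(f$standard_errors["x"]),
        t = unname(f$t_values["x"]), r2_mult = f$r2_mult,
        p = unname(f$p_values["x"]), stringsAsFactors = FALSE)
    }
  }
  M <- as.matrix(comp[, vars])
  keep <- apply(M, 2L, stats::sd) > 0
  list(regressions = do.call(rbind, rows),
       correlations = stats::cor(M[, keep, drop = FALSE]))
}
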