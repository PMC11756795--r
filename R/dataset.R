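#' Construct a regression dataset
#'
#' Bundles a numeric predictor matrix and a response vector, tagged with the
#' role the dataset plays in a transfer-learning analysis: the `"target"`
#' dataset whose coefficients are of interest, or one of the auxiliary
#' `"source"` datasets that may be borrowed from.
#'
#' @param X numeric matrix of predictors, one row per observation.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param role `"target"` or `"source"`.
#' @param id optional integer identifier for source datasets.
#'
#' @return An object of class `ptlr_dataset` with elements `X`, `y`, `role`,
#'   `id`, `n` and `p`.
#' @examples
#' d <- ptlr_dataset(matrix(rnorm(20), 10, 2), rnorm(10))
#' d$n; d$p
#' @export
ptlr_dataset <- function(X, y, role = c("target", "source"), id = NA_integer_) {
  role <- match.arg(role)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("X has ", nrow(X), " rows but y has length ", length(y))
  }
  if (nrow(X) < 2L) stop("a dataset needs at least 2 observations")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite entries")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains missing or non-finite entries")
  structure(
    list(X = X, y = y, role = role, id = as.integer(id),
         n = nrow(X), p = ncol(X)),
    class = "ptlr_dataset"
  )
}

#' @export
print.ptlr_dataset <- function(x, ...) {
  tag <- if (x$role == "source" && !is.na(x$id)) paste0("source ", x$id) else x$role
  cat(sprintf("<ptlr_dataset: %s, n = %d, p = %d>\n", tag, x$n, x$p))
  invisible(x)
}

# Subset the rows of a dataset (used for CV folds and the detection split).
dataset_rows <- function(data, rows) {
  ptlr_dataset(data$X[rows, , drop = FALSE], data$y[rows],
               role = data$role, id = data$id)
}

#' EM fitting configuration
#'
#' Collects the tunable parameters of the penalized EM fit and of the
#' cross-validation used to choose the penalty level.
#'
#' @param tol convergence threshold on the L1 change of the full parameter
#'   vector (coefficients, scale, degrees of freedom) between EM iterations.
#' @param max_iter cap on EM iterations.
#' @param nu_bounds search interval for the degrees of freedom; the fit is
#'   treated as near-Gaussian when the estimate sits at the upper bound.
#' @param estimate_nu if `FALSE` the degrees of freedom stay at their initial
#'   value (5 unless overridden via `nu_init`).
#' @param nu_init initial degrees of freedom.
#' @param lambda_grid optional explicit penalty grid; when `NULL` a log-spaced
#'   grid of `nlambda` values from the data-derived `lambda_max` down to
#'   `lambda_min_ratio * lambda_max` is used.
#' @param nlambda,lambda_min_ratio shape of the automatic grid.
#' @param cv_folds folds for penalty selection.
#' @param seed seed for fold shuffling.
#' @param fit_intercept include an unpenalized intercept column.
#' @param standardize scale predictor columns to unit standard deviation before
#'   fitting (coefficients are returned on the original scale).
#' @param cd_tol,cd_max_sweeps inner tolerance and sweep cap for the
#'   coordinate-descent solver of the penalized M-step.
#'
#' @return A list of class `em_config`.
#' @export
em_config <- function(tol = 1e-6, max_iter = 200L,
                      nu_bounds = c(1, 100), estimate_nu = TRUE, nu_init = 5,
                      lambda_grid = NULL, nlambda = 50L, lambda_min_ratio = 0.01,
                      cv_folds = 5L, seed = 1L,
                      fit_intercept = FALSE, standardize = FALSE,
                      cd_tol = 1e-8, cd_max_sweeps = 10000L) {
  stopifnot(tol > 0, max_iter >= 1,
            length(nu_bounds) == 2, nu_bounds[1] > 0, nu_bounds[1] < nu_bounds[2],
            nlambda >= 1, lambda_min_ratio > 0, lambda_min_ratio <= 1,
            cv_folds >= 2, nu_init > 0)
  if (!is.null(lambda_grid)) {
    lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
    if (length(lambda_grid) == 0 || any(lambda_grid < 0)) {
      stop("lambda_grid must be nonempty and nonnegative")
    }
  }
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         nu_bounds = as.numeric(nu_bounds), estimate_nu = isTRUE(estimate_nu),
         nu_init = nu_init,
         lambda_grid = lambda_grid, nlambda = as.integer(nlambda),
         lambda_min_ratio = lambda_min_ratio,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed),
         fit_intercept = isTRUE(fit_intercept), standardize = isTRUE(standardize),
         cd_tol = cd_tol, cd_max_sweeps = as.integer(cd_max_sweeps)),
    class = "em_config"
  )
}
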