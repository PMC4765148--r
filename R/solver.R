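# ---- standardization -------------------------------------------------------

# Center/scale the design and center the response. Columns are scaled by the
# sample standard deviation; constant columns get scale 1 and are zeroed so
# they can never enter the active set (they receive weight 0).
standardize_design <- function(x, y, standardize = TRUE, intercept = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite entries in the design matrix")
  if (!all(is.finite(y))) stop("non-finite entries in the response")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nrow(x) < 2L) stop("need at least two observations")
  p <- ncol(x)
  center <- if (intercept) colMeans(x) else rep(0, p)
  xs <- sweep(x, 2L, center, "-")
  scl <- rep(1, p)
  constant <- logical(p)
  if (standardize) {
    scl <- apply(x, 2L, stats::sd)
    constant <- scl < 1e-12
    scl[constant] <- 1
    xs <- sweep(xs, 2L, scl, "/")
  } else {
    constant <- apply(x, 2L, function(v) max(v) - min(v) < 1e-12)
  }
  if (any(constant)) xs[, constant] <- 0
  ymean <- if (intercept) mean(y) else 0
  list(x = xs, y = y - ymean, center = center, scale = scl,
       ymean = ymean, constant = constant,
       standardize = standardize, intercept = intercept)
}

# Map standardized-scale coefficients back to the original scale and recover
# the intercept from the standardization record.
destandardize_beta <- function(beta_std, record) {
  beta <- beta_std / record$scale
  intercept <- record$ymean - sum(beta * record$center)
  list(beta = beta, intercept = intercept)
}

# ---- LARS core -------------------------------------------------------------

# Least angle regression with the lasso modification, in the convention
#   minimize  sum((y - X b)^2) + lambda * sum(|b|)
# on a design that is already standardized/centered by the caller (the
# elastic-net augmentation rows must not be re-centered, so the core never
# touches the data). Returns the knots of the piecewise-linear path; lambda
# at a knot equals twice the maximal absolute inner product X^T residual.
#
# Columns whose admission would make the active Gram matrix singular (exact
# duplicates, linear dependence once the rank is exhausted) are blacklisted
# and stay at weight zero. Ties when several variables reach the maximal
# correlation simultaneously are broken toward the lowest column index.
lars_core <- function(x, y, lambda_min = 0, max_steps = NULL, tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(max_steps)) max_steps <- 8L * min(n, p) + 10L
  beta <- numeric(p)
  c_vec <- drop(crossprod(x, y))
  C <- max(abs(c_vec))
  knot_lambda <- 2 * C
  knot_beta <- matrix(0, p, 1L)
  if (C < tol) {
    return(list(lambda = knot_lambda, beta = knot_beta, lambda_max = knot_lambda))
  }
  active <- integer(0)
  ignored <- rep(FALSE, p)
  R <- matrix(0, 0, 0)  # Cholesky factor of X_A^T X_A, updated incrementally

  add_var <- function(j) {
    xj <- x[, j]
    if (length(active) == 0L) {
      d <- sum(xj * xj)
      if (d < tol) return(FALSE)
      R <<- matrix(sqrt(d), 1L, 1L)
    } else {
      r <- forwardsolve(t(R), drop(crossprod(x[, active, drop = FALSE], xj)))
      d <- sum(xj * xj) - sum(r * r)
      if (d < tol) return(FALSE)
      k <- length(active)
      Rnew <- matrix(0, k + 1L, k + 1L)
      Rnew[seq_len(k), seq_len(k)] <- R
      Rnew[seq_len(k), k + 1L] <- r
      Rnew[k + 1L, k + 1L] <- sqrt(d)
      R <<- Rnew
    }
    active <<- c(active, j)
    TRUE
  }

  first <- sort(which(abs(c_vec) >= C - tol * max(1, C)))
  for (j in first) if (!add_var(j)) ignored[j] <- TRUE
  if (length(active) == 0L) {
    return(list(lambda = knot_lambda, beta = knot_beta, lambda_max = knot_lambda))
  }

  step <- 0L
  while (C > tol && 2 * C > lambda_min + tol && step < max_steps) {
    step <- step + 1L
    if (length(active) == 0L) {  # can happen right after a drop
      cand <- sort(which(abs(c_vec) >= C - tol * max(1, C) & !ignored))
      for (j in cand) if (!add_var(j)) ignored[j] <- TRUE
      if (length(active) == 0L) break
    }
    sA <- sign(c_vec[active]); sA[sA == 0] <- 1
    w <- backsolve(R, forwardsolve(t(R), sA))
    a <- drop(crossprod(x, x[, active, drop = FALSE] %*% w))

    gamma_join <- Inf; join_j <- NA_integer_
    inact <- setdiff(which(!ignored), active)
    if (length(inact)) {
      cj <- c_vec[inact]; aj <- a[inact]
      g1 <- (C - cj) / (1 - aj)
      g2 <- (C + cj) / (1 + aj)
      g1[!(g1 > tol)] <- Inf
      g2[!(g2 > tol)] <- Inf
      g <- pmin(g1, g2)
      gm <- min(g)
      if (is.finite(gm)) {
        gamma_join <- gm
        # lowest column index among (near-)ties
        join_j <- inact[which(g <= gm * (1 + 1e-10))][1L]
      }
    }

    gamma_drop <- Inf; drop_pos <- NA_integer_
    cross <- which(w * beta[active] < 0)
    if (length(cross)) {
      gd <- -beta[active][cross] / w[cross]
      gamma_drop <- min(gd)
      drop_pos <- cross[which.min(gd)]
    }

    gamma <- min(C, gamma_join, gamma_drop)
    beta[active] <- beta[active] + gamma * w
    c_vec <- c_vec - gamma * a
    C <- C - gamma

    if (gamma == gamma_drop) {
      jd <- active[drop_pos]
      beta[jd] <- 0
      active <- active[-drop_pos]
      R <- if (length(active)) {
        chol(crossprod(x[, active, drop = FALSE]))
      } else matrix(0, 0, 0)
    } else if (gamma == gamma_join) {
      if (!add_var(join_j)) ignored[join_j] <- TRUE
    }

    knot_lambda <- c(knot_lambda, 2 * C)
    knot_beta <- cbind(knot_beta, beta)
    if (gamma <= tol && !is.finite(gamma_join) && !is.finite(gamma_drop)) break
  }
  list(lambda = knot_lambda, beta = knot_beta, lambda_max = knot_lambda[1L])
}

# Evaluate a knot path at one lambda by linear interpolation (the path is
# affine in lambda between knots). Above lambda_max the solution is zero;
# below the last computed knot the last knot is returned.
eval_knots <- function(lambda_knots, beta_knots, lambda) {
  if (lambda >= lambda_knots[1L]) return(beta_knots[, 1L] * 0)
  k <- max(which(lambda_knots > lambda - 1e-15 * max(1, lambda_knots[1L])))
  if (k == length(lambda_knots)) return(beta_knots[, k])
  f <- (lambda_knots[k] - lambda) / (lambda_knots[k] - lambda_knots[k + 1L])
  beta_knots[, k] + f * (beta_knots[, k + 1L] - beta_knots[, k])
}

# ---- public solver interface -----------------------------------------------

#' Full LASSO coefficient path by least angle regression
#'
#' Traces the piecewise-linear solution path of
#' \deqn{\min_\beta \sum_i (y_i - \beta^\top x_i)^2 + \lambda \sum_j |\beta_j|}
#' using least angle regression with the lasso modification (variables may
#' leave the active set). Note the penalty convention: the squared-error sum
#' is not halved, so \eqn{\lambda} here is twice the \eqn{\lambda} of
#' conventions that use \eqn{\frac{1}{2}}RSS, and \eqn{2N} times that of
#' conventions that use \eqn{\frac{1}{2N}}RSS.
#'
#' @param x numeric design matrix (N x T).
#' @param y numeric response of length N.
#' @param standardize center and scale columns to unit sample standard
#'   deviation before fitting (the penalty applies on the standardized
#'   scale); coefficients are always reported on the original scale.
#' @param intercept fit a bias via centering.
#' @param lambda_min stop tracing the path once lambda falls below this
#'   value (0 traces to the unpenalized end).
#' @param max_steps safety cap on path steps.
#' @return an object of class `"lasso_path"`: knot lambdas (decreasing,
#'   starting at `lambda_max`), the standardized-scale coefficient matrix at
#'   the knots, and the standardization record.
#' @seealso [fit_lasso()], [fit_elastic_net()]
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x[, 1] - 2 * x[, 2] + rnorm(20, sd = 0.1)
#' p <- fit_lasso_path(x, y)
#' coef(p, lambda = p$lambda_max / 4)
#' @export
fit_lasso_path <- function(x, y, standardize = TRUE, intercept = TRUE,
                           lambda_min = 0, max_steps = NULL) {
  record <- standardize_design(x, y, standardize, intercept)
  core <- lars_core(record$x, record$y, lambda_min = lambda_min,
                    max_steps = max_steps)
  structure(list(lambda = core$lambda, beta_std = core$beta,
                 lambda_max = core$lambda_max, record = record,
                 dim = dim(record$x)),
            class = "lasso_path")
}

#' @param object a `"lasso_path"`.
#' @param lambda penalty value at which to evaluate the path.
#' @param ... ignored.
#' @return for `coef`: a list with `beta` (original scale) and `intercept`.
#' @rdname fit_lasso_path
#' @export
coef.lasso_path <- function(object, lambda, ...) {
  bs <- eval_knots(object$lambda, object$beta_std, lambda)
  destandardize_beta(bs, object$record)
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("LASSO path: %d x %d problem, %d knots, lambda_max = %.4g\n",
              x$dim[1L], x$dim[2L], length(x$lambda), x$lambda_max))
  invisible(x)
}

new_sparse_fit <- function(beta_std, record, lambda, gamma, lambda_max) {
  ds <- destandardize_beta(beta_std, record)
  structure(list(beta = ds$beta, intercept = ds$intercept,
                 beta_std = beta_std, lambda = lambda, gamma = gamma,
                 lambda_max = lambda_max,
                 active = which(beta_std != 0), record = record),
            class = "sparse_fit")
}

#' Fit a single LASSO or elastic-net regression
#'
#' `fit_lasso` minimizes \eqn{\sum_i (y_i - \beta^\top x_i)^2 + \lambda
#' \sum_j |\beta_j|}; `fit_elastic_net` adds the ridge term \eqn{\gamma
#' \sum_j \beta_j^2}. The elastic net is solved exactly as a LASSO on
#' augmented data: the standardized design is stacked over
#' \eqn{\sqrt{\gamma} I} and the response padded with zeros, which turns the
#' penalized problem into a pure L1 problem with the same minimizer. With
#' `gamma = 0` the two functions produce identical output.
#'
#' @inheritParams fit_lasso_path
#' @param lambda L1 penalty (>= 0). At `lambda = 0` the fit is ordinary
#'   least squares (full-rank case) / the least-angle terminal solution;
#'   at `lambda >= lambda_max` all coefficients are zero.
#' @param gamma L2 penalty (>= 0); `fit_elastic_net` only.
#' @return an object of class `"sparse_fit"` with elements `beta` (original
#'   scale), `intercept`, `beta_std`, `active` (indices of non-zero
#'   standardized coefficients), `lambda`, `gamma`, `lambda_max` and the
#'   standardization `record`.
#' @examples
#' x <- matrix(rnorm(100), 25, 4)
#' y <- 2 * x[, 2] + rnorm(25, sd = 0.2)
#' f <- fit_lasso(x, y, lambda = 1)
#' f$active
#' @export
fit_lasso <- function(x, y, lambda, standardize = TRUE, intercept = TRUE) {
  if (lambda < 0) stop("lambda must be non-negative")
  record <- standardize_design(x, y, standardize, intercept)
  core <- lars_core(record$x, record$y, lambda_min = lambda)
  bs <- eval_knots(core$lambda, core$beta, lambda)
  new_sparse_fit(bs, record, lambda, gamma = 0, lambda_max = core$lambda_max)
}

#' @rdname fit_lasso
#' @export
fit_elastic_net <- function(x, y, lambda, gamma, standardize = TRUE,
                            intercept = TRUE) {
  if (lambda < 0 || gamma < 0) stop("penalties must be non-negative")
  if (gamma == 0) return(fit_lasso(x, y, lambda, standardize, intercept))
  record <- standardize_design(x, y, standardize, intercept)
  p <- ncol(record$x)
  xa <- rbind(record$x, sqrt(gamma) * diag(p))
  if (any(record$constant)) xa[nrow(record$x) + which(record$constant), ] <- 0
  ya <- c(record$y, numeric(p))
  core <- lars_core(xa, ya, lambda_min = lambda)
  bs <- eval_knots(core$lambda, core$beta, lambda)
  new_sparse_fit(bs, record, lambda, gamma = gamma,
                 lambda_max = core$lambda_max)
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf(
    "sparse fit: lambda = %.4g, gamma = %.4g, %d / %d non-zero, intercept = %.4g\n",
    x$lambda, x$gamma, length(x$active), length(x$beta), x$intercept))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual of a sparse fit
#'
#' Checks optimality on the standardized problem: every inactive coordinate
#' must satisfy \eqn{|2 x_j^\top r| \le \lambda} and every active coordinate
#' \eqn{2 x_j^\top r = \lambda\,\mathrm{sign}(\beta_j)} (with the ridge
#' gradient folded in for the elastic net). Returns the largest violation;
#' values around 1e-8 or below indicate an (numerically) exact solution.
#'
#' @param fit a `"sparse_fit"`.
#' @param x,y the data the fit was computed from.
#' @return maximal KKT violation (non-negative scalar).
#' @export
kkt_residual <- function(fit, x, y) {
  record <- standardize_design(x, y, fit$record$standardize,
                               fit$record$intercept)
  r <- record$y - record$x %*% fit$beta_std
  g <- 2 * drop(crossprod(record$x, r)) - 2 * fit$gamma * fit$beta_std
  viol_inactive <- pmax(abs(g) - fit$lambda, 0)
  viol_inactive[fit$active] <- 0
  viol_active <- abs(g[fit$active] - fit$lambda * sign(fit$beta_std[fit$active]))
  viol_inactive[record$constant] <- 0
  max(c(viol_inactive, viol_active, 0))
}

# ---- penalty selection -----------------------------------------------------

#' Choose penalties by k-fold cross-validation
#'
#' Per-class penalty selection used by [sparseloc()]: a 20-point logarithmic
#' lambda grid from the path's `lambda_max` downward (to
#' `lambda_min_ratio * lambda_max`), optionally crossed with a small gamma
#' grid for the elastic net, scored by mean squared prediction error over
#' `nfolds` folds. Ties are broken toward the largest lambda (then the
#' smallest gamma), i.e. the sparsest model among the best.
#'
#' Fold assignment consumes the R random number stream once, so results are
#' reproducible under `set.seed`; passing `folds` makes the call fully
#' deterministic.
#'
#' @inheritParams fit_lasso_path
#' @param gamma numeric vector of candidate L2 penalties (use `0` for pure
#'   LASSO).
#' @param nfolds number of folds (default 5).
#' @param nlambda grid size (default 20).
#' @param lambda_min_ratio grid floor as a fraction of `lambda_max`.
#' @param folds optional integer vector of fold labels of length N.
#' @return list with `lambda`, `gamma`, the `grid`, and the matrix of mean
#'   CV errors (`cvm`, gamma by lambda).
#' @export
cv_penalty <- function(x, y, gamma = 0, nfolds = 5L, nlambda = 20L,
                       lambda_min_ratio = 0.01, standardize = TRUE,
                       intercept = TRUE, folds = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(folds)) folds <- sample(rep(seq_len(nfolds), length.out = n))
  nfolds <- length(unique(folds))
  record <- standardize_design(x, y, standardize, intercept)
  lmax <- 2 * max(abs(crossprod(record$x, record$y)))
  if (lmax <= 0) lmax <- 1
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  cvm <- matrix(0, length(gamma), nlambda,
                dimnames = list(paste0("gamma=", gamma), NULL))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    rec <- standardize_design(x[tr, , drop = FALSE], y[tr],
                              standardize, intercept)
    xv <- sweep(sweep(x[!tr, , drop = FALSE], 2L, rec$center), 2L,
                rec$scale, "/")
    xv[, rec$constant] <- 0
    yv <- y[!tr] - rec$ymean
    for (gi in seq_along(gamma)) {
      g <- gamma[gi]
      if (g == 0) {
        core <- lars_core(rec$x, rec$y, lambda_min = grid[nlambda] * 0.9)
      } else {
        p <- ncol(rec$x)
        xa <- rbind(rec$x, sqrt(g) * diag(p))
        if (any(rec$constant)) xa[nrow(rec$x) + which(rec$constant), ] <- 0
        core <- lars_core(xa, c(rec$y, numeric(p)),
                          lambda_min = grid[nlambda] * 0.9)
      }
      for (l in seq_len(nlambda)) {
        b <- eval_knots(core$lambda, core$beta, grid[l])
        cvm[gi, l] <- cvm[gi, l] + sum((yv - xv %*% b)^2)
      }
    }
  }
  cvm <- cvm / n
  best <- which(cvm <= min(cvm) + 1e-12, arr.ind = TRUE)
  # prefer largest lambda (lowest column index), then smallest gamma
  best <- best[order(best[, 2L], best[, 1L]), , drop = FALSE][1L, ]
  list(lambda = grid[best[2L]], gamma = gamma[best[1L]],
       grid = grid, cvm = cvm)
}
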