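#' Gaussian similarity between two vectors
#'
#' `exp(-||a - b||^2 / (2 sigma^2))`, in (0, 1].
#'
#' @param a,b Equal-length numeric vectors.
#' @param sigma Kernel width, > 0.
#' @return Similarity scalar.
#' @export
gaussian_similarity <- function(a, b, sigma) {
  if (length(a) != length(b)) stop("dimension mismatch")
  stopifnot(sigma > 0)
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

#' WSRC configuration
#'
#' @param epsilon Reconstruction tolerance of the constrained l1 problem
#'   (default 0.005; meaningful on the unit-normalised feature scale).
#' @param sigma Gaussian kernel width for the sample weights (default 1.5).
#' @param weight_mode `"literal"` uses the Gaussian similarity itself as the
#'   l1 penalty weight of each training sample; `"inverse"` uses its
#'   reciprocal, so that near neighbours are penalised less and attract
#'   larger coefficients.
#' @param solver_tol Relative optimisation tolerance of the solver.
#' @param normalize_query Normalise the query to unit l2 norm before solving
#'   (default TRUE; keeps `epsilon` on the same scale as the dictionary
#'   columns).
#' @return List of class `wsrc_config`.
#' @export
wsrc_config <- function(epsilon = 0.005, sigma = 1.5,
                        weight_mode = c("literal", "inverse"),
                        solver_tol = 1e-6, normalize_query = TRUE) {
  stopifnot(epsilon > 0, sigma > 0, solver_tol > 0)
  structure(list(epsilon = epsilon, sigma = sigma,
                 weight_mode = match.arg(weight_mode),
                 solver_tol = solver_tol,
                 normalize_query = isTRUE(normalize_query)),
            class = "wsrc_config")
}

#' Build a WSRC dictionary from training pair vectors
#'
#' Columns are the training samples, normalised to unit l2 norm (original
#' norms are retained). This is the whole "model": WSRC is a lazy classifier
#' with no fitted parameters.
#'
#' @param X d x n numeric matrix, one column per training sample, or an
#'   n x d matrix with `byrow = TRUE`.
#' @param labels Length-n vector of class labels (1 interacting /
#'   0 non-interacting).
#' @param byrow Set TRUE when samples are rows of `X`.
#' @return Object of class `wsrc_dictionary`.
#' @export
wsrc_dictionary <- function(X, labels, byrow = FALSE) {
  if (byrow) X <- t(X)
  stopifnot(is.matrix(X), ncol(X) == length(labels))
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) stop("dictionary contains an all-zero column")
  structure(list(
    columns = sweep(X, 2, norms, "/"),
    labels = as.integer(labels),
    column_norms = norms
  ), class = "wsrc_dictionary")
}

#' @export
print.wsrc_dictionary <- function(x, ...) {
  cat(sprintf("WSRC dictionary: %d samples x %d dims; classes: %s\n",
              ncol(x$columns), nrow(x$columns),
              paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Gaussian weight vector for a query
#'
#' Diagonal of the weight matrix W: one Gaussian similarity per dictionary
#' column. In `"literal"` mode the similarity itself is the penalty weight;
#' in `"inverse"` mode its reciprocal is used, implementing the locality
#' rationale that near samples should be penalised less.
#'
#' @param y Query vector (same dimension as dictionary columns; normalise it
#'   if `normalize_query` is in effect).
#' @param dict A `wsrc_dictionary`.
#' @param config A `wsrc_config`.
#' @return Strictly positive numeric vector, one entry per column.
#' @export
weight_matrix <- function(y, dict, config = wsrc_config()) {
  stopifnot(inherits(dict, "wsrc_dictionary"))
  d2 <- colSums((dict$columns - y)^2)
  sim <- exp(-d2 / (2 * config$sigma^2))
  sim <- pmax(sim, .Machine$double.xmin)
  if (config$weight_mode == "inverse") 1 / sim else sim
}

# 1-column special case: minimise w|a| s.t. ||y - x a|| <= eps.
solve_single_column <- function(y, x, epsilon) {
  xx <- sum(x^2); xy <- sum(x * y); yy <- sum(y^2)
  # ||y - x a||^2 = yy - 2 a xy + a^2 xx <= eps^2
  disc <- xy^2 - xx * (yy - epsilon^2)
  if (disc < 0) stop("infeasible: no coefficient satisfies the residual bound")
  lo <- (xy - sqrt(disc)) / xx
  hi <- (xy + sqrt(disc)) / xx
  if (lo <= 0 && hi >= 0) return(0)
  if (abs(lo) < abs(hi)) lo else hi
}

#' Solve the weighted l1 minimisation with a residual-ball constraint
#'
#' Minimises `sum_i w_i |alpha_i|` subject to `||y - X alpha||_2 <= epsilon`.
#' With the substitution `beta_i = w_i alpha_i` this is basis-pursuit
#' denoising in the column-rescaled dictionary; it is solved by root-finding
#' on the lasso regularisation path (successively refined penalty grids, each
#' fitted by coordinate descent via \pkg{glmnet}), selecting the largest
#' penalty whose residual norm still meets the constraint.
#'
#' @param y Query vector, length d.
#' @param X d x n dictionary matrix (unit-norm columns expected) or a
#'   `wsrc_dictionary`.
#' @param w Strictly positive weight vector, length n.
#' @param epsilon Residual tolerance, > 0.
#' @param solver_tol Relative accuracy of the path search.
#' @param relax_to_feasible When the query lies outside the reachable
#'   epsilon-ball (fewer dictionary columns than dimensions), enlarge the
#'   ball to the least-squares residual instead of erroring
#'   (default FALSE: raise an infeasibility error).
#' @return Numeric vector `alpha` of length n with attributes `residual`
#'   (achieved `||y - X alpha||`) and `objective` (`sum(w |alpha|)`).
#' @export
solve_weighted_l1 <- function(y, X, w, epsilon, solver_tol = 1e-6,
                              relax_to_feasible = FALSE) {
  if (inherits(X, "wsrc_dictionary")) X <- X$columns
  stopifnot(is.matrix(X), length(y) == nrow(X), length(w) == ncol(X),
            all(w > 0), epsilon > 0)
  n <- ncol(X); d <- nrow(X)

  finish <- function(alpha) {
    res <- sqrt(sum((y - as.numeric(X %*% alpha))^2))
    structure(alpha, residual = res, objective = sum(w * abs(alpha)))
  }
  if (sqrt(sum(y^2)) <= epsilon) return(finish(numeric(n)))
  if (n == 1L) return(finish(solve_single_column(y, X[, 1], epsilon)))

  A <- sweep(X, 2, w, "/")  # BPDN substitution: beta = w * alpha
  # feasibility: least-squares residual must be inside the ball
  r_min <- sqrt(sum(stats::lm.fit(A, y)$residuals^2))
  if (r_min > epsilon * (1 + 1e-8) + 1e-12) {
    if (!relax_to_feasible) {
      stop(sprintf(
        "infeasible: minimum attainable residual %.3g exceeds epsilon %.3g",
        r_min, epsilon))
    }
    epsilon <- r_min * (1 + 1e-6) + 1e-12
  }

  fit_grid <- function(grid) {
    fit <- glmnet::glmnet(A, y, family = "gaussian", alpha = 1,
                          lambda = grid, intercept = FALSE,
                          standardize = FALSE, thresh = 1e-12,
                          maxit = 10^7)
    B <- as.matrix(fit$beta)  # p x nlambda, no intercept
    list(lambda = fit$lambda, B = B,
         resid = sqrt(colSums((y - A %*% B)^2)))
  }
  # residual norm decreases as the penalty decreases; find the largest
  # penalty whose solution is inside the epsilon ball, refining the grid
  lam_max <- max(abs(crossprod(A, y))) / d
  lam_hi <- lam_max          # infeasible side (beta = 0 there)
  lam_lo <- NA_real_         # feasible penalty, once found
  beta_best <- NULL
  cur_hi <- lam_max
  for (descend in 1:5) {     # geometric descent until the ball is reached
    sol <- fit_grid(cur_hi * 10^seq(0, -8, length.out = 45L))
    ok <- which(sol$resid <= epsilon)
    if (length(ok) > 0L) {
      k <- ok[1L]
      lam_lo <- sol$lambda[k]
      if (k > 1L) lam_hi <- sol$lambda[k - 1L]
      beta_best <- sol$B[, k]
      break
    }
    cur_hi <- cur_hi * 1e-8
  }
  if (is.null(beta_best)) {
    stop("solver failed to reach the feasible region (ill-conditioned instance)")
  }
  for (refine in 1:3) {      # zoom on the bracket [lam_lo, lam_hi]
    if (lam_hi / lam_lo - 1 < solver_tol) break
    sol <- fit_grid(exp(seq(log(lam_hi), log(lam_lo), length.out = 40L)))
    ok <- which(sol$resid <= epsilon)
    if (length(ok) == 0L) {
      # path differences can leave even the low end marginally outside the
      # ball; shift the bracket downward and try again
      lam_hi <- lam_lo
      lam_lo <- lam_lo * 0.5
      next
    }
    k <- ok[1L]
    lam_lo <- sol$lambda[k]
    if (k > 1L) lam_hi <- sol$lambda[k - 1L]
    beta_best <- sol$B[, k]
  }
  finish(beta_best / w)
}

#' Classify a query pair vector by weighted sparse representation
#'
#' Normalises the query (optional), computes Gaussian sample weights, solves
#' the weighted l1 problem, and assigns the class whose coefficients alone
#' reconstruct the query with the smallest Euclidean residual. Ties go to the
#' non-interacting class. The continuous score is
#' `residual(non-interacting) - residual(interacting)`: positive means
#' interacting.
#'
#' @param y Query pair vector.
#' @param dict A `wsrc_dictionary` (both classes present).
#' @param config A `wsrc_config`.
#' @return List of class `sparse_solution`: `alpha`, `weights`, `residuals`
#'   (named by class), `label`, `score`.
#' @export
wsrc_classify <- function(y, dict, config = wsrc_config()) {
  stopifnot(inherits(dict, "wsrc_dictionary"))
  classes <- sort(unique(dict$labels))
  if (!all(c(0L, 1L) %in% classes)) {
    stop("dictionary must contain both interacting (1) and non-interacting (0) samples")
  }
  if (config$normalize_query) {
    ny <- sqrt(sum(y^2))
    if (ny > 0) y <- y / ny
  }
  w <- weight_matrix(y, dict, config)
  # with fewer training samples than pair-vector dimensions the epsilon
  # ball can be unreachable; classification then uses the tightest ball
  alpha <- solve_weighted_l1(y, dict$columns, w, config$epsilon,
                             config$solver_tol, relax_to_feasible = TRUE)
  residuals <- vapply(classes, function(cl) {
    a <- ifelse(dict$labels == cl, alpha, 0)
    sqrt(sum((y - as.numeric(dict$columns %*% a))^2))
  }, numeric(1))
  names(residuals) <- as.character(classes)
  score <- residuals[["0"]] - residuals[["1"]]
  label <- if (score > 0) 1L else 0L  # tie -> non-interacting
  structure(list(alpha = as.numeric(alpha), weights = w,
                 residuals = residuals, label = label,
                 score = unname(score)),
            class = "sparse_solution")
}

#' @export
print.sparse_solution <- function(x, ...) {
  cat(sprintf("WSRC solution: label %d, score %.4g, nnz(alpha) = %d\n",
              x$label, x$score, sum(x$alpha != 0)))
  invisible(x)
}
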