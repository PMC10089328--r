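## Model-matrix building blocks: dummy coding, B-spline bases with
## difference penalties, the GMRF precision, and sum-to-zero constraints.
## Each block pairs an n x r design matrix with an r x r penalty whose
## inverse-variance-scaled quadratic form is the block's Gaussian prior.

#' Create a design block
#'
#' Low-level constructor pairing a design matrix with its (possibly
#' rank-deficient) penalty.  Most users build blocks via [dummy_code()],
#' [bspline_basis()] or [star_fit()] rather than directly.
#'
#' @param matrix Numeric n x r design matrix.
#' @param penalty r x r symmetric positive semidefinite penalty; `NULL`
#'   means a zero penalty (diffuse fixed effects).
#' @param label Term label.
#' @param penalty_rank Rank of the penalty; computed from the eigenvalues
#'   when missing.
#' @param constraint `"none"` or `"sumzero"` (set by [apply_sum_to_zero()]).
#' @param info Optional list of term metadata (knots, levels, ...).
#' @return Object of class `design_block`.
#' @export
design_block <- function(matrix, penalty = NULL, label = "term",
                         penalty_rank = NULL, constraint = "none",
                         info = list()) {
  matrix <- as.matrix(matrix)
  r <- ncol(matrix)
  if (is.null(penalty)) penalty <- base::matrix(0, r, r)
  penalty <- as.matrix(penalty)
  stopifnot(nrow(penalty) == r, ncol(penalty) == r)
  if (max(abs(penalty - t(penalty))) > 1e-8)
    stop("penalty must be symmetric", call. = FALSE)
  penalty <- (penalty + t(penalty)) / 2
  if (is.null(penalty_rank)) {
    ev <- eigen(penalty, symmetric = TRUE, only.values = TRUE)$values
    penalty_rank <- sum(ev > max(1e-10, 1e-10 * max(abs(ev), 1)))
  }
  structure(
    list(matrix = matrix, penalty = penalty, penalty_rank = penalty_rank,
         label = label, constraint = constraint, info = info),
    class = "design_block")
}

#' @export
print.design_block <- function(x, ...) {
  cat("design_block '", x$label, "': ", nrow(x$matrix), " x ", ncol(x$matrix),
      ", penalty rank ", x$penalty_rank,
      if (x$constraint != "none") paste0(" [", x$constraint, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Dummy-code a categorical covariate
#'
#' One indicator column per non-reference level; the penalty is zero,
#' i.e. the coefficients get diffuse priors.  A record at the reference
#' level yields an all-zero row.
#'
#' @param values Character or factor vector of observed values.
#' @param levels Ordered level set; defaults to the factor levels of
#'   `values`.
#' @param reference Reference level (default the first of `levels`).
#' @param label Term label used to prefix column names.
#' @return A [design_block()] with `levels`/`reference` stored in `info`.
#' @examples
#' dummy_code(c("m", "f", "m"), levels = c("f", "m"), label = "gender")
#' @export
dummy_code <- function(values, levels = NULL, reference = NULL,
                       label = "term") {
  if (is.null(levels))
    levels <- if (is.factor(values)) base::levels(values) else
      sort(unique(as.character(values)))
  values <- as.character(values)
  bad <- !values %in% levels
  if (any(bad))
    stop("unseen level(s) in '", label, "': ",
         paste(unique(values[bad]), collapse = ", "), call. = FALSE)
  if (is.null(reference)) reference <- levels[1]
  if (!reference %in% levels)
    stop("reference not among levels", call. = FALSE)
  other <- setdiff(levels, reference)
  X <- vapply(other, function(l) as.numeric(values == l),
              numeric(length(values)))
  X <- base::matrix(X, nrow = length(values), ncol = length(other),
                    dimnames = list(NULL, paste0(label, ":", other)))
  design_block(X, penalty = NULL, label = label,
               info = list(levels = levels, reference = reference))
}

#' Equidistant B-spline basis
#'
#' Basis of `segments + degree` B-splines on an equidistant augmented knot
#' grid spanning `range`.  Rows sum to one everywhere on the interval
#' (partition of unity), so the basis contains the constant function.
#'
#' @param x Numeric vector of evaluation points, all within `range`.
#' @param segments Number of interior intervals (default 20).
#' @param degree Spline degree (default 3, cubic).
#' @param range Numeric length-2 knot range; defaults to `range(x)`.
#' @param label Term label.
#' @return A [design_block()] with a zero penalty; attach a difference
#'   penalty via [difference_penalty()].  Knot metadata is kept in `info`
#'   so the basis can be re-evaluated on a prediction grid.
#' @examples
#' b <- bspline_basis(seq(0, 59, by = 1), segments = 20, degree = 3)
#' range(rowSums(b$matrix))  # all 1
#' @export
bspline_basis <- function(x, segments = 20, degree = 3, range = NULL,
                          label = "s(x)") {
  stopifnot(segments >= 1, degree >= 0)
  x <- as.numeric(x)
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) stop("degenerate knot range", call. = FALSE)
  if (any(x < lo | x > hi))
    stop("x outside knot range", call. = FALSE)
  h <- (hi - lo) / segments
  knots <- lo + h * seq(-degree, segments + degree)
  ndist <- length(unique(x))
  if (ndist < segments + degree)
    warning("fewer distinct x values (", ndist, ") than basis functions (",
            segments + degree, ")", call. = FALSE)
  X <- .eval_bspline(knots, x, degree, hi)
  colnames(X) <- paste0(label, ".", seq_len(ncol(X)))
  design_block(X, penalty = NULL, label = label,
               info = list(knots = knots, degree = degree, range = range,
                           segments = segments))
}

# splineDesign with right-boundary handling: for degree 0 the basis is
# right-open, so a point exactly at the upper boundary is assigned to the
# last interval explicitly.
.eval_bspline <- function(knots, x, degree, hi) {
  at_hi <- x == hi
  if (degree == 0 && any(at_hi)) {
    X <- base::matrix(0, length(x), length(knots) - 1L)
    if (any(!at_hi))
      X[!at_hi, ] <- splines::splineDesign(knots, x[!at_hi], ord = 1)
    X[at_hi, ncol(X)] <- 1
    return(X)
  }
  splines::splineDesign(knots, x, ord = degree + 1)
}

#' Random-walk difference penalty
#'
#' `K = t(D) %*% D` with `D` the `order`-th forward-difference matrix, the
#' penalty implied by a Gaussian random-walk prior of that order on
#' adjacent B-spline coefficients.  `K` has rank `size - order`; its null
#' space contains the constant vector (and, for order 2, linear trends).
#'
#' @param order Random-walk order, 1 or 2.
#' @param size Number of coefficients; must exceed `order`.
#' @return `size x size` penalty matrix.
#' @examples
#' difference_penalty(1, 3)
#' @export
difference_penalty <- function(order, size) {
  order <- as.integer(order)
  if (!order %in% 1:2) stop("order must be 1 or 2", call. = FALSE)
  if (size <= order) stop("size must exceed order", call. = FALSE)
  D <- diff(diag(size), differences = order)
  crossprod(D)
}

#' Intrinsic GMRF precision (neighbourhood) matrix of a region graph
#'
#' Diagonal entries are the neighbour counts, off-diagonals are -1 for
#' adjacent pairs and 0 otherwise.  Row sums are zero and, on a connected
#' graph, the rank is `n_regions - 1` with the constant vector spanning
#' the null space.  Scaled by `1 / variance` this is the precision of the
#' intrinsic GMRF spatial prior: conditionally on its neighbours, a
#' region's effect is Gaussian with mean the neighbour average and
#' variance `variance / N_s`.
#'
#' @param graph A [region_graph()].
#' @return Symmetric matrix with region labels as dimnames.
#' @examples
#' gmrf_precision(make_lattice_graph(1, 3))
#' @export
gmrf_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  n <- length(graph$ids)
  K <- base::matrix(0, n, n, dimnames = list(graph$ids, graph$ids))
  diag(K) <- graph$n_neighbours
  i <- match(graph$edges[, 1], graph$ids)
  j <- match(graph$edges[, 2], graph$ids)
  K[cbind(i, j)] <- -1
  K[cbind(j, i)] <- -1
  K
}

#' Apply a sum-to-zero constraint to a design block
#'
#' Reparameterises the block onto the orthonormal null space of a single
#' linear constraint `sum(constraint * coef) = 0`, dropping one column.
#' With the default constraint vector `colSums(matrix)` the fitted effect
#' sums to zero over observations (the usual centring of a smooth term);
#' passing a vector of ones constrains the coefficients themselves to sum
#' to zero (the usual identifiability constraint on an intrinsic GMRF
#' spatial field).  When the constraint direction lies in the penalty null
#' space — true for both cases above, since the penalties annihilate
#' constants — the penalty rank is unchanged, and in the presence of a
#' free intercept the span of fitted predictors is also unchanged.
#'
#' @param block A [design_block()].
#' @param constraint Numeric vector of length `ncol(block$matrix)`;
#'   default `colSums(block$matrix)`.
#' @return The constrained [design_block()] with one fewer column; the
#'   reparameterisation matrix `Z` is stored in `info$Z` so effects can be
#'   mapped back to the original coefficients (`coef = Z %*% alpha`).
#' @export
apply_sum_to_zero <- function(block, constraint = NULL) {
  stopifnot(inherits(block, "design_block"))
  r <- ncol(block$matrix)
  if (r < 2) stop("cannot constrain a single-column block", call. = FALSE)
  if (is.null(constraint)) constraint <- colSums(block$matrix)
  stopifnot(length(constraint) == r)
  if (all(constraint == 0)) stop("zero constraint vector", call. = FALSE)
  Z <- qr.Q(qr(base::matrix(constraint, ncol = 1)), complete = TRUE)[, -1,
                                                                     drop = FALSE]
  Xc <- block$matrix %*% Z
  colnames(Xc) <- paste0(block$label, ".c", seq_len(ncol(Xc)))
  Kc <- t(Z) %*% block$penalty %*% Z
  info <- block$info
  info$Z <- Z
  info$constraint_vector <- constraint
  ev <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE, only.values = TRUE)$values
  design_block(Xc, (Kc + t(Kc)) / 2, label = block$label,
               penalty_rank = sum(ev > 1e-10 * max(1, max(abs(ev)))),
               constraint = "sumzero", info = info)
}
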