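## Model specification (terms, priors, chain configuration) and assembly
## of the per-term design blocks for the geo-additive logistic model.

#' Smooth-term settings
#'
#' @param segments Number of equidistant B-spline segments (default 20).
#' @param degree Spline degree (default 3).
#' @param order Random-walk penalty order, 1 or 2 (default 2).
#' @param a,b Inverse-gamma hyperparameters of the smoothing variance
#'   (default `a = b = 0.001`, the weakly informative standard choice;
#'   `a = 1, b = 0.005` is the usual sensitivity alternative).
#' @return List of class `smooth_term`.
#' @export
smooth_term <- function(segments = 20, degree = 3, order = 2,
                        a = 0.001, b = 0.001) {
  stopifnot(segments >= 1, degree >= 0, order %in% 1:2, a > 0, b > 0)
  structure(list(segments = segments, degree = degree, order = order,
                 a = a, b = b), class = "smooth_term")
}

#' Spatial-term settings
#'
#' @param variable Name of the region id column (default `"region"`).
#' @param structured Include the intrinsic-GMRF (spatially correlated)
#'   effect (default `TRUE`).
#' @param unstructured Include the i.i.d. region heterogeneity effect
#'   (default `TRUE`).
#' @param a,b Inverse-gamma hyperparameters for both spatial variances.
#' @return List of class `spatial_term`.
#' @export
spatial_term <- function(variable = "region", structured = TRUE,
                         unstructured = TRUE, a = 0.001, b = 0.001) {
  stopifnot(a > 0, b > 0, structured || unstructured)
  structure(list(variable = variable, structured = structured,
                 unstructured = unstructured, a = a, b = b),
            class = "spatial_term")
}

#' Specify a geo-additive logistic model
#'
#' Defines the structured additive predictor
#' `logit P(y = 1) = v' beta + sum_r f_r(x_r) + f_str(s) + f_unstr(s)`:
#' linear fixed effects for the `fixed` covariates (categorical variables
#' are dummy-coded against their reference level, numeric ones enter as
#' centred linear columns), P-spline smooths for the `smooth` covariates,
#' and optional structured + unstructured region effects.
#'
#' @param outcome Name of the binary outcome column.
#' @param fixed Character vector of covariate names entering linearly.
#' @param smooth Named list of [smooth_term()]s, one per continuous
#'   covariate modelled non-linearly.
#' @param spatial A [spatial_term()] or `NULL` for a non-spatial model.
#' @param intercept Include an intercept (default `TRUE`).
#' @return Object of class `star_spec`.
#' @examples
#' star_spec("outcome", fixed = c("gender", "diarrhoea"),
#'           smooth = list(child_age = smooth_term()),
#'           spatial = spatial_term("region"))
#' @export
star_spec <- function(outcome, fixed = character(), smooth = list(),
                      spatial = NULL, intercept = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  if (length(smooth) && is.null(names(smooth)))
    stop("smooth terms must be a named list", call. = FALSE)
  for (s in smooth) stopifnot(inherits(s, "smooth_term"))
  if (!is.null(spatial)) stopifnot(inherits(spatial, "spatial_term"))
  structure(list(outcome = outcome, fixed = fixed, smooth = smooth,
                 spatial = spatial, intercept = intercept),
            class = "star_spec")
}

#' @export
print.star_spec <- function(x, ...) {
  cat("star_spec: logit(", x$outcome, ") ~",
      if (x$intercept) "1 +" else "",
      paste(x$fixed, collapse = " + "),
      if (length(x$smooth))
        paste("+", paste0("f(", names(x$smooth), ")", collapse = " + ")),
      if (!is.null(x$spatial))
        paste0("+ spat(", x$spatial$variable, ")"), "\n")
  invisible(x)
}

#' MCMC chain configuration
#'
#' Defaults follow the package's standard analysis settings: 12,000
#' iterations thinned every 10th after a burn-in of 2,000, storing 1,000
#' draws per parameter.
#'
#' @param iterations Total sweeps (default 12000).
#' @param burnin Discarded initial sweeps (default 2000; must be smaller
#'   than `iterations`).
#' @param thin Thinning interval (default 10).
#' @param seed Integer RNG seed (default 1).
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(iterations = 12000, burnin = 2000, thin = 10,
                         seed = 1) {
  stopifnot(iterations >= 1, burnin >= 0, burnin < iterations, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "chain_config")
}

# Fixed-effect block: intercept + dummy columns + centred numeric columns.
.build_fixed_block <- function(spec, data) {
  n <- nrow(data)
  cols <- list()
  if (spec$intercept)
    cols[["(Intercept)"]] <- rep(1, n)
  for (v in spec$fixed) {
    if (!v %in% names(data))
      stop("fixed covariate '", v, "' not in data", call. = FALSE)
    x <- data[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x - mean(x)
    } else {
      db <- dummy_code(x, label = v)
      for (j in seq_len(ncol(db$matrix)))
        cols[[colnames(db$matrix)[j]]] <- db$matrix[, j]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  design_block(X, penalty = NULL, label = "fixed")
}

#' Build all design blocks for a model specification
#'
#' Assembles the fixed-effect block (zero penalty), one constrained
#' P-spline block per smooth term (difference penalty, observation
#' sum-to-zero), and the structured (GMRF penalty, region sum-to-zero)
#' and unstructured (identity penalty) spatial blocks.
#'
#' @param spec A [star_spec()].
#' @param data Data frame with the outcome and covariates.
#' @param graph A [region_graph()]; required when `spec$spatial` is set.
#' @return Named list with elements `y` (outcome vector), `blocks`
#'   (named list of [design_block()]s in update order) and `region_index`.
#' @export
build_design <- function(spec, data, graph = NULL) {
  stopifnot(inherits(spec, "star_spec"))
  y <- data[[spec$outcome]]
  if (is.null(y)) stop("outcome column '", spec$outcome, "' missing",
                       call. = FALSE)
  y <- as.integer(y)
  if (any(is.na(y)) || any(!y %in% 0:1))
    stop("outcome must be binary 0/1", call. = FALSE)
  n <- nrow(data)
  blocks <- list(fixed = .build_fixed_block(spec, data))
  for (v in names(spec$smooth)) {
    st <- spec$smooth[[v]]
    if (!v %in% names(data))
      stop("smooth covariate '", v, "' not in data", call. = FALSE)
    bb <- bspline_basis(data[[v]], segments = st$segments,
                        degree = st$degree, label = paste0("s(", v, ")"))
    bb$penalty <- difference_penalty(st$order, ncol(bb$matrix))
    bb$penalty_rank <- ncol(bb$matrix) - st$order
    bb <- apply_sum_to_zero(bb)
    bb$info$a <- st$a; bb$info$b <- st$b; bb$info$order <- st$order
    blocks[[paste0("s(", v, ")")]] <- bb
  }
  region_index <- NULL
  if (!is.null(spec$spatial)) {
    if (is.null(graph))
      stop("spatial term requires a region graph", call. = FALSE)
    rv <- spec$spatial$variable
    if (!rv %in% names(data))
      stop("region column '", rv, "' not in data", call. = FALSE)
    reg <- as.character(data[[rv]])
    missing_regions <- setdiff(unique(reg), graph$ids)
    if (length(missing_regions))
      stop("region(s) in data missing from graph: ",
           paste(missing_regions, collapse = ", "), call. = FALSE)
    region_index <- match(reg, graph$ids)
    S <- length(graph$ids)
    Z <- base::matrix(0, n, S, dimnames = list(NULL, graph$ids))
    Z[cbind(seq_len(n), region_index)] <- 1
    if (spec$spatial$structured) {
      db <- design_block(Z, gmrf_precision(graph), label = "Structured",
                         penalty_rank = S - 1,
                         info = list(regions = graph$ids))
      db <- apply_sum_to_zero(db, constraint = rep(1, S))
      db$info$a <- spec$spatial$a; db$info$b <- spec$spatial$b
      blocks[["Structured"]] <- db
    }
    if (spec$spatial$unstructured) {
      db <- design_block(Z, diag(S), label = "Unstructured",
                         penalty_rank = S,
                         info = list(regions = graph$ids,
                                     a = spec$spatial$a,
                                     b = spec$spatial$b))
      blocks[["Unstructured"]] <- db
    }
  }
  list(y = y, blocks = blocks, region_index = region_index)
}
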