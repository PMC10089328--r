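## Child-table CSV schema and reader.  Complete-case handling: rows with
## missing values in declared model variables are dropped with a logged
## count, mirroring the usual reduction of survey analytic samples.

#' Declare a child-table schema
#'
#' @param categorical Named list: for each categorical variable a list
#'   with `levels` (reference first) — as produced by
#'   [default_covariate_mix()] or hand-written.
#' @param continuous Named list: for each continuous variable a numeric
#'   `c(min, max)` range.
#' @param region Region id column name (default `"region"`).
#' @param zscores Require `haz`/`whz`/`waz` columns (default `FALSE`;
#'   they are optional when a precomputed `ciaf` column is present).
#' @return Object of class `child_schema`.
#' @export
child_schema <- function(categorical = list(),
                         continuous = list(child_age = c(0, 59),
                                           mother_age = c(15, 49)),
                         region = "region", zscores = FALSE) {
  structure(list(categorical = categorical, continuous = continuous,
                 region = region, zscores = zscores),
            class = "child_schema")
}

#' Default child-table schema (survey variable set)
#'
#' Categorical level sets from [default_covariate_mix()], child age 0-59
#' months, mother age 15-49 years.
#'
#' @inheritParams child_schema
#' @return A [child_schema()].
#' @export
default_child_schema <- function(zscores = FALSE) {
  mix <- default_covariate_mix()
  child_schema(categorical = lapply(mix, function(m) list(levels = m$levels)),
               zscores = zscores)
}

#' Read and validate a child-level CSV
#'
#' Checks the header against the schema, coerces categorical columns to
#' factors with the declared level order (reference first), range-checks
#' ages, and drops rows with missing values in any declared model
#' variable (complete-case analysis) with a logged count.  An
#' undeclared category level or a malformed numeric value is a hard
#' error naming the offending column and value.
#'
#' @param path CSV file path.
#' @param schema A [child_schema()] (default [default_child_schema()]).
#' @param graph Optional [region_graph()]; when given, region ids are
#'   validated against it.
#' @return Validated data frame.
#' @export
read_children_csv <- function(path, schema = default_child_schema(),
                              graph = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(schema, "child_schema"))
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c(schema$region, names(schema$continuous),
              names(schema$categorical),
              if (schema$zscores) c("haz", "whz", "waz"))
  absent <- setdiff(needed, names(raw))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  for (v in names(schema$categorical)) {
    lev <- schema$categorical[[v]]$levels
    vals <- raw[[v]]
    bad <- !is.na(vals) & !vals %in% lev
    if (any(bad)) {
      i <- which(bad)[1]
      stop("unknown level '", vals[i], "' in column '", v, "' (row ", i,
           ")", call. = FALSE)
    }
    raw[[v]] <- factor(vals, levels = lev)
  }
  for (v in names(schema$continuous)) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    newly_na <- is.na(x) & !is.na(raw[[v]])
    if (any(newly_na)) {
      i <- which(newly_na)[1]
      stop("malformed numeric '", raw[[v]][i], "' in column '", v,
           "' (row ", i, ")", call. = FALSE)
    }
    rng <- schema$continuous[[v]]
    out_of_range <- !is.na(x) & (x < rng[1] | x > rng[2])
    if (any(out_of_range)) {
      i <- which(out_of_range)[1]
      stop("value ", x[i], " outside range [", rng[1], ", ", rng[2],
           "] in column '", v, "' (row ", i, ")", call. = FALSE)
    }
    raw[[v]] <- x
  }
  if (schema$zscores) {
    for (v in c("haz", "whz", "waz")) {
      x <- suppressWarnings(as.numeric(raw[[v]]))
      if (any(is.na(x) & !is.na(raw[[v]])))
        stop("malformed numeric in column '", v, "'", call. = FALSE)
      raw[[v]] <- x
    }
  }
  if (!is.null(graph)) {
    reg <- as.character(raw[[schema$region]])
    unknown <- setdiff(stats::na.omit(unique(reg)), graph$ids)
    if (length(unknown))
      stop("region id(s) not in graph: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    raw[[schema$region]] <- factor(reg, levels = graph$ids)
  }
  complete <- stats::complete.cases(raw[, needed, drop = FALSE])
  if (any(!complete))
    message("dropped ", sum(!complete), " incomplete rows")
  raw[complete, , drop = FALSE]
}
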