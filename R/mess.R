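# similarity score of query values p against one reference vector (canonical
# rank-based MESS formula; f = percentage of reference values strictly
# below p)
.mess_scores <- function(p, ref, var_name = "") {
  rmin <- min(ref); rmax <- max(ref); n <- length(ref)
  if (rmax - rmin <= 0) {
    warning("reference variable '", var_name,
            "' has zero range; non-matching queries get a large negative ",
            "similarity sentinel", call. = FALSE)
    return(ifelse(p == rmin, 100, -1e9))
  }
  sr <- sort(ref)
  # counts of reference values strictly below each query
  below <- findInterval(p, sr, left.open = TRUE)
  f <- 100 * below / n
  s <- numeric(length(p))
  i0 <- f == 0
  s[i0] <- 100 * (p[i0] - rmin) / (rmax - rmin)
  ilo <- f > 0 & f <= 50
  s[ilo] <- 2 * f[ilo]
  ihi <- f > 50 & f < 100
  s[ihi] <- 2 * (100 - f[ihi])
  i1 <- f == 100
  s[i1] <- 100 * (rmax - p[i1]) / (rmax - rmin)
  s
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Scores how similar each query location's environment is to the reference
#' sample. For each variable, with reference min/max and \eqn{f} the
#' percentage of reference values below the query value \eqn{p}:
#' \deqn{S = 100 (p - min)/(max - min) \textrm{ if } f = 0;\quad 2f
#' \textrm{ if } 0 < f \le 50;\quad 2(100 - f) \textrm{ if } 50 < f < 100;
#' \quad 100 (max - p)/(max - min) \textrm{ if } f = 100.}
#' The cell score is the minimum over variables, with the limiting variable
#' recorded. Negative scores flag extrapolation: at least one variable is
#' outside the reference min-max envelope.
#'
#' @param reference data.frame (or named list) of reference values, one
#'   column per environmental variable.
#' @param query either a named list of \code{grid_raster}s (one per
#'   variable, same grid) or a data.frame with the same variable names.
#' @return If \code{query} is a raster list: a list of class
#'   \code{mess_layer} with \code{score} (a \code{grid_raster}),
#'   \code{limiting} (matrix of limiting-variable indices) and
#'   \code{variables}. If a data.frame: a data.frame with \code{score} and
#'   \code{limiting}.
#' @export
mess <- function(reference, query) {
  reference <- as.data.frame(reference)
  vars <- names(reference)
  if (!length(vars)) stop("no reference variables", call. = FALSE)
  if (any(!vapply(reference, function(v) sum(!is.na(v)) > 0, logical(1))))
    stop("a reference variable has no non-missing values", call. = FALSE)
  raster_mode <- !is.data.frame(query) && all(vars %in% names(query)) &&
    inherits(query[[vars[1]]], "grid_raster")
  if (raster_mode) {
    qmat <- vapply(vars, function(v) as.vector(query[[v]]$values),
                   numeric(length(query[[vars[1]]]$values)))
  } else {
    query <- as.data.frame(query)
    if (!all(vars %in% names(query)))
      stop("query lacks variables: ",
           paste(setdiff(vars, names(query)), collapse = ", "),
           call. = FALSE)
    qmat <- as.matrix(query[, vars, drop = FALSE])
  }
  smat <- vapply(seq_along(vars), function(j)
    .mess_scores(qmat[, j], reference[[j]][!is.na(reference[[j]])],
                 vars[j]),
    numeric(nrow(qmat)))
  if (is.null(dim(smat))) smat <- matrix(smat, nrow = 1)
  limiting <- max.col(-smat, ties.method = "first")
  score <- smat[cbind(seq_len(nrow(smat)), limiting)]
  if (raster_mode) {
    g <- query[[vars[1]]]
    g$values <- matrix(score, g$nrow, g$ncol)
    structure(list(score = g,
                   limiting = matrix(limiting, g$nrow, g$ncol),
                   variables = vars),
              class = "mess_layer")
  } else {
    data.frame(score = score, limiting = vars[limiting])
  }
}

#' @export
print.mess_layer <- function(x, ...) {
  v <- x$score$values
  cat(sprintf(
    "MESS layer: %.1f%% of cells inside the reference envelope (score >= 0)\n",
    100 * mean(v >= 0, na.rm = TRUE)))
  cat(sprintf("  score range [%.1f, %.1f]; variables: %s\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}
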