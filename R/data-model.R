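## Long-format data -> per-cluster blocks with a shared design matrix.
##
## A "cluster block" carries everything the estimating equation needs for
## one cluster: the 0/1 outcome vector y, the n_i x p design matrix X and
## the integer occasion positions (indices into the pooled occasion set).

#' Split model data into per-cluster blocks
#'
#' Builds the design matrix from `formula` (standard treatment coding;
#' the lowest-sorted level of a factor is the reference) and partitions the
#' rows by cluster. When `repeated` is supplied, rows are ordered within
#' each cluster by occasion label and occasion labels must be unique within
#' a cluster; otherwise rows of one cluster must be contiguous and file
#' order is kept. Rows with missing values in the outcome or any model term
#' are dropped with a message.
#'
#' @param formula model formula, e.g. `Wheeze ~ City + factor(Age)`.
#' @param data data frame in long format.
#' @param id cluster identifier: a vector of length `nrow(data)`, or the
#'   name of a column of `data`.
#' @param repeated optional occasion identifier, same conventions as `id`.
#'   Treated as a categorical position label, not a numeric time.
#' @return an object of class `"gee_blocks"`: a list with elements
#'   `blocks` (list of per-cluster lists `id`, `y`, `X`, `occ`),
#'   `occasion_levels`, `p`, `K`, `n_obs`, `xnames`, `terms`,
#'   `dropped` (count of incomplete rows removed).
#' @export
build_clusters <- function(formula, data, id, repeated = NULL) {
  if (!inherits(formula, "formula")) formula <- stats::as.formula(formula)
  data <- as.data.frame(data)

  id <- resolve_column(id, data, "id")
  if (anyNA(id)) stop("missing values in the cluster identifier", call. = FALSE)
  if (!is.null(repeated)) repeated <- resolve_column(repeated, data, "repeated")

  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  complete <- stats::complete.cases(mf)
  dropped <- sum(!complete)
  if (dropped > 0L) {
    message("dropping ", dropped, " row(s) with missing outcome or covariates")
    mf <- mf[complete, , drop = FALSE]
    id <- id[complete]
    if (!is.null(repeated)) repeated <- repeated[complete]
    y <- y[complete]
  }
  if (is.logical(y)) y <- as.numeric(y)
  if (!is.numeric(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary, coded 0/1", call. = FALSE)

  X <- stats::model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient; drop aliased terms", call. = FALSE)

  id_chr <- as.character(id)
  if (is.null(repeated)) {
    ## contiguity check: each id must occupy one run of rows
    runs <- rle(id_chr)$values
    if (anyDuplicated(runs))
      stop("rows of a cluster must be contiguous when 'repeated' is not ",
           "supplied; sort the data or provide 'repeated'", call. = FALSE)
    uid <- unique(id_chr)
    occ_levels <- seq_len(max(tabulate(factor(id_chr, levels = uid))))
    blocks <- lapply(uid, function(u) {
      idx <- which(id_chr == u)
      list(id = u, y = as.numeric(y[idx]), X = X[idx, , drop = FALSE],
           occ = seq_along(idx))
    })
    occasion_levels <- as.character(occ_levels)
  } else {
    occ_levels <- sort(unique(repeated))
    occ_pos <- match(repeated, occ_levels)
    uid <- unique(id_chr)
    blocks <- lapply(uid, function(u) {
      idx <- which(id_chr == u)
      pos <- occ_pos[idx]
      if (anyDuplicated(pos))
        stop("duplicate occasion label within cluster '", u, "'",
             call. = FALSE)
      o <- order(pos)
      idx <- idx[o]
      list(id = u, y = as.numeric(y[idx]), X = X[idx, , drop = FALSE],
           occ = pos[o])
    })
    occasion_levels <- as.character(occ_levels)
  }

  structure(list(blocks = blocks,
                 occasion_levels = occasion_levels,
                 p = p, K = length(blocks),
                 n_obs = sum(vapply(blocks, function(b) length(b$y), 0)),
                 xnames = colnames(X),
                 terms = attr(mf, "terms"),
                 xlev = stats::.getXlevels(attr(mf, "terms"), mf),
                 dropped = dropped),
            class = "gee_blocks")
}

resolve_column <- function(x, data, what) {
  if (is.character(x) && length(x) == 1L && x %in% names(data))
    return(data[[x]])
  if (length(x) != nrow(data))
    stop("'", what, "' must name a column of 'data' or be a vector with ",
         "one entry per row", call. = FALSE)
  x
}

#' @export
print.gee_blocks <- function(x, ...) {
  cat("Clustered data: K =", x$K, "clusters,", x$n_obs, "observations,",
      "p =", x$p, "design columns\n")
  invisible(x)
}
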