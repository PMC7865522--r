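#' Labelled symmetric kinase similarity matrix
#'
#' Thin S3 wrapper around a base matrix that records the measure's name
#' and its admissible value range ([0, 1] for set-overlap measures,
#' [-1, 1] for correlations). Undefined entries are \code{NaN}.
#'
#' @param values square numeric matrix with identical row and column
#'   labels; must be symmetric wherever both entries are defined.
#' @param measure_name string, e.g. \code{"LigProfSim"}.
#' @param range numeric length-2 admissible range.
#' @return an object of class \code{similarity_matrix}.
#' @export
similarity_matrix <- function(values, measure_name = "similarity",
                              range = c(0, 1)) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("k", seq_len(nrow(values)))
  stopifnot(identical(rownames(values), colnames(values)))
  both <- is.finite(values) & is.finite(t(values))
  if (any(abs(values[both] - t(values)[both]) > 1e-12))
    stop("matrix is not symmetric")
  fin <- values[is.finite(values)]
  if (length(fin) && (any(fin < range[1] - 1e-12) ||
                      any(fin > range[2] + 1e-12)))
    stop("entries outside declared range [", range[1], ", ", range[2], "]")
  structure(values, class = c("similarity_matrix", "matrix", "array"),
            measure_name = measure_name, range = range)
}

#' @export
print.similarity_matrix <- function(x, digits = 3, ...) {
  cat(attr(x, "measure_name"), " matrix (", nrow(x), " x ", ncol(x),
      ", range [", attr(x, "range")[1], ", ", attr(x, "range")[2], "])\n",
      sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, digits))
  invisible(x)
}

#' Per-kinase mean and standard deviation of a similarity matrix
#'
#' Summarises each kinase's row, including the diagonal self-similarity,
#' so a kinase's mean reflects its similarity to every set member
#' including itself. \code{NaN} entries are excluded pairwise and counted.
#'
#' @param matrix a \code{\link{similarity_matrix}}.
#' @param sd_type \code{"sample"} (n - 1 denominator, default) or
#'   \code{"population"}.
#' @param include_diagonal include the self-similarity entry in each row
#'   summary (default \code{TRUE}).
#' @return data.frame with columns \code{kinase}, \code{mean}, \code{sd},
#'   \code{n_used}, \code{n_undefined}.
#' @export
summarize_similarity <- function(matrix,
                                 sd_type = c("sample", "population"),
                                 include_diagonal = TRUE) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  sd_type <- match.arg(sd_type)
  labs <- rownames(matrix)
  out <- lapply(seq_along(labs), function(i) {
    row <- unclass(matrix)[i, ]
    if (!include_diagonal) row <- row[-i]
    ok <- is.finite(row)
    vals <- row[ok]
    n <- length(vals)
    if (n == 0L) {
      warning("all entries undefined for kinase ", labs[[i]])
      return(data.frame(kinase = labs[[i]], mean = NaN, sd = NaN,
                        n_used = 0L, n_undefined = sum(!ok)))
    }
    s <- if (n < 2L) NA_real_
         else if (sd_type == "sample") stats::sd(vals)
         else sqrt(mean((vals - mean(vals))^2))
    data.frame(kinase = labs[[i]], mean = mean(vals), sd = s,
               n_used = n, n_undefined = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
summary.similarity_matrix <- function(object, ...) {
  summarize_similarity(object, ...)
}

#' Correlate two similarity measures over kinase pairs
#'
#' Vectorises the off-diagonal upper triangle of both matrices over their
#' common kinase labels and computes the Pearson correlation with a
#' two-sided test. Diagonal entries are excluded because self-similarity
#' means something different for each measure (promiscuity, perfect
#' sequence identity, best same-kinase structure pair, ...). Pairs where
#' either measure is undefined are dropped.
#'
#' @param a,b \code{\link{similarity_matrix}} objects sharing >= 3 kinase
#'   labels with defined off-diagonal values.
#' @param method correlation flavour passed to \code{stats::cor.test}
#'   (default \code{"pearson"}).
#' @return list with elements \code{r}, \code{p_value}, \code{n_pairs},
#'   \code{n_dropped}.
#' @export
compare_measures <- function(a, b, method = "pearson") {
  stopifnot(inherits(a, "similarity_matrix"),
            inherits(b, "similarity_matrix"))
  labs <- intersect(rownames(a), rownames(b))
  if (length(labs) < 3L) stop("need >= 3 common kinases")
  ma <- unclass(a)[labs, labs]
  mb <- unclass(b)[labs, labs]
  ut <- upper.tri(ma)
  va <- ma[ut]
  vb <- mb[ut]
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3L) {
    warning("fewer than 3 complete off-diagonal pairs; correlation undefined")
    return(list(r = NaN, p_value = NaN, n_pairs = sum(ok),
                n_dropped = sum(!ok)))
  }
  ct <- stats::cor.test(va[ok], vb[ok], method = method,
                        alternative = "two.sided", exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ok), n_dropped = sum(!ok))
}

#' Write / read a similarity matrix as labelled CSV
#'
#' @param matrix a \code{\link{similarity_matrix}}.
#' @param path output CSV path.
#' @return \code{path} invisibly.
#' @export
write_similarity_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  utils::write.csv(as.data.frame(unclass(matrix)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @param measure_name,range passed to \code{\link{similarity_matrix}}.
#' @export
read_similarity_matrix <- function(path, measure_name = "similarity",
                                   range = c(0, 1)) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  similarity_matrix(as.matrix(df), measure_name = measure_name,
                    range = range)
}

#' Heatmap of a similarity matrix
#'
#' Base-graphics heatmap with kinase labels; undefined entries are left
#' blank.
#'
#' @param x a \code{\link{similarity_matrix}}.
#' @param col colour ramp.
#' @param ... passed to \code{graphics::image}.
#' @export
plot.similarity_matrix <- function(x, col = grDevices::hcl.colors(25,
                                     "YlOrRd", rev = TRUE), ...) {
  m <- unclass(x)
  n <- nrow(m)
  rng <- attr(x, "range")
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = rng, col = col, axes = FALSE, xlab = "", ylab = "",
                  main = attr(x, "measure_name"), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
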