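#' Training ranges for the HEOM dissimilarity
#'
#' Computes, per numeric attribute, the observed minimum, maximum and range
#' on a training (construction) set, plus the observed (non-missing) count
#' for every attribute.  Ranges must come from training data only; test
#' values falling outside them are clipped at distance 1.
#'
#' @param dataset a [mixed_dataset()] (the construction set).
#' @return A `heom_ranges` list with named numeric vectors `min`, `max`,
#'   `range` (numeric attributes) and integer vector `observed` (all
#'   attributes).
#' @export
heom_ranges <- function(dataset) {
  kinds <- attribute_kinds(dataset)
  num <- names(kinds)[kinds == "numeric"]
  mn <- mx <- stats::setNames(numeric(length(num)), num)
  for (nm in num) {
    v <- dataset$x[[nm]]
    v <- v[!is.na(v)]
    if (length(v) == 0) { mn[nm] <- NA_real_; mx[nm] <- NA_real_ }
    else { mn[nm] <- min(v); mx[nm] <- max(v) }
  }
  structure(list(
    min = mn, max = mx, range = mx - mn,
    observed = vapply(dataset$x, function(col) sum(!is.na(col)), integer(1))
  ), class = "heom_ranges")
}

#' Per-attribute HEOM distance
#'
#' The Heterogeneous Euclidean-Overlap Metric compares one attribute of two
#' instances: the distance is 1 if either value is missing; for nominal
#' attributes 0 if equal, else 1; for numeric attributes `|a - b| / range`
#' clipped to \[0, 1\], where the range is the training range.  A zero-range
#' attribute compares by equality (0 if equal, else 1).
#'
#' @param a,b scalar values (`NA` = missing); for nominal attributes,
#'   factors or their character labels.
#' @param kind `"numeric"` or `"nominal"`.
#' @param range training range (numeric attributes only).
#' @param categories valid category labels (nominal attributes; optional,
#'   used to reject foreign payloads).
#' @return A distance in \[0, 1\].
#' @examples
#' attribute_distance(2, 6, "numeric", range = 10)   # 0.4
#' attribute_distance(NA, 5, "numeric", range = 10)  # 1
#' attribute_distance("yes", "no", "nominal")        # 1
#' @export
attribute_distance <- function(a, b, kind = c("numeric", "nominal"),
                               range = NULL, categories = NULL) {
  kind <- match.arg(kind)
  if (is.factor(a)) a <- as.character(a)
  if (is.factor(b)) b <- as.character(b)
  if (is.na(a) || is.na(b)) return(1)
  if (kind == "nominal") {
    if (!is.null(categories) && !all(c(a, b) %in% categories)) {
      stopf("nominal payload outside the declared categories")
    }
    return(if (identical(as.character(a), as.character(b))) 0 else 1)
  }
  if (is.null(range)) stopf("numeric attribute needs a training range")
  # NA range = attribute never observed in training; compare by equality,
  # like a zero-range attribute.
  if (is.na(range) || range == 0) return(if (a == b) 0 else 1)
  min(abs(a - b) / range, 1)
}

#' HEOM dissimilarity between two instances
#'
#' Root-sum-of-squares aggregation of [attribute_distance()] over all
#' predictive attributes:
#' `heom(x, y) = sqrt(sum_a d_a(x_a, y_a)^2)`.
#' It is symmetric and bounded by `sqrt(m)` for `m` attributes; any pattern
#' of missing values is allowed (missing contributes distance 1).
#'
#' @param x,y single instances: one-row data.frames (or named lists) whose
#'   columns match the training schema.
#' @param kinds named character vector of attribute kinds, as from
#'   [attribute_kinds()].
#' @param ranges a [heom_ranges()] object from the training set.
#' @return A non-negative dissimilarity.
#' @export
heom <- function(x, y, kinds, ranges) {
  nms <- names(kinds)
  if (!all(nms %in% names(x)) || !all(nms %in% names(y))) {
    stopf("instances do not conform to the schema")
  }
  s <- 0
  for (nm in nms) {
    d <- attribute_distance(x[[nm]][1], y[[nm]][1], kinds[[nm]],
                            range = ranges$range[nm])
    s <- s + d * d
  }
  sqrt(s)
}

# Vectorized HEOM: n x m distance matrix between the rows of data.frames
# A and B.  Missing values (either side) contribute 1 per attribute.
heom_cross <- function(A, B, kinds, ranges) {
  n <- nrow(A); m <- nrow(B)
  D2 <- matrix(0, n, m)
  for (nm in names(kinds)) {
    va <- A[[nm]]; vb <- B[[nm]]
    if (kinds[[nm]] == "numeric") {
      r <- ranges$range[[nm]]
      if (is.na(r) || r == 0) {
        d <- outer(va, vb, "!=") * 1
      } else {
        d <- pmin(abs(outer(va, vb, "-")) / r, 1)
      }
    } else {
      d <- outer(as.integer(va), as.integer(vb), "!=") * 1
    }
    d[is.na(d)] <- 1
    D2 <- D2 + d * d
  }
  sqrt(D2)
}

#' Dissimilarity strategy registry
#'
#' The dissimilarity used throughout fitting and classification is a named,
#' pluggable strategy; `"heom"` is the default and currently the only
#' built-in.  A strategy is a function `(A, B, kinds, ranges)` returning the
#' `nrow(A) x nrow(B)` matrix of pairwise dissimilarities.
#'
#' @param name strategy name.
#' @param fn for `register_dissimilarity`, the strategy function.
#' @return `get_dissimilarity` returns the strategy function.
#' @export
get_dissimilarity <- function(name = "heom") {
  fn <- dissimilarity_registry[[name]]
  if (is.null(fn)) stopf("unknown dissimilarity strategy '%s'", name)
  fn
}

#' @rdname get_dissimilarity
#' @export
register_dissimilarity <- function(name, fn) {
  assign(name, fn, envir = dissimilarity_registry)
  invisible(name)
}

dissimilarity_registry <- new.env(parent = emptyenv())
assign("heom", heom_cross, envir = dissimilarity_registry)
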