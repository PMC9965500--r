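#' Mixed, possibly incomplete tabular dataset
#'
#' A `mixed_dataset` couples a predictor table with a class label per row.
#' Numeric attributes are stored as double columns, nominal attributes as
#' factor columns whose level order is meaningful: it is the category order
#' declared in an ARFF header or the order of first appearance in a CSV file,
#' and it is used downstream for deterministic mode tie-breaking.  Missing
#' values are plain `NA` in any predictor cell; class labels may never be
#' missing.
#'
#' @param x data.frame of predictors; columns must be numeric or factor.
#' @param y class labels, coerced to factor; length `nrow(x)`, no `NA`.
#' @param name optional dataset name (used in reports).
#' @return An object of class `mixed_dataset` with elements `x` (data.frame),
#'   `y` (factor) and `name`.
#' @examples
#' d <- mixed_dataset(
#'   data.frame(age = c(31, NA, 58), smoker = factor(c("yes", "no", "yes"))),
#'   y = c("benign", "benign", "malignant")
#' )
#' n_instances(d)
#' @export
mixed_dataset <- function(x, y, name = "dataset") {
  if (!is.data.frame(x)) stopf("predictors must be a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.character(x[[j]]) || is.logical(x[[j]])) {
      x[[j]] <- factor(x[[j]], levels = unique(x[[j]][!is.na(x[[j]])]))
    } else if (is.integer(x[[j]])) {
      x[[j]] <- as.double(x[[j]])
    } else if (!is.numeric(x[[j]]) && !is.factor(x[[j]])) {
      stopf("attribute '%s' is neither numeric nor nominal", names(x)[j])
    }
  }
  if (anyDuplicated(names(x))) stopf("attribute names must be unique")
  if (length(y) != nrow(x)) stopf("labels must match the number of instances")
  if (anyNA(y)) stopf("class labels may not be missing")
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  y <- droplevels(y)
  if (nrow(x) > 0 && nlevels(y) < 1) stopf("dataset needs at least one class")
  structure(list(x = x, y = y, name = name), class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat(sprintf(
    "<mixed_dataset '%s': %d instances, %d attributes (%d numeric, %d nominal), %d classes>\n",
    x$name, n_instances(x), n_attributes(x),
    sum(attribute_kinds(x) == "numeric"), sum(attribute_kinds(x) == "nominal"),
    nlevels(x$y)
  ))
  invisible(x)
}

#' Dataset accessors
#'
#' Small helpers over a [mixed_dataset()]: instance/attribute counts, the
#' attribute kind (`"numeric"` or `"nominal"`) per column, and the ordered
#' class identifiers.
#' @param dataset a `mixed_dataset`.
#' @return `n_instances`/`n_attributes` return counts; `attribute_kinds` a
#'   named character vector; `dataset_classes` a character vector of class
#'   labels in level order.
#' @export
n_instances <- function(dataset) nrow(dataset$x)

#' @rdname n_instances
#' @export
n_attributes <- function(dataset) ncol(dataset$x)

#' @rdname n_instances
#' @export
attribute_kinds <- function(dataset) {
  vapply(dataset$x, function(col) if (is.numeric(col)) "numeric" else "nominal",
         character(1))
}

#' @rdname n_instances
#' @export
dataset_classes <- function(dataset) levels(dataset$y)

# Row subset preserving factor levels and label levels.
subset_dataset <- function(dataset, idx) {
  structure(
    list(x = dataset$x[idx, , drop = FALSE],
         y = factor(as.character(dataset$y[idx]), levels = levels(dataset$y)),
         name = dataset$name),
    class = "mixed_dataset"
  )
}

#' Read a mixed dataset from CSV or ARFF
#'
#' CSV files must carry a header row; `"?"` and empty cells are the missing
#' markers.  A CSV column is numeric iff every non-missing cell parses as a
#' number, otherwise nominal with categories ordered by first appearance.
#' ARFF attribute kinds and category order come from the `@attribute`
#' declarations (`numeric`/`real`/`integer` or `{a,b,...}`); `"?"` is missing.
#'
#' @param path file path.
#' @param format `"csv"`, `"arff"`, or `"auto"` (by file extension).
#' @param class_column name of the decision attribute, or `"last"`.
#' @return A [mixed_dataset()].
#' @export
read_dataset <- function(path, format = c("auto", "csv", "arff"),
                         class_column = "last") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "csv") read_dataset_csv(path, class_column)
  else read_dataset_arff(path, class_column)
}

read_dataset_csv <- function(path, class_column) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = character(0), strip.white = TRUE),
    error = function(e) stopf("malformed CSV '%s': %s", path, conditionMessage(e))
  )
  if (ncol(raw) < 2) stopf("'%s' needs at least one predictor and a class column", path)
  for (j in seq_along(raw)) raw[[j]][raw[[j]] %in% c("?", "")] <- NA
  build_dataset_from_character(raw, class_column, path,
                               declared = NULL, name = basename(path))
}

read_dataset_arff <- function(path, class_column) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("%.*$", "", lines)
  trimmed <- trimws(lines)
  att_names <- character(0)
  att_specs <- list()
  data_at <- NA_integer_
  for (i in seq_along(trimmed)) {
    ln <- trimmed[i]
    if (ln == "") next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@attribute")) {
      m <- regmatches(ln, regexec(
        "^@[aA][tT][tT][rR][iI][bB][uU][tT][eE]\\s+('[^']*'|\"[^\"]*\"|\\S+)\\s+(.*)$", ln))[[1]]
      if (length(m) < 3) stopf("malformed @attribute at line %d of '%s'", i, path)
      nm <- gsub("^['\"]|['\"]$", "", m[2])
      spec <- trimws(m[3])
      if (grepl("^\\{", spec)) {
        cats <- strsplit(gsub("^\\{|\\}$", "", spec), ",")[[1]]
        cats <- gsub("^['\"]|['\"]$", "", trimws(cats))
        att_specs[[length(att_specs) + 1L]] <- list(kind = "nominal", categories = cats)
      } else if (tolower(spec) %in% c("numeric", "real", "integer")) {
        att_specs[[length(att_specs) + 1L]] <- list(kind = "numeric")
      } else {
        stopf("unsupported attribute type '%s' at line %d of '%s'", spec, i, path)
      }
      att_names <- c(att_names, nm)
      next
    }
    if (startsWith(low, "@data")) { data_at <- i; break }
  }
  if (is.na(data_at)) stopf("no @data section in '%s'", path)
  if (length(att_names) == 0) stopf("no @attribute declarations in '%s'", path)
  body <- trimmed[seq(data_at + 1L, length.out = max(0L, length(trimmed) - data_at))]
  body <- body[body != ""]
  if (length(body) == 0) stopf("empty @data section in '%s'", path)
  raw <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), header = FALSE,
                    colClasses = "character", na.strings = character(0),
                    strip.white = TRUE, quote = "'\""),
    error = function(e) stopf("malformed @data in '%s': %s", path, conditionMessage(e))
  )
  if (ncol(raw) != length(att_names)) {
    stopf("'%s': %d attributes declared but %d columns in @data",
          path, length(att_names), ncol(raw))
  }
  names(raw) <- att_names
  for (j in seq_along(raw)) raw[[j]][raw[[j]] == "?"] <- NA
  build_dataset_from_character(raw, class_column, path,
                               declared = att_specs, name = basename(path))
}

# Shared CSV/ARFF assembly: resolve the class column, type the predictors,
# reject unlabeled rows.
build_dataset_from_character <- function(raw, class_column, path, declared, name) {
  cls_idx <- if (identical(class_column, "last")) ncol(raw)
             else match(class_column, names(raw))
  if (is.na(cls_idx)) stopf("class column '%s' not found in '%s'", class_column, path)
  ylab <- raw[[cls_idx]]
  if (anyNA(ylab)) {
    stopf("missing class value on data row(s) %s of '%s'",
          paste(which(is.na(ylab)), collapse = ", "), path)
  }
  xs <- raw[, -cls_idx, drop = FALSE]
  decl <- if (!is.null(declared)) declared[-cls_idx] else NULL
  for (j in seq_along(xs)) {
    col <- xs[[j]]
    if (!is.null(decl)) {
      if (decl[[j]]$kind == "numeric") {
        num <- suppressWarnings(as.numeric(col))
        if (any(is.na(num) & !is.na(col))) {
          stopf("non-numeric value in numeric attribute '%s' of '%s'", names(xs)[j], path)
        }
        xs[[j]] <- num
      } else {
        bad <- !is.na(col) & !(col %in% decl[[j]]$categories)
        if (any(bad)) {
          stopf("undeclared category '%s' in attribute '%s' of '%s'",
                col[bad][1], names(xs)[j], path)
        }
        xs[[j]] <- factor(col, levels = decl[[j]]$categories)
      }
    } else {
      num <- suppressWarnings(as.numeric(col))
      if (!any(is.na(num) & !is.na(col)) && any(!is.na(col))) {
        xs[[j]] <- num
      } else {
        xs[[j]] <- factor(col, levels = unique(col[!is.na(col)]))
      }
    }
  }
  ycls <- if (!is.null(declared) && declared[[cls_idx]]$kind == "nominal") {
    factor(ylab, levels = declared[[cls_idx]]$categories)
  } else {
    factor(ylab, levels = unique(ylab))
  }
  mixed_dataset(xs, droplevels(ycls), name = name)
}

#' Write a mixed dataset to CSV or ARFF
#'
#' Missing cells are written as `"?"`.  Numeric values are written with 17
#' significant digits so that a write/read round trip reproduces them
#' exactly; nominal category order is preserved (ARFF: in the declaration;
#' CSV: implied by row order at re-inference time only).
#'
#' @param dataset a [mixed_dataset()].
#' @param path output file path.
#' @param format `"csv"`, `"arff"`, or `"auto"` (by extension).
#' @param class_name column/attribute name for the labels.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("auto", "csv", "arff"),
                          class_name = "class") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  quote_csv <- function(v) {
    needs <- grepl('[",\n]', v)
    v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
    v
  }
  fmt_cell <- function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "?", sprintf("%.17g", col))
    else ifelse(is.na(col), "?", as.character(col))
  }
  cells <- lapply(dataset$x, fmt_cell)
  cells[[class_name]] <- as.character(dataset$y)
  if (format == "csv") {
    cells <- lapply(cells, quote_csv)
    header <- paste(quote_csv(names(cells)), collapse = ",")
    rows <- do.call(paste, c(cells, sep = ","))
    writeLines(c(header, rows), path)
  } else {
    kinds <- attribute_kinds(dataset)
    decls <- vapply(seq_along(dataset$x), function(j) {
      if (kinds[j] == "numeric") sprintf("@attribute %s numeric", names(dataset$x)[j])
      else sprintf("@attribute %s {%s}", names(dataset$x)[j],
                   paste(levels(dataset$x[[j]]), collapse = ","))
    }, character(1))
    decls <- c(decls, sprintf("@attribute %s {%s}", class_name,
                              paste(levels(dataset$y), collapse = ",")))
    rows <- do.call(paste, c(cells, sep = ","))
    writeLines(c(sprintf("@relation %s", gsub("\\s+", "_", dataset$name)),
                 "", decls, "", "@data", rows), path)
  }
  invisible(path)
}

#' Profile a dataset: size, imbalance ratio, missingness
#'
#' The imbalance ratio (IR) is the majority-to-minority class size ratio
#' (global max/min for multiclass data).  A dataset is conventionally called
#' imbalanced when IR exceeds 1.5.  `imbalance_ratio_display` renders the IR
#' truncated — not rounded — to two decimals, the convention used in
#' benchmark summary tables (187/175 renders as "1.06").
#'
#' @param dataset a non-empty [mixed_dataset()].
#' @return A `dataset_profile` list: `n_attributes`, `n_instances`,
#'   `imbalance_ratio` (full precision), `imbalance_ratio_display` (string),
#'   `has_missing`, `class_counts` (named integer vector).
#' @examples
#' d <- mixed_dataset(data.frame(v = rnorm(6)), rep(c("a", "b"), c(4, 2)))
#' dataset_profile(d)$imbalance_ratio_display  # "2.00"
#' @export
dataset_profile <- function(dataset) {
  if (n_instances(dataset) == 0) stopf("cannot profile an empty dataset")
  counts <- table(dataset$y)
  ir <- max(counts) / min(counts)
  structure(list(
    n_attributes = n_attributes(dataset),
    n_instances = n_instances(dataset),
    imbalance_ratio = as.numeric(ir),
    imbalance_ratio_display = truncate2(ir),
    has_missing = anyNA(dataset$x),
    class_counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "dataset_profile")
}

#' @export
print.dataset_profile <- function(x, ...) {
  cat(sprintf("instances: %d  attributes: %d  IR: %s  missing: %s\n",
              x$n_instances, x$n_attributes, x$imbalance_ratio_display,
              if (x$has_missing) "yes" else "no"))
  cat("class counts:", paste(names(x$class_counts), x$class_counts,
                             sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Stratified hold-out split
#'
#' Splits a dataset into a construction part and a validation part.  Per
#' class `c` with `n_c` instances, `round(fraction * n_c)` (half-up) go to
#' construction, clamped so both parts keep at least one instance whenever
#' `n_c >= 2`; a singleton class goes entirely to construction.  The split
#' is deterministic given `seed`.
#'
#' @param dataset a [mixed_dataset()].
#' @param fraction construction fraction, in (0, 1).
#' @param seed integer seed.
#' @return A list with `construction` and `validation` (`mixed_dataset`s) and
#'   the corresponding row indices `construction_idx`, `validation_idx`.
#' @export
stratified_holdout <- function(dataset, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stopf("fraction must lie strictly between 0 and 1")
  }
  idx_by_class <- split(seq_len(n_instances(dataset)), dataset$y)
  con_idx <- integer(0)
  with_seed(seed, {
    for (idx in idx_by_class) {
      n_c <- length(idx)
      if (n_c == 0) next
      if (n_c == 1) { con_idx <- c(con_idx, idx); next }
      k <- round_half_up(fraction * n_c)
      k <- min(max(k, 1L), n_c - 1L)
      shuffled <- idx[sample.int(n_c)]
      con_idx <- c(con_idx, shuffled[seq_len(k)])
    }
  })
  con_idx <- sort(con_idx)
  val_idx <- setdiff(seq_len(n_instances(dataset)), con_idx)
  list(construction = subset_dataset(dataset, con_idx),
       validation = subset_dataset(dataset, val_idx),
       construction_idx = con_idx,
       validation_idx = val_idx)
}
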