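#' Specification for the synthetic mixed-data generator
#'
#' Describes a class-conditional generative model for mixed-type,
#' incomplete, imbalanced classification data: numeric attributes are
#' class-conditional Gaussians with unit within-class standard deviation
#' and class means offset by `class_separation`; nominal attributes place
#' extra probability mass on a class-preferred category,
#' `1/q + (1 - 1/q) * (1 - exp(-class_separation / 2))` for `q` categories
#' (exactly uniform at separation 0, so separation has a uniform meaning
#' across attribute kinds).  Missingness is MCAR on predictive attributes
#' only.
#'
#' Defaults emulate a mid-sized clinical benchmark table: a few hundred
#' instances, a handful of mixed attributes, moderate imbalance and a low
#' missing rate.
#'
#' @param n_instances number of instances.
#' @param class_proportions class probabilities, summing to 1, all > 0.
#' @param n_numeric,n_nominal attribute counts (at least one attribute in
#'   total).
#' @param categories_per_nominal categories per nominal attribute (>= 2).
#' @param class_separation non-negative; numeric class-mean offset in
#'   within-class standard deviations.
#' @param missing_rate MCAR cell-missingness probability, in \[0, 1).
#' @param seed integer seed.
#' @return A `mixed_data_spec` list.
#' @export
mixed_data_spec <- function(n_instances = 300,
                            class_proportions = c(0.7, 0.3),
                            n_numeric = 4, n_nominal = 3,
                            categories_per_nominal = 3,
                            class_separation = 2,
                            missing_rate = 0.05,
                            seed = 1) {
  if (n_instances < 2) stopf("need at least two instances")
  if (length(class_proportions) < 2) stopf("need at least two classes")
  if (any(class_proportions <= 0) || abs(sum(class_proportions) - 1) > 1e-8) {
    stopf("class_proportions must be positive and sum to 1")
  }
  if (n_numeric < 0 || n_nominal < 0 || n_numeric + n_nominal < 1) {
    stopf("need at least one predictive attribute")
  }
  if (categories_per_nominal < 2) stopf("nominal attributes need >= 2 categories")
  if (class_separation < 0) stopf("class_separation must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  structure(list(
    n_instances = as.integer(n_instances),
    class_proportions = class_proportions,
    n_numeric = as.integer(n_numeric), n_nominal = as.integer(n_nominal),
    categories_per_nominal = as.integer(categories_per_nominal),
    class_separation = class_separation,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "mixed_data_spec")
}

#' Generate a synthetic mixed, incomplete, imbalanced dataset
#'
#' Draws class labels from the specified proportions (every class is
#' guaranteed at least one instance), then attribute values from the
#' class-conditional model of [mixed_data_spec()], and finally applies
#' MCAR missingness via [inject_missing()].  Deterministic given the
#' spec's seed.
#'
#' @param spec a [mixed_data_spec()].
#' @return A [mixed_dataset()]; labels are never missing.
#' @export
generate_mixed <- function(spec) {
  k <- length(spec$class_proportions)
  classes <- paste0("class", seq_len(k))
  n <- spec$n_instances
  with_seed(derive_seed(spec$seed, 11L), {
    ci <- sample.int(k, n, replace = TRUE, prob = spec$class_proportions)
    missing_cls <- setdiff(seq_len(k), unique(ci))
    if (length(missing_cls) > 0) {
      # guarantee every class at least one instance
      slots <- sample.int(n, length(missing_cls))
      ci[slots] <- missing_cls
    }
    cols <- list()
    for (j in seq_len(spec$n_numeric)) {
      mu <- (ci - 1) * spec$class_separation
      cols[[sprintf("num%d", j)]] <- stats::rnorm(n, mean = mu, sd = 1)
    }
    q <- spec$categories_per_nominal
    lv <- paste0("c", seq_len(q))
    p_pref <- 1 / q + (1 - 1 / q) * (1 - exp(-spec$class_separation / 2))
    for (j in seq_len(spec$n_nominal)) {
      vals <- character(n)
      for (cls in seq_len(k)) {
        rows <- which(ci == cls)
        pref <- ((cls - 1L + j - 1L) %% q) + 1L
        probs <- rep((1 - p_pref) / (q - 1), q)
        probs[pref] <- p_pref
        vals[rows] <- lv[sample.int(q, length(rows), replace = TRUE, prob = probs)]
      }
      cols[[sprintf("nom%d", j)]] <- factor(vals, levels = lv)
    }
    d <- mixed_dataset(as.data.frame(cols, check.names = FALSE),
                       factor(classes[ci], levels = classes),
                       name = "synthetic")
    inject_missing(d, spec$missing_rate, derive_seed(spec$seed, 13L))
  })
}

#' Inject MCAR missingness into predictive attributes
#'
#' Each predictor cell is independently set missing with probability
#' `rate`; class labels are never touched and the input dataset is not
#' modified.
#'
#' @param dataset a [mixed_dataset()].
#' @param rate missingness probability, in \[0, 1).
#' @param seed integer seed.
#' @return A new [mixed_dataset()] with missing cells added.
#' @export
inject_missing <- function(dataset, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  if (rate == 0) return(dataset)
  out <- dataset
  with_seed(derive_seed(seed, 17L), {
    n <- n_instances(dataset)
    for (j in seq_len(n_attributes(dataset))) {
      hit <- stats::runif(n) < rate
      out$x[[j]][hit] <- NA
    }
  })
  out
}
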