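# Independent oracles used across the suite.  These deliberately share no
# code with the package: plain scalar loops and explicit rules.

# HEOM by definition: per-attribute distance, root-sum-of-squares.
brute_heom <- function(xrow, yrow, kinds, rmin, rmax) {
  total <- 0
  for (nm in names(kinds)) {
    a <- xrow[[nm]]; b <- yrow[[nm]]
    if (is.factor(a)) a <- as.character(a)
    if (is.factor(b)) b <- as.character(b)
    if (is.na(a) || is.na(b)) {
      d <- 1
    } else if (kinds[[nm]] == "nominal") {
      d <- if (a == b) 0 else 1
    } else {
      r <- rmax[[nm]] - rmin[[nm]]
      if (is.na(r) || r == 0) {
        d <- if (a == b) 0 else 1
      } else {
        d <- abs(a - b) / r
        if (d > 1) d <- 1
      }
    }
    total <- total + d * d
  }
  sqrt(total)
}

# 1-NN over a construction set: distances to every instance, first minimum.
brute_nn <- function(con, query, kinds, rmin, rmax) {
  dists <- vapply(seq_len(nrow(con$x)), function(i) {
    brute_heom(con$x[i, , drop = FALSE], query, kinds, rmin, rmax)
  }, numeric(1))
  best <- min(dists)
  winners <- which(dists == best)
  list(label = as.character(con$y[winners[1]]),
       dist = best,
       tied_classes = unique(as.character(con$y[winners])))
}

# Exact two-sided Wilcoxon signed-rank decision by enumeration of all 2^n
# sign assignments (requires distinct non-zero differences, so ranks are a
# permutation of 1..n).
exact_wilcoxon <- function(d, alpha = 0.05) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w <- min(sum(r[d > 0]), sum(r[d < 0]))
  maxs <- n * (n + 1) / 2
  cnt <- numeric(maxs + 1)
  cnt[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), cnt)[seq_len(maxs + 1)]
    cnt <- cnt + shifted
  }
  p <- min(1, 2 * sum(cnt[seq_len(w + 1)]) / 2^n)
  list(p = p, reject = p < alpha)
}

# A random generator specification exercising mixed kinds, missingness and
# 2-3 classes at small n.
random_spec <- function(seed) {
  set.seed(seed)
  k <- sample(2:3, 1)
  props <- runif(k, 0.5, 2)
  mixed_data_spec(
    n_instances = sample(25:60, 1),
    class_proportions = props / sum(props),
    n_numeric = sample(1:3, 1),
    n_nominal = sample(1:3, 1),
    categories_per_nominal = sample(2:4, 1),
    class_separation = runif(1, 0.5, 3),
    missing_rate = runif(1, 0, 0.3),
    seed = seed
  )
}
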