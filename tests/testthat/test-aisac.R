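# Helper: build an aisac_state by hand from explicit bags, so the movement
# pass can be exercised on a designed fixture.
manual_state <- function(con, val, bags, params = aisac_params(seed = 1)) {
  kinds <- attribute_kinds(con)
  ranges <- heom_ranges(con)
  protos <- do.call(rbind, lapply(bags, merge_bag, construction = con))
  proto_class <- vapply(bags, `[[`, character(1), "class")
  D <- aisacmmd:::heom_cross(val$x, protos, kinds, ranges)
  st <- structure(list(
    construction = con, validation = val, params = params,
    kinds = kinds, ranges = ranges,
    class_counts = table(factor(c(as.character(con$y), as.character(val$y)),
                                levels = levels(con$y))),
    bags = bags, prototypes = protos, proto_class = proto_class, D = D,
    val_groups = split(seq_len(n_instances(val)), val$y, drop = TRUE),
    val_y = as.character(val$y),
    fitness = NA_real_, history = numeric(0), step = 0L
  ), class = "aisac_state")
  st$fitness <- aisacmmd:::state_fitness(st)
  st$history <- st$fitness
  st
}

# Independent evaluation of a bag configuration for the 1-attribute
# fixtures below: merge by mean, nearest prototype, balanced accuracy.
eval_bags_1d <- function(con, val, bags) {
  protos <- vapply(bags, function(b) mean(con$x$v[b$members]), numeric(1))
  pcls <- vapply(bags, `[[`, character(1), "class")
  pred <- vapply(seq_len(n_instances(val)), function(i) {
    pcls[which.min(abs(val$x$v[i] - protos))]
  }, character(1))
  correct <- pred == as.character(val$y)
  mean(vapply(split(correct, val$y), mean, numeric(1)))
}

test_that("parameter validation rejects out-of-domain values", {
  expect_error(aisac_params(holdout_fraction = 1), "between 0 and 1")
  expect_error(aisac_params(bag_size = 0), "positive integer")
  expect_error(aisac_params(n_clones = 0), "positive integer")
  expect_error(aisac_params(mutation_rate = 0), "\\(0, 1\\]")
  expect_error(aisac_params(dissimilarity = "bogus"), "unknown dissimilarity")
  expect_silent(aisac_params(max_generations = 0))
})

test_that("bags are class-pure, cover the construction set, and respect the bag count rule", {
  params <- aisac_params(seed = 5, bag_size = 5)
  # a class with fewer instances than bag_size forms exactly one bag
  small <- mixed_dataset(data.frame(v = c(1, 2, 3)), c("a", "a", "a"))
  bags <- build_bags(small, params, heom_ranges(small))
  expect_length(bags, 1)
  expect_setequal(bags[[1]]$members, 1:3)

  # bag_size 1: every instance its own bag
  d1 <- generate_mixed(mixed_data_spec(n_instances = 20, seed = 8))
  b1 <- build_bags(d1, aisac_params(seed = 5, bag_size = 1), heom_ranges(d1))
  expect_length(b1, 20)
  expect_true(all(lengths(lapply(b1, `[[`, "members")) == 1))

  # general case: ceil(n_c / bag_size) bags per class, disjoint cover
  d <- generate_mixed(mixed_data_spec(n_instances = 57, seed = 9,
                                      class_proportions = c(0.6, 0.4)))
  bags <- build_bags(d, params, heom_ranges(d))
  all_members <- unlist(lapply(bags, `[[`, "members"))
  expect_setequal(all_members, seq_len(n_instances(d)))
  expect_identical(anyDuplicated(all_members), 0L)
  for (b in bags) {
    expect_true(all(as.character(d$y)[b$members] == b$class))
  }
  for (cls in dataset_classes(d)) {
    n_c <- sum(d$y == cls)
    expect_length(Filter(function(b) b$class == cls, bags),
                  max(1, ceiling(n_c / 5)))
  }
})

test_that("non-seed members join their HEOM-nearest seed (ties to the lowest seed index)", {
  d <- generate_mixed(mixed_data_spec(n_instances = 40, seed = 21, missing_rate = 0.1))
  params <- aisac_params(seed = 3, bag_size = 4)
  kinds <- attribute_kinds(d)
  ranges <- heom_ranges(d)
  bags <- build_bags(d, params, ranges)
  # the first stored member of each bag is its seed
  for (cls in dataset_classes(d)) {
    cls_bags <- Filter(function(b) b$class == cls, bags)
    seeds <- vapply(cls_bags, function(b) b$members[1], integer(1))
    for (k in seq_along(cls_bags)) {
      for (m in cls_bags[[k]]$members[-1]) {
        dmine <- heom(d$x[m, , drop = FALSE], d$x[seeds[k], , drop = FALSE],
                      kinds, ranges)
        dall <- vapply(seeds, function(s) {
          heom(d$x[m, , drop = FALSE], d$x[s, , drop = FALSE], kinds, ranges)
        }, numeric(1))
        expect_lte(dmine, min(dall) + 1e-12)
        # tie rule: no earlier seed achieves a strictly equal distance
        expect_identical(which(dall <= dmine + 1e-12)[1], k)
      }
    }
  }
})

test_that("merging a bag takes observed means and modes, earliest category on ties", {
  con <- mixed_dataset(
    data.frame(v = c(2, 4, NA),
               g = factor(c("b", "a", "a"), levels = c("a", "b", "z"))),
    c("x", "x", "x")
  )
  p <- merge_bag(list(class = "x", members = 1:3), con)
  expect_equal(p$v, 3)                         # mean of observed {2, 4}
  expect_identical(as.character(p$g), "a")     # strict mode
  # mode tie resolves to the category earliest in schema order
  con2 <- mixed_dataset(
    data.frame(g = factor(c("b", "a"), levels = c("z", "a", "b"))), c("x", "x"))
  p2 <- merge_bag(list(class = "x", members = 1:2), con2)
  expect_identical(as.character(p2$g), "a")
  # singleton bag: the prototype is the instance, missing cells included
  con3 <- mixed_dataset(data.frame(v = c(NA, 7), w = c(1, 2)), c("x", "x"))
  p3 <- merge_bag(list(class = "x", members = 1), con3)
  expect_true(is.na(p3$v))
  expect_equal(p3$w, 1)
  expect_error(merge_bag(list(class = "x", members = integer(0)), con3), "empty bag")
})

test_that("the movement pass repatriates a deliberately swapped instance", {
  con <- mixed_dataset(
    data.frame(v = c(0, 0.1, 0.2, 10, 10.1, 0.3, 5, 5.1, 5.2, 15, 15.1, 15.2)),
    rep(c("A", "B"), each = 6)
  )
  val <- mixed_dataset(data.frame(v = c(0.15, 10.0, 5.15, 6.9)),
                       c("A", "A", "B", "B"))
  val <- mixed_dataset(val$x, factor(as.character(val$y), levels = c("A", "B")))
  bags <- list(list(class = "A", members = c(1L, 2L, 3L)),
               list(class = "A", members = c(4L, 5L, 6L)),  # instance 6 swapped in
               list(class = "B", members = c(7L, 8L, 9L)),
               list(class = "B", members = c(10L, 11L, 12L)))
  st <- manual_state(con, val, bags)

  # oracle: exhaustively evaluate every candidate single-instance move
  base <- eval_bags_1d(con, val, bags)
  expect_equal(st$fitness, base)
  improving <- list()
  for (i in 1:12) {
    src <- which(vapply(bags, function(b) i %in% b$members, logical(1)))
    for (dst in setdiff(which(vapply(bags, `[[`, character(1), "class") ==
                                bags[[src]]$class), src)) {
      cand <- bags
      cand[[src]]$members <- setdiff(cand[[src]]$members, i)
      cand[[dst]]$members <- c(cand[[dst]]$members, i)
      cand <- Filter(function(b) length(b$members) > 0, cand)
      if (eval_bags_1d(con, val, cand) > base) {
        improving[[length(improving) + 1]] <- c(i, dst)
      }
    }
  }
  expect_identical(improving, list(c(6L, 1L)))  # only the swapped instance moves

  st2 <- movement_pass(st)
  expect_true(attr(st2, "accepted"))
  expect_gt(st2$fitness, st$fitness)
  expect_equal(st2$fitness, 1)
  expect_true(6L %in% st2$bags[[1]]$members)
  expect_false(6L %in% st2$bags[[2]]$members)
})

test_that("the movement pass is a no-op at perfect fitness or without a destination bag", {
  con <- mixed_dataset(data.frame(v = c(0, 0.2, 10, 10.2)), c("A", "A", "B", "B"))
  val <- mixed_dataset(data.frame(v = c(0.1, 10.1)), c("A", "B"))
  val <- mixed_dataset(val$x, factor(as.character(val$y), levels = c("A", "B")))
  bags <- list(list(class = "A", members = 1:2), list(class = "B", members = 3:4))
  st <- manual_state(con, val, bags)
  expect_equal(st$fitness, 1)
  st2 <- movement_pass(st)  # one bag per class: no candidate moves exist
  expect_false(attr(st2, "accepted"))
  expect_identical(st2$bags, st$bags)
  expect_identical(st2$prototypes, st$prototypes)
})

test_that("clonal selection is elitist: fitness never decreases, clones stay in range", {
  for (seed in 1:6) {
    d <- generate_mixed(random_spec(seed + 300))
    st <- aisac_init(d, aisac_params(seed = seed, bag_size = 4))
    f0 <- st$fitness
    st2 <- clonal_pass(st)
    expect_gte(st2$fitness, f0)
    expect_false(is.unsorted(st2$history))
    for (nm in names(st2$kinds)) {
      if (st2$kinds[[nm]] == "numeric") {
        vals <- st2$prototypes[[nm]]
        vals <- vals[!is.na(vals)]
        if (length(vals) && !is.na(st2$ranges$range[[nm]])) {
          expect_true(all(vals >= st2$ranges$min[[nm]] - 1e-12))
          expect_true(all(vals <= st2$ranges$max[[nm]] + 1e-12))
        }
      }
    }
    # missing prototype attributes stay missing through cloning
    expect_identical(is.na(st2$prototypes), is.na(st$prototypes))
  }
})

test_that("fitting is deterministic and never mutates the training data", {
  d <- generate_mixed(mixed_data_spec(n_instances = 80, seed = 14, missing_rate = 0.1))
  d_copy <- list(x = data.frame(d$x), y = d$y)
  params <- aisac_params(seed = 4, max_generations = 2)
  m1 <- aisac_fit(d, params)
  m2 <- aisac_fit(d, params)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_memory(m1, f1); write_memory(m2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical memory
  expect_identical(d$x, d_copy$x)
  expect_identical(d$y, d_copy$y)
  expect_error(aisac_fit(mixed_dataset(data.frame(v = 1:4), rep("a", 4)), params),
               "two classes")
})

test_that("the accepted-fitness history is non-decreasing and the frozen fitness re-evaluates", {
  d <- generate_mixed(mixed_data_spec(n_instances = 90, seed = 31,
                                      class_separation = 1.5, missing_rate = 0.1))
  mem <- aisac_fit(d, aisac_params(seed = 2, max_generations = 3))
  expect_false(is.unsorted(mem$history))
  expect_equal(mem$fitness, max(mem$history))
  expect_gte(mem$fitness, 0); expect_lte(mem$fitness, 1)
  # re-evaluate the stored prototypes on the stored validation partition
  pred <- classify(mem, mem$validation)
  ba <- balanced_accuracy(confusion_matrix(mem$validation$y, pred,
                                           classes = mem$classes))
  expect_equal(ba$value, mem$fitness)
  # every construction class is represented by at least one prototype
  expect_setequal(unique(mem$proto_class),
                  unique(as.character(mem$construction$y)))
})

test_that("well-separated classes are learned almost perfectly", {
  train <- generate_mixed(mixed_data_spec(n_instances = 300, class_separation = 3,
                                          class_proportions = c(0.5, 0.5),
                                          missing_rate = 0, seed = 77))
  test <- generate_mixed(mixed_data_spec(n_instances = 150, class_separation = 3,
                                         class_proportions = c(0.5, 0.5),
                                         missing_rate = 0, seed = 78))
  mem <- aisac_fit(train, aisac_params(seed = 7, max_generations = 3))
  pred <- classify(mem, test)
  ba <- balanced_accuracy(confusion_matrix(test$y, pred,
                                           classes = levels(test$y)))$value
  expect_gt(ba, 0.95)
})

test_that("classification returns the nearest prototype's class with the documented tie rules", {
  # majority class "a" (3 training instances) vs "b" (2)
  d <- mixed_dataset(data.frame(v = c(0, 0.5, 1, 10, 10.5)),
                     c("a", "a", "a", "b", "b"))
  mem <- aisac_fit(d, aisac_params(seed = 1, bag_size = 5, max_generations = 0,
                                   holdout_fraction = 0.6))
  # x near the "a" prototype
  expect_identical(as.character(classify(mem, data.frame(v = 2))), "a")
  # x equal to a stored prototype gets that prototype's class
  for (i in seq_len(nrow(mem$prototypes))) {
    expect_identical(as.character(classify(mem, mem$prototypes[i, , drop = FALSE])),
                     mem$proto_class[i])
  }
  # an all-missing instance ties with every prototype -> majority class
  expect_identical(as.character(classify(mem, data.frame(v = NA_real_))), "a")
  expect_error(classify(mem, data.frame(zzz = 1)), "schema")
})

test_that("memory persistence round-trips bit-exactly and restores behaviour", {
  d <- generate_mixed(mixed_data_spec(n_instances = 70, seed = 19, missing_rate = 0.15))
  mem <- aisac_fit(d, aisac_params(seed = 9, max_generations = 1))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_memory(mem, f1)
  mem2 <- read_memory(f1)
  write_memory(mem2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(mem2$proto_class, mem$proto_class)
  expect_identical(mem2$prototypes, mem$prototypes)
  expect_equal(mem2$ranges$range, mem$ranges$range)
  expect_identical(mem2$params, mem$params)
  q <- generate_mixed(mixed_data_spec(n_instances = 25, seed = 20, missing_rate = 0.2))
  expect_identical(classify(mem2, q), classify(mem, q))
})
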