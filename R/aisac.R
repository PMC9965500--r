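#' Parameters of the AISAC-MMD classifier
#'
#' All knobs of the immune-inspired prototype generator.  Defaults follow
#' the magnitudes customary for clonal-selection classifiers (mutation
#' factor 0.1, 10 generations); no automatic tuning is performed.
#'
#' @param holdout_fraction fraction of the training set used for prototype
#'   construction; the rest is the validation partition that drives fitness.
#' @param bag_size target number of instances per class-pure bag; per class
#'   `c`, `max(1, ceiling(n_c / bag_size))` bags are seeded.
#' @param max_generations upper bound on movement/cloning generations.
#' @param n_clones perturbed copies generated per prototype and generation.
#' @param mutation_rate numeric perturbation scale (standard deviation as a
#'   fraction of the attribute's training range) and per-attribute category
#'   resampling probability, in (0, 1].
#' @param patience generations without validation-fitness improvement before
#'   early stop.
#' @param seed integer seed; together with the data and parameters it fully
#'   determines the fitted memory.
#' @param dissimilarity name of a registered dissimilarity strategy.
#' @return An `aisac_params` list.
#' @export
aisac_params <- function(holdout_fraction = 0.7, bag_size = 5,
                         max_generations = 10, n_clones = 5,
                         mutation_rate = 0.1, patience = 3,
                         seed = 1, dissimilarity = "heom") {
  chk_pos_int <- function(v, what) {
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != floor(v)) {
      stopf("%s must be a positive integer", what)
    }
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stopf("holdout_fraction must lie strictly between 0 and 1")
  }
  chk_pos_int(bag_size, "bag_size")
  if (!is.numeric(max_generations) || max_generations < 0 ||
      max_generations != floor(max_generations)) {
    stopf("max_generations must be a non-negative integer")
  }
  chk_pos_int(n_clones, "n_clones")
  if (mutation_rate <= 0 || mutation_rate > 1) {
    stopf("mutation_rate must lie in (0, 1]")
  }
  chk_pos_int(patience, "patience")
  get_dissimilarity(dissimilarity)  # validates the name
  structure(list(
    holdout_fraction = holdout_fraction, bag_size = as.integer(bag_size),
    max_generations = as.integer(max_generations),
    n_clones = as.integer(n_clones), mutation_rate = mutation_rate,
    patience = as.integer(patience), seed = as.integer(seed),
    dissimilarity = dissimilarity
  ), class = "aisac_params")
}

# ---- Phase 1: class-pure bags ------------------------------------------

#' Build class-pure bags (Phase 1)
#'
#' For each class `c` with `n_c` construction instances,
#' `max(1, ceiling(n_c / bag_size))` seed instances are drawn without
#' replacement by the seeded generator; every remaining instance of the
#' class joins its nearest seed under the dissimilarity (ties go to the
#' lowest seed index).  Classes are processed in tie-break rank order
#' (larger class first, then level order), which fixes the prototype
#' ordering used for deterministic nearest-prototype ties.
#'
#' @param construction a [mixed_dataset()].
#' @param params an [aisac_params()].
#' @param ranges a [heom_ranges()] from the construction set.
#' @return A list of bags, each `list(class =, members =)` with members as
#'   row indices into `construction`.
#' @export
build_bags <- function(construction, params, ranges) {
  if (n_instances(construction) == 0) stopf("construction set is empty")
  kinds <- attribute_kinds(construction)
  disfn <- get_dissimilarity(params$dissimilarity)
  counts <- table(construction$y)
  class_order <- class_rank_order(construction$y)
  bags <- list()
  with_seed(derive_seed(params$seed, 2L), {
    for (cls in class_order) {
      idx <- which(as.character(construction$y) == cls)
      n_c <- length(idx)
      if (n_c == 0) next
      b_c <- max(1L, ceiling(n_c / params$bag_size))
      seeds <- idx[sample.int(n_c, b_c)]
      rest <- setdiff(idx, seeds)
      assign_to <- integer(0)
      if (length(rest) > 0) {
        D <- disfn(construction$x[rest, , drop = FALSE],
                   construction$x[seeds, , drop = FALSE], kinds, ranges)
        assign_to <- max.col(-D, ties.method = "first")
      }
      for (k in seq_along(seeds)) {
        members <- c(seeds[k], rest[assign_to == k])
        bags[[length(bags) + 1L]] <- list(class = cls, members = members)
      }
    }
  })
  bags
}

# Classes ordered by the nearest-prototype tie-break rank:
# larger training count first, then original level order.
class_rank_order <- function(y) {
  counts <- table(y)
  levels(y)[order(-as.integer(counts), seq_along(counts))]
}

# ---- Phase 2: merge bags into prototypes -------------------------------

#' Merge a bag into one prototype (Phase 2)
#'
#' Attribute-wise aggregate over the bag members' observed values: mean for
#' numeric attributes, mode for nominal ones (ties resolved toward the
#' category earliest in schema order).  An attribute observed in no member
#' stays missing in the prototype — the dissimilarity's missing rule then
#' handles it.  Original instances are never modified.
#'
#' @param bag a bag from [build_bags()].
#' @param construction the [mixed_dataset()] the member indices refer to.
#' @return A one-row data.frame with the construction schema.
#' @export
merge_bag <- function(bag, construction) {
  if (length(bag$members) == 0) stopf("cannot merge an empty bag")
  merge_members(construction$x, bag$members)
}

merge_members <- function(xdf, members) {
  out <- xdf[members[1], , drop = FALSE]
  rownames(out) <- NULL
  for (j in seq_along(xdf)) {
    col <- xdf[[j]][members]
    obs <- col[!is.na(col)]
    if (is.numeric(col)) {
      out[[j]] <- if (length(obs)) mean(obs) else NA_real_
    } else {
      if (length(obs)) {
        tab <- tabulate(as.integer(obs), nbins = nlevels(col))
        out[[j]] <- factor(levels(col)[which.max(tab)], levels = levels(col))
      } else {
        out[[j]] <- factor(NA_character_, levels = levels(col))
      }
    }
  }
  out
}

# ---- Fit state ----------------------------------------------------------

#' Initialize the immune response (hold-out split, Phases 1–2)
#'
#' Splits the training data into construction and validation partitions,
#' builds bags, merges them into the initial prototype set, and evaluates
#' the initial validation fitness (balanced accuracy of the
#' 1-nearest-prototype classifier).  The returned state is the input to
#' [movement_pass()] and [clonal_pass()].
#'
#' @param training a [mixed_dataset()] with at least two classes.
#' @param params an [aisac_params()].
#' @return An `aisac_state` list.
#' @export
aisac_init <- function(training, params = aisac_params()) {
  if (nlevels(training$y) < 2) stopf("training data must contain at least two classes")
  split <- stratified_holdout(training, params$holdout_fraction,
                              derive_seed(params$seed, 1L))
  con <- split$construction
  val <- split$validation
  kinds <- attribute_kinds(con)
  ranges <- heom_ranges(con)
  bags <- build_bags(con, params, ranges)
  protos <- do.call(rbind, lapply(bags, merge_bag, construction = con))
  proto_class <- vapply(bags, `[[`, character(1), "class")
  disfn <- get_dissimilarity(params$dissimilarity)
  D <- if (n_instances(val) > 0) disfn(val$x, protos, kinds, ranges) else
    matrix(0, 0, nrow(protos))
  state <- structure(list(
    construction = con, validation = val, params = params,
    kinds = kinds, ranges = ranges,
    class_counts = table(training$y),
    bags = bags, prototypes = protos, proto_class = proto_class,
    D = D,
    val_groups = split(seq_len(n_instances(val)), val$y, drop = TRUE),
    val_y = as.character(val$y),
    fitness = NA_real_, history = numeric(0), step = 0L
  ), class = "aisac_state")
  state$fitness <- state_fitness(state)
  state$history <- state$fitness
  state
}

# Balanced accuracy of the nearest-prototype classifier on the validation
# partition, given the cached distance matrix.  Prototype columns are in
# class rank order, so ties.method = "first" realizes the class tie rule.
state_fitness <- function(state, D = state$D, proto_class = state$proto_class) {
  if (nrow(D) == 0) return(NA_real_)
  pred <- proto_class[max.col(-D, ties.method = "first")]
  correct <- pred == state$val_y
  mean(vapply(state$val_groups, function(ix) mean(correct[ix]), numeric(1)))
}

# ---- Phase 3: instance movement ----------------------------------------

#' Instance movement pass (Phase 3)
#'
#' Visits the construction instances in seeded random order; for each,
#' evaluates reassigning it to every other bag of its own class (re-merging
#' only the two affected prototypes) and accepts the single best move if it
#' strictly increases validation balanced accuracy.  A bag left empty by a
#' move is dropped.
#'
#' @param state an `aisac_state` from [aisac_init()].
#' @return The updated state; `attr(, "accepted")` reports whether any move
#'   was accepted during the pass.
#' @export
movement_pass <- function(state) {
  state$step <- state$step + 1L
  disfn <- get_dissimilarity(state$params$dissimilarity)
  con <- state$construction
  accepted_any <- FALSE
  if (nrow(state$D) == 0) {
    attr(state, "accepted") <- FALSE
    return(state)
  }
  order_idx <- with_seed(derive_seed(state$params$seed, 100L + state$step),
                         sample.int(n_instances(con)))
  for (i in order_idx) {
    src <- which(vapply(state$bags, function(b) i %in% b$members, logical(1)))
    cls <- state$bags[[src]]$class
    dests <- setdiff(which(state$proto_class == cls), src)
    if (length(dests) == 0) next
    src_rest <- setdiff(state$bags[[src]]$members, i)
    src_proto <- if (length(src_rest)) merge_members(con$x, src_rest) else NULL
    src_col <- if (length(src_rest)) {
      disfn(state$validation$x, src_proto, state$kinds, state$ranges)
    } else NULL
    best <- list(fit = state$fitness, dest = NA_integer_)
    for (d in dests) {
      dest_members <- c(state$bags[[d]]$members, i)
      dest_proto <- merge_members(con$x, dest_members)
      dest_col <- disfn(state$validation$x, dest_proto, state$kinds, state$ranges)
      Dc <- state$D
      Dc[, d] <- dest_col
      if (is.null(src_col)) {
        keep <- setdiff(seq_len(ncol(Dc)), src)
        f <- state_fitness(state, Dc[, keep, drop = FALSE], state$proto_class[keep])
      } else {
        Dc[, src] <- src_col
        f <- state_fitness(state, Dc)
      }
      if (f > best$fit) best <- list(fit = f, dest = d, proto = dest_proto, col = dest_col)
    }
    if (!is.na(best$dest)) {
      d <- best$dest
      state$bags[[d]]$members <- c(state$bags[[d]]$members, i)
      state$prototypes[d, ] <- best$proto
      state$D[, d] <- best$col
      if (length(src_rest)) {
        state$bags[[src]]$members <- src_rest
        state$prototypes[src, ] <- src_proto
        state$D[, src] <- src_col
      } else {
        keep <- setdiff(seq_along(state$bags), src)
        state$bags <- state$bags[keep]
        state$prototypes <- state$prototypes[keep, , drop = FALSE]
        state$proto_class <- state$proto_class[keep]
        state$D <- state$D[, keep, drop = FALSE]
      }
      state$fitness <- best$fit
      state$history <- c(state$history, state$fitness)
      accepted_any <- TRUE
    }
  }
  attr(state, "accepted") <- accepted_any
  state
}

# ---- Phase 4: clonal selection -----------------------------------------

#' Clonal selection pass (Phase 4)
#'
#' For each prototype, generates `n_clones` perturbed copies: numeric
#' attributes receive Gaussian noise with standard deviation
#' `mutation_rate * range`, clipped to the training min/max; nominal
#' attributes are replaced, with probability `mutation_rate`, by a uniformly
#' drawn category; missing attributes remain missing.  The prototype is
#' replaced by its best clone only if validation balanced accuracy strictly
#' improves (elitist acceptance).
#'
#' @param state an `aisac_state`.
#' @return The updated state; `attr(, "accepted")` reports whether any clone
#'   was accepted.
#' @export
clonal_pass <- function(state) {
  state$step <- state$step + 1L
  disfn <- get_dissimilarity(state$params$dissimilarity)
  params <- state$params
  accepted_any <- FALSE
  if (nrow(state$D) == 0) {
    attr(state, "accepted") <- FALSE
    return(state)
  }
  with_seed(derive_seed(params$seed, 5000L + state$step), {
    for (p in seq_along(state$proto_class)) {
      best <- list(fit = state$fitness)
      for (k in seq_len(params$n_clones)) {
        clone <- mutate_prototype(state$prototypes[p, , drop = FALSE],
                                  state$kinds, state$ranges, params$mutation_rate)
        col <- disfn(state$validation$x, clone, state$kinds, state$ranges)
        Dc <- state$D
        Dc[, p] <- col
        f <- state_fitness(state, Dc)
        if (f > best$fit) best <- list(fit = f, proto = clone, col = col)
      }
      if (!is.null(best$proto)) {
        state$prototypes[p, ] <- best$proto
        state$D[, p] <- best$col
        state$fitness <- best$fit
        state$history <- c(state$history, state$fitness)
        accepted_any <- TRUE
      }
    }
  })
  attr(state, "accepted") <- accepted_any
  state
}

mutate_prototype <- function(proto, kinds, ranges, mutation_rate) {
  clone <- proto
  for (nm in names(kinds)) {
    v <- clone[[nm]]
    if (is.na(v)) next
    if (kinds[[nm]] == "numeric") {
      r <- ranges$range[[nm]]
      if (is.na(r)) next
      newv <- v + stats::rnorm(1, 0, mutation_rate * r)
      clone[[nm]] <- min(max(newv, ranges$min[[nm]]), ranges$max[[nm]])
    } else {
      if (stats::runif(1) < mutation_rate) {
        lv <- levels(proto[[nm]])
        clone[[nm]] <- factor(lv[sample.int(length(lv), 1)], levels = lv)
      }
    }
  }
  clone
}

# ---- Fit / classify -----------------------------------------------------

#' Fit the AISAC-MMD classifier
#'
#' Runs the full adaptive immune response: stratified hold-out split,
#' bag construction (Phase 1), bag merging into initial prototypes
#' (Phase 2), then alternating instance-movement (Phase 3) and clonal
#' selection (Phase 4) passes for up to `max_generations`, stopping early
#' after `patience` generations without validation-fitness improvement.
#' Both passes only accept strictly improving states, so the sequence of
#' accepted fitness values is non-decreasing and the final state is the
#' best seen.  The training data are never modified.
#'
#' @param training a [mixed_dataset()] with `>= 2` classes.
#' @param params an [aisac_params()].
#' @return An `aisac_mmd` immune memory: the prototype set, the training
#'   ranges and schema, the class tie-break counts, the parameters, the
#'   validation fitness at freeze time and the accepted-fitness history.
#' @examples
#' d <- generate_mixed(mixed_data_spec(n_instances = 60, class_separation = 3,
#'                                     seed = 7))
#' mem <- aisac_fit(d, aisac_params(seed = 7, max_generations = 2))
#' table(predict(mem, d), d$y)
#' @export
aisac_fit <- function(training, params = aisac_params()) {
  state <- aisac_init(training, params)
  if (params$max_generations > 0 && nrow(state$D) > 0) {
    stall <- 0L
    for (g in seq_len(params$max_generations)) {
      f0 <- state$fitness
      state <- movement_pass(state)
      state <- clonal_pass(state)
      if (state$fitness > f0) stall <- 0L else stall <- stall + 1L
      if (stall >= params$patience) break
    }
  }
  structure(list(
    prototypes = state$prototypes,
    proto_class = state$proto_class,
    ranges = state$ranges,
    kinds = state$kinds,
    classes = levels(training$y),
    class_counts = stats::setNames(as.integer(state$class_counts),
                                   names(state$class_counts)),
    params = state$params,
    fitness = state$fitness,
    history = state$history,
    validation = state$validation,
    construction = state$construction
  ), class = "aisac_mmd")
}

#' @export
print.aisac_mmd <- function(x, ...) {
  cat(sprintf("<aisac_mmd: %d prototypes over %d classes, validation fitness %.3f>\n",
              nrow(x$prototypes), length(x$classes), x$fitness))
  invisible(x)
}

#' Classify instances with a fitted immune memory
#'
#' Returns the class of the nearest prototype under the memory's
#' dissimilarity.  Distance ties are broken toward the class with the
#' larger training count, then the lower class index; an all-missing
#' instance is therefore assigned the majority class.
#'
#' @param memory an `aisac_mmd` from [aisac_fit()].
#' @param x instances: a one-row data.frame, a data.frame of rows, or a
#'   [mixed_dataset()].
#' @return A factor of predicted class labels with the memory's class levels.
#' @export
classify <- function(memory, x) {
  X <- if (inherits(x, "mixed_dataset")) x$x else as.data.frame(x)
  if (!all(names(memory$kinds) %in% names(X))) {
    stopf("instances do not conform to the memory schema")
  }
  disfn <- get_dissimilarity(memory$params$dissimilarity)
  X <- conform_columns(X, memory)
  D <- disfn(X, memory$prototypes, memory$kinds, memory$ranges)
  # class tie-break rank per prototype: larger training count, then lower
  # class index
  proto_rank <- order(order(-memory$class_counts[memory$proto_class],
                            match(memory$proto_class, memory$classes)))
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    di <- D[i, ]
    cand <- which(di == min(di))
    pred[i] <- memory$proto_class[cand[which.min(proto_rank[cand])]]
  }
  factor(pred, levels = memory$classes)
}

# Coerce incoming columns to the training schema (factor levels aligned;
# unseen categories become missing).
conform_columns <- function(X, memory) {
  out <- X[, names(memory$kinds), drop = FALSE]
  for (nm in names(memory$kinds)) {
    if (memory$kinds[[nm]] == "numeric") {
      out[[nm]] <- as.double(out[[nm]])
    } else {
      lv <- levels(memory$prototypes[[nm]])
      out[[nm]] <- factor(as.character(out[[nm]]), levels = lv)
    }
  }
  out
}

#' @rdname classify
#' @param object,newdata,... standard predict-method arguments; `newdata`
#'   defaults to the memory's construction partition.
#' @export
predict.aisac_mmd <- function(object, newdata = object$construction, ...) {
  classify(object, newdata)
}

# ---- Persistence --------------------------------------------------------

#' Save / load an immune memory as JSON
#'
#' The model file is a documented JSON text format holding the schema
#' (attribute names, kinds, category orders), class list and tie-break
#' counts, training ranges, all parameters (seed included), the frozen
#' validation fitness and every prototype with explicit missing markers
#' (JSON `null`).  Numeric values are written with 17 significant digits so
#' write/read/write round-trips are byte-identical.
#'
#' @param memory an `aisac_mmd`.
#' @param path file path.
#' @return `write_memory` returns `path` invisibly; `read_memory` returns
#'   the restored `aisac_mmd` (without the construction/validation
#'   partitions, which are not part of the persisted model).
#' @export
write_memory <- function(memory, path) {
  schema <- lapply(names(memory$kinds), function(nm) {
    s <- list(name = nm, kind = memory$kinds[[nm]])
    if (s$kind == "nominal") s$categories <- levels(memory$prototypes[[nm]])
    s
  })
  protos <- lapply(seq_len(nrow(memory$prototypes)), function(i) {
    vals <- lapply(memory$prototypes[i, , drop = FALSE], function(v) {
      v <- if (is.factor(v)) as.character(v) else v
      if (is.na(v)) NULL else v
    })
    list(class = memory$proto_class[i], values = vals)
  })
  doc <- list(
    format = "aisac-mmd-memory",
    version = 1L,
    schema = schema,
    classes = memory$classes,
    class_counts = as.list(memory$class_counts),
    ranges = list(min = as.list(memory$ranges$min),
                  max = as.list(memory$ranges$max),
                  observed = as.list(memory$ranges$observed)),
    params = unclass(memory$params),
    fitness = memory$fitness,
    history = memory$history,
    prototypes = protos
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_memory
#' @export
read_memory <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "aisac-mmd-memory")) {
    stopf("'%s' is not an AISAC-MMD memory file", path)
  }
  kinds <- stats::setNames(
    vapply(doc$schema, `[[`, character(1), "kind"),
    vapply(doc$schema, `[[`, character(1), "name"))
  cols <- stats::setNames(vector("list", length(doc$schema)), names(kinds))
  for (s in doc$schema) {
    vals <- lapply(doc$prototypes, function(p) p$values[[s$name]])
    vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
    if (s$kind == "numeric") {
      cols[[s$name]] <- as.double(unlist(vals))
    } else {
      cols[[s$name]] <- factor(unlist(lapply(vals, as.character)),
                               levels = unlist(s$categories))
    }
  }
  protos <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  num <- names(kinds)[kinds == "numeric"]
  as_named <- function(x, nms) stats::setNames(as.double(unlist(x) %||% numeric(0)), nms)
  mn <- as_named(doc$ranges$min[num], num)
  mx <- as_named(doc$ranges$max[num], num)
  ranges <- structure(list(
    min = mn, max = mx, range = mx - mn,
    observed = stats::setNames(as.integer(unlist(doc$ranges$observed)),
                               names(doc$ranges$observed))
  ), class = "heom_ranges")
  params <- do.call(aisac_params, doc$params)
  structure(list(
    prototypes = protos,
    proto_class = vapply(doc$prototypes, `[[`, character(1), "class"),
    ranges = ranges,
    kinds = kinds,
    classes = unlist(doc$classes),
    class_counts = stats::setNames(as.integer(unlist(doc$class_counts)),
                                   names(doc$class_counts)),
    params = params,
    fitness = if (is.null(doc$fitness)) NA_real_ else as.double(doc$fitness),
    history = as.double(unlist(doc$history) %||% numeric(0)),
    validation = NULL,
    construction = NULL
  ), class = "aisac_mmd")
}
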