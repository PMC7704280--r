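#' Fit a sequential decision-tree synthesizer
#'
#' Fits the classic sequential tree synthesis scheme: variables are
#' ordered in a sequence; the first is modelled by its empirical
#' marginal; each later variable is modelled by a decision tree on all
#' variables earlier in the sequence (classification trees for
#' nominal/binary targets, regression-style partitions for continuous
#' targets). Generation then walks the same sequence, routing each
#' partially synthesized record down the fitted tree and sampling a
#' training value from the predicted terminal node, so synthetic
#' values are always values observed in the training data.
#'
#' Trees are grown by binary recursive partitioning
#' (deviance-reduction splitting via the \pkg{tree} package) with a
#' minimum terminal node size and a minimum deviance fraction as
#' stopping rules; other tree algorithms fit the same contract.
#'
#' @param real an [sdc_dataset()] or data.frame of training records.
#' @param sequence character vector: the synthesis order; defaults to
#'   column order. Variables outside `sequence` are not modelled.
#' @param min_leaf minimum number of training records per terminal
#'   node. Larger values coarsen the partition and reduce the
#'   disclosure risk of the output (less overfitting); default 5.
#' @param mindev minimum within-node deviance, as a fraction of the
#'   root deviance, for a split to be attempted; default 0.001.
#' @return an object of class `sequential_generator`.
#' @seealso [synth_generate()]
#' @export
synth_fit <- function(real, sequence = NULL, min_leaf = 5, mindev = 0.001) {
  records <- if (inherits(real, "sdc_dataset")) real$records else real
  meta <- if (inherits(real, "sdc_dataset")) real$meta else NULL
  stopifnot(is.data.frame(records), nrow(records) >= 1, min_leaf >= 1)
  if (is.null(sequence)) sequence <- names(records)
  if (!all(sequence %in% names(records)) || anyDuplicated(sequence)) {
    stop("`sequence` must be distinct column names of the training data", call. = FALSE)
  }
  if (nrow(records) < min_leaf) stop("fewer training records than `min_leaf`", call. = FALSE)

  df <- records[, sequence, drop = FALSE]
  factor_levels <- list()
  for (nm in sequence) {
    if (!is.numeric(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
      factor_levels[[nm]] <- levels(df[[nm]])
    }
  }

  n <- nrow(df)
  models <- vector("list", length(sequence))
  names(models) <- sequence
  for (i in seq_along(sequence)) {
    if (i == 1) next
    target <- sequence[i]
    preds <- sequence[seq_len(i - 1)]
    fml <- stats::as.formula(paste(backtick(target), "~",
                                   paste(backtick(preds), collapse = " + ")))
    ctl <- tree::tree.control(nobs = n, mincut = min_leaf,
                              minsize = max(2 * min_leaf, 2), mindev = mindev)
    fit <- tryCatch(
      tree::tree(fml, data = df, control = ctl),
      error = function(e) NULL)
    if (is.null(fit) || inherits(fit, "singlenode")) {
      # constant target or no admissible split: root node holds everything
      models[[target]] <- list(tree = NULL, node_values = list(df[[target]]))
    } else {
      where <- fit$where
      vals <- split(df[[target]], where)
      models[[target]] <- list(tree = fit, node_values = vals)
    }
  }

  structure(list(
    sequence = sequence,
    first_marginal = df[[sequence[1]]],
    models = models,
    factor_levels = factor_levels,
    meta = meta,
    fit_params = list(min_leaf = min_leaf, mindev = mindev),
    n_train = n
  ), class = "sequential_generator")
}

backtick <- function(x) paste0("`", x, "`")

#' @export
print.sequential_generator <- function(x, ...) {
  cat(sprintf("<sequential_generator> %d variables, %d training records\n",
              length(x$sequence), x$n_train))
  cat("  sequence:", paste(x$sequence, collapse = " -> "), "\n")
  sizes <- vapply(x$models, function(m)
    if (is.null(m)) NA_integer_ else length(m$node_values), integer(1))
  cat("  terminal nodes per model:",
      paste(sprintf("%s=%s", names(sizes)[-1], sizes[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' Generate fully synthetic records from a fitted sequential generator
#'
#' Samples the first variable from its empirical marginal, then walks
#' the sequence: each partial synthetic record is routed down the
#' fitted tree for the next variable and a value is drawn uniformly
#' with replacement from the training values in its terminal node.
#' Because values are resampled training values, synthetic categories
#' are always a subset of the real ones. A predictor combination
#' involving a category unseen when the tree was fitted is routed via
#' the training-modal category (documented fallback; it cannot arise
#' when the generator's own output is the only predictor source).
#'
#' @param gen a [synth_fit()] result.
#' @param m number of synthetic records to generate.
#' @param seed integer seed; the same seed reproduces the output
#'   bit-exactly.
#' @return an [sdc_dataset()] labelled `synthetic_sample` when the
#'   generator was fitted on one (a plain data.frame otherwise).
#' @examples
#' d <- data.frame(a = rep(c("x", "y"), 10), b = rep(c(1, 2), 10))
#' g <- synth_fit(d, min_leaf = 1)
#' synth_generate(g, 5, seed = 1)
#' @export
synth_generate <- function(gen, m, seed = NULL) {
  stopifnot(inherits(gen, "sequential_generator"), m >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)

  out <- vector("list", length(gen$sequence))
  names(out) <- gen$sequence
  out[[gen$sequence[1]]] <- resample(gen$first_marginal, m)

  for (i in seq_along(gen$sequence)[-1]) {
    target <- gen$sequence[i]
    model <- gen$models[[target]]
    if (is.null(model$tree)) {
      out[[target]] <- resample(model$node_values[[1]], m)
      next
    }
    nd <- as.data.frame(out[seq_len(i - 1)], stringsAsFactors = FALSE,
                        optional = TRUE)
    for (p in names(nd)) {
      lv <- gen$factor_levels[[p]]
      if (!is.null(lv)) {
        v <- as.character(nd[[p]])
        unseen <- !(v %in% lv) & !is.na(v)
        if (any(unseen)) v[unseen] <- modal_value(gen$first_marginal, lv, gen, p)
        nd[[p]] <- factor(v, levels = lv)
      }
    }
    where <- predict(model$tree, nd, type = "where")
    vals <- model$node_values
    drawn <- vector(mode = mode(vals[[1]]), length = m)
    if (is.factor(vals[[1]])) drawn <- factor(rep(NA, m), levels = levels(vals[[1]]))
    for (w in unique(where)) {
      rows <- which(where == w)
      pool <- vals[[as.character(w)]]
      drawn[rows] <- resample(pool, length(rows))
    }
    out[[target]] <- drawn
  }

  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  if (!is.null(gen$meta)) {
    meta <- gen$meta[intersect(names(gen$meta), names(df))]
    return(sdc_dataset(df, meta, label = "synthetic_sample"))
  }
  df
}

resample <- function(pool, m) {
  pool[sample.int(length(pool), m, replace = TRUE)]
}

modal_value <- function(marginal, lv, gen, p) {
  # most frequent training category of predictor p
  counts <- table(factor(as.character(gen_training_column(gen, p)), levels = lv))
  names(counts)[which.max(counts)]
}

gen_training_column <- function(gen, p) {
  if (p == gen$sequence[1]) return(gen$first_marginal)
  unlist(gen$models[[p]]$node_values, use.names = FALSE)
}
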