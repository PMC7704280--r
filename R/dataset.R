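#' Declare a variable's role in a disclosure risk assessment
#'
#' Every column of a dataset is either a quasi-identifier (knowable to
#' an adversary and used for matching, e.g. age, ZIP code, sex),
#' a sensitive variable (the information whose disclosure causes harm
#' and the object of the learn-something-new test), or ignored.
#' Quasi-identifiers may carry a generalization hierarchy: an ordered
#' list of coarsenings (level 0 is always the raw values) used when
#' enumerating attack modalities; see [hierarchy_level()].
#'
#' @param name column name.
#' @param role one of `"quasi_identifier"`, `"sensitive"`, `"ignored"`.
#' @param kind one of `"nominal"`, `"binary"`, `"continuous"`. Binary
#'   variables are treated identically to nominal throughout.
#' @param hierarchy optional list of [hierarchy_level()] specifications,
#'   ordered from finest (level 1) to coarsest. Only allowed on
#'   quasi-identifiers.
#' @return an object of class `variable_spec`.
#' @examples
#' variable_spec("origin", "quasi_identifier", "nominal")
#' variable_spec("age", "quasi_identifier", "continuous",
#'               hierarchy = list(hierarchy_level("bin", breaks = seq(0, 120, 10)),
#'                                hierarchy_level("suppress")))
#' @export
variable_spec <- function(name,
                          role = c("quasi_identifier", "sensitive", "ignored"),
                          kind = c("nominal", "binary", "continuous"),
                          hierarchy = NULL) {
  role <- match.arg(role)
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.null(hierarchy)) {
    if (role != "quasi_identifier") {
      stop(sprintf("variable '%s': hierarchies are only allowed on quasi-identifiers", name),
           call. = FALSE)
    }
    if (!is.list(hierarchy) || length(hierarchy) == 0) {
      stop("`hierarchy` must be a non-empty list of hierarchy_level() specs", call. = FALSE)
    }
    hierarchy <- lapply(hierarchy, as_hierarchy_level)
  }
  structure(list(name = name, role = role, kind = kind, hierarchy = hierarchy),
            class = "variable_spec")
}

#' Generalization hierarchy level
#'
#' One coarsening step for a quasi-identifier. Supported types:
#' * `"bin"`: cut numeric values into intervals (`breaks`, optional
#'   `labels`); intervals are left-closed (`[a, b)`).
#' * `"prefix"`: keep the first `keep` characters, masking the rest
#'   with `*` (ZIP 98101 with `keep = 3` becomes `981**`).
#' * `"map"`: explicit recoding via a named character vector
#'   (`mapping[old] = new`); values absent from the mapping error.
#' * `"suppress"`: all values collapse to `"*"`.
#'
#' Each level is defined on the raw (level 0) values. Levels must
#' strictly coarsen: two raw values mapped together at level i must
#' also map together at level i + 1 (checked against observed data by
#' [validate_datasets()]).
#'
#' @param type level type, see above.
#' @param breaks,labels for `"bin"`.
#' @param keep for `"prefix"`.
#' @param mapping for `"map"`.
#' @return an object of class `hierarchy_level`.
#' @export
hierarchy_level <- function(type = c("bin", "prefix", "map", "suppress"),
                            breaks = NULL, labels = NULL, keep = NULL,
                            mapping = NULL) {
  type <- match.arg(type)
  spec <- switch(type,
    bin = {
      stopifnot(is.numeric(breaks), length(breaks) >= 2)
      list(type = "bin", breaks = sort(breaks), labels = labels)
    },
    prefix = {
      stopifnot(is.numeric(keep), length(keep) == 1, keep >= 1)
      list(type = "prefix", keep = as.integer(keep))
    },
    map = {
      if (is.null(names(mapping)) || !is.character(mapping)) {
        stop("`mapping` must be a named character vector", call. = FALSE)
      }
      list(type = "map", mapping = mapping)
    },
    suppress = list(type = "suppress")
  )
  structure(spec, class = "hierarchy_level")
}

as_hierarchy_level <- function(x) {
  if (inherits(x, "hierarchy_level")) return(x)
  if (is.list(x) && !is.null(x$type)) {
    return(hierarchy_level(x$type, breaks = x$breaks, labels = x$labels,
                           keep = x$keep, mapping = unlist_mapping(x$mapping)))
  }
  stop("cannot interpret hierarchy level specification", call. = FALSE)
}

unlist_mapping <- function(m) {
  if (is.null(m) || is.character(m)) return(m)
  out <- vapply(m, as.character, character(1))
  out
}

# apply one hierarchy level to raw values; returns character
apply_hierarchy_level <- function(values, level) {
  switch(level$type,
    bin = {
      v <- suppressWarnings(as.numeric(values))
      lab <- if (is.null(level$labels)) {
        br <- level$breaks
        sprintf("[%g,%g)", br[-length(br)], br[-1])
      } else level$labels
      out <- as.character(cut(v, breaks = level$breaks, labels = lab,
                              right = FALSE, include.lowest = TRUE))
      out[is.na(v)] <- NA_character_
      out
    },
    prefix = {
      v <- as.character(values)
      keep <- level$keep
      out <- vapply(v, function(s) {
        if (is.na(s)) return(NA_character_)
        if (nchar(s) <= keep) return(s)
        paste0(substr(s, 1, keep), strrep("*", nchar(s) - keep))
      }, character(1), USE.NAMES = FALSE)
      out
    },
    map = {
      v <- as.character(values)
      unseen <- setdiff(unique(v[!is.na(v)]), names(level$mapping))
      if (length(unseen)) {
        stop(sprintf("hierarchy mapping has no entry for value(s): %s",
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
      out <- unname(level$mapping[v])
      out[is.na(v)] <- NA_character_
      out
    },
    suppress = {
      out <- rep("*", length(values))
      out[is.na(values)] <- NA_character_
      out
    }
  )
}

#' Built-in generalization hierarchies for common health quasi-identifiers
#'
#' Convenience constructors for typical attack-search lattices:
#' `"age"` gives 5-year bands, 10-year bands, then suppression;
#' `"year_month"` coarsens ISO dates (`YYYY-MM-DD`) to month then year;
#' `"zip"` masks to a 3-character then 1-character prefix;
#' `"suppress"` is suppression only (for sex, region and similar
#' low-cardinality variables).
#'
#' @param type one of `"age"`, `"year_month"`, `"zip"`, `"suppress"`.
#' @param max_age upper bound used for the age bands.
#' @return list of [hierarchy_level()] objects.
#' @export
default_hierarchy <- function(type = c("age", "year_month", "zip", "suppress"),
                              max_age = 125) {
  type <- match.arg(type)
  switch(type,
    age = list(
      hierarchy_level("bin", breaks = seq(0, ceiling(max_age / 5) * 5, 5)),
      hierarchy_level("bin", breaks = seq(0, ceiling(max_age / 10) * 10, 10)),
      hierarchy_level("suppress")
    ),
    year_month = list(
      hierarchy_level("prefix", keep = 7),  # YYYY-MM
      hierarchy_level("prefix", keep = 4),  # YYYY
      hierarchy_level("suppress")
    ),
    zip = list(
      hierarchy_level("prefix", keep = 3),
      hierarchy_level("prefix", keep = 1),
      hierarchy_level("suppress")
    ),
    suppress = list(hierarchy_level("suppress"))
  )
}

#' Assemble a dataset for disclosure risk assessment
#'
#' Couples a rectangular table of records with per-variable metadata
#' and a label saying which role the table plays: the real sample, the
#' synthetic sample, or the population. Continuous columns are coerced
#' to numeric (an unparseable cell is an error naming the row);
#' nominal/binary columns are kept as character tokens. Columns present
#' in `records` but absent from `meta` are carried along with role
#' `"ignored"`.
#'
#' @param records a data.frame of records (rows are individuals).
#' @param meta list of [variable_spec()] objects.
#' @param label one of `"real_sample"`, `"synthetic_sample"`,
#'   `"population"`.
#' @return an object of class `sdc_dataset` with elements `records`,
#'   `meta`, `label`.
#' @seealso [read_dataset()], [write_dataset()], [validate_datasets()]
#' @export
sdc_dataset <- function(records, meta,
                        label = c("real_sample", "synthetic_sample", "population")) {
  label <- match.arg(label)
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("dataset has no records", call. = FALSE)
  if (anyDuplicated(names(records))) stop("duplicate column names in records", call. = FALSE)

  meta <- lapply(meta, function(m) {
    if (!inherits(m, "variable_spec")) stop("`meta` must be a list of variable_spec objects",
                                            call. = FALSE)
    m
  })
  meta_names <- vapply(meta, `[[`, character(1), "name")
  if (anyDuplicated(meta_names)) stop("duplicate variable names in metadata", call. = FALSE)
  missing_cols <- setdiff(meta_names, names(records))
  if (length(missing_cols)) {
    stop(sprintf("declared column(s) missing from data: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(records), meta_names)
  for (nm in extra) {
    kind <- if (is.numeric(records[[nm]])) "continuous" else "nominal"
    meta <- c(meta, list(variable_spec(nm, role = "ignored", kind = kind)))
  }
  meta_names <- vapply(meta, `[[`, character(1), "name")
  names(meta) <- meta_names

  for (m in meta) {
    col <- records[[m$name]]
    if (m$kind == "continuous") {
      if (!is.numeric(col)) {
        raw <- as.character(col)
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(!is.na(raw) & nzchar(raw) & is.na(num))
        if (length(bad)) {
          stop(sprintf("column '%s': unparseable continuous value '%s' at row %d",
                       m$name, raw[bad[1]], bad[1]), call. = FALSE)
        }
        num[!is.na(raw) & !nzchar(raw)] <- NA_real_
        records[[m$name]] <- num
      }
    } else {
      v <- as.character(col)
      v[!is.na(v) & !nzchar(v)] <- NA_character_
      records[[m$name]] <- v
    }
  }
  # keep column order stable: declared order first, then extras
  records <- records[, c(intersect(meta_names, names(records))), drop = FALSE]

  structure(list(records = records, meta = meta, label = label),
            class = "sdc_dataset")
}

#' @export
print.sdc_dataset <- function(x, ...) {
  cat(sprintf("<sdc_dataset: %s>  %d records x %d variables\n",
              x$label, nrow(x$records), ncol(x$records)))
  roles <- vapply(x$meta, `[[`, character(1), "role")
  cat(sprintf("  quasi-identifiers: %s\n",
              paste(names(roles)[roles == "quasi_identifier"], collapse = ", ")))
  cat(sprintf("  sensitive: %s\n",
              paste(names(roles)[roles == "sensitive"], collapse = ", ")))
  invisible(x)
}

#' @rdname sdc_dataset
#' @param ds an `sdc_dataset`.
#' @export
n_records <- function(ds) nrow(ds$records)

#' Names of variables by role
#' @param x an `sdc_dataset` or a list of [variable_spec()].
#' @return character vector of variable names.
#' @export
qi_names <- function(x) names_with_role(x, "quasi_identifier")

#' @rdname qi_names
#' @export
sensitive_names <- function(x) names_with_role(x, "sensitive")

names_with_role <- function(x, role) {
  meta <- if (inherits(x, "sdc_dataset")) x$meta else x
  nm <- unname(vapply(meta, `[[`, character(1), "name"))
  nm[vapply(meta, `[[`, character(1), "role") == role]
}

#' Read / write datasets as CSV
#'
#' `read_dataset()` reads an RFC-4180 comma-separated file with a
#' header row and returns an [sdc_dataset()]; `write_dataset()` writes
#' one back. A written-then-reloaded dataset reproduces every cell and
#' the column order.
#'
#' @param path file path.
#' @param meta list of [variable_spec()]; columns not covered are kept
#'   with role `"ignored"`.
#' @param label dataset role, as in [sdc_dataset()].
#' @return `read_dataset()`: an `sdc_dataset`; `write_dataset()`: the
#'   path, invisibly.
#' @export
read_dataset <- function(path, meta,
                         label = c("real_sample", "synthetic_sample", "population")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  records <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                             na.strings = c("NA", ""))
  sdc_dataset(records, meta, label = match.arg(label))
}

#' @rdname read_dataset
#' @param ds an `sdc_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sdc_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Cross-dataset consistency checks
#'
#' Compares the real sample, synthetic sample and population and
#' returns a data.frame of findings (severity `"error"` or
#' `"warning"`) rather than failing, so the caller decides what is
#' fatal. Checks: the quasi-identifier sets agree across datasets; the
#' real sample is not larger than the population; synthetic
#' quasi-identifier categories absent from the population (possible
#' but suspicious for a synthesizer trained on a population subset)
#' are flagged as warnings; declared hierarchies strictly coarsen on
#' the observed values.
#'
#' @param real,synthetic,population `sdc_dataset` objects.
#' @return data.frame with columns `severity`, `code`, `message`;
#'   zero rows if everything is consistent.
#' @export
validate_datasets <- function(real, synthetic, population) {
  findings <- list()
  add <- function(severity, code, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  }

  qsets <- list(real = sort(qi_names(real)), synthetic = sort(qi_names(synthetic)),
                population = sort(qi_names(population)))
  if (!identical(qsets$real, qsets$synthetic) || !identical(qsets$real, qsets$population)) {
    add("error", "qi_mismatch",
        "quasi-identifier sets differ between real, synthetic and population datasets")
  }
  if (n_records(real) > n_records(population)) {
    add("error", "sample_larger_than_population",
        sprintf("sample larger than population (n=%d > N=%d)",
                n_records(real), n_records(population)))
  }
  common_qi <- intersect(qi_names(synthetic), qi_names(population))
  for (q in common_qi) {
    if (synthetic$meta[[q]]$kind == "continuous") next
    novel <- setdiff(unique(stats::na.omit(synthetic$records[[q]])),
                     unique(stats::na.omit(population$records[[q]])))
    if (length(novel)) {
      add("warning", "novel_synthetic_category",
          sprintf("synthetic '%s' has categories absent from population: %s",
                  q, paste(novel, collapse = ", ")))
    }
  }
  for (ds in list(real, population)) {
    for (m in ds$meta) {
      if (is.null(m$hierarchy)) next
      msg <- check_hierarchy_coarsens(ds$records[[m$name]], m$hierarchy, m$name)
      if (!is.null(msg)) add("error", "hierarchy_not_coarsening", msg)
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(), code = character(), message = character(),
               stringsAsFactors = FALSE)
}

# each level-i value must map to exactly one level-(i+1) value on observed data
check_hierarchy_coarsens <- function(values, hierarchy, name) {
  vals <- unique(values[!is.na(values)])
  if (!length(vals)) return(NULL)
  prev <- as.character(vals)
  for (i in seq_along(hierarchy)) {
    cur <- apply_hierarchy_level(vals, hierarchy[[i]])
    split_prev <- split(cur, prev)
    bad <- names(split_prev)[vapply(split_prev, function(g) length(unique(g)) > 1L, logical(1))]
    if (length(bad)) {
      return(sprintf("variable '%s': level %d value '%s' maps to multiple level-%d values",
                     name, i - 1L, bad[1], i))
    }
    prev <- cur
  }
  NULL
}
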