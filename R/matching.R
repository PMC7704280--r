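#' Attack configuration: quasi-identifier subset and generalization levels
#'
#' An attack modality is a non-empty subset of the quasi-identifiers
#' together with a generalization level for each (level 0 = raw
#' values). Matching, and therefore every equivalence class quantity,
#' is defined relative to such a configuration.
#'
#' @param qi character vector of quasi-identifier names.
#' @param levels integer vector of generalization levels, recycled to
#'   `length(qi)`; level 0 means raw values, level i >= 1 is the i-th
#'   entry of the variable's hierarchy.
#' @return an object of class `attack_config`.
#' @export
attack_config <- function(qi, levels = 0L) {
  stopifnot(is.character(qi), length(qi) >= 1, !anyDuplicated(qi))
  qi <- unname(qi)
  levels <- as.integer(rep_len(levels, length(qi)))
  stopifnot(all(levels >= 0))
  structure(list(qi = qi, levels = stats::setNames(levels, qi)),
            class = "attack_config")
}

#' @export
print.attack_config <- function(x, ...) {
  cat("<attack_config> ",
      paste(sprintf("%s@%d", x$qi, x$levels), collapse = " + "), "\n")
  invisible(x)
}

as_attack_config <- function(x, ds = NULL) {
  if (inherits(x, "attack_config")) return(x)
  if (is.character(x)) return(attack_config(x, 0L))
  stop("`qi` must be an attack_config or a character vector of QI names", call. = FALSE)
}

# sentinel prefix: missing QI values never match anything, so each
# missing-valued record gets a key unique to itself
.na_sentinel <- "\x01NA\x01"

# generalized key per record for the active configuration; character vector
qi_keys <- function(ds, config) {
  bad_role <- config$qi[vapply(config$qi, function(q) {
    is.null(ds$meta[[q]]) || ds$meta[[q]]$role != "quasi_identifier"
  }, logical(1))]
  if (length(bad_role)) {
    stop(sprintf("not quasi-identifier(s): %s", paste(bad_role, collapse = ", ")),
         call. = FALSE)
  }
  cols <- lapply(config$qi, function(q) {
    lev <- config$levels[[q]]
    m <- ds$meta[[q]]
    if (lev == 0L) {
      if (m$kind == "continuous") {
        stop(sprintf(paste0("continuous quasi-identifier '%s' cannot be matched on raw ",
                            "values; bin it via a hierarchy level first"), q),
             call. = FALSE)
      }
      as.character(ds$records[[q]])
    } else {
      if (is.null(m$hierarchy) || lev > length(m$hierarchy)) {
        stop(sprintf("variable '%s' has no generalization level %d", q, lev),
             call. = FALSE)
      }
      apply_hierarchy_level(ds$records[[q]], m$hierarchy[[lev]])
    }
  })
  key <- do.call(paste, c(cols, sep = "\x1f"))
  miss <- Reduce(`|`, lapply(cols, is.na))
  if (any(miss)) {
    # label qualifies the sentinel so a missing real record can never
    # collide with a missing synthetic record at the same row index
    key[miss] <- paste0(.na_sentinel, ds$label, ":", which(miss))
  }
  key
}

#' Equivalence classes on the active quasi-identifiers
#'
#' Partitions a dataset's records into classes of identical (possibly
#' generalized) quasi-identifier tuples. Records with a missing value
#' on any active quasi-identifier form singleton classes: a missing
#' value never matches anything.
#'
#' @param ds an [sdc_dataset()].
#' @param qi an [attack_config()] or a character vector of
#'   quasi-identifier names (matched at raw level).
#' @return named list mapping the key (QI values joined by the unit
#'   separator) to the integer indices of records in that class.
#' @examples
#' ex <- worked_example()
#' lengths(equivalence_classes(ex$real, "origin"))
#' @export
equivalence_classes <- function(ds, qi) {
  config <- as_attack_config(qi)
  keys <- qi_keys(ds, config)
  split(seq_along(keys), keys)
}

#' Match a real sample against synthetic sample and population
#'
#' Computes, for every record s of the real sample, the equivalence
#' class sizes f_s (in the real sample) and F_s (in the population),
#' the binary indicator I_s of whether at least one synthetic record
#' carries the identical quasi-identifier tuple, and the list of
#' matching synthetic record indices. All three datasets are keyed on
#' the same configuration, so matching is exact equality on the
#' (generalized) tuple.
#'
#' F_s is taken as the exact population class size; a real record
#' whose tuple does not occur in the population is an error (the real
#' sample must be a subset of the population on the
#' quasi-identifiers). Alternatively, precomputed population class
#' sizes can be supplied via `population_counts`, a data.frame with
#' one column per active quasi-identifier (values at the same
#' generalization level as the match) plus a column `F` of counts.
#' Records with a missing active quasi-identifier get
#' f_s = F_s = 1 and I_s = 0: they never match and never contribute
#' risk.
#'
#' @param real,synthetic,population [sdc_dataset()] objects;
#'   `population` may be `NULL` when `population_counts` is given.
#' @param qi an [attack_config()] or character vector of QI names.
#' @param population_counts optional data.frame of per-class
#'   population sizes (see above).
#' @return an object of class `match_state`: list with per-record
#'   vectors `f`, `F`, `I`, list `partners`, the active `config`, and
#'   sizes `n`, `N`.
#' @examples
#' ex <- worked_example()
#' ms <- compute_match_state(ex$real, ex$synthetic, ex$population, "origin")
#' ms$f; ms$F; ms$I
#' @export
compute_match_state <- function(real, synthetic, population, qi,
                                population_counts = NULL) {
  config <- as_attack_config(qi)
  rk <- qi_keys(real, config)
  sk <- qi_keys(synthetic, config)
  n <- length(rk)
  miss <- startsWith(rk, .na_sentinel)

  f <- as.integer(table(rk)[rk])
  f[miss] <- 1L

  if (!is.null(population_counts)) {
    stopifnot(is.data.frame(population_counts), "F" %in% names(population_counts))
    if (!all(config$qi %in% names(population_counts))) {
      stop("`population_counts` must have one column per active quasi-identifier",
           call. = FALSE)
    }
    pc_key <- do.call(paste, c(population_counts[config$qi], sep = "\x1f"))
    Fmap <- stats::setNames(as.numeric(population_counts$F), pc_key)
    N <- sum(population_counts$F)
  } else {
    stopifnot(inherits(population, "sdc_dataset"))
    pk <- qi_keys(population, config)
    Fmap <- table(pk)
    N <- length(pk)
  }
  Fs <- rep(NA_real_, n)
  Fs[miss] <- 1
  lookup <- as.numeric(Fmap[rk[!miss]])
  if (anyNA(lookup)) {
    stop("real sample is not a subset of population on quasi-identifiers",
         call. = FALSE)
  }
  Fs[!miss] <- lookup

  syn_by_key <- split(seq_along(sk), sk)
  partners <- vector("list", n)
  partners[miss] <- list(integer(0))
  hit <- syn_by_key[rk[!miss]]
  hit[vapply(hit, is.null, logical(1))] <- list(integer(0))
  partners[!miss] <- hit
  I <- as.integer(lengths(partners) > 0)

  structure(list(f = f, F = Fs, I = I, partners = partners,
                 config = config, n = n, N = as.integer(N)),
            class = "match_state")
}

#' @export
print.match_state <- function(x, ...) {
  cat(sprintf("<match_state> n=%d, N=%d, QI: %s\n", x$n, x$N,
              paste(sprintf("%s@%d", x$config$qi, x$config$levels), collapse = " + ")))
  cat(sprintf("  matched (I=1): %d/%d records;  f in [%d, %d];  F in [%g, %g]\n",
              sum(x$I), x$n, min(x$f), max(x$f), min(x$F), max(x$F)))
  invisible(x)
}
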