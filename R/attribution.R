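#' Learn-something-new test for nominal and binary sensitive variables
#'
#' An adversary learns something new from a matched sensitive value
#' when the real value is unusual in the real sample and the synthetic
#' value agrees with it. The distance of value j from the rest of the
#' sample is `d_j = 1 - p_j` (p_j = proportion of the real sample with
#' value j), the similarity of a matched pair is the Iverson bracket
#' `[X_s = Y_t]`, and the weighted similarity `d_j * [X_s = Y_t]` must
#' exceed one Bernoulli standard deviation `sqrt(p_j (1 - p_j))`.
#' For an exact value match this inequality reduces to `p_j < 1/2`:
#' the adversary learns something new exactly when fewer than half the
#' sample shares the value.
#'
#' @param x real-sample value.
#' @param y matched synthetic value.
#' @param p_j proportion of real-sample records sharing value `x`;
#'   must be positive (x occurs in the real sample).
#' @return `"learned"`, `"not_learned"`, or `"skipped_missing"` when
#'   either value is missing.
#' @export
nominal_learn_new <- function(x, y, p_j) {
  if (is.na(x) || is.na(y)) return("skipped_missing")
  if (!is.numeric(p_j) || p_j <= 0 || p_j > 1) {
    stop("`p_j` must be in (0, 1]: x must occur in the real sample", call. = FALSE)
  }
  same <- as.character(x) == as.character(y)
  if (same && (1 - p_j) * 1 > sqrt(p_j * (1 - p_j))) "learned" else "not_learned"
}

#' Median absolute deviation about the median (unscaled)
#'
#' The robust spread measure used by the continuous
#' learn-something-new inequality: `median(|x - median(x)|)`, with no
#' consistency constant — the 1.48 multiplier that makes it equivalent
#' to one standard deviation under normality is applied separately
#' (see [continuous_learn_new()] and the `mad_multiplier` parameter).
#'
#' @param values numeric vector; missing values are dropped.
#' @return nonnegative scalar.
#' @examples
#' mad_unscaled(c(70, 100, 130, 65, 95))  # 25
#' @export
mad_unscaled <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  stats::mad(values, constant = 1)
}

#' Discretize a continuous variable by univariate k-means
#'
#' Continuous sensitive variables are discretized with univariate
#' k-means so each record gets a cluster proportion `p_s` (size of its
#' cluster over n), playing the role the value proportion `p_j` plays
#' for nominal variables. The cluster count is chosen by majority rule
#' over a panel of indices — average silhouette, Calinski-Harabasz,
#' Davies-Bouldin, and the within-SS elbow (largest second difference)
#' — across `k = 2 .. min(max_k, #distinct)`, ties broken toward the
#' smaller k. Initial centers are deterministic (evenly spaced
#' quantiles), so the clustering is reproducible without a seed.
#'
#' @param values numeric vector (missing values allowed; they get
#'   `NA` cluster and proportion).
#' @param max_k largest cluster count considered.
#' @return list with `cluster` (integer label per value), `p`
#'   (cluster proportion per value), `k`, `centers`, and `votes` (the
#'   per-index chosen k).
#' @export
discretize_continuous <- function(values, max_k = 10) {
  stopifnot(is.numeric(values))
  ok <- !is.na(values)
  x <- values[ok]
  n <- length(x)
  if (n == 0) stop("no non-missing values", call. = FALSE)
  distinct <- sort(unique(x))

  out <- list(cluster = rep(NA_integer_, length(values)),
              p = rep(NA_real_, length(values)))
  if (length(distinct) < 2) {
    out$cluster[ok] <- 1L
    out$p[ok] <- 1
    out$k <- 1L; out$centers <- distinct; out$votes <- NULL
    return(out)
  }

  ks <- 2:min(max_k, length(distinct))
  fits <- lapply(ks, function(k) kmeans_1d(x, k))
  names(fits) <- ks

  # index panel computed on (a deterministic thinning of) the data
  idx <- if (n > 1500) round(seq(1, n, length.out = 1500)) else seq_len(n)
  xs <- x[idx]
  d <- stats::dist(xs)
  score <- lapply(fits, function(f) {
    cl <- f$cluster[idx]
    list(
      sil = mean_silhouette(cl, d),
      ch = calinski_harabasz(xs, cl),
      db = davies_bouldin(xs, cl),
      wss = f$tot.withinss
    )
  })
  sil <- vapply(score, `[[`, numeric(1), "sil")
  ch <- vapply(score, `[[`, numeric(1), "ch")
  db <- vapply(score, `[[`, numeric(1), "db")
  wss <- vapply(score, `[[`, numeric(1), "wss")

  pick_max <- function(v) ks[which.max(round(v, 10))]
  pick_min <- function(v) ks[which.min(round(v, 10))]
  votes <- c(
    silhouette = pick_max(sil),
    calinski_harabasz = pick_max(ch),
    davies_bouldin = pick_min(db),
    elbow = elbow_k(ks, wss)
  )
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_best <- min(winners)

  fit <- fits[[as.character(k_best)]]
  sizes <- tabulate(fit$cluster, nbins = k_best)
  out$cluster[ok] <- fit$cluster
  out$p[ok] <- sizes[fit$cluster] / n
  out$k <- k_best
  out$centers <- as.numeric(fit$centers)
  out$votes <- votes
  out
}

# deterministic 1-d Lloyd k-means: evenly spaced quantile starting
# centers; an emptied cluster is reseeded at the point farthest from
# its current center (standard fix, deterministic)
kmeans_1d <- function(x, k) {
  centers <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  centers <- unique(centers)
  while (length(centers) < k) {
    spare <- setdiff(sort(unique(x)), centers)
    centers <- sort(c(centers, spare[seq_len(min(k - length(centers), length(spare)))]))
  }
  assign_nearest <- function(ctr) {
    ctr_s <- sort(ctr)
    mids <- (ctr_s[-1] + ctr_s[-length(ctr_s)]) / 2
    findInterval(x, mids) + 1L  # label by sorted-center order
  }
  cl <- NULL
  for (iter in 1:100) {
    centers <- sort(centers)
    cl_new <- assign_nearest(centers)
    present <- tabulate(cl_new, nbins = k)
    if (any(present == 0)) {
      dists <- abs(x - centers[cl_new])
      centers[which(present == 0)[1]] <- x[which.max(dists)]
      next
    }
    if (!is.null(cl) && identical(cl, cl_new)) break
    cl <- cl_new
    centers <- vapply(seq_len(k), function(j) mean(x[cl == j]), numeric(1))
  }
  centers <- sort(centers)
  cl <- assign_nearest(centers)
  wss <- sum((x - centers[cl])^2)
  list(cluster = cl, centers = centers, tot.withinss = wss)
}

mean_silhouette <- function(cl, d) {
  if (length(unique(cl)) < 2) return(-Inf)
  s <- cluster::silhouette(cl, d)
  if (!is.matrix(s)) return(-Inf)  # all-singleton clustering: undefined
  mean(s[, "sil_width"])
}

calinski_harabasz <- function(x, cl) {
  n <- length(x); k <- length(unique(cl))
  if (k < 2 || k >= n) return(-Inf)
  gm <- mean(x)
  ns <- tapply(x, cl, length)
  ms <- tapply(x, cl, mean)
  ssb <- sum(ns * (ms - gm)^2)
  ssw <- sum((x - ms[as.character(cl)])^2)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

davies_bouldin <- function(x, cl) {
  labs <- sort(unique(cl))
  k <- length(labs)
  if (k < 2) return(Inf)
  ms <- vapply(labs, function(l) mean(x[cl == l]), numeric(1))
  sp <- vapply(labs, function(l) mean(abs(x[cl == l] - mean(x[cl == l]))), numeric(1))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) {
      sep <- abs(ms[i] - ms[j])
      if (sep == 0) Inf else (sp[i] + sp[j]) / sep
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

# knee of the within-SS curve: k maximizing the second difference;
# endpoints fall back to the largest drop
elbow_k <- function(ks, wss) {
  if (length(ks) < 3) {
    drops <- -diff(c(wss[1] * 2, wss))
    return(ks[which.max(drops)])
  }
  second <- diff(diff(wss))  # wss[i+2] - 2 wss[i+1] + wss[i], convexity
  ks[which.max(second) + 1L]
}

#' Learn-something-new test for continuous sensitive variables
#'
#' The continuous analogue of [nominal_learn_new()]: the distance
#' weight is the cluster proportion `d_s = p_s` from
#' [discretize_continuous()], and the adversary learns something new
#' when the weighted absolute difference between real and synthetic
#' values falls within the robust spread of the variable:
#' `p_s * |x - y| < multiplier * MAD`.
#'
#' @param x real-sample value.
#' @param y matched synthetic value.
#' @param p_s cluster proportion of the real value, in (0, 1\].
#' @param mad_x unscaled MAD of the variable in the real sample.
#' @param multiplier scale factor, default 1.48 (one Gaussian SD).
#' @return `"learned"`, `"not_learned"`, or `"skipped_missing"`.
#' @examples
#' continuous_learn_new(95, 100, p_s = 1, mad_x = 25)   # learned
#' continuous_learn_new(70, 110, p_s = 1, mad_x = 25)   # not learned
#' @export
continuous_learn_new <- function(x, y, p_s, mad_x, multiplier = 1.48) {
  if (is.na(x) || is.na(y)) return("skipped_missing")
  stopifnot(p_s > 0, p_s <= 1, mad_x >= 0, multiplier > 0)
  if (p_s * abs(x - y) < multiplier * mad_x) "learned" else "not_learned"
}

# precompute per-sensitive-variable quantities on the real sample:
# nominal -> value proportions; continuous -> clustering p per record + MAD
sensitive_profiles <- function(real, params = risk_parameters()) {
  sens <- sensitive_names(real)
  profiles <- list()
  for (v in sens) {
    m <- real$meta[[v]]
    col <- real$records[[v]]
    if (m$kind == "continuous") {
      disc <- discretize_continuous(col, max_k = params$kmeans_max_k)
      profiles[[v]] <- list(kind = "continuous", p = disc$p,
                            mad = if (all(is.na(col))) NA_real_ else mad_unscaled(col),
                            k = disc$k)
    } else {
      ok <- !is.na(col)
      tab <- table(col[ok]) / sum(ok)
      profiles[[v]] <- list(kind = "nominal",
                            prop = stats::setNames(as.numeric(tab), names(tab)))
    }
  }
  profiles
}

#' Does the adversary learn something new about one matched record?
#'
#' Applies the per-variable learn-something-new tests over every
#' matched synthetic partner of a real record and aggregates with the
#' L% rule: for each partner, the fraction of applicable (non-missing)
#' sensitive variables with verdict `"learned"` is computed, and
#' R_s = 1 if any partner reaches at least `L`%. A record with zero
#' applicable sensitive variables is conservatively assigned R_s = 1
#' (pure identity disclosure, flagged via a warning by the pipeline).
#'
#' @param real_record one-row data.frame (the real record s).
#' @param partner_records data.frame of matched synthetic records.
#' @param profiles output of the internal sensitive-variable
#'   profiling; entries named by sensitive variable.
#' @param p_s_record named numeric: for continuous variables, the
#'   cluster proportion of this record's real value.
#' @param L percentage threshold.
#' @param mad_multiplier multiplier for the continuous test.
#' @return list with binary `R` and per-partner `fractions`.
#' @keywords internal
record_learns_new <- function(real_record, partner_records, profiles,
                              p_s_record, L, mad_multiplier = 1.48) {
  sens <- names(profiles)
  fractions <- vapply(seq_len(nrow(partner_records)), function(t) {
    learned <- 0L; applicable <- 0L
    for (v in sens) {
      pr <- profiles[[v]]
      x <- real_record[[v]]
      y <- partner_records[[v]][t]
      if (pr$kind == "nominal") {
        if (is.na(x) || is.na(y)) next
        verdict <- nominal_learn_new(x, y, pr$prop[[as.character(x)]])
      } else {
        if (is.na(x) || is.na(y)) next
        verdict <- continuous_learn_new(x, y, p_s_record[[v]], pr$mad,
                                        multiplier = mad_multiplier)
      }
      applicable <- applicable + 1L
      if (verdict == "learned") learned <- learned + 1L
    }
    if (applicable == 0L) return(1)
    learned / applicable
  }, numeric(1))
  list(R = as.integer(length(fractions) > 0 && any(fractions >= L / 100)),
       fractions = fractions)
}

#' Attribution verdicts for all matched records
#'
#' Computes the learn-something-new indicator R_s for every
#' real-sample record with I_s = 1; records without a synthetic match
#' get `NA` (the test is not applicable where there is no match, and
#' those records contribute zero risk regardless).
#'
#' @param real,synthetic [sdc_dataset()] objects.
#' @param ms a [compute_match_state()] result.
#' @param params [risk_parameters()].
#' @param profiles optionally precomputed sensitive profiles (reused
#'   across attack configurations; sensitive variables are never
#'   generalized).
#' @return object of class `attribution_result`: list with integer
#'   vector `R` (NA where I_s = 0) and list `fractions`.
#' @export
attribution_results <- function(real, synthetic, ms,
                                params = risk_parameters(),
                                profiles = NULL) {
  if (is.null(profiles)) profiles <- sensitive_profiles(real, params)
  n <- ms$n
  R <- rep(NA_integer_, n)
  fr <- vector("list", n)
  if (length(profiles) == 0 && any(ms$I == 1)) {
    warning("no applicable sensitive variables: matches count as pure identity disclosure (R_s = 1)",
            call. = FALSE)
  }
  cont <- names(profiles)[vapply(profiles, function(p) p$kind == "continuous", logical(1))]
  for (s in which(ms$I == 1)) {
    p_s_record <- stats::setNames(
      lapply(cont, function(v) profiles[[v]]$p[s]), cont)
    res <- record_learns_new(real$records[s, , drop = FALSE],
                             synthetic$records[ms$partners[[s]], , drop = FALSE],
                             profiles, p_s_record,
                             L = params$L, mad_multiplier = params$mad_multiplier)
    R[s] <- res$R
    fr[[s]] <- res$fractions
  }
  structure(list(R = R, fractions = fr), class = "attribution_result")
}
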