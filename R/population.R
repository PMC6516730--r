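#' One-dimensional k-medoids clustering with square-root dissimilarity
#'
#' PAM-style clustering of scalar estimates using
#' \eqn{d(v, m) = \sqrt{|v - m|}} as the dissimilarity, which discounts
#' extreme outliers more strongly than the Euclidean distance.  Medoids
#' are initialized deterministically at evenly spaced order statistics
#' and refined by a full swap phase (every medoid / non-medoid exchange
#' that lowers the objective), so the result is independent of input
#' order and of the random seed.
#'
#' @param values numeric vector of M estimates.
#' @param K number of clusters (K <= M).
#' @return List with `assignment` (cluster index per value, clusters
#'   ordered by increasing medoid), `medoids` (values), `sizes` and
#'   `objective` (sum of dissimilarities to assigned medoids).
#' @export
kmedoids_1d <- function(values, K) {
  M <- length(values)
  stopifnot(K >= 1, M >= K)
  diss <- function(v, m) sqrt(abs(v - m))
  obj_of <- function(meds) {
    d <- sapply(meds, diss, v = values)
    d <- matrix(d, M, length(meds))
    sum(apply(d, 1, min))
  }
  sv <- sort(values)
  meds <- unique(sv[pmin(pmax(ceiling((seq_len(K) - 0.5) / K * M), 1), M)])
  while (length(meds) < K) {        # duplicated order stats: pad
    cand <- setdiff(values, meds)
    if (!length(cand)) { meds <- c(meds, meds[1]); next }
    meds <- c(meds, cand[1])
  }
  best <- obj_of(meds)
  repeat {
    improved <- FALSE
    for (ki in seq_len(K)) {
      for (cand in setdiff(unique(values), meds)) {
        trial <- meds; trial[ki] <- cand
        o <- obj_of(trial)
        if (o < best - 1e-12) {
          meds <- trial; best <- o; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  meds <- sort(meds)
  d <- matrix(sapply(meds, diss, v = values), M, K)
  assign <- apply(d, 1, which.min)
  list(assignment = as.integer(assign), medoids = meds,
       sizes = tabulate(assign, nbins = K), objective = best)
}

#' Combine per-train estimates under parallel processing
#'
#' Clusters the M individual decoding estimates of each interval into K
#' categories by [kmedoids_1d()] and reports the median of each cluster
#' as the estimate of one stimulus component.  Clusters containing at
#' most 5 percent of the estimates (inclusive) are flagged as outlier
#' categories: their medians are discarded and the median of the largest
#' surviving cluster is reported for the flagged components instead.  If
#' every cluster is flagged the overall median is reported for all
#' components, with a warning.
#'
#' @param estimates N x M matrix (or length-M vector for one interval)
#'   of per-train estimates.
#' @param K number of stimulus components.
#' @param flag_threshold flagging fraction (default 0.05).
#' @return List with `clusters`, a data frame
#'   (`interval, cluster, median, size, flagged`), and `estimates`, the
#'   N x K matrix of reported component estimates (ascending per
#'   interval).
#' @export
combine_parallel_estimates <- function(estimates, K,
                                       flag_threshold = 0.05) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, 1)
  stopifnot(all(is.finite(estimates)))
  N <- nrow(estimates); M <- ncol(estimates)
  rows <- vector("list", N)
  est <- matrix(NA_real_, N, K)
  for (n in seq_len(N)) {
    km <- kmedoids_1d(estimates[n, ], K)
    med <- vapply(seq_len(K), function(k) {
      memb <- estimates[n, km$assignment == k]
      if (length(memb)) stats::median(memb) else NA_real_
    }, numeric(1))
    flagged <- km$sizes <= flag_threshold * M
    rows[[n]] <- data.frame(interval = n, cluster = seq_len(K),
                            median = med, size = km$sizes,
                            flagged = flagged)
    if (all(flagged)) {
      warning("all clusters flagged at interval ", n,
              "; reporting the overall median")
      est[n, ] <- stats::median(estimates[n, ])
    } else if (any(flagged)) {
      keep <- which(!flagged)
      big <- keep[which.max(km$sizes[keep])]
      rep_med <- med
      rep_med[flagged] <- med[big]
      est[n, ] <- sort(rep_med)
    } else {
      est[n, ] <- sort(med)
    }
  }
  list(clusters = do.call(rbind, rows), estimates = est)
}
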