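#' Consecutive-assessment deltas
#'
#' Differences between consecutive assessments, \code{delta[i] =
#' value[i+1] - value[i]}, for the PLUS score and (when a series data frame
#' is given) each raw scale.
#'
#' @param x Either a numeric vector of PLUS scores in timepoint order, or a
#'   data frame with a \code{plus_score} column and optionally the six raw
#'   scale columns, one row per assessment in timepoint order.
#' @return For a vector: numeric vector of deltas. For a data frame: a data
#'   frame of deltas with one row per consecutive pair.
#' @export
compute_deltas <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("plus_score", "pss10", "swls", "nmq",
                        "mbi_ee", "mbi_dp", "mbi_pa"), names(x))
    if (length(cols) == 0L) stop("no score columns found", call. = FALSE)
    if (nrow(x) < 2L) {
      stop("insufficient data: need at least 2 assessments, got ", nrow(x),
           call. = FALSE)
    }
    as.data.frame(lapply(x[cols], diff))
  } else {
    stopifnot(is.numeric(x))
    if (length(x) < 2L) {
      stop("insufficient data: need at least 2 assessments, got ", length(x),
           call. = FALSE)
    }
    diff(x)
  }
}

#' Detect deterioration in a PLUS trajectory
#'
#' Flags a subject when some consecutive drop in the PLUS score reaches the
#' threshold, and classifies the trend: \code{"deteriorating"} when every
#' step declines, \code{"improving"} when every step rises, \code{"stable"}
#' when every step stays within the threshold band, else \code{"mixed"}.
#'
#' @param plus_scores Numeric vector of PLUS scores in timepoint order
#'   (at least 2).
#' @param threshold Non-negative decline size on the PLUS scale that counts
#'   as deterioration (default 0.05).
#' @return A list of class \code{deterioration_report}: \code{deltas},
#'   \code{trend}, \code{flag}, \code{max_decline} (magnitude of the largest
#'   drop, 0 if none).
#' @examples
#' detect_deterioration(c(0.411, 0.351, 0.238))           # flagged, deteriorating
#' detect_deterioration(c(0.501, 0.457, 0.492))           # stable
#' @export
detect_deterioration <- function(plus_scores, threshold = 0.05) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  d <- compute_deltas(as.numeric(plus_scores))
  trend <- if (all(d < 0)) "deteriorating"
           else if (all(d > 0)) "improving"
           else if (all(abs(d) <= threshold)) "stable"
           else "mixed"
  # a zero step is never a decline, even at threshold 0
  flag <- any(d <= -threshold & d < 0)
  structure(list(deltas = d, trend = trend, flag = flag,
                 max_decline = max(0, -min(d)), threshold = threshold),
            class = "deterioration_report")
}

#' @export
print.deterioration_report <- function(x, ...) {
  cat(sprintf("Deterioration report (threshold %.3g): %s%s\n", x$threshold,
              x$trend, if (x$flag) " [FLAGGED]" else ""))
  cat("  deltas:", paste(sprintf("%+.3f", x$deltas), collapse = " "),
      sprintf(" max decline %.3f\n", x$max_decline))
  invisible(x)
}

#' Summary statistics of a group's PLUS scores
#'
#' Sum, minimum, quartiles (linear interpolation on order statistics at
#' position \code{(n-1)p}), maximum, mean and sample (n-1) standard
#' deviation. These conventions reproduce the published group summaries of
#' the reference cohorts.
#'
#' @param scores Numeric vector of PLUS scores (one per subject), length
#'   at least 2.
#' @return Named numeric vector: \code{sum}, \code{min}, \code{q1},
#'   \code{median}, \code{q3}, \code{max}, \code{mean}, \code{sd}.
#' @export
summarize_group <- function(scores) {
  stopifnot(is.numeric(scores))
  if (length(scores) < 2L) {
    stop("need at least 2 subjects, got ", length(scores), call. = FALSE)
  }
  q <- quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(sum = sum(scores), min = min(scores), q1 = q[1], median = q[2],
    q3 = q[3], max = max(scores), mean = mean(scores), sd = sd(scores))
}

#' Spearman correlation between two change series
#'
#' Rank correlation (average ranks for ties) between paired delta vectors,
#' e.g. the change in a raw test score versus the change in the model
#' outcome. The two-sided p-value uses the t approximation
#' \code{t = rho * sqrt((n-2) / (1-rho^2))} on \code{n - 2} degrees of
#' freedom; an exact permutation p is available for small n.
#'
#' @param dx,dy Paired numeric vectors of equal length (at least 3).
#' @param p_method \code{"t"} (default) or \code{"permutation"}.
#' @param n_perm Number of permutations when \code{p_method =
#'   "permutation"}; with \code{n <= 7} all permutations are enumerated.
#' @param alpha Significance level (default 0.05).
#' @return List of class \code{change_correlation}: \code{rho}, \code{p},
#'   \code{n}, \code{significant}.
#' @export
change_correlation <- function(dx, dy, p_method = c("t", "permutation"),
                               n_perm = 10000, alpha = 0.05) {
  p_method <- match.arg(p_method)
  stopifnot(is.numeric(dx), is.numeric(dy))
  if (length(dx) != length(dy)) {
    stop("delta vectors must have equal length", call. = FALSE)
  }
  n <- length(dx)
  if (n < 3L) stop("need at least 3 paired deltas", call. = FALSE)
  if (length(unique(dx)) == 1L || length(unique(dy)) == 1L) {
    stop("correlation undefined for an all-constant input", call. = FALSE)
  }
  rx <- rank(dx); ry <- rank(dy)
  rho <- stats::cor(rx, ry)
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  } else {
    obs <- abs(rho)
    if (n <= 7L) {
      perms <- .all_permutations(n)
      stats_perm <- apply(perms, 1L, function(idx) abs(stats::cor(rx, ry[idx])))
      p <- mean(stats_perm >= obs - 1e-12)
    } else {
      stats_perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
      p <- (sum(stats_perm >= obs - 1e-12) + 1) / (n_perm + 1)
    }
  }
  structure(list(rho = rho, p = p, n = n, significant = p < alpha,
                 alpha = alpha, p_method = p_method),
            class = "change_correlation")
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.change_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (%s, n = %d)%s\n", x$rho, x$p,
              x$p_method, x$n,
              if (x$significant) "" else "  [not significant]"))
  invisible(x)
}

#' Longitudinal monitoring over a scored records table
#'
#' Runs the PLUS model over every row of a validated records table, then
#' produces one deterioration report per subject and one group summary per
#' (group, timepoint).
#'
#' @param records A validated records data frame (see
#'   \code{\link{read_records}}).
#' @param threshold Deterioration threshold on the PLUS scale.
#' @param timepoint_order Character vector fixing the chronological order of
#'   timepoint labels.
#' @param model A \code{plus_model}.
#' @return List with \code{scored} (records plus model outputs),
#'   \code{reports} (data frame, one row per subject) and \code{summaries}
#'   (data frame, one row per group x timepoint).
#' @export
plus_monitor <- function(records, threshold = 0.05,
                         timepoint_order = c("t1", "t2", "t3"),
                         model = plus_default_model()) {
  scored <- plus_score_records(records, model)
  unknown <- setdiff(unique(scored$timepoint), timepoint_order)
  if (length(unknown) > 0L) {
    stop("timepoint label(s) not in timepoint_order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  scored <- scored[order(match(scored$timepoint, timepoint_order)), ]

  reports <- do.call(rbind, lapply(split(scored, scored$subject_id),
                                   function(d) {
    if (nrow(d) < 2L) {
      stop("insufficient data: subject '", d$subject_id[1],
           "' has fewer than 2 assessments", call. = FALSE)
    }
    rep <- detect_deterioration(d$plus_score, threshold)
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               n_assessments = nrow(d), trend = rep$trend,
               flag = rep$flag, max_decline = rep$max_decline)
  }))
  rownames(reports) <- NULL

  cells <- split(scored, list(scored$group, scored$timepoint), drop = TRUE)
  summaries <- do.call(rbind, lapply(cells, function(d) {
    cbind(data.frame(group = d$group[1], timepoint = d$timepoint[1]),
          as.data.frame(as.list(summarize_group(d$plus_score))))
  }))
  summaries <- summaries[order(summaries$group,
                               match(summaries$timepoint, timepoint_order)), ]
  rownames(summaries) <- NULL
  list(scored = scored, reports = reports, summaries = summaries)
}
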