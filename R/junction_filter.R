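## Read-count threshold and event filtering ---------------------------------
##
## Junctions are filtered on the minimum skipped-junction read count (SJC)
## across replicates: min SJC must reach a tissue-specific threshold theta.
## Theta is estimated by fitting a two-component Gaussian mixture to
## log2(count + 1) of the per-event min SJC values, separating lowly and
## highly expressed junctions, and taking the smallest integer count whose
## posterior probability of belonging to the high component reaches a
## cutoff (default 0.95). Events with significant replicate inconsistency
## (rMATS PValue <= p_cutoff, default 0.01) are removed.

#' Fit the skipped-junction read-count mixture and derive the threshold
#'
#' Fits a two-component Gaussian mixture by expectation-maximisation on
#' `log2(count + 1)` of the supplied minimum-SJC values. Initialisation is
#' deterministic (lower/upper tertile means, pooled standard deviation,
#' equal weights), so the fit is reproducible without restarts; `seed` is
#' accepted for interface uniformity but the fit involves no sampling.
#' The component with the larger mean is the "highly expressed" group, and
#' the threshold theta is the smallest integer count `c` with
#' `P(high | log2(c + 1)) >= posterior_cutoff`.
#'
#' @param min_sjc_values non-negative integer counts, one per event
#'   (at least 50; with fewer events supply a manual threshold instead).
#' @param posterior_cutoff posterior probability cutoff (default 0.95).
#' @param seed integer, unused by the deterministic fit (kept for API
#'   stability).
#' @param max_iter EM iteration cap (default 1000).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @return an object of class `"count_threshold"` with elements `theta`,
#'   `component_means`, `component_sds`, `component_weights`,
#'   `posterior_cutoff`, `n_events_fit`, `degenerate`, `scale`,
#'   `log_likelihood`, `iterations`.
#' @export
fit_count_mixture <- function(min_sjc_values, posterior_cutoff = 0.95,
                              seed = 1L, max_iter = 1000L, tol = 1e-6) {
  x <- min_sjc_values
  if (length(x) < 50L) {
    stop("fewer than 50 count values supplied (n = ", length(x),
         "); the mixture threshold cannot be estimated reliably - ",
         "supply a manual threshold (manual_theta) instead")
  }
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  stopifnot(posterior_cutoff > 0, posterior_cutoff < 1)
  y <- log2(x + 1)

  degenerate <- function(reason) {
    structure(list(theta = 0L,
                   component_means = c(mean(y), mean(y)),
                   component_sds = c(NA_real_, NA_real_),
                   component_weights = c(0.5, 0.5),
                   posterior_cutoff = posterior_cutoff,
                   n_events_fit = length(x),
                   degenerate = TRUE, degenerate_reason = reason,
                   scale = "log2(count+1)",
                   log_likelihood = NA_real_, iterations = 0L),
              class = "count_threshold")
  }
  if (stats::sd(y) < 1e-8) return(degenerate("zero variance"))

  qs <- stats::quantile(y, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  mu <- c(mean(y[y <= qs[1L]]), mean(y[y >= qs[2L]]))
  if (!is.finite(mu[1L]) || !is.finite(mu[2L]) || diff(mu) < 1e-9)
    mu <- range(y)
  sdev <- rep(max(stats::sd(y) / 2, 1e-3), 2L)
  w <- c(0.5, 0.5)
  sd_floor <- 1e-3

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d1 <- w[1L] * stats::dnorm(y, mu[1L], sdev[1L])
    d2 <- w[2L] * stats::dnorm(y, mu[2L], sdev[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(y) - n2
    if (n1 < 1e-8 || n2 < 1e-8) return(degenerate("component collapse"))
    mu <- c(sum((1 - r2) * y) / n1, sum(r2 * y) / n2)
    sdev <- c(sqrt(sum((1 - r2) * (y - mu[1L])^2) / n1),
              sqrt(sum(r2 * (y - mu[2L])^2) / n2))
    sdev <- pmax(sdev, sd_floor)
    w <- c(n1, n2) / length(y)
  }
  fit <- list(mu = mu, sd = sdev, w = w, ll = ll_old, iterations = iter)
  if (!converged) {
    cond <- structure(
      class = c("junctiondb_em_error", "error", "condition"),
      list(message = paste0("EM did not converge within ", max_iter,
                            " iterations"),
           call = sys.call(-1L), partial_fit = fit))
    stop(cond)
  }

  ## order components so index 2 is the high-mean ("highly expressed") one
  if (mu[1L] > mu[2L]) {
    mu <- rev(mu); sdev <- rev(sdev); w <- rev(w)
  }
  if (abs(diff(mu)) < 1e-6) return(degenerate("indistinguishable means"))

  post_high <- function(counts) {
    yy <- log2(counts + 1)
    d1 <- w[1L] * stats::dnorm(yy, mu[1L], sdev[1L])
    d2 <- w[2L] * stats::dnorm(yy, mu[2L], sdev[2L])
    d2 / pmax(d1 + d2, .Machine$double.xmin)
  }
  grid <- 0:(as.integer(max(x)) + 1L)
  ok <- which(post_high(grid) >= posterior_cutoff)
  theta <- if (length(ok)) grid[ok[1L]] else max(grid) + 1L

  structure(list(theta = as.integer(theta),
                 component_means = mu, component_sds = sdev,
                 component_weights = w,
                 posterior_cutoff = posterior_cutoff,
                 n_events_fit = length(x),
                 degenerate = FALSE, degenerate_reason = NA_character_,
                 scale = "log2(count+1)",
                 log_likelihood = ll_old, iterations = iter),
            class = "count_threshold")
}

#' Posterior-scan threshold from known mixture parameters
#'
#' Computes the smallest integer count whose posterior probability of the
#' high-mean component reaches `posterior_cutoff`, given explicit mixture
#' parameters on the `log2(count + 1)` scale. Used as the closed-form
#' oracle against which the EM fit is validated, and internally for the
#' threshold scan.
#'
#' @param means,sds,weights two-component parameters (log2 scale).
#' @param posterior_cutoff posterior probability cutoff.
#' @param max_count upper bound for the integer scan.
#' @return integer threshold (`max_count + 1` if never reached).
#' @export
posterior_scan_threshold <- function(means, sds, weights,
                                     posterior_cutoff = 0.95,
                                     max_count = 10000L) {
  o <- order(means)
  means <- means[o]; sds <- sds[o]; weights <- weights[o]
  grid <- 0:max_count
  yy <- log2(grid + 1)
  d1 <- weights[1L] * stats::dnorm(yy, means[1L], sds[1L])
  d2 <- weights[2L] * stats::dnorm(yy, means[2L], sds[2L])
  p <- d2 / pmax(d1 + d2, .Machine$double.xmin)
  ok <- which(p >= posterior_cutoff)
  if (length(ok)) grid[ok[1L]] else max_count + 1L
}

#' @export
print.count_threshold <- function(x, ...) {
  cat("Skipped-junction count threshold (two-component Gaussian mixture)\n")
  cat(sprintf("  theta: %d  (posterior cutoff %.2f, scale %s)\n",
              x$theta, x$posterior_cutoff, x$scale))
  if (isTRUE(x$degenerate)) {
    cat("  DEGENERATE fit:", x$degenerate_reason, "\n")
  } else {
    cat(sprintf("  low  component: mean %.3f sd %.3f weight %.3f\n",
                x$component_means[1L], x$component_sds[1L],
                x$component_weights[1L]))
    cat(sprintf("  high component: mean %.3f sd %.3f weight %.3f\n",
                x$component_means[2L], x$component_sds[2L],
                x$component_weights[2L]))
  }
  cat(sprintf("  fitted on %d events, %d EM iterations\n",
              x$n_events_fit, x$iterations))
  invisible(x)
}

#' Manual count threshold
#'
#' Wraps a user-chosen integer threshold in a `"count_threshold"` object,
#' bypassing the mixture fit (used e.g. to reproduce a known per-tissue
#' setting such as a minimum of 4 reads).
#'
#' @param theta non-negative integer threshold.
#' @return `"count_threshold"` object with `manual = TRUE`.
#' @export
manual_threshold <- function(theta) {
  stopifnot(length(theta) == 1L, !is.na(theta), theta >= 0,
            theta == floor(theta))
  structure(list(theta = as.integer(theta),
                 component_means = c(NA_real_, NA_real_),
                 component_sds = c(NA_real_, NA_real_),
                 component_weights = c(NA_real_, NA_real_),
                 posterior_cutoff = NA_real_, n_events_fit = 0L,
                 degenerate = FALSE, degenerate_reason = NA_character_,
                 scale = "count", manual = TRUE,
                 log_likelihood = NA_real_, iterations = 0L),
            class = "count_threshold")
}

#' Filter events by count threshold and replicate consistency
#'
#' Keeps an event iff its minimum skipped-junction count across replicates
#' is at least `theta` AND its rMATS PValue is either missing or greater
#' than `p_cutoff`. A missing PValue passes: the consistency filter
#' excludes events with demonstrated inconsistency (p <= cutoff), and NA
#' cannot satisfy that. Each rejected event carries exactly one primary
#' reason code, `low_count` tested first, then `inconsistent`.
#'
#' @param events a `splice_event_table`.
#' @param threshold a `"count_threshold"` object or bare integer theta.
#' @param p_cutoff consistency p-value cutoff in (0, 1] (default 0.01).
#' @return list with elements `kept` (event table) and `rejected`
#'   (event table with an extra `reason` column).
#' @export
filter_events <- function(events, threshold, p_cutoff = 0.01) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1)
  theta <- if (inherits(threshold, "count_threshold")) threshold$theta
           else as.integer(threshold)
  stopifnot(length(theta) == 1L, !is.na(theta), theta >= 0)
  if (nrow(events) == 0L) {
    return(list(kept = events,
                rejected = cbind(events, reason = character(0L))))
  }
  msjc <- event_min_sjc(events)
  low <- msjc < theta
  incons <- !is.na(events$p_value) & events$p_value <= p_cutoff
  reason <- ifelse(low, "low_count", ifelse(incons, "inconsistent", NA))
  keep <- is.na(reason)
  kept <- events[keep]
  rejected <- events[!keep]
  data.table::set(rejected, j = "reason", value = reason[!keep])
  data.table::setattr(kept, "class", class(events))
  data.table::setattr(rejected, "class", class(events))
  list(kept = kept[], rejected = rejected[])
}

#' Write a small key-value threshold report
#'
#' @param threshold `"count_threshold"` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_threshold_report <- function(threshold, path) {
  t <- threshold
  lines <- c(
    sprintf("theta\t%d", t$theta),
    sprintf("posterior_cutoff\t%s", format(t$posterior_cutoff)),
    sprintf("scale\t%s", t$scale),
    sprintf("mean_low\t%s", format(t$component_means[1L])),
    sprintf("mean_high\t%s", format(t$component_means[2L])),
    sprintf("sd_low\t%s", format(t$component_sds[1L])),
    sprintf("sd_high\t%s", format(t$component_sds[2L])),
    sprintf("weight_low\t%s", format(t$component_weights[1L])),
    sprintf("weight_high\t%s", format(t$component_weights[2L])),
    sprintf("n_events_fit\t%d", t$n_events_fit),
    sprintf("degenerate\t%s", isTRUE(t$degenerate)),
    sprintf("manual\t%s", isTRUE(t$manual)))
  writeLines(lines, path)
  invisible(path)
}
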