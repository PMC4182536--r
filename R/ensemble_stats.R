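# Distributional analysis of scalar observables: maximum-likelihood Gaussian
# fits, two-component mixture decomposition by EM, and classification of
# frames into open / closed / intermediate compactness states.

.SD_FLOOR <- 1e-6  # nm; prevents EM variance collapse

.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.mixture_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.mixture_fit_result <- function(k, w, mu, sd, ll, n_iter, converged,
                                ll_trace = numeric(0)) {
  ord <- order(mu, decreasing = TRUE)  # components in descending mean order
  structure(list(k = k, weights = w[ord] / sum(w), means = mu[ord],
                 sds = sd[ord], log_likelihood = ll,
                 n_iter = n_iter, converged = converged,
                 ll_trace = ll_trace),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, logLik = %.4f (%s, %d iter)\n",
              x$k, x$log_likelihood,
              if (x$converged) "converged" else "not converged", x$n_iter))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.4f, sd %.4f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Maximum-likelihood single-Gaussian fit
#'
#' Population-form estimates (`sd = sqrt(mean((x - mean)^2))`). Zero-variance
#' samples are floored at `1e-6` with a warning.
#'
#' @param values Numeric sample, n >= 2.
#' @return A `mixture_fit` with k = 1.
#' @export
fit_gaussian <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 values")
  mu <- mean(x)
  sd <- sqrt(mean((x - mu)^2))
  if (sd < .SD_FLOOR) {
    warning("zero variance; sd floored at ", .SD_FLOOR)
    sd <- .SD_FLOOR
  }
  .mixture_fit_result(1L, 1, mu, sd, .mixture_loglik(x, 1, mu, sd), 0L, TRUE)
}

#' Gaussian-mixture fit by expectation-maximization
#'
#' EM on the raw values (not on binned counts) from `n_starts` k-means
#' initializations; the best log-likelihood is kept. Convergence when the
#' log-likelihood improves by less than 1e-8 or after 500 iterations.
#' Components are reported in descending mean order; the fit is
#' bit-reproducible for a fixed seed and leaves the caller's RNG untouched.
#'
#' @param values Numeric sample, n >= 10 k.
#' @param k Number of components (1 or 2 are the intended uses).
#' @param n_starts Number of initializations (default 5).
#' @param seed Integer seed (required: initialization is stochastic).
#' @param binned Optional alternative: least-squares fit to a histogram of
#'   `binned` bins instead of ML on raw values (comparison mode; the
#'   returned log-likelihood is still evaluated on the raw values).
#' @return A `mixture_fit`.
#' @export
fit_gaussian_mixture <- function(values, k = 2L, n_starts = 5L, seed,
                                 binned = NULL) {
  x <- as.numeric(values)
  if (length(x) < 10L * k) stop("need at least 10 values per component")
  if (stats::sd(x) == 0) stop("degenerate sample: all values identical")
  if (missing(seed)) stop("seed is required for a reproducible mixture fit")
  if (k == 1L) return(fit_gaussian(x))
  if (!is.null(binned)) return(.mixture_lsq_binned(x, k, binned, seed))
  n <- length(x)
  best <- NULL
  .with_preserved_rng(seed, {
    for (s in seq_len(n_starts)) {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
      mu <- as.numeric(km$centers)
      sd <- vapply(seq_len(k), function(j) {
        xs <- x[km$cluster == j]
        max(sqrt(mean((xs - mean(xs))^2)), .SD_FLOOR)
      }, numeric(1))
      w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
      w[w == 0] <- 1e-6; w <- w / sum(w)
      ll <- .mixture_loglik(x, w, mu, sd)
      trace <- ll
      conv <- FALSE; it <- 0L
      while (it < 500L) {
        it <- it + 1L
        # E step
        resp <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                       numeric(n))
        rs <- rowSums(resp)
        rs[rs < 1e-300] <- 1e-300
        resp <- resp / rs
        # M step
        nk <- colSums(resp)
        w <- nk / n
        mu <- colSums(resp * x) / nk
        sd <- pmax(sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk), .SD_FLOOR)
        ll_new <- .mixture_loglik(x, w, mu, sd)
        trace <- c(trace, ll_new)
        if (abs(ll_new - ll) < 1e-8) { ll <- ll_new; conv <- TRUE; break }
        ll <- ll_new
      }
      if (is.null(best) || ll > best$log_likelihood) {
        best <- .mixture_fit_result(k, w, mu, sd, ll, it, conv, trace)
      }
    }
  })
  best
}

# Least-squares Gaussian interpolation of a binned histogram; comparison
# mode for the ML route above.
.mixture_lsq_binned <- function(x, k, nbins, seed) {
  h <- graphics::hist(x, breaks = nbins, plot = FALSE)
  mids <- h$mids; dens <- h$density
  init <- fit_gaussian_mixture(x, k = k, n_starts = 3L, seed = seed)
  par0 <- c(init$weights[-k], init$means, log(init$sds))
  obj <- function(p) {
    w <- c(p[seq_len(k - 1)], 1 - sum(p[seq_len(k - 1)]))
    if (any(w < 0)) return(1e9)
    mu <- p[k:(2 * k - 1)]; sd <- exp(p[(2 * k):(3 * k - 1)])
    pred <- rowSums(vapply(seq_len(k), function(j) w[j] * stats::dnorm(mids, mu[j], sd[j]),
                           numeric(length(mids))))
    sum((pred - dens)^2)
  }
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  w <- c(fit$par[seq_len(k - 1)], 1 - sum(fit$par[seq_len(k - 1)]))
  mu <- fit$par[k:(2 * k - 1)]; sd <- pmax(exp(fit$par[(2 * k):(3 * k - 1)]), .SD_FLOOR)
  .mixture_fit_result(k, w, mu, sd, .mixture_loglik(x, w, mu, sd),
                      as.integer(fit$counts[1]), fit$convergence == 0)
}

#' Classify frames into open / closed / intermediate states
#'
#' A frame is closed when the observable is at most
#' `closed_center + band`, open when at least `open_center - band`, and
#' intermediate otherwise (strict inequalities in between). The two bands
#' must not overlap.
#'
#' @param series A [scalar_series()] (e.g. hairpin-sensitive RG).
#' @param open_center,closed_center State centres in the observable's units
#'   (typically the fitted mixture means; open > closed).
#' @param band Half-width of each state's acceptance band (typically one
#'   fitted SD).
#' @return Object of class `state_series`: `labels`, `times`, `thresholds`.
#' @export
classify_states <- function(series, open_center, closed_center, band) {
  if (open_center - band <= closed_center + band) {
    stop("state bands overlap: open_center - band must exceed ",
         "closed_center + band")
  }
  v <- series$values
  labels <- ifelse(v <= closed_center + band, "closed",
                   ifelse(v >= open_center - band, "open", "intermediate"))
  structure(list(labels = labels, times = series$times,
                 thresholds = c(closed_max = closed_center + band,
                                open_min = open_center - band)),
            class = "state_series")
}

#' Per-state summary of a scalar observable
#'
#' @param states A [classify_states()] result.
#' @param series A [scalar_series()] over the same frames.
#' @return data.frame: state, n, mean, sd, flagged (TRUE when n < 2, where
#'   the SD is undefined).
#' @export
per_state_statistics <- function(states, series) {
  if (length(states$labels) != length(series$values)) {
    stop("states and observable cover different frame counts")
  }
  out <- do.call(rbind, lapply(c("open", "intermediate", "closed"), function(s) {
    v <- series$values[states$labels == s]
    data.frame(state = s, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               flagged = length(v) < 2)
  }))
  rownames(out) <- NULL
  out
}

#' Per-state region RMSF
#'
#' Recomputes the region-mean RMSF on each state's frame subset; states with
#' fewer than 2 frames are flagged with an `NA` value rather than failing.
#'
#' @param traj A trajectory.
#' @param states A [classify_states()] result over the same frames.
#' @param region A [region_spec()].
#' @param fit_selection Atom indices for the superposition fit.
#' @return data.frame: state, n, rmsf (region mean, nm), flagged.
#' @export
per_state_rmsf <- function(traj, states, region,
                           fit_selection = seq_len(n_atoms(traj))) {
  if (length(states$labels) != n_frames(traj)) {
    stop("states and trajectory cover different frame counts")
  }
  region_atoms <- resolve_region(traj, region)
  out <- do.call(rbind, lapply(c("open", "intermediate", "closed"), function(s) {
    idx <- which(states$labels == s)
    if (length(idx) < 2) {
      return(data.frame(state = s, n = length(idx), rmsf = NA_real_,
                        flagged = TRUE))
    }
    sub <- trajectory(traj$topology, traj$coords[, , idx, drop = FALSE],
                      times = traj$times[idx])
    prof <- rmsf_profile(sub, fit_selection = fit_selection)
    inreg <- prof$chain == region$chain & prof$resid >= region$first_resid &
      prof$resid <= region$last_resid
    data.frame(state = s, n = length(idx), rmsf = mean(prof$rmsf[inreg]),
               flagged = FALSE)
  }))
  rownames(out) <- NULL
  out
}
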