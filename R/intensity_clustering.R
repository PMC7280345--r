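# Intensity clustering (1-D k-means, CLU) and deterministic equal-spacing
# quantization (QNT). Both render a label map by replacing each pixel with
# its cluster centroid / bin centre, so the rendering is monotone in
# intensity and reproducible (no random palettes).

#' 1-D k-means over pixel intensities
#'
#' Lloyd's algorithm on the intensity histogram (each distinct intensity
#' weighted by its pixel count, which is exact for integer images):
#' assignment to the nearest centroid under the Euclidean metric (ties go
#' to the lower centroid index), centroid update to the mean of assigned
#' intensities, until no centroid moves more than `tol` or `max_iter`
#' iterations. An emptied cluster is re-seeded at the intensity farthest
#' from its current centroid. Initialization is either `"quantile"`
#' (k evenly spaced quantiles of the intensity distribution,
#' deterministic) or `"random"` (`nstart` restarts from k distinct
#' observed intensities drawn under `seed`). In addition the
#' deterministic equal-spacing start is always refined too — its first
#' Lloyd step reproduces the equal-width partition exactly — and the
#' lowest-SSE solution over all starts is returned, so the fit is never
#' worse than equal-spacing quantization and is reproducible: same seed,
#' same labels.
#'
#' @param image a `radiograph` (the processing paths cluster the 8-bit
#'   preprocessed image).
#' @param k number of clusters (>= 2, and at most the number of distinct
#'   intensities).
#' @param seed integer RNG seed for random initialization.
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on centroid movement (default 1e-6).
#' @param init `"quantile"` or `"random"`.
#' @param nstart number of random restarts (ignored for quantile init).
#' @return list with `model` (class `cluster_model`: sorted centroids,
#'   `sse`, per-iteration `sse_trace` of the winning start, `reseeds`,
#'   `iterations_run`, `converged`, `k`, `seed`) and `map` (a
#'   label-valued `feature_map` rendering each pixel as its centroid
#'   intensity).
#' @export
kmeans_intensity <- function(image, k, seed = 1L, max_iter = 100L,
                             tol = 1e-6, init = c("quantile", "random"),
                             nstart = 40L) {
  stopifnot(inherits(image, "radiograph"))
  init <- match.arg(init)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  v <- as.vector(image$pixels)
  vals <- sort(unique(v))
  if (k > length(vals)) {
    stop("k (", k, ") exceeds the number of distinct intensities (",
         length(vals), ")")
  }
  wts <- tabulate(match(v, vals), nbins = length(vals))

  force_distinct <- function(cent) {
    if (anyDuplicated(cent)) {
      cent <- unique(cent)
      pool <- setdiff(vals, cent)
      cent <- c(cent, pool[seq_len(k - length(cent))])
    }
    cent
  }
  starts <- if (init == "quantile") {
    # k evenly spaced quantiles; can repeat on skewed histograms
    list(force_distinct(as.double(
      stats::quantile(v, probs = (seq_len(k) - 0.5) / k,
                      names = FALSE, type = 1))))
  } else {
    local_rng(seed, lapply(seq_len(nstart), function(r) {
      as.double(sample(vals, k))
    }))
  }

  assign_lab <- function(cent) {
    # nearest centroid; ties resolved to the lower centroid index
    d <- abs(outer(vals, cent, "-"))
    max.col(-d, ties.method = "first")
  }
  sse_of <- function(cent, lab) sum(wts * (vals - cent[lab])^2)
  run_lloyd <- function(cent) {
    iterations <- 0L
    reseeds <- 0L
    converged <- FALSE
    lab <- assign_lab(cent)
    sse_trace <- sse_of(cent, lab)
    best <- list(centroids = cent, lab = lab, sse = sse_trace[1])
    for (it in seq_len(max_iter)) {
      iterations <- it
      newc <- cent
      for (j in seq_len(k)) {
        sel <- lab == j
        if (any(sel)) {
          newc[j] <- sum(vals[sel] * wts[sel]) / sum(wts[sel])
        } else {
          # re-seed the empty cluster at the intensity farthest from its
          # current centroid (can transiently raise the SSE)
          newc[j] <- vals[which.max(abs(vals - cent[j]))]
          reseeds <- reseeds + 1L
        }
      }
      moved <- max(abs(newc - cent))
      cent <- newc
      lab <- assign_lab(cent)
      s <- sse_of(cent, lab)
      sse_trace <- c(sse_trace, s)
      # a reseed can take the trajectory uphill; remember the best state
      if (s < best$sse) best <- list(centroids = cent, lab = lab, sse = s)
      if (moved <= tol) { converged <- TRUE; break }
    }
    list(centroids = best$centroids, lab = best$lab, sse = best$sse,
         sse_trace = sse_trace, reseeds = reseeds,
         iterations = iterations, converged = converged)
  }

  # refine every start plus the deterministic equal-spacing start, and
  # keep the lowest-SSE solution
  lo <- min(v); hi <- max(v)
  fit <- NULL
  if (hi > lo) {
    wdt <- (hi - lo + 1) / k
    starts <- c(starts, list(lo + (seq_len(k) - 0.5) * wdt))
    # the exact equal-width partition itself (bin means as centroids) is
    # always a candidate, so the fit is never worse than equal-spacing
    # quantization by construction
    bin <- pmin(floor((vals - lo) / wdt), k - 1L) + 1L
    bcent <- lo + (seq_len(k) - 0.5) * wdt - 0.5
    for (j in unique(bin)) {
      sel <- bin == j
      bcent[j] <- sum(vals[sel] * wts[sel]) / sum(wts[sel])
    }
    fit <- list(centroids = bcent, lab = bin, sse = sse_of(bcent, bin),
                sse_trace = sse_of(bcent, bin), reseeds = 0L,
                iterations = 0L, converged = TRUE)
  }
  for (cent in starts) {
    cand <- run_lloyd(cent)
    if (is.null(fit) || cand$sse < fit$sse) fit <- cand
  }
  centroids <- fit$centroids
  lab <- fit$lab
  sse <- fit$sse

  ord <- order(centroids)
  centroids_sorted <- centroids[ord]
  relab <- match(seq_len(k), ord)[lab]   # label in sorted order
  px_lab <- relab[match(v, vals)]
  rendered <- matrix(centroids_sorted[px_lab],
                     nrow(image$pixels), ncol(image$pixels))
  model <- structure(list(k = k, centroids = centroids_sorted, seed = seed,
                          iterations_run = fit$iterations,
                          converged = fit$converged,
                          sse = sse, sse_trace = fit$sse_trace,
                          reseeds = fit$reseeds, init = init),
                     class = "cluster_model")
  map <- feature_map(rendered,
                     provenance = list(operator = "CLU", k = k, seed = seed,
                                       feature = paste0("CLU-k", k)),
                     value_domain = "label")
  list(model = model, map = map)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, SSE = %.6g, %d iteration(s)%s\n",
              x$k, x$sse, x$iterations_run,
              if (x$converged) ", converged" else " (iteration cap hit)"))
  cat("centroids:", paste(signif(x$centroids, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cluster_model <- function(object, ...) object$centroids

#' Equal-spacing quantization map
#'
#' Deterministic companion to [kmeans_intensity()]: the discrete intensity
#' range `[min, max]` is split into `k` equal-width bins (bin width
#' `(max - min + 1) / k`; half-open bins, last bin closed) and every pixel
#' is replaced by the centre of its bin, so the number of output colors
#' matches the clustering variant while the division is fixed rather than
#' data-adaptive.
#'
#' @param image a `radiograph`.
#' @param k number of bins (>= 2).
#' @return a label-valued `feature_map` (at most `k` distinct values); a
#'   constant image yields a single color with a warning.
#' @export
equal_spacing_quantize_map <- function(image, k) {
  stopifnot(inherits(image, "radiograph"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  m <- image$pixels
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("constant image: equal-spacing quantization yields one color")
    vals <- matrix(as.double(lo), nrow(m), ncol(m))
  } else {
    wdt <- (hi - lo + 1) / k
    b <- pmin(floor((m - lo) / wdt), k - 1L)
    vals <- lo + (b + 0.5) * wdt - 0.5
  }
  feature_map(vals,
              provenance = list(operator = "QNT", k = k,
                                feature = paste0("QNT-k", k)),
              value_domain = "label")
}

#' Within-cluster sum of squares of an equal-spacing partition
#'
#' Helper used to compare the adaptive clustering against the fixed
#' equal-width partition at the same `k` (k-means refines, so its final
#' SSE can only be lower or equal).
#'
#' @param image a `radiograph`.
#' @param k number of bins.
#' @return scalar SSE of pixels about their equal-width bin means.
#' @export
equal_spacing_sse <- function(image, k) {
  m <- image$pixels
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(0)
  wdt <- (hi - lo + 1) / k
  b <- pmin(floor((as.vector(m) - lo) / wdt), k - 1L)
  mu <- stats::ave(as.double(as.vector(m)), b)
  sum((as.vector(m) - mu)^2)
}
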