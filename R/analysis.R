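# Trained-model subtraction, retention of the largest relative changes, and
# ten-zone scalp summaries.

#' Subtract two trained models
#'
#' Edge-wise weight difference `w_post - w_pre` over the (identical) sparsity
#' pattern. Positive deltas are "increase" connections (drawn green in the
#' field's figures), negative deltas "decrease" (red).
#'
#' @param pre,post `snn_trained_model`s sharing grid, sparsity pattern and
#'   provenance (same seeded initial reservoir).
#' @return `snn_connectivity_delta`: list with `edges` (data.frame `i`, `j`,
#'   `w_pre`, `w_post`, `delta`, `relative`, `retained`), `grid`, `input_map`,
#'   `retain_fraction` (NA until [retain_top()]), `labels` = c(pre, post)
#'   condition tags.
#' @export
subtract_models <- function(pre, post) {
  stopifnot(inherits(pre, "snn_trained_model"),
            inherits(post, "snn_trained_model"))
  mp <- pre$model; mq <- post$model
  if (!isTRUE(all.equal(mp$grid$coords, mq$grid$coords)))
    stop("models were built on different grids")
  if (nrow(mp$edges) != nrow(mq$edges) ||
      any(mp$edges$i != mq$edges$i) || any(mp$edges$j != mq$edges$j))
    stop("models have different sparsity patterns")
  eps <- 1e-6
  edges <- data.frame(i = mp$edges$i, j = mp$edges$j,
                      w_pre = mp$edges$w, w_post = mq$edges$w)
  edges$delta <- edges$w_post - edges$w_pre
  edges$relative <- abs(edges$delta) / pmax(abs(edges$w_pre), eps)
  edges$retained <- FALSE
  structure(list(edges = edges, grid = mp$grid, input_map = mp$input_map,
                 retain_fraction = NA_real_,
                 labels = c(pre = pre$trained_on, post = post$trained_on)),
            class = "snn_connectivity_delta")
}

#' @export
print.snn_connectivity_delta <- function(x, ...) {
  cat(sprintf("<snn_connectivity_delta> %s -> %s: %d edges, %d retained\n",
              x$labels[["pre"]], x$labels[["post"]], nrow(x$edges),
              sum(x$edges$retained)))
  invisible(x)
}

#' Retain the largest relative connectivity changes
#'
#' Keeps the `ceiling(fraction * M)` edges of largest relative change
#' `|delta| / max(|w_pre|, 1e-6)` among the M edges with nonzero delta
#' (default fraction 0.05 — "5% of relative changes"). Ties break by edge
#' index for determinism. Set `relative = FALSE` to rank by `|delta|`
#' instead.
#'
#' @param delta an `snn_connectivity_delta`.
#' @param fraction retention fraction in (0, 1].
#' @param relative rank by relative (default) or absolute change.
#' @return The delta with its `retained` flags set.
#' @export
retain_top <- function(delta, fraction = 0.05, relative = TRUE) {
  stopifnot(inherits(delta, "snn_connectivity_delta"),
            fraction > 0, fraction <= 1)
  e <- delta$edges
  nz <- which(e$delta != 0)
  k <- ceiling(fraction * length(nz))
  score <- if (relative) e$relative[nz] else abs(e$delta[nz])
  keep <- nz[order(-score, nz)[seq_len(k)]]
  e$retained <- FALSE
  e$retained[keep] <- TRUE
  delta$edges <- e
  delta$retain_fraction <- fraction
  delta
}

#' Region summary of a connectivity delta
#'
#' Assigns each retained edge to the zone pair of the electrodes nearest its
#' two endpoint neurons (endpoints farther than `max_dist` from every
#' electrode, or nearest to an auxiliary channel, are left unassigned and
#' dropped), sums increase and decrease magnitudes per ordered zone pair, and
#' computes a hemispheric dominance index.
#'
#' Dominance is `(R - L) / (R + L)` over the total `|delta|` assigned to each
#' hemisphere (each endpoint contributes half its edge's magnitude to its
#' hemisphere), 0 when both totals are 0: -1 means all change is
#' left-lateralized, +1 all right.
#'
#' @param delta an `snn_connectivity_delta` after [retain_top()].
#' @param scheme [region_scheme()].
#' @param montage the recording montage (electrode positions in grid space).
#' @param max_dist assignment cap in mm (default 40).
#' @return `snn_region_summary`: list with `increase` and `decrease`
#'   (10 x 10 matrices, source zone x target zone; increase >= 0,
#'   decrease <= 0), `dominance`, `n_assigned`, `n_retained`.
#' @export
summarize_regions <- function(delta, scheme = region_scheme(),
                              montage = make_default_montage(),
                              max_dist = 40) {
  stopifnot(inherits(delta, "snn_connectivity_delta"))
  zones <- names(scheme)
  inc <- dec <- matrix(0, 10, 10, dimnames = list(zones, zones))
  ret <- delta$edges[delta$edges$retained, , drop = FALSE]
  L <- R <- 0
  if (nrow(ret)) {
    # nearest electrode (and its zone) per neuron, computed once
    pos <- montage$positions
    co <- delta$grid$coords
    need <- sort(unique(c(ret$i, ret$j)))
    zone_of <- setNames(rep(NA_character_, length(need)), need)
    ch_zone <- vapply(montage$labels, electrode_zone, character(1),
                      scheme = scheme, montage = montage)
    for (nn in need) {
      d2 <- colSums((t(pos) - co[nn, ])^2)
      k <- which.min(d2)
      if (sqrt(d2[k]) <= max_dist && ch_zone[k] != "unassigned")
        zone_of[as.character(nn)] <- ch_zone[k]
    }
    zi <- zone_of[as.character(ret$i)]
    zj <- zone_of[as.character(ret$j)]
    ok <- !is.na(zi) & !is.na(zj)
    for (r in which(ok)) {
      if (ret$delta[r] > 0)
        inc[zi[r], zj[r]] <- inc[zi[r], zj[r]] + ret$delta[r]
      else
        dec[zi[r], zj[r]] <- dec[zi[r], zj[r]] + ret$delta[r]
      for (z in c(zi[r], zj[r])) {
        h <- zone_hemisphere(z)
        if (identical(h, "left")) L <- L + abs(ret$delta[r]) / 2
        if (identical(h, "right")) R <- R + abs(ret$delta[r]) / 2
      }
    }
    n_assigned <- sum(ok)
  } else n_assigned <- 0L
  dominance <- if (L + R == 0) 0 else (R - L) / (R + L)
  structure(list(increase = inc, decrease = dec, dominance = dominance,
                 n_assigned = n_assigned, n_retained = nrow(ret),
                 labels = delta$labels),
            class = "snn_region_summary")
}

#' @export
print.snn_region_summary <- function(x, ...) {
  cat(sprintf("<snn_region_summary> %s -> %s: %d/%d edges assigned, dominance %+0.3f\n",
              x$labels[["pre"]], x$labels[["post"]], x$n_assigned,
              x$n_retained, x$dominance))
  invisible(x)
}

# combined |change| per unordered zone pair
.zone_pair_magnitude <- function(summary) {
  m <- summary$increase - summary$decrease        # both contributions, >= 0
  zones <- rownames(m)
  out <- list()
  for (a in seq_along(zones)) for (b in a:length(zones)) {
    val <- if (a == b) m[a, b] else m[a, b] + m[b, a]
    out[[paste(zones[a], zones[b], sep = "|")]] <- val
  }
  unlist(out)
}

#' Planted-coupling recovery score
#'
#' Fraction of the fixture's planted zone pairs that rank in the top quartile
#' of the summary's (unordered) zone-pair change magnitudes.
#'
#' @param summary an `snn_region_summary`.
#' @param planted a planted-edge data.frame from [make_study_fixture()]
#'   metadata (needs `source_zone`, `target_zone`; at least one row).
#' @return Fraction in `[0, 1]`.
#' @export
recovery_score <- function(summary, planted) {
  stopifnot(inherits(summary, "snn_region_summary"))
  if (is.null(planted) || nrow(planted) == 0)
    stop("no planted edges in metadata")
  mags <- .zone_pair_magnitude(summary)
  top_k <- ceiling(length(mags) / 4)
  top <- names(sort(mags, decreasing = TRUE))[seq_len(top_k)]
  zones <- names(region_scheme())
  key <- function(a, b) {
    idx <- sort(match(c(a, b), zones))
    paste(zones[idx[1]], zones[idx[2]], sep = "|")
  }
  pairs <- unique(mapply(key, planted$source_zone, planted$target_zone))
  mean(pairs %in% top)
}
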