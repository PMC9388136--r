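#' Signed microtubule sliding speed
#'
#' For each filament and each disjoint analysis window of width `delta_t`,
#' the (unwrapped) displacement of the minus end is projected onto the
#' filament axis at the window start, oriented plus-to-minus, and divided by
#' `delta_t`. Averaging over filaments and windows gives the overall signed
#' speed: positive means minus-end-leading unidirectional sliding (the
#' signature of plus-end-directed cross-linker driven transport), negative
#' means plus-end-leading. A large `delta_t` suppresses the small nonzero
#' contribution of rotational diffusion.
#'
#' @param traj An `mt_trajectory` from [run_until()].
#' @param delta_t Window width (s); must be a multiple of the trajectory's
#'   frame interval.
#' @return Mean signed speed (um/s), `NA` if no filament spans a window.
#' @export
signed_mt_speed <- function(traj, delta_t) {
  w <- speed_windows(traj, delta_t)
  if (nrow(w) == 0) return(NA_real_)
  mean(w$speed)
}

# per-window per-filament signed speeds; internal work-horse
speed_windows <- function(traj, delta_t) {
  stopifnot(inherits(traj, "mt_trajectory"))
  frames <- traj$frames
  if (length(frames) < 2) stop("trajectory spans less than delta_t")
  times <- vapply(frames, `[[`, 0, "time")
  fi <- traj$meta$frame_interval
  if (is.na(fi)) fi <- times[2] - times[1]
  k <- round(delta_t / fi)
  if (abs(k * fi - delta_t) > 1e-9 * delta_t || k < 1) {
    stop("delta_t is not representable on the frame grid (interval ", fi, " s)")
  }
  if (length(frames) < k + 1) stop("trajectory spans less than delta_t")
  # anchor windows at the first frame that contains filaments (systems that
  # nucleate from seeds have an empty initial frame)
  first <- which(vapply(frames, function(f) length(f$nv) > 0, TRUE))[1]
  if (is.na(first) || first > length(frames) - k) {
    return(data.frame(window = integer(0), time = numeric(0),
                      speed = numeric(0)))
  }
  starts <- seq(first, length(frames) - k, by = k)
  out <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    i0 <- starts[si]; i1 <- i0 + k
    f0 <- frames[[i0]]; f1 <- frames[[i1]]
    n0 <- length(f0$nv)
    if (n0 == 0) next
    off0 <- cumsum(c(0, f0$nv))
    off1 <- cumsum(c(0, f1$nv))
    sp <- rep(NA_real_, n0)
    for (f in seq_len(n0)) {
      minus0 <- f0$vertices[off0[f] + 1, ]
      plus0 <- f0$vertices[off0[f] + f0$nv[f], ]
      minus1 <- f1$vertices[off1[f] + 1, ]
      ax <- minus0 - plus0
      nn <- sqrt(sum(ax^2))
      if (nn == 0) next
      sp[f] <- sum((minus1 - minus0) * ax) / nn / delta_t
    }
    sp <- sp[!is.na(sp)]
    if (length(sp)) {
      out[[si]] <- data.frame(window = si, time = times[i1],
                              speed = mean(sp))
    }
  }
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                   list(data.frame(window = integer(0), time = numeric(0),
                                   speed = numeric(0)))))
}

#' Cross-linker connected-component (cluster) analysis of one frame
#'
#' Builds a graph whose nodes are filaments, with one edge per doubly bound
#' cross-linker of the requested type, and reports the connected components.
#' By convention the largest-component fraction is the bundle size for
#' KIF11-type linkers and the aster size for HSET-type linkers, normalized
#' by the total number of filaments.
#'
#' @param frame One element of an `mt_trajectory`'s `frames`.
#' @param linker_type Catalog name of the linker type, or `"any"` to pool
#'   all types.
#' @param type_names Character vector mapping the frame's type indices to
#'   names (from `traj$meta$linker_type_names`).
#' @return List of class `cluster_report` with `linker_type`,
#'   `largest_fraction`, `component_sizes` and `n_filaments`.
#' @export
crosslink_clusters <- function(frame, linker_type, type_names = character()) {
  n <- length(frame$nv)
  lk <- frame$linkers
  sel <- lk$fil_a > 0 & lk$fil_b > 0 & lk$fil_a != lk$fil_b
  if (!identical(linker_type, "any")) {
    idx <- which(type_names == linker_type)
    if (length(idx) == 0) sel <- sel & FALSE
    else sel <- sel & lk$type %in% idx
  }
  edges <- cbind(lk$fil_a[sel], lk$fil_b[sel])
  sizes <- component_sizes(n, edges)
  structure(list(linker_type = linker_type,
                 largest_fraction = if (n > 0) max(sizes) / n else NA_real_,
                 component_sizes = sizes,
                 n_filaments = n),
            class = "cluster_report")
}

#' Connected-component sizes of a filament graph
#'
#' @param n Number of filaments (nodes).
#' @param edges Two-column matrix of node indices (1-based); duplicates and
#'   zero rows allowed.
#' @return Sorted (decreasing) integer vector of component sizes; all ones
#'   when there are no edges.
#' @export
component_sizes <- function(n, edges) {
  if (n == 0) return(integer(0))
  if (is.null(edges) || nrow(edges) == 0) return(rep(1L, n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

#' Time course of sliding speed and largest cluster fractions
#'
#' One row per analysis window (disjoint windows of width `delta_t`):
#' window end time, mean signed sliding speed over the window, and the
#' largest-cluster fraction per linker type (and pooled over all types) at
#' the window-end frame. For a single-frame trajectory only the cluster
#' columns are produced.
#'
#' @param traj An `mt_trajectory`.
#' @param delta_t Analysis window (s); ignored for single-frame input.
#' @return A data.frame.
#' @export
timeseries_summary <- function(traj, delta_t = NULL) {
  stopifnot(inherits(traj, "mt_trajectory"))
  frames <- traj$frames
  if (length(frames) == 0) stop("empty trajectory")
  tn <- traj$meta$linker_type_names
  cluster_cols <- function(frame) {
    out <- list()
    for (nm in unique(tn)) {
      out[[paste0("largest_", nm)]] <-
        crosslink_clusters(frame, nm, tn)$largest_fraction
    }
    out$largest_any <- crosslink_clusters(frame, "any", tn)$largest_fraction
    out
  }
  if (length(frames) == 1) {
    return(as.data.frame(c(list(time = frames[[1]]$time),
                           cluster_cols(frames[[1]]))))
  }
  if (is.null(delta_t)) stop("delta_t required for multi-frame trajectories")
  w <- speed_windows(traj, delta_t)
  times <- vapply(frames, `[[`, 0, "time")
  rows <- lapply(seq_len(nrow(w)), function(i) {
    fr <- frames[[which.min(abs(times - w$time[i]))]]
    as.data.frame(c(list(time = w$time[i], mean_speed = w$speed[i]),
                    cluster_cols(fr)))
  })
  do.call(rbind, rows)
}
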