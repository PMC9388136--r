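# Independent oracles and fixture builders used across the suite.

# Brute-force connected components by label propagation: every node starts
# with its own label; repeatedly each edge pulls both endpoints to the
# smaller label until a fixed point. Independent of the igraph-based path.
label_propagation_sizes <- function(n, edges) {
  lab <- seq_len(n)
  if (!is.null(edges) && nrow(edges) > 0) {
    repeat {
      new <- lab
      for (k in seq_len(nrow(edges))) {
        a <- edges[k, 1]; b <- edges[k, 2]
        m <- min(new[a], new[b])
        new[a] <- m
        new[b] <- m
      }
      if (identical(new, lab)) break
      lab <- new
    }
  }
  sort(as.vector(table(lab)), decreasing = TRUE)
}

# Minimum-image oracle: enumerate candidate periodic images per axis and
# pick the smallest magnitude; exact half ties resolve to -L/2 (the
# half-open convention).
min_image_enum <- function(dx, L) {
  ks <- -4:4
  cands <- dx - ks * L
  ab <- abs(cands)
  best <- which(ab == min(ab))
  if (length(best) > 1) best <- best[which.min(cands[best])]
  cands[best]
}

# Iterated mirror-reflection oracle for the Z slab.
reflect_oracle <- function(z, L) {
  while (z < 0 || z > L) {
    if (z < 0) z <- -z
    if (z > L) z <- 2 * L - z
  }
  z
}

# Central finite differences of a scalar function of a vertex matrix.
fd_gradient <- function(f, vertices, h = 1e-6) {
  g <- matrix(0, nrow(vertices), ncol(vertices))
  for (i in seq_len(nrow(vertices))) {
    for (c in seq_len(ncol(vertices))) {
      vp <- vertices; vp[i, c] <- vp[i, c] + h
      vm <- vertices; vm[i, c] <- vm[i, c] - h
      g[i, c] <- (f(vp) - f(vm)) / (2 * h)
    }
  }
  g
}

# Hand-built trajectory: list of frames from a list of per-frame vertex
# matrices (one filament per element of nv) plus an optional linker table.
make_traj <- function(times, vertices_list, nv, linkers = NULL,
                      type_names = character()) {
  if (is.null(linkers)) {
    linkers <- list(type = integer(0), fil_a = integer(0),
                    fil_b = integer(0), absc_a = numeric(0),
                    absc_b = numeric(0))
  }
  frames <- lapply(seq_along(times), function(i) {
    list(time = times[i], nv = nv, vertices = vertices_list[[i]],
         length = rep(NA_real_, length(nv)), linkers = linkers,
         polymerized = NA_real_, total_length = NA_real_)
  })
  structure(list(meta = list(linker_type_names = type_names,
                             frame_interval = if (length(times) > 1)
                               times[2] - times[1] else NA_real_,
                             seed = 0L, format_version = 1L),
                 frames = frames),
            class = "mt_trajectory")
}

# Small two-filament system builder for mechanics tests.
two_filament_system <- function(box = simulation_box(20, 20, 0.2),
                                physics = physics_params(),
                                types = list(), seed = 1L) {
  new_system(box, physics, linker_types = types, seed = seed)
}
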