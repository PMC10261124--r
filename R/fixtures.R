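#' Deterministic end-to-end test fixtures
#'
#' Generates a (intensity, labels, vector field) triplet with a known
#' geometric property:
#' * `"separated"` — every pair of nuclei is at least 2 voxels apart, so
#'   connected-component labeling of the mask equals the instance count;
#' * `"touching"` — at least one pair of nuclei overlaps (pre-priority),
#'   so component labeling undercounts;
#' * `"dense"` — high count with a positive overlap budget;
#' * `"deformed"` — random placement followed by elastic deformation.
#'
#' @param name Fixture name.
#' @param size Volume dimensions (X, Y, Z).
#' @param seed Integer seed; the triplet is a deterministic function of
#'   `(name, size, seed)`.
#' @param render_cfg Optional [render_config()].
#' @return List with `intensity`, `labels`, `vec`.
#' @export
make_fixture <- function(name = c("separated", "touching", "dense",
                                  "deformed"),
                         size = c(64L, 64L, 64L), seed = 1L,
                         render_cfg = render_config()) {
  name <- match.arg(name)
  size <- as.integer(size)
  set.seed(seed)
  n_base <- max(4L, as.integer(round(prod(size) / 12000)))
  labels <- switch(name,
    separated = .place_separated(size, n_base),
    touching = .place_touching(size, n_base),
    dense = {
      cfg <- synth_config(size, 2L * n_base, a_min = 3, a_max = 6,
                          t_ov = 20L, sigma = 0)
      suppressWarnings(place_nuclei(cfg))
    },
    deformed = {
      cfg <- synth_config(size, n_base, a_min = 3, a_max = 6,
                          t_ov = 10L, d = 5L, sigma = 2)
      suppressWarnings(synth_labels(cfg))
    })
  list(intensity = render_volume(labels, render_cfg),
       labels = labels,
       vec = generate_vector_field(labels))
}

# placement with a guaranteed >= 2 voxel gap between every pair: the
# 1-voxel-inflated rasterizations must not touch existing inflated
# occupancy
.place_separated <- function(size, n) {
  cfg <- synth_config(size, n, a_min = 3, a_max = 6, t_ov = 0L, sigma = 0)
  vol <- array(0L, size)
  occ <- array(FALSE, size)   # inflated occupancy
  k <- 0L
  for (i in seq_len(n)) {
    for (att in 1:100) {
      p <- sample_ellipsoid(cfg, k + 1L)
      pin <- p; pin$a <- p$a + 1
      cin <- rasterize_ellipsoid(pin, size)
      if (nrow(cin) == 0L) next
      iin <- coords_to_index(cin, size)
      if (any(occ[iin])) next
      co <- rasterize_ellipsoid(p, size)
      if (nrow(co) == 0L) next
      k <- k + 1L
      vol[coords_to_index(co, size)] <- k
      occ[iin] <- TRUE
      break
    }
  }
  vol
}

# placement in pairs with guaranteed positive (pre-priority) overlap for
# at least one pair
.place_touching <- function(size, n) {
  cfg <- synth_config(size, n, a_min = 3, a_max = 6, t_ov = 40L, sigma = 0)
  vol <- array(0L, size)
  k <- 0L
  pairs <- max(1L, n %/% 2L)
  for (i in seq_len(pairs)) {
    for (att in 1:200) {
      p1 <- sample_ellipsoid(cfg, k + 1L)
      c1 <- rasterize_ellipsoid(p1, size)
      if (nrow(c1) < 20L) next
      i1 <- coords_to_index(c1, size)
      if (any(vol[i1] != 0L)) next
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p2 <- sample_ellipsoid(cfg, k + 2L)
      p2$center <- pmin(pmax(p1$center + dir * 0.75 *
                               (mean(p1$a) + mean(p2$a)), 0), size - 1)
      c2 <- rasterize_ellipsoid(p2, size)
      if (nrow(c2) < 20L) next
      i2 <- coords_to_index(c2, size)
      ov <- sum(i2 %in% i1)
      if (ov < 1L || ov > cfg$t_ov) next
      if (sum(vol[i2] != 0L & vol[i2] != k + 1L) > 0L) next
      k <- k + 1L
      vol[i1] <- k
      k <- k + 1L
      free <- i2[vol[i2] == 0L]
      vol[free] <- k
      break
    }
  }
  if (max(vol) < 2L)
    stop("failed to construct a touching pair; try another seed",
         call. = FALSE)
  vol
}
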