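## shared fixture builders for the test suite

# constant-section cylinder as a station series
cylinder_series <- function(n_stations = 3, r_dv = 1, r_lm = 0.5, l = 4,
                            region = "trunk") {
  x <- seq(0, l, length.out = n_stations)
  station_series(x, rep(2 * r_dv, n_stations), rep(0, n_stations),
                 rep(r_lm, n_stations), rep(region, n_stations - 1L))
}

# multi-region body with constant sections per region (exact volumes known)
blocky_body <- function() {
  x <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7)
  region <- c("head", "head", "neck", "neck", "trunk", "trunk",
              "tail", "tail", "tail")
  depth <- c(0.4, 0.4, 0.3, 0.3, 1.0, 1.0, 0.6, 0.6, 0.6, 0.6)
  width <- c(0.15, 0.15, 0.12, 0.12, 0.4, 0.4, 0.25, 0.25, 0.25, 0.25)
  station_series(x, 0.5 + depth / 2, 0.5 - depth / 2, width, region)
}

# true centroid of a linearly tapering circular frustum by slab integration
slab_com <- function(r_ant, r_post, l, n = 2e5) {
  xm <- (seq_len(n) - 0.5) / n * l
  r <- r_ant + (r_post - r_ant) * xm / l
  sum(xm * r^2) / sum(r^2)
}

# true volume of a linearly tapering elliptical solid by slab integration
slab_volume <- function(r_ant_dv, r_ant_lm, r_post_dv, r_post_lm, l,
                        n = 2e5) {
  xm <- (seq_len(n) - 0.5) / n * l
  rdv <- r_ant_dv + (r_post_dv - r_ant_dv) * xm / l
  rlm <- r_ant_lm + (r_post_lm - r_ant_lm) * xm / l
  sum(pi * rdv * rlm) * l / n
}

# single-frustum chain with circular faces
one_frustum_chain <- function(r_ant, r_post, l, k = 2, rho = 1000) {
  body <- station_series(c(0, l), c(r_ant, r_post), c(-r_ant, -r_post),
                         c(r_ant, r_post), "trunk")
  slice_to_frusta(body, k = k, densities = c(trunk = rho))
}

# hand-built 4-tip balanced tree: ((A:1,B:1):2,(C:1.5,D:1.5):1.5);
balanced_tree4 <- function() {
  ape::read.tree(text = "((A:1,B:1):2,(C:1.5,D:1.5):1.5);")
}

# brute-force patristic distances by summing edges along root-to-tip paths
path_sum_distances <- function(tree) {
  n <- length(tree$tip.label)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  depth <- ape::node.depth.edgelength(tree)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      anc <- ape::getMRCA(tree, c(i, j))
      D[i, j] <- D[j, i] <- depth[i] + depth[j] - 2 * depth[anc]
    }
  }
  D
}
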