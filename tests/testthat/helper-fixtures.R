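# Shared fixtures: all generated in code, nothing on disk.

# 4-atom single-bond path A-B-C-D
path4 <- function() {
  molecule_graph(rep(6L, 4L),
                 data.frame(i = 1:3, j = 2:4, order = 1L),
                 coords = cbind(0:3 * 1.5, 0, 0), name = "path4")
}

# small model used across encoder/score tests
tiny_model <- function(seed = 7L, ...) {
  init_score_model(model_config(hidden = 16L, reduced = 8L, n_blocks = 2L,
                                gin_depth = 2L, ...), seed = seed)
}

tiny_schedule <- function(T_steps = 20L, gamma_t = "one") {
  make_schedule(diffusion_config(T_steps, 1e-4, 0.1, gamma_t = gamma_t))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# random connected molecule with single bonds, for graph property tests
random_molecule <- function(n, seed) {
  set.seed(seed)
  parent <- c(0L, vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1L)))
  bonds <- data.frame(i = parent[-1L], j = 2:n, order = 1L)
  # a few extra edges to create cycles
  extra <- 0L
  while (extra < 2L && n > 3L) {
    ij <- sort(sample.int(n, 2L))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (!(paste(ij[1L], ij[2L]) %in% key)) {
      bonds <- rbind(bonds, data.frame(i = ij[1L], j = ij[2L], order = 1L))
    }
    extra <- extra + 1L
  }
  molecule_graph(sample(c(6L, 7L, 8L), n, replace = TRUE), bonds,
                 coords = matrix(stats::rnorm(3 * n, sd = 2), n, 3L),
                 name = paste0("rnd", seed))
}

# manual reimplementation of the adaptive-scaling gate (oracle)
adaptive_scale_of <- function(m, h, prefix) {
  p <- m$params
  pooled <- matrix(colMeans(h), 1L)
  z1 <- pmax(sweep(pooled %*% p[[paste0(prefix, ".ads.l1.W")]], 2L,
                   -p[[paste0(prefix, ".ads.l1.b")]][1L, ]), 0)
  z2 <- sweep(z1 %*% p[[paste0(prefix, ".ads.l2.W")]], 2L,
              -p[[paste0(prefix, ".ads.l2.b")]][1L, ])
  as.vector(2 / (1 + exp(-z2)))
}

# edge-set helpers over the package internals
edge_set2 <- function(...) confdiff:::edge_set(...)
n_edges2 <- function(es) nrow(es$pairs)

# collapse a directed edge set into named undirected types ("i-j" with i<j);
# fails if the two directions disagree
undirected_types <- function(es) {
  if (nrow(es$pairs) == 0L) return(stats::setNames(integer(0), character(0)))
  key <- paste0(pmin(es$pairs[, 1L], es$pairs[, 2L]), "-",
                pmax(es$pairs[, 1L], es$pairs[, 2L]))
  out <- tapply(es$types, key, function(tt) {
    stopifnot(length(unique(tt)) == 1L, length(tt) == 2L)
    tt[1L]
  })
  stats::setNames(as.integer(out), names(out))
}

# independent breadth-first shortest-path distances (oracle for hop typing)
bfs_distances <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i) {
    c(bonds$j[bonds$i == i], bonds$i[bonds$j == i])
  })
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (d[s, v] > d[s, u] + 1) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}
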