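# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the burst oracle enumerates candidate index
# windows set-wise; the Sholl oracle solves the sphere-segment quadratic.

# All maximal runs satisfying "every ISI < isi_max and span <= max_span",
# resolved left to right, by exhaustive candidate enumeration.
burst_oracle <- function(t, isi_max = 0.080, max_span = 0.160) {
  n <- length(t)
  isi <- diff(t)
  # candidate set C = {(i, j): every ISI in i..j below threshold and
  # span within the cap}; checked via the prefix maximum, not a scan
  valid_j <- function(i) {
    if (i >= n) return(integer(0))
    js <- (i + 1L):n
    ok <- cummax(isi[i:(n - 1L)]) < isi_max & (t[js] - t[i]) <= max_span
    js[ok]
  }
  res <- list()
  cur <- 1L
  while (cur < n) {
    advanced <- FALSE
    for (i in cur:(n - 1L)) {
      vj <- valid_j(i)
      if (length(vj)) {
        j <- max(vj)
        res[[length(res) + 1L]] <- i:j
        cur <- j + 1L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }
  res
}

# number of intersections of the sphere |p| = r (centered on the soma)
# with the segment p1 -> p2, counting tangency once and a boundary
# endpoint as a crossing
sphere_segment_crossings <- function(p1, p2, r, tol = 1e-9) {
  d <- p2 - p1
  a <- sum(d * d)
  b <- 2 * sum(p1 * d)
  cc <- sum(p1 * p1) - r^2
  if (a == 0) return(0L)
  disc <- b^2 - 4 * a * cc
  if (disc < -tol) return(0L)
  disc <- max(disc, 0)
  s <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  s <- unique(round(s, 12))
  sum(s >= -tol & s <= 1 + tol)
}

sholl_oracle <- function(m, r0 = 20, step = 20) {
  nd <- m$nodes
  root <- which(nd$parent_id == -1)
  soma <- c(nd$x[root], nd$y[root], nd$z[root])
  dmax <- max(sqrt((nd$x - soma[1])^2 + (nd$y - soma[2])^2 +
                     (nd$z - soma[3])^2))
  if (dmax < r0) return(integer(0))
  radii <- seq(r0, dmax, by = step)
  child <- which(nd$parent_id != -1 & nd$type == 3L)
  parent <- match(nd$parent_id[child], nd$id)
  vapply(radii, function(r) {
    tot <- 0L
    for (k in seq_along(child)) {
      p1 <- c(nd$x[parent[k]], nd$y[parent[k]], nd$z[parent[k]]) - soma
      p2 <- c(nd$x[child[k]], nd$y[child[k]], nd$z[child[k]]) - soma
      tot <- tot + sphere_segment_crossings(p1, p2, r)
    }
    tot
  }, integer(1))
}

# brute-force total cable length of a morphology
tree_length_oracle <- function(m) {
  nd <- m$nodes
  child <- which(nd$parent_id != -1)
  parent <- match(nd$parent_id[child], nd$id)
  sum(sqrt((nd$x[child] - nd$x[parent])^2 +
             (nd$y[child] - nd$y[parent])^2 +
             (nd$z[child] - nd$z[parent])^2))
}

# random spike train with a mix of short and long ISIs (seconds)
random_mixed_train <- function(n_max = 50L) {
  n <- sample(2:n_max, 1)
  isis <- sample(c(stats::rexp(n, 1 / 0.03), stats::rexp(n, 1 / 0.3)), n)
  cumsum(isis)
}
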