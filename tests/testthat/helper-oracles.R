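# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: betweenness by exhaustive simple-path enumeration,
# partial correlation by explicit normal equations, eigenvector by a dense
# eigendecomposition.

# all-pairs betweenness by enumerating every simple path and fractionally
# crediting interior nodes of the minimum-length ones
brute_betweenness <- function(w, distance = c("inverse", "neglog"), tol = 1e-12) {
  distance <- match.arg(distance)
  n <- nrow(w)
  pos <- w > 0
  len <- matrix(Inf, n, n)
  len[pos] <- if (distance == "inverse") 1 / w[pos] else -log(w[pos])
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      best <- Inf
      minpaths <- list()
      rec <- function(node, visited, acc) {
        if (acc > best + tol) return()
        if (node == t) {
          if (acc < best - tol) {
            best <<- acc
            minpaths <<- list(visited)
          } else {
            minpaths[[length(minpaths) + 1L]] <<- visited
          }
          return()
        }
        for (nxt in which(pos[node, ])) {
          if (!(nxt %in% visited)) rec(nxt, c(visited, nxt), acc + len[node, nxt])
        }
      }
      rec(s, s, 0)
      if (length(minpaths)) {
        # a late shorter path may leave stale equal-to-old-best entries; refilter
        plens <- vapply(minpaths, function(p) {
          sum(len[cbind(p[-length(p)], p[-1])])
        }, numeric(1))
        minpaths <- minpaths[plens <= best + tol]
        for (p in minpaths) {
          interior <- p[-c(1, length(p))]
          btw[interior] <- btw[interior] + 1 / length(minpaths)
        }
      }
    }
  }
  stats::setNames(btw, rownames(w))
}

# rank, project out the covariate design with explicit normal equations,
# then correlate the residuals
oracle_partial_spearman <- function(x, y, design) {
  rx <- rank(x)
  ry <- rank(y)
  beta_x <- solve(t(design) %*% design, t(design) %*% rx)
  beta_y <- solve(t(design) %*% design, t(design) %*% ry)
  ex <- rx - design %*% beta_x
  ey <- ry - design %*% beta_y
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

oracle_eigen <- function(w) {
  es <- eigen(w, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  stats::setNames(v, rownames(w))
}

# random symmetric weighted graph; dyadic weights make shortest-path lengths
# exact in binary so tie detection agrees across implementations
random_graph <- function(n, p = 0.5, dyadic = FALSE) {
  w <- matrix(0, n, n)
  pick <- function(k) {
    if (dyadic) sample(c(0.125, 0.25, 0.5, 1), k, replace = TRUE)
    else runif(k, 0.1, 1)
  }
  up <- upper.tri(w)
  sel <- up & matrix(runif(n * n) < p, n, n)
  w[sel] <- pick(sum(sel))
  w <- w + t(w)
  rownames(w) <- colnames(w) <- paste0("r", seq_len(n))
  w
}

# tiny helper: a cohort table built directly, bypassing the simulator
toy_cohort <- function(n_hc = 10, n_ibs = 12, seed = 1) {
  withr::with_seed(seed, {
    n <- n_hc + n_ibs
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n)),
      group = rep(c("HC", "IBS"), c(n_hc, n_ibs)),
      age = round(runif(n, 20, 60), 1),
      sex = rbinom(n, 1, 0.5),
      g1 = runif(n, 0, 0.2), g2 = runif(n, 0, 0.2),
      b1 = rnorm(n), b2 = rnorm(n),
      p1 = rnorm(n, 50, 10), p2 = rnorm(n, 5, 2)
    ) |>
      tripnet::cohort_table(c(g1 = "microbe", g2 = "microbe",
                              b1 = "brain", b2 = "brain",
                              p1 = "phenotype", p2 = "phenotype"))
  })
}
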