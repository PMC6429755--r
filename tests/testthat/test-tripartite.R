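test_that("partial Spearman reduces to plain Spearman without covariates", {
  expect_equal(partial_spearman(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_equal(partial_spearman(1:5, exp(-(1:5)))$r, -1)
  withr::with_seed(1, {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(partial_spearman(x, y)$r, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  })
})

test_that("partial Spearman matches the explicit normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  cv <- c(1, 1, 2, 2, 3, 3)
  got <- partial_spearman(x, y, covariates = cbind(cv))
  D <- cbind(1, cv)
  expect_equal(got$r, oracle_partial_spearman(x, y, D), tolerance = 1e-10)
  expect_equal(got$df, 6 - 2 - 1)

  withr::with_seed(42, {
    for (i in 1:60) {
      n <- sample(10:30, 1)
      x <- rnorm(n); y <- rnorm(n)
      D <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
      got <- partial_spearman(x, y, covariates = D)
      expect_equal(got$r, oracle_partial_spearman(x, y, D), tolerance = 1e-10)
    }
  })
})

test_that("partial Spearman handles ties, NAs, and degenerate input", {
  x <- c(1, 1, 2, 2, 3, 3, NA)
  y <- c(2, 2, 3, 1, 5, 4, 9)
  got <- partial_spearman(x, y)
  expect_equal(got$n, 6)
  expect_equal(got$r, cor(x[1:6], y[1:6], method = "spearman"), tolerance = 1e-12)
  # zero variance after ranking
  expect_true(is.na(partial_spearman(rep(1, 10), rnorm(10))$r))
})

test_that("the Fisher r-to-z difference test follows the closed form", {
  id <- fisher_z_difference(0.4, 30, 0.4, 50)
  expect_equal(id$z_diff, 0)
  expect_equal(id$p_diff, 1)

  ex <- fisher_z_difference(r_hc = 0, n_hc = 21, r_ibs = 0.5, n_ibs = 65)
  expect_equal(ex$z_diff, 2.0516, tolerance = 1e-3)
  expect_equal(ex$z_diff, atanh(0.5) / sqrt(1 / 62 + 1 / 18), tolerance = 1e-12)
  expect_gt(ex$z_diff, 0)  # IBS > HC is positive

  # swapping groups negates z, p unchanged
  sw <- fisher_z_difference(r_hc = 0.5, n_hc = 65, r_ibs = 0, n_ibs = 21)
  expect_equal(sw$z_diff, -ex$z_diff)
  expect_equal(sw$p_diff, ex$p_diff)

  expect_error(fisher_z_difference(1, 30, 0.2, 30), "infinite")
  expect_error(fisher_z_difference(0.5, 3, 0.2, 30), "n > 3")
})

test_that("correlate_all enumerates exactly the pairs the policy allows", {
  co <- toy_cohort()
  e_mp <- correlate_all(co, policy = block_pair_policy("microbe-phenotype"))
  expect_equal(nrow(e_mp), 4)  # 2 genera x 2 phenotypes
  expect_true(all(e_mp$block_a == "microbe" & e_mp$block_b == "phenotype"))

  e <- correlate_all(co)
  pair_type <- tibble::tibble(a = e$block_a, b = e$block_b)
  expect_false(any(pair_type$a == "brain" & pair_type$b == "brain"))
  expect_false(any(pair_type$a == "phenotype" & pair_type$b == "phenotype"))
  # 1 microbe-microbe + 4 microbe-brain + 4 microbe-phenotype + 4 brain-phenotype
  expect_equal(nrow(e), 13)
  expect_error(block_pair_policy("microbe-plasma"), "not a valid block pair")
})

test_that("edge statistics agree with per-pair recomputation, with and without NAs", {
  co <- toy_cohort(seed = 9)
  co$b1[c(2, 15)] <- NA  # force the pairwise-complete path
  e <- correlate_all(co)
  design_of <- function(grp, keep) covariate_design(co[co$group == grp, ][keep, ])
  for (i in seq_len(nrow(e))) {
    for (grp in c("HC", "IBS")) {
      rows <- co[co$group == grp, ]
      x <- rows[[e$var_a[i]]]; y <- rows[[e$var_b[i]]]
      ref <- partial_spearman(x, y, covariates = covariate_design(rows))
      suffix <- if (grp == "HC") "_hc" else "_ibs"
      expect_equal(e[[paste0("r", suffix)]][i], ref$r, tolerance = 1e-10)
      expect_equal(e[[paste0("n", suffix)]][i], ref$n)
      expect_equal(e[[paste0("p", suffix)]][i], ref$p_value, tolerance = 1e-10)
    }
    ref_z <- fisher_z_difference(e$r_hc[i], e$n_hc[i], e$r_ibs[i], e$n_ibs[i])
    expect_equal(e$z_diff[i], ref_z$z_diff, tolerance = 1e-12)
    expect_equal(e$direction[i], sign(e$z_diff[i]))
  }
})

test_that("results are invariant under strictly monotone transforms", {
  co <- toy_cohort(seed = 4)
  e1 <- correlate_all(co)
  co2 <- co
  co2$p1 <- exp(co2$p1 / 20)
  co2$g1 <- co2$g1^3
  co2 <- cohort_table(co2, var_blocks(co))
  e2 <- correlate_all(co2)
  expect_equal(e1$r_hc, e2$r_hc, tolerance = 1e-12)
  expect_equal(e1$z_diff, e2$z_diff, tolerance = 1e-12)
  expect_equal(e1$p_diff, e2$p_diff, tolerance = 1e-12)
})

test_that("relabelling the groups negates every z and keeps the difference set", {
  co <- toy_cohort(seed = 8)
  e1 <- correlate_all(co)
  flipped <- co
  flipped$group <- ifelse(co$group == "HC", "IBS", "HC")
  flipped <- cohort_table(flipped, var_blocks(co))
  e2 <- correlate_all(flipped)
  expect_equal(e2$z_diff, -e1$z_diff, tolerance = 1e-12)
  expect_equal(e2$p_diff, e1$p_diff, tolerance = 1e-12)
  d1 <- build_network(e1, "difference")
  d2 <- build_network(e2, "difference")
  expect_equal(d2$edges[, c("var_a", "var_b")], d1$edges[, c("var_a", "var_b")])
})

test_that("pearson flavour is exposed and differs from spearman appropriately", {
  co <- toy_cohort(seed = 3)
  ep <- correlate_all(co, method = "pearson", covariates = character(0))
  rows <- co[co$group == "HC", ]
  expect_equal(ep$r_hc[ep$var_a == "g1" & ep$var_b == "g2"],
               cor(rows$g1, rows$g2), tolerance = 1e-10)
})

test_that("network construction thresholds edges exactly", {
  edges <- tibble::tibble(
    var_a = paste0("m", 1:10), block_a = "microbe",
    var_b = paste0("p", 1:10), block_b = "phenotype",
    r_hc = 0.1, n_hc = 21, p_hc = seq(0.001, 0.9, length.out = 10),
    r_ibs = 0.2, n_ibs = 65, p_ibs = rev(seq(0.001, 0.9, length.out = 10)),
    z_diff = rep(c(1.5, -1.5), 5),
    p_diff = c(0.049, 0.051, 0.01, 0.2, 0.04, 0.6, 0.03, 0.5, 0.02, 0.9)
  )
  edges$direction <- sign(edges$z_diff)
  dn <- build_network(edges, "difference", alpha = 0.05)
  expect_equal(dn$edges$p_diff, edges$p_diff[edges$p_diff < 0.05])
  expect_true("m1" %in% dn$nodes$name)
  expect_false("m2" %in% dn$nodes$name)

  hc <- build_network(edges, "group-HC", alpha = 0.05)
  ibs <- build_network(edges, "group-IBS", alpha = 0.05)
  expect_equal(nrow(hc$edges), sum(edges$p_hc < 0.05))
  expect_equal(nrow(ibs$edges), sum(edges$p_ibs < 0.05))
  # an edge significant in HC only
  only_hc <- edges$var_a[edges$p_hc < 0.05 & edges$p_ibs >= 0.05]
  expect_true(all(only_hc %in% hc$edges$var_a))
  expect_false(any(only_hc %in% ibs$edges$var_a))

  # brute-force filter oracle
  expect_equal(dn$edges, edges[edges$p_diff < 0.05, , drop = FALSE])
  # BH correction shrinks (or keeps) the retained set
  dn_bh <- build_network(edges, "difference", alpha = 0.05, p_adjust = "BH")
  expect_lte(nrow(dn_bh$edges), nrow(dn$edges))
})

make_random_network <- function(seed, n_nodes = 12, n_edges = 14) {
  withr::with_seed(seed, {
    blocks <- sample(c("microbe", "brain", "phenotype"), n_nodes, replace = TRUE)
    names(blocks) <- paste0("v", seq_len(n_nodes))
    pairs <- t(utils::combn(names(blocks), 2))
    pick <- sample(nrow(pairs), n_edges)
    edges <- tibble::tibble(
      var_a = pairs[pick, 1], block_a = unname(blocks[pairs[pick, 1]]),
      var_b = pairs[pick, 2], block_b = unname(blocks[pairs[pick, 2]]),
      r_hc = runif(n_edges, -1, 1), n_hc = 21, p_hc = runif(n_edges),
      r_ibs = runif(n_edges, -1, 1), n_ibs = 65, p_ibs = runif(n_edges),
      z_diff = rnorm(n_edges), p_diff = runif(n_edges, 0, 0.04)
    )
    edges$direction <- sign(edges$z_diff)
    build_network(edges, "difference", alpha = 0.05)
  })
}

test_that("subnetwork extraction is the induced first-neighbour subgraph", {
  # star centred on the focus: subnetwork is the whole star
  star <- tibble::tibble(
    var_a = "genus", block_a = "microbe",
    var_b = c("b1", "b2", "p1"), block_b = c("brain", "brain", "phenotype"),
    r_hc = .5, n_hc = 21, p_hc = .01, r_ibs = 0, n_ibs = 65, p_ibs = .5,
    z_diff = -2.2, p_diff = .02, direction = -1
  )
  net <- build_network(star, "difference")
  sub <- extract_subnetwork(net, "genus")
  expect_equal(nrow(sub$edges), 3)

  # neighbour-neighbour edge retained by the induced rule
  tri <- dplyr::bind_rows(
    star[1, ],
    tibble::tibble(var_a = "b1", block_a = "brain", var_b = "p9",
                   block_b = "phenotype", r_hc = .6, n_hc = 21, p_hc = .01,
                   r_ibs = 0, n_ibs = 65, p_ibs = .6, z_diff = -2.5,
                   p_diff = .01, direction = -1),
    tibble::tibble(var_a = "p9", block_a = "phenotype", var_b = "genus",
                   block_b = "microbe", r_hc = .7, n_hc = 21, p_hc = .01,
                   r_ibs = 0, n_ibs = 65, p_ibs = .7, z_diff = -2.9,
                   p_diff = .004, direction = -1)
  )
  netx <- build_network(tri, "difference")
  subx <- extract_subnetwork(netx, "genus")
  expect_true(any(subx$edges$var_a == "b1" & subx$edges$var_b == "p9"))

  expect_error(extract_subnetwork(net, "absent"), "not in the network")

  # brute-force neighbourhood + induced-edge oracle on random networks
  for (s in 1:8) {
    net <- make_random_network(s)
    if (!nrow(net$nodes)) next
    focus <- net$nodes$name[1]
    sub <- extract_subnetwork(net, focus)
    e <- net$edges
    nbrs <- unique(c(e$var_b[e$var_a == focus], e$var_a[e$var_b == focus]))
    keep <- c(focus, nbrs)
    oracle <- e[e$var_a %in% keep & e$var_b %in% keep, ]
    expect_equal(sub$edges, oracle)
    # incident mode keeps a superset
    inc <- extract_subnetwork(net, focus, mode = "incident")
    expect_gte(nrow(inc$edges), nrow(sub$edges))
  }
})

test_that("direct and indirect associations are classified topologically", {
  mk <- function(a, ba, b, bb) {
    tibble::tibble(var_a = a, block_a = ba, var_b = b, block_b = bb,
                   r_hc = .6, n_hc = 21, p_hc = .01, r_ibs = 0, n_ibs = 65,
                   p_ibs = .9, z_diff = -2.4, p_diff = .015, direction = -1)
  }
  # genus - B1 - PainThresh chain: one direct edge, one indirect path
  chain <- dplyr::bind_rows(mk("genus", "microbe", "B1", "brain"),
                            mk("B1", "brain", "PainThresh", "phenotype"))
  net <- build_network(chain, "difference")
  cls <- classify_associations(extract_subnetwork(net, "genus", mode = "incident"))
  expect_equal(nrow(cls$direct), 1)
  expect_equal(cls$indirect,
               tibble::tibble(genus = "genus", brain = "B1",
                              phenotype = "PainThresh"))

  # direct genus-phenotype edge only: no indirect path
  only <- mk("genus", "microbe", "PainThresh", "phenotype")
  cls2 <- classify_associations(extract_subnetwork(build_network(only, "difference"),
                                                   "genus"))
  expect_equal(nrow(cls2$direct), 1)
  expect_equal(nrow(cls2$indirect), 0)

  # a phenotype also directly linked to the genus is not indirect
  both <- dplyr::bind_rows(chain, mk("genus", "microbe", "PainThresh", "phenotype"))
  cls3 <- classify_associations(extract_subnetwork(build_network(both, "difference"),
                                                   "genus", mode = "incident"))
  expect_equal(nrow(cls3$indirect), 0)
  # an induced first-neighbour subnetwork cannot carry two-step paths
  cls_ind <- classify_associations(extract_subnetwork(net, "genus"))
  expect_equal(nrow(cls_ind$indirect), 0)

  # oracle: exhaustive 2-path enumeration on random subnetworks
  for (s in 11:16) {
    net <- make_random_network(s, n_nodes = 10, n_edges = 16)
    genera <- net$nodes$name[net$nodes$block == "microbe"]
    if (!length(genera)) next
    focus <- genera[1]
    sub <- extract_subnetwork(net, focus, mode = "incident")
    cls <- classify_associations(sub)
    e <- sub$edges
    adj <- function(a, b) any((e$var_a == a & e$var_b == b) |
                                (e$var_a == b & e$var_b == a))
    block_of <- setNames(sub$nodes$block, sub$nodes$name)
    expected <- list()
    for (b in sub$nodes$name[sub$nodes$block == "brain"]) {
      if (!adj(focus, b)) next
      for (p in sub$nodes$name[sub$nodes$block == "phenotype"]) {
        if (adj(b, p) && !adj(focus, p)) {
          expected[[length(expected) + 1]] <- paste(b, p)
        }
      }
    }
    got <- paste(cls$indirect$brain, cls$indirect$phenotype)
    expect_setequal(got, as.character(unlist(expected)))
    expect_true(all(cls$direct$var_a == focus | cls$direct$var_b == focus))
  }
})

test_that("analytic difference power is sane and monotone", {
  # equal correlations: power collapses to the test's size, which sits a
  # little above alpha (variance inflation of adjusted rank correlations)
  size <- analytic_difference_power(0.3, 0.3)
  expect_gt(size, 0.05)
  expect_lt(size, 0.08)
  p <- vapply(c(0.3, 0.5, 0.7), function(d) analytic_difference_power(d, 0),
              numeric(1))
  expect_true(all(diff(p) > 0))
  # pearson flavour: no attenuation, so more power at the same latent rho
  expect_gt(analytic_difference_power(0.7, 0, method = "pearson"),
            analytic_difference_power(0.7, 0, method = "spearman"))
})
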