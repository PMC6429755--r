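test_that("negative weights are zeroed and the diagonal cleared", {
  cm <- connectivity_matrix(matrix(c(1, .5, -.2, .5, 1, .3, -.2, .3, 1), 3),
                            c("a", "b", "c"))
  g <- build_functional_network(cm)
  expect_equal(g["a", "b"], 0.5)
  expect_equal(g["b", "c"], 0.3)
  expect_equal(g["a", "c"], 0)
  expect_equal(diag(unclass(g)), c(a = 0, b = 0, c = 0))

  # all-nonnegative input unchanged except the diagonal
  w <- matrix(c(1, .4, .4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  g2 <- build_functional_network(connectivity_matrix(w))
  expect_equal(g2["x", "y"], 0.4)
  expect_equal(diag(unclass(g2)), c(x = 0, y = 0))

  # all-negative off-diagonals: empty graph
  w3 <- matrix(c(1, -.4, -.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_true(all(unclass(build_functional_network(connectivity_matrix(w3))) == 0))
})

test_that("connectivity validation names the first offending cell", {
  w <- matrix(c(1, .5, .2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(connectivity_matrix(w), "not symmetric")
  w2 <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(connectivity_matrix(w2), "out of range")
  expect_error(connectivity_matrix(matrix(1, 2, 3)), "square")
  w4 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "a"), c("a", "a")))
  expect_error(connectivity_matrix(w4), "unique")
})

test_that("degree strength equals row sums of positive weights", {
  # path a - b - c with weights .5 and .3
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w["a", "b"] <- w["b", "a"] <- .5
  w["b", "c"] <- w["c", "b"] <- .3
  diag(w) <- 1
  g <- build_functional_network(connectivity_matrix(w))
  expect_equal(degree_strength(g), c(a = .5, b = .8, c = .3))

  # empty graph
  e <- build_functional_network(connectivity_matrix(diag(3), c("a", "b", "c")))
  expect_equal(degree_strength(e), c(a = 0, b = 0, c = 0))

  # random graph: row-sum oracle, and the zero-negatives identity
  withr::with_seed(10, {
    for (i in 1:10) {
      w <- random_graph(6)
      signs <- matrix(sample(c(-1, 1), 36, TRUE), 6)
      signs <- signs * t(signs)  # symmetric sign flips
      wc <- w * signs
      diag(wc) <- 1
      g <- build_functional_network(connectivity_matrix(wc))
      expect_equal(degree_strength(g), rowSums(unclass(g)), tolerance = 1e-12)
      pos_only <- wc; pos_only[pos_only < 0] <- 0; diag(pos_only) <- 0
      expect_equal(degree_strength(g), rowSums(pos_only), tolerance = 1e-12)
    }
  })
})

test_that("betweenness matches exhaustive path enumeration, including ties", {
  # 4-leaf star: center routes all 6 leaf pairs
  w <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  w[1, 2:5] <- w[2:5, 1] <- 0.5
  diag(w) <- 1
  b <- betweenness_centrality(build_functional_network(connectivity_matrix(w)))
  expect_equal(unname(b), c(6, 0, 0, 0, 0))

  # triangle: direct edges always shortest
  tw <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tw) <- 1
  expect_equal(unname(betweenness_centrality(connectivity_matrix(tw))), c(0, 0, 0))

  # explicit tie: two equal-length 2-hop routes split 1/2 each
  tie <- matrix(0, 4, 4, dimnames = list(c("s", "a", "b", "t"), c("s", "a", "b", "t")))
  tie["s", "a"] <- tie["a", "t"] <- tie["s", "b"] <- tie["b", "t"] <- 0.5
  tie <- tie + t(tie); diag(tie) <- 1
  bt <- betweenness_centrality(build_functional_network(connectivity_matrix(tie)))
  expect_equal(bt[["a"]], 0.5)
  expect_equal(bt[["b"]], 0.5)
  expect_equal(bt, brute_betweenness(build_functional_network(connectivity_matrix(tie))))

  # property: dyadic weights give exactly representable inverse lengths, so
  # tie splits are compared exactly; continuous weights (no ties a.s.) cover
  # both distance transforms
  withr::with_seed(33, {
    for (i in 1:20) {
      n <- sample(4:7, 1)
      w <- random_graph(n, p = 0.5, dyadic = TRUE)
      g <- structure(w, class = c("trip_brain_graph", "matrix", "array"))
      expect_equal(betweenness_centrality(g, distance = "inverse"),
                   brute_betweenness(w, distance = "inverse"), tolerance = 1e-9)
    }
    for (i in 1:10) {
      n <- sample(4:7, 1)
      w <- random_graph(n, p = 0.5)
      g <- structure(w, class = c("trip_brain_graph", "matrix", "array"))
      for (d in c("inverse", "neglog")) {
        expect_equal(betweenness_centrality(g, distance = d),
                     brute_betweenness(w, distance = d), tolerance = 1e-9)
      }
    }
  })
})

test_that("betweenness normalization scales by 2/((n-1)(n-2))", {
  withr::with_seed(2, {
    w <- random_graph(6)
    g <- structure(w, class = c("trip_brain_graph", "matrix", "array"))
    expect_equal(betweenness_centrality(g, normalized = TRUE),
                 betweenness_centrality(g) * 2 / (5 * 4))
  })
})

test_that("eigenvector centrality matches a dense eigensolver", {
  # two nodes, one edge: both 1/sqrt(2)
  w <- matrix(c(0, .7, .7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- structure(w, class = c("trip_brain_graph", "matrix", "array"))
  expect_equal(unname(eigenvector_centrality(g)), rep(1 / sqrt(2), 2))

  # star: center strictly dominant, leaves equal
  s <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  s[1, 2:5] <- s[2:5, 1] <- 0.5
  gs <- structure(s, class = c("trip_brain_graph", "matrix", "array"))
  ev <- eigenvector_centrality(gs)
  expect_gt(ev[[1]], max(ev[-1]))
  expect_equal(stats::sd(ev[-1]), 0, tolerance = 1e-10)

  withr::with_seed(77, {
    for (i in 1:15) {
      w <- random_graph(5, p = 0.8)
      g <- structure(w, class = c("trip_brain_graph", "matrix", "array"))
      expect_equal(eigenvector_centrality(g), oracle_eigen(w), tolerance = 1e-8)
      # invariance under uniform rescaling of the weights
      g4 <- structure(w * 0.25, class = c("trip_brain_graph", "matrix", "array"))
      expect_equal(eigenvector_centrality(g4), eigenvector_centrality(g),
                   tolerance = 1e-8)
    }
  })

  zero <- structure(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                    class = c("trip_brain_graph", "matrix", "array"))
  expect_error(eigenvector_centrality(zero), "no edges")
})

test_that("permuting region order permutes all centralities consistently", {
  withr::with_seed(14, {
    w <- random_graph(6)
    diag(w) <- 1
    perm <- sample(6)
    cm1 <- connectivity_matrix(w)
    cm2 <- connectivity_matrix(w[perm, perm])
    for (f in list(degree_strength, betweenness_centrality, eigenvector_centrality)) {
      v1 <- f(build_functional_network(cm1))
      v2 <- f(build_functional_network(cm2))
      expect_equal(v2, v1[rownames(w)[perm]], tolerance = 1e-10)
    }
  })
})

test_that("the centrality table labels, restricts, and recomputes correctly", {
  withr::with_seed(5, {
    labels <- c("Pu_L", "Pu_R", "CaN_L", "CaN_R")
    mats <- lapply(1:10, function(i) {
      w <- random_graph(4, p = 0.9)
      diag(w) <- 1
      connectivity_matrix(w, labels)
    })
    names(mats) <- sprintf("s%02d", 1:10)

    tab <- centrality_table(mats, roi = c("Pu", "CaN"))
    expect_equal(nrow(tab), 10)
    expect_equal(ncol(tab), 1 + 3 * 4)  # 3 metrics x 4 lateralised regions
    expect_true(all(c("S_L_Pu", "B_R_CaN", "E_L_CaN") %in% names(tab)))

    # restriction happens after whole-graph computation
    sub <- centrality_table(mats, roi = "Pu")
    expect_equal(ncol(sub), 1 + 3 * 2)
    expect_equal(sub$S_L_Pu, tab$S_L_Pu)
    expect_equal(sub$B_R_Pu, tab$B_R_Pu)

    # per-subject independent recomputation
    for (i in c(1, 7)) {
      g <- build_functional_network(mats[[i]])
      expect_equal(tab$S_L_Pu[i], degree_strength(g)[["Pu_L"]])
      expect_equal(tab$B_R_CaN[i], betweenness_centrality(g)[["CaN_R"]])
      expect_equal(tab$E_L_CaN[i], eigenvector_centrality(g)[["CaN_L"]])
    }

    expect_error(centrality_table(mats, roi = c("Pu", "Tha")), "Tha")
    # mismatched label order across subjects
    bad <- mats
    bad[[2]] <- connectivity_matrix(unclass(bad[[2]]), rev(labels))
    expect_error(centrality_table(bad, roi = "Pu"), "same region label ordering")
  })
})

test_that("centrality labels parse and render round-trip", {
  lab <- centrality_label(c("S", "B", "E"), c("L", "R", NA), c("Pu", "SbCG_S", "Tha"))
  expect_equal(lab, c("S_L_Pu", "B_R_SbCG_S", "E_Tha"))
  parsed <- parse_centrality_label(lab)
  expect_equal(parsed$metric, c("S", "B", "E"))
  expect_equal(parsed$laterality, c("L", "R", NA))
  expect_equal(parsed$region, c("Pu", "SbCG_S", "Tha"))
  expect_error(centrality_label("Q", "L", "Pu"), "unknown")
  expect_error(parse_centrality_label("nope"), "X_Y_Z")
})
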