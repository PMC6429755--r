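#' Region-by-region connectivity matrix
#'
#' A validated square symmetric matrix of correlation weights in \[-1, 1\]
#' with unique region labels, as produced by region-to-region functional
#' connectivity analysis.
#'
#' @param weights Square numeric matrix.
#' @param region_labels Character vector of unique labels, one per row;
#'   defaults to the matrix dimnames.
#' @param tol Symmetry tolerance.
#' @return A `trip_connectivity` matrix with region labels as dimnames.
#' @export
#' @examples
#' cm <- connectivity_matrix(diag(3), c("a", "b", "c"))
connectivity_matrix <- function(weights, region_labels = rownames(weights), tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) abort("connectivity matrix must be square")
  if (is.null(region_labels)) abort("region labels are required")
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(weights)) {
    abort("label list length must equal the matrix dimension")
  }
  if (anyDuplicated(region_labels)) abort("region labels must be unique")
  asym <- abs(weights - t(weights))
  if (any(asym > tol)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort(sprintf("matrix not symmetric: weights[%d,%d] = %.6g but weights[%d,%d] = %.6g",
                  idx[1], idx[2], weights[idx[1], idx[2]],
                  idx[2], idx[1], weights[idx[2], idx[1]]))
  }
  out_of_range <- which(abs(weights) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1, ]
    abort(sprintf("entry out of range [-1, 1]: weights[%d,%d] = %.6g",
                  i[1], i[2], weights[i[1], i[2]]))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(weights, class = c("trip_connectivity", "matrix", "array"))
}

#' Build the functional brain graph from a connectivity matrix
#'
#' Negative correlation weights are set to zero and the diagonal is zeroed,
#' yielding a weighted undirected graph with non-negative edge weights.
#'
#' @param cm A [connectivity_matrix()] (or a plain labelled symmetric matrix).
#' @return A `trip_brain_graph` matrix: symmetric, non-negative, zero
#'   diagonal, labels preserved.
#' @export
#' @examples
#' cm <- connectivity_matrix(matrix(c(1, .5, -.2, .5, 1, .3, -.2, .3, 1), 3),
#'                           c("a", "b", "c"))
#' build_functional_network(cm)
build_functional_network <- function(cm) {
  if (!inherits(cm, "trip_connectivity")) cm <- connectivity_matrix(cm)
  w <- unclass(cm)
  w[w < 0] <- 0
  diag(w) <- 0
  structure(w, class = c("trip_brain_graph", "matrix", "array"))
}

as_brain_graph <- function(g) {
  if (inherits(g, "trip_brain_graph")) return(g)
  build_functional_network(g)
}

brain_igraph <- function(g, distance = c("inverse", "neglog")) {
  distance <- match.arg(distance)
  ig <- igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  w <- igraph::E(ig)$weight
  igraph::E(ig)$length <- switch(distance, inverse = 1 / w, neglog = -log(w))
  ig
}

#' Regional centrality measures of a weighted brain graph
#'
#' `degree_strength()` is the sum of a region's edge weights.
#' `betweenness_centrality()` is weighted shortest-path betweenness with edge
#' lengths `1/w` (or `-log(w)`), fractional counting over tied shortest
#' paths, reported as raw unordered source-target pair counts (optionally
#' normalised by `2 / ((n-1)(n-2))`). `eigenvector_centrality()` is the
#' principal eigenvector of the non-negative weight matrix, computed by
#' shifted power iteration, scaled to unit Euclidean norm with the
#' largest-magnitude entry positive.
#'
#' @param g A `trip_brain_graph` (a [connectivity_matrix()] is accepted and
#'   passed through [build_functional_network()] first).
#' @return A named numeric vector, one value per region.
#' @export
#' @examples
#' g <- build_functional_network(
#'   connectivity_matrix(matrix(c(1, .5, 0, .5, 1, .3, 0, .3, 1), 3),
#'                       c("a", "b", "c")))
#' degree_strength(g)
degree_strength <- function(g) {
  g <- as_brain_graph(g)
  rowSums(unclass(g))
}

#' @rdname degree_strength
#' @param distance Edge length transform for shortest paths: `"inverse"`
#'   (`1/w`, default) or `"neglog"` (`-log(w)`).
#' @param normalized If `TRUE`, scale counts by `2 / ((n-1)(n-2))`.
#' @export
betweenness_centrality <- function(g, distance = c("inverse", "neglog"),
                                   normalized = FALSE) {
  g <- as_brain_graph(g)
  n <- nrow(g)
  if (n < 3) abort("betweenness requires at least 3 regions")
  ig <- brain_igraph(g, distance)
  b <- igraph::betweenness(ig, weights = igraph::E(ig)$length, directed = FALSE,
                           normalized = FALSE)
  out <- setNames(numeric(n), rownames(g))
  out[names(b)] <- b
  if (normalized) out <- out * 2 / ((n - 1) * (n - 2))
  out
}

#' @rdname degree_strength
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Maximal number of power iterations.
#' @export
eigenvector_centrality <- function(g, tol = 1e-14, max_iter = 10000L) {
  g <- as_brain_graph(g)
  w <- unclass(g)
  if (all(w == 0)) abort("no edges: eigenvector centrality undefined")
  n <- nrow(w)
  # shift guarantees the dominant eigenvalue is the (unique-sign) largest in
  # magnitude, so iteration cannot oscillate on bipartite components
  shift <- 1
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    u <- as.vector(w %*% v) + shift * v
    u <- u / sqrt(sum(u^2))
    if (max(abs(u - v)) < tol) { v <- u; break }
    v <- u
  }
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  setNames(v, rownames(w))
}

#' Per-subject centrality feature table
#'
#' Computes all three centrality metrics on each subject's whole functional
#' graph, then restricts to the regions of interest, labelling features
#' `X_Y_Z` (metric, laterality, region). Matrix region labels are expected as
#' `<abbreviation>_L` / `<abbreviation>_R` (or a bare abbreviation for
#' midline structures).
#'
#' @param matrices A (preferably named) list of [connectivity_matrix()]
#'   objects sharing one label ordering, or a single matrix.
#' @param roi A tibble with column `abbreviation` ([roi_table()] by default);
#'   a character vector of abbreviations is also accepted.
#' @param distance,normalized Passed to [betweenness_centrality()].
#' @return A tibble: `subject_id` plus one column per `X_Y_Z` feature.
#' @export
#' @examples
#' cfg <- simulation_config(n_regions = 8, seed = 1)
#' stack <- simulate_connectivity_stack(cfg, n_subjects = 3)
#' centrality_table(stack, roi = c("PosCG", "PosCS"))
centrality_table <- function(matrices, roi = roi_table(),
                             distance = c("inverse", "neglog"),
                             normalized = FALSE) {
  if (inherits(matrices, "trip_connectivity")) matrices <- list(matrices)
  if (!length(matrices)) abort("no connectivity matrices supplied")
  abbrs <- if (is.data.frame(roi)) roi$abbreviation else as.character(roi)
  labels0 <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), labels0)) {
      abort("all connectivity matrices must share the same region label ordering")
    }
  }

  feat <- list_rbind(lapply(abbrs, function(a) {
    hits <- tibble(matrix_label = c(paste0(a, "_L"), paste0(a, "_R"), a),
                   laterality = c("L", "R", NA))
    hits <- hits[hits$matrix_label %in% labels0, , drop = FALSE]
    if (!nrow(hits)) return(tibble(abbreviation = a, matrix_label = NA_character_,
                                   laterality = NA_character_))
    hits$abbreviation <- a
    hits
  }))
  missing <- feat$abbreviation[is.na(feat$matrix_label)]
  if (length(missing)) {
    abort(paste0("ROI abbreviation(s) not found among matrix labels: ",
                 paste(missing, collapse = ", ")))
  }

  ids <- names(matrices) %||% sprintf("subj%03d", seq_along(matrices))
  rows <- lapply(seq_along(matrices), function(s) {
    g <- build_functional_network(matrices[[s]])
    vals <- list(S = degree_strength(g),
                 B = betweenness_centrality(g, distance = distance, normalized = normalized),
                 E = eigenvector_centrality(g))
    cols <- unlist(lapply(c("S", "B", "E"), function(m) {
      setNames(vals[[m]][feat$matrix_label],
               centrality_label(m, feat$laterality, feat$abbreviation))
    }))
    bind_cols(tibble(subject_id = ids[s]), as_tibble(as.list(cols)))
  })
  list_rbind(rows)
}
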