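#' Covariate-adjusted (partial) Spearman correlation
#'
#' Both variables are rank-transformed (average ranks for ties), residualised
#' against the covariate design (always including an intercept), and the
#' product-moment correlation of the residuals is returned. With an
#' intercept-only design this is exactly the Spearman correlation. The
#' two-sided p-value uses `t = r * sqrt(df) / sqrt(1 - r^2)` with
#' `df = n - 2 - k`, `k` the number of non-constant covariates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates A covariate data frame (passed to [covariate_design()])
#'   or a ready design matrix with intercept; `NULL` for no adjustment.
#' @param method `"spearman"` (rank transform first, default) or `"pearson"`.
#' @return A one-row tibble: `r`, `n` (pairwise-complete sample size), `df`,
#'   `statistic`, `p_value`. `r` is `NA` (with reason attribute) when a
#'   variable has zero variance after ranking.
#' @export
#' @examples
#' partial_spearman(1:5, c(2, 4, 6, 8, 10))
partial_spearman <- function(x, y, covariates = NULL, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  design <- prepare_design(covariates, length(x))
  keep <- complete.cases(x, y, design)
  res <- adjusted_cor(x[keep], y[keep], design[keep, , drop = FALSE],
                      rank_transform = method == "spearman")
  tibble(r = res$r, n = res$n, df = res$df, statistic = res$statistic,
         p_value = res$p_value)
}

prepare_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.data.frame(covariates)) return(covariate_design(covariates))
  m <- as.matrix(covariates)
  if (!any(apply(m, 2, function(col) all(col == col[1])))) m <- cbind(`(Intercept)` = 1, m)
  m
}

# core: assumes complete cases; drops constant covariate columns
adjusted_cor <- function(x, y, design, rank_transform = TRUE) {
  n <- length(x)
  const <- apply(design, 2, function(col) length(col) == 0 || var(col) == 0)
  # keep exactly one constant column as the intercept
  if (any(const)) design <- design[, c(which(const)[1], which(!const)), drop = FALSE]
  k <- ncol(design) - 1L
  out <- list(r = NA_real_, n = n, df = NA_real_, statistic = NA_real_,
              p_value = NA_real_, reason = NULL)
  if (n < k + 4) { out$reason <- "too few pairwise-complete observations"; return(out) }
  if (rank_transform) { x <- rank(x); y <- rank(y) }
  qrd <- qr(design)
  rx <- qr.resid(qrd, x)
  ry <- qr.resid(qrd, y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  if (sx < n * 1e-12 || sy < n * 1e-12) {
    out$reason <- "zero variance after ranking/adjustment"
    return(out)
  }
  r <- sum(rx * ry) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2 - k
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, n = n, df = df, statistic = tstat,
       p_value = 2 * pt(-abs(tstat), df), reason = NULL)
}

#' Fisher r-to-z test for a correlation difference between two groups
#'
#' `z_diff = (atanh(r_ibs) - atanh(r_hc)) / sqrt(1/(n_ibs - 3) + 1/(n_hc - 3))`
#' (IBS minus HC, so positive values mean the IBS correlation exceeds the HC
#' one), with a two-sided standard-normal p-value.
#'
#' @param r_hc,r_ibs Correlations with `|r| < 1`.
#' @param n_hc,n_ibs Group sample sizes, each greater than 3.
#' @return A tibble with columns `z_diff` and `p_diff` (vectorised).
#' @export
#' @examples
#' fisher_z_difference(r_hc = 0, n_hc = 21, r_ibs = 0.5, n_ibs = 65)
fisher_z_difference <- function(r_hc, n_hc, r_ibs, n_ibs) {
  if (any(abs(c(r_hc, r_ibs)) >= 1)) {
    abort("|r| = 1: Fisher transform is infinite; the difference test is undefined")
  }
  if (any(c(n_hc, n_ibs) <= 3)) abort("both groups need n > 3")
  z <- (atanh(r_ibs) - atanh(r_hc)) / sqrt(1 / (n_ibs - 3) + 1 / (n_hc - 3))
  tibble(z_diff = z, p_diff = 2 * pnorm(-abs(z)))
}

#' Block-pair correlation policy
#'
#' Which unordered block pairs are correlated. The default mirrors the
#' tripartite design: genus-genus, genus-brain, genus-phenotype and
#' brain-phenotype edges, but no brain-brain or phenotype-phenotype edges.
#'
#' @param pairs Character vector of `"blockA-blockB"` pairs (order within a
#'   pair is irrelevant).
#' @return A normalised character vector of class `trip_policy`.
#' @export
#' @examples
#' block_pair_policy(c("microbe-phenotype"))
block_pair_policy <- function(pairs = c("microbe-microbe", "microbe-brain",
                                        "microbe-phenotype", "brain-phenotype")) {
  canon <- vapply(strsplit(pairs, "-", fixed = TRUE), function(p) {
    if (length(p) != 2 || !all(p %in% c("microbe", "brain", "phenotype"))) {
      abort(paste0("not a valid block pair: '", paste(p, collapse = "-"), "'"))
    }
    paste(sort(p), collapse = "-")
  }, character(1))
  canon <- unique(canon)
  if (!length(canon)) abort("policy must allow at least one block pair")
  structure(canon, class = "trip_policy")
}

canonical_pair <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}

#' Per-group adjusted correlations and group-difference tests for all
#' allowed variable pairs
#'
#' For every variable pair allowed by the block-pair policy, computes the
#' covariate-adjusted correlation separately within the HC and IBS groups on
#' pairwise-complete cases, then the Fisher r-to-z difference test. Pairs
#' with an undefined correlation in either group (zero variance, too few
#' observations, or `|r| = 1`) are excluded and logged.
#'
#' @param table A [cohort_table()].
#' @param policy A [block_pair_policy()].
#' @param method Correlation flavour: `"spearman"` (default) or `"pearson"`.
#' @param covariates Covariate columns to adjust for (default age and sex;
#'   use `character(0)` for unadjusted correlations).
#' @param var_adjust Variance convention for the Fisher-z difference test:
#'   `"classic"` (default) uses `1/(n - 3)` per group, the textbook
#'   independent-correlations Z test; `"df_penalty"` uses `1/(n - 3 - k)`
#'   with `k` the number of covariates regressed out, which compensates for
#'   the degrees of freedom the adjustment consumes and improves the
#'   calibration of the difference test at small n.
#' @return A `trip_edges` tibble with columns `var_a`, `block_a`, `var_b`,
#'   `block_b`, `r_hc`, `n_hc`, `p_hc`, `r_ibs`, `n_ibs`, `p_ibs`, `z_diff`,
#'   `p_diff`, `direction` (`sign(z_diff)`, +1 means IBS > HC). Skipped
#'   pairs, with reasons, are in the `skipped` attribute; the correlation
#'   flavour in the `method` attribute.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 5, n_genera = 2,
#'   brain_features = default_brain_features("Pu")))
#' edges <- correlate_all(sim$cohort)
#' edges
correlate_all <- function(table, policy = block_pair_policy(),
                          method = c("spearman", "pearson"),
                          covariates = c("age", "sex"),
                          var_adjust = c("classic", "df_penalty")) {
  method <- match.arg(method)
  var_adjust <- match.arg(var_adjust)
  if (!inherits(policy, "trip_policy")) policy <- block_pair_policy(policy)
  blocks <- var_blocks(table)
  vars <- names(blocks)
  for (grp in c("HC", "IBS")) {
    n_g <- sum(table$group == grp)
    if (n_g < 8) warn(sprintf("group %s has only %d subjects: power is very limited", grp, n_g))
  }
  pair_idx <- which(outer(blocks, blocks, canonical_pair) %in% unclass(policy) &
                      upper.tri(diag(length(vars))), arr.ind = TRUE)
  pairs <- tibble(var_a = vars[pair_idx[, 1]], block_a = unname(blocks[pair_idx[, 1]]),
                  var_b = vars[pair_idx[, 2]], block_b = unname(blocks[pair_idx[, 2]]))

  per_group <- function(grp) {
    rows <- table[table$group == grp, , drop = FALSE]
    design <- if (length(covariates)) covariate_design(rows, covariates)
              else matrix(1, nrow(rows), 1)
    v <- as.matrix(rows[, vars, drop = FALSE])
    if (!anyNA(v)) {
      group_cor_fast(v, design, pair_idx, rank_transform = method == "spearman")
    } else {
      group_cor_pairwise(v, design, pair_idx, rank_transform = method == "spearman")
    }
  }
  hc <- per_group("HC")
  ibs <- per_group("IBS")
  res <- bind_cols(pairs,
                   tibble(r_hc = hc$r, n_hc = hc$n, p_hc = hc$p),
                   tibble(r_ibs = ibs$r, n_ibs = ibs$n, p_ibs = ibs$p))

  undef <- is.na(res$r_hc) | is.na(res$r_ibs) |
    abs(res$r_hc) >= 1 | abs(res$r_ibs) >= 1 |
    res$n_hc <= 3 | res$n_ibs <= 3
  skipped <- res[undef, c("var_a", "var_b", "r_hc", "n_hc", "r_ibs", "n_ibs")]
  if (nrow(skipped)) {
    skipped$reason <- dplyr::case_when(
      is.na(skipped$r_hc) | is.na(skipped$r_ibs) ~ "undefined correlation (zero variance or too few cases)",
      abs(skipped$r_hc) >= 1 | abs(skipped$r_ibs) >= 1 ~ "correlation of magnitude 1: Fisher transform infinite",
      TRUE ~ "fewer than 4 pairwise-complete cases in a group"
    )
  } else skipped$reason <- character(0)
  res <- res[!undef, , drop = FALSE]
  pen_hc <- if (var_adjust == "df_penalty") hc$k else 0
  pen_ibs <- if (var_adjust == "df_penalty") ibs$k else 0
  fz <- fisher_z_difference(res$r_hc, res$n_hc - pen_hc,
                            res$r_ibs, res$n_ibs - pen_ibs)
  res$z_diff <- fz$z_diff
  res$p_diff <- fz$p_diff
  res$direction <- sign(res$z_diff)
  structure(res, class = c("trip_edges", class(res)),
            method = method, covariates = covariates, skipped = skipped)
}

# all variables share the same complete rows: one residualisation, one
# crossproduct
group_cor_fast <- function(v, design, pair_idx, rank_transform = TRUE) {
  n <- nrow(v)
  const <- apply(design, 2, var) == 0
  if (any(const)) design <- design[, c(which(const)[1], which(!const)), drop = FALSE]
  k <- ncol(design) - 1L
  if (rank_transform) v <- apply(v, 2, rank)
  r_all <- qr.resid(qr(design), v)
  ss <- sqrt(colSums(r_all^2))
  ok <- ss > n * 1e-12
  scaled <- sweep(r_all, 2, pmax(ss, .Machine$double.eps), "/")
  cmat <- crossprod(scaled)
  r <- cmat[pair_idx]
  r[!ok[pair_idx[, 1]] | !ok[pair_idx[, 2]]] <- NA_real_
  if (n < k + 4) r[] <- NA_real_
  r <- pmax(-1, pmin(1, r))
  df <- n - 2 - k
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(r = r, n = rep(n, nrow(pair_idx)), p = 2 * pt(-abs(tstat), df), k = k)
}

group_cor_pairwise <- function(v, design, pair_idx, rank_transform = TRUE) {
  res <- lapply(seq_len(nrow(pair_idx)), function(e) {
    x <- v[, pair_idx[e, 1]]; y <- v[, pair_idx[e, 2]]
    keep <- complete.cases(x, y, design)
    adjusted_cor(x[keep], y[keep], design[keep, , drop = FALSE], rank_transform)
  })
  list(r = map_dbl(res, "r"), n = map_dbl(res, "n"), p = map_dbl(res, "p_value"),
       k = max(0, ncol(design) - 1L))
}

#' Build a group or difference network from an edge table
#'
#' The difference network keeps edges whose Fisher-z difference test is
#' significant (`p_diff < alpha`); the group networks keep edges whose
#' within-group correlation is significant (`p_hc` / `p_ibs` `< alpha`). The
#' node set is the endpoints of the retained edges.
#'
#' @param edges A `trip_edges` tibble from [correlate_all()].
#' @param kind `"difference"`, `"group-HC"`, or `"group-IBS"`.
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @param p_adjust Optional multiple-testing correction applied to the
#'   selecting p-value before thresholding (a [stats::p.adjust()] method such
#'   as `"BH"`); default `"none"`, matching an exploratory, uncorrected
#'   analysis.
#' @return A `trip_network`: list with `kind`, `alpha`, `nodes` (tibble
#'   `name`, `block`) and `edges`.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 5, n_genera = 3,
#'   brain_features = default_brain_features("Pu")))
#' net <- build_network(correlate_all(sim$cohort), kind = "difference")
#' net
build_network <- function(edges, kind = c("difference", "group-HC", "group-IBS"),
                          alpha = 0.05, p_adjust = "none") {
  kind <- match.arg(kind)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  p <- switch(kind, difference = edges$p_diff, `group-HC` = edges$p_hc,
              `group-IBS` = edges$p_ibs)
  p <- stats::p.adjust(p, method = p_adjust)
  keep <- !is.na(p) & p < alpha
  kept <- as_tibble(edges[keep, , drop = FALSE])
  nodes <- dplyr::distinct(bind_rows(
    tibble(name = kept$var_a, block = kept$block_a),
    tibble(name = kept$var_b, block = kept$block_b)
  ))
  structure(list(kind = kind, alpha = alpha, nodes = nodes, edges = kept),
            class = "trip_network")
}

#' @export
print.trip_network <- function(x, ...) {
  cat(sprintf("<trip_network: %s> alpha = %g; %d node(s), %d edge(s)\n",
              x$kind, x$alpha, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$block)
    cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

network_has_edge <- function(net, a, b) {
  any((net$edges$var_a == a & net$edges$var_b == b) |
        (net$edges$var_a == b & net$edges$var_b == a))
}

node_neighbors <- function(net, node) {
  e <- net$edges
  unique(c(e$var_b[e$var_a == node], e$var_a[e$var_b == node]))
}

#' First-neighbour subnetwork around a focus node
#'
#' Selects the focus node and its first neighbours, keeping (by default) the
#' induced subgraph: every edge of the network whose two endpoints both lie
#' in that node set, so neighbour-neighbour edges are retained.
#' `mode = "incident"` instead keeps all edges incident to any selected node,
#' importing second-order nodes.
#'
#' @param net A `trip_network`.
#' @param focus Name of a node of `net` (typically a genus).
#' @param mode `"induced"` (default) or `"incident"`.
#' @return A `trip_network` with the same kind and alpha; the focus is
#'   recorded in the `focus` element.
#' @export
extract_subnetwork <- function(net, focus, mode = c("induced", "incident")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "trip_network"))
  if (!focus %in% net$nodes$name) {
    abort(paste0("focus node '", focus, "' is not in the network"))
  }
  keep_nodes <- c(focus, node_neighbors(net, focus))
  e <- net$edges
  sel <- if (mode == "induced") {
    e$var_a %in% keep_nodes & e$var_b %in% keep_nodes
  } else {
    e$var_a %in% keep_nodes | e$var_b %in% keep_nodes
  }
  kept <- e[sel, , drop = FALSE]
  nodes <- dplyr::distinct(bind_rows(
    tibble(name = kept$var_a, block = kept$block_a),
    tibble(name = kept$var_b, block = kept$block_b),
    net$nodes[net$nodes$name == focus, , drop = FALSE]
  ))
  structure(list(kind = net$kind, alpha = net$alpha, nodes = nodes,
                 edges = kept, focus = focus),
            class = "trip_network")
}

#' Direct and indirect associations of a genus subnetwork
#'
#' Direct associations are the edges incident to the focus genus. Indirect
#' associations are phenotype nodes *not* directly linked to the genus but
#' reachable from it in two steps through a brain node, reported as
#' (genus, brain, phenotype) paths. Note that an induced first-neighbour
#' subnetwork cannot contain such paths by construction (the phenotype
#' endpoint is a second-order node); pass the full network or a
#' `mode = "incident"` subnetwork to enumerate them.
#'
#' @param subnet A `trip_network`, typically from [extract_subnetwork()].
#' @param focus The focus genus; defaults to the subnetwork's recorded focus.
#' @return A list of class `trip_classification`: `direct` (edge tibble) and
#'   `indirect` (tibble with columns `genus`, `brain`, `phenotype`).
#' @export
classify_associations <- function(subnet, focus = subnet$focus) {
  stopifnot(inherits(subnet, "trip_network"))
  if (is.null(focus)) abort("no focus node recorded or supplied")
  e <- subnet$edges
  inc <- e$var_a == focus | e$var_b == focus
  direct <- e[inc, , drop = FALSE]
  nb <- node_neighbors(subnet, focus)
  block_of <- setNames(subnet$nodes$block, subnet$nodes$name)
  brain_nb <- nb[block_of[nb] == "brain"]
  paths <- list()
  for (b in brain_nb) {
    ph <- node_neighbors(subnet, b)
    ph <- ph[block_of[ph] == "phenotype"]
    ph <- ph[!vapply(ph, function(p) network_has_edge(subnet, focus, p), logical(1))]
    if (length(ph)) paths[[b]] <- tibble(genus = focus, brain = b, phenotype = ph)
  }
  indirect <- if (length(paths)) list_rbind(unname(paths))
              else tibble(genus = character(), brain = character(), phenotype = character())
  structure(list(direct = direct, indirect = indirect, focus = focus),
            class = "trip_classification")
}

#' @export
print.trip_classification <- function(x, ...) {
  cat(sprintf("<trip_classification> focus '%s': %d direct edge(s), %d indirect path(s)\n",
              x$focus, nrow(x$direct), nrow(x$indirect)))
  invisible(x)
}

#' Population Spearman correlation of a Gaussian copula
#'
#' For bivariate Gaussian latent variables with correlation `rho` and
#' strictly monotone marginal transforms, the population Spearman correlation
#' is `(6 / pi) * asin(rho / 2)`.
#'
#' @param rho Latent (Pearson) correlation in \[-1, 1\].
#' @return The attenuated Spearman correlation.
#' @export
#' @examples
#' pearson_to_spearman(0.8)
pearson_to_spearman <- function(rho) 6 / pi * asin(rho / 2)

#' Analytic power of the Fisher r-to-z difference test
#'
#' Approximates the probability that a variable pair with group-specific
#' latent correlations enters the difference network at level `alpha`. For
#' the Spearman pipeline the latent correlations are first attenuated with
#' [pearson_to_spearman()] and the true sampling variance of the Fisher
#' transform uses the Fieller-David inflation `1.06 / (n - 3 - k)` (with `k`
#' covariates regressed out), while the test statistic itself keeps the
#' classic `1 / (n - 3)` scaling. At `rho_hc == rho_ibs` this returns the
#' test's actual size, slightly above `alpha` at small n.
#'
#' @param rho_hc,rho_ibs Latent correlations in each group.
#' @param n_hc,n_ibs Group sizes.
#' @param alpha Two-sided level of the difference test.
#' @param method `"spearman"` (default) or `"pearson"` (no attenuation, unit
#'   variance scaling).
#' @param n_covariates Number of covariates regressed out before correlating
#'   (default 2, age and sex); each consumes a degree of freedom in the true
#'   sampling variance, while the test statistic keeps the classic scaling.
#' @return Power (probability of rejection), vectorised over inputs.
#' @export
#' @examples
#' analytic_difference_power(0.7, 0, n_hc = 21, n_ibs = 65)
analytic_difference_power <- function(rho_hc, rho_ibs, n_hc = 21, n_ibs = 65,
                                      alpha = 0.05,
                                      method = c("spearman", "pearson"),
                                      n_covariates = 2) {
  method <- match.arg(method)
  k <- n_covariates
  if (method == "spearman") {
    r1 <- pearson_to_spearman(rho_hc); r2 <- pearson_to_spearman(rho_ibs)
    v1 <- 1.06 / (n_hc - 3 - k); v2 <- 1.06 / (n_ibs - 3 - k)
  } else {
    r1 <- rho_hc; r2 <- rho_ibs
    v1 <- 1 / (n_hc - 3 - k); v2 <- 1 / (n_ibs - 3 - k)
  }
  delta <- atanh(r2) - atanh(r1)
  se_test <- sqrt(1 / (n_hc - 3) + 1 / (n_ibs - 3))
  se_true <- sqrt(v1 + v2)
  za <- qnorm(1 - alpha / 2)
  pnorm((delta - za * se_test) / se_true) + pnorm((-delta - za * se_test) / se_true)
}
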