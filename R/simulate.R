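#' Declare a planted cross-block correlation
#'
#' A planted edge fixes the latent (Gaussian-copula) correlation between two
#' simulated variables separately in each group. Because every marginal
#' transform in the generator is strictly monotone, the planted value maps to
#' a population Spearman correlation of `(6 / pi) * asin(rho / 2)`.
#'
#' @param var_a,var_b Variable names (must exist in the simulation config).
#' @param block_a,block_b Block of each variable: `"microbe"`, `"brain"`, or
#'   `"phenotype"`.
#' @param rho_hc,rho_ibs Target latent correlations in (-1, 1) for the healthy
#'   control and IBS groups.
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()] and passed as `planted_edges` to
#'   [simulation_config()].
#' @export
#' @examples
#' planted_edge("Coprococcus", "microbe", "OATT", "phenotype",
#'              rho_hc = 0.6, rho_ibs = 0)
planted_edge <- function(var_a, block_a, var_b, block_b, rho_hc = 0, rho_ibs = 0) {
  stopifnot(is.character(var_a), is.character(var_b))
  if (any(var_a == var_b)) abort("planted edge endpoints must differ")
  if (any(abs(c(rho_hc, rho_ibs)) >= 1)) abort("planted |rho| must be < 1")
  tibble(var_a = var_a, block_a = block_a, var_b = var_b, block_b = block_b,
         rho_hc = rho_hc, rho_ibs = rho_ibs)
}

empty_planted_edges <- function() {
  tibble(var_a = character(), block_a = character(), var_b = character(),
         block_b = character(), rho_hc = numeric(), rho_ibs = numeric())
}

#' Configure the synthetic cohort generator
#'
#' Defaults encode the study conditions the analysis was designed for: 21
#' healthy controls and 65 IBS patients; the nine-genus Clostridiales panel of
#' [genus_panel()]; the phenotype battery of [phenotype_reference()] with its
#' group means and standard deviations; female proportions 16/21 (HC) and
#' 46/65 (IBS); age normal with mean 33.3 truncated to 18-65 years.
#'
#' @param n_hc,n_ibs Group sizes (each at least 5).
#' @param genera Character vector of genus names for the microbe block, or
#'   `NULL` to use `n_genera` names from [genus_panel()].
#' @param n_genera Number of panel genera to simulate when `genera` is `NULL`.
#' @param phenotype_specs Tibble with columns `name`, `mean_hc`, `sd_hc`,
#'   `mean_ibs`, `sd_ibs`; defaults to [phenotype_reference()].
#' @param brain_features Character vector of `X_Y_Z` centrality labels for the
#'   brain block ([default_brain_features()]).
#' @param planted_edges Tibble of [planted_edge()] rows, or `NULL` for a null
#'   (no cross-block structure) cohort.
#' @param missingness Named numeric `c(HC = , IBS = )`: per-genus probability
#'   of non-detection (recorded as abundance 0) in each group, in \[0, 1\].
#' @param detection_limit Relative abundances below this value are recorded
#'   as 0 (non-detected).
#' @param abundance_caps Optional per-genus maximal relative abundances
#'   (must sum to at most 1); defaults to a geometric series totalling 0.45,
#'   the remainder standing for all other (unmodelled) genera.
#' @param abundance_location,abundance_scale Location and scale of the
#'   logistic-normal abundance factor.
#' @param age Named numeric `c(mean_hc, sd_hc, mean_ibs, sd_ibs)` in years.
#' @param female Named numeric `c(HC = , IBS = )` proportion of females.
#' @param skew_phenotypes If `TRUE`, phenotype marginals are lognormal with
#'   the configured mean and SD (right-skewed, as AUC-type measures are)
#'   instead of normal. Ranks, and hence all Spearman-based results, are
#'   unaffected.
#' @param n_regions Number of brain regions for
#'   [simulate_connectivity_stack()].
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `trip_sim_config` list, validated.
#' @export
#' @examples
#' cfg <- simulation_config(n_hc = 21, n_ibs = 65, seed = 7)
#' sim <- simulate_cohort(cfg)
#' sim$cohort
simulation_config <- function(n_hc = 21, n_ibs = 65,
                              genera = NULL, n_genera = NULL,
                              phenotype_specs = NULL,
                              brain_features = default_brain_features(),
                              planted_edges = NULL,
                              missingness = c(HC = 0.1, IBS = 0.1),
                              detection_limit = 1e-4,
                              abundance_caps = NULL,
                              abundance_location = -1, abundance_scale = 1.5,
                              age = c(mean_hc = 33.3, sd_hc = 9.56,
                                      mean_ibs = 33.3, sd_ibs = 10.2),
                              female = c(HC = 16 / 21, IBS = 46 / 65),
                              skew_phenotypes = FALSE,
                              n_regions = 36,
                              seed = 1) {
  if (is.null(genera)) {
    pool <- genus_panel()$genus
    n_genera <- n_genera %||% length(pool)
    if (n_genera <= length(pool)) {
      genera <- pool[seq_len(n_genera)]
    } else {
      genera <- c(pool, sprintf("Genus%02d", seq_len(n_genera - length(pool))))
    }
  }
  if (is.null(phenotype_specs)) {
    ref <- phenotype_reference()
    phenotype_specs <- tibble(name = ref$variable, mean_hc = ref$mean_hc,
                              sd_hc = ref$sd_hc, mean_ibs = ref$mean_ibs,
                              sd_ibs = ref$sd_ibs)
  }
  planted_edges <- planted_edges %||% empty_planted_edges()
  if (is.null(abundance_caps)) {
    w <- 0.75^(seq_along(genera) - 1)
    abundance_caps <- 0.45 * w / sum(w)
  }
  cfg <- structure(list(
    n_hc = as.integer(n_hc), n_ibs = as.integer(n_ibs),
    genera = genera, phenotype_specs = as_tibble(phenotype_specs),
    brain_features = brain_features,
    planted_edges = as_tibble(planted_edges),
    missingness = missingness, detection_limit = detection_limit,
    abundance_caps = abundance_caps,
    abundance_location = abundance_location, abundance_scale = abundance_scale,
    age = age, female = female, skew_phenotypes = skew_phenotypes,
    n_regions = as.integer(n_regions), seed = as.integer(seed)
  ), class = "trip_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_hc < 5 || cfg$n_ibs < 5) abort("group sizes must be at least 5")
  ps <- cfg$phenotype_specs
  need <- c("name", "mean_hc", "sd_hc", "mean_ibs", "sd_ibs")
  if (!all(need %in% names(ps))) {
    abort(paste0("phenotype_specs must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(c(ps$sd_hc, ps$sd_ibs) <= 0)) abort("phenotype SDs must be positive")
  if (any(cfg$missingness < 0 | cfg$missingness > 1)) {
    abort("missingness rates must lie in [0, 1]")
  }
  if (!setequal(names(cfg$missingness), c("HC", "IBS"))) {
    abort("missingness must be named c(HC = , IBS = )")
  }
  if (sum(cfg$abundance_caps) > 1 + 1e-12 || any(cfg$abundance_caps <= 0)) {
    abort("abundance caps must be positive and sum to at most 1")
  }
  if (length(cfg$abundance_caps) != length(cfg$genera)) {
    abort("abundance_caps must have one entry per genus")
  }
  vars <- sim_variable_blocks(cfg)
  if (anyDuplicated(names(vars))) abort("simulated variable names must be unique")
  pe <- cfg$planted_edges
  if (nrow(pe)) {
    if (any(pe$var_a == pe$var_b)) abort("planted edge endpoints must differ")
    if (any(abs(c(pe$rho_hc, pe$rho_ibs)) >= 1)) abort("planted |rho| must be < 1")
    for (i in seq_len(nrow(pe))) {
      for (side in c("a", "b")) {
        v <- pe[[paste0("var_", side)]][i]
        b <- pe[[paste0("block_", side)]][i]
        if (is.na(vars[v]) || !v %in% names(vars)) {
          abort(paste0("planted edge names unknown variable '", v, "'"))
        }
        if (vars[[v]] != b) {
          abort(paste0("planted edge assigns variable '", v, "' to block '", b,
                       "' but it belongs to block '", vars[[v]], "'"))
        }
      }
    }
  }
  invisible(cfg)
}

# named character vector variable -> block, in cohort column order
sim_variable_blocks <- function(cfg) {
  c(setNames(rep("microbe", length(cfg$genera)), cfg$genera),
    setNames(rep("phenotype", nrow(cfg$phenotype_specs)), cfg$phenotype_specs$name),
    setNames(rep("brain", length(cfg$brain_features)), cfg$brain_features))
}

# group-specific latent correlation matrix; errors if not positive definite
sim_latent_sigma <- function(cfg, group) {
  vars <- names(sim_variable_blocks(cfg))
  p <- length(vars)
  sigma <- diag(p)
  dimnames(sigma) <- list(vars, vars)
  pe <- cfg$planted_edges
  rho_col <- if (group == "HC") "rho_hc" else "rho_ibs"
  for (i in seq_len(nrow(pe))) {
    a <- pe$var_a[i]; b <- pe$var_b[i]
    sigma[a, b] <- sigma[b, a] <- pe[[rho_col]][i]
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    offending <- paste0(pe$var_a, " -- ", pe$var_b, collapse = "; ")
    abort(paste0("target latent correlation matrix for group ", group,
                 " is not positive definite; planted edges involved: ", offending))
  }
  sigma
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# lognormal quantile transform matched to a target mean and sd (mean > 0)
lnorm_from_moments <- function(z, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::qlnorm(pnorm(z), meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a tripartite cohort with known ground truth
#'
#' Draws latent standard Gaussians with the group-specific planted correlation
#' structure (Gaussian copula), then maps them through strictly monotone
#' marginal transforms: genus abundances are per-genus capacities times a
#' logistic-normal factor (compositional, non-negative, summing below 1, with
#' detection-limit and extra non-detection zeros); phenotypes are normal (or
#' lognormal if `skew_phenotypes`) with the configured group means/SDs; brain
#' centrality features are lognormal-positive. Age and sex are generated
#' independently of the planted structure.
#'
#' @param config A [simulation_config()].
#' @return A list of class `trip_simulation` with elements `cohort` (a
#'   [cohort_table()]) and `ground_truth` (the planted-edge tibble).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 42))
#' dplyr::count(sim$cohort, group)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "trip_sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    blocks <- sim_variable_blocks(config)
    vars <- names(blocks)
    ps <- config$phenotype_specs
    per_group <- function(grp, n) {
      sigma <- sim_latent_sigma(config, grp)
      z <- matrix(rnorm(n * length(vars)), n) %*% chol(sigma)
      colnames(z) <- vars
      key <- if (grp == "HC") "hc" else "ibs"

      age <- round(rtruncnorm1(n, config$age[[paste0("mean_", key)]],
                               config$age[[paste0("sd_", key)]], 18, 65), 1)
      sex <- rbinom(n, 1, config$female[[grp]])  # 1 = female

      ab <- vapply(seq_along(config$genera), function(j) {
        a <- config$abundance_caps[j] *
          stats::plogis(config$abundance_location + config$abundance_scale * z[, config$genera[j]])
        a[a < config$detection_limit] <- 0
        a[runif(n) < config$missingness[[grp]]] <- 0
        a
      }, numeric(n))
      colnames(ab) <- config$genera

      ph <- vapply(seq_len(nrow(ps)), function(j) {
        zz <- z[, ps$name[j]]
        m <- ps[[paste0("mean_", key)]][j]
        s <- ps[[paste0("sd_", key)]][j]
        if (isTRUE(config$skew_phenotypes) && m > 0) lnorm_from_moments(zz, m, s)
        else m + s * zz
      }, numeric(n))
      colnames(ph) <- ps$name

      br <- exp(z[, config$brain_features, drop = FALSE] / 2)

      bind_cols(
        tibble(subject_id = sprintf("%s%03d", grp, seq_len(n)),
               group = grp, age = age, sex = sex),
        as_tibble(ab), as_tibble(ph), as_tibble(br)
      )
    }
    cohort <- bind_rows(per_group("HC", config$n_hc), per_group("IBS", config$n_ibs))
    structure(
      list(cohort = cohort_table(cohort, blocks),
           ground_truth = config$planted_edges),
      class = "trip_simulation"
    )
  })
}

#' @export
print.trip_simulation <- function(x, ...) {
  cat("<trip_simulation> cohort of", nrow(x$cohort), "subjects;",
      nrow(x$ground_truth), "planted edge(s)\n")
  invisible(x)
}

#' Declare a centrality coupling for the connectivity simulator
#'
#' @param region Region label of the simulated matrices (e.g. `"Pu_L"`).
#' @param metric Centrality metric expected to respond (`"S"`, `"B"`, `"E"`);
#'   recorded for bookkeeping — a coupling perturbs all edges of the region,
#'   so every centrality of that region responds monotonically.
#' @param latent Name of the subject-level latent variable driving the
#'   coupling.
#' @param strength Non-negative coupling strength.
#' @return A one-row tibble.
#' @export
coupling_spec <- function(region, metric = "S", latent = "latent1", strength = 0.5) {
  stopifnot(is.finite(strength))
  tibble(region = region, metric = metric, latent = latent, strength = strength)
}

#' Simulate a stack of per-subject connectivity matrices
#'
#' Each subject's region-by-region matrix is a fixed template (drawn once from
#' the config seed) perturbed by symmetric noise on the Fisher-z scale, then
#' mapped back through `tanh` so entries stay in (-1, 1); the diagonal is 1.
#' A coupling adds `0.25 * strength * latent` to all Fisher-z edge weights of
#' its region, so that region's centralities increase with the subject's
#' latent variable.
#'
#' @param config A [simulation_config()]; `n_regions` and the group sizes set
#'   the dimensions, `seed` fixes template, noise, and latents.
#' @param coupling Tibble of [coupling_spec()] rows, or `NULL`.
#' @param noise Standard deviation of the subject-level Fisher-z noise.
#' @param n_subjects Number of matrices (default `n_hc + n_ibs`).
#' @return A named list of [connectivity_matrix()] objects with a `latents`
#'   attribute: a tibble of the subject-level latent variables.
#' @export
#' @examples
#' cfg <- simulation_config(n_regions = 8, seed = 3)
#' stack <- simulate_connectivity_stack(cfg, noise = 0.05)
#' length(stack)
simulate_connectivity_stack <- function(config, coupling = NULL, noise = 0.1,
                                        n_subjects = NULL) {
  stopifnot(inherits(config, "trip_sim_config"))
  p <- config$n_regions
  if (p < 3) abort("n_regions must be at least 3")
  coupling <- coupling %||% tibble(region = character(), metric = character(),
                                   latent = character(), strength = numeric())
  n <- n_subjects %||% (config$n_hc + config$n_ibs)
  labels <- connectivity_region_labels(p)
  bad <- setdiff(coupling$region, labels)
  if (length(bad)) abort(paste0("coupling names unknown region(s): ", paste(bad, collapse = ", ")))

  withr::with_seed(config$seed, {
    template <- matrix(0, p, p)
    template[upper.tri(template)] <- runif(p * (p - 1) / 2, 0.05, 0.55)
    template <- template + t(template)
    zt <- atanh(template)

    latent_names <- unique(coupling$latent)
    latents <- matrix(rnorm(n * length(latent_names)), n,
                      dimnames = list(NULL, latent_names))
    ids <- sprintf("subj%03d", seq_len(n))

    mats <- lapply(seq_len(n), function(s) {
      e <- matrix(rnorm(p * p, sd = noise), p)
      zs <- zt + (e + t(e)) / 2
      for (k in seq_len(nrow(coupling))) {
        r <- match(coupling$region[k], labels)
        bump <- 0.25 * coupling$strength[k] * latents[s, coupling$latent[k]]
        zs[r, ] <- zs[r, ] + bump
        zs[, r] <- zs[, r] + bump
      }
      w <- tanh(zs)
      diag(w) <- 1
      w <- (w + t(w)) / 2
      if (max(abs(w - t(w))) > 1e-12) abort("internal error: generated matrix not symmetric")
      connectivity_matrix(w, labels)
    })
    names(mats) <- ids
    lat_tb <- bind_cols(tibble(subject_id = ids), as_tibble(latents))
    attr(mats, "latents") <- lat_tb
    mats
  })
}

# region labels: ROI abbreviations crossed with L/R, padded if needed
connectivity_region_labels <- function(p) {
  base <- roi_table()$abbreviation
  lab <- as.vector(t(outer(base, c("L", "R"), function(a, s) paste(a, s, sep = "_"))))
  if (p <= length(lab)) return(lab[seq_len(p)])
  c(lab, sprintf("X%02d", seq_len(p - length(lab))))
}
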