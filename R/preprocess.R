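#' Cohort analysis table
#'
#' A tibble of row-aligned subject-level blocks: `subject_id`, `group`
#' (`"HC"`/`"IBS"`), covariates `age` and `sex`, and one column per analysis
#' variable. Block membership (`"microbe"`, `"brain"`, `"phenotype"`) is
#' carried in the `blocks` attribute and retrieved with [var_blocks()].
#'
#' @param data A data frame with at least `subject_id`, `group`, `age`, `sex`
#'   and the variable columns named in `blocks`.
#' @param blocks Named character vector mapping variable columns to blocks.
#' @return A `trip_cohort` tibble.
#' @export
cohort_table <- function(data, blocks) {
  data <- as_tibble(data)
  class(data) <- c("tbl_df", "tbl", "data.frame")
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("cohort table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(data$subject_id)) abort("duplicate subject ids in cohort table")
  if (!all(data$group %in% c("HC", "IBS"))) abort("group labels must be 'HC' or 'IBS'")
  if (!all(names(blocks) %in% names(data))) {
    abort(paste0("block variables absent from table: ",
                 paste(setdiff(names(blocks), names(data)), collapse = ", ")))
  }
  if (!all(blocks %in% c("microbe", "brain", "phenotype"))) {
    abort("blocks must be 'microbe', 'brain' or 'phenotype'")
  }
  mic <- names(blocks)[blocks == "microbe"]
  for (v in mic) {
    x <- data[[v]]
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad)) {
      abort(sprintf("abundance out of [0, 1]: variable '%s', row %d (value %.4g)",
                    v, bad[1], x[bad[1]]))
    }
  }
  structure(data, blocks = blocks, class = c("trip_cohort", class(data)))
}

#' @rdname cohort_table
#' @param x A `trip_cohort`.
#' @return [var_blocks()]: the named block vector.
#' @export
var_blocks <- function(x) {
  b <- attr(x, "blocks", exact = TRUE)
  if (is.null(b)) abort("not a cohort table: no block attribute")
  b
}

#' @export
print.trip_cohort <- function(x, ...) {
  b <- attr(x, "blocks", exact = TRUE)
  cat(sprintf("<trip_cohort> %d subjects (%d HC, %d IBS); %d microbe, %d brain, %d phenotype variable(s)\n",
              nrow(x), sum(x$group == "HC"), sum(x$group == "IBS"),
              sum(b == "microbe"), sum(b == "brain"), sum(b == "phenotype")))
  NextMethod()
}

#' Filter genera by per-group missingness
#'
#' A genus is excluded when its fraction of missing values is strictly
#' greater than `max_missing_fraction` in the healthy-control group *or* in
#' the IBS group; a fraction exactly at the threshold is retained. Missing
#' means recorded as 0 or absent (`NA`) under the default non-detection
#' semantics of amplicon genus tables; set `missing = "na_only"` to count
#' only `NA`.
#'
#' @param table A [cohort_table()].
#' @param panel Genus names to consider: a character vector or a tibble with
#'   a `genus` column (default [genus_panel()] restricted to the table's
#'   microbe block must be explicit — any panel genus absent from the table
#'   is an error).
#' @param max_missing_fraction Exclusion threshold (default 0.80).
#' @param missing `"zero_or_na"` (default) or `"na_only"`.
#' @return The filtered `trip_cohort`; excluded genera are dropped from the
#'   table and block map. The per-genus report (columns `genus`,
#'   `frac_missing_hc`, `frac_missing_ibs`, `retained`) is attached as the
#'   `filter_report` attribute and retrievable with [filter_report()].
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 1))
#' filtered <- filter_genera(sim$cohort)
#' filter_report(filtered)
filter_genera <- function(table, panel = genus_panel(),
                          max_missing_fraction = 0.80,
                          missing = c("zero_or_na", "na_only")) {
  missing <- match.arg(missing)
  blocks <- var_blocks(table)
  genera <- if (is.data.frame(panel)) panel$genus else as.character(panel)
  genera <- unique(genera)
  absent <- setdiff(genera, names(blocks)[blocks == "microbe"])
  if (length(absent)) {
    abort(paste0("panel genus/genera absent from table: ", paste(absent, collapse = ", ")))
  }
  if (!any(table$group == "HC") || !any(table$group == "IBS")) {
    abort("both groups must be represented")
  }
  is_missing <- function(x) if (missing == "na_only") is.na(x) else (is.na(x) | x == 0)
  frac <- function(grp, g) mean(is_missing(table[[g]][table$group == grp]))
  report <- tibble(
    genus = genera,
    frac_missing_hc = map_dbl(genera, ~ frac("HC", .x)),
    frac_missing_ibs = map_dbl(genera, ~ frac("IBS", .x))
  )
  report$retained <- report$frac_missing_hc <= max_missing_fraction &
    report$frac_missing_ibs <= max_missing_fraction
  drop <- report$genus[!report$retained]
  out <- table[, setdiff(names(table), drop)]
  new_blocks <- blocks[setdiff(names(blocks), drop)]
  out <- cohort_table(out, new_blocks)
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_genera
#' @param x A table returned by `filter_genera()`.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report", exact = TRUE)
}

#' Covariate design matrix
#'
#' Builds the adjustment design (intercept, age in years, sex coded
#' female = 1) used to residualise ranks. Character/factor sex is mapped
#' `F`/`female` to 1 and `M`/`male` to 0; numeric sex must already be 0/1.
#' A covariate that is constant within the supplied rows is dropped with a
#' warning so downstream adjustment cannot fail on a degenerate group.
#'
#' @param data A data frame with the covariate columns.
#' @param covariates Covariate column names (default `c("age", "sex")`).
#' @return A numeric matrix with an `(Intercept)` column; the sex coding is
#'   recorded in the `sex_code` attribute.
#' @export
#' @examples
#' covariate_design(tibble::tibble(age = c(30, 40, 50), sex = c("F", "M", "F")))
covariate_design <- function(data, covariates = c("age", "sex")) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  sex_code <- NULL
  for (cv in covariates) {
    x <- data[[cv]]
    if (cv == "sex") {
      if (is.character(x) || is.factor(x)) {
        x <- as.character(x)
        lo <- tolower(x)
        coded <- ifelse(lo %in% c("f", "female"), 1,
                        ifelse(lo %in% c("m", "male"), 0, NA_real_))
        if (any(is.na(coded) & !is.na(x))) {
          abort(paste0("non-binary sex values: ",
                       paste(unique(x[is.na(coded) & !is.na(x)]), collapse = ", ")))
        }
        x <- coded
        sex_code <- c(female = 1, male = 0)
      } else {
        if (!all(is.na(x) | x %in% c(0, 1))) abort("numeric sex must be coded 0/1")
        sex_code <- c(female = 1, male = 0)
      }
    }
    if (anyNA(x)) {
      who <- if ("subject_id" %in% names(data)) data$subject_id[is.na(x)] else which(is.na(x))
      abort(paste0("missing covariate '", cv, "' for: ", paste(who, collapse = ", ")))
    }
    cols[[cv]] <- as.numeric(x)
  }
  m <- do.call(cbind, cols)
  keep <- c(TRUE, vapply(seq_len(ncol(m) - 1) + 1, function(j) var(m[, j]) > 0, logical(1)))
  if (!all(keep)) {
    warn(paste0("constant covariate(s) dropped from design: ",
                paste(colnames(m)[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  attr(m, "sex_code") <- sex_code
  m
}

#' Align subject-level blocks into one cohort table
#'
#' Inner-joins the microbe, phenotype, brain, and covariate blocks on
#' `subject_id`, sorts rows by id, and records which ids each block lost in a
#' `join_report` attribute.
#'
#' @param microbe,phenotype,brain Data frames keyed by `subject_id`; `brain`
#'   may be `NULL` when no brain block is analysed.
#' @param covariates Data frame with `subject_id`, `group`, `age`, `sex`.
#' @return A [cohort_table()] with block membership inferred from the source
#'   of each column.
#' @export
align_blocks <- function(microbe, phenotype, brain = NULL, covariates) {
  blocks_in <- list(microbe = microbe, phenotype = phenotype, brain = brain,
                    covariates = covariates)
  blocks_in <- blocks_in[!vapply(blocks_in, is.null, logical(1))]
  for (nm in names(blocks_in)) {
    b <- blocks_in[[nm]]
    if (!"subject_id" %in% names(b)) abort(paste0("block '", nm, "' lacks subject_id"))
    if (anyDuplicated(b$subject_id)) {
      abort(paste0("duplicate subject id within block '", nm, "'"))
    }
  }
  ids <- Reduce(intersect, lapply(blocks_in, function(b) b$subject_id))
  if (!length(ids)) abort("no subject ids common to all blocks")
  ids <- sort(ids)
  dropped <- lapply(blocks_in, function(b) setdiff(b$subject_id, ids))

  var_cols <- function(nm) setdiff(names(blocks_in[[nm]]), "subject_id")
  covar <- as_tibble(blocks_in$covariates)
  covar <- covar[match(ids, covar$subject_id), , drop = FALSE]
  out <- covar
  blocks <- character()
  for (nm in setdiff(names(blocks_in), "covariates")) {
    b <- as_tibble(blocks_in[[nm]])
    b <- b[match(ids, b$subject_id), var_cols(nm), drop = FALSE]
    clash <- intersect(names(b), names(out))
    if (length(clash)) abort(paste0("duplicate variable name(s) across blocks: ",
                                    paste(clash, collapse = ", ")))
    out <- bind_cols(out, b)
    blocks <- c(blocks, setNames(rep(nm, ncol(b)), names(b)))
  }
  out <- cohort_table(out, blocks)
  attr(out, "join_report") <- tibble(block = names(dropped),
                                     n_dropped = unname(lengths(dropped)),
                                     dropped_ids = unname(map_chr(dropped, paste, collapse = ";")))
  out
}
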