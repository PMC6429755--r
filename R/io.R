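detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_delim(path, delim = detect_delim(path), show_col_types = FALSE,
                    progress = FALSE)
}

rename_id <- function(tb, id_col, path) {
  if (!id_col %in% names(tb)) {
    abort(paste0(path, ": subject-id column '", id_col, "' not found"))
  }
  names(tb)[names(tb) == id_col] <- "subject_id"
  tb$subject_id <- as.character(tb$subject_id)
  if (anyDuplicated(tb$subject_id)) {
    abort(paste0(path, ": duplicate subject ids: ",
                 paste(unique(tb$subject_id[duplicated(tb$subject_id)]), collapse = ", ")))
  }
  tb
}

check_numeric_cells <- function(tb, path, lower = -Inf, upper = Inf) {
  for (v in setdiff(names(tb), "subject_id")) {
    x <- tb[[v]]
    if (!is.numeric(x)) {
      abort(paste0(path, ": column '", v, "' is not numeric"))
    }
    bad <- which(!is.na(x) & (x < lower | x > upper))
    if (length(bad)) {
      abort(sprintf("%s: value out of [%g, %g] at row %d, column '%s' (%.6g)",
                    path, lower, upper, bad[1], v, x[bad[1]]))
    }
  }
  tb
}

#' Read the delimited analysis tables
#'
#' Comma or tab delimiters are auto-detected from the header line. Values are
#' range-validated (abundances in \[0, 1\], matrix entries in \[-1, 1\]) with
#' errors naming the file, row, and column.
#'
#' @param path Path to a delimited file with a header row.
#' @param id_col Name of the subject-id column (default `"subject_id"`).
#' @return A tibble (abundance/phenotype/covariate/centrality readers) or a
#'   [connectivity_matrix()].
#' @name readers
#' @export
read_abundance_table <- function(path, id_col = "subject_id") {
  tb <- rename_id(read_table_auto(path), id_col, path)
  check_numeric_cells(tb, path, lower = 0, upper = 1)
}

#' @rdname readers
#' @export
read_phenotype_table <- function(path, id_col = "subject_id") {
  tb <- rename_id(read_table_auto(path), id_col, path)
  check_numeric_cells(tb, path)
}

#' @rdname readers
#' @export
read_centrality_table <- function(path, id_col = "subject_id") {
  tb <- rename_id(read_table_auto(path), id_col, path)
  check_numeric_cells(tb, path, lower = -Inf, upper = Inf)
}

#' @rdname readers
#' @export
read_edge_table <- function(path) {
  tb <- read_table_auto(path)
  need <- c("var_a", "block_a", "var_b", "block_b", "r_hc", "n_hc", "p_hc",
            "r_ibs", "n_ibs", "p_ibs", "z_diff", "p_diff", "direction")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    abort(paste0(path, ": not an edge table; missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tb
}

#' @rdname readers
#' @param group_col Name of the group-label column.
#' @export
read_covariate_table <- function(path, id_col = "subject_id", group_col = "group") {
  tb <- rename_id(read_table_auto(path), id_col, path)
  if (!group_col %in% names(tb)) {
    abort(paste0(path, ": group column '", group_col, "' not found"))
  }
  names(tb)[names(tb) == group_col] <- "group"
  if (!all(tb$group %in% c("HC", "IBS"))) {
    abort(paste0(path, ": group labels must be 'HC' or 'IBS'"))
  }
  tb
}

#' @rdname readers
#' @export
read_connectivity_matrix <- function(path) {
  tb <- read_table_auto(path)
  labels <- as.character(tb[[1]])
  m <- as.matrix(tb[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0(path, ": non-numeric matrix cells"))
  if (nrow(m) != ncol(m)) abort(paste0(path, ": matrix is not square"))
  if (!identical(labels, colnames(m))) {
    abort(paste0(path, ": row labels do not match column labels"))
  }
  rownames(m) <- labels
  connectivity_matrix(m, labels)
}

#' @rdname readers
#' @param dir Directory of per-subject matrix files (`<subject_id>.csv` or
#'   `.tsv`), one labelled square matrix each.
#' @export
read_connectivity_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  if (!length(files)) abort(paste0("no .csv/.tsv matrix files in ", dir))
  files <- sort(files)
  mats <- lapply(files, read_connectivity_matrix)
  names(mats) <- sub("\\.(csv|tsv)$", "", basename(files))
  mats
}

#' Write delimited outputs
#'
#' @param x A data frame (or, for `write_connectivity_matrix()`, a matrix).
#' @param path Output path; `.tsv` extension writes tab-delimited, anything
#'   else comma-delimited.
#' @return `path`, invisibly.
#' @name writers
#' @export
write_delim_auto <- function(x, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' @rdname writers
#' @export
write_connectivity_matrix <- function(x, path) {
  tb <- bind_cols(tibble(region = rownames(x)), as_tibble(as.data.frame(unclass(x))))
  write_delim_auto(tb, path)
}

trip_network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges)) {
      cbind(net$edges[, c("var_a", "var_b")],
            net$edges[, setdiff(names(net$edges),
                                c("var_a", "var_b", "block_a", "block_b"))],
            color = ifelse(net$edges$z_diff > 0, "red", "blue"))
    } else {
      data.frame(var_a = character(), var_b = character())
    },
    directed = FALSE,
    vertices = if (nrow(net$nodes)) as.data.frame(net$nodes) else data.frame(name = character())
  )
  igraph::graph_attr(g, "kind") <- net$kind
  igraph::graph_attr(g, "alpha") <- net$alpha
  g
}

#' Export a tripartite network for Cytoscape
#'
#' `"graphml"` writes a GraphML document with the node attribute `block` and
#' edge attributes (correlations, sample sizes, p-values, `z_diff`,
#' `direction`, and a `color` tag: red for positive `z_diff`, i.e. IBS > HC,
#' blue for negative). `"sif"` writes `A assoc B` interaction lines plus a
#' `<stem>_edges.tsv` attribute table. `"edge-table"` writes the edge list as
#' a delimited table.
#'
#' @param net A `trip_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"`, or `"edge-table"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "edge-table")) {
  stopifnot(inherits(net, "trip_network"))
  if (!format[1] %in% c("graphml", "sif", "edge-table")) {
    abort(paste0("unknown format '", format[1],
                 "'; supported: graphml, sif, edge-table"))
  }
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(trip_network_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      paste(net$edges$var_a, "assoc", net$edges$var_b, sep = "\t")
    } else character(0)
    writeLines(lines, path)
    write_delim_auto(net$edges, sub("\\.sif$", "_edges.tsv", path))
  } else {
    write_delim_auto(net$edges, path)
  }
  invisible(path)
}

#' Re-import a GraphML tripartite network
#'
#' Reconstructs the `trip_network` written by [export_network()]; the
#' round trip preserves nodes, edges, and attributes.
#'
#' @param path Path to a GraphML file written by [export_network()].
#' @return A `trip_network`.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(name = igraph::V(g)$name %||% character(0),
                  block = igraph::V(g)$block %||% character(0))
  el <- igraph::as_edgelist(g)
  block_of <- setNames(nodes$block, nodes$name)
  edges <- tibble(var_a = el[, 1], block_a = unname(block_of[el[, 1]]),
                  var_b = el[, 2], block_b = unname(block_of[el[, 2]]))
  for (a in c("r_hc", "n_hc", "p_hc", "r_ibs", "n_ibs", "p_ibs",
              "z_diff", "p_diff", "direction")) {
    v <- igraph::edge_attr(g, a)
    edges[[a]] <- if (is.null(v)) rep(NA_real_, nrow(edges)) else as.numeric(v)
  }
  structure(list(kind = igraph::graph_attr(g, "kind"),
                 alpha = as.numeric(igraph::graph_attr(g, "alpha")),
                 nodes = nodes, edges = edges),
            class = "trip_network")
}
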