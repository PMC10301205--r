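#' Link weight from an association p-value
#'
#' Co-occurrence strength on a 0-100 scale: `w = 100 * (1 - p)`. A
#' statistically significant association (p < 0.05) therefore receives a
#' weight above 95.
#'
#' @param p p-value in (0, 1].
#' @return Weight in \[0, 100).
#' @examples
#' link_weight(0.05)  # 95
#' @export
link_weight <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    stop_validation("p must be a single value in (0, 1]", "dynetox_bad_pvalue")
  }
  100 * (1 - p)
}

new_adjacency_matrix <- function(group, timepoint, A) {
  stopifnot(isSymmetric(A), all(diag(A) == 0),
            all(A >= 0), all(A <= 100))
  structure(list(group = group, timepoint = timepoint, A = A),
            class = "adjacency_matrix")
}

#' Weighted adjacency matrix from an association matrix
#'
#' An edge is drawn between two abnormalities when their association is
#' significant at level `alpha`; its weight is `100 * (1 - p)`. Entries
#' failing the threshold are 0, the diagonal is 0 and the matrix is
#' symmetric. `alpha = 1` disables the threshold and keeps the raw weight
#' transform for every pair.
#'
#' @param assoc An `association_matrix` (see [association_matrices()]).
#' @param alpha Significance level in (0, 1].
#' @return An `adjacency_matrix` object (fields `group`, `timepoint`, `A`).
#' @export
build_adjacency <- function(assoc, alpha = 0.05) {
  stopifnot(inherits(assoc, "association_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_validation("alpha must lie in (0, 1]", "dynetox_bad_alpha")
  }
  p <- assoc$p
  A <- ifelse(p < alpha, 100 * (1 - p), 0)
  diag(A) <- 0
  dimnames(A) <- dimnames(p)
  new_adjacency_matrix(assoc$group, assoc$timepoint, A)
}

#' Assemble the dynamic network
#'
#' One weighted adjacency matrix per (group, timepoint) makes up the dynamic
#' network G(t): nodes are the catalog endpoints (fixed over time), links
#' appear and disappear as pairwise associations cross the significance
#' threshold. With 6 nodes there are 15 potential links per timepoint, hence
#' 90 per group over a 6-day window and 360 across 4 exposure groups.
#'
#' @param matrices List of `association_matrix` objects covering each
#'   (group, timepoint) exactly once.
#' @param alpha Significance level for edge presence, see
#'   [build_adjacency()].
#' @param catalog An [outcome_catalog()].
#' @return A `dynamic_network`: list with `catalog`, `alpha` and `groups`
#'   (per group, a list mapping timepoint to `adjacency_matrix`).
#' @export
build_dynamic_network <- function(matrices, alpha = 0.05,
                                  catalog = outcome_catalog()) {
  keys <- vapply(matrices, function(m) paste0(m$group, "@", m$timepoint), "")
  if (anyDuplicated(keys)) {
    stop_validation(paste0("duplicate (group, timepoint): ",
                           keys[duplicated(keys)][1]),
                    "dynetox_duplicate_matrix")
  }
  groups <- list()
  for (m in matrices) {
    adj <- build_adjacency(m, alpha)
    groups[[m$group]][[as.character(m$timepoint)]] <- adj
  }
  # keep timepoints sorted within each group
  for (g in names(groups)) {
    groups[[g]] <- groups[[g]][order(as.integer(names(groups[[g]])))]
  }
  structure(list(catalog = catalog, alpha = alpha, groups = groups),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  nt <- vapply(x$groups, length, 0L)
  cat("Dynamic co-occurrence network: ", length(x$groups), " group(s), ",
      "alpha = ", x$alpha, "\n", sep = "")
  for (g in names(x$groups)) {
    links <- vapply(x$groups[[g]], link_count, 0L)
    cat("  ", g, ": ", nt[[g]], " timepoints, links [",
        paste(links, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Number of links in an adjacency matrix
#'
#' Counts unordered node pairs with positive weight. A complete 6-node
#' network has 15.
#'
#' @param adj An `adjacency_matrix`.
#' @return Integer link count.
#' @export
link_count <- function(adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  sum(adj$A[upper.tri(adj$A)] > 0)
}

#' Link census of a dynamic network
#'
#' Realized link counts per (group, timepoint) alongside the potential-link
#' budget: `choose(K, 2)` per timepoint, summed over the dynamic span per
#' group and over groups in total.
#'
#' @param net A `dynamic_network`.
#' @return List with `counts` (data.frame `group`, `dpf`, `links`),
#'   `potential_per_group` (named integer vector) and `potential_total`.
#' @export
link_census <- function(net) {
  K <- catalog_size(net$catalog)
  m <- as.integer(choose(K, 2))
  rows <- list()
  per_group <- integer(0)
  for (g in names(net$groups)) {
    adjs <- net$groups[[g]]
    rows[[g]] <- data.frame(
      group = g,
      dpf = as.integer(names(adjs)),
      links = vapply(adjs, link_count, 0L),
      stringsAsFactors = FALSE
    )
    per_group[g] <- m * length(adjs)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, potential_per_group = per_group,
       potential_total = as.integer(sum(per_group)))
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

adjacency_to_igraph <- function(adj, catalog) {
  g <- igraph::graph_from_adjacency_matrix(adj$A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$label <- catalog$labels
  g
}

#' Export a dynamic network to CSV and GraphML files
#'
#' Writes, for each (group, timepoint), the labeled adjacency matrix as CSV
#' and the undirected weighted graph as GraphML (edge attribute `weight`,
#' node attribute `label`). Filenames are deterministic:
#' `<group>_<dpf>dpf.{csv,graphml}` with group labels sanitized to
#' `[A-Za-z0-9_]`.
#'
#' @param net A `dynamic_network`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in names(net$groups)) {
    for (adj in net$groups[[g]]) {
      base <- file.path(dir, paste0(sanitize_label(g), "_",
                                    adj$timepoint, "dpf"))
      csv <- paste0(base, ".csv")
      utils::write.csv(adj$A, csv, row.names = TRUE, quote = FALSE)
      gml <- paste0(base, ".graphml")
      ig <- adjacency_to_igraph(adj, net$catalog)
      igraph::write_graph(ig, gml, format = "graphml")
      files <- c(files, csv, gml)
    }
  }
  invisible(files)
}

#' Read an adjacency matrix back from an exported GraphML file
#'
#' Inverse of the GraphML half of [export_network()]; node order follows
#' the catalog.
#'
#' @param path GraphML file.
#' @param catalog An [outcome_catalog()].
#' @return K x K numeric adjacency matrix with catalog dimnames.
#' @export
read_adjacency_graphml <- function(path, catalog = outcome_catalog()) {
  g <- igraph::read_graph(path, format = "graphml")
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0)
    "weight" else NULL, sparse = FALSE)
  labels <- igraph::V(g)$label
  dimnames(A) <- list(labels, labels)
  A <- A[catalog$labels, catalog$labels]
  mode(A) <- "numeric"
  A
}
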