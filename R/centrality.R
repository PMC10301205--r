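#' Degree centrality
#'
#' The degree of a node in a weighted network is the sum of the weights of
#' the links attached to it, i.e. the row sum of the adjacency matrix. High
#' degree marks an abnormality that co-occurs strongly with the others at
#' that timepoint.
#'
#' @param adj An `adjacency_matrix` or a plain symmetric nonnegative matrix.
#' @return Named numeric vector of node degrees.
#' @export
degree_centrality <- function(adj) {
  A <- adjacency_of(adj)
  rowSums(A)
}

adjacency_of <- function(adj) {
  if (inherits(adj, "adjacency_matrix")) adj$A else as.matrix(adj)
}

#' Maximum degree and the nodes attaining it
#'
#' The global degree score of a network at one timepoint is its maximum node
#' degree; every node within `tol` of the maximum is reported (two-node ties
#' are common when a single link dominates). An all-zero network has score 0
#' and an empty node set.
#'
#' @param adj An `adjacency_matrix` or plain matrix.
#' @param tol Absolute tie tolerance on the 0-100 weight scale.
#' @return List with `score` and `nodes` (character vector, possibly empty).
#' @export
max_degree <- function(adj, tol = 1e-9) {
  d <- degree_centrality(adj)
  s <- max(d)
  list(score = s, nodes = critical_nodes(d, tol))
}

#' Eigenvector centrality by power iteration
#'
#' Leading eigenvector of the (symmetric, entrywise nonnegative) adjacency
#' matrix, oriented nonnegative and scaled to unit Euclidean norm; by
#' Perron-Frobenius such an orientation always exists. An all-zero matrix
#' returns the all-zero vector. Nodes connected to influential nodes score
#' higher than their raw degree suggests (transitive influence).
#'
#' Iteration runs on the diagonally shifted matrix `A + cI` (c = max
#' degree), which leaves the eigenvectors untouched while making the leading
#' eigenvalue strictly dominant — otherwise bipartite link patterns (whose
#' spectrum is symmetric about 0) need not converge. If the tolerance is not
#' reached within `max_iter` sweeps the dense symmetric eigendecomposition
#' is used instead.
#'
#' @param adj An `adjacency_matrix` or plain matrix.
#' @param tol Convergence tolerance on the iterate (sup norm).
#' @param max_iter Iteration cap before the dense fallback.
#' @return Named numeric vector, entrywise >= 0, unit 2-norm (or all zero).
#' @export
eigenvector_centrality <- function(adj, tol = 1e-10, max_iter = 10000L) {
  A <- adjacency_of(adj)
  K <- nrow(A)
  labels <- rownames(A)
  if (all(A == 0)) {
    return(stats::setNames(numeric(K), labels))
  }
  shift <- max(rowSums(A))
  B <- A + diag(shift, K)
  v <- rep(1 / sqrt(K), K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- drop(B %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) {
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
  }
  v <- pmax(v, 0)              # clip numerical dust; Perron vector is >= 0
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, labels)
}

#' Spectral radius
#'
#' Largest-magnitude eigenvalue of the adjacency matrix; for a symmetric
#' nonnegative matrix this equals the largest eigenvalue, computed here as
#' the Rayleigh quotient of the converged power-iteration vector (accuracy
#' is quadratic in the eigenvector error). Satisfies
#' `mean(degree) <= rho <= max(degree)`.
#'
#' @inheritParams eigenvector_centrality
#' @return Nonnegative scalar.
#' @export
spectral_radius <- function(adj, tol = 1e-10, max_iter = 10000L) {
  A <- adjacency_of(adj)
  if (all(A == 0)) return(0)
  v <- eigenvector_centrality(A, tol = tol, max_iter = max_iter)
  drop(t(v) %*% A %*% v)
}

#' Normalize a centrality score to \[0, 1\]
#'
#' Both the maximum degree and the spectral radius of a K-node network with
#' weights capped at 100 are bounded by `100 * (K - 1)` (attained by the
#' complete network with all p-values approaching 0), so one constant
#' normalizes both trajectory families onto a common \[0, 1\] axis.
#'
#' @param score Nonnegative score on the 0-100 weight scale.
#' @param kind `"degree"` or `"eigen"` (spectral radius); recorded for
#'   interface clarity — the bound is shared.
#' @param K Number of nodes.
#' @return Score divided by `100 * (K - 1)`.
#' @export
normalize_score <- function(score, kind = c("degree", "eigen"), K = 6) {
  kind <- match.arg(kind)
  if (any(score < 0)) {
    stop_validation("centrality scores must be nonnegative",
                    "dynetox_bad_score")
  }
  score / (100 * (K - 1))
}

#' Critical nodes of a score vector
#'
#' All nodes within absolute tolerance `tol` of the maximum score. When
#' every score is zero (no co-occurrence at all) the set is empty — reported
#' as "-" in critical-node tables.
#'
#' @param scores Named numeric vector (one score per node).
#' @param tol Absolute tie tolerance.
#' @return Character vector of node labels (possibly empty).
#' @export
critical_nodes <- function(scores, tol = 1e-9) {
  m <- max(scores)
  if (m <= 0) return(character(0))
  names(scores)[m - scores <= tol]
}

#' Full centrality profile of one adjacency matrix
#'
#' @param adj An `adjacency_matrix`.
#' @param tol Tie tolerance for critical-node sets.
#' @return A `centrality_result`: list with `group`, `timepoint`, `degree`,
#'   `eigen`, `max_degree`, `spectral_radius`, `degree_critical`,
#'   `eigen_critical`.
#' @export
centrality_scores <- function(adj, tol = 1e-9) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  d <- degree_centrality(adj)
  v <- eigenvector_centrality(adj)
  structure(list(
    group = adj$group,
    timepoint = adj$timepoint,
    degree = d,
    eigen = v,
    max_degree = max(d),
    spectral_radius = spectral_radius(adj),
    degree_critical = critical_nodes(d, tol),
    eigen_critical = critical_nodes(v, tol)
  ), class = "centrality_result")
}

#' Per-node centrality trajectories
#'
#' Long-format degree and eigenvector centrality of every node over the
#' dynamic span, including the normalized degree used for global-trajectory
#' plots.
#'
#' @param net A `dynamic_network`.
#' @param tol Tie tolerance passed through to [centrality_scores()].
#' @return data.frame with columns `group`, `dpf`, `node`, `degree`,
#'   `degree_norm`, `eigen`.
#' @export
centrality_trajectories <- function(net, tol = 1e-9) {
  K <- catalog_size(net$catalog)
  rows <- list()
  for (g in names(net$groups)) {
    for (adj in net$groups[[g]]) {
      cs <- centrality_scores(adj, tol)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, dpf = adj$timepoint, node = net$catalog$labels,
        degree = unname(cs$degree),
        degree_norm = unname(normalize_score(cs$degree, "degree", K)),
        eigen = unname(cs$eigen),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Global centrality trajectories
#'
#' Maximum degree and spectral radius per (group, timepoint), raw and
#' normalized — the two group-level summaries of network connectivity over
#' developmental time.
#'
#' @inheritParams centrality_trajectories
#' @return data.frame with columns `group`, `dpf`, `max_degree`,
#'   `max_degree_norm`, `spectral_radius`, `spectral_radius_norm`.
#' @export
global_centrality <- function(net, tol = 1e-9) {
  K <- catalog_size(net$catalog)
  rows <- list()
  for (g in names(net$groups)) {
    for (adj in net$groups[[g]]) {
      md <- max_degree(adj, tol)
      rho <- spectral_radius(adj)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, dpf = adj$timepoint,
        max_degree = md$score,
        max_degree_norm = normalize_score(md$score, "degree", K),
        spectral_radius = rho,
        spectral_radius_norm = normalize_score(rho, "eigen", K),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Critical-node table
#'
#' For every (group, timepoint) and both score kinds (degree; eigenvector /
#' spectral radius) records the set of nodes attaining the maximum score.
#' Mirrors the reporting convention of published critical-node tables:
#' empty sets ("-") where no node has any centrality, two-node ties reported
#' in full, ties of three or more nodes flagged `omitted` (the membership is
#' retained in the `nodes` field for machine use, but writers replace it
#' with the literal "omitted").
#'
#' @param net A `dynamic_network`.
#' @param tol Tie tolerance.
#' @return A `critical_node_table`: data.frame with columns `group`, `dpf`,
#'   `kind` ("degree" or "eigen"), `nodes` (comma-joined labels, "" when
#'   empty), `n_nodes`, `omitted`.
#' @export
critical_node_table <- function(net, tol = 1e-9) {
  rows <- list()
  for (g in names(net$groups)) {
    for (adj in net$groups[[g]]) {
      cs <- centrality_scores(adj, tol)
      for (kind in c("degree", "eigen")) {
        nodes <- if (kind == "degree") cs$degree_critical else
          cs$eigen_critical
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, dpf = adj$timepoint, kind = kind,
          nodes = paste(nodes, collapse = ","),
          n_nodes = length(nodes),
          omitted = length(nodes) >= 3,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("critical_node_table", "data.frame"))
}

#' Read / write critical-node tables as CSV
#'
#' The CSV mirrors the published layout: "-" for empty cells, comma-joined
#' labels for ties of two, the literal "omitted" for ties of three or more.
#' `read_critical_node_table()` accepts both package-written files and
#' hand-encoded tables (e.g. a table transcribed from a publication).
#'
#' @param tbl A `critical_node_table`.
#' @param path CSV path.
#' @return `write_critical_node_table()`: the path, invisibly;
#'   `read_critical_node_table()`: a `critical_node_table`.
#' @export
write_critical_node_table <- function(tbl, path) {
  out <- data.frame(
    group = tbl$group, dpf = tbl$dpf, kind = tbl$kind,
    nodes = ifelse(tbl$omitted, "omitted",
                   ifelse(tbl$nodes == "", "-", tbl$nodes)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_critical_node_table
#' @export
read_critical_node_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(group = "character",
                                       kind = "character",
                                       nodes = "character"))
  need <- c("group", "dpf", "kind", "nodes")
  if (!all(need %in% names(df))) {
    stop_validation("critical-node table needs columns group,dpf,kind,nodes",
                    "dynetox_missing_column")
  }
  nodes <- trimws(df$nodes)
  omitted <- nodes == "omitted"
  nodes[omitted | nodes == "-"] <- ""
  res <- data.frame(
    group = df$group, dpf = as.integer(df$dpf), kind = df$kind,
    nodes = nodes,
    n_nodes = ifelse(nodes == "", 0L,
                     lengths(strsplit(nodes, ",", fixed = TRUE))),
    omitted = omitted,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("critical_node_table", "data.frame"))
}

round_half_up <- function(x) floor(x + 0.5)

#' Node-importance summary of a critical-node table
#'
#' Two complementary percentages over the non-omitted cells of a
#' critical-node table (both score kinds pooled):
#' \describe{
#'   \item{unique}{share of single-node cells whose sole critical node is v;
#'     the unique percentages sum to 100 whenever any single-node cell
#'     exists.}
#'   \item{with ties}{share of all node appearances belonging to v, counting
#'     each member of a tie once.}
#' }
#' Percentages are reported both unrounded and rounded to the nearest
#' integer (half away from zero).
#'
#' @param tbl A `critical_node_table`.
#' @param catalog An [outcome_catalog()] fixing the node universe.
#' @return An `importance_summary`: list with `unique_pct`,
#'   `unique_pct_rounded`, `with_ties_pct`, `with_ties_pct_rounded` (named
#'   numeric vectors over the catalog) plus denominators `n_unique_cells`
#'   and `n_appearances`. An all-empty table yields zero percentages, zero
#'   denominators and a warning.
#' @export
summarize_importance <- function(tbl, catalog = outcome_catalog()) {
  stopifnot(inherits(tbl, "critical_node_table") || is.data.frame(tbl))
  use <- tbl[!tbl$omitted & tbl$nodes != "", , drop = FALSE]
  labels <- catalog$labels
  zero <- stats::setNames(numeric(length(labels)), labels)

  sets <- strsplit(use$nodes, ",", fixed = TRUE)
  sets <- lapply(sets, trimws)
  bad <- setdiff(unlist(sets), labels)
  if (length(bad) > 0) {
    stop_validation(paste0("unknown node label(s): ",
                           paste(unique(bad), collapse = ", ")),
                    "dynetox_unknown_endpoint")
  }

  singles <- unlist(sets[lengths(sets) == 1])
  appearances <- unlist(sets)
  n_unique <- length(singles)
  n_app <- length(appearances)

  unique_pct <- zero
  with_ties_pct <- zero
  if (n_unique > 0) {
    tab <- table(factor(singles, levels = labels))
    unique_pct[] <- 100 * as.numeric(tab) / n_unique
  }
  if (n_app > 0) {
    tab <- table(factor(appearances, levels = labels))
    with_ties_pct[] <- 100 * as.numeric(tab) / n_app
  }
  if (n_app == 0) {
    warning("critical-node table has no populated cells; ",
            "importance summary is all zero")
  }
  structure(list(
    unique_pct = unique_pct,
    unique_pct_rounded = round_half_up(unique_pct),
    with_ties_pct = with_ties_pct,
    with_ties_pct_rounded = round_half_up(with_ties_pct),
    n_unique_cells = n_unique,
    n_appearances = n_app
  ), class = "importance_summary")
}

#' @export
print.importance_summary <- function(x, ...) {
  cat("Node importance (", x$n_unique_cells, " single-node cells, ",
      x$n_appearances, " appearances)\n", sep = "")
  df <- data.frame(unique_pct = round(x$unique_pct, 2),
                   with_ties_pct = round(x$with_ties_pct, 2))
  print(df)
  invisible(x)
}
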