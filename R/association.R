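#' 2x2 contingency table
#'
#' Cell layout for a pair of binary endpoints: `a` = both present, `b` =
#' first only, `c` = second only, `d` = neither; `a+b+c+d` is the number of
#' included individuals.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop_validation("contingency cells must be nonnegative integers",
                    "dynetox_infeasible_table")
  }
  x <- as.integer(round(x))
  structure(list(a = x[1], b = x[2], c = x[3], d = x[4]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("j=1", "j=0"), c("i=1", "i=0")))
  print(t(m))
  invisible(x)
}

#' Hypergeometric probability of a 2x2 cell under fixed margins
#'
#' Probability of observing cell count `a` in a 2x2 table with row margins
#' `r1` (= a+b), `r2` (= c+d) and first column margin `c1` (= a+c) when the
#' two classifications are independent. Computed in log space (via
#' `lchoose`) so tables with n up to 1e4 do not overflow. This is the null
#' kernel of Fisher's exact test.
#'
#' @param a Cell count; must lie in the feasible range
#'   `[max(0, c1 - r2), min(r1, c1)]`.
#' @param r1,r2 Row margins.
#' @param c1 First column margin.
#' @return Probability (numeric scalar).
#' @examples
#' hypergeom_pmf(3, 3, 3, 3)  # choose(3,3)*choose(3,0)/choose(6,3) = 0.05
#' @export
hypergeom_pmf <- function(a, r1, r2, c1) {
  x <- c(a, r1, r2, c1)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)) || c1 > r1 + r2) {
    stop_validation("inconsistent hypergeometric margins",
                    "dynetox_infeasible_table")
  }
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  if (a < lo || a > hi) {
    stop_validation(
      sprintf("cell count a=%d outside feasible range [%d, %d]", a, lo, hi),
      "dynetox_infeasible_table"
    )
  }
  exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
}

# log-pmf over the full feasible support for fixed margins
log_pmf_support <- function(r1, r2, c1) {
  supp <- seq.int(max(0, c1 - r2), min(r1, c1))
  list(supp = supp,
       logp = lchoose(r1, supp) + lchoose(r2, c1 - supp) -
              lchoose(r1 + r2, c1))
}

#' Two-sided Fisher exact test
#'
#' Exact two-sided p-value for independence in a 2x2 table by the
#' probability-mass rule: the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table. A relative tolerance (`tie_tol`, default 1e-7)
#' absorbs floating-point ties in the "equally probable" comparison, the
#' convention of mainstream statistics toolboxes. Degenerate tables (any
#' zero margin) carry no information about association and return 1. The
#' result is clipped to (0, 1].
#'
#' @param table A [contingency_table()] or numeric vector `c(a, b, c, d)`.
#' @param tie_tol Relative tolerance for probability ties.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(contingency_table(3, 0, 0, 3))  # 0.1
#' @export
fisher_exact_two_sided <- function(table, tie_tol = 1e-7) {
  if (inherits(table, "contingency_table")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    stopifnot(is.numeric(table), length(table) == 4)
    a <- table[1]; b <- table[2]; c <- table[3]; d <- table[4]
  }
  # canonical orientation (b <= c): transposing the table swaps b and c,
  # so this makes p(i, j) and p(j, i) bit-identical, not merely equal
  if (b > c) {
    tmp <- b; b <- c; c <- tmp
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    return(1)
  }
  s <- log_pmf_support(r1, r2, c1)
  probs <- exp(s$logp)
  p_obs <- probs[s$supp == a]
  p <- sum(probs[probs <= p_obs * (1 + tie_tol)])
  min(p, 1)
}

#' Build a pairwise 2x2 table from a cohort
#'
#' Cross-tabulates the resolved statuses of endpoints `i` and `j` at
#' timepoint `t` over the individuals of one exposure group. Individuals
#' with `NA` resolved status in either endpoint (possible only under the
#' `missing_after_death` policy) are excluded.
#'
#' @param study A `cohort_study`.
#' @param group Group label.
#' @param i,j Distinct endpoint codes.
#' @param t Study timepoint (dpf).
#' @param policy Post-mortality status policy, see [resolve_status()].
#' @return A [contingency_table()].
#' @export
build_contingency <- function(study, group, i, j, t,
                              policy = c("carry_forward",
                                         "missing_after_death")) {
  policy <- match.arg(policy)
  catalog <- attr(study, "catalog")
  if (!all(c(i, j) %in% catalog$labels)) {
    stop_validation("unknown endpoint code", "dynetox_unknown_endpoint")
  }
  if (i == j) {
    stop_validation("endpoints i and j must differ", "dynetox_bad_pair")
  }
  if (!t %in% study_timepoints(study)) {
    stop_validation(paste0("t=", t, " is not a study timepoint"),
                    "dynetox_bad_timepoint")
  }
  arr <- resolved_group_array(study, group, policy)
  ti <- match(t, study_timepoints(study))
  xi <- arr[, ti, i]
  xj <- arr[, ti, j]
  keep <- !is.na(xi) & !is.na(xj)
  xi <- xi[keep]; xj <- xj[keep]
  contingency_table(sum(xi == 1 & xj == 1), sum(xi == 1 & xj == 0),
                    sum(xi == 0 & xj == 1), sum(xi == 0 & xj == 0))
}

new_association_matrix <- function(group, timepoint, p) {
  stopifnot(isSymmetric(p), all(diag(p) == 1),
            all(p > 0), all(p <= 1))
  structure(list(group = group, timepoint = timepoint, p = p),
            class = "association_matrix")
}

#' Pairwise exact-test association matrices
#'
#' For every (group, timepoint) cell of the study, computes the two-sided
#' Fisher exact p-value for each of the `choose(K, 2)` unordered endpoint
#' pairs from the resolved 2x2 tables. With the six-endpoint catalog and a
#' 2-7 dpf window this yields 15 pairs in each of `4 groups x 6 days = 24`
#' matrices. Matrices are symmetric with unit diagonal by construction; an
#' outcome-free group has all off-diagonal p = 1.
#'
#' No multiplicity adjustment is applied by default — each pair is reported
#' at its raw exact-test level; `p_adjust` optionally applies
#' Bonferroni or Benjamini-Hochberg correction across the 15 pairs within
#' each (group, timepoint) matrix.
#'
#' @param study A `cohort_study`.
#' @param policy Post-mortality status policy, see [resolve_status()].
#' @param p_adjust Multiplicity correction across the pairs of one matrix:
#'   `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return List of `association_matrix` objects (fields `group`,
#'   `timepoint`, `p`), ordered by group then timepoint.
#' @export
association_matrices <- function(study,
                                 policy = c("carry_forward",
                                            "missing_after_death"),
                                 p_adjust = c("none", "bonferroni", "BH")) {
  policy <- match.arg(policy)
  p_adjust <- match.arg(p_adjust)
  catalog <- attr(study, "catalog")
  labels <- catalog$labels
  K <- length(labels)
  tps <- study_timepoints(study)
  out <- list()
  for (g in study_groups(study)) {
    arr <- resolved_group_array(study, g, policy, tps)
    for (ti in seq_along(tps)) {
      p <- diag(nrow = K)
      dimnames(p) <- list(labels, labels)
      diag(p) <- 1
      for (ii in 1:(K - 1)) {
        for (jj in (ii + 1):K) {
          xi <- arr[, ti, ii]
          xj <- arr[, ti, jj]
          keep <- !is.na(xi) & !is.na(xj)
          xi2 <- xi[keep]; xj2 <- xj[keep]
          pv <- fisher_exact_two_sided(c(
            sum(xi2 == 1 & xj2 == 1), sum(xi2 == 1 & xj2 == 0),
            sum(xi2 == 0 & xj2 == 1), sum(xi2 == 0 & xj2 == 0)
          ))
          p[ii, jj] <- pv
          p[jj, ii] <- pv
        }
      }
      if (p_adjust != "none") {
        up <- upper.tri(p)
        adj <- pmin(stats::p.adjust(p[up], method = p_adjust), 1)
        p[up] <- adj
        p[lower.tri(p)] <- t(p)[lower.tri(p)]
      }
      out[[length(out) + 1L]] <- new_association_matrix(g, tps[ti], p)
    }
  }
  out
}

#' Export association p-values as a long-format table
#'
#' One row per (group, dpf, unordered endpoint pair), pairs deduplicated to
#' catalog order (i before j). Optionally renders one p-value heatmap per
#' (group, dpf) via \pkg{pheatmap} when `plot_dir` is given.
#'
#' @param matrices List of `association_matrix` objects, as returned by
#'   [association_matrices()].
#' @param path Output CSV path.
#' @param plot_dir Optional directory for heatmap PNGs (requires the
#'   \pkg{pheatmap} package).
#' @return The long-format data.frame, invisibly.
#' @export
export_heatmap_table <- function(matrices, path, plot_dir = NULL) {
  rows <- lapply(matrices, function(m) {
    labels <- rownames(m$p)
    K <- length(labels)
    idx <- which(upper.tri(m$p), arr.ind = TRUE)
    data.frame(group = m$group, dpf = m$timepoint,
               endpoint_i = labels[idx[, 1]], endpoint_j = labels[idx[, 2]],
               p = m$p[idx], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_dir)) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      warning("package 'pheatmap' not available; skipping heatmap rendering")
    } else {
      dir.create(plot_dir, recursive = TRUE, showWarnings = FALSE)
      for (m in matrices) {
        f <- file.path(plot_dir, paste0(sanitize_label(m$group), "_",
                                        m$timepoint, "dpf_pvalues.png"))
        pheatmap::pheatmap(m$p, cluster_rows = FALSE, cluster_cols = FALSE,
                           display_numbers = TRUE, filename = f,
                           main = paste0(m$group, ", ", m$timepoint, " dpf"))
      }
    }
  }
  invisible(df)
}
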