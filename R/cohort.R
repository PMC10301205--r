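#' @keywords internal
cohort_columns <- function(catalog) {
  c("individual_id", "group", "dpf", catalog$labels)
}

#' Assemble and validate a cohort study
#'
#' A cohort study holds per-individual longitudinal binary endpoint records:
#' one row per individual per observation day (dpf, days post-fertilization),
#' one 0/1 column per catalog endpoint. Validation enforces the data model:
#' all columns present, binary values, integer timepoints, no duplicate
#' (individual, dpf) rows, and mortality as an absorbing state (M never
#' reverts from 1 to 0). Non-mortality endpoints are allowed to revert, since
#' real scoring data may contain transient calls.
#'
#' @param data A data.frame with columns `individual_id`, `group`, `dpf` and
#'   one column per endpoint code in `catalog$labels`.
#' @param catalog An [outcome_catalog()].
#' @return A `cohort_study`: the validated data.frame, sorted canonically by
#'   (group, individual_id, dpf), with the catalog attached as an attribute.
#' @details Validation failures raise classed conditions:
#'   `dynetox_missing_column`, `dynetox_nonbinary_value`,
#'   `dynetox_bad_timepoint`, `dynetox_duplicate_row`,
#'   `dynetox_mortality_reversal` (all subclasses of
#'   `dynetox_validation_error`).
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort_study <- function(data, catalog = outcome_catalog()) {
  data <- as.data.frame(data)
  need <- cohort_columns(catalog)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      "dynetox_missing_column"
    )
  }
  data <- data[need]
  data$individual_id <- as.character(data$individual_id)
  data$group <- as.character(data$group)

  if (!is.numeric(data$dpf) || any(is.na(data$dpf)) ||
      any(data$dpf != round(data$dpf))) {
    stop_validation("dpf must be integer-valued days post-fertilization",
                    "dynetox_bad_timepoint")
  }
  data$dpf <- as.integer(data$dpf)

  for (e in catalog$labels) {
    v <- data[[e]]
    if (!is.numeric(v) || any(is.na(v)) || !all(v %in% c(0, 1))) {
      stop_validation(paste0("endpoint '", e, "' contains non-binary values"),
                      "dynetox_nonbinary_value")
    }
    data[[e]] <- as.integer(v)
  }

  key <- paste(data$individual_id, data$dpf, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_validation(
      paste0("duplicate (individual, dpf) row: ",
             sub("\r", " at dpf ", dup, fixed = TRUE)),
      "dynetox_duplicate_row"
    )
  }

  # radix sort: locale-independent canonical order, so written CSVs are
  # byte-stable across platforms
  ord <- order(data$group, data$individual_id, data$dpf, method = "radix")
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  for (id in unique(data$individual_id)) {
    m <- data$M[data$individual_id == id]   # already dpf-sorted within id
    if (any(diff(m) < 0)) {
      stop_validation(
        paste0("mortality reversal (M goes 1 -> 0) for individual '", id, "'"),
        "dynetox_mortality_reversal"
      )
    }
  }

  structure(data,
            catalog = catalog,
            class = c("cohort_study", "data.frame"))
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("Cohort study: ", length(unique(x$individual_id)), " individuals, ",
      length(unique(x$group)), " group(s), dpf ",
      min(x$dpf), "-", max(x$dpf), "\n", sep = "")
  NextMethod()
}

#' Study timepoints and groups
#'
#' @param study A `cohort_study`.
#' @return `study_timepoints()`: sorted integer vector of observed dpf values.
#'   `study_groups()`: character vector of group labels in canonical order.
#' @export
study_timepoints <- function(study) sort(unique(study$dpf))

#' @rdname study_timepoints
#' @export
study_groups <- function(study) {
  sort(unique(study$group), method = "radix")
}

#' Read / write cohort CSV files
#'
#' Plain UTF-8 CSV with header exactly
#' `individual_id,group,dpf,PE,YSE,CM,SD,SBI,M` (endpoint columns follow the
#' catalog order) and 0/1 endpoint values. `write_cohort()` emits rows in
#' canonical (group, individual, dpf) order so identical studies produce
#' byte-identical files.
#'
#' @param path File path.
#' @param catalog An [outcome_catalog()].
#' @param study A `cohort_study`.
#' @return `read_cohort()`: a validated `cohort_study`. `write_cohort()`:
#'   the path, invisibly.
#' @export
read_cohort <- function(path, catalog = outcome_catalog()) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("cohort file not found: ", path),
                        class = c("dynetox_io_error")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(individual_id = "character",
                                       group = "character"))
  cohort_study(df, catalog)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(study, path) {
  stopifnot(inherits(study, "cohort_study"))
  utils::write.csv(as.data.frame(study), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Resolve one individual's endpoint statuses at arbitrary study timepoints.
#
# Returns a length(timepoints) x K integer matrix. Mortality is cumulative
# (1 from the first observed death day onward). For non-mortality endpoints
# the value at t is the last value recorded at dpf <= min(t, death day)
# (0 if none): under carry_forward a dead individual keeps the last status
# observed while alive; under missing_after_death those entries become NA at
# timepoints strictly after the death day.
resolve_series_matrix <- function(series, timepoints, policy, catalog) {
  labels <- catalog$labels
  ord <- order(series$dpf)
  dpf <- series$dpf[ord]
  m <- series$M[ord]
  death <- if (any(m == 1)) min(dpf[m == 1]) else Inf

  out <- matrix(0L, nrow = length(timepoints), ncol = length(labels),
                dimnames = list(timepoints, labels))
  alive_idx <- which(dpf <= death)          # rows at or before the death day
  adpf <- dpf[alive_idx]
  pos <- findInterval(timepoints, adpf)
  for (e in setdiff(labels, "M")) {
    vals <- series[[e]][ord][alive_idx]
    out[, e] <- ifelse(pos == 0L, 0L, vals[pmax(pos, 1L)])
  }
  out[, "M"] <- as.integer(timepoints >= death)
  if (policy == "missing_after_death" && is.finite(death)) {
    after <- timepoints > death
    if (any(after)) {
      out[after, setdiff(labels, "M")] <- NA_integer_
    }
  }
  out
}

#' Resolve an individual's endpoint status at a timepoint
#'
#' Scoring stops at death: once mortality occurs no further abnormality can
#' be assessed. This operation makes the post-mortality rule explicit. Under
#' `carry_forward` (the default) a non-mortality endpoint keeps, after death,
#' the last status observed while the individual was alive (0 if it was never
#' abnormal), so every enrolled individual contributes to every contingency
#' table; under `missing_after_death` such entries are `NA` at timepoints
#' strictly after the death day and the individual drops out of those tables.
#' Mortality itself always resolves cumulatively.
#'
#' @param series Rows of a `cohort_study` for a single individual (a
#'   data.frame with `dpf` and endpoint columns).
#' @param endpoint Endpoint code (one of the catalog labels).
#' @param t Integer timepoint (dpf).
#' @param policy `"carry_forward"` or `"missing_after_death"`.
#' @param catalog An [outcome_catalog()].
#' @return 0, 1 or `NA` (integer).
#' @export
resolve_status <- function(series, endpoint, t,
                           policy = c("carry_forward", "missing_after_death"),
                           catalog = outcome_catalog()) {
  policy <- match.arg(policy)
  if (!endpoint %in% catalog$labels) {
    stop_validation(paste0("unknown endpoint code: ", endpoint),
                    "dynetox_unknown_endpoint")
  }
  if (length(unique(series$individual_id)) > 1) {
    stop_validation("resolve_status expects rows for a single individual",
                    "dynetox_bad_series")
  }
  m <- resolve_series_matrix(series, t, policy, catalog)
  unname(m[1, endpoint])
}

# All individuals of one group resolved at every study timepoint:
# a list with ids and a 3-d array [individual, timepoint, endpoint].
resolved_group_array <- function(study, group, policy,
                                 timepoints = study_timepoints(study)) {
  catalog <- attr(study, "catalog")
  rows <- study[study$group == group, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_validation(paste0("unknown or empty group: ", group),
                    "dynetox_unknown_group")
  }
  ids <- unique(rows$individual_id)
  arr <- array(NA_integer_,
               dim = c(length(ids), length(timepoints),
                       catalog_size(catalog)),
               dimnames = list(ids, timepoints, catalog$labels))
  for (k in seq_along(ids)) {
    series <- rows[rows$individual_id == ids[k], , drop = FALSE]
    arr[k, , ] <- resolve_series_matrix(series, timepoints, policy, catalog)
  }
  arr
}

#' Incidence summary per group, timepoint and endpoint
#'
#' Counts individuals with resolved status 1 for every (group, dpf,
#' endpoint) cell; the denominator is the number of individuals with a
#' non-`NA` resolved status (under `carry_forward` this is always the
#' enrolled n of the group).
#'
#' @param study A `cohort_study`.
#' @param policy Post-mortality status policy, see [resolve_status()].
#' @return An `incidence_table`: data.frame with columns `group`, `dpf`,
#'   `endpoint`, `count`, `denominator`.
#' @export
incidence_summary <- function(study,
                              policy = c("carry_forward",
                                         "missing_after_death")) {
  policy <- match.arg(policy)
  catalog <- attr(study, "catalog")
  tps <- study_timepoints(study)
  out <- list()
  for (g in study_groups(study)) {
    arr <- resolved_group_array(study, g, policy, tps)
    for (ti in seq_along(tps)) {
      slab <- arr[, ti, , drop = FALSE]
      dim(slab) <- dim(slab)[c(1, 3)]
      out[[length(out) + 1L]] <- data.frame(
        group = g,
        dpf = tps[ti],
        endpoint = catalog$labels,
        count = as.integer(colSums(slab == 1L, na.rm = TRUE)),
        denominator = as.integer(colSums(!is.na(slab))),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("incidence_table", "data.frame"))
}
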