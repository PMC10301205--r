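#' Canonical abnormality catalog
#'
#' The six binary endpoints scored daily in a zebrafish embryo toxicity
#' assay, in the fixed node order used by every matrix in the package:
#' pericardial edema (PE), yolk sac edema (YSE), cranial malformation (CM),
#' spinal deformity (SD), delayed/failed swim bladder inflation (SBI) and
#' mortality (M). Mortality is always the last node; SBI is only defined
#' from 4 dpf onwards (a swim bladder is scored as delayed if not inflated
#' by 4 dpf).
#'
#' @return An object of class `outcome_catalog`: a list with components
#'   `labels` (ordered character vector of endpoint codes) and `long_names`
#'   (named character vector mapping code to description).
#' @examples
#' outcome_catalog()$labels
#' @export
outcome_catalog <- function() {
  structure(
    list(
      labels = c("PE", "YSE", "CM", "SD", "SBI", "M"),
      long_names = c(
        PE  = "pericardial edema",
        YSE = "yolk sac edema",
        CM  = "cranial malformation",
        SD  = "spinal deformity",
        SBI = "delayed/failed swim bladder inflation",
        M   = "mortality"
      )
    ),
    class = "outcome_catalog"
  )
}

#' @export
print.outcome_catalog <- function(x, ...) {
  cat("Outcome catalog (", length(x$labels), " endpoints):\n", sep = "")
  for (l in x$labels) cat("  ", format(l, width = 4), x$long_names[[l]], "\n")
  invisible(x)
}

catalog_size <- function(catalog) length(catalog$labels)

# Classed error so callers can tell data-validation failures apart from
# I/O or numerical ones (the CLI maps these to distinct exit codes).
stop_validation <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dynetox_validation_error")))
}
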