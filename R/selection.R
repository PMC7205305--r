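# Forward stepwise covariate selection by DIC.

#' Forward stepwise covariate selection by DIC
#'
#' Starting from the base gravity specification, each remaining candidate
#' covariate is added singly and its model fitted; the candidate with the
#' lowest DIC is adopted if it improves the incumbent DIC by more than
#' `threshold`. Selection stops when no candidate improves enough or the
#' candidates are exhausted. Fit failures for individual candidates are
#' skipped with a warning; selection errors only if every candidate fails.
#'
#' @param base character vector: the starting covariate set.
#' @param candidates character vector of covariates to consider, disjoint
#'   from `base`.
#' @param fit function taking a covariate-name vector and returning a list
#'   with at least element `dic`; must be deterministic given its own
#'   seeding.
#' @param threshold minimum DIC improvement to adopt a candidate
#'   (default 2, the conventional "substantial" DIC difference).
#' @return data.frame trace with columns `iteration`, `added`,
#'   `covariates` (comma-separated set), `dic`; attribute `"fits"` holds
#'   the fit object of each adopted model (the base first).
#' @export
forwardSelect <- function(base, candidates, fit, threshold = 2) {
  if (length(intersect(base, candidates)))
    stop("base and candidates must be disjoint")
  current <- base
  fitted <- fit(current)
  trace <- data.frame(iteration = 1L, added = "",
                      covariates = paste(current, collapse = ","),
                      dic = fitted$dic, stringsAsFactors = FALSE)
  fits <- list(fitted)
  remaining <- candidates
  while (length(remaining)) {
    dics <- rep(NA_real_, length(remaining))
    cand_fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      res <- tryCatch(fit(c(current, remaining[k])), error = function(e) {
        warning("fit failed for candidate ", remaining[k], ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) { dics[k] <- res$dic; cand_fits[[k]] <- res }
    }
    if (all(is.na(dics))) {
      if (nrow(trace) == 1L) stop("all candidate fits failed")
      break
    }
    best <- which.min(dics)  # ties: first (candidate order) wins
    if (trace$dic[nrow(trace)] - dics[best] <= threshold) break
    current <- c(current, remaining[best])
    trace <- rbind(trace, data.frame(
      iteration = nrow(trace) + 1L, added = remaining[best],
      covariates = paste(current, collapse = ","), dic = dics[best],
      stringsAsFactors = FALSE))
    fits <- c(fits, list(cand_fits[[best]]))
    remaining <- remaining[-best]
  }
  attr(trace, "fits") <- fits
  trace
}

#' Write a selection trace as delimited text
#'
#' Mirrors the iterative-selection table shape: iteration, explanatory
#' variables, DIC.
#'
#' @param trace the data.frame returned by [forwardSelect()].
#' @param path file path.
#' @param header optional `#`-prefixed comment lines.
#' @export
writeSelectionTrace <- function(trace, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  out <- data.frame(iteration = trace$iteration,
                    explanatory_variables = trace$covariates,
                    DIC = trace$dic)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
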