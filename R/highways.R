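#' Summarize transfer highways across gene families
#'
#' Counts, for every ordered (donor, recipient) species-edge pair, the
#' number of families in which a transfer over that pair has posterior
#' probability at or above `threshold` (inclusive, "50 % or more").  Edge
#' pairs exchanging genes in many families at high posterior probability are
#' candidate LGT highways.
#'
#' @param summaries list of `dlt_realization_summary` objects (one per
#'   family), or of data frames with columns `from`, `to`, `probability`.
#' @param threshold inclusive posterior probability cutoff, in (0, 1].
#' @return a data frame of class `dlt_highways`: `from`, `to`, `count`,
#'   sorted by decreasing count, with attributes `n_families` and
#'   `threshold`.
#' @export
summarize_highways <- function(summaries, threshold = 0.5) {
  if (!length(summaries)) stop("no family summaries supplied")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  tab <- list()
  for (s in summaries) {
    pp <- if (inherits(s, "dlt_realization_summary")) s$pair_prob else s
    stopifnot(all(c("from", "to", "probability") %in% names(pp)))
    hit <- pp[pp$probability >= threshold, , drop = FALSE]
    for (k in paste(hit$from, hit$to, sep = " -> "))
      tab[[k]] <- (tab[[k]] %||% 0L) + 1L
  }
  if (length(tab)) {
    sp <- strsplit(names(tab), " -> ", fixed = TRUE)
    out <- data.frame(from = vapply(sp, `[`, "", 1),
                      to = vapply(sp, `[`, "", 2),
                      count = unlist(tab, use.names = FALSE),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(from = character(), to = character(), count = integer())
  }
  attr(out, "n_families") <- length(summaries)
  attr(out, "threshold") <- threshold
  class(out) <- c("dlt_highways", "data.frame")
  out
}

#' @export
print.dlt_highways <- function(x, ...) {
  cat("Transfer highways across", attr(x, "n_families"),
      "families (posterior >=", attr(x, "threshold"), "):\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  else cat("  none\n")
  invisible(x)
}
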