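# Plain-text serialization of traces, realization posteriors and simulation
# truth records (all tab-separated with '#' header lines).

#' Read and write MCMC traces, realization samples and truth records
#'
#' Traces are tab-separated with one row per thinned sample (iteration, the
#' five model parameters, the two log densities and the gene-tree newick).
#' Realization posteriors are line-delimited: one row per (sample, vertex)
#' with the gene tree recorded in a `# gene=` header.  Truth records store
#' the simulation parameters, the true gene tree, the continuous realization
#' and the per-edge rates of the relaxed clock.
#'
#' @param fit a [dltrs] fit (or a trace data frame).
#' @param file path.
#' @return readers return the corresponding object; writers return `file`.
#' @export
write_trace <- function(fit, file) {
  tr <- if (inherits(fit, "dltrs")) fit$trace else fit
  utils::write.table(tr, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_trace
#' @param post a `dlt_realizations` posterior.
#' @export
write_realizations <- function(post, file) {
  stopifnot(inherits(post, "dlt_realizations"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(paste0("# gene=", vtree_newick(post$vt)), con)
  writeLines(paste0("# topology=", post$topology), con)
  writeLines(paste("sample", "clade", "point", "time", "delta", "type",
                   "from", "to", sep = "\t"), con)
  for (i in seq_along(post$samples)) {
    r <- post$samples[[i]]
    writeLines(paste(i, r$clade, r$point, format(r$time, digits = 12),
                     format(r$delta, digits = 12), r$type,
                     ifelse(is.na(r$from), ".", r$from),
                     ifelse(is.na(r$to), ".", r$to), sep = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_trace
#' @export
read_realizations <- function(file) {
  ln <- readLines(file, warn = FALSE)
  hd <- ln[startsWith(ln, "# ")]
  gene <- sub("^# gene=", "", hd[startsWith(hd, "# gene=")])
  topo <- sub("^# topology=", "", hd[startsWith(hd, "# topology=")])
  body <- ln[!startsWith(ln, "#")]
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          na.strings = ".")
  vt <- as_vtree(ape::read.tree(text = gene))
  samples <- lapply(split(df, df$sample), function(s) {
    r <- s[, c("clade", "point", "time", "delta", "type", "from", "to")]
    structure(r, class = c("dlt_realization", "data.frame"), topology = topo)
  })
  names(samples) <- NULL
  structure(list(samples = samples, vt = vt, grid = NULL, topology = topo),
            class = "dlt_realizations")
}

#' @rdname write_trace
#' @param h a usable `dlt_history` (after [relax_clock()]).
#' @export
write_truth <- function(h, file) {
  stopifnot(inherits(h, "dlt_history"), isTRUE(h$usable))
  con <- file(file, "w"); on.exit(close(con))
  th <- h$theta
  writeLines(c(
    paste0("# theta=", paste(names(th), unclass(th), sep = "=", collapse = ",")),
    paste0("# gene=", vtree_newick(h$pruned$vt)),
    paste0("# topology=", vtree_topology_key(h$pruned$vt))), con)
  r <- h$pruned$realization
  writeLines("[events]", con)
  writeLines(paste("clade", "time", "type", "from", "to", sep = "\t"), con)
  writeLines(paste(r$clade, format(r$time, digits = 12), r$type,
                   ifelse(is.na(r$from), ".", r$from),
                   ifelse(is.na(r$to), ".", r$to), sep = "\t"), con)
  if (!is.null(h$pruned$rates)) {
    vt <- h$pruned$vt
    keys <- vtree_clade_keys(vt)
    nonroot <- setdiff(seq_len(vt$nvert), vt$root)
    writeLines("[rates]", con)
    writeLines(paste("clade", "rate", "duration", "length", sep = "\t"), con)
    writeLines(paste(keys[nonroot],
                     format(h$pruned$rates[nonroot], digits = 12),
                     format(h$pruned$durations[nonroot], digits = 12),
                     format(h$pruned$vt$len[nonroot], digits = 12),
                     sep = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_trace
#' @export
read_truth <- function(file) {
  ln <- readLines(file, warn = FALSE)
  topo <- sub("^# topology=", "", ln[startsWith(ln, "# topology=")])
  gene <- sub("^# gene=", "", ln[startsWith(ln, "# gene=")])
  thline <- sub("^# theta=", "", ln[startsWith(ln, "# theta=")])
  kv <- strsplit(strsplit(thline, ",")[[1]], "=")
  theta <- as.numeric(vapply(kv, `[`, "", 2))
  names(theta) <- vapply(kv, `[`, "", 1)
  ev0 <- which(ln == "[events]")
  ev1 <- which(ln == "[rates]")
  end <- if (length(ev1)) ev1 - 1L else length(ln)
  events <- utils::read.table(text = paste(ln[(ev0 + 1L):end], collapse = "\n"),
                              header = TRUE, sep = "\t", na.strings = ".",
                              stringsAsFactors = FALSE)
  rates <- if (length(ev1))
    utils::read.table(text = paste(ln[(ev1 + 1L):length(ln)], collapse = "\n"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else NULL
  real <- data.frame(vertex = NA_integer_, clade = events$clade,
                     point = NA_integer_, time = events$time, delta = 0,
                     type = events$type, from = events$from, to = events$to,
                     stringsAsFactors = FALSE)
  real <- structure(real, class = c("dlt_realization", "data.frame"),
                    topology = topo, continuous = TRUE)
  list(realization = real, gene = ape::read.tree(text = gene),
       topology = topo, theta = as_params(theta), rates = rates)
}
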