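#' Evaluate an inferred realization posterior against simulated truth
#'
#' Compares a posterior of realizations with the recorded ground truth of a
#' simulated family.  Evaluation requires the posterior's gene-tree topology
#' to equal the true one (vertices are identified by leaf clades); families
#' whose MAP topology differs are flagged `skipped`.
#'
#' Reported per family: the fraction of posterior samples with the correct
#' number of transfers; the mean, over true transfer vertices, of the
#' posterior probability that that vertex is a transfer; the posterior
#' probability that the true donor (`from`), recipient (`to`) and exact
#' (from, to) pair appear, with indicators of whether each clears
#' `threshold`; and the four expected distances of [expected_distances()].
#'
#' @param truth a `dlt_realization` with attribute `topology` (e.g.
#'   `history$pruned$realization`) or a `dlt_history`.
#' @param post a `dlt_realizations` posterior.
#' @param grid the discretized species tree used for inference.
#' @param threshold posterior probability cutoff (inclusive).
#' @return a one-row data frame of class `dlt_evaluation`.
#' @export
evaluate_family <- function(truth, post, grid, threshold = 0.5) {
  if (inherits(truth, "dlt_history")) truth <- truth$pruned$realization
  stopifnot(inherits(post, "dlt_realizations"))
  tkey <- attr(truth, "topology")
  pkey <- post$topology
  base <- data.frame(skipped = FALSE, n_samples = length(post$samples),
                     true_transfers = sum(truth$type == "transfer"))
  if (!identical(tkey, pkey)) {
    out <- cbind(base, correct_count_frac = NA, vertex_frac = NA,
                 p_from = NA, p_to = NA, p_pair = NA,
                 from_recovered = NA, to_recovered = NA, pair_recovered = NA,
                 E_DGa = NA, E_DGm = NA, E_DTa = NA, E_DTm = NA)
    out$skipped <- TRUE
    class(out) <- c("dlt_evaluation", "data.frame")
    return(out)
  }
  ntrue <- sum(truth$type == "transfer")
  counts <- vapply(post$samples, function(r) sum(r$type == "transfer"), 0)
  su <- posterior_summary(post, threshold)
  tt <- truth[truth$type == "transfer", , drop = FALSE]
  n <- length(post$samples)
  if (nrow(tt)) {
    vertex_frac <- mean(vapply(tt$clade, function(cl)
      (su$vertex_transfer_prob[cl] %||% 0), 0))
    p_from <- mean(vapply(tt$from, function(f)
      mean(vapply(post$samples, function(r)
        any(r$type == "transfer" & r$from == f), TRUE)), 0))
    p_to <- mean(vapply(tt$to, function(f)
      mean(vapply(post$samples, function(r)
        any(r$type == "transfer" & r$to == f), TRUE)), 0))
    p_pair <- mean(vapply(seq_len(nrow(tt)), function(i) {
      hit <- su$pair_prob$probability[su$pair_prob$from == tt$from[i] &
                                      su$pair_prob$to == tt$to[i]]
      if (length(hit)) hit[1] else 0
    }, 0))
  } else {
    vertex_frac <- NA; p_from <- NA; p_to <- NA; p_pair <- NA
  }
  ed <- expected_distances(truth, post, grid)
  out <- cbind(base,
               correct_count_frac = mean(counts == ntrue),
               vertex_frac = vertex_frac,
               p_from = p_from, p_to = p_to, p_pair = p_pair,
               from_recovered = if (is.na(p_from)) NA else p_from >= threshold,
               to_recovered = if (is.na(p_to)) NA else p_to >= threshold,
               pair_recovered = if (is.na(p_pair)) NA else p_pair >= threshold,
               E_DGa = ed$E_DGa, E_DGm = ed$E_DGm,
               E_DTa = ed$E_DTa, E_DTm = ed$E_DTm)
  class(out) <- c("dlt_evaluation", "data.frame")
  out
}

#' @export
print.dlt_evaluation <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("Family skipped: inferred topology differs from the true gene tree\n")
    return(invisible(x))
  }
  cat("Family evaluation (", x$n_samples, " posterior samples, ",
      x$true_transfers, " true transfers):\n", sep = "")
  cat("  correct transfer count fraction:", format(x$correct_count_frac), "\n")
  if (!is.na(x$vertex_frac))
    cat("  true transfer vertex posterior:", format(x$vertex_frac),
        " from/to/pair probs:", format(x$p_from), format(x$p_to),
        format(x$p_pair), "\n")
  cat("  expected distances: DGa", format(x$E_DGa), " DGm", format(x$E_DGm),
      " DTa", format(x$E_DTa), " DTm", format(x$E_DTm), "\n")
  invisible(x)
}
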