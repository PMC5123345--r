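#' Multiple sequence alignments
#'
#' Alignments are stored as a labelled integer matrix (rows = sequences,
#' columns = sites) with codes 0..3 for A,C,G,T and 4 for missing (gaps and
#' any ambiguity code are treated as missing data).
#'
#' @param seqs named character vector of aligned sequences (equal lengths).
#' @return an object of class `dlt_msa`.
#' @export
dlt_msa <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be aligned (equal lengths)")
  chars <- toupper(do.call(rbind, strsplit(seqs, "")))
  codes <- matrix(match(chars, c("A", "C", "G", "T")) - 1L,
                  nrow = length(seqs))
  codes[is.na(codes)] <- 4L
  rownames(codes) <- names(seqs)
  structure(list(codes = codes, labels = names(seqs), nsite = ncol(codes)),
            class = "dlt_msa")
}

#' @export
print.dlt_msa <- function(x, ...) {
  cat("Alignment:", length(x$labels), "sequences x", x$nsite, "sites\n")
  invisible(x)
}

#' @rdname dlt_msa
#' @param file FASTA file path.
#' @export
read_fasta <- function(file) {
  dna <- ape::read.FASTA(file)
  seqs <- vapply(as.character(dna), paste, "", collapse = "")
  dlt_msa(seqs)
}

#' @rdname dlt_msa
#' @param msa a `dlt_msa`.
#' @export
write_fasta <- function(msa, file) {
  s <- apply(msa$codes, 1, function(r) paste(c("A", "C", "G", "T", "N")[r + 1],
                                             collapse = ""))
  writeLines(paste0(">", msa$labels, "\n", s), file)
  invisible(file)
}

# collapse identical columns into patterns with weights
msa_patterns <- function(msa, labels = msa$labels) {
  idx <- match(labels, msa$labels)
  if (anyNA(idx)) stop("alignment is missing sequences: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  m <- msa$codes[idx, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = m[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

#' Substitution models
#'
#' Constructs a reversible nucleotide substitution model with the rate matrix
#' normalized to one expected substitution per unit branch length.  `"JC69"`
#' (the default) has equal frequencies and exchangeabilities; `"GTR"` takes
#' stationary frequencies `pi` (length 4, summing to 1) and exchangeabilities
#' `rates` (length 6: AC, AG, AT, CG, CT, GT).
#'
#' @param name `"JC69"` or `"GTR"`.
#' @param pi stationary frequencies (GTR).
#' @param rates exchangeabilities (GTR).
#' @return an object of class `dlt_submodel`.
#' @export
substitution_model <- function(name = c("JC69", "GTR"), pi = NULL, rates = NULL) {
  name <- match.arg(name)
  if (name == "JC69") {
    pi <- rep(0.25, 4)
    Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
    mod <- list(name = name, pi = pi, Q = Q, type = 0L)
  } else {
    if (is.null(pi)) pi <- rep(0.25, 4)
    if (is.null(rates)) rates <- rep(1, 6)
    if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
    R <- matrix(0, 4, 4)
    R[lower.tri(R)] <- rates   # col-major lower tri = AC, AG, AT, CG, CT, GT
    R <- R + t(R)
    Q <- R %*% diag(pi)
    diag(Q) <- -rowSums(Q)
    norm <- -sum(pi * diag(Q))
    Q <- Q / norm
    # eigendecomposition of the symmetrized generator for stable P(t)
    B <- diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi))
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    U <- diag(1 / sqrt(pi)) %*% eg$vectors
    Uinv <- t(eg$vectors) %*% diag(sqrt(pi))
    mod <- list(name = name, pi = pi, Q = Q, type = 1L,
                U = U, Uinv = Uinv, lam = eg$values)
  }
  class(mod) <- "dlt_submodel"
  mod
}

# transition probability matrix
submodel_P <- function(model, t) {
  if (model$type == 0L) {
    ee <- exp(-4 * t / 3)
    P <- matrix(0.25 - 0.25 * ee, 4, 4)
    diag(P) <- 0.25 + 0.75 * ee
    P
  } else {
    P <- model$U %*% diag(exp(model$lam * t)) %*% model$Uinv
    P[P < 0] <- 0
    P
  }
}

submodel_cpp <- function(model) {
  if (model$type == 0L) list(type = 0L, pi = model$pi)
  else list(type = 1L, pi = model$pi, U = model$U, Uinv = model$Uinv,
            lam = model$lam)
}

#' Peeling likelihood of an alignment on a gene tree
#'
#' Computes `log P(D | G, l)` by the standard postorder peeling (pruning)
#' algorithm, with per-column rescaling.  Gaps and ambiguity codes are
#' missing data (all-ones tip partials).
#'
#' @param msa a [dlt_msa].
#' @param gene a rooted binary [ape::phylo] gene tree with edge lengths;
#'   leaf labels must match the alignment.
#' @param model a [substitution_model].
#' @return the log-likelihood (a scalar).
#' @export
peeling_likelihood <- function(msa, gene, model = substitution_model("JC69")) {
  vt <- if (inherits(gene, "phylo")) as_vtree(gene) else gene
  if (any(vt$len[-vt$root] < 0, na.rm = TRUE)) stop("negative edge length")
  pat <- msa_patterns(msa, vt$label)
  gcpp <- gene_cpp_peel(vt)
  lens <- vt$len; lens[vt$root] <- 0
  cpp_peel(pat$patterns, pat$weights, gcpp, lens, submodel_cpp(model))
}

# peeling needs no grid anchoring; lighter payload than gene_cpp()
gene_cpp_peel <- function(vt) {
  post <- vtree_postorder(vt)
  list(M = vt$nvert,
       children1 = ifelse(is.na(vt$children[, 1]), 0L, vt$children[, 1]),
       children2 = ifelse(is.na(vt$children[, 2]), 0L, vt$children[, 2]),
       postorder = post[post > vt$ntip],
       root = vt$root,
       tiprow = c(seq_len(vt$ntip), integer(vt$nvert - vt$ntip)))
}
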