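# Shared fixtures: all built in code, no data files.

fix_cherry <- function(stem = 0.3) dated_species_tree("(A:1,B:1);", stem = stem)

fix_3leaf <- function(stem = 0.2) dated_species_tree("((A:1,B:1):1,C:2);",
                                                     stem = stem)

fix_5leaf <- function(stem = 0.2)
  dated_species_tree("(((A:1,B:1):0.5,C:1.5):0.5,(D:1,E:1):1);", stem = stem)

fix_6leaf <- function(stem = 0.2)
  dated_species_tree("((((A:0.5,B:0.5):0.5,C:1):0.5,D:1.5):0.5,(E:1,F:1):1);",
                     stem = stem)

# random ultrametric species tree via a coalescent draw, rescaled to height h
rand_species_tree <- function(n, h = 1, stem = 0.1 * h) {
  phy <- ape::rcoal(n, tip.label = LETTERS[seq_len(n)])
  depth <- max(ape::node.depth.edgelength(phy)[seq_len(n)])
  phy$edge.length <- phy$edge.length / depth * h
  dated_species_tree(phy, stem = stem)
}

# random rooted binary gene tree over given leaf labels, exponential lengths
rand_gene_tree <- function(labels, mean_len = 0.3) {
  phy <- ape::rtree(length(labels), tip.label = labels, rooted = TRUE)
  phy$edge.length <- stats::rexp(nrow(phy$edge), 1 / mean_len)
  phy
}

rand_msa <- function(labels, nsite = 50) {
  seqs <- vapply(labels, function(x)
    paste(sample(c("A", "C", "G", "T"), nsite, replace = TRUE), collapse = ""),
    "")
  dlt_msa(seqs)
}

# chi-square goodness-of-fit with pooling of low-expectation categories
chisq_pooled <- function(obs, expd, min_exp = 5) {
  keep <- expd >= min_exp
  o <- c(obs[keep], sum(obs[!keep]))
  e <- c(expd[keep], sum(expd[!keep]))
  nz <- e > 0
  stat <- sum((o[nz] - e[nz])^2 / e[nz])
  df <- sum(nz) - 1L
  stats::pchisq(stat, df, lower.tail = FALSE)
}
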