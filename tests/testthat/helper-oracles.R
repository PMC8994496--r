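# Independent brute-force oracles used to validate the analytical routines.
# Each oracle implements the definition directly and stays independent of the
# package code path it checks.

# BH step-up from the definition: adj_(i) = min_{j >= i} m * p_(j) / j on the
# sorted vector, capped at 1, mapped back to the input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability as an explicit sum over k' >= k.
hyper_tail_bruteforce <- function(k, K, n, N) {
  kk <- seq(k, min(K, n))
  if (length(kk) == 0) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# One-sided Fisher p by enumerating every 2x2 table with the observed margins.
fisher_enum <- function(a, b, c, d) {
  row1 <- a + b
  col1 <- a + c
  N <- a + b + c + d
  avals <- max(0, col1 - (N - row1)):min(row1, col1)
  probs <- vapply(avals, function(x)
    choose(col1, x) * choose(N - col1, row1 - x) / choose(N, row1),
    numeric(1))
  sum(probs[avals >= a])
}

# Strict-containment gene-QTL mapping by an all-pairs double loop.
qtl_bruteforce <- function(loci, qtls) {
  rows <- list()
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(qtls))) {
    if (loci$chrom[i] == qtls$chrom[j] &&
        qtls$start[j] <= loci$start[i] && loci$end[i] <= qtls$end[j]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = loci$gene[i], qtl_id = qtls$qtl_id[j],
        trait = qtls$trait[j], trait_class = qtls$trait_class[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), qtl_id = character(),
                      trait = character(), trait_class = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$qtl_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Network extraction by scanning every node against the filter definitions.
network_bruteforce <- function(db, seeds, params, profile) {
  reg_cut <- if (profile == "common") params$min_degree_regulator_common
  else params$min_degree_regulator
  regulators <- targets <- character()
  for (node in setdiff(db$nodes, seeds)) {
    re <- db$edges[db$edges$source == node &
                     db$edges$relation_type == "Regulation" &
                     db$edges$target %in% seeds, , drop = FALSE]
    if (nrow(re) > 0 &&
        length(unique(re$target)) >= params$min_connected &&
        max(re$n_references) >= params$min_refs_regulator &&
        db$degree[[node]] >= reg_cut)
      regulators <- c(regulators, node)
    te <- db$edges[db$edges$target == node &
                     db$edges$relation_type == "Expression" &
                     db$edges$source %in% seeds, , drop = FALSE]
    if (nrow(te) > 0 &&
        length(unique(te$source)) >= params$min_connected &&
        max(te$n_references) >= params$min_refs_target &&
        db$degree[[node]] >= params$min_degree_target)
      targets <- c(targets, node)
  }
  list(regulators = sort(regulators), targets = sort(targets))
}

# Random edge list for oracle-equivalence tests.
random_edge_list <- function(n_nodes, n_edges) {
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  dst <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != dst
  data.frame(source = src[keep], target = dst[keep],
             relation_type = sample(c("Regulation", "Expression"),
                                    sum(keep), replace = TRUE),
             n_references = sample(1:8, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}
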