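# Shared in-code fixtures for the suite.

# 3-gene / 3-sample matrix used across the pairwise-method tests:
# A and B are parallel (their difference is constant), C wobbles.
abc_matrix <- function() {
  v <- rbind(A = c(20, 21, 22),
             B = c(25, 26, 27),
             C = c(20, 22, 21))
  colnames(v) <- c("s1", "s2", "s3")
  cq_matrix(v)
}

# random complete cq_matrix, genes x samples
random_cq_matrix <- function(G = 5, S = 8, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(G * S, mean = 20, sd = 2), G, S,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(S))))
  cq_matrix(v)
}

# brute-force mean pairwise dCq SD, written independently of the package path
brute_force_deltacq <- function(v) {
  G <- nrow(v)
  sapply(seq_len(G), function(j) {
    sds <- c()
    for (k in seq_len(G)) {
      if (k == j) next
      d <- v[j, ] - v[k, ]
      sds <- c(sds, sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
    }
    mean(sds)
  })
}

# brute-force geNorm M from a quantity matrix
brute_force_genorm_m <- function(q) {
  G <- nrow(q)
  sapply(seq_len(G), function(j) {
    vjk <- c()
    for (k in seq_len(G)) {
      if (k == j) next
      a <- log2(q[j, ] / q[k, ])
      vjk <- c(vjk, sqrt(sum((a - mean(a))^2) / (length(a) - 1)))
    }
    mean(vjk)
  })
}

# a stop-terminated synthetic CDS of the requested nucleotide length
# (start codon + sense codons + stop), avoiding internal ATG/stop artifacts
synthetic_cds <- function(n_nt, seed = 1) {
  stopifnot(n_nt %% 3 == 0, n_nt >= 6)
  set.seed(seed)
  sense <- c("GCT", "GCC", "TTT", "GGA", "CTG", "AAA", "GAT", "CCA",
             "TCT", "GTG", "CAT", "AGG")
  body <- sample(sense, n_nt / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}
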