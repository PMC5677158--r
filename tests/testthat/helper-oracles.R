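suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
  library(purrr)
  library(withr)
})

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans and direct enumeration.

# brute-force both-strand exact mapper: scan every position of every
# chromosome on both strands for the fragment
brute_force_map <- function(fragment, genome) {
  hits <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    rc <- as.character(Biostrings::reverseComplement(genome[[ch]]))
    L <- nchar(s)
    w <- nchar(fragment)
    for (i in seq_len(L - w + 1)) {
      if (substr(s, i, i + w - 1) == fragment) {
        hits[[length(hits) + 1]] <- list(chrom = ch, pos = i - 1L,
                                         strand = "+")
      }
      if (substr(rc, i, i + w - 1) == fragment) {
        # rc 1-based start i -> plus-strand 0-based junction = L - i
        hits[[length(hits) + 1]] <- list(chrom = ch, pos = L - i,
                                         strand = "-")
      }
    }
  }
  hits
}

brute_force_status <- function(fragment, genome) {
  hits <- brute_force_map(fragment, genome)
  if (length(hits) == 0) return(list(status = "UNMAPPED"))
  if (length(hits) > 1) return(list(status = "MULTI"))
  c(list(status = "UNIQUE"), hits[[1]])
}

# enumeration oracle for the exact two-sided Wilcoxon rank-sum p-value,
# computed by direct pair counting (not rank sums) over all labelings
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  labelings <- utils::combn(N, n1)
  devs <- apply(labelings, 2, function(idx) abs(u_of(idx) - mu))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

event_key <- function(d) paste(d$chrom, d$pos, d$strand)

# small standard simulated library used by several tests
make_small_pipeline <- function(n = 60, len = 30000, seed = 5) {
  g <- sim_genome(1, len, seed = seed)
  p <- sim_params(n_insertions = n, seed = seed)
  truth <- sim_insertions(g, NULL, NULL, p)
  reads <- sim_library(g, truth, p)
  mappings <- map_fragments(trim_junction(reads, tag = p$tag), g)
  list(genome = g, params = p, truth = truth, reads = reads,
       mappings = mappings,
       events = call_insertions(mappings, "toy"))
}
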