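# Independent oracles and small random-instance generators used across the
# suite. These deliberately avoid the package's main code paths.

# a complete, fully functional landscape with integer-ish random lambdas
random_functional_landscape <- function(L, lambda_anc = 357, integer = TRUE) {
  n <- 2L^L
  lam <- lambda_anc + c(0, if (integer) sample(-30:60, n - 1L, replace = TRUE)
                        else stats::rnorm(n - 1L, 0, 15))
  landscape(paste0("m", seq_len(L)), lambda_anc, lambda = lam,
            functional = rep(TRUE, n))
}

# random landscape with a random nonfunctional set (ancestor always kept)
random_lethal_landscape <- function(L, p_nf = 0.3, lambda_anc = 357) {
  n <- 2L^L
  lam <- lambda_anc + c(0, sample(-30:60, n - 1L, replace = TRUE))
  fun <- c(TRUE, stats::runif(n - 1L) >= p_nf)
  lam[!fun] <- NA_real_
  landscape(paste0("m", seq_len(L)), lambda_anc, lambda = lam,
            functional = fun)
}

# exhaustive minimum-change count over all internal-node labelings
brute_fitch_score <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  alphabet <- sort(unique(states))
  n_int <- tree$Nnode
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), n_int),
                    list(stringsAsFactors = FALSE)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- c(states, unlist(grid[i, ], use.names = FALSE))
    changes <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    best <- min(best, changes)
  }
  best
}

# accessibility count by a direct walk over explicitly listed permutations,
# written against the landscape's raw vectors (no trajectory code)
brute_accessible_count <- function(ls) {
  L <- ls$L
  P <- permutations(seq_len(L))
  bitvals <- 2L^(0:(L - 1L))
  ok <- 0L
  for (i in seq_len(nrow(P))) {
    m <- 0L
    good <- TRUE
    for (j in seq_len(L)) {
      m <- m + bitvals[P[i, j]]
      if (!ls$functional[m + 1L]) { good <- FALSE; break }
    }
    if (good) ok <- ok + 1L
  }
  ok
}
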