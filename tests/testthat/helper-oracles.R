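# Independent oracles used across tests. These are deliberately written as
# direct enumerations, not via the package's matrix builders.

# Combined natural-abundance + purity forward matrix by exhaustive 2^n
# enumeration of heavy/light states: each of the j nominally labeled atoms is
# heavy with probability p + (1 - p) * a (a failed tracer atom is an ordinary
# light atom with its natural chance of being heavy), each unlabeled atom
# with probability a. Set p = 1 for the natural-abundance matrix alone, a = 0
# for the purity matrix alone.
brute_force_matrix <- function(n, a, p) {
  Fm <- matrix(0, n + 1, n + 1)
  cfgs <- as.matrix(expand.grid(rep(list(0:1), n)))
  heavy <- rowSums(cfgs)
  for (j in 0:n) {
    probs <- c(rep(p + (1 - p) * a, j), rep(a, n - j))
    pr <- apply(cfgs, 1, function(cfg) prod(ifelse(cfg == 1, probs, 1 - probs)))
    for (i in 0:n) Fm[i + 1, j + 1] <- sum(pr[heavy == i])
  }
  Fm
}

# Exhaustive grid search over the weight simplex (step `step`) minimising
# ||A w - b||; the independent oracle for the constrained isotopomer solver.
grid_simplex_search <- function(A, b, step = 1e-3) {
  k <- ncol(A)
  stopifnot(k <= 3)
  g <- seq(0, 1, by = step)
  if (k == 1) return(1)
  if (k == 2) {
    W <- rbind(g, 1 - g)
  } else {
    W <- do.call(cbind, lapply(g, function(w1) {
      w2 <- g[g <= 1 - w1 + 1e-12]
      rbind(w1, w2, 1 - w1 - w2)
    }))
  }
  resid <- colSums((A %*% W - as.numeric(b))^2)
  W[, which.min(resid)]
}

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

noise_free_params <- function(preset = "healthy", ...) {
  simulation_params(preset, noise_cv = 0, protein_cv = 0, ...)
}
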