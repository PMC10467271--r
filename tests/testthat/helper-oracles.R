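# Definition-level brute-force oracles used to cross-check the package's
# graph-metric implementations. These deliberately use different algorithms
# (Floyd-Warshall, exhaustive triple enumeration, path-counting identities,
# closed-form OLS) than the package (BFS expansion, Brandes accumulation).

rand_adjacency <- function(n, p) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A | t(A)
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering_nodal <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]]) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

oracle_efficiencies <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D; diag(inv) <- 0
  eg <- sum(inv) / (n * (n - 1))
  ne <- rowSums(inv) / (n - 1)
  nle <- sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    Ds <- oracle_distances(sub)
    invs <- 1 / Ds; diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  })
  list(Eg = eg, Ne = ne, NLe = nle, Eloc = mean(nle))
}

# number of shortest s->t paths from Floyd-Warshall distances by dynamic
# programming over distance layers
oracle_sigma <- function(A, D, s) {
  n <- nrow(A)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(D[s, ])
  for (t in ord) {
    if (t == s || !is.finite(D[s, t])) next
    pre <- which(A[t, ] & D[s, ] == D[s, t] - 1)
    sigma[t] <- sum(sigma[pre])
  }
  sigma
}

# pair-counting betweenness: Bc(i) = sum over s<t of
# sigma(s,i) sigma(i,t) / sigma(s,t) when i lies on a shortest s-t path
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sig <- t(sapply(seq_len(n), function(s) oracle_sigma(A, D, s)))
  bc <- numeric(n)
  for (s in seq_len(n - 1))
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || sig[s, t] == 0) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
            D[s, i] + D[i, t] == D[s, t])
          bc[i] <- bc[i] + sig[s, i] * sig[i, t] / sig[s, t]
      }
    }
  bc
}

# Newman's assortativity through the summation formula over edges
oracle_assortativity <- function(A) {
  e <- which(upper.tri(A) & A, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  k <- rowSums(A)
  j_ <- c(k[e[, 1]], k[e[, 2]])
  h_ <- c(k[e[, 2]], k[e[, 1]])
  m <- length(j_)
  num <- mean(j_ * h_) - mean((j_ + h_) / 2)^2
  den <- mean((j_^2 + h_^2) / 2) - mean((j_ + h_) / 2)^2
  if (den == 0) return(NA_real_)
  num / den
}

oracle_hierarchy <- function(A) {
  k <- rowSums(A)
  ncp <- oracle_clustering_nodal(A)
  elig <- which(k >= 2 & ncp > 0)
  if (length(elig) < 2) return(NA_real_)
  lx <- log(k[elig]); ly <- log(ncp[elig])
  if (stats::sd(lx) == 0) return(NA_real_)
  -unname(stats::coef(stats::lm(ly ~ lx))[2])
}

# sort-and-cut binarization oracle
oracle_binarize <- function(z, sparsity) {
  n <- nrow(z)
  z[z < 0] <- 0
  k_target <- floor(sparsity * n * (n - 1) / 2)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], w = z[ut])
  df <- df[order(-df$w, df$i, df$j), ]
  df <- df[df$w > 0, , drop = FALSE]
  sel <- df[seq_len(min(k_target, nrow(df))), , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(sel))) {
    adj[sel$i[r], sel$j[r]] <- TRUE
    adj[sel$j[r], sel$i[r]] <- TRUE
  }
  adj
}

# ring lattice where each node connects to its k nearest neighbours, with
# random rewiring probability p (small-world construction)
ring_lattice <- function(n = 14, k = 4, p = 0) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- TRUE
    }
  if (p > 0) {
    e <- which(upper.tri(A) & A, arr.ind = TRUE)
    for (r in seq_len(nrow(e))) {
      if (stats::runif(1) < p) {
        i <- e[r, 1]
        cand <- which(!A[i, ] & seq_len(n) != i)
        if (length(cand)) {
          j_new <- cand[sample.int(length(cand), 1)]
          A[e[r, 1], e[r, 2]] <- A[e[r, 2], e[r, 1]] <- FALSE
          A[i, j_new] <- A[j_new, i] <- TRUE
        }
      }
    }
  }
  A
}
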