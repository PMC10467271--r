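#' Degree centrality
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return Integer vector of node degrees (Dc).
#' @export
degree_centrality <- function(net) {
  A <- as_adjacency(net)
  as.integer(rowSums(A))
}

#' Nodal and mean clustering coefficients
#'
#' `NCp_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node i; nodes with degree < 2 get 0. `Cp` is the mean of `NCp`
#' over all nodes.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return List with `nodal` (NCp vector) and `global` (Cp).
#' @export
clustering_coefficient <- function(net) {
  A <- as_adjacency(net) * 1
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ncp <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(nodal = ncp, global = mean(ncp))
}

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first expansion by boolean matrix products; unreachable pairs are
#' `Inf`, the diagonal 0.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return Node x node distance matrix.
#' @export
shortest_path_lengths <- function(net) {
  A <- as_adjacency(net) * 1
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  cur <- diag(1, n)
  d <- 0
  repeat {
    d <- d + 1
    nxt <- ((cur %*% A) > 0) * 1
    nxt <- pmax(nxt, cur)
    new <- nxt > cur
    if (!any(new)) break
    D[new] <- d
    cur <- nxt
  }
  D
}

#' Characteristic path length
#'
#' Mean hop count over connected ordered node pairs; disconnected pairs are
#' excluded. `NA` if no pair is connected.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param D Optional precomputed distance matrix.
#' @return Lp (scalar, possibly `NA`).
#' @export
characteristic_path_length <- function(net, D = NULL) {
  if (is.null(D)) D <- shortest_path_lengths(net)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (!length(fin)) return(NA_real_)
  mean(fin)
}

#' Global, nodal and local efficiencies
#'
#' `Eg` is the mean inverse distance over ordered pairs (disconnected pairs
#' contribute 0); `Ne_i` the mean inverse distance from node i to all
#' others; `NLe_i` the global efficiency of the subgraph induced by i's
#' neighbors (0 when degree < 2); `Eloc` the mean of `NLe`.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param D Optional precomputed distance matrix.
#' @return List with `Eg`, `Ne`, `NLe`, `Eloc`.
#' @export
network_efficiencies <- function(net, D = NULL) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (is.null(D)) D <- shortest_path_lengths(A)
  inv <- 1 / D
  diag(inv) <- 0
  eg <- sum(inv) / (n * (n - 1))
  ne <- rowSums(inv) / (n - 1)
  nle <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    Ds <- shortest_path_lengths(sub)
    invs <- 1 / Ds
    diag(invs) <- 0
    m <- length(nb)
    nle[i] <- sum(invs) / (m * (m - 1))
  }
  list(Eg = eg, Ne = ne, NLe = nle, Eloc = mean(nle))
}

#' Betweenness centrality (Brandes' algorithm, unnormalized)
#'
#' Fraction of shortest paths between all node pairs passing through each
#' node, summed over unordered pairs within components.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return Numeric vector of Bc values.
#' @export
betweenness_centrality <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

#' Degree assortativity (Newman's r)
#'
#' Pearson correlation of the degrees at the two endpoints of each edge,
#' each edge counted in both orientations. `NA` when the endpoint degrees
#' have zero variance (e.g. regular graphs) or fewer than 2 edges exist.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return r in [-1, 1], or `NA`.
#' @export
assortativity_coefficient <- function(net) {
  A <- as_adjacency(net)
  k <- rowSums(A)
  e <- which(upper.tri(A) & A, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Hierarchy coefficient
#'
#' Exponent b of the power-law decline of clustering with degree,
#' `NCp ~ Dc^-b`, estimated as minus the OLS slope of `log(NCp)` on
#' `log(Dc)` over eligible nodes (degree >= 2 and NCp > 0). `NA` when fewer
#' than 2 eligible nodes remain or their degrees do not vary.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @return b (scalar, possibly `NA`).
#' @export
hierarchy_coefficient <- function(net) {
  A <- as_adjacency(net)
  k <- rowSums(A)
  ncp <- clustering_coefficient(A)$nodal
  elig <- which(k >= 2 & ncp > 0)
  if (length(elig) < 2) return(NA_real_)
  lx <- log(k[elig]); ly <- log(ncp[elig])
  if (stats::sd(lx) == 0) return(NA_real_)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  -slope
}

#' Degree-preserving rewired reference networks
#'
#' Generates random surrogates with the exact degree sequence of the input
#' by repeated double-edge swaps (at least `10 * E` attempted swaps per
#' surrogate). Connectedness is not enforced. If no swap is ever possible
#' (e.g. stars, complete graphs) the surrogate equals the original and a
#' warning is issued.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param n_rand Number of surrogates.
#' @param seed Optional seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return List of adjacency matrices.
#' @export
random_references <- function(net, n_rand = 100, seed = NULL,
                              swaps_per_edge = 10) {
  A0 <- as_adjacency(net)
  if (!is.null(seed)) set.seed(seed)
  e0 <- which(upper.tri(A0) & A0, arr.ind = TRUE)
  n_e <- nrow(e0)
  if (n_e < 2) stop("need at least 2 edges to rewire")
  out <- vector("list", n_rand)
  for (r in seq_len(n_rand)) {
    A <- A0
    edges <- e0
    attempts <- swaps_per_edge * n_e
    swapped <- FALSE
    for (it in seq_len(attempts)) {
      pick <- sample.int(n_e, 2)
      a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
      c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      # propose (a,d) and (c_,b)
      if (a == d || c_ == b) next
      if (A[a, d] || A[c_, b]) next
      A[a, b] <- A[b, a] <- FALSE
      A[c_, d] <- A[d, c_] <- FALSE
      A[a, d] <- A[d, a] <- TRUE
      A[c_, b] <- A[b, c_] <- TRUE
      edges[pick[1], ] <- c(min(a, d), max(a, d))
      edges[pick[2], ] <- c(min(c_, b), max(c_, b))
      swapped <- TRUE
    }
    if (!swapped)
      warning("no valid double-edge swap found; surrogate equals original")
    out[[r]] <- A
  }
  out
}

#' Small-world indices against rewired references
#'
#' `Gamma = Cp / mean(Cp_rand)`, `Lambda = Lp / mean(Lp_rand)`,
#' `Sigma = Gamma / Lambda`. A value is `NA` when its normalization is
#' degenerate (zero mean reference clustering, undefined path length).
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param refs List of reference adjacency matrices, e.g. from
#'   [random_references()].
#' @return Named list with `Gamma`, `Lambda`, `Sigma`.
#' @export
small_world_indices <- function(net, refs) {
  if (!length(refs)) stop("refs must be a nonempty list")
  cp <- clustering_coefficient(net)$global
  lp <- characteristic_path_length(net)
  cp_r <- mean(vapply(refs, function(a) clustering_coefficient(a)$global,
                      numeric(1)))
  lp_r <- mean(vapply(refs, function(a) characteristic_path_length(a),
                      numeric(1)), na.rm = TRUE)
  gamma <- if (is.na(cp) || cp_r == 0) NA_real_ else cp / cp_r
  lambda <- if (is.na(lp) || is.na(lp_r) || lp_r == 0) NA_real_ else lp / lp_r
  sigma <- if (is.na(gamma) || is.na(lambda) || lambda == 0) NA_real_ else
    gamma / lambda
  list(Gamma = gamma, Lambda = lambda, Sigma = sigma)
}

#' Area under the metric-vs-sparsity curve
#'
#' Trapezoidal integral of a metric across the sparsity sweep, the
#' threshold-free summary used for group comparison and classification. Any
#' missing value makes the AUC missing (with the reason attached).
#'
#' @param values Metric values at each threshold.
#' @param sparsities Ascending thresholds (same length).
#' @return The AUC, or `NA` with attribute `"reason"`.
#' @export
metric_auc <- function(values, sparsities) {
  stopifnot(length(values) == length(sparsities), length(values) >= 2,
            !is.unsorted(sparsities))
  if (anyNA(values)) {
    out <- NA_real_
    attr(out, "reason") <- paste0("missing at threshold(s) ",
                                  paste(sparsities[is.na(values)],
                                        collapse = ", "))
    return(out)
  }
  sum(diff(sparsities) * (values[-1] + values[-length(values)]) / 2)
}

.global_metric_names <- c("Cp", "Lp", "Gamma", "Lambda", "Sigma",
                          "Eloc", "Eg", "r", "b")
.nodal_metric_names <- c("NCp", "Ne", "NLe", "Dc", "Bc")

#' All global and nodal metrics of one binary network
#'
#' Computes the 9 global metrics (Cp, Lp, Gamma, Lambda, Sigma, Eloc, Eg,
#' assortativity r, hierarchy b) and the 5 nodal metrics (NCp, Ne, NLe, Dc,
#' Bc). The small-world triple requires rewired references; without `refs`
#' it is `NA`.
#'
#' @param net A `binary_network` or adjacency matrix.
#' @param refs Optional list of reference adjacencies for Gamma/Lambda/Sigma.
#' @return List with `global` (named length-9 vector) and `nodal`
#'   (5 x n matrix, rows NCp/Ne/NLe/Dc/Bc).
#' @export
network_metrics <- function(net, refs = NULL) {
  A <- as_adjacency(net)
  n <- nrow(A)
  cl <- clustering_coefficient(A)
  D <- shortest_path_lengths(A)
  lp <- characteristic_path_length(A, D)
  eff <- network_efficiencies(A, D)
  bc <- betweenness_centrality(A)
  dc <- degree_centrality(A)
  sw <- if (!is.null(refs)) small_world_indices(A, refs) else
    list(Gamma = NA_real_, Lambda = NA_real_, Sigma = NA_real_)
  glob <- c(Cp = cl$global, Lp = lp, Gamma = sw$Gamma, Lambda = sw$Lambda,
            Sigma = sw$Sigma, Eloc = eff$Eloc, Eg = eff$Eg,
            r = assortativity_coefficient(A), b = hierarchy_coefficient(A))
  nodal <- rbind(NCp = cl$nodal, Ne = eff$Ne, NLe = eff$NLe,
                 Dc = as.numeric(dc), Bc = bc)
  colnames(nodal) <- sprintf("ch%02d", seq_len(n))
  list(global = glob, nodal = nodal)
}

#' Metric sweep and AUC summary for one connectivity matrix
#'
#' Binarizes the matrix across the sparsity sweep, computes all metrics at
#' each threshold (with seeded degree-preserving surrogates for the
#' small-world triple) and integrates each metric curve into its AUC.
#'
#' @param cm A `connectivity_matrix`.
#' @param sparsities Threshold sweep (default 0.15 to 0.50 by 0.05).
#' @param n_rand Surrogates per threshold for Gamma/Lambda/Sigma; 0 skips
#'   the small-world triple.
#' @param seed Seed for the surrogate generator.
#' @return An object of class `metric_set`: list with `per_threshold`
#'   (`global` 9 x T matrix, `nodal` 5 x N x T array), `auc` (`global`
#'   length-9 vector, `nodal` 5 x N matrix), and `sparsities`.
#' @export
metric_sweep <- function(cm, sparsities = seq(0.15, 0.50, by = 0.05),
                         n_rand = 100, seed = NULL) {
  nets <- threshold_sweep(cm, sparsities)
  nT <- length(nets)
  n <- nrow(as_adjacency(nets[[1]]))
  glob <- matrix(NA_real_, length(.global_metric_names), nT,
                 dimnames = list(.global_metric_names, names(nets)))
  nodal <- array(NA_real_, dim = c(length(.nodal_metric_names), n, nT),
                 dimnames = list(.nodal_metric_names,
                                 sprintf("ch%02d", seq_len(n)), names(nets)))
  if (!is.null(seed)) set.seed(seed)
  for (tix in seq_len(nT)) {
    refs <- if (n_rand > 0)
      suppressWarnings(random_references(nets[[tix]], n_rand = n_rand)) else
        NULL
    m <- network_metrics(nets[[tix]], refs = refs)
    glob[, tix] <- m$global
    nodal[, , tix] <- m$nodal
  }
  auc_glob <- apply(glob, 1, function(v) as.numeric(metric_auc(v, sparsities)))
  auc_nodal <- apply(nodal, c(1, 2),
                     function(v) as.numeric(metric_auc(v, sparsities)))
  structure(list(per_threshold = list(global = glob, nodal = nodal),
                 auc = list(global = auc_glob, nodal = auc_nodal),
                 sparsities = sparsities),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("Network metric set over sparsities",
      paste(range(x$sparsities), collapse = "-"), "\n")
  cat("AUC (global):\n")
  print(round(x$auc$global, 4))
  invisible(x)
}
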