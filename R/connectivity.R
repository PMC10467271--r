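#' Split an HbO recording into rest and task segments
#'
#' Rest covers `[0, rest_end_s)` and task `[rest_end_s, task_end_s)`; sample
#' counts are `floor(duration * fs)`. At the default 11 Hz with a 20-s
#' baseline and 360-s task this yields 220 rest and 3960 task samples.
#'
#' @param rec An hbo-stage [optical_recording()].
#' @param schedule The subject's `stimulus_schedule`.
#' @return List with `rest` and `task` channel x sample matrices.
#' @export
segment_states <- function(rec, schedule) {
  stopifnot(inherits(rec, "optical_recording"),
            inherits(schedule, "stimulus_schedule"))
  if (rec$stage != "hbo") stop("expected an hbo-stage recording")
  fs <- rec$fs_hz
  n <- n_samples(rec)
  n_rest <- floor(schedule$rest_end_s * fs)
  n_task_end <- floor(schedule$task_end_s * fs)
  if (n_task_end > n)
    stop("schedule task end (", schedule$task_end_s,
         " s) lies beyond the recording")
  if (n_rest < 1 || n_task_end - n_rest < 1)
    stop("empty rest or task segment")
  list(rest = rec$data[, seq_len(n_rest), drop = FALSE],
       task = rec$data[, (n_rest + 1):n_task_end, drop = FALSE])
}

#' Fisher-z transformed Pearson connectivity matrix
#'
#' Pearson correlations between the HbO series of all channel pairs,
#' Fisher-z transformed (`z = atanh(r)` with `|r|` clipped at `1 - 1e-7` to
#' keep z finite). The diagonal is set to zero and excluded from all
#' downstream computation.
#'
#' @param segment Channel x sample matrix (>= 3 samples).
#' @param state Optional state label (`"rest"`/`"task"`).
#' @param subject_id Optional subject identifier.
#' @return An object of class `connectivity_matrix`: the symmetric z matrix
#'   with `state` and `subject_id` attributes.
#' @export
pearson_fisher <- function(segment, state = NULL, subject_id = NULL) {
  stopifnot(is.matrix(segment))
  if (ncol(segment) < 3) stop("need at least 3 samples per segment")
  sds <- apply(segment, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(t(segment))
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(z, class = c("connectivity_matrix", "matrix"),
            state = state, subject_id = subject_id)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix (%d channels, Fisher-z Pearson%s%s)\n",
              nrow(x),
              if (!is.null(attr(x, "state"))) paste0(", ", attr(x, "state")) else "",
              if (!is.null(attr(x, "subject_id"))) paste0(", ", attr(x, "subject_id")) else ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Negative entries are zeroed first (positive connectivity only); the
#' `K = floor(sparsity * N(N-1)/2)` largest remaining off-diagonal weights
#' become edges. Ties are broken deterministically by ascending channel-pair
#' lexicographic order. If fewer than `K` positive weights exist, all
#' positive weights become edges and a warning is issued.
#'
#' @param cm A `connectivity_matrix` (or plain symmetric matrix).
#' @param sparsity Fraction of retained edges, in (0, 1).
#' @return An object of class `binary_network`: list with `adjacency`
#'   (logical matrix, zero diagonal), `sparsity` and `n_edges`.
#' @export
binarize_by_sparsity <- function(cm, sparsity) {
  if (!(is.numeric(sparsity) && length(sparsity) == 1 &&
        sparsity > 0 && sparsity < 1))
    stop("sparsity must lie strictly between 0 and 1")
  z <- unclass(cm)
  n <- nrow(z)
  z[z < 0] <- 0
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[ut]
  k_target <- floor(sparsity * n * (n - 1) / 2)
  pos <- which(w > 0)
  if (length(pos) < k_target) {
    warning("only ", length(pos), " positive weights available for ",
            k_target, " requested edges; keeping all positive weights")
    sel <- pos
  } else {
    ord <- order(-w, ut[, 1], ut[, 2])
    sel <- ord[seq_len(k_target)]
    sel <- sel[w[sel] > 0]
  }
  adj <- matrix(FALSE, n, n)
  adj[ut[sel, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  structure(list(adjacency = adj, sparsity = sparsity,
                 n_edges = length(sel)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("Binary network: %d nodes, %d edges (sparsity %.2f)\n",
              nrow(x$adjacency), x$n_edges, x$sparsity))
  invisible(x)
}

#' Binarize across the full sparsity sweep
#'
#' Applies [binarize_by_sparsity()] at each threshold of the standard sweep
#' 0.15, 0.20, ..., 0.50. With distinct weights the edge sets are nested:
#' each higher-sparsity network contains all edges of the lower ones.
#'
#' @param cm A `connectivity_matrix`.
#' @param sparsities Ascending numeric vector of thresholds.
#' @return Named list of `binary_network`s (names are the thresholds).
#' @export
threshold_sweep <- function(cm, sparsities = seq(0.15, 0.50, by = 0.05)) {
  stopifnot(length(sparsities) >= 1, !is.unsorted(sparsities))
  nets <- lapply(sparsities, function(s) binarize_by_sparsity(cm, s))
  names(nets) <- sprintf("%.2f", sparsities)
  nets
}

# internal: accept binary_network or plain adjacency
as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency
  else if (is.matrix(net)) (net != 0) & !diag(TRUE, nrow(net))
  else stop("expected a binary_network or adjacency matrix")
}
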