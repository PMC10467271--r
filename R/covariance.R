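#' Project a symmetric matrix to the nearest positive-semidefinite matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to `eps` and the
#' matrix reassembled. For correlation-like inputs the unit diagonal is
#' restored afterwards by symmetric rescaling.
#'
#' @param mat Symmetric numeric matrix.
#' @param eps Smallest admissible eigenvalue after projection.
#' @param rescale_diag If `TRUE`, rescale so the diagonal is all ones.
#' @return The projected symmetric PSD matrix.
#' @export
nearest_psd <- function(mat, eps = 1e-8, rescale_diag = FALSE) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= 0) return(mat)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- (out + t(out)) / 2
  if (rescale_diag) {
    s <- 1 / sqrt(diag(out))
    out <- out * tcrossprod(s)
  }
  out
}

# channel sets carrying the planted group effects; channel 7 is the
# mid-frontal node, the listed partners are the lateral channels reported
# weakened in the task state, and (4,6)/(2,5) the left-hemisphere pairs
# elevated at rest in the depressed group.
.task_effect_edges <- function() cbind(7L, c(1L, 3L, 4L, 10L, 11L, 13L, 14L))
.rest_effect_edges <- function() rbind(c(4L, 6L), c(2L, 5L))
# adjacent within-hemisphere pairs (excluding the mid-frontal channels)
# whose coupling is raised in the depressed task state: the "elevated local
# clustering" component of the planted effect
.task_clustering_edges <- function()
  cbind(c(1:5, 9:13), c(2:6, 10:14))

#' Group- and state-specific inter-channel covariance
#'
#' Constructs the channel-by-channel covariance used as ground truth for the
#' low-frequency hemodynamic fluctuations of one group in one state. A common
#' baseline correlation structure (stronger within a hemisphere, decaying
#' with channel distance, weaker across hemispheres) is shared by all four
#' group-by-state profiles; the depressed-group (PSD) profiles additionally
#' carry planted effects scaled by `effect_size`:
#'
#' * task state: coupling of the mid-frontal channel 7 with the lateral
#'   channels 1, 3, 4, 10, 11, 13, 14 is reduced by `0.30 * effect_size`,
#'   and the coupling of adjacent within-hemisphere lateral pairs is raised
#'   by `0.12 * effect_size` (elevated local clustering in the depressed
#'   group);
#' * rest state: coupling of channel pairs (4,6) and (2,5) is raised by
#'   `0.25 * effect_size`.
#'
#' At `effect_size = 0` all four profiles are identical. If planting drives
#' the matrix indefinite it is projected back to the nearest PSD matrix and a
#' warning is issued.
#'
#' @param group `"PSD"` or `"nonPSD"`.
#' @param state `"rest"` or `"task"`.
#' @param effect_size Non-negative scalar scaling the planted group effects.
#' @param n_channels Number of channels (14 for the DLPFC montage).
#' @param sd_uM Per-channel fluctuation standard deviation in micromolar.
#' @return Symmetric PSD covariance matrix (µM²) with attribute
#'   `"correlation"` holding the underlying correlation matrix.
#' @examples
#' cv <- generate_group_covariance("PSD", "task", effect_size = 1)
#' min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
#' @export
generate_group_covariance <- function(group = c("nonPSD", "PSD"),
                                      state = c("rest", "task"),
                                      effect_size = 1,
                                      n_channels = 14,
                                      sd_uM = 0.5) {
  group <- match.arg(group)
  state <- match.arg(state)
  stopifnot(effect_size >= 0, n_channels >= 2, sd_uM > 0)

  n <- n_channels
  hemi <- ifelse(seq_len(n) <= ceiling(n / 2), 1L, 2L)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (hemi[i] == hemi[j]) {
        r[i, j] <- max(0.50 - 0.03 * abs(i - j), 0.10)
      } else {
        # homologous mirror pairs couple more strongly than generic
        # cross-hemisphere pairs
        r[i, j] <- if (i + j == n + 1) 0.32 else 0.22
      }
    }
  }

  if (group == "PSD" && effect_size > 0) {
    if (state == "task") {
      ed <- .task_effect_edges()
      for (k in seq_len(nrow(ed))) {
        i <- ed[k, 1]; j <- ed[k, 2]
        if (i <= n && j <= n) {
          r[i, j] <- r[j, i] <- max(r[i, j] - 0.30 * effect_size, 0.02)
        }
      }
      ec <- .task_clustering_edges()
      for (k in seq_len(nrow(ec))) {
        i <- ec[k, 1]; j <- ec[k, 2]
        if (i <= n && j <= n) {
          r[i, j] <- r[j, i] <- min(r[i, j] + 0.12 * effect_size, 0.90)
        }
      }
    } else {
      ed <- .rest_effect_edges()
      for (k in seq_len(nrow(ed))) {
        i <- ed[k, 1]; j <- ed[k, 2]
        if (i <= n && j <= n) {
          r[i, j] <- r[j, i] <- min(r[i, j] + 0.25 * effect_size, 0.90)
        }
      }
    }
  }
  diag(r) <- 1

  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    warning("planted correlation matrix indefinite (min eigenvalue ",
            format(ev_min), "); projecting to nearest PSD matrix")
    r <- nearest_psd(r, eps = 1e-8, rescale_diag = TRUE)
  }

  cv <- r * sd_uM^2
  attr(cv, "correlation") <- r
  attr(cv, "group") <- group
  attr(cv, "state") <- state
  cv
}

#' All four group-by-state covariance profiles
#'
#' Convenience wrapper returning the covariances for both groups in both
#' states. `effect_states` restricts which states carry the planted group
#' effect: passing `"task"` only yields a task-state-only effect cohort with
#' identical rest covariances across groups.
#'
#' @inheritParams generate_group_covariance
#' @param effect_states Character subset of `c("rest", "task")`.
#' @return Nested list: `profiles$PSD$task`, `profiles$nonPSD$rest`, etc.
#' @export
group_covariance_profiles <- function(effect_size = 1,
                                      effect_states = c("rest", "task"),
                                      n_channels = 14, sd_uM = 0.5) {
  stopifnot(all(effect_states %in% c("rest", "task")))
  out <- list()
  for (g in c("PSD", "nonPSD")) {
    out[[g]] <- list()
    for (s in c("rest", "task")) {
      es <- if (g == "PSD" && s %in% effect_states) effect_size else 0
      out[[g]][[s]] <- generate_group_covariance(g, s, effect_size = es,
                                                 n_channels = n_channels,
                                                 sd_uM = sd_uM)
    }
  }
  out
}
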