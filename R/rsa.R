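# Time-resolved representational similarity analysis: Mahalanobis-distance
# neural RDMs over condition-mean topographies, z-scored model-RDM multiple
# regression per timepoint, and one-sample cluster-based permutation
# inference across participants.

upper_tri <- function(m) m[upper.tri(m)]

zscore <- function(v) {
  s <- stats::sd(v)
  if (s == 0) stop("cannot z-score a constant vector")
  (v - mean(v)) / s
}

#' Binary model RDMs for the design factors
#'
#' For each factor, an NxN symmetric binary dissimilarity matrix over the
#' crossed design cells: 0 where two cells share the factor's level, 1 where
#' they differ. For the full 2x2x2 design each model has exactly 16 ones in
#' its 28-entry upper triangle, and the three upper-triangle vectors are
#' mutually orthogonal after z-scoring.
#'
#' @param factors factors to cross (in slowest-to-fastest cell order).
#' @return named list of binary matrices.
#' @export
model_rdms <- function(factors = c("beneficiary", "magnitude", "time")) {
  ct <- cell_table(factors)
  out <- lapply(factors, function(f) {
    m <- outer(ct[[f]], ct[[f]], FUN = function(a, b) as.numeric(a != b))
    dimnames(m) <- list(ct$cell, ct$cell)
    m
  })
  names(out) <- factors
  out
}

# Ledoit-Wolf (2004) shrinkage intensity toward the scaled identity, computed
# from accumulated statistics: S (sample covariance over N centered rows),
# sum_x4 = sum_i ||x_i||^4.
lw_lambda <- function(S, N, sum_x4) {
  C <- ncol(S)
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, C))^2)
  if (d2 == 0) return(0)
  b2bar <- (sum_x4 / N - sum(S^2)) / N
  max(0, min(1, b2bar / d2))
}

#' Time series of Mahalanobis-distance neural RDMs
#'
#' Per timepoint, condition-mean topographies over the selected channels are
#' computed and the pairwise Mahalanobis distance
#' sqrt((m_i - m_j)' Sigma^-1 (m_i - m_j)) forms an NxN RDM. Sigma is
#' estimated once from trial-level residuals (each trial minus its cell mean)
#' pooled over all timepoints, with shrinkage toward the scaled identity
#' (analytic Ledoit-Wolf intensity by default).
#'
#' @param e epochset.
#' @param channels channel names to use (default: all non-mastoid channels).
#' @param factors design factors defining the cells.
#' @param shrinkage "lw" for the analytic intensity, or a number in [0, 1].
#' @param time_window optional (start, end) ms restriction.
#' @param sigma optional fixed channel covariance matrix overriding the
#'   pooled-residual estimate (e.g. the identity, which reduces the distances
#'   to Euclidean).
#' @return list of class `neural_rdm`: `rdm` (cell x cell x time), `times`,
#'   `cells`, `lambda`.
#' @export
neural_rdm <- function(e, channels = NULL,
                       factors = c("beneficiary", "magnitude", "time"),
                       shrinkage = "lw", time_window = NULL, sigma = NULL) {
  if (is.null(channels)) channels <- setdiff(e$channels$name, c("M1", "M2"))
  e <- subset_epochs(e, channels = channels, time_window = time_window)
  ct <- cell_table(factors)
  nc <- nrow(ct)
  key <- do.call(paste, c(e$conditions[factors], sep = "."))
  cellkey <- do.call(paste, c(ct[factors], sep = "."))
  groups <- lapply(cellkey, function(k) which(key == k))
  if (any(lengths(groups) < 2))
    stop("need >= 2 trials per cell; empty/singleton cell(s): ",
         paste(cellkey[lengths(groups) < 2], collapse = ", "))
  d <- dim(e$data)
  nch <- d[2]; ntp <- d[3]
  means <- array(0, dim = c(nc, nch, ntp))
  XtX <- matrix(0, nch, nch)
  sum_x4 <- 0
  N <- 0
  for (tp in seq_len(ntp)) {
    M <- e$data[, , tp, drop = TRUE]           # trial x channel
    if (is.null(dim(M))) M <- matrix(M, ncol = nch)
    R <- M
    for (k in seq_len(nc)) {
      mu <- colMeans(M[groups[[k]], , drop = FALSE])
      means[k, , tp] <- mu
      R[groups[[k]], ] <- sweep(M[groups[[k]], , drop = FALSE], 2, mu)
    }
    XtX <- XtX + crossprod(R)
    sum_x4 <- sum_x4 + sum(rowSums(R^2)^2)
    N <- N + nrow(R)
  }
  S <- XtX / N
  lambda <- if (identical(shrinkage, "lw")) lw_lambda(S, N, sum_x4)
            else as.numeric(shrinkage)
  Sigma <- if (!is.null(sigma)) { lambda <- NA_real_; sigma }
           else (1 - lambda) * S + lambda * diag(mean(diag(S)), nch)
  Sinv <- tryCatch(solve(Sigma), error = function(err)
    stop("covariance is singular; use shrinkage (shrinkage = \"lw\" or > 0)"))
  rdm <- array(0, dim = c(nc, nc, ntp))
  for (tp in seq_len(ntp)) {
    M <- means[, , tp, drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = nc)
    for (i in seq_len(nc - 1)) {
      for (j in seq((i + 1), nc)) {
        dv <- M[i, ] - M[j, ]
        rdm[i, j, tp] <- rdm[j, i, tp] <- sqrt(drop(dv %*% Sinv %*% dv))
      }
    }
  }
  structure(list(rdm = rdm, times = e$times, cells = ct, lambda = lambda,
                 participant_id = e$participant_id),
            class = "neural_rdm")
}

#' Model-RDM multiple regression per timepoint
#'
#' The upper-triangle vectors of the neural and model RDMs are z-scored and
#' the neural vector is regressed on all model vectors jointly (with an
#' intercept, which is ~0 after z-scoring) at every timepoint.
#'
#' @param n `neural_rdm`.
#' @param models named list of model RDMs (as [model_rdms()]).
#' @return list of class `coding_series`: `coef` (time x predictor), `times`.
#' @export
rdm_regression <- function(n, models = model_rdms()) {
  stopifnot(inherits(n, "neural_rdm"), length(models) >= 1)
  Z <- vapply(models, function(m) zscore(upper_tri(m)),
              numeric(sum(upper.tri(models[[1]]))))
  nm <- names(models)
  if (length(models) > 1) {
    cc <- stats::cor(Z)
    bad <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad))
      stop("collinear model RDMs: ", nm[bad[1, 1]], " and ", nm[bad[1, 2]])
  }
  X <- cbind(`(Intercept)` = 1, Z)
  XtXinv <- solve(crossprod(X))
  ntp <- dim(n$rdm)[3]
  coefs <- matrix(0, ntp, length(models), dimnames = list(NULL, nm))
  for (tp in seq_len(ntp)) {
    y <- zscore(upper_tri(n$rdm[, , tp]))
    b <- XtXinv %*% crossprod(X, y)
    coefs[tp, ] <- b[-1, 1]
  }
  structure(list(coef = coefs, times = n$times,
                 participant_id = n$participant_id),
            class = "coding_series")
}

#' Stack per-participant coding series into a participant x time matrix
#' @param series_list list of `coding_series`.
#' @param predictor predictor name.
#' @export
stack_coding <- function(series_list, predictor) {
  t(vapply(series_list, function(s) s$coef[, predictor],
           numeric(nrow(series_list[[1]]$coef))))
}

find_clusters <- function(tval, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- sgn * tval > tcrit
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1]] <- list(start = starts[k], end = ends[k],
                                     mass = sum(tval[starts[k]:ends[k]]))
  }
  out
}

#' One-sample cluster-based permutation test on a coding time series
#'
#' Per timepoint, a one-sample t statistic across participants is computed;
#' contiguous runs with |t| above the two-sided critical value at
#' `alpha_cluster` form clusters with mass = sum of t. The null distribution
#' of the maximum |cluster mass| is built by coherent participant-wise sign
#' flips of the whole series; cluster p = (1 + #{null >= observed}) /
#' (1 + n_perm).
#'
#' @param coefs participant x time matrix of coefficients.
#' @param times time axis (ms).
#' @param n_perm number of sign-flip permutations (>= 500).
#' @param alpha_cluster cluster-forming alpha (two-sided).
#' @param seed integer seed.
#' @return list of class `cluster_result`: `clusters` data.frame (t_start_ms,
#'   t_end_ms, mass, p), `tval`, `times`, `n_perm`, `alpha_cluster`, `seed`.
#' @export
cluster_permutation <- function(coefs, times, n_perm = 1000,
                                alpha_cluster = 0.05, seed = 1) {
  np <- nrow(coefs)
  stopifnot(np >= 8, n_perm >= 500, ncol(coefs) == length(times))
  set.seed(seed)
  tcrit <- stats::qt(1 - alpha_cluster / 2, np - 1)
  tstat <- function(S1) {
    mean_ <- S1 / np
    v <- (css - np * mean_^2) / (np - 1)
    mean_ / sqrt(v / np)
  }
  css <- colSums(coefs^2)
  tobs <- tstat(colSums(coefs))
  obs <- find_clusters(tobs, tcrit)
  signs <- matrix(sample(c(-1, 1), n_perm * np, replace = TRUE), n_perm, np)
  S <- signs %*% coefs                              # n_perm x time
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    tp <- tstat(S[p, ])
    cl <- find_clusters(tp, tcrit)
    null_max[p] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
  }
  clusters <- data.frame(t_start_ms = numeric(0), t_end_ms = numeric(0),
                         mass = numeric(0), p = numeric(0))
  for (cl in obs) {
    pval <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    clusters <- rbind(clusters,
                      data.frame(t_start_ms = times[cl$start],
                                 t_end_ms = times[cl$end],
                                 mass = cl$mass, p = pval))
  }
  if (nrow(clusters)) clusters <- clusters[order(clusters$p), ]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, tval = tobs, times = times,
                 n_perm = n_perm, alpha_cluster = alpha_cluster, seed = seed),
            class = "cluster_result")
}

#' Split RSA by reward time
#'
#' Repeats the RDM-regression analysis separately within each level of the
#' split factor; with `split_factor = "time"` the cells form a 4x4 design
#' (beneficiary x magnitude, 6-entry upper triangle) and the two remaining
#' model RDMs are used.
#'
#' @param e epochset.
#' @param split_factor factor to condition on ("time" by default).
#' @param channels channel subset for the neural RDM.
#' @param shrinkage passed to [neural_rdm()].
#' @param time_window passed to [neural_rdm()].
#' @return named list (one `coding_series` per split level).
#' @export
rsa_by_time_condition <- function(e, split_factor = "time", channels = NULL,
                                  shrinkage = "lw", time_window = NULL) {
  all_factors <- c("beneficiary", "magnitude", "time")
  stopifnot(split_factor %in% all_factors)
  keep_factors <- setdiff(all_factors, split_factor)
  levels <- .factor_levels[[split_factor]]
  out <- list()
  for (lv in levels) {
    sel <- which(e$conditions[[split_factor]] == lv)
    if (!length(sel)) stop("split level '", lv, "' has no trials")
    es <- subset_epochs(e, trials = sel)
    nr <- neural_rdm(es, channels = channels, factors = keep_factors,
                     shrinkage = shrinkage, time_window = time_window)
    out[[lv]] <- rdm_regression(nr, model_rdms(keep_factors))
  }
  out
}
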