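# epochs whose cell-mean topographies are fully controlled: cell k gets
# pattern M[k, ] plus i.i.d. channel noise
patterned_epochs <- function(M, trials_per_cell = 4, noise_sd = 1, nt = 20,
                             seed = 1, layout = small_layout()) {
  set.seed(seed)
  nch <- ncol(M)
  ct <- cell_table()
  ntr <- 8 * trials_per_cell
  cond <- ct[rep(seq_len(8), each = trials_per_cell), ]
  rownames(cond) <- NULL
  data <- array(0, dim = c(ntr, nch, nt))
  for (i in seq_len(ntr))
    data[i, , ] <- M[cond$cell[i], ] + matrix(rnorm(nch * nt, sd = noise_sd),
                                              nch, nt)
  make_epochs(data, fs = 250, t0 = 0, conditions = cond,
              layout = layout[seq_len(nch), ])
}

test_that("the three factorial model RDMs are binary and balanced, with the exact pairwise overlap", {
  rdms <- model_rdms()
  expect_named(rdms, c("beneficiary", "magnitude", "time"))
  Z <- list()
  for (nm in names(rdms)) {
    m <- rdms[[nm]]
    expect_true(all(m %in% c(0, 1)))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_equal(sum(m[upper.tri(m)]), 16)
    Z[[nm]] <- prosorew:::zscore(m[upper.tri(m)])
  }
  # dropping the diagonal unbalances the pair counts, so the upper-triangle
  # indicator vectors of a full factorial correlate at exactly -1/6 (they are
  # orthogonal only over the full matrix including the diagonal); the joint
  # regression absorbs this overlap, as the exact-identification test shows
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(stats::cor(Z[[pair[1]]], Z[[pair[2]]]), -1 / 6,
                 tolerance = 1e-12)
  full <- lapply(rdms, function(m) as.vector(m) - mean(m))
  expect_equal(sum(full[[1]] * full[[2]]), 0, tolerance = 1e-12)
})

test_that("identity covariance reduces Mahalanobis distances to Euclidean", {
  set.seed(2)
  nch <- 6
  M <- matrix(rnorm(8 * nch, sd = 2), 8, nch)
  e <- patterned_epochs(M, noise_sd = 0.5, nt = 5)
  nr <- neural_rdm(e, channels = e$channels$name[seq_len(nch)],
                   sigma = diag(nch))
  # cell means estimated from the data themselves, distances via plain norm
  got <- nr$rdm[, , 3]
  key <- e$conditions$cell
  Mhat <- t(vapply(1:8, function(k)
    colMeans(e$data[key == k, seq_len(nch), 3, drop = FALSE][, , 1]),
    numeric(nch)))
  expect_equal(got, as.matrix(stats::dist(Mhat)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # identical mean topographies give zero distance
  M0 <- M; M0[2, ] <- M0[1, ]
  e0 <- patterned_epochs(M0, noise_sd = 0, nt = 3)
  nr0 <- neural_rdm(e0, channels = e0$channels$name[seq_len(nch)],
                    sigma = diag(nch))
  expect_equal(nr0$rdm[1, 2, 2], 0, tolerance = 1e-12)
})

test_that("a 3-channel RDM matches the hand-computed quadratic form", {
  Sigma <- matrix(c(2, 0.5, 0.1,
                    0.5, 1.5, 0.3,
                    0.1, 0.3, 1.0), 3, 3)
  M <- matrix(0, 8, 3)
  M[1, ] <- c(1, 2, 3)
  M[2, ] <- c(-1, 0, 2)
  e <- patterned_epochs(M, noise_sd = 0, nt = 3, trials_per_cell = 2)
  nr <- neural_rdm(e, channels = e$channels$name[1:3], sigma = Sigma)
  dv <- M[1, ] - M[2, ]
  hand <- sqrt(drop(dv %*% solve(Sigma) %*% dv))
  expect_equal(nr$rdm[1, 2, 1], hand, tolerance = 1e-10)
})

test_that("adding a common topography to every trial leaves the RDM unchanged", {
  set.seed(3)
  nch <- 6
  M <- matrix(rnorm(8 * nch), 8, nch)
  e <- patterned_epochs(M, noise_sd = 0.5, nt = 4)
  shift <- rnorm(nch, sd = 5)
  e2 <- e
  e2$data <- e$data + aperm(array(shift, dim = c(nch, dim(e$data)[1],
                                                 dim(e$data)[3])), c(2, 1, 3))
  ch <- e$channels$name[seq_len(nch)]
  nr1 <- neural_rdm(e, channels = ch, shrinkage = 0.1)
  nr2 <- neural_rdm(e2, channels = ch, shrinkage = 0.1)
  expect_equal(nr1$rdm, nr2$rdm, tolerance = 1e-9)
})

test_that("singleton cells and singular covariances are caught", {
  set.seed(4)
  M <- matrix(rnorm(48), 8, 6)
  e <- patterned_epochs(M, trials_per_cell = 1, noise_sd = 1, nt = 3)
  expect_error(neural_rdm(e, channels = e$channels$name[1:6]), ">= 2 trials")
  # rank-deficient residuals (one timepoint, few trials) without shrinkage
  e2 <- patterned_epochs(matrix(rnorm(8 * 10), 8, 10), trials_per_cell = 2,
                         noise_sd = 1, nt = 1)
  expect_error(neural_rdm(e2, channels = e2$channels$name[1:10], shrinkage = 0),
               "singular")
})

# build a neural_rdm object directly from a given series of matrices
as_neural_rdm <- function(rdm_series, times) {
  structure(list(rdm = rdm_series, times = times, cells = cell_table(),
                 lambda = 0, participant_id = "T01"), class = "neural_rdm")
}

test_that("regression on a model-RDM copy returns coefficient 1, others 0", {
  rdms <- model_rdms()
  nt <- 4
  rdm_series <- array(0, dim = c(8, 8, nt))
  for (tp in seq_len(nt)) rdm_series[, , tp] <- rdms$magnitude
  cs <- rdm_regression(as_neural_rdm(rdm_series, seq_len(nt)), rdms)
  expect_equal(unname(cs$coef[, "magnitude"]), rep(1, nt), tolerance = 1e-12)
  expect_equal(unname(cs$coef[, "beneficiary"]), rep(0, nt), tolerance = 1e-12)
  expect_equal(unname(cs$coef[, "time"]), rep(0, nt), tolerance = 1e-12)
})

test_that("regression recovers the weights of a z-scored model mixture", {
  rdms <- model_rdms()
  zb <- prosorew:::zscore(prosorew:::upper_tri(rdms$beneficiary))
  zt <- prosorew:::zscore(prosorew:::upper_tri(rdms$time))
  mix <- 0.5 * zb + 0.25 * zt
  # the neural vector is z-scored before the regression, so the exact linear
  # representation is rescaled by 1/sd(mix): beta = (0.5, 0.25) / sd(mix)
  beta_b_hand <- 0.5 / stats::sd(mix)
  beta_t_hand <- 0.25 / stats::sd(mix)
  rdm <- matrix(0, 8, 8)
  rdm[upper.tri(rdm)] <- mix - min(mix) + 0.1      # nonneg., zero diagonal
  rdm <- rdm + t(rdm)
  series <- array(rdm, dim = c(8, 8, 2))
  cs <- rdm_regression(as_neural_rdm(series, 1:2), rdms)
  expect_equal(unname(cs$coef[1, "beneficiary"]), beta_b_hand, tolerance = 1e-10)
  expect_equal(unname(cs$coef[1, "time"]), beta_t_hand, tolerance = 1e-10)
  expect_equal(unname(cs$coef[1, "magnitude"]), 0, tolerance = 1e-10)
  # the mixing ratio itself is recovered exactly
  expect_equal(unname(cs$coef[1, "beneficiary"] / cs$coef[1, "time"]), 2,
               tolerance = 1e-10)
})

test_that("pure-noise RDMs give near-zero average coefficients", {
  set.seed(5)
  nt <- 400
  series <- array(0, dim = c(8, 8, nt))
  for (tp in seq_len(nt)) {
    m <- matrix(0, 8, 8)
    m[upper.tri(m)] <- abs(rnorm(28, 2, 0.5))
    series[, , tp] <- m + t(m)
  }
  cs <- rdm_regression(as_neural_rdm(series, seq_len(nt)), model_rdms())
  expect_true(all(abs(colMeans(cs$coef)) < 0.1))
})

test_that("collinear model RDMs are refused by name", {
  rdms <- model_rdms()
  rdms$copycat <- rdms$magnitude
  series <- array(rdms$time, dim = c(8, 8, 2))
  expect_error(rdm_regression(as_neural_rdm(series, 1:2), rdms),
               "magnitude and copycat")
})

test_that("cluster mass flips sign coherently when all participants flip", {
  set.seed(6)
  np <- 12; nt <- 60
  coefs <- matrix(rnorm(np * nt, 0, 1), np, nt)
  coefs[, 21:30] <- coefs[, 21:30] + 1.2
  a <- cluster_permutation(coefs, seq_len(nt), n_perm = 500, seed = 3)
  b <- cluster_permutation(-coefs, seq_len(nt), n_perm = 500, seed = 3)
  expect_equal(nrow(a$clusters), nrow(b$clusters))
  expect_equal(sort(abs(a$clusters$mass)), sort(abs(b$clusters$mass)),
               tolerance = 1e-12)
  expect_equal(a$clusters$p, b$clusters$p)
})

test_that("a strong boxcar effect yields a dominant, highly significant cluster", {
  set.seed(7)
  np <- 16; nt <- 100
  times <- seq(0, 990, by = 10)
  box <- times >= 300 & times < 500                # 200 ms boxcar
  coefs <- matrix(rnorm(np * nt, 0, 1), np, nt)
  coefs[, box] <- coefs[, box] + 6                 # 6 SD shift
  res <- cluster_permutation(coefs, times, n_perm = 1000, seed = 8)
  expect_gte(nrow(res$clusters), 1)
  top <- res$clusters[1, ]
  covered <- sum(times >= top$t_start_ms & times <= top$t_end_ms & box) / sum(box)
  expect_gte(covered, 0.8)
  expect_lte(top$p, 0.002)
})

test_that("series with no supra-threshold points return an empty cluster list", {
  # balanced +-1 columns: every per-timepoint t is exactly 0
  coefs <- matrix(rep(c(-1, 1), each = 5), 10, 50)
  res <- cluster_permutation(coefs, seq_len(50), n_perm = 500, seed = 9)
  expect_equal(nrow(res$clusters), 0)
})

test_that("time-split RSA returns identical series when both levels share data", {
  set.seed(10)
  nch <- 6
  # magnitude-only structure, identical for immediate and delayed trials
  ct <- cell_table()
  M <- matrix(0, 8, nch)
  M[ct$mag > 0, ] <- 2
  e <- patterned_epochs(M, trials_per_cell = 6, noise_sd = 0.8, nt = 10)
  res <- rsa_by_time_condition(e, channels = e$channels$name[seq_len(nch)],
                               shrinkage = 0.2)
  expect_named(res, c("immediate", "delayed"))
  expect_equal(dim(res$immediate$coef), c(10, 2))
  expect_equal(colnames(res$immediate$coef), c("beneficiary", "magnitude"))
  # same generative structure in both splits: coefficient series agree closely
  expect_equal(mean(res$immediate$coef[, "magnitude"]),
               mean(res$delayed$coef[, "magnitude"]), tolerance = 0.2)
  expect_gt(mean(res$immediate$coef[, "magnitude"]), 0.5)
  expect_lt(abs(mean(res$immediate$coef[, "beneficiary"])), 0.2)
})
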