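# Construct a table whose matrices at consecutive lengths are controlled
# copies: the baseline for exactness checks on the convergence ratio.
shifted_table <- function(n_rows = 40, n_features = 100, shift_frac = 0.5,
                          shift_sds = 10, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n_rows * n_features), n_rows, n_features)
  rownames(A) <- sprintf("s%03d", seq_len(n_rows))
  B <- A
  n_shift <- round(shift_frac * n_features)
  if (n_shift > 0) {
    sds <- apply(A[, seq_len(n_shift), drop = FALSE], 2, sd)
    B[, seq_len(n_shift)] <- sweep(B[, seq_len(n_shift), drop = FALSE], 2,
                                   shift_sds * sds, `+`)
  }
  length_feature_table(list(`1` = A, `2` = B))
}

test_that("identical matrices at consecutive lengths give a zero ratio", {
  tab <- shifted_table(shift_frac = 0)
  cv <- convergence_ratio_curve(tab)
  expect_equal(cv$curve$ratio, 0)
})

test_that("shifting exactly half the features gives a ratio of one half", {
  cv <- convergence_ratio_curve(shifted_table(shift_frac = 0.5))
  expect_equal(cv$curve$ratio, 0.5)
  # and the ratio is invariant to duplicating every feature column
  tab <- shifted_table(shift_frac = 0.5)
  dup <- length_feature_table(lapply(tab$matrices, function(m) cbind(m, m)))
  expect_equal(convergence_ratio_curve(dup)$curve$ratio, 0.5)
})

test_that("on i.i.d. feature tables the ratio floor is the test level", {
  set.seed(99)
  mats <- lapply(1:6, function(k) {
    m <- matrix(rnorm(60 * 150), 60, 150)
    rownames(m) <- sprintf("s%03d", 1:60)
    m
  })
  names(mats) <- 1:6
  cv <- convergence_ratio_curve(length_feature_table(mats))
  mean_ratio <- mean(cv$curve$ratio)
  se <- sqrt(0.05 * 0.95 / (5 * 150))
  expect_lt(abs(mean_ratio - 0.05), 4 * se)
})

test_that("curves demand at least two usable consecutive lengths", {
  single <- length_feature_table(list(`1` = matrix(rnorm(40), 10, 4)))
  expect_error(convergence_ratio_curve(single),
               class = "somnaudit_insufficient_data_error")
})

test_that("cosine convergence requires a sustained crossing", {
  # identical vectors everywhere: converged at the first comparable prefix
  flat <- matrix(rep(c(1, 2, 3), 6), nrow = 6, byrow = TRUE)
  expect_equal(cosine_convergence_length(flat), 2)

  # target similarity sequence 0.80, 0.96, 0.90, 0.97, 0.98 for n = 2..6:
  # the crossing at n = 3 is not sustained (dip at n = 4); n = 5 is
  sims <- c(0.80, 0.96, 0.90, 0.97, 0.98)
  angles <- cumsum(c(0, acos(sims)))
  vecs <- cbind(cos(angles), sin(angles))
  expect_equal(cosine_convergence_length(vecs, threshold = 0.95), 5)

  # orthogonal consecutive vectors never converge
  orth <- diag(4)
  expect_true(is.na(cosine_convergence_length(orth)))

  expect_error(cosine_convergence_length(rbind(c(0, 0), c(1, 1))),
               class = "somnaudit_degenerate_error")
})

test_that("standardization changes which features drive the cosine", {
  set.seed(5)
  # one huge stable feature plus many small drifting ones: raw cosine says
  # converged, standardized cosine does not
  k <- 8
  big <- rep(1000, k)
  small <- matrix(rnorm(k * 50), k, 50)
  M <- cbind(big, small)
  raw <- cosine_convergence_length(M, threshold = 0.95)
  std <- cosine_convergence_length(M, threshold = 0.95, standardize = TRUE)
  expect_equal(raw, 2)
  expect_true(is.na(std))
})

test_that("the length recommendation picks the sustained threshold crossing", {
  fake_curve <- function(r) {
    structure(list(curve = tibble::tibble(n = seq_along(r), ratio = r,
                                          n_rows_a = 40, n_rows_b = 40),
                   alpha = 0.05, n_features = 100, paired = FALSE,
                   fingerprint = NA_character_),
              class = "convergence_curve")
  }
  expect_equal(recommend_min_length(fake_curve(c(0.40, 0.30, 0.20, 0.12, 0.10)),
                                    theta = 0.15)$min_length_s, 4)
  expect_equal(recommend_min_length(fake_curve(c(0.12, 0.20, 0.10)),
                                    theta = 0.15)$min_length_s, 3)
  expect_true(is.na(recommend_min_length(fake_curve(c(0.5, 0.4, 0.3)),
                                         theta = 0.15)$min_length_s))
  # theta = 0 cannot be sustained under a noisy floor
  set.seed(1)
  expect_true(is.na(recommend_min_length(fake_curve(runif(10, 0.01, 0.1)),
                                         theta = 0)$min_length_s))
})

test_that("the paired variant is more sensitive on paired shifts", {
  set.seed(8)
  A <- matrix(rnorm(30 * 20), 30, 20)
  rownames(A) <- sprintf("s%02d", 1:30)
  B <- A + 0.3   # constant within-sample shift, small vs between-sample sd
  tab <- length_feature_table(list(`1` = A, `2` = B))
  unpaired <- convergence_ratio_curve(tab)$curve$ratio
  paired <- convergence_ratio_curve(tab, paired = TRUE)$curve$ratio
  expect_gte(paired, unpaired)
  expect_equal(paired, 1)
})
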