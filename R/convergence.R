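#' Per-feature Mann-Whitney convergence-ratio curve
#'
#' For each prefix length `n`, every feature column is compared between the
#' vectors extracted at `n` seconds and at `n + 1` seconds by an unpaired
#' two-sided Mann-Whitney U test, and `r(n)` is the fraction of features
#' whose distributions differ at level `alpha`. A high ratio means an extra
#' second still moves the features — they have not converged; once the
#' recordings are long enough, the curve settles at its floor, which is the
#' test's false-positive rate `alpha`, not zero.
#'
#' Tests are unpaired across the pooled sub-sample populations and
#' uncorrected for multiplicity, mirroring the published procedure; a paired
#' Wilcoxon variant (statistically more efficient, since the same samples
#' appear at both lengths) is available behind `paired = TRUE` as an
#' extension.
#'
#' @param table a `length_feature_table`.
#' @param alpha significance level (default 0.05).
#' @param paired use the paired signed-rank variant on common samples.
#' @return A list of class `convergence_curve`: tibble `curve` with columns
#'   `n` (seconds), `ratio`, `n_rows_a`, `n_rows_b`, plus `alpha` and
#'   `n_features`.
#' @export
convergence_ratio_curve <- function(table, alpha = 0.05, paired = FALSE) {
  lens <- sort(table$lengths)
  step <- table$step_s %||% 1
  rows <- list()
  for (n in lens) {
    a_key <- as.character(round(n))
    b_key <- as.character(round(n + step))
    if (!b_key %in% names(table$matrices)) next
    A <- table$matrices[[a_key]]
    B <- table$matrices[[b_key]]
    if (nrow(A) < 2 || nrow(B) < 2) next
    n_feat <- ncol(A)
    sig <- logical(n_feat)
    for (j in seq_len(n_feat)) {
      x <- A[, j]; y <- B[, j]
      if (paired) {
        common <- intersect(rownames(A), rownames(B))
        d <- A[common, j] - B[common, j]
        if (all(d == 0)) { sig[j] <- FALSE; next }
        p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
        sig[j] <- is.finite(p) && p < alpha
      } else {
        res <- mann_whitney_u(x, y)
        sig[j] <- res$p_value < alpha
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      n = n, ratio = mean(sig), n_rows_a = nrow(A), n_rows_b = nrow(B)
    )
  }
  if (!length(rows)) {
    abort("need at least two consecutive lengths with >= 2 rows each",
          class = "somnaudit_insufficient_data_error")
  }
  structure(
    list(curve = dplyr::bind_rows(rows), alpha = alpha,
         n_features = ncol(table$matrices[[1]]),
         paired = paired, fingerprint = table$fingerprint),
    class = "convergence_curve"
  )
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf("<convergence_curve> %d features, alpha = %g%s\n",
              x$n_features, x$alpha, if (x$paired) " (paired)" else ""))
  print(x$curve, n = Inf)
  invisible(x)
}

#' Cosine-similarity convergence length of one sample
#'
#' Given the ordered feature vectors of one sample's nested prefixes,
#' returns the smallest length `n` from which the cosine similarity between
#' consecutive vectors reaches the threshold *and stays there*: a single
#' crossing followed by a dip does not count. Without standardization the
#' largest-magnitude features dominate the cosine; `standardize = TRUE`
#' z-scores each feature across the prefix set first.
#'
#' @param prefix_vectors list (or matrix rows) of feature vectors ordered by
#'   prefix length; element `k` corresponds to length `lengths[k]`.
#' @param threshold similarity threshold (default 0.95).
#' @param standardize z-score features across prefixes before comparing.
#' @param lengths numeric lengths in seconds (default `seq_along`).
#' @return The convergence length in seconds, or `NA` when the similarity
#'   never stays above the threshold.
#' @export
cosine_convergence_length <- function(prefix_vectors, threshold = 0.95,
                                      standardize = FALSE,
                                      lengths = NULL) {
  if (is.matrix(prefix_vectors)) {
    prefix_vectors <- split(prefix_vectors, row(prefix_vectors))
  }
  k <- length(prefix_vectors)
  if (k < 2) {
    abort("need at least 2 prefix vectors",
          class = "somnaudit_argument_error")
  }
  lengths <- lengths %||% seq_len(k)
  M <- do.call(rbind, lapply(prefix_vectors, as.numeric))
  if (standardize) {
    mu <- colMeans(M)
    s <- apply(M, 2, sd)
    s[s == 0] <- 1
    M <- sweep(sweep(M, 2, mu), 2, s, `/`)
  }
  norms <- sqrt(rowSums(M^2))
  if (any(norms == 0)) {
    abort("zero-norm feature vector", class = "somnaudit_degenerate_error")
  }
  sims <- vapply(2:k, function(i) {
    sum(M[i, ] * M[i - 1, ]) / (norms[i] * norms[i - 1])
  }, numeric(1))
  above <- sims >= threshold
  # smallest n such that every comparison at k > n is above the threshold
  ok_from <- rev(cumprod(rev(above))) == 1
  if (!any(ok_from)) return(NA_real_)
  lengths[1 + which(ok_from)[1]]
}

#' Minimum-length recommendation from a convergence curve
#'
#' The recommended minimum sample length is the smallest `n` whose
#' non-convergence ratio stays at or below `theta` for every length from `n`
#' on (a sustained crossing, not the first dip below the threshold).
#'
#' @param curve a [convergence_ratio_curve()] result.
#' @param theta maximum tolerated fraction of non-converged features
#'   (default 0.15).
#' @return A list of class `convergence_recommendation` with `min_length_s`
#'   (`NA` when the ratio never stays below `theta`), `theta` and `basis`.
#' @export
recommend_min_length <- function(curve, theta = 0.15) {
  stopifnot(inherits(curve, "convergence_curve"))
  tab <- curve$curve
  if (nrow(tab) == 0) {
    abort("empty curve", class = "somnaudit_argument_error")
  }
  ok <- tab$ratio <= theta
  ok_from <- rev(cumprod(rev(ok))) == 1
  min_length <- if (any(ok_from)) tab$n[which(ok_from)[1]] else NA_real_
  structure(
    list(min_length_s = min_length, theta = theta, basis = "mw_ratio",
         alpha = curve$alpha, n_features = curve$n_features),
    class = "convergence_recommendation"
  )
}

#' @export
print.convergence_recommendation <- function(x, ...) {
  if (is.na(x$min_length_s)) {
    cat(sprintf("<convergence_recommendation> undetermined (ratio never sustained <= %g)\n",
                x$theta))
  } else {
    cat(sprintf("<convergence_recommendation> minimum sample length %g s (theta = %g, basis %s)\n",
                x$min_length_s, x$theta, x$basis))
  }
  invisible(x)
}

#' Plot a convergence curve
#'
#' @param curve a [convergence_ratio_curve()] result.
#' @param theta optional threshold drawn as a horizontal reference.
#' @return A ggplot object.
#' @export
plot_convergence_curve <- function(curve, theta = 0.15) {
  ggplot2::ggplot(curve$curve, ggplot2::aes(x = .data$n, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = curve$alpha, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "prefix length n (s)",
      y = "fraction of features not converged, r(n)",
      title = "Per-feature Mann-Whitney convergence ratio",
      subtitle = sprintf("dashed: theta = %g; dotted: alpha floor = %g",
                         theta, curve$alpha)
    ) +
    ggplot2::theme_minimal()
}
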