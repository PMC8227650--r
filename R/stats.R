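#' Fisher's ratio between two classes
#'
#' `|mean(x0) - mean(x1)| / (var(x0) + var(x1))` with sample (n-1) variances:
#' a scale-dependent measure of linear discriminating power (shift-invariant;
#' scales as 1/s under joint rescaling by s).
#'
#' @param x0,x1 Numeric vectors, each with >= 2 values.
#' @return A single nonnegative number.
#' @export
#' @examples
#' fishers_ratio(c(0, 2), c(4, 6))  # 1
fishers_ratio <- function(x0, x1) {
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each class needs at least 2 values", call. = FALSE)
  }
  denom <- var(x0) + var(x1)
  if (denom == 0) stop("zero total variance", call. = FALSE)
  abs(mean(x0) - mean(x1)) / denom
}

#' AUROC with a subject-stratified bootstrap confidence interval
#'
#' Area under the ROC curve by the Mann-Whitney pair-counting identity (ties
#' count 1/2), equal to the probability that a random positive outranks a
#' random negative. The 95% CI is a percentile bootstrap with 2000 resamples:
#' stratified by subject when `subjects` is given (whole subjects are
#' resampled), otherwise stratified by label.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical); both classes must be present.
#' @param subjects Optional subject id per observation, for subject-stratified
#'   resampling.
#' @param ci Compute the bootstrap CI (default `TRUE`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return Tibble with columns `auroc`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), ci = FALSE)  # 0.75
auroc <- function(scores, labels, subjects = NULL, ci = TRUE,
                  n_boot = 2000, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  est <- auroc_point(scores, labels)
  if (!ci) return(tibble(auroc = est, ci_low = NA_real_, ci_high = NA_real_))
  keep <- .Random.seed_exists(); set.seed(seed)
  boots <- numeric(n_boot)
  if (!is.null(subjects)) {
    us <- unique(subjects)
    idx_by <- split(seq_along(scores), subjects)
    for (b in seq_len(n_boot)) {
      pick <- sample(us, length(us), replace = TRUE)
      idx <- unlist(idx_by[as.character(pick)], use.names = FALSE)
      boots[b] <- if (length(unique(labels[idx])) < 2) NA_real_
                  else auroc_point(scores[idx], labels[idx])
    }
  } else {
    i0 <- which(labels == 0); i1 <- which(labels == 1)
    for (b in seq_len(n_boot)) {
      idx <- c(sample(i0, length(i0), replace = TRUE),
               sample(i1, length(i1), replace = TRUE))
      boots[b] <- auroc_point(scores[idx], labels[idx])
    }
  }
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble(auroc = est, ci_low = qs[1], ci_high = qs[2])
}

# Mann-Whitney AUC via midranks; exact pair counting with ties = 1/2.
auroc_point <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS test of `x` against a normal distribution with the sample
#' mean and standard deviation (parameters are plugged in, as in common
#' practice; the p-value is therefore conservative only in large samples).
#'
#' @param x Numeric vector, n >= 5, nondegenerate.
#' @return The p-value.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need at least 5 values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate sample (zero sd)", call. = FALSE)
  suppressWarnings(ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Subject-nested permutation rank test
#'
#' Tests for a label effect while respecting the nesting of segments within
#' subjects. The statistic is the mean over subjects of the within-subject
#' rank-sum z-score of class 1; the null distribution is built by permuting
#' labels independently within each subject. Two-sided p-value
#' `(1 + #extreme) / (1 + n_perm)`. Subjects missing one of the two classes
#' are excluded with a warning.
#'
#' @param values Numeric outcomes.
#' @param labels Binary labels (0/1).
#' @param subjects Subject id per observation.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed (default 1).
#' @return Tibble with columns `statistic`, `p_value`, `n_subjects`.
#' @export
nested_rank_test <- function(values, labels, subjects, n_perm = 10000, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  df <- split(seq_along(values), subjects)
  ok <- vapply(df, function(i) length(unique(labels[i])) == 2, TRUE)
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) excluded: only one label class present",
            call. = FALSE)
    df <- df[ok]
  }
  if (length(df) < 1) stop("no subject has both label classes", call. = FALSE)

  zsub <- function(v, l) {
    r <- rank(v, ties.method = "average")
    n1 <- sum(l == 1); n0 <- sum(l == 0); n <- n0 + n1
    w <- sum(r[l == 1])
    (w - n1 * (n + 1) / 2) / sqrt(n0 * n1 * (n + 1) / 12)
  }
  stat_for <- function(labs) {
    mean(vapply(df, function(i) zsub(values[i], labs[i]), 0))
  }
  obs <- stat_for(labels)

  keep <- .Random.seed_exists(); set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pl <- labels
    for (i in df) pl[i] <- labels[i][sample.int(length(i))]
    perm[b] <- stat_for(pl)
  }
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  tibble(statistic = obs, p_value = p, n_subjects = length(df))
}

#' Discriminability statistics for every segment feature
#'
#' For each of the six segment features, compares painless vs pain segments:
#' Fisher's ratio, AUROC with subject-stratified bootstrap CI, KS normality
#' p-values per class (informational), and the subject-nested permutation
#' rank test p-value.
#'
#' @param segments A segment feature table (from [extract_segments()] or
#'   [pool_datasets()]).
#' @param n_perm Permutations for the nested rank test (default 2000).
#' @param n_boot Bootstrap resamples for the AUROC CI (default 2000).
#' @param seed Seed (default 1).
#' @return An object of class `feature_comparison`: a tibble with one row per
#'   feature (`feature`, `fishers_ratio`, `auroc`, `ci_low`, `ci_high`,
#'   `ks_p_painless`, `ks_p_pain`, `p_value`, `test_used`).
#' @export
compare_segment_features <- function(segments, n_perm = 2000, n_boot = 2000,
                                     seed = 1L) {
  stopifnot(all(feature_names() %in% names(segments)))
  out <- purrr::map_dfr(feature_names(), function(f) {
    v <- segments[[f]]
    lab <- segments$label
    a <- auroc(v, lab, subjects = segments$subject_id, n_boot = n_boot,
               seed = seed)
    nt <- nested_rank_test(v, lab, segments$subject_id, n_perm = n_perm,
                           seed = seed)
    tibble(
      feature = f,
      fishers_ratio = fishers_ratio(v[lab == 0], v[lab == 1]),
      auroc = a$auroc, ci_low = a$ci_low, ci_high = a$ci_high,
      ks_p_painless = ks_normality(v[lab == 0]),
      ks_p_pain = ks_normality(v[lab == 1]),
      p_value = nt$p_value,
      test_used = "nested_rank_permutation"
    )
  })
  class(out) <- c("feature_comparison", class(out))
  out
}

#' @export
tidy.feature_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "feature_comparison")
  out
}

#' @export
glance.feature_comparison <- function(x, ...) {
  tibble(n_features = nrow(x),
         best_feature = x$feature[which.max(x$auroc)],
         best_auroc = max(x$auroc),
         all_significant_05 = all(x$p_value < 0.05))
}
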