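# Second-level (group) inference on subject contrast images: parametric
# two-sample t and one-way ANOVA maps, and nonparametric max-statistic
# permutation inference.

as_map_array <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) return(maps)
  d <- dim(maps[[1]])
  if (any(!vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("group maps must share one grid")
  array(unlist(maps), dim = c(d, length(maps)))
}

#' Second-level two-sample t-test map
#'
#' Pixelwise pooled-variance two-sample t between two groups of co-registered
#' subject contrast images, `df = nA + nB - 2`. The map is signed: positive
#' and negative t-scores mark stronger activation in group A or B.
#'
#' @param mapsA,mapsB Lists of matrices (or 3D arrays, pixel x pixel x
#'   subject), at least 2 subjects per group.
#' @param p_threshold Two-sided significance threshold.
#' @param correction `"none"` or `"fdr"`.
#' @return An `"activation_map"` with `stat_type = "t"`.
#' @export
second_level_ttest <- function(mapsA, mapsB, p_threshold = 0.05,
                               correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  A <- as_map_array(mapsA); B <- as_map_array(mapsB)
  if (!identical(dim(A)[1:2], dim(B)[1:2])) stop("groups must share one grid")
  nA <- dim(A)[3]; nB <- dim(B)[3]
  if (nA < 2 || nB < 2) stop("need at least 2 maps per group")
  tv <- two_sample_t(A, B)
  pval <- 2 * stats::pt(abs(tv$t), tv$df, lower.tail = FALSE)
  new_activation_map(tv$t, df = tv$df, p = pval, p_threshold = p_threshold,
                     correction = correction, stat_type = "t")
}

two_sample_t <- function(A, B) {
  nA <- dim(A)[3]; nB <- dim(B)[3]
  mA <- rowMeans(A, dims = 2); mB <- rowMeans(B, dims = 2)
  ssA <- rowSums((A - as.vector(mA))^2, dims = 2)
  ssB <- rowSums((B - as.vector(mB))^2, dims = 2)
  df <- nA + nB - 2
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, (mA - mB) / se, 0)
  list(t = t, df = df)
}

#' Second-level one-way ANOVA map
#'
#' Pixelwise one-way ANOVA F across k groups of subject maps, with
#' `(k - 1, N - k)` degrees of freedom. For two groups, `F = t^2` of the
#' two-sample t-test.
#'
#' @param groups List of groups; each group a list of matrices (or a 3D
#'   array). At least 2 groups with at least 2 maps each.
#' @param p_threshold Significance threshold.
#' @param correction `"none"` or `"fdr"`.
#' @return An `"activation_map"` with `stat_type = "F"` and `df = c(k-1, N-k)`.
#' @export
second_level_anova <- function(groups, p_threshold = 0.05,
                               correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  arrs <- lapply(groups, as_map_array)
  d <- dim(arrs[[1]])[1:2]
  if (any(!vapply(arrs, function(a) identical(dim(a)[1:2], d), logical(1))))
    stop("groups must share one grid")
  k <- length(arrs)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(arrs, function(a) dim(a)[3], integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 maps")
  N <- sum(ns)
  gm <- lapply(arrs, rowMeans, dims = 2)
  grand <- Reduce(`+`, Map(function(m, n) m * n, gm, ns)) / N
  ss_b <- Reduce(`+`, Map(function(m, n) n * (m - grand)^2, gm, ns))
  ss_w <- Reduce(`+`, Map(function(a, m) rowSums((a - as.vector(m))^2, dims = 2),
                          arrs, gm))
  df1 <- k - 1; df2 <- N - k
  Fv <- ifelse(ss_w > 0, (ss_b / df1) / (ss_w / df2), 0)
  pval <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  new_activation_map(Fv, df = c(df1, df2), p = pval,
                     p_threshold = p_threshold, correction = correction,
                     stat_type = "F")
}

#' Max-statistic permutation inference (SnPM-style)
#'
#' Nonparametric group inference: the group labels are permuted (two-group
#' design) or the signs of the subject maps are flipped (one-sample design),
#' the pixelwise statistic is recomputed for every permutation, and the
#' family-wise-error-corrected p-value of each pixel is the fraction of
#' permutations (including the observed labeling) whose maximum |statistic|
#' reaches that pixel's observed |statistic|. When the number of distinct
#' permutations does not exceed `n_perm`, the exhaustive enumeration is used
#' and reported.
#'
#' @param groups For the two-group design, a list of two groups of maps; for
#'   the one-sample (sign-flip) design, a single group (list of maps or 3D
#'   array).
#' @param n_perm Maximum number of permutations (>= 100 unless exhaustive).
#' @param seed Integer seed for random permutations.
#' @param p_threshold FWE threshold.
#' @return An `"activation_map"` with `correction = "permutation"`, fields
#'   `n_perm_used` and `exhaustive`.
#' @export
permutation_map <- function(groups, n_perm = 1000L, seed = 1L,
                            p_threshold = 0.05) {
  is_group <- function(g) is.list(g) ||
    (is.array(g) && length(dim(g)) == 3)
  if (is.list(groups) && length(groups) == 2 &&
      is_group(groups[[1]]) && is_group(groups[[2]])) {
    A <- as_map_array(groups[[1]]); B <- as_map_array(groups[[2]])
    perm_two_sample(A, B, n_perm, seed, p_threshold)
  } else {
    A <- as_map_array(groups)
    perm_sign_flip(A, n_perm, seed, p_threshold)
  }
}

perm_two_sample <- function(A, B, n_perm, seed, p_threshold) {
  nA <- dim(A)[3]; nB <- dim(B)[3]
  if (nA < 2 || nB < 2) stop("need at least 2 maps per group")
  all_maps <- array(c(A, B), dim = c(dim(A)[1:2], nA + nB))
  n <- nA + nB
  total <- choose(n, nA)
  exhaustive <- total <= n_perm
  if (exhaustive) {
    combs <- utils::combn(n, nA)
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100")
    set.seed(as.integer(seed))
    combs <- cbind(seq_len(nA),
                   replicate(n_perm - 1L, sort(sample(n, nA))))
  }
  nper <- ncol(combs)
  obs <- two_sample_t(A, B)
  maxnull <- numeric(nper)
  for (i in seq_len(nper)) {
    ia <- combs[, i]
    ti <- two_sample_t(all_maps[, , ia, drop = FALSE],
                       all_maps[, , -ia, drop = FALSE])$t
    maxnull[i] <- max(abs(ti))
  }
  p_fwe <- matrix(vapply(abs(obs$t), function(v) mean(maxnull >= v - 1e-12),
                         numeric(1)), dim(A)[1], dim(A)[2])
  new_activation_map(obs$t, df = obs$df, p = p_fwe,
                     p_threshold = p_threshold, correction = "permutation",
                     stat_type = "t", n_perm_used = nper,
                     exhaustive = exhaustive)
}

perm_sign_flip <- function(A, n_perm, seed, p_threshold) {
  n <- dim(A)[3]
  if (n < 2) stop("need at least 2 maps")
  total <- 2^n
  exhaustive <- total <= n_perm
  signsets <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100")
    set.seed(as.integer(seed))
    rbind(rep(1, n),
          matrix(sample(c(1, -1), (n_perm - 1L) * n, TRUE), ncol = n))
  }
  Y <- matrix(A, ncol = n)      # pixels x subjects
  one_t <- function(s) {
    Ys <- sweep(Y, 2, s, "*")
    m <- rowMeans(Ys)
    sd <- sqrt(pmax(rowSums((Ys - m)^2), 0) / (n - 1))
    ifelse(sd > 0, m / (sd / sqrt(n)), 0)
  }
  tobs <- one_t(rep(1, n))
  maxnull <- apply(signsets, 1, function(s) max(abs(one_t(s))))
  p_fwe <- matrix(vapply(abs(tobs), function(v) mean(maxnull >= v - 1e-12),
                         numeric(1)), dim(A)[1], dim(A)[2])
  new_activation_map(matrix(tobs, dim(A)[1], dim(A)[2]), df = n - 1,
                     p = p_fwe, p_threshold = p_threshold,
                     correction = "permutation", stat_type = "t",
                     n_perm_used = nrow(signsets), exhaustive = exhaustive)
}
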