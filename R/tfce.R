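#' Parameters for 1-D TFCE permutation testing
#'
#' Threshold-free cluster enhancement defaults for one-dimensional trial
#' series: extent exponent `E = 1` (extent is a run length in 1-D) and
#' height exponent `H = 2`, following standard TFCE practice; both are
#' configurable. The integration step `dh` defaults to 1/100 of the maximum
#' absolute statistic when left `NULL`.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step (> 0), or `NULL` for automatic.
#' @param n_permutations number of permutations.
#' @param tail `"one"` (positive tail) or `"two"` sided.
#' @param seed integer seed for the permutation draw.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 1, H = 2, dh = NULL, n_permutations = 10000,
                        tail = c("one", "two"), seed = 1L) {
  tail <- match.arg(tail)
  if (E < 0 || H < 0) stop("E and H must be non-negative")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  out <- list(E = E, H = H, dh = dh, n_permutations = n_permutations,
              tail = tail, seed = as.integer(seed))
  class(out) <- "tfce_params"
  out
}

resolve_dh <- function(x, p) {
  if (!is.null(p$dh)) return(p$dh)
  mx <- max(abs(x))
  if (mx == 0) 1 else mx / 100
}

#' Threshold-free cluster enhancement of a 1-D statistic series
#'
#' For each position, integrates `extent^E * h^H * dh` over supra-threshold
#' heights `h`, where the extent is the length of the contiguous run
#' containing that position at threshold `h`. One-sided enhancement scores
#' the positive part only; two-sided enhancement scores each sign
#' separately and returns signed scores.
#'
#' @param x finite numeric statistic series.
#' @param p a [tfce_params()].
#' @return numeric vector of TFCE scores (signed if `tail = "two"`).
#' @export
tfce_transform <- function(x, p = tfce_params()) {
  if (any(!is.finite(x))) stop("statistic series must be finite")
  dh <- resolve_dh(x, p)
  pos <- .tfce_pos(pmax(x, 0), p$E, p$H, dh)
  if (p$tail == "one") return(pos)
  neg <- .tfce_pos(pmax(-x, 0), p$E, p$H, dh)
  pos - neg
}

# per-trial one-sample t statistics for all sign-flip assignments
# flips: n_perm x n matrix of +/-1
flip_t_matrix <- function(X, flips) {
  n <- nrow(X)
  m <- (flips %*% X) / n
  ssq <- matrix(colSums(X^2), nrow(flips), ncol(X), byrow = TRUE)
  v <- (ssq - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# per-trial pooled two-sample t statistics for permuted group assignments
# memb: n_perm x n 0/1 matrix of group-1 membership (row sums = n1)
perm_t_matrix <- function(X, memb) {
  n1 <- sum(memb[1, ]); n2 <- ncol(memb) - n1
  X2 <- X^2
  sA <- memb %*% X; sB <- (1 - memb) %*% X
  qA <- memb %*% X2; qB <- (1 - memb) %*% X2
  mA <- sA / n1; mB <- sB / n2
  pv <- (qA - n1 * mA^2 + qB - n2 * mB^2) / (n1 + n2 - 2)
  pv[pv < .Machine$double.eps] <- .Machine$double.eps
  (mA - mB) / sqrt(pv * (1 / n1 + 1 / n2))
}

observed_stat_series <- function(X, design, groups) {
  if (design == "within") {
    as.vector(flip_t_matrix(X, matrix(1, 1, nrow(X))))
  } else {
    memb <- matrix(as.integer(groups == levels(factor(groups))[1]), 1)
    as.vector(perm_t_matrix(X, memb))
  }
}

#' Permutation null distribution of the maximum TFCE score
#'
#' Within-participant designs permute by sign-flipping each participant's
#' difference series (exact under exchangeability of the paired contrast);
#' between-participant designs permute group labels. For each permutation
#' the per-trial t series is recomputed, TFCE-enhanced, and its maximum
#' retained, yielding the max-statistic null that controls the family-wise
#' error over trials. Deterministic given `p$seed`.
#'
#' @param X participants x trials matrix of (differential) responses.
#' @param design `"within"` (sign-flipping) or `"between"` (label
#'   permutation).
#' @param p a [tfce_params()].
#' @param groups group labels (length `nrow(X)`), required for
#'   `design = "between"`.
#' @param exhaustive enumerate all `2^n` sign flips instead of sampling
#'   (within-participant only).
#' @return list of class `tfce_null`: `null_max` (max TFCE per
#'   permutation), `observed_stat` (t series), `observed_scores` (TFCE),
#'   `dh`, and the inputs.
#' @export
permutation_null <- function(X, design = c("within", "between"),
                             p = tfce_params(), groups = NULL,
                             exhaustive = FALSE) {
  design <- match.arg(design)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 participants")
  set.seed(p$seed)
  obs_stat <- observed_stat_series(X, design, groups)
  dh <- resolve_dh(obs_stat, p)
  pp <- p; pp$dh <- dh
  obs_scores <- tfce_transform(obs_stat, pp)

  if (design == "within") {
    if (exhaustive) {
      if (n > 20) stop("exhaustive enumeration limited to n <= 20")
      flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      flips <- matrix(sample(c(-1, 1), p$n_permutations * n, replace = TRUE),
                      p$n_permutations, n)
    }
    tm <- flip_t_matrix(X, flips)
  } else {
    if (is.null(groups)) stop("groups required for between design")
    g1 <- levels(factor(groups))[1]
    base <- as.integer(groups == g1)
    memb <- t(replicate(p$n_permutations, sample(base)))
    tm <- perm_t_matrix(X, memb)
  }
  null_max <- .tfce_max_rows(tm, p$E, p$H, dh,
                             if (p$tail == "two") 2L else 1L)
  out <- list(null_max = as.vector(null_max), observed_stat = obs_stat,
              observed_scores = obs_scores, dh = dh, params = p,
              design = design, n = n, stat_matrix = tm)
  class(out) <- "tfce_null"
  out
}

#' Family-wise-error p-values from a max-statistic null distribution
#'
#' `p_fwe[i] = (1 + #\{null >= |observed[i]|\}) / (n_perm + 1)` (the
#' add-one estimator, so p can never be exactly zero and is floored at
#' `1/(n_perm + 1)`). Significant clusters are maximal contiguous runs of
#' trials with `p_fwe <= alpha`.
#'
#' @param observed_scores TFCE scores per trial (signed allowed).
#' @param null_max null distribution of the maximum TFCE score, or a
#'   `tfce_null` object.
#' @param alpha cluster-reporting threshold.
#' @return data frame of class `cluster_result` with columns `trial`,
#'   `score`, `p_fwe`, `cluster` (NA outside clusters); cluster extents are
#'   attached as attribute `"clusters"`.
#' @export
fwe_pvalues <- function(observed_scores, null_max, alpha = 0.05) {
  if (inherits(null_max, "tfce_null")) {
    if (missing(observed_scores) || is.null(observed_scores)) {
      observed_scores <- null_max$observed_scores
    }
    null_max <- null_max$null_max
  }
  n_perm <- length(null_max)
  p_fwe <- vapply(abs(observed_scores), function(s) {
    (1 + sum(null_max >= s)) / (n_perm + 1)
  }, numeric(1))
  sig <- p_fwe <= alpha
  cl <- rep(NA_integer_, length(sig))
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    k <- 0L
    for (seg in seq_along(r$values)) {
      if (!r$values[seg]) next
      k <- k + 1L
      cl[starts[seg]:ends[seg]] <- k
    }
  }
  out <- data.frame(trial = seq_along(observed_scores),
                    score = observed_scores, p_fwe = p_fwe, cluster = cl)
  cls <- NULL
  if (any(!is.na(cl))) {
    cls <- do.call(rbind, lapply(unique(cl[!is.na(cl)]), function(k) {
      idx <- which(cl == k)
      data.frame(cluster = k, from = min(idx), to = max(idx),
                 p_fwe = min(p_fwe[idx]))
    }))
  }
  attr(out, "clusters") <- cls
  class(out) <- c("cluster_result", "data.frame")
  out
}

#' TFCE cluster-based permutation test of a trial series
#'
#' Convenience wrapper: builds the observed per-trial t series, enhances it
#' with TFCE, draws the max-statistic permutation null and returns
#' family-wise-error corrected p-values per trial.
#'
#' @inheritParams permutation_null
#' @param alpha cluster-reporting threshold.
#' @return a `cluster_result` (see [fwe_pvalues()]) with the `tfce_null`
#'   attached as attribute `"null"`.
#' @export
tfce_permutation_test <- function(X, design = c("within", "between"),
                                  p = tfce_params(), groups = NULL,
                                  alpha = 0.05) {
  nul <- permutation_null(X, design, p, groups)
  out <- fwe_pvalues(nul$observed_scores, nul$null_max, alpha)
  out$stat <- nul$observed_stat
  attr(out, "null") <- nul
  out
}

#' Cluster-mass permutation test with a quantile cluster-forming threshold
#'
#' The cluster-forming threshold is the `q` quantile of the permutation
#' distribution of `|t|` (pooled over trials and permutations). Observed
#' clusters are contiguous runs with `|t|` above the threshold; the cluster
#' mass is the sum of `|t|` within the run, compared against the null
#' distribution of the maximum cluster mass.
#'
#' @inheritParams permutation_null
#' @param q cluster-forming quantile of the permutation `|t|` distribution.
#' @return list of class `cluster_mass_result`: `threshold`, `clusters`
#'   (data frame with `from`, `to`, `mass`, `p_fwe`; empty if nothing
#'   exceeds the threshold), `observed_stat`, `null_max_mass`.
#' @export
cluster_mass_variant <- function(X, design = c("within", "between"),
                                 p = tfce_params(), groups = NULL,
                                 q = 0.90) {
  design <- match.arg(design)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 participants")
  set.seed(p$seed)
  obs_stat <- observed_stat_series(X, design, groups)
  if (design == "within") {
    flips <- matrix(sample(c(-1, 1), p$n_permutations * nrow(X),
                           replace = TRUE), p$n_permutations, nrow(X))
    tm <- flip_t_matrix(X, flips)
  } else {
    if (is.null(groups)) stop("groups required for between design")
    base <- as.integer(groups == levels(factor(groups))[1])
    memb <- t(replicate(p$n_permutations, sample(base)))
    tm <- perm_t_matrix(X, memb)
  }
  thr <- quantile(abs(tm), q, names = FALSE)
  max_mass <- function(tv) {
    above <- abs(tv) > thr
    if (!any(above)) return(0)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(vapply(which(r$values), function(seg) {
      sum(abs(tv[starts[seg]:ends[seg]]))
    }, numeric(1)))
  }
  null_max_mass <- apply(tm, 1, max_mass)
  above <- abs(obs_stat) > thr
  clusters <- data.frame(from = integer(0), to = integer(0),
                         mass = numeric(0), p_fwe = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    clusters <- do.call(rbind, lapply(which(r$values), function(seg) {
      mass <- sum(abs(obs_stat[starts[seg]:ends[seg]]))
      data.frame(from = starts[seg], to = ends[seg], mass = mass,
                 p_fwe = (1 + sum(null_max_mass >= mass)) /
                   (p$n_permutations + 1))
    }))
  }
  out <- list(threshold = thr, clusters = clusters,
              observed_stat = obs_stat, null_max_mass = null_max_mass,
              q = q, params = p)
  class(out) <- "cluster_mass_result"
  out
}
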