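#' Median-of-ratios size factors
#'
#' Per-sample normalization constants estimated by the median-of-ratios
#' method: each sample's counts are divided by the per-gene geometric mean
#' across samples, and the size factor is the median of those ratios over
#' genes with all-positive counts. Size factors are rescaled so their
#' geometric mean is 1, making them deterministic and comparable across
#' runs.
#'
#' @param counts a [count_matrix()] or a plain counts matrix.
#' @param pseudo_reference if no gene has positive counts in every sample,
#'   setting this to `TRUE` computes the per-gene geometric mean over the
#'   positive entries only and takes the median over each sample's nonzero
#'   ratios.
#' @return Named numeric vector of positive size factors (geometric mean 1).
#' @examples
#' m <- matrix(c(4L, 10L, 8L, 20L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' size_factors(m)   # b is 2x a: factors (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (nrow(k) == 0) stop("cannot estimate size factors without genes")
  logk <- log(k)
  all_pos <- rowSums(k > 0) == ncol(k)
  if (!any(all_pos) && !pseudo_reference) {
    stop("no gene has positive counts in every sample; ",
         "re-run with pseudo_reference = TRUE")
  }
  if (any(all_pos)) {
    loggeo <- rowMeans(logk[all_pos, , drop = FALSE])
    s <- apply(logk[all_pos, , drop = FALSE], 2,
               function(col) exp(stats::median(col - loggeo)))
  } else {
    loggeo <- apply(logk, 1, function(r) mean(r[is.finite(r)]))
    s <- apply(logk, 2, function(col) {
      ok <- is.finite(col) & is.finite(loggeo)
      if (!any(ok)) stop("sample with no usable gene for size-factor estimation")
      exp(stats::median(col[ok] - loggeo[ok]))
    })
  }
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(k))
}

#' Per-gene dispersion estimation
#'
#' Method-of-moments negative-binomial dispersion (variance = mu + alpha *
#' mu^2) from within-group normalized counts: per group, alpha_hat =
#' (v - mu) / mu^2, pooled across groups by residual degrees of freedom,
#' floored at `floor_alpha`. A mean-dispersion trend is then fitted by
#' log-log least squares over genes with above-floor estimates, and the
#' final per-gene dispersion is the conservative maximum of the gene-wise
#' estimate and the fitted trend.
#'
#' @param counts a [count_matrix()] or matrix of raw counts.
#' @param sf per-sample size factors (see [size_factors()]).
#' @param groups list of column-index (or sample-id) vectors, one per
#'   condition group; every group needs >= 2 samples.
#' @param floor_alpha lower bound on the dispersion (default 1e-8).
#' @return List with `alpha` (named per-gene dispersions) and `fit_method`.
#' @export
estimate_dispersion <- function(counts, sf, groups, floor_alpha = 1e-8) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  norm <- sweep(k, 2, sf, "/")
  idx <- lapply(groups, function(g) {
    if (is.character(g)) g <- match(g, colnames(k))
    if (anyNA(g)) stop("unknown sample in group")
    g
  })
  sizes <- lengths(idx)
  if (any(sizes < 2)) stop("every group needs >= 2 samples for dispersion estimation")
  num <- 0; den <- 0; mu_all <- 0
  for (g in idx) {
    mu <- rowMeans(norm[, g, drop = FALSE])
    v <- apply(norm[, g, drop = FALSE], 1, stats::var)
    w <- length(g) - 1
    a <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    num <- num + w * a
    den <- den + w
    mu_all <- mu_all + mu * length(g)
  }
  mu_all <- mu_all / sum(sizes)
  alpha_raw <- pmax(num / den, floor_alpha)
  # mean-dispersion trend: log-log least squares over informative genes
  use <- alpha_raw > floor_alpha & mu_all > 0
  alpha_trend <- rep(floor_alpha, nrow(k))
  fit_method <- "gene-wise only (too few informative genes for a trend)"
  if (sum(use) >= 10) {
    fit <- stats::lm(la ~ lmu, data.frame(la = log(alpha_raw[use]),
                                          lmu = log(mu_all[use])))
    pred <- stats::predict(fit, newdata = data.frame(
      lmu = log(pmax(mu_all, min(mu_all[use])))))
    alpha_trend <- pmax(exp(pred), floor_alpha)
    fit_method <- "max(gene-wise MoM, log-log trend)"
  }
  alpha <- pmax(alpha_raw, alpha_trend, floor_alpha)
  list(alpha = stats::setNames(alpha, rownames(k)), fit_method = fit_method)
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Conditional exact test on the per-group count sums: with observed sums
#' `k_a`, `k_b`, condition on `K = k_a + k_b` and compute the two-sided
#' p-value `p = sum of P(a, K - a) over all a with
#' P(a, K - a) <= P(k_a, k_b), divided by the sum over all a`, where `P` is
#' the product of two negative-binomial probabilities for the group sums.
#' Each group sum has mean `q * sum(sf)` (`q = K / sum of all size
#' factors`) and variance aggregated over the group's samples by the NB
#' variance function, `sum(q * s_j + alpha * q^2 * s_j^2)` — so the sum's
#' effective dispersion shrinks roughly as `alpha / n`, as it must for a
#' sum of independent NB counts. `alpha = 0` reduces to Poisson.
#'
#' @param k_a,k_b group count sums (non-negative integers).
#' @param sf_a,sf_b per-sample size factors of each group (positive
#'   vectors; a scalar means a single sample).
#' @param alpha per-sample dispersion (>= 0); variance = mu + alpha mu^2.
#' @return p-value in (0, 1].
#' @examples
#' nb_exact_test(5, 5, 1, 1, 0.1)    # symmetric observation: p = 1
#' nb_exact_test(2, 40, 1, 1, 0.01)  # strongly unbalanced: small p
#' @export
nb_exact_test <- function(k_a, k_b, sf_a, sf_b, alpha) {
  if (alpha < 0) stop("dispersion alpha must be >= 0")
  if (any(sf_a <= 0) || any(sf_b <= 0)) stop("size factors must be positive")
  if (k_a < 0 || k_b < 0) stop("counts must be non-negative")
  K <- k_a + k_b
  if (K == 0) return(1)
  s_a <- sum(sf_a); s_b <- sum(sf_b)
  q <- K / (s_a + s_b)
  group_logpmf <- function(x, sf) {
    mu <- q * sum(sf)
    v <- sum(q * sf + alpha * q^2 * sf^2)
    if (v <= mu * (1 + 1e-12)) {
      stats::dpois(x, mu, log = TRUE)
    } else {
      stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu), log = TRUE)
    }
  }
  a <- 0:K
  logp <- group_logpmf(a, sf_a) + group_logpmf(K - a, sf_b)
  logp <- logp - max(logp)
  p <- exp(logp)
  pobs <- p[k_a + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]) / sum(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: `q_(i) = min_{j >= i} m * p_(j) / j`
#' capped at 1, order-preserving. Validates the input and delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs not allowed).
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. For small samples
#' (combined n <= `exact_limit`, default 16) the null distribution is
#' enumerated exhaustively over all group assignments of the observed
#' values, which is valid under ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. The exact path
#' can be forced with `exact = TRUE` regardless of sample size.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"greater"` (x tends larger than y) or `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` chooses by `exact_limit`.
#' @param exact_limit combined-size threshold for the exact path.
#' @return p-value.
#' @examples
#' wilcoxon_one_sided(c(1, 2), c(3, 4), "less")   # exact: 1/6
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less"),
                               exact = NULL, exact_limit = 16L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  comb <- c(x, y)
  r <- rank(comb)   # midranks
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- N <= exact_limit
  if (exact) {
    sets <- utils::combn(N, nx)
    rk <- rank(comb)
    Us <- colSums(matrix(rk[sets], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    if (alternative == "greater") {
      mean(Us >= U_obs - eps)
    } else {
      mean(Us <= U_obs + eps)
    }
  } else {
    mu <- nx * ny / 2
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    sd0 <- sqrt(sigma2)
    if (alternative == "greater") {
      stats::pnorm((U_obs - mu - 0.5) / sd0, lower.tail = FALSE)
    } else {
      stats::pnorm((U_obs - mu + 0.5) / sd0, lower.tail = TRUE)
    }
  }
}

#' Chi-square goodness-of-fit test
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts rescaled to the observed
#' total; p-value from the chi-square distribution with
#' `categories - 1` degrees of freedom.
#'
#' @param observed non-negative counts per category.
#' @param expected positive expected weights (rescaled to `sum(observed)`).
#' @return List with `statistic`, `p_value` and `df`.
#' @export
chi_square_gof <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (sum(observed) <= 0) stop("observed counts sum to zero")
  if (any(expected <= 0)) stop("expected counts must be positive")
  e <- expected / sum(expected) * sum(observed)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df)
}
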