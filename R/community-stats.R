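#' Gini-Simpson diversity
#'
#' `1 - sum(p_i^2)`: the probability that two random draws belong to
#' different taxa. The raw Simpson concentration `sum(p_i^2)` is available
#' via `raw = TRUE`.
#'
#' @param p Non-negative abundance vector; renormalized to sum to 1 with a
#'   warning when it does not.
#' @param raw Return the concentration `sum(p^2)` instead (default FALSE).
#' @return Diversity in [0, 1] (or concentration). An all-zero vector is
#'   undefined and returns `NA` with a warning.
#' @export
gini_simpson <- function(p, raw = FALSE) {
  if (any(p < 0)) stop("abundances must be >= 0", call. = FALSE)
  s <- sum(p)
  if (s == 0) {
    warning("all-zero abundance vector: diversity undefined", call. = FALSE)
    return(NA_real_)
  }
  if (abs(s - 1) > 1e-9) {
    warning("abundances renormalized to sum to 1", call. = FALSE)
    p <- p / s
  }
  conc <- sum(p^2)
  if (raw) conc else 1 - conc
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over a shared taxon set.
#'
#' @param x Numeric matrix, samples in rows, taxa in columns, non-negative.
#' @return Symmetric matrix of dissimilarities in [0, 1] with zero
#'   diagonal. Pairs where both samples are all-zero are undefined and set
#'   to `NA` with a warning.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be >= 0", call. = FALSE)
  zero_rows <- rowSums(x) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(zero_rows)) {
    warning("all-zero sample(s): pairwise dissimilarity undefined for ",
            paste(rownames(x)[zero_rows], collapse = ", "), call. = FALSE)
    zz <- outer(zero_rows, zero_rows, `&`)
    diag(zz) <- FALSE
    d[zz] <- NA_real_
  }
  diag(d) <- 0
  d
}

#' Principal coordinates ordination
#'
#' Classical scaling of a dissimilarity matrix: double-center `-D^2/2`,
#' eigendecompose, and scale eigenvectors by the square roots of the
#' positive eigenvalues. Negative eigenvalues (from non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but not used for
#' coordinates.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of ordination axes requested (default 2); truncated
#'   with a warning when fewer positive eigenvalues exist.
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   ordered), and `explained` (proportion of the positive-eigenvalue sum
#'   per retained axis).
#' @export
pcoa_ordination <- function(d, k = 2L) {
  stopifnot(k >= 1L)
  d <- as.matrix(d)
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1L), eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); coordinates truncated",
            call. = FALSE)
  }
  k_eff <- max(min(k, n_pos), 0L)
  coords <- if (k_eff > 0L) {
    fit$points[, seq_len(k_eff), drop = FALSE]
  } else {
    matrix(0, nrow = n, ncol = 0L, dimnames = list(rownames(d), NULL))
  }
  pos_sum <- sum(eig[eig > 0])
  explained <- if (k_eff > 0L && pos_sum > 0) {
    eig[seq_len(k_eff)] / pos_sum
  } else numeric(0L)
  list(coordinates = coords, eigenvalues = eig, explained = explained)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on
#' `groups - 1` degrees of freedom. Identical values throughout give
#' `H = 0`, `p = 1` (no evidence, rather than an undefined statistic).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector of the same length (>= 2 groups with >= 1
#'   value each).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop(">= 2 groups required", call. = FALSE)
  if (length(values) != length(groups)) {
    stop("`values` and `groups` lengths differ", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1))
  }
  fit <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' For each pair of groups, the standardized difference of mean ranks
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` with ties pooled over the whole sample, two-sided
#' p-values from the standard normal, and Benjamini-Hochberg adjustment
#' across all pairs of the response.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (>= 2 non-empty groups; empty levels are
#'   dropped with a warning).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Tibble `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "BH") {
  if (!is.factor(groups)) groups <- as.factor(as.character(groups))
  empty <- levels(groups)[tabulate(groups, nlevels(groups)) == 0L]
  if (length(empty) > 0L) {
    warning("empty group(s) excluded: ", paste(empty, collapse = ", "),
            call. = FALSE)
    groups <- droplevels(groups)
  }
  lev <- levels(groups)
  if (length(lev) < 2L) stop(">= 2 groups required", call. = FALSE)

  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    se <- sqrt(var_base * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
                 p_value = p,
                 p_adjusted = stats::p.adjust(p, method = p_adjust))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: sort p ascending, take
#' `min_{j >= i} p_j m / j`, cap at 1, return in input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
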