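#' Expected synapse-count distribution under the Poisson wiring model
#'
#' Null model in which each of `N` synapses is assigned independently and
#' uniformly among `M` candidate cells. The expected number of cells with
#' exactly `k` synapses is `M * (N/M)^k * exp(-N/M) / k!` — i.e. `M`
#' times the Poisson pmf with mean `N/M`. There are no free parameters;
#' the variance of each count equals its expectation, so the reported SD
#' is `sqrt(c_k)`. The full (untruncated) expected counts sum to `M`.
#'
#' @param N Total synapse count.
#' @param M Number of candidate cells (>= 1).
#' @param k_max Largest count to tabulate.
#' @return Numeric vector `c_0 .. c_k_max` (names give k).
#' @examples
#' # 151 synapses over 78 posterior KCs: ~21.8 cells expected with k = 1
#' poisson_expected_counts(151, 78, 4)
#' @export
poisson_expected_counts <- function(N, M, k_max) {
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  stopifnot(N >= 0, k_max >= 0)
  k <- 0:k_max
  out <- M * stats::dpois(k, N / M)
  names(out) <- k
  out
}

#' Chi-square goodness of fit with a minimum-expected-count rule
#'
#' Retains only bins whose expected count is at least `min_expected`
#' (default 0.5), computes `chi2 = sum (o - e)^2 / e` over the retained
#' bins, and takes the p-value from the chi-square distribution. The
#' default degrees-of-freedom convention counts every retained bin
#' (`df_convention = "bins"`), which reproduces the published worked
#' example (chi2 = 5.3 with 7 df for 7 retained bins); the standard
#' convention subtracting 2 (one for the total, one for the estimated
#' mean) is available as `"bins_minus_2"` and is the better-calibrated
#' choice when the mean is estimated from the data.
#'
#' @param observed,expected Equal-length numeric vectors of bin counts.
#' @param min_expected Minimum expected count for a bin to be retained.
#' @param df_convention `"bins"` (default) or `"bins_minus_2"`.
#' @return List with `chi2`, `df`, `p_value`, and the logical `retained`
#'   mask.
#' @export
chi2_gof <- function(observed, expected, min_expected = 0.5,
                     df_convention = c("bins", "bins_minus_2")) {
  df_convention <- match.arg(df_convention)
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length", call. = FALSE)
  if (any(expected < 0)) stop("expected counts must be >= 0", call. = FALSE)
  keep <- expected >= min_expected
  if (!any(keep))
    stop("no bin has expected count >= ", min_expected, call. = FALSE)
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep)
  if (df_convention == "bins_minus_2") df <- max(df - 2L, 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       retained = keep)
}

#' Classify a Poisson-fit p-value
#'
#' Three-way colour classification of goodness-of-fit p-values: `green`
#' (statistically indistinguishable from Poisson, p > 0.05), `magenta`
#' (more than three sigma different, p < 0.003), `yellow` (intermediate).
#'
#' @param p_value Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of classes.
#' @export
classify_fit <- function(p_value) {
  stopifnot(all(p_value >= 0 & p_value <= 1))
  ifelse(p_value > 0.05, "green",
         ifelse(p_value < 0.003, "magenta", "yellow"))
}

#' Fit the Poisson wiring model to a per-cell count vector
#'
#' Tabulates the observed number of cells with k synapses (zeros
#' included), computes the model expectation from `M = length(counts)`
#' and `N = sum(counts)`, and evaluates [chi2_gof()] with the
#' minimum-expected-count rule, returning the colour class of the fit.
#'
#' @param counts Integer vector of per-cell synapse counts (one entry per
#'   candidate cell, zeros included), as from [per_cell_counts()].
#' @param min_expected Bin-retention threshold.
#' @param df_convention Passed to [chi2_gof()].
#' @return List of class `poisson_fit`: `M`, `N`, `lambda`, `observed`,
#'   `expected` (vectors over k = 0..k_max), `chi2`, `df`, `p_value`,
#'   `fit_class`.
#' @export
poisson_fit <- function(counts, min_expected = 0.5,
                        df_convention = c("bins", "bins_minus_2")) {
  df_convention <- match.arg(df_convention)
  M <- length(counts)
  if (M < 1) stop("counts must have at least one cell", call. = FALSE)
  N <- sum(counts)
  k_max <- max(counts, ceiling(stats::qpois(0.9999, N / M)))
  obs <- tabulate(counts + 1L, nbins = k_max + 1L)
  names(obs) <- 0:k_max
  exp_ <- poisson_expected_counts(N, M, k_max)
  gof <- chi2_gof(obs, exp_, min_expected, df_convention)
  structure(
    list(M = M, N = N, lambda = N / M, observed = obs, expected = exp_,
         chi2 = gof$chi2, df = gof$df, p_value = gof$p_value,
         fit_class = classify_fit(gof$p_value)),
    class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf(
    "<poisson_fit> M = %d cells, N = %d synapses, lambda = %.3f\n",
    x$M, x$N, x$lambda))
  cat(sprintf("  chi2 = %.2f, df = %d, p = %.4g  [%s]\n",
              x$chi2, x$df, x$p_value, x$fit_class))
  invisible(x)
}

#' Poisson-fit grid over connection types
#'
#' For every combination of presynaptic cell type and postsynaptic cell,
#' fits the Poisson wiring model to the per-cell synapse-count vector and
#' reports p-value and colour class — the batch view used to scan a whole
#' connectome for departures from independent random wiring.
#'
#' @param x A `connectome`.
#' @param pre_types Character vector of presynaptic cell-type tokens
#'   (default: the KC subtypes present).
#' @param post_cells Postsynaptic neuron ids (default: all MBONs and
#'   DANs).
#' @param compartment Optional compartment restriction.
#' @param min_pairs Minimum number of presynaptic cells for a fit.
#' @param df_convention Passed to [chi2_gof()].
#' @return Data frame with one row per (pre_type, post_cell): `M`, `N`,
#'   `lambda`, `chi2`, `df`, `p_value`, `fit_class`.
#' @export
poisson_fit_grid <- function(x, pre_types = NULL, post_cells = NULL,
                             compartment = NULL, min_pairs = 5L,
                             df_convention = c("bins", "bins_minus_2")) {
  df_convention <- match.arg(df_convention)
  stopifnot(inherits(x, "connectome"))
  if (is.null(pre_types))
    pre_types <- intersect(kc_subtypes(), unique(x$neurons$cell_type))
  if (is.null(post_cells))
    post_cells <- x$neurons$neuron_id[x$neurons$type_class %in%
                                        c("MBON", "DAN")]
  rows <- list()
  for (pt in pre_types) {
    pre <- x$neurons$neuron_id[x$neurons$cell_type == pt]
    if (length(pre) < min_pairs) next
    for (pc in post_cells) {
      cnt <- per_cell_counts(x, pre, pc, compartment)
      if (sum(cnt) == 0L) next
      fit <- poisson_fit(cnt, df_convention = df_convention)
      rows[[length(rows) + 1L]] <- data.frame(
        pre_type = pt, post_cell = pc, M = fit$M, N = fit$N,
        lambda = fit$lambda, chi2 = fit$chi2, df = fit$df,
        p_value = fit$p_value, fit_class = fit$fit_class)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pre_type = character(0), post_cell = character(0),
               M = integer(0), N = integer(0), lambda = numeric(0),
               chi2 = numeric(0), df = integer(0), p_value = numeric(0),
               fit_class = character(0))
  rownames(out) <- NULL
  out
}

#' Shared-partner independence (Fisher exact test)
#'
#' Cross-classifies a universe of candidate partner cells by whether they
#' are targets of cell A and of cell B, and tests independence of the two
#' connection patterns with a two-sided Fisher exact test (summing tables
#' with probability at most that observed; the published analysis does
#' not state sidedness, so the standard two-sided convention is used).
#'
#' @param targets_a,targets_b Character vectors of partner cell ids
#'   (subsets of `universe`).
#' @param universe Character vector of all candidate partner cells.
#' @return List of class `shared_partner_table`: `both`, `only_a`,
#'   `only_b`, `neither`, `p_value`.
#' @export
fisher_shared_partners <- function(targets_a, targets_b, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(targets_a %in% universe) || !all(targets_b %in% universe))
    stop("targets must be subsets of the universe", call. = FALSE)
  in_a <- universe %in% targets_a
  in_b <- universe %in% targets_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(
    list(both = tab[1, 1], only_a = tab[2, 1], only_b = tab[1, 2],
         neither = tab[2, 2], p_value = p),
    class = "shared_partner_table")
}

#' @export
print.shared_partner_table <- function(x, ...) {
  n <- x$both + x$only_a + x$only_b + x$neither
  cat("<shared_partner_table>\n")
  cat(sprintf("  both %d (%.1f%%), only A %d, only B %d, neither %d (%.1f%%)\n",
              x$both, 100 * x$both / n, x$only_a, x$only_b,
              x$neither, 100 * x$neither / n))
  cat(sprintf("  Fisher exact (two-sided) p = %.3g\n", x$p_value))
  invisible(x)
}

#' Pearson correlation of paired per-cell synapse counts
#'
#' Correlates the synapse counts each presynaptic cell makes onto two
#' targets (e.g. the two MBONs of a compartment). Zero variance in
#' either vector makes the coefficient undefined; that case returns `NA`
#' with a warning rather than an arbitrary value.
#'
#' @param counts_a,counts_b Equal-length numeric vectors (length >= 3).
#' @return Pearson r, or `NA` when undefined.
#' @export
paired_target_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length", call. = FALSE)
  if (length(counts_a) < 3L)
    stop("need at least 3 paired cells", call. = FALSE)
  if (stats::var(counts_a) == 0 || stats::var(counts_b) == 0) {
    warning("zero variance in a count vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(counts_a, counts_b, method = "pearson")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper reporting the two-sample KS statistic (maximum ECDF gap)
#' and its asymptotic p-value.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
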