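#' Permutation test for repeated co-convergence of KC pairs
#'
#' Asks whether two KCs that participate in one rosette have an increased
#' chance of converging again in another rosette elsewhere in the lobe.
#' The statistic is the number of unordered KC pairs that co-occur in at
#' least two rosettes. The null resamples KC identities while keeping the
#' rosette sizes fixed (labels drawn without replacement within each
#' rosette from the candidate pool), and the p-value is the standard
#' permutation estimate `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param memberships List of character vectors, each the distinct KC ids
#'   of one rosette (length >= 2); at least two rosettes.
#' @param n_perm Number of permutations; fewer than 100 triggers a
#'   warning.
#' @param seed Optional integer seed.
#' @param kc_pool Candidate KC ids for resampling; defaults to the union
#'   of all observed members.
#' @return List of class `rosette_repeat_test`: `statistic`, `p_value`,
#'   `perm_stats` (the permutation distribution), `n_perm`.
#' @export
rosette_repeat_test <- function(memberships, n_perm = 1000L, seed = NULL,
                                kc_pool = NULL) {
  if (length(memberships) < 2L)
    stop("need at least two rosettes", call. = FALSE)
  if (n_perm < 100L)
    warning("n_perm < 100 gives a coarse p-value")
  if (!is.null(seed)) set.seed(as.integer(seed))
  memberships <- lapply(memberships, unique)
  sizes <- lengths(memberships)
  if (any(sizes < 2L))
    stop("each rosette needs >= 2 distinct KCs", call. = FALSE)
  if (is.null(kc_pool)) kc_pool <- unique(unlist(memberships))
  if (max(sizes) > length(kc_pool))
    stop("kc_pool smaller than the largest rosette", call. = FALSE)

  repeat_pairs <- function(mem) {
    pairs <- unlist(lapply(mem, function(m) {
      m <- sort(m)
      if (length(m) < 2L) return(character(0))
      cmb <- utils::combn(m, 2L)
      paste(cmb[1, ], cmb[2, ], sep = "\r")
    }))
    if (!length(pairs)) return(0L)
    sum(table(pairs) >= 2L)
  }

  obs <- repeat_pairs(memberships)
  perm <- vapply(seq_len(n_perm), function(i) {
    repeat_pairs(lapply(sizes, function(s) sample(kc_pool, s)))
  }, numeric(1))
  structure(
    list(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
         perm_stats = perm, n_perm = n_perm),
    class = "rosette_repeat_test")
}

#' @export
print.rosette_repeat_test <- function(x, ...) {
  cat(sprintf(
    "<rosette_repeat_test> %d KC pair(s) repeat across rosettes; p = %.3g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm))
  invisible(x)
}
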