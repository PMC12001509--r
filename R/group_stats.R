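# Nonparametric k-group comparison: tie-corrected Kruskal-Wallis,
# Dunn's many-to-one post-hoc z tests on pooled mid-ranks, multiplicity
# adjustment and significance star coding.

# pooled mid-ranks and the tie-size table
pooled_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)  # mid-ranks for ties
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  ties <- table(x)
  list(r = r, idx = idx, sizes = sizes, N = length(x),
       tie_sizes = as.numeric(ties[ties > 1]))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Computes the tie-corrected statistic
#' \eqn{H_c = H / (1 - \sum(t^3 - t)/(N^3 - N))} on pooled mid-ranks.
#' The p-value uses the chi-square approximation with k - 1 degrees of
#' freedom, except that for very small samples (`p_method = "auto"`,
#' at most `exact_limit` distinct group assignments) the exact
#' permutation null is enumerated instead, because the chi-square
#' approximation is unreliable there.
#'
#' @param groups list of >= 2 numeric vectors, each non-empty, with at
#'   least two distinct values overall.
#' @param p_method `"auto"` (default), `"chisq"` or `"exact"`.
#' @param exact_limit maximum number of assignments enumerated by the
#'   exact method.
#' @return object of class `kw_result`: `H` (tie-corrected), `df`,
#'   `p_value`, `n`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("auto", "chisq", "exact"),
                           exact_limit = 1e5) {
  p_method <- match.arg(p_method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must contain at least one value")
  pr <- pooled_ranks(groups)
  if (length(unique(unlist(groups))) < 2)
    stop("all values are identical; the statistic is undefined")
  H <- kw_statistic(pr$r, pr$idx, pr$sizes, pr$N, pr$tie_sizes)
  df <- length(groups) - 1L

  n_assign <- exp(lgamma(pr$N + 1) - sum(lgamma(pr$sizes + 1)))
  use_exact <- switch(p_method,
                      exact = TRUE,
                      chisq = FALSE,
                      auto = n_assign <= exact_limit)
  if (use_exact && n_assign > exact_limit)
    stop("exact enumeration infeasible: ", format(n_assign),
         " assignments exceed exact_limit")
  if (use_exact) {
    hs <- kw_enumerate(pr$r, pr$sizes, pr$N, pr$tie_sizes)
    p <- mean(hs >= H - 1e-9)
    method <- "exact permutation"
  } else {
    p <- pchisq(H, df, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  structure(list(H = H, df = df, p_value = p, n = pr$N, method = method),
            class = "kw_result")
}

kw_statistic <- function(r, idx, sizes, N, tie_sizes) {
  Rsum <- vapply(split(r, idx), sum, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  if (C <= 0) stop("all values are identical; the statistic is undefined")
  H / C
}

# enumerate H over all distinct assignments of the pooled ranks to the
# group sizes (breadth-first over combinations)
kw_enumerate <- function(r, sizes, N, tie_sizes) {
  splits <- list(seq_len(N))
  assign_list <- list(integer(0))
  for (g in seq_len(length(sizes) - 1L)) {
    new_splits <- list(); new_assign <- list()
    for (s in seq_along(splits)) {
      avail <- splits[[s]]
      cmb <- utils::combn(avail, sizes[g])
      for (k in seq_len(ncol(cmb))) {
        chosen <- cmb[, k]
        new_splits[[length(new_splits) + 1]] <- setdiff(avail, chosen)
        new_assign[[length(new_assign) + 1]] <-
          c(assign_list[[s]], list(chosen))
      }
    }
    splits <- new_splits; assign_list <- new_assign
  }
  vapply(seq_along(splits), function(s) {
    members <- c(assign_list[[s]], list(splits[[s]]))
    idx <- integer(N)
    for (g in seq_along(members)) idx[members[[g]]] <- g
    kw_statistic(r, idx, sizes, N, tie_sizes)
  }, numeric(1))
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%s, N = %d)\n",
              x$H, x$df, x$p_value, x$method, x$n))
  invisible(x)
}

#' Dunn's many-to-one post-hoc comparisons
#'
#' For each non-reference group i, the rank-based z statistic against
#' the reference r is
#' \deqn{z = (\bar R_i - \bar R_r) / \sqrt{(N(N+1)/12 -
#'   \sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_r)}}
#' on pooled mid-ranks, with a two-sided normal p-value and multiplicity
#' adjustment over the k - 1 comparisons performed.
#'
#' @param groups named list of numeric vectors.
#' @param reference_label name of the reference (control) group.
#' @param adjustment `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return data.frame of class `dunn_result`: one row per comparison
#'   with `group`, `reference`, `n_group`, `n_reference`, `mean_rank`,
#'   `z`, `p_raw`, `p_adjusted`, `stars`.
#' @export
dunn_many_to_one <- function(groups, reference_label,
                             adjustment = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (!reference_label %in% names(groups))
    stop("reference group '", reference_label, "' not found")
  if (!adjustment %in% c("bonferroni", "holm", "none"))
    stop("unknown adjustment method: ", adjustment)
  pr <- pooled_ranks(groups)
  mean_ranks <- vapply(split(pr$r, pr$idx), mean, numeric(1))
  names(mean_ranks) <- names(groups)
  N <- pr$N
  tie_term <- sum(pr$tie_sizes^3 - pr$tie_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  ref <- reference_label
  others <- setdiff(names(groups), ref)
  n <- pr$sizes; names(n) <- names(groups)
  z <- vapply(others, function(g) {
    se <- sqrt(var_base * (1 / n[[g]] + 1 / n[[ref]]))
    (mean_ranks[[g]] - mean_ranks[[ref]]) / se
  }, numeric(1))
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjustment)
  out <- data.frame(group = others, reference = ref,
                    n_group = as.integer(n[others]),
                    n_reference = n[[ref]],
                    mean_rank = as.numeric(mean_ranks[others]),
                    z = as.numeric(z), p_raw = as.numeric(p_raw),
                    p_adjusted = as.numeric(p_adj),
                    stars = assign_stars(as.numeric(p_adj)),
                    row.names = NULL)
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Significance star codes
#'
#' Maps adjusted p-values to the conventional star coding with strict
#' inequalities: `ns` for p >= 0.05, `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001, `****` for p < 0.0001 (the most
#' significant bin wins).
#'
#' @param p_adjusted numeric vector of p-values in `[0, 1]`.
#' @return character vector of star codes.
#' @export
assign_stars <- function(p_adjusted) {
  if (any(is.na(p_adjusted)) || any(p_adjusted < 0 | p_adjusted > 1))
    stop("p-values must lie in [0, 1]")
  vapply(p_adjusted, function(p) {
    if (p < 0.0001) "****"
    else if (p < 0.001) "***"
    else if (p < 0.01) "**"
    else if (p < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Write the statistics report CSV
#'
#' One header comment row with the omnibus Kruskal-Wallis result, then
#' one row per Dunn comparison.
#'
#' @param kw a `kw_result`.
#' @param dunn a `dunn_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(kw, dunn, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("# Kruskal-Wallis H = %.6g df = %d p = %.6g N = %d",
                       kw$H, kw$df, kw$p_value, kw$n), con)
    write.csv(as.data.frame(dunn), con, row.names = FALSE)
  })
}
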