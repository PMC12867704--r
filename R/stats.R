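# Rank-based comparison statistics used for the assay contrasts:
# Mann-Whitney U (exact by enumeration for small samples), Kruskal-Wallis
# with Dunn's post hoc z tests, and Benjamini-Hochberg FDR control.

#' Mann-Whitney U test
#'
#' U is computed from midranks (ties counted 1/2). For combined sample sizes
#' up to `exact_max` the p-value is exact, obtained by complete enumeration
#' of all group assignments; otherwise a tie-corrected normal approximation
#' with continuity correction is used. Fully tied data return p = 1 with a
#' `degenerate` flag.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_max Largest combined sample size for which the exact
#'   enumeration is used.
#' @return A list with `U` (for `x`), `p`, `method` and `degenerate`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # exact 2/6
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_max = 12) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  r <- rank(comb)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(comb)) == 1L)
    return(list(U = u, p = 1, method = "degenerate", degenerate = TRUE))
  if (n <= exact_max) {
    idx <- utils::combn(n, nx)
    rs <- colSums(matrix(r[idx], nrow = nx))
    us <- rs - nx * (nx + 1) / 2
    p <- switch(alternative,
                two.sided = min(1, 2 * min(mean(us <= u), mean(us >= u))),
                greater = mean(us >= u),
                less = mean(us <= u))
    return(list(U = u, p = p, method = "exact", degenerate = FALSE))
  }
  mu <- nx * ny / 2
  ties <- table(comb)
  sigma <- sqrt(nx * ny / 12 *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z <- u - mu
  cc <- switch(alternative, two.sided = sign(z) * 0.5,
               greater = 0.5, less = -0.5)
  z <- (z - cc) / sigma
  p <- switch(alternative,
              two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(U = u, p = min(1, p), method = "normal", degenerate = FALSE)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H with a chi-square p-value, via [stats::kruskal.test()].
#'
#' @param groups A list of numeric vectors, one per group (at least two
#'   non-empty groups).
#' @return A list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(!lengths(groups))) stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the usual
#' tie correction; two-sided p-values adjusted for multiplicity
#' (Benjamini-Hochberg by default).
#'
#' @param groups Named list of numeric vectors.
#' @param p_adjust_method Passed to [stats::p.adjust()].
#' @return A data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, p_adjust_method = "BH") {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  rbar <- tapply(r, rep(names(groups), sizes), mean)[names(groups)]
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = p_adjust_method)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, delegated to
#' [stats::p.adjust()] after input validation.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}
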