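# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every global
# alignment recursively, the rank-test oracles enumerate group assignments
# in value space.

# Score one explicit gapped alignment (two equal-length letter vectors)
# under the affine convention: a gap run of length L costs
# open + (L - 1) * extend.
score_gapped <- function(ca, cb, mat, open, ext) {
  s <- 0
  in_gap <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") {
      s <- s + if (in_gap) ext else open
      in_gap <- TRUE
    } else {
      s <- s + mat[ca[k], cb[k]]
      in_gap <- FALSE
    }
  }
  s
}

# Best global alignment score by exhaustive enumeration of all alignments.
oracle_align_score <- function(a, b, mat, open, ext) {
  la <- strsplit(a, "")[[1]]
  lb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(la) && j > length(lb)) {
      s <- score_gapped(ca, cb, mat, open, ext)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(la) && j <= length(lb))
      rec(i + 1, j + 1, c(ca, la[i]), c(cb, lb[j]))
    if (i <= length(la)) rec(i + 1, j, c(ca, la[i]), c(cb, "-"))
    if (j <= length(lb)) rec(i, j + 1, c(ca, "-"), c(cb, lb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# Exact two-sided Mann-Whitney p by enumeration over all assignments of the
# pooled values to the two groups, with U computed by pair counting.
oracle_mw_p <- function(x, y) {
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  mu <- nx * length(y) / 2
  u_obs <- u_stat(x, y)
  us <- apply(utils::combn(n, nx), 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Tie-corrected Kruskal-Wallis H through the rank-variance identity
# H = (N - 1) * SS_between(ranks) / SS_total(ranks).
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  r <- rank(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, g, mean)
  ss_between <- sum(lengths(groups) * (rbar - mean(r))^2)
  ss_total <- sum((r - mean(r))^2)
  (length(pooled) - 1) * ss_between / ss_total
}

# Step-up Benjamini-Hochberg by the hand formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Small deterministic movie: blobs rendered without any noise.
toy_movie <- function(positions_by_frame, dim = c(64, 64), fps = 25,
                      amplitude = 100, sigma = 1.2,
                      flash_frame = NA_integer_) {
  frames <- lapply(positions_by_frame, function(pos) {
    img <- matrix(0, dim[1], dim[2])
    for (ci in seq_len(nrow(pos))) {
      rr <- pmax(1, round(pos[ci, 1]) - 5):pmin(dim[1], round(pos[ci, 1]) + 5)
      cc <- pmax(1, round(pos[ci, 2]) - 5):pmin(dim[2], round(pos[ci, 2]) + 5)
      img[rr, cc] <- img[rr, cc] + amplitude *
        exp(-outer((rr - pos[ci, 1])^2, (cc - pos[ci, 2])^2, "+") /
              (2 * sigma^2))
    }
    img
  })
  movie_stack(frames, fps, flash_frame)
}
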