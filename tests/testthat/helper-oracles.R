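# Independent numeric oracles, written against the raw trapezoid geometry
# so they share no code with the piecewise-linear inference engine.

# membership of trapezoid p = c(l, k1, k2, r), kernel wins at degenerate shoulders
oracle_trapezoid <- function(p, x) {
  mu <- numeric(length(x))
  mu[x >= p[2] & x <= p[3]] <- 1
  if (p[2] > p[1]) {
    i <- x > p[1] & x < p[2]
    mu[i] <- (x[i] - p[1]) / (p[2] - p[1])
  }
  if (p[4] > p[3]) {
    i <- x > p[3] & x < p[4]
    mu[i] <- (p[4] - x[i]) / (p[4] - p[3])
  }
  mu
}

# dense-grid trapezoid-rule centroid of max_j min(h_j, trapezoid_j)
# pieces: list of list(params = c(l,k1,k2,r), h = clip level)
oracle_cog <- function(pieces, lo, hi, step = 1e-4) {
  x <- seq(lo, hi, by = step)
  mu <- rep(0, length(x))
  for (p in pieces) {
    mu <- pmax(mu, pmin(p$h, oracle_trapezoid(p$params, x)))
  }
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  trapz(x * mu) / trapz(mu)
}

# numeric oracle for a tier-1 normalizer built from printed parameters:
# sets_in / sets_out are lists of c(l,k1,k2,r); cons maps input set index
# to output set index
oracle_normalize <- function(x, sets_in, sets_out, cons, lo, hi, step = 1e-4) {
  pieces <- list()
  for (i in seq_along(sets_in)) {
    h <- oracle_trapezoid(sets_in[[i]], x)
    if (h > 0) {
      pieces[[length(pieces) + 1L]] <- list(params = sets_out[[cons[i]]], h = h)
    }
  }
  oracle_cog(pieces, lo, hi, step)
}

# brute-force Spearman rho: Pearson correlation of average ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

default_scores <- function() {
  c(pss10 = 20, swls = 19.5, nmq = 20, mbi_ee = 21.5, mbi_dp = 11,
    mbi_pa = 35)
}

# small valid records table for I/O tests
make_records <- function() {
  data.frame(
    subject_id = rep(c("s1", "s2"), each = 3),
    group = "g",
    timepoint = rep(c("t1", "t2", "t3"), 2),
    pss10 = c(10, 20, 30, 12, 12, 14),
    swls = c(30, 25, 15, 28, 27, 28),
    nmq = c(1, 2, 5, 0, 0, 1),
    mbi_ee = c(10, 20, 40, 12, 13, 12),
    mbi_dp = c(4, 10, 20, 5, 6, 5),
    mbi_pa = c(40, 35, 20, 41, 40, 42))
}
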