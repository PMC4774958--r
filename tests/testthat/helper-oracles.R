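# Independent oracles, deliberately on different code paths than the package.

# Brute-force exact two-sided Mann-Whitney p: U computed by pairwise counting
# (greater + half ties), enumerating every group assignment of the pooled
# values with combn.  The package computes U from midrank sums instead.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  center <- na * (n - na) / 2
  obs <- abs(u_of(a, b) - center)
  sets <- combn(n, na)
  devs <- apply(sets, 2, function(ix)
    abs(u_of(pooled[ix], pooled[-ix]) - center))
  mean(devs >= obs - 1e-9)
}

# random feature matrix over n labelled rows
random_features <- function(n, p = 3) {
  m <- matrix(runif(n * p, 0.1, 1), n, p)
  rownames(m) <- paste0("sp", seq_len(n))
  m
}
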