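# Shared fixtures and independent oracles, built in code at test time.

# random valid flexible-logistic parameters on study-plausible scales
random_params <- function() {
  c(vf = runif(1, 0.05, 0.4),
    x0 = runif(1, 0.2, 0.6),
    k = runif(1, 4, 25),
    n = runif(1, 0.3, 3))
}

# exhaustive hidden-path enumeration oracle for the selfed-RIL HMM.
# obs: character vector ("AA"/"BB"/NA) at each grid position;
# d: inter-position distances in cM. Returns P x 2 posterior matrix.
hmm_enumeration_oracle <- function(obs, d, error_rate) {
  P <- length(obs)
  stopifnot(P <= 12, length(d) == P - 1)
  R <- kinqtl::ril_selfing_R(kinqtl::haldane_r(d))
  emis <- function(state, o) {
    if (is.na(o)) 1 else if (o == c("AA", "BB")[state]) 1 - error_rate else error_rate
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), P)))
  joint <- apply(paths, 1L, function(s) {
    p <- 0.5 * emis(s[1], obs[1])
    if (P > 1) for (j in 2:P) {
      tr <- if (s[j] == s[j - 1]) 1 - R[j - 1] else R[j - 1]
      p <- p * tr * emis(s[j], obs[j])
    }
    p
  })
  post <- matrix(0, P, 2)
  for (j in 1:P) for (g in 1:2) post[j, g] <- sum(joint[paths[, j] == g])
  post / rowSums(post)
}

# explicit normal-equations OLS for the Haley-Knott LOD at one position
hk_lod_oracle <- function(p_bb, y) {
  n <- length(y)
  X1 <- cbind(1, p_bb)
  b1 <- solve(t(X1) %*% X1, t(X1) %*% y)
  rss1 <- sum((y - X1 %*% b1)^2)
  rss0 <- sum((y - mean(y))^2)
  (n / 2) * log10(rss0 / rss1)
}

# tiny two-chromosome map used by several scan tests
toy_map <- function() {
  kinqtl::genetic_map(
    marker = c("a1", "a2", "a3", "b1", "b2"),
    chromosome = c("1", "1", "1", "2", "2"),
    position = c(0, 12, 30, 0, 20)
  )
}
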