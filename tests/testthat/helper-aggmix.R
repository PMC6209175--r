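# fixtures and independent oracles used across test files

tiny_dataset <- function() {
  as_aggregations(data.frame(
    site = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    aggregation_id = c("a1", "a1", "a2", "a3", "b1", "b1", "b2"),
    species = c("sp1", "sp2", "sp1", "sp2", "sp1", "sp3", "sp3"),
    count = c(3, 2, 4, 1, 2, 5, 6)
  ))
}

# brute-force enumeration of every multinomial composition of size n over
# the species in p; returns a data frame of compositions and probabilities.
# Independent of the inclusion-exclusion path it checks.
enumerate_multinomial <- function(p, n) {
  k <- length(p)
  grids <- rep(list(0:n), k)
  comp <- expand.grid(grids)
  comp <- comp[rowSums(comp) == n, , drop = FALSE]
  prob <- apply(comp, 1, function(x) stats::dmultinom(x, prob = p))
  list(counts = as.matrix(comp), prob = prob)
}

# exact pattern probability by enumeration
enum_pattern_prob <- function(pattern_idx, p, n) {
  e <- enumerate_multinomial(p, n)
  present <- e$counts > 0
  target <- seq_along(p) %in% pattern_idx
  hit <- apply(present, 1, function(z) all(z == target))
  sum(e$prob[hit])
}

# exact expected richness by enumeration
enum_expected_richness <- function(p, n) {
  e <- enumerate_multinomial(p, n)
  sum(rowSums(e$counts > 0) * e$prob)
}

# all n^n equally likely bootstrap resample means of a proportion vector
enum_bootstrap_means <- function(props) {
  n <- length(props)
  idx <- expand.grid(rep(list(seq_len(n)), n))
  apply(idx, 1, function(i) mean(props[as.integer(i)]))
}
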