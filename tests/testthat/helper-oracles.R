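# Brute-force oracles: exhaustive enumeration over all richness-preserving
# assignments of communities to specimens. Each specimen i independently
# receives one of choose(S, k[i]) equally likely subsets, so event
# probabilities are exact fractions of the product space. Tractable only
# for tiny instances; kept deliberately independent of the package's
# closed-form implementations.

oracle_enumerate <- function(k, S, event) {
  subsets <- lapply(k, function(ki) {
    if (ki == 0) list(integer(0)) else asplit(utils::combn(S, ki), 2)
  })
  counts <- vapply(subsets, length, integer(1))
  total <- prod(counts)
  stopifnot(total <= 2e5)
  hits <- 0
  idx <- rep(1L, length(k))
  for (r in seq_len(total)) {
    assign <- lapply(seq_along(k), function(i) subsets[[i]][[idx[i]]])
    if (event(assign)) hits <- hits + 1
    # odometer increment
    for (i in seq_along(idx)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= counts[i]) break
      idx[i] <- 1L
    }
  }
  hits / total
}

# P(taxa `pair` never co-occur in any specimen).
oracle_pair_absence <- function(k, S, pair = c(1, 2)) {
  oracle_enumerate(k, S, function(assign) {
    !any(vapply(assign, function(s) all(pair %in% s), logical(1)))
  })
}

# P(every specimen holds at least one of taxa 1..m).
oracle_guarantee <- function(k, S, m) {
  oracle_enumerate(k, S, function(assign) {
    all(vapply(assign, function(s) any(s <= m), logical(1)))
  })
}
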