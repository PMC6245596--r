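# Shared fixture builders. Everything is generated in code; no files.

# R1: -> A, R2: A -> B, R3: A ->   (B has no consumer: seeding R2 must be
# infeasible — the canonical dead-end construction)
dead_end_network <- function() {
  metabolic_network(rbind(c(1, -1, -1), c(0, 1, 0)),
                    c("A", "B"), c("R1", "R2", "R3"), rep(FALSE, 3))
}

# canonical support as a single comparable string
support_key <- function(supp, split_net = NULL) {
  paste(canonical_support(supp, split_net), collapse = ",")
}

# all supports of an extraction result as keys
result_support_keys <- function(res) {
  vapply(res$solutions, function(s) support_key(s$support, res$split_net),
         character(1))
}

# a random network drawn under the fixture defaults used across the tests
test_random_network <- function(rng_seed = 1L) {
  make_random(m = 8, n = 20, density = 0.3, reversible_fraction = 0.2,
              rng_seed = rng_seed)
}
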