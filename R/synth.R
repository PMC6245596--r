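#' Linear chain fixture network
#'
#' `R1: -> M1`, `Rj: M(j-1) -> Mj`, `R(L+1): ML ->`. All-irreversible, the
#' chain has exactly one EFM — the full reaction set — which makes it the
#' degenerate reference case: every extraction iteration must return the
#' same support, and all frequencies converge to 1.
#'
#' @param L chain length (number of internal metabolites, `>= 1`).
#' @param reversible_middle make the middle reaction reversible, which after
#'   splitting adds the futile two-cycle `{mid_fwd, mid_bwd}` to the EFM
#'   set.
#' @return A [metabolic_network()] with `L` metabolites and `L + 1`
#'   reactions.
#' @export
make_chain <- function(L, reversible_middle = FALSE) {
  stopifnot(L >= 1)
  n <- L + 1L
  S <- matrix(0, L, n)
  for (j in seq_len(n)) {
    if (j <= L) S[j, j] <- 1       # produces M_j
    if (j >= 2L) S[j - 1L, j] <- -1  # consumes M_{j-1}
  }
  reversible <- logical(n)
  if (reversible_middle) reversible[ceiling(n / 2)] <- TRUE
  metabolic_network(S, paste0("M", seq_len(L)), paste0("R", seq_len(n)),
                    reversible)
}

#' Parallel-branch fixture network
#'
#' `R_in: -> A`, `b` branch reactions `A -> B`, `R_out: B ->`. There are
#' exactly `b` EFMs, `{R_in, branch_i, R_out}`; `b = 2` is the classic
#' diamond. Because the branches are exchangeable, this is the canonical
#' testbed for solution diversity: an unpenalized solver may settle on one
#' branch, while penalization should spread solutions over all `b`.
#'
#' @param b number of parallel branches (`>= 2`).
#' @return A [metabolic_network()] with 2 metabolites and `b + 2` reactions
#'   (`R_in`, `B1..Bb`, `R_out`).
#' @export
make_parallel <- function(b) {
  stopifnot(b >= 2)
  n <- b + 2L
  S <- matrix(0, 2, n)
  S[1, 1] <- 1                        # R_in: -> A
  S[1, 2:(b + 1L)] <- -1              # branches consume A
  S[2, 2:(b + 1L)] <- 1               # branches produce B
  S[2, n] <- -1                       # R_out: B ->
  metabolic_network(S, c("A", "B"),
                    c("R_in", paste0("B", seq_len(b)), "R_out"),
                    logical(n))
}

#' Random sparse fixture network
#'
#' Integer stoichiometric coefficients in `{-2, -1, 1, 2}` placed uniformly
#' at the requested density, a uniform share of reversible reactions, and
#' rejection resampling until the network admits at least one nontrivial
#' pathway (checked by a feasibility LP requiring total split flux `>= 1`).
#' Integer coefficients keep rank computations exact at these scales;
#' rejection is necessary because random sparse matrices frequently admit
#' only the all-zero steady state.
#'
#' @param m number of metabolites.
#' @param n number of reactions (`>= 2`).
#' @param density fraction of nonzero entries in `(0, 1]`.
#' @param reversible_fraction fraction of reactions flagged reversible.
#' @param rng_seed integer seed; the network is a pure function of the
#'   arguments.
#' @param max_tries abort after this many rejected draws.
#' @return A [metabolic_network()].
#' @export
make_random <- function(m, n, density = 0.25, reversible_fraction = 0,
                        rng_seed = 1L, max_tries = 100L) {
  stopifnot(m >= 1, n >= 2, density > 0, density <= 1,
            reversible_fraction >= 0, reversible_fraction <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(rng_seed)
  for (try in seq_len(max_tries)) {
    S <- matrix(0, m, n)
    nz <- which(matrix(stats::runif(m * n) < density, m, n))
    S[nz] <- sample(c(-2, -1, 1, 2), length(nz), replace = TRUE)
    # a reaction must touch at least one metabolite; give empty columns one
    for (j in which(colSums(abs(S)) == 0))
      S[sample.int(m, 1L), j] <- sample(c(-2, -1, 1, 2), 1L)
    reversible <- stats::runif(n) < reversible_fraction
    net <- metabolic_network(S, paste0("M", seq_len(m)), paste0("R", seq_len(n)),
                             reversible)
    if (has_nontrivial_pathway(net)) return(net)
  }
  stop("no network with a nontrivial pathway found in ", max_tries,
       " draws; increase density or the network size", call. = FALSE)
}

# Feasibility LP: is there v >= 0 with S_split v = 0 and sum(v) >= 1?
has_nontrivial_pathway <- function(net) {
  sn <- as_split_network(net)
  n <- length(sn$reaction_ids)
  # add slack s: sum(v) - s = 1, s >= 0
  A <- rbind(cbind(sn$S, 0), c(rep(1, n), -1))
  res <- .simplex_core(A, c(numeric(nrow(sn$S)), 1), numeric(n + 1L), 1e-9)
  res$status == 0L
}
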