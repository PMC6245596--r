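#' Canonical form of a support set
#'
#' @param ids character vector of split-reaction ids (or an integer support
#'   plus the `split_net` to resolve it against).
#' @param split_net optional `split_network` used to translate indices.
#' @return Sorted, duplicate-free character vector; two supports are the
#'   same pathway support iff their canonical forms are identical.
#' @export
canonical_support <- function(ids, split_net = NULL) {
  if (is.numeric(ids)) {
    stopifnot(!is.null(split_net))
    ids <- split_net$reaction_ids[as.integer(ids)]
  }
  sort(unique(as.character(ids)))
}

#' Is a flux vector a pathway?
#'
#' A pathway (flux mode) is a nonzero, nonnegative flux vector at steady
#' state on the split network: `S v = 0` within tolerance, `v >= 0`, and
#' `v != 0`. The all-zero vector always solves the system but carries no
#' biological information, so it is excluded.
#'
#' @param split_net a `split_network`.
#' @param v numeric flux vector over the split reactions.
#' @param tol relative tolerance; the residual test is
#'   `max|S v| <= tol * (1 + max|v|)`.
#' @return `TRUE` or `FALSE`.
#' @export
is_pathway <- function(split_net, v, tol = 1e-9) {
  split_net <- as_split_network(split_net)
  stopifnot(length(v) == length(split_net$reaction_ids))
  resid <- max(abs(split_net$S %*% v))
  resid <= tol * (1 + max(abs(v))) && min(v) >= -tol && any(abs(v) > tol)
}

# Numeric matrix rank via SVD; tolerance relative to the largest singular
# value, suited to the small integer stoichiometries used here.
mat_rank <- function(M, rel_tol = 1e-9) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  sv <- svd(M, nu = 0, nv = 0)$d
  sum(sv > rel_tol * sv[1L])
}

# Is there a pathway with support exactly `support`? Feasibility LP on the
# support columns only (off-support fluxes are structurally zero), with
# every retained flux >= 1 so the support is exact.
support_feasible <- function(split_net, support, tol = 1e-9) {
  Ssub <- split_net$S[, support, drop = FALSE]
  !is.null(solve_seeded_lp(Ssub, seq_along(support), rep(0, length(support)),
                           1.0, tol))
}

#' Rank-based elementarity test
#'
#' A pathway is an Elementary Flux Mode (EFM) iff no other pathway's support
#' is strictly contained in its own — equivalently, iff the steady-state
#' solution space restricted to its support columns is a single ray. That
#' holds exactly when `rank(S[, support]) == |support| - 1`, which this
#' test checks; it depends on the support only, so it is invariant to flux
#' rescaling.
#'
#' @param split_net a `split_network`.
#' @param support integer vector of split-column indices or character vector
#'   of split-reaction ids. A pathway with exactly this support must exist;
#'   if none does, the question is not defined and an error is raised.
#' @return `TRUE` or `FALSE`.
#' @export
is_elementary <- function(split_net, support) {
  split_net <- as_split_network(split_net)
  if (is.character(support)) {
    support <- match(support, split_net$reaction_ids)
    if (anyNA(support)) stop("unknown split reaction id in support", call. = FALSE)
  }
  support <- sort(unique(as.integer(support)))
  if (length(support) == 0L)
    stop("support must be non-empty", call. = FALSE)
  if (min(support) < 1L || max(support) > length(split_net$reaction_ids))
    stop("support index out of range", call. = FALSE)
  if (!support_feasible(split_net, support))
    stop("no pathway exists with exactly this support; ",
         "elementarity is undefined for it", call. = FALSE)
  mat_rank(split_net$S[, support, drop = FALSE]) == length(support) - 1L
}

#' Brute-force EFM enumeration for small networks
#'
#' The independent ground-truth oracle: every subset of split reactions is
#' tested, in increasing size, for admitting a pathway with exactly that
#' support (feasibility LP with `v >= 1` on the subset and `v = 0` off it);
#' accepted subsets that strictly contain an already-accepted one are
#' pruned, so the result is exactly the set of support-minimal pathways —
#' the EFMs. Exponential in the reaction count, hence the hard cap.
#'
#' @param split_net a `split_network` (a `metabolic_network` is split
#'   first).
#' @param max_reactions refuse networks with more split reactions than this
#'   (default 15; the enumeration is `O(2^n)`).
#' @return A list of canonical supports (sorted character vectors), ordered
#'   by size then lexicographically.
#' @export
brute_force_efms <- function(split_net, max_reactions = 15L) {
  split_net <- as_split_network(split_net)
  n <- length(split_net$reaction_ids)
  if (n > max_reactions)
    stop("network has ", n, " split reactions; brute_force_efms is capped at ",
         max_reactions, call. = FALSE)
  accepted <- list()
  for (size in 1:n) {
    for (subset in utils::combn(n, size, simplify = FALSE)) {
      contains_efm <- any(vapply(accepted,
                                 function(e) all(e %in% subset), logical(1)))
      if (contains_efm) next
      if (support_feasible(split_net, subset)) accepted <- c(accepted, list(subset))
    }
  }
  lapply(accepted, canonical_support, split_net = split_net)
}

#' Deduplicate extraction solutions by support
#'
#' @param solutions list of `flux_solution` objects (or an
#'   `extraction_result`).
#' @param split_net the `split_network` the solutions refer to (taken from
#'   the result when one is passed).
#' @param drop_two_cycles when `TRUE`, solutions whose support is exactly the
#'   `{fwd, bwd}` split pair of one reversible reaction are removed before
#'   counting — such two-cycles solve the split system but are biologically
#'   vacuous.
#' @return A list with `supports` (distinct canonical supports),
#'   `n_distinct`, and `n_repetitions` (= solutions counted − distinct).
#' @export
deduplicate <- function(solutions, split_net = NULL, drop_two_cycles = FALSE) {
  if (inherits(solutions, "extraction_result")) {
    split_net <- solutions$split_net
    solutions <- solutions$solutions
  }
  stopifnot(!is.null(split_net))
  supports <- lapply(solutions, function(s) canonical_support(s$support, split_net))
  if (drop_two_cycles) {
    is_two_cycle <- vapply(solutions, function(s) {
      length(s$support) == 2L &&
        seed_has_two_cycle(split_net, s$support)
    }, logical(1))
    supports <- supports[!is_two_cycle]
  }
  keys <- vapply(supports, paste, character(1), collapse = "\r")
  distinct <- supports[!duplicated(keys)]
  list(supports = distinct, n_distinct = length(distinct),
       n_repetitions = length(supports) - length(distinct))
}

#' Validate a set of solutions against the network
#'
#' Per solution: is the flux vector a pathway, and is its support
#' elementary? On networks small enough for [brute_force_efms()] the oracle
#' column reports membership of the support in the exact EFM set.
#'
#' @param result an `extraction_result`, or a list of `flux_solution`s plus
#'   `split_net`.
#' @param split_net the `split_network` (when `result` is a plain list).
#' @param oracle_cap run the brute-force oracle when the network has at most
#'   this many split reactions (default 15); beyond it the `in_oracle`
#'   column is `NA`.
#' @return Data frame with one row per solution: `support`
#'   (comma-joined ids), `is_pathway`, `is_elementary`, `in_oracle`.
#' @export
validate_solutions <- function(result, split_net = NULL, oracle_cap = 15L) {
  if (inherits(result, "extraction_result")) {
    split_net <- result$split_net
    solutions <- result$solutions
  } else solutions <- result
  stopifnot(!is.null(split_net))
  n <- length(split_net$reaction_ids)
  oracle <- if (n <= oracle_cap) {
    vapply(brute_force_efms(split_net), paste, character(1), collapse = ",")
  } else NULL
  rows <- lapply(solutions, function(s) {
    supp <- canonical_support(s$support, split_net)
    key <- paste(supp, collapse = ",")
    data.frame(support = key,
               is_pathway = is_pathway(split_net, s$v),
               is_elementary = is_elementary(split_net, s$support),
               in_oracle = if (is.null(oracle)) NA else key %in% oracle,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
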