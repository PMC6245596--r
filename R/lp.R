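#' Numerical settings for the extraction LP
#'
#' @param seed_lower_bound positive flux floor `c` imposed on every seed
#'   reaction. An LP cannot express strict positivity, and because the
#'   constraint set is a cone any `c > 0` gives the same supports up to
#'   scaling; 1 is a solver-friendly choice.
#' @param support_threshold relative tolerance for calling a flux nonzero: a
#'   split reaction is in the support when `v > support_threshold * max(v)`.
#'   Relative thresholding keeps the support invariant under rescaling.
#' @param solver_feas_tol feasibility/pivot tolerance handed to the simplex
#'   solver.
#' @return An object of class `lp_settings`.
#' @export
lp_settings <- function(seed_lower_bound = 1.0, support_threshold = 1e-6,
                        solver_feas_tol = 1e-9) {
  if (seed_lower_bound <= 0 || support_threshold <= 0 || solver_feas_tol <= 0)
    stop("all lp_settings values must be strictly positive", call. = FALSE)
  if (support_threshold >= 1)
    stop("support_threshold must be < 1", call. = FALSE)
  structure(list(seed_lower_bound = seed_lower_bound,
                 support_threshold = support_threshold,
                 solver_feas_tol = solver_feas_tol),
            class = "lp_settings")
}

# Solve min c'v  s.t.  S v = 0, v >= 0, v[seed] >= c0, via the variable
# shift u = v - c0*1_seed, which turns the seed bounds into plain
# nonnegativity and leaves an equality-only standard-form LP. Rows are
# equilibrated to unit max-norm (genome-scale matrices mix coefficients over
# several orders of magnitude, e.g. biomass stoichiometries), and a pivot
# tolerance that proves too tight for the instance is loosened on a fixed
# deterministic ladder before giving up.
solve_seeded_lp <- function(S, seed_idx, w, c0, tol) {
  n <- ncol(S)
  shift <- numeric(n)
  shift[seed_idx] <- c0
  b <- -as.vector(S %*% shift)
  rmax <- pmax(apply(abs(S), 1L, max), .Machine$double.eps)
  S_eq <- S / rmax
  b_eq <- b / rmax
  for (tol_k in tol * c(1, 100, 1e4)) {
    res <- .simplex_core(S_eq, b_eq, w, tol_k)
    if (res$status == 1L) return(NULL)
    if (res$status == 0L) {
      v <- as.numeric(res$x) + shift
      return(list(v = v, objective = sum(w * v)))
    }
  }
  stop("simplex did not converge (status ", res$status,
       "); this is retriable with looser solver_feas_tol", call. = FALSE)
}

#' Solve one seeded, weighted extraction LP
#'
#' Solves `min sum(w_i v_i)` subject to `S v = 0`, `v >= 0` and
#' `v_j >= seed_lower_bound` for every seed reaction `j`, on the split
#' (all-irreversible) network. With nonnegative costs and variables the
#' program is always bounded below, so the only outcomes are an optimal
#' vertex or infeasibility. Infeasibility is an expected, informative result
#' (a seed can force production of a metabolite nothing consumes), so it is
#' reported as `NULL`, not as an error.
#'
#' @param split_net a `split_network` (a `metabolic_network` is split on the
#'   fly).
#' @param seed integer vector of split-reaction indices forced to carry
#'   positive flux.
#' @param w numeric weight vector (one weight `>= 1` per split reaction);
#'   defaults to all ones, the unpenalized program.
#' @param settings an [lp_settings()].
#' @return `NULL` when the seed is infeasible; otherwise a `flux_solution`
#'   with fields `v` (flux vector), `support` (integer indices where
#'   `v > support_threshold * max(v)`), `seed`, `objective`, and `elementary`
#'   (`NA` until filled by [is_elementary()] / [cmd_validate()]).
#' @export
solve_iteration <- function(split_net, seed, w = NULL, settings = lp_settings()) {
  split_net <- as_split_network(split_net)
  n <- length(split_net$reaction_ids)
  seed <- sort(unique(as.integer(seed)))
  if (length(seed) < 1L || min(seed) < 1L || max(seed) > n)
    stop("seed indices must be distinct and within 1..", n, call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n)
    stop("weight vector length ", length(w), " does not match ", n,
         " split reactions", call. = FALSE)
  if (any(w < 1))
    stop("weights must be >= 1 elementwise", call. = FALSE)
  sol <- solve_seeded_lp(split_net$S, seed, w, settings$seed_lower_bound,
                         settings$solver_feas_tol)
  if (is.null(sol)) return(NULL)
  support <- which(sol$v > settings$support_threshold * max(sol$v))
  structure(list(v = sol$v, support = support, seed = seed,
                 objective = sol$objective, elementary = NA),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution: |support| = ", length(x$support),
      ", seed = {", paste(x$seed, collapse = ","), "}",
      ", objective = ", format(x$objective), "\n", sep = "")
  invisible(x)
}
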