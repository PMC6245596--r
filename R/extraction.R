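#' Draw a uniformly random positive seed
#'
#' The seed generator is deliberately the simplest fair one: `k` distinct
#' split-reaction indices drawn uniformly without replacement from R's
#' current random stream. A neutral generator keeps seed bias out of the
#' frequency comparisons, so that any difference between experiments can be
#' attributed to the objective-function penalization.
#'
#' @param n_split number of split reactions in the network.
#' @param k seed size (the experiment default used throughout is 4).
#' @return Sorted integer vector of `k` distinct indices.
#' @export
generate_seed <- function(n_split, k) {
  if (k < 1L || k > n_split)
    stop("seed size k must satisfy 1 <= k <= n_split (= ", n_split, ")",
         call. = FALSE)
  sort(sample.int(n_split, k))
}

#' Penalized objective weights
#'
#' Computes `w_i = 1 + p * F_i`: the weight of a reaction grows linearly with
#' the frequency `F_i` at which it has appeared in the solutions obtained so
#' far. Minimizing `sum(w_i v_i)` then discourages — without forbidding —
#' reactions the extraction has already seen often. `p = 0` recovers the
#' plain unweighted program.
#'
#' @param F numeric vector of frequencies in `[0, 1]`.
#' @param p penalization, a scalar `>= 0`.
#' @return Numeric weight vector, elementwise in `[1, 1 + p]`.
#' @export
compute_weights <- function(F, p) {
  if (length(p) != 1L || is.na(p) || p < 0)
    stop("penalization p must be a single number >= 0", call. = FALSE)
  if (anyNA(F) || any(F < 0) || any(F > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  1 + p * F
}

new_extraction_state <- function(n_split, p) {
  structure(list(N = 0L, O = integer(n_split),
                 F = numeric(n_split), w = rep(1, n_split), p = p),
            class = "extraction_state")
}

#' Fold one solution into the running extraction state
#'
#' Increments the iteration counter `N` and, for every split reaction in the
#' solution's support, its occurrence count `O_i`; frequencies `F_i = O_i/N`
#' and weights `w_i = 1 + p*F_i` are recomputed. Repeated identical solutions
#' still count: `F` is defined per iteration, which is what keeps it in
#' `[0, 1]`.
#'
#' @param state an `extraction_state`.
#' @param sol a feasible `flux_solution`.
#' @return The updated `extraction_state`.
#' @export
update_state <- function(state, sol) {
  stopifnot(inherits(state, "extraction_state"), inherits(sol, "flux_solution"))
  state$N <- state$N + 1L
  state$O[sol$support] <- state$O[sol$support] + 1L
  state$F <- state$O / state$N
  state$w <- compute_weights(state$F, state$p)
  state
}

#' Run a full penalized extraction experiment
#'
#' The extraction loop: draw a random positive seed, build the weighted LP,
#' solve it, record the solution and update occurrence counts, until
#' `N_target` feasible solutions have been collected. Infeasible seeds are
#' discarded and redrawn — they do not advance `N`, since the frequency
#' `F_i = O_i/N` presumes every counted iteration yielded a solution. A run
#' of `drought_cap` consecutive infeasible seeds aborts with partial results.
#'
#' @param net a `metabolic_network` (split internally) or `split_network`.
#' @param N_target number of feasible solutions to collect.
#' @param p penalization (`>= 0`); weights are `w_i = 1 + p*F_i`.
#' @param k seed size (default 4, the experiment protocol used throughout).
#' @param rng_seed integer seed for the random stream; identical inputs give
#'   bit-identical solution lists.
#' @param settings an [lp_settings()].
#' @param weight_mode `"dynamic"` (default) recomputes weights from the
#'   running frequencies before every iteration; `"static"` fixes them from
#'   the frequency vector `F0` for the whole run; `"off"` uses unit weights
#'   throughout (identical to `p = 0`).
#' @param F0 frequency vector for `weight_mode = "static"`.
#' @param drought_cap abort after this many consecutive infeasible seeds.
#' @param no_two_cycle_seeds when `TRUE`, redraw any seed containing both
#'   split directions of one reversible reaction.
#' @return An object of class `extraction_result`: a list with `solutions`
#'   (list of `flux_solution`), `state` (final `extraction_state`),
#'   `split_net`, `status` (`"complete"` or `"drought"`), `n_infeasible`,
#'   and the configuration used.
#' @export
run_extraction <- function(net, N_target, p = 0, k = 4, rng_seed = 1L,
                           settings = lp_settings(),
                           weight_mode = c("dynamic", "static", "off"),
                           F0 = NULL, drought_cap = 1000L,
                           no_two_cycle_seeds = FALSE) {
  weight_mode <- match.arg(weight_mode)
  split_net <- as_split_network(net)
  n <- length(split_net$reaction_ids)
  if (N_target < 1L) stop("N_target must be >= 1", call. = FALSE)
  if (weight_mode == "static") {
    if (is.null(F0) || length(F0) != n)
      stop("weight_mode = 'static' needs a frequency vector F0 of length ", n,
           call. = FALSE)
    w_static <- compute_weights(F0, p)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(rng_seed)

  state <- new_extraction_state(n, p)
  solutions <- vector("list", N_target)
  n_infeasible <- 0L
  consecutive <- 0L
  status <- "complete"

  while (state$N < N_target) {
    seed <- generate_seed(n, k)
    if (no_two_cycle_seeds && seed_has_two_cycle(split_net, seed)) next
    w <- switch(weight_mode,
                dynamic = state$w,
                static = w_static,
                off = rep(1, n))
    sol <- solve_iteration(split_net, seed, w, settings)
    if (is.null(sol)) {
      n_infeasible <- n_infeasible + 1L
      consecutive <- consecutive + 1L
      if (consecutive >= drought_cap) {
        status <- "drought"
        break
      }
      next
    }
    consecutive <- 0L
    state <- update_state(state, sol)
    solutions[[state$N]] <- sol
  }

  structure(list(solutions = solutions[seq_len(state$N)], state = state,
                 split_net = split_net, status = status,
                 n_infeasible = n_infeasible,
                 config = list(N_target = N_target, p = p, k = k,
                               rng_seed = rng_seed, weight_mode = weight_mode,
                               drought_cap = drought_cap,
                               no_two_cycle_seeds = no_two_cycle_seeds,
                               settings = settings)),
            class = "extraction_result")
}

# TRUE when the seed contains both split directions of one source reaction
seed_has_two_cycle <- function(split_net, seed) {
  src <- split_net$origin$source_index[seed]
  anyDuplicated(src) > 0L
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("extraction_result: ", x$state$N, " solutions (target ",
      x$config$N_target, ", p = ", x$state$p, ", k = ", x$config$k, "), ",
      x$n_infeasible, " infeasible seeds, status '", x$status, "'\n", sep = "")
  invisible(x)
}

#' Reaction-frequency table of an extraction experiment
#'
#' @param result an `extraction_result`.
#' @return A data frame with one row per split reaction: `reaction_id`,
#'   `occurrences`, `frequency`, `final_weight`, carrying the iteration count
#'   `N` and penalization `p` as attributes.
#' @export
frequency_table <- function(result) {
  stopifnot(inherits(result, "extraction_result"))
  tab <- data.frame(reaction_id = result$split_net$reaction_ids,
                    occurrences = result$state$O,
                    frequency = result$state$F,
                    final_weight = result$state$w,
                    stringsAsFactors = FALSE)
  attr(tab, "N") <- result$state$N
  attr(tab, "p") <- result$state$p
  class(tab) <- c("frequency_table", "data.frame")
  tab
}

meta_header <- function(config_lines) {
  c(paste0("# fluxpen ", as.character(utils::packageVersion("fluxpen"))),
    paste0("# ", config_lines))
}

#' Write / read a frequency table as TSV
#'
#' The file carries `#` comment lines with the package version, `N`, `p` and
#' the full extraction configuration, followed by a header row and one row
#' per split reaction.
#'
#' @param tab a `frequency_table` (for writing).
#' @param path file path.
#' @param config optional named list echoed into the `#` metadata lines.
#' @return `path` invisibly (write); a `frequency_table` (read).
#' @export
write_frequency_tsv <- function(tab, path, config = NULL) {
  stopifnot(inherits(tab, "frequency_table"))
  meta <- c(paste0("N=", attr(tab, "N")), paste0("p=", attr(tab, "p")))
  if (!is.null(config))
    meta <- c(meta, paste0(names(config), "=", vapply(config, format, character(1))))
  lines <- c(meta_header(meta),
             "reaction_id\toccurrences\tfrequency\tfinal_weight",
             sprintf("%s\t%d\t%.10g\t%.10g", tab$reaction_id,
                     tab$occurrences, tab$frequency, tab$final_weight))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_frequency_tsv
#' @export
read_frequency_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^# ", key, "="), "", hit[1L])) else NA_real_
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  need <- c("reaction_id", "occurrences", "frequency", "final_weight")
  if (!all(need %in% names(tab)))
    stop("frequency TSV ", basename(path), " lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  attr(tab, "N") <- get_meta("N")
  attr(tab, "p") <- get_meta("p")
  class(tab) <- c("frequency_table", "data.frame")
  tab
}

#' Write / read extraction solutions as TSV
#'
#' One row per solution: iteration index, comma-joined seed ids, comma-joined
#' support ids, objective value, elementarity flag, and the support fluxes as
#' `id=value` pairs. `#` metadata lines record the configuration.
#'
#' @param result an `extraction_result` (for writing).
#' @param path file path.
#' @return `path` invisibly (write); for reading, a data frame with columns
#'   `iteration`, `seed`, `support`, `objective`, `elementary`, `fluxes`
#'   where `seed` and `support` are lists of character vectors.
#' @export
write_solutions_tsv <- function(result, path) {
  stopifnot(inherits(result, "extraction_result"))
  ids <- result$split_net$reaction_ids
  cfg <- result$config
  meta <- c(paste0("N_target=", cfg$N_target), paste0("p=", cfg$p),
            paste0("k=", cfg$k), paste0("rng_seed=", cfg$rng_seed),
            paste0("weight_mode=", cfg$weight_mode),
            paste0("status=", result$status))
  rows <- vapply(seq_along(result$solutions), function(i) {
    s <- result$solutions[[i]]
    flux <- sprintf("%s=%.10g", ids[s$support], s$v[s$support])
    paste(i, paste(ids[s$seed], collapse = ","),
          paste(ids[s$support], collapse = ","),
          sprintf("%.10g", s$objective),
          ifelse(is.na(s$elementary), "NA", ifelse(s$elementary, "1", "0")),
          paste(flux, collapse = ","), sep = "\t")
  }, character(1))
  lines <- c(meta_header(meta),
             "iteration\tseed\tsupport\tobjective\telementary\tfluxes", rows)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_solutions_tsv
#' @export
read_solutions_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           colClasses = c(elementary = "character"))
  if (nrow(tab) == 0L) {
    return(data.frame(iteration = integer(), objective = numeric(),
                      elementary = logical()))
  }
  tab$seed <- strsplit(tab$seed, ",", fixed = TRUE)
  tab$support <- strsplit(tab$support, ",", fixed = TRUE)
  tab$elementary <- ifelse(tab$elementary == "NA", NA,
                           tab$elementary == "1")
  tab
}
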