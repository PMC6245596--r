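#' Construct a metabolic network
#'
#' A `metabolic_network` is the minimal constraint-based representation of a
#' metabolism: a stoichiometric matrix `S` (rows = metabolites, columns =
#' reactions, entries = production (+) / consumption (-) coefficients), the
#' identifier lists for both axes, and a per-reaction reversibility flag.
#' Flux-bound magnitudes are deliberately not part of the representation: the
#' extraction LP constrains fluxes only by nonnegativity on the split network,
#' so the only information a bound carries here is its sign.
#'
#' @param S numeric matrix, metabolites x reactions.
#' @param metabolite_ids character vector of unique metabolite identifiers.
#' @param reaction_ids character vector of unique reaction identifiers.
#' @param reversible logical vector, one flag per reaction.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(S, metabolite_ids, reaction_ids, reversible) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  reversible <- as.logical(reversible)
  net <- structure(
    list(S = S, metabolite_ids = as.character(metabolite_ids),
         reaction_ids = as.character(reaction_ids), reversible = reversible),
    class = "metabolic_network")
  validate_network(net)
}

validate_network <- function(net) {
  if (nrow(net$S) != length(net$metabolite_ids))
    stop("row count of S (", nrow(net$S), ") does not match number of metabolite ids (",
         length(net$metabolite_ids), ")", call. = FALSE)
  if (ncol(net$S) != length(net$reaction_ids))
    stop("column count of S (", ncol(net$S), ") does not match number of reaction ids (",
         length(net$reaction_ids), ")", call. = FALSE)
  if (ncol(net$S) != length(net$reversible))
    stop("reversible flags do not match number of reactions", call. = FALSE)
  if (ncol(net$S) == 0L || nrow(net$S) == 0L)
    stop("empty model: a network needs at least one metabolite and one reaction",
         call. = FALSE)
  dup <- unique(net$metabolite_ids[duplicated(net$metabolite_ids)])
  if (length(dup))
    stop("duplicate metabolite identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(net$reaction_ids[duplicated(net$reaction_ids)])
  if (length(dup))
    stop("duplicate reaction identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  zero <- which(colSums(abs(net$S)) == 0)
  if (length(zero))
    stop("reaction(s) with all-zero stoichiometry: ",
         paste(net$reaction_ids[zero], collapse = ", "), call. = FALSE)
  if (anyNA(net$S) || anyNA(net$reversible))
    stop("stoichiometry and reversibility must not contain NA", call. = FALSE)
  dimnames(net$S) <- list(net$metabolite_ids, net$reaction_ids)
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network: ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (", sum(x$reversible),
      " reversible)\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from disk
#'
#' Supported formats are SBML (Level 2/3, including the `fbc` flux-bound
#' extension), COBRA-JSON, and the package's own TSV stoichiometric-matrix
#' dialect (see [write_network_tsv()]). For SBML and COBRA-JSON a reaction is
#' taken to be reversible when its lower flux bound is negative; bound
#' magnitudes are otherwise discarded, because the extraction LP has no
#' finite bounds.
#'
#' @param path path to a model file.
#' @param format one of `"auto"`, `"tsv"`, `"sbml"`, `"cobra-json"`.
#'   `"auto"` (default) picks by file extension (`.tsv`, `.xml`/`.sbml`,
#'   `.json`).
#' @return A [metabolic_network()].
#' @export
read_model <- function(path, format = c("auto", "tsv", "sbml", "cobra-json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(sub("\\.gz$", "", path))))
    on.exit(unlink(tmp))
    writeLines(readLines(gzfile(path, encoding = "UTF-8")), tmp, useBytes = TRUE)
    path <- tmp
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv",
                     xml = "sbml", sbml = "sbml",
                     json = "cobra-json",
                     stop("cannot auto-detect model format from extension of ",
                          basename(path), "; pass format= explicitly",
                          call. = FALSE))
  }
  switch(format,
         "tsv" = read_network_tsv(path),
         "sbml" = read_sbml(path),
         "cobra-json" = read_cobra_json(path))
}

# TSV dialect: row 1 = "metabolite" + reaction ids; row 2 = "reversible" +
# 0/1 flags; remaining rows = metabolite id + coefficients. Tab-separated,
# "." decimal, UTF-8.
read_network_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 3L)
    stop("TSV model ", basename(path),
         ": need a header row, a reversible row and at least one metabolite row",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] != "metabolite")
    stop("TSV model ", basename(path),
         ": first cell must be 'metabolite', found '", header[1L], "'",
         call. = FALSE)
  rxn_ids <- header[-1L]
  rev_row <- cells[[2L]]
  if (rev_row[1L] != "reversible" || length(rev_row) != length(header))
    stop("TSV model ", basename(path), ": second row must be 'reversible' + ",
         length(rxn_ids), " 0/1 flags", call. = FALSE)
  rev_flags <- rev_row[-1L]
  if (!all(rev_flags %in% c("0", "1")))
    stop("TSV model ", basename(path), ": reversible flags must be 0 or 1",
         call. = FALSE)
  body <- cells[-(1:2)]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("TSV model ", basename(path), ": row ", bad[1L] + 2L,
         " has ", lengths(body)[bad[1L]], " cells, expected ", length(header),
         call. = FALSE)
  met_ids <- vapply(body, `[`, character(1), 1L)
  S <- t(vapply(body, function(r) as.numeric(r[-1L]), numeric(length(rxn_ids))))
  if (length(rxn_ids) == 1L) S <- matrix(S, ncol = 1L)
  if (anyNA(S))
    stop("TSV model ", basename(path), ": non-numeric stoichiometric coefficient",
         call. = FALSE)
  metabolic_network(S, met_ids, rxn_ids, rev_flags == "1")
}

#' Write a network in the TSV stoichiometric-matrix dialect
#'
#' The dialect is: row 1 = `metabolite` followed by the reaction ids; row 2 =
#' `reversible` followed by 0/1 flags; each further row = a metabolite id
#' followed by its stoichiometric coefficients. Tab-separated, `.` decimal,
#' UTF-8. Reading the file back with [read_model()] reproduces the network
#' exactly.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  header <- paste(c("metabolite", net$reaction_ids), collapse = "\t")
  revrow <- paste(c("reversible", as.integer(net$reversible)), collapse = "\t")
  body <- vapply(seq_along(net$metabolite_ids), function(i) {
    paste(c(net$metabolite_ids[i],
            format(net$S[i, ], trim = TRUE, scientific = FALSE, digits = 15)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, revrow, body), path, useBytes = TRUE)
  invisible(path)
}

read_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse COBRA-JSON ",
                                           basename(path), ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("COBRA-JSON ", basename(path),
         ": missing 'metabolites' or 'reactions' array", call. = FALSE)
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), character(1))
  rxn_ids <- vapply(doc$reactions, function(r) as.character(r$id), character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids))
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(doc$reactions)) {
    coeffs <- doc$reactions[[j]]$metabolites
    for (mid in names(coeffs)) {
      i <- met_index[[mid]]
      if (is.null(i))
        stop("COBRA-JSON ", basename(path), ": reaction '", rxn_ids[j],
             "' references unknown metabolite '", mid, "'", call. = FALSE)
      S[i, j] <- as.numeric(coeffs[[mid]])
    }
  }
  lb <- vapply(doc$reactions, function(r) {
    if (is.null(r$lower_bound)) 0 else as.numeric(r$lower_bound)
  }, numeric(1))
  metabolic_network(S, met_ids, rxn_ids, lb < 0)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML ", basename(path),
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  ns <- "d1"  # default-namespace alias assigned by xml2
  nss <- xml2::xml_ns(doc)
  find <- function(node, what) xml2::xml_find_all(node, paste0(".//", ns, ":", what), nss)
  species <- find(doc, "listOfSpecies/d1:species")
  reactions <- find(doc, "listOfReactions/d1:reaction")
  if (length(species) == 0L || length(reactions) == 0L)
    stop("SBML ", basename(path), ": no species or no reactions found",
         call. = FALSE)
  met_ids <- xml2::xml_attr(species, "id")
  rxn_ids <- xml2::xml_attr(reactions, "id")
  met_index <- stats::setNames(seq_along(met_ids), met_ids)

  # fbc:lowerFluxBound attributes point at global parameters
  params <- find(doc, "listOfParameters/d1:parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  S <- matrix(0, length(met_ids), length(rxn_ids))
  reversible <- logical(length(rxn_ids))
  for (j in seq_along(reactions)) {
    rxn <- reactions[[j]]
    add_side <- function(list_name, sign) {
      refs <- find(rxn, paste0(list_name, "/d1:speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        i <- met_index[[sid]]
        if (is.null(i) || is.na(i))
          stop("SBML ", basename(path), ": reaction '", rxn_ids[j],
               "' references unknown species '", sid, "'", call. = FALSE)
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        S[i, j] <<- S[i, j] + sign * st
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)

    lb_ref <- xml2::xml_attr(rxn, "lowerFluxBound")
    if (!is.na(lb_ref) && !is.na(pvals[lb_ref])) {
      reversible[j] <- pvals[[lb_ref]] < 0
    } else {
      rev_attr <- xml2::xml_attr(rxn, "reversible")
      reversible[j] <- !is.na(rev_attr) && rev_attr %in% c("true", "1")
    }
  }
  metabolic_network(S, met_ids, rxn_ids, reversible)
}

#' Split reversible reactions into irreversible pairs
#'
#' Replaces every reversible reaction by two opposed irreversible columns
#' ("de-doubling"): the forward column is the original, the backward column
#' its negation. Thermodynamic feasibility then reduces to plain
#' nonnegativity of the flux vector, which is what the extraction LP needs.
#' Irreversible reactions keep their column and identifier verbatim;
#' reversible ones get `_fwd` / `_bwd` suffixes.
#'
#' @param net a [metabolic_network()].
#' @return An object of class `split_network` with fields `S` (metabolites x
#'   split reactions), `reaction_ids`, `metabolite_ids`, and `origin`, a
#'   data frame with one row per split column giving the source reaction id,
#'   its index in `net`, and the direction (`"forward"`/`"backward"`).
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  n <- length(net$reaction_ids)
  cols <- vector("list", n)
  for (j in seq_len(n)) {
    if (net$reversible[j]) {
      cols[[j]] <- data.frame(
        source_id = net$reaction_ids[j], source_index = j,
        direction = c("forward", "backward"),
        id = paste0(net$reaction_ids[j], c("_fwd", "_bwd")),
        stringsAsFactors = FALSE)
    } else {
      cols[[j]] <- data.frame(
        source_id = net$reaction_ids[j], source_index = j,
        direction = "forward", id = net$reaction_ids[j],
        stringsAsFactors = FALSE)
    }
  }
  origin <- do.call(rbind, cols)
  sign_ <- ifelse(origin$direction == "forward", 1, -1)
  S_split <- net$S[, origin$source_index, drop = FALSE] *
    rep(sign_, each = nrow(net$S))
  dimnames(S_split) <- list(net$metabolite_ids, origin$id)
  structure(
    list(S = S_split, reaction_ids = origin$id,
         metabolite_ids = net$metabolite_ids,
         origin = origin[, c("source_id", "source_index", "direction")]),
    class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat("split_network: ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " split (all-irreversible) reactions\n", sep = "")
  invisible(x)
}

# Accept either network flavour where only the split form makes sense.
as_split_network <- function(net) {
  if (inherits(net, "split_network")) return(net)
  if (inherits(net, "metabolic_network")) return(split_reversible(net))
  stop("expected a metabolic_network or split_network", call. = FALSE)
}

#' Map split-reaction support back to original reactions
#'
#' Translates a set of split-reaction indices into `(original reaction,
#' direction)` pairs. Both directions of a reversible reaction can appear
#' together, which is how a two-cycle stays visible after projection.
#'
#' @param split_net a `split_network`.
#' @param support integer vector of split-column indices (or character vector
#'   of split-reaction ids).
#' @return A data frame with columns `reaction_id` and `direction`, one row
#'   per element of `support`.
#' @export
project_support <- function(split_net, support) {
  stopifnot(inherits(split_net, "split_network"))
  if (is.character(support)) {
    idx <- match(support, split_net$reaction_ids)
    if (anyNA(idx))
      stop("unknown split reaction id(s): ",
           paste(support[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(support)
    if (length(idx) && (min(idx) < 1L || max(idx) > length(split_net$reaction_ids)))
      stop("split-reaction index out of range 1..",
           length(split_net$reaction_ids), call. = FALSE)
  }
  data.frame(reaction_id = split_net$origin$source_id[idx],
             direction = split_net$origin$direction[idx],
             stringsAsFactors = FALSE)
}

#' Locate a local copy of the core E. coli metabolic model
#'
#' The core E. coli model (BiGG `e_coli_core`, the 95-reaction educational
#' subset of iAF1260, 154 reactions after de-doubling) is the standard small
#' genome-scale benchmark for extraction experiments. This helper looks for a
#' local copy without ever touching the network: first the
#' `FLUXPEN_CORE_MODEL` environment variable, then any explicitly supplied
#' paths, then the model catalogue of an installed cobrapy Python
#' distribution, which ships the identical model as `textbook.xml.gz`.
#'
#' @param extra_paths additional candidate file paths to try first.
#' @return A file path readable by [read_model()], or `NULL` when no copy is
#'   found.
#' @export
locate_core_model <- function(extra_paths = character()) {
  env <- Sys.getenv("FLUXPEN_CORE_MODEL", "")
  for (p in c(if (nzchar(env)) env, extra_paths))
    if (file.exists(p)) return(p)
  python <- Sys.which("python")
  if (nzchar(python)) {
    p <- suppressWarnings(tryCatch(
      system2(python,
              c("-c", shQuote(paste0(
                "import cobra, os; print(os.path.join(",
                "os.path.dirname(cobra.__file__), 'data', 'textbook.xml.gz'))"))),
              stdout = TRUE, stderr = FALSE),
      error = function(e) character()))
    if (length(p) == 1L && file.exists(p)) return(p)
  }
  NULL
}
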