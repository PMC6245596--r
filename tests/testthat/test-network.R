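test_that("network construction enforces its invariants", {
  S <- rbind(c(1, -1, 0), c(0, 1, -1))
  net <- metabolic_network(S, c("A", "B"), c("R1", "R2", "R3"), rep(FALSE, 3))
  expect_s3_class(net, "metabolic_network")

  expect_error(metabolic_network(S, c("A", "A"), c("R1", "R2", "R3"),
                                 rep(FALSE, 3)), "duplicate metabolite")
  expect_error(metabolic_network(S, c("A", "B"), c("R1", "R1", "R3"),
                                 rep(FALSE, 3)), "duplicate reaction")
  expect_error(metabolic_network(cbind(S, 0), c("A", "B"),
                                 c("R1", "R2", "R3", "R4"), rep(FALSE, 4)),
               "all-zero")
  expect_error(metabolic_network(S, c("A", "B", "C"), c("R1", "R2", "R3"),
                                 rep(FALSE, 3)), "row count")
  expect_error(metabolic_network(matrix(0, 0, 0), character(), character(),
                                 logical()), "empty model")
})

test_that("TSV dialect round-trips exactly", {
  net <- make_chain(2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_model(path)
  expect_identical(back$S, net$S)
  expect_identical(back$metabolite_ids, net$metabolite_ids)
  expect_identical(back$reaction_ids, net$reaction_ids)
  expect_identical(back$reversible, net$reversible)

  # fractional coefficients and reversibility flags survive too
  net2 <- metabolic_network(rbind(c(0.5, -1.25), c(2, -0.1)),
                            c("m1", "m2"), c("a", "b"), c(TRUE, FALSE))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net2, path2)
  back2 <- read_model(path2)
  expect_identical(back2$S, net2$S)
  expect_identical(back2$reversible, c(TRUE, FALSE))
})

test_that("TSV reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tR1\tR1", "reversible\t0\t0", "A\t1\t-1"), path)
  expect_error(read_model(path), "duplicate reaction")
  writeLines(c("metabolite\tR1", "reversible\t2", "A\t1"), path)
  expect_error(read_model(path), "0 or 1")
  writeLines(c("wrong\tR1", "reversible\t0", "A\t1"), path)
  expect_error(read_model(path), "metabolite")
})

test_that("COBRA-JSON reader builds S and derives reversibility from bounds", {
  doc <- list(
    metabolites = list(list(id = "A"), list(id = "B")),
    reactions = list(
      list(id = "R1", metabolites = list(A = 1), lower_bound = 0,
           upper_bound = 1000),
      list(id = "R2", metabolites = list(A = -1, B = 1), lower_bound = -1000,
           upper_bound = 1000),
      list(id = "R3", metabolites = list(B = -1), lower_bound = 0,
           upper_bound = 1000)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  net <- read_model(path)
  expect_identical(net$reaction_ids, c("R1", "R2", "R3"))
  expect_identical(net$reversible, c(FALSE, TRUE, FALSE))
  expect_identical(unname(net$S),
                   rbind(c(1, -1, 0), c(0, 1, -1)))
})

test_that("SBML reader handles plain L2-style and fbc-style reversibility", {
  sbml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1"><model id="toy">',
    '<listOfParameters>',
    '<parameter id="lb_neg" value="-1000"/>',
    '<parameter id="lb_zero" value="0"/>',
    '</listOfParameters>',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false" fbc:lowerFluxBound="lb_zero">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/>',
    '</listOfProducts></reaction>',
    '<reaction id="R2" reversible="false" fbc:lowerFluxBound="lb_neg">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/>',
    '</listOfProducts></reaction>',
    '<reaction id="R3" reversible="true">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/>',
    '</listOfReactants></reaction>',
    '</listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- read_model(path)
  expect_identical(net$reaction_ids, c("R1", "R2", "R3"))
  # R2: fbc lower bound -1000 wins over reversible="false";
  # R3: no fbc bound, falls back to the reversible attribute
  expect_identical(net$reversible, c(FALSE, TRUE, TRUE))
  expect_identical(unname(net$S), rbind(c(1, -1, 0), c(0, 2, -1)))
})

test_that("splitting negates reversible columns and obeys the count law", {
  net <- make_chain(2, reversible_middle = TRUE)
  sn <- split_reversible(net)
  expect_identical(sn$reaction_ids, c("R1", "R2_fwd", "R2_bwd", "R3"))
  expect_identical(sn$S[, "R2_bwd"], -sn$S[, "R2_fwd"])
  expect_identical(sn$S[, "R1"], net$S[, "R1"])

  # |split columns| = n + n_rev on random networks
  for (seed in 1:10) {
    net <- test_random_network(seed)
    sn <- split_reversible(net)
    expect_identical(length(sn$reaction_ids),
                     length(net$reaction_ids) + sum(net$reversible))
  }
})

test_that("split-level steady state projects to net steady state", {
  # summing forward - backward flux per source reaction must conserve S v = 0
  for (seed in 1:5) {
    net <- test_random_network(seed)
    sn <- split_reversible(net)
    res <- run_extraction(sn, 5, p = 0, k = 2, rng_seed = seed)
    for (sol in res$solutions) {
      sgn <- ifelse(sn$origin$direction == "forward", 1, -1)
      v_net <- as.vector(tapply(sol$v * sgn, sn$origin$source_index, sum))
      expect_lt(max(abs(net$S %*% v_net)), 1e-8 * (1 + max(abs(v_net))))
    }
  }
})

test_that("support projection maps split indices to origin pairs", {
  sn <- split_reversible(make_chain(2, reversible_middle = TRUE))
  out <- project_support(sn, c("R2_bwd"))
  expect_identical(out$reaction_id, "R2")
  expect_identical(out$direction, "backward")

  both <- project_support(sn, c("R1", "R2_fwd", "R2_bwd"))
  expect_identical(nrow(both), 3L)  # a two-cycle stays visible
  expect_identical(both$reaction_id, c("R1", "R2", "R2"))

  expect_identical(nrow(project_support(sn, integer())), 0L)
  expect_error(project_support(sn, 99), "out of range")
})
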