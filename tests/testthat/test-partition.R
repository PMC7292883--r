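# Elemental partitioning, condition correlation, production analysis.

test_that("element throughput equals a hand atom count", {
  toy <- make_toy_diazotroph()
  # glucose -> 2 pyruvate (lumped glycolysis) at v = 2: product-side carbon
  # includes 2x3 from pyruvate plus the ATP/NADH cofactor carbon
  r <- toy$model$reactions$GLYCLUMP
  prods <- r$stoich[r$stoich > 0]
  E <- element_matrix(toy$model)
  hand <- 2 * sum(prods * E["C", names(prods)])
  expect_equal(element_throughput(toy$model, "GLYCLUMP", 2, "C"), hand)
  # zero flux, zero throughput
  expect_equal(element_throughput(toy$model, "GLYCLUMP", 0, "C"), 0)
  # nitrogenase at v = 1: product side carries 2 N in ammonium plus
  # 16 x 5 N in ADP (hand count on the toy stoichiometry)
  expect_equal(element_throughput(toy$model, "NIT", 1, "N"), 2 + 16 * 5)
  # balanced reactions: product side equals substrate side (conservation)
  for (rid in c("GLYCLUMP", "EDLUMP", "TCALUMP", "NIT", "OXPHOS")) {
    r <- toy$model$reactions[[rid]]
    subs <- -r$stoich[r$stoich < 0]
    expect_equal(element_throughput(toy$model, rid, 1.7, "C"),
                 1.7 * sum(subs * E["C", names(subs)]), label = rid)
  }
})

test_that("subsystem partitioning averages member throughputs", {
  toy <- make_toy_diazotroph()
  pf <- pfba(toy$model, medium = toy$manifest$media$glucose_ammonium)
  pc <- partition_fluxes(toy$model, pf, "C")
  # hand recomputation for one subsystem, zero-flux members included
  members <- names(toy$model$reactions)[vapply(toy$model$reactions,
    function(r) r$subsystem == "TCA cycle", logical(1))]
  hand <- mean(vapply(members, function(rid)
    element_throughput(toy$model, rid, pf$fluxes[[rid]], "C"), numeric(1)))
  expect_equal(unname(pc["TCA cycle"]), hand, tolerance = 1e-9)
  # an entirely blocked subsystem averages zero
  med <- toy$manifest$media$glucose_ammonium
  med$EX_alg_e <- c(0, 0)
  pf2 <- pfba(toy$model, medium = med)
  pc2 <- partition_fluxes(toy$model, pf2, "C")
  expect_equal(unname(pc2["Glycan biosynthesis"]), 0)
  # transport and exchange are flagged out of the headline summary
  expect_setequal(attr(pc, "excluded"), c("Transport", "Exchange"))
})

test_that("condition correlations behave like Pearson r", {
  tab <- matrix(c(1, 2, 3, 4,
                  2, 1, 5, 3,
                  0, 0, 0, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), paste0("c", 1:4)))
  # identical tables: r = 1 everywhere it is defined
  cc <- compare_conditions(tab, tab)
  expect_equal(cc$table$r[1:2], c(1, 1))
  expect_true(is.na(cc$table$r[3]))      # constant vector -> undefined
  expect_equal(cc$global_percent_change, 0)
  # scaling one table by 0.95: r still 1, global change -5%
  cs <- compare_conditions(tab * 0.95, tab)
  expect_equal(cs$table$r[1:2], c(1, 1))
  expect_equal(cs$global_percent_change, -5, tolerance = 1e-9)
  # invariance under common positive rescaling of both tables
  c2 <- compare_conditions(tab * 3.7, tab * 3.7)
  expect_equal(c2$table$r, cc$table$r)
  expect_error(compare_conditions(tab, tab[1:2, ]), "share")
})

test_that("toy screen correlations separate nitrogen-coupled subsystems", {
  toy <- make_toy_diazotroph()
  srcs <- c("glc__D_e", "fru_e", "mnl_e", "sucr_e", "glyc_e", "pyr_e")
  conds <- function(mode) lapply(srcs, function(s)
    screen_condition(s, "carbon", mode, id = s))
  td <- partition_table(toy$model, conds("diazotrophic"), "C")
  tn <- partition_table(toy$model, conds("non-diazotrophic"), "C")
  cc <- compare_conditions(td, tn)
  r <- stats::setNames(cc$table$r, cc$table$subsystem)
  # carbohydrate catabolism correlates strongly across regimes;
  # nitrogen fixation machinery does not (it is silent on ammonium)
  expect_gt(r[["Carbohydrate metabolism"]], 0.9)
  nitro <- r[["Nitrogen metabolism"]]
  expect_true(is.na(nitro) || nitro < r[["Carbohydrate metabolism"]])
  # growth-coupled subsystems lose carbon throughput under diazotrophy in
  # every condition (the ATP bill of nitrogenase diverts resources);
  # note the *global* sum can rise because the cofactor-inclusive
  # throughput convention counts the extra ATP cycling itself
  expect_true(all(td["Biomass and maintenance functions", ] <=
                  tn["Biomass and maintenance functions", ] + 1e-9))
  expect_true(all(td["Amino acid metabolism", ] <=
                  tn["Amino acid metabolism", ] + 1e-9))
})

test_that("sinks are added idempotently and leave unused flux untouched", {
  toy <- make_toy_diazotroph()
  m <- add_sink(toy$model, "phb_c")
  expect_true("SK_phb_c" %in% names(m$reactions))
  expect_equal(m$reactions$SK_phb_c$lb, 0)
  expect_equal(m$reactions$SK_phb_c$ub, 1000)
  m2 <- add_sink(m, "phb_c")
  expect_equal(length(m2$reactions), length(m$reactions))
  expect_equal(fba(m)$objective_value, fba(toy$model)$objective_value,
               tolerance = 1e-9)
  expect_error(add_sink(m, "nothere_c"), "unknown metabolite")
})

test_that("production analysis trades growth against product", {
  toy <- make_toy_diazotroph()
  med <- toy$manifest$media$glucose_ammonium
  m <- add_sink(toy$model, "phb_c")
  # growth_fraction 0: the maximum theoretical yield, more than at optimum
  p0 <- production_rate(m, "SK_phb_c", medium = med, growth_fraction = 0)
  p1 <- production_rate(m, "SK_phb_c", medium = med, growth_fraction = 1)
  expect_gte(p0[["production"]], p1[["production"]])
  expect_gt(p0[["production"]], 0)
  # reproducible across runs (deterministic solver)
  p0b <- production_rate(m, "SK_phb_c", medium = med, growth_fraction = 0)
  expect_identical(p0, p0b)
  # ammonium supports at least the diazotrophic production at equal carbon
  alg <- build_alginate_bof(toy$model, 0.25)
  pn <- production_rate(alg, "EX_alg_e",
                        medium = toy$manifest$media$glucose_ammonium,
                        growth_fraction = 0.5)
  pd <- production_rate(alg, "EX_alg_e",
                        medium = toy$manifest$media$glucose_n2,
                        growth_fraction = 0.5)
  expect_gte(pn[["production"]], pd[["production"]] - 1e-9)
  expect_gte(pn[["mu"]], pd[["mu"]] - 1e-9)
})

test_that("flux-map normalisation and comparison follow the conventions", {
  v <- c(EX_glc = -5, PGI = 2.5, PYK = 4, IDLE = 0)
  nm <- normalize_flux_map(v, "EX_glc")
  expect_equal(unname(abs(nm["EX_glc"])), 100)
  expect_equal(unname(nm["PGI"]), 50)
  # ratios preserved exactly, idempotent under re-normalisation
  expect_equal(nm["PYK"] / nm["PGI"], v["PYK"] / v["PGI"])
  expect_equal(normalize_flux_map(nm, "EX_glc"), nm)
  expect_error(normalize_flux_map(c(EX_glc = 0), "EX_glc"), "zero flux")
  # percent-error comparison with the 20% agreement threshold
  cmp <- compare_flux_maps(c(A = 90, B = 130, C = 0, D = 1),
                           c(A = 100, B = 100, C = 0, D = 0))
  tab <- cmp$table
  expect_equal(tab$percent_error[tab$reaction_id == "A"], 10)
  expect_true(tab$agree[tab$reaction_id == "A"])
  expect_equal(tab$percent_error[tab$reaction_id == "B"], 30)
  expect_false(tab$agree[tab$reaction_id == "B"])
  expect_equal(tab$percent_error[tab$reaction_id == "C"], 0)
  expect_true(is.infinite(tab$percent_error[tab$reaction_id == "D"]))
  # identical maps agree everywhere
  cmp2 <- compare_flux_maps(c(A = 1, B = 2), c(A = 1, B = 2))
  expect_equal(cmp2$n_agree, 2)
})
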