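test_that("register enumeration matches exhaustive placement counts", {
  prof <- subsite_profile("custom")

  g3 <- enumerate_registers(3, prof)
  expect_equal(nrow(g3), 7)  # fully inside the 9-subsite array
  expect_equal(sum(g3$productive), 2)
  prod_starts <- sort(g3$start_subsite[g3$productive])
  expect_equal(prod_starts, c(-2L, -1L))  # spans -2..+1 and -1..+2

  g1 <- enumerate_registers(1, prof)
  expect_equal(nrow(g1), 9)
  expect_equal(sum(g1$productive), 0)  # one unit cannot straddle -1/+1

  g5 <- enumerate_registers(5, prof)
  inside <- purrr::map_lgl(g5$occupied, ~ all(.x >= -6 & .x <= 3))
  expect_equal(sum(inside), 5)
  expect_equal(sum(g5$productive), 4)  # -4..+1, -3..+2, -2..+3, -1..+3+overhang
  overhang <- g5[!inside, ]
  expect_equal(nrow(overhang), 1)
  expect_true(all(overhang$productive))
  expect_true(4 %in% overhang$occupied[[1]])
})

test_that("register weights are affinity products with neutral overhang", {
  uniform <- subsite_profile("custom")
  g4 <- enumerate_registers(4, uniform)
  expect_true(all(g4$weight == 1))

  hand <- subsite_profile("custom", affinities = c("-1" = 2, "1" = 3, "2" = 5))
  expect_equal(register_weight(c(-1L, 1L), hand), 6)
  expect_equal(register_weight(c(-1L, 1L, 2L), hand), 30)
  expect_equal(register_weight(c(1L, 2L, 3L, 4L), hand), 15)  # +4 is overhang

  gh77 <- subsite_profile("GH77_contrast")
  regs <- enumerate_registers(5, gh77)
  occupies_p2 <- purrr::map_lgl(regs$occupied, ~ 2L %in% .x)
  expect_true(all(regs$weight[occupies_p2] == 0))
  expect_true(all(regs$weight[!occupies_p2] > 0))
})

test_that("cleavage partitions the chain at the -1/+1 bond", {
  prof <- subsite_profile("GH57_PSGT")
  st <- reaction_state(c(G5 = 10))

  regs <- enumerate_registers(5, prof)
  at_m2 <- regs[purrr::map_lgl(regs$occupied, ~ identical(range(.x), c(-2L, 3L))), ]
  st1 <- cleave_and_partition(st, "G5", at_m2)
  expect_equal(st1$amounts[["G5"]], 9)
  expect_equal(st1$amounts[["G3"]], 1)           # released acceptor-side G3
  expect_equal(st1$intermediates[["G2"]], 1)     # enzyme-held donor G2

  at_m1 <- regs[regs$start_subsite == -1 & regs$productive, ]
  st2 <- cleave_and_partition(st, "G5", at_m1)
  expect_equal(st2$amounts[["G4"]], 1)           # overhang register releases G4
  expect_equal(st2$intermediates[["G1"]], 1)

  nonprod <- regs[!regs$productive, ][1, ]
  expect_warning(st3 <- cleave_and_partition(st, "G5", nonprod))
  expect_equal(st3$amounts, st$amounts)

  # conservation across a cleavage + transfer + hydrolysis chain
  expect_equal(glucan_units(st1), glucan_units(st))
  st4 <- transfer_intermediate(st1, 2, "G3", prof)
  expect_equal(st4$amounts[["G5"]], 10)          # 2 + 3 -> G5 back
  expect_equal(glucan_units(st4), glucan_units(st))
  st5 <- hydrolyze_intermediate(st2, 1)
  expect_equal(st5$amounts[["G1"]], 1)
  expect_equal(glucan_units(st5), glucan_units(st))
})

test_that("pNP-labelled chains release the labelled acceptor fragment", {
  prof <- subsite_profile("GH57_PSGT")
  regs <- enumerate_registers(6, prof, label = "pNP")
  # glucoses on -4..+2 with the pNP group on +3: released pNPG2, held G4
  reg <- regs[regs$start_subsite == -4 & regs$productive, ]
  expect_equal(nrow(reg), 1)
  st <- reaction_state(c(pNPG6 = 5))
  st1 <- cleave_and_partition(st, "pNPG6", reg)
  expect_equal(st1$amounts[["pNPG2"]], 1)
  expect_equal(st1$intermediates[["G4"]], 1)
  # the held G4 transferred onto pNPG6 gives pNPG10
  st2 <- transfer_intermediate(st1, 4, "pNPG6", prof)
  expect_equal(st2$amounts[["pNPG10"]], 1)
  expect_equal(glucan_units(st2), glucan_units(st))

  # transfer of a held G1 to acceptor G3 gives G4
  st3 <- reaction_state(c(G3 = 1), intermediates = c(G1 = 1))
  st4 <- transfer_intermediate(st3, 1, "G3", prof)
  expect_equal(st4$amounts[["G4"]], 1)
})

test_that("deterministic trajectories conserve glucose units", {
  prof <- subsite_profile("GH57_PSGT")
  for (init in list(c(G5 = 10), c(G4 = 10), c(G5 = 5, G3 = 5))) {
    sim <- simulate_disproportionation(init, prof, duration = 2)
    tot <- glucan_unit_totals(sim)
    expected <- sum(as.integer(sub("G", "", names(init))) * init)
    expect_lt(max(abs(tot$total_units - expected)), 1e-9)
  }
})

test_that("transfer-dominant preset reproduces the family's product ordering", {
  prof <- subsite_profile("GH57_PSGT")
  sim <- simulate_disproportionation(c(G5 = 10), prof, duration = 2)
  early <- product_profile(sim, 2)
  amt <- function(p, sp) ifelse(sp %in% p$species, p$amount[match(sp, p$species)], 0)
  # G4 and G3 (with their transfer partners) dominate; G1 and G2 stay near zero
  expect_gt(amt(early, "G4"), amt(early, "G2"))
  expect_gt(amt(early, "G4"), amt(early, "G1"))
  expect_gt(amt(early, "G3"), amt(early, "G2"))
  expect_gt(amt(early, "G3"), amt(early, "G1"))
  expect_lt(amt(early, "G1") + amt(early, "G2"),
            0.1 * (amt(early, "G3") + amt(early, "G4")))

  # maltotetraose substrate: maltotriose is the top product, glucose minor
  sim4 <- simulate_disproportionation(c(G4 = 10), prof, duration = 2)
  early4 <- product_profile(sim4, 2)
  expect_equal(early4$species[1], "G3")
  expect_lt(amt(early4, "G1"), amt(early4, "G3"))
})

test_that("short chains are poor substrates for the transfer-dominant preset", {
  prof <- subsite_profile("GH57_PSGT")
  turnover <- function(init_sp) {
    sim <- simulate_disproportionation(stats::setNames(10, init_sp), prof, 2)
    traj <- sim$trajectory
    final <- traj$amount[traj$species == init_sp & traj$time == max(traj$time)]
    (10 - final) / 10
  }
  t5 <- turnover("G5"); t3 <- turnover("G3"); t2 <- turnover("G2")
  expect_lt(t3, 0.5 * t5)
  expect_lt(t2, 0.2 * t5)
})

test_that("the +2 steric-hindrance preset releases glucose as a dominant product", {
  gh77 <- subsite_profile("GH77_contrast")
  sim <- simulate_disproportionation(c(G5 = 10), gh77, duration = 2)
  early <- product_profile(sim, 2)
  expect_true("G1" %in% early$species[1:2])
})

test_that("product profiles are ranked and normalised", {
  prof <- subsite_profile("GH57_PSGT")
  sim <- simulate_disproportionation(c(G5 = 10), prof, duration = 2)
  p <- product_profile(sim, 1)
  expect_true(all(diff(p$amount) <= 0))
  expect_equal(sum(p$fraction), 1, tolerance = 1e-9)
  expect_false("G5" %in% p$species)
  expect_false(any(startsWith(p$species, "E:")))
  # t = 0: no products beyond the substrate; without exclusion the profile is
  # exactly the initial amounts
  expect_equal(nrow(product_profile(sim, 0)), 0)
  p0 <- product_profile(sim, 0, exclude = character(0))
  expect_equal(p0$species, "G5")
  expect_equal(p0$amount, 10)
  expect_error(product_profile(sim, 99), class = "gt_validation_error")
})

test_that("stochastic runs are seed-reproducible and conserve counts exactly", {
  prof <- subsite_profile("GH57_PSGT")
  a <- simulate_disproportionation(c(G5 = 2000), prof, 2, mode = "stochastic",
                                   seed = 99, omega = 200)
  b <- simulate_disproportionation(c(G5 = 2000), prof, 2, mode = "stochastic",
                                   seed = 99, omega = 200)
  expect_identical(a$trajectory, b$trajectory)
  tot <- glucan_unit_totals(a)
  expect_true(all(tot$total_units == 10000))
  c_run <- simulate_disproportionation(c(G5 = 2000), prof, 2, mode = "stochastic",
                                       seed = 100, omega = 200)
  expect_false(identical(c_run$trajectory, a$trajectory))
})

test_that("stochastic means track the deterministic solution at large counts", {
  prof <- subsite_profile("GH57_PSGT")
  omega <- 1e4
  det <- simulate_disproportionation(c(G5 = 10), prof, 2)
  sto <- simulate_disproportionation(c(G5 = 10 * omega), prof, 2,
                                     mode = "stochastic", seed = 7, omega = omega)
  at_end <- function(sim) {
    tr <- sim$trajectory
    stats::setNames(tr$amount[tr$time == max(tr$time)],
                    tr$species[tr$time == max(tr$time)])
  }
  d <- at_end(det); s <- at_end(sto)
  for (sp in c("G3", "G4", "G5", "G6", "G7")) {
    expected_counts <- d[[sp]] * omega
    se <- sqrt(max(expected_counts, 1))
    expect_lt(abs(s[[sp]] - expected_counts), 3 * se + 1e-9)
  }
})

test_that("profile validation enforces the core subsites and rate signs", {
  expect_error(subsite_profile("custom", affinities = c("-1" = 0)),
               class = "gt_validation_error")
  expect_error(subsite_profile("custom", affinities = c("9" = 1)),
               class = "gt_validation_error")
  expect_error(subsite_profile("custom", transfer_rate = -1),
               class = "gt_validation_error")
  expect_error(simulate_disproportionation(c(G25 = 1), subsite_profile(), 1),
               class = "gt_validation_error")
  expect_error(reaction_state(c(Q5 = 1)), class = "gt_validation_error")
  expect_error(reaction_state(c(G5 = -1)), class = "gt_validation_error")
})
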