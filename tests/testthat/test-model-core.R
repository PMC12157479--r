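test_that("AMP production rate follows the promoter-competition forms", {
  imd <- tiny_params("IMD", beta5 = 10)
  # competitive default: beta5 * x * x/(x+y)
  expect_equal(amp_production_rate(0, 0, imd), 0)
  expect_equal(amp_production_rate(4, 4, imd), 10 * 4 * 0.5)
  expect_equal(amp_production_rate(3, 0, imd), 10 * 3)

  occ <- tiny_params("IMD", beta5 = 10, amp_form = "occupancy")
  expect_equal(amp_production_rate(0, 0, occ), 0)
  expect_equal(amp_production_rate(4, 4, occ), 5) # symmetric competition halves
  occ7 <- tiny_params("IMD", beta5 = 7, amp_form = "occupancy")
  expect_equal(amp_production_rate(3, 0, occ7), 7)

  toll <- tiny_params("TOLL", beta5 = 5)
  expect_equal(amp_production_rate(2, 9, toll), 10) # S never enters Toll rate

  leaky <- tiny_params("IMD", beta5 = 6, amp_form = "leaky")
  expect_equal(amp_production_rate(2, 3, leaky), 6 * 2 / (1 + 2 + 3))

  expect_error(amp_production_rate(-1, 0, imd), "must be >= 0")
})

test_that("AMP rate is monotone in the repressor and ratio-invariant", {
  p <- tiny_params("IMD", beta5 = 8)
  for (N in c(1, 3, 10)) {
    rates <- amp_production_rate(N, 0:10, p)
    expect_true(all(diff(rates) <= 0)) # non-increasing in S
  }
  occ <- tiny_params("IMD", beta5 = 8, amp_form = "occupancy")
  # occupancy depends only on S/N when Zn = Zs: invariant under joint scaling
  expect_equal(amp_production_rate(3, 5, occ), amp_production_rate(12, 20, occ))
  # competitive form scales linearly under (N, S) -> (cN, cS)
  expect_equal(amp_production_rate(12, 20, p), 4 * amp_production_rate(3, 5, p))
})

test_that("network has the expected channel sets per topology", {
  nimd <- build_network(tiny_params("IMD"))
  ntoll <- build_network(tiny_params("TOLL"))
  expect_length(nimd$bacterial_channels, 2)
  expect_length(nimd$immune_channels, 11)
  expect_length(ntoll$bacterial_channels, 2)
  expect_length(ntoll$immune_channels, 12)
  ids <- vapply(ntoll$immune_channels, `[[`, character(1), "id")
  expect_true("cactus_nfkb_removal" %in% ids)
  expect_false("cactus_nfkb_removal" %in%
                 vapply(nimd$immune_channels, `[[`, character(1), "id"))
})

test_that("knocked-down NFLs keep their channels but at zero propensity", {
  p <- model_params("IMD", beta3 = 0, beta4 = 0, beta1 = 2, beta2 = 2,
                    beta5 = 2, lam = 0.2)
  net <- build_network(p)
  ids <- vapply(net$immune_channels, `[[`, character(1), "id")
  expect_true(all(c("pirk_production", "downstream_nfl_production") %in% ids))
  set.seed(11)
  for (i in 1:20) {
    a <- propensity_vector(random_state(), net$immune_channels, p)
    expect_equal(unname(a[["pirk_production"]]), 0)
    expect_equal(unname(a[["downstream_nfl_production"]]), 0)
  }
})

test_that("propensity_vector evaluates channels and validates the state", {
  p <- tiny_params("IMD", beta2 = 4)
  net <- build_network(p)
  zero <- system_state()
  expect_true(all(propensity_vector(zero, net$immune_channels, p) == 0))
  expect_true(all(propensity_vector(zero, net$bacterial_channels, p) == 0))
  s <- system_state(B = 2, R = 3)
  a <- propensity_vector(s, net$immune_channels, p)
  expect_equal(unname(a[["nfkb_activation"]]), 4 * 3 * 2)
  bad <- system_state(R = 1)
  bad[["R"]] <- -1
  expect_error(propensity_vector(bad, net$immune_channels, p), "invalid state")
})

test_that("firing a positive-propensity channel never drives counts negative", {
  set.seed(202)
  for (i in 1:40) {
    p <- random_params()
    net <- build_network(p)
    s <- random_state()
    for (ch in c(net$bacterial_channels, net$immune_channels)) {
      if (ch$propensity(s, p) > 0) {
        expect_true(all(s + ch$delta >= 0),
                    info = paste("channel", ch$id))
      }
    }
  }
})

test_that("S only enters the AMP channel (IMD) and never the AMP rate (TOLL)", {
  pim <- tiny_params("IMD")
  pto <- tiny_params("TOLL")
  nim <- build_network(pim)
  nto <- build_network(pto)
  set.seed(33)
  for (i in 1:15) {
    s1 <- random_state()
    s2 <- s1
    s2[["S"]] <- s1[["S"]] + 7
    attr(s2, "t") <- attr(s1, "t")
    # IMD: changing S shifts only amp_production (and S degradation)
    a1 <- propensity_vector(s1, nim$immune_channels, pim)
    a2 <- propensity_vector(s2, nim$immune_channels, pim)
    changed <- names(a1)[a1 != a2]
    expect_true(all(changed %in% c("amp_production", "deg_S")))
    # TOLL: amp rate unchanged by S
    b1 <- propensity_vector(s1, nto$immune_channels, pto)
    b2 <- propensity_vector(s2, nto$immune_channels, pto)
    expect_equal(b1[["amp_production"]], b2[["amp_production"]])
  }
})

test_that("compiled engine propensities agree with the R channel objects", {
  set.seed(91)
  for (i in 1:30) {
    p <- random_params()
    net <- build_network(p)
    s <- random_state()
    cpp <- cpp_propensities(s, p)
    expect_equal(unname(propensity_vector(s, net$bacterial_channels, p)),
                 cpp$bacterial)
    expect_equal(unname(propensity_vector(s, net$immune_channels, p)),
                 cpp$immune)
  }
})

test_that("parameter validation rejects bad rates and binding energies", {
  expect_error(model_params("IMD", beta1 = -1), "rate constants")
  expect_error(model_params("IMD", Zn = 0), "binding energies")
  expect_error(model_params("IMD", Zs = -2), "binding energies")
  expect_error(system_state(B = -1), ">= 0")
})
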