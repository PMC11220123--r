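test_that("province fixture has the documented regional structure", {
  fx <- province_fixture()
  expect_length(fx$labels, 31)
  expect_equal(unname(table(fx$regions)[c("east", "central", "west")]),
               c(11L, 8L, 12L), ignore_attr = TRUE)
  expect_true(all(fx$labels %in% names(fx$regions)))
  expect_false(anyDuplicated(fx$labels) > 0)
  # Tibet borders exactly Xinjiang, Qinghai, Sichuan, Yunnan
  nb <- with(fx$edges, c(unit_b[unit_a == "Tibet"], unit_a[unit_b == "Tibet"]))
  expect_setequal(nb, c("Xinjiang", "Qinghai", "Sichuan", "Yunnan"))
})

test_that("the contiguity graph is connected after the island join", {
  fx <- province_fixture()
  w <- contiguity_weights(fx$edges, fx$labels, style = "B")
  # breadth-first search from an arbitrary unit reaches all 31
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(colSums(w$W[frontier, , drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_length(seen, 31)
})

test_that("generation is deterministic given the seed", {
  g1 <- generate_panel(sim_config(seed = 42))
  g2 <- generate_panel(sim_config(seed = 42))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel(g1$panel, f1); write_panel(g2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_panel(sim_config(seed = 43))
  expect_false(identical(g1$panel$inputs, g3$panel$inputs))
})

test_that("the no-inefficiency limit puts every DMU-year on the frontier", {
  g <- generate_panel(sim_config(sigma_mu = 0, sigma_v = 0, rho = 0,
                                 spatial_sd = 0, delta = c(0, 0, 0, 0),
                                 seed = 5))
  expect_true(all(g$truth$u == 0))
  d <- run_dea_by_year(g$panel)
  expect_true(all(d$scores$pte == 1))
})

test_that("panel round-trips through CSV and rejects broken files", {
  g <- small_panel(seed = 61)
  f <- tempfile(fileext = ".csv")
  write_panel(g$panel, f)
  p2 <- read_panel(f)
  expect_equal(p2$inputs, g$panel$inputs, tolerance = 1e-12)
  expect_equal(p2$outputs, g$panel$outputs, tolerance = 1e-12)
  expect_equal(p2$dmu_ids, g$panel$dmu_ids)
  # drop one DMU-year row: the offending cell is named
  df <- read.csv(f)
  broken <- tempfile(fileext = ".csv")
  write.csv(df[-5, ], broken, row.names = FALSE)
  expect_error(read_panel(broken), "missing cell.*DMU02 2013")
})

test_that("stage-1 efficiency tracks the simulated truth", {
  # pooled frontier so that scores are comparable across years
  rhos <- vapply(1:5, function(b) {
    g <- generate_panel(sim_config(sigma_mu = 0.3, seed = 700 + b))
    d <- run_dea_by_year(g$panel, frontier_scope = "pooled")
    key <- paste(d$scores$dmu, d$scores$year)
    tr <- g$truth[match(key, paste(g$truth$dmu, g$truth$year)), ]
    cor(d$scores$te, tr$efficiency, method = "spearman")
  }, 0)
  expect_gte(mean(rhos), 0.7)
})

test_that("raising a covariate effect raises its recovered slack coefficient", {
  # sign recovery: positive delta on urbanization must surface as a
  # positive fitted SFA coefficient on urbanization
  hits <- 0
  for (b in 1:5) {
    g <- generate_panel(sim_config(delta = c(0, 0, 0.3, 0), sigma_mu = 0.15,
                                   rho = 0, spatial_sd = 0, seed = 800 + b))
    d <- run_dea_by_year(g$panel)
    ef <- tridea:::env_design(g$panel)
    sl <- d$slacks[d$slacks$input == "personnel", ]
    key <- match(paste(ef$dmu, ef$year), paste(sl$dmu, sl$year))
    fit <- fit_sfa(sl$slack[key], ef$Z)
    if (fit$beta["urbanization"] > 0) hits <- hits + 1
  }
  expect_gte(hits, 5 * 0.95)
})

test_that("frontier progress appears as TECHCH above one", {
  g <- generate_panel(sim_config(n_dmus = 12, n_years = 3, g = 1.08,
                                 sigma_mu = 0.1, seed = 71))
  ov <- summarize_malmquist(run_malmquist(g$panel), by = "overall")
  expect_gt(ov$techch, 1)
})

test_that("spatial autocorrelation in the truth yields positive Moran's I", {
  # the spatial share of inefficiency variance must dominate for the sign
  # to be near-certain: measured 97% positive at rho = 0.8 with innovation
  # scale 0.25 over 100 replicates
  hits <- 0
  for (b in 1:20) {
    g <- generate_panel(sim_config(rho = 0.8, spatial_sd = 0.25,
                                   seed = 900 + b))
    eff <- g$truth$efficiency[g$truth$year == 2012]
    gI <- global_moran(eff, g$weights, n_perm = 0)
    if (gI$I > 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("non-fixture sizes fall back to knn neighbourhoods", {
  g <- generate_panel(sim_config(n_dmus = 6, n_years = 2, seed = 72))
  expect_length(g$panel$dmu_ids, 6)
  expect_match(g$weights$source, "knn")
  expect_null(g$panel$regions)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(rho = 1, seed = 1))
  expect_error(sim_config(sigma_mu = -1, seed = 1))
})
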