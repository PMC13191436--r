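test_that("replicate simulation is seeded, truncated and degenerate-safe", {
  means <- flat_means(n_analytes = 4, mean = 2, sd = 0.5)
  cfg <- simulation_config(means, n_replicates = 3, seed = 11)
  a <- simulate_replicates(cfg)
  b <- simulate_replicates(cfg)
  expect_identical(a, b)                       # identical config -> identical table
  c <- simulate_replicates(simulation_config(means, n_replicates = 3, seed = 12))
  expect_true(any(a$value != c$value))         # different seed -> different draws
  expect_true(all(a$value >= 0))

  # SD = 0 degenerates to the group means
  m0 <- as.data.frame(means); m0$sd <- 0
  z <- simulate_replicates(simulation_config(
    analyte_table(m0, "concentration_mg_per_kg"), n_replicates = 3, seed = 1))
  expect_equal(z$value, rep(m0$value, 3))

  expect_error(simulation_config(means, n_replicates = 1), "at least 2")
  m_na <- as.data.frame(means); m_na$sd[1] <- NA
  expect_error(simulation_config(
    analyte_table(m_na, "concentration_mg_per_kg")), "SD")
})

test_that("per-group sample means stay inside normal-theory bounds", {
  # published volatile means/SDs, triplicates: the 4*SD/sqrt(3) bound should
  # hold for essentially every cell across seeds
  fx <- load_fixtures()
  n_ok <- 0; n_tot <- 0
  for (s in 1:100) {
    sim <- simulate_replicates(simulation_config(
      fx$voc_table, n_replicates = 3, seed = s, renormalize = FALSE))
    gm <- stats::aggregate(value ~ analyte_id + form + sample_group,
                           data = sim, FUN = mean)
    key <- paste(gm$analyte_id, gm$form, gm$sample_group)
    ref <- as.data.frame(fx$voc_table)
    idx <- match(key, paste(ref$analyte_id, ref$form, ref$sample_group))
    ok <- abs(gm$value - ref$value[idx]) <= 4 * ref$sd[idx] / sqrt(3) + 1e-12
    n_ok <- n_ok + sum(ok); n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("simulated moments recover the configured mean and SD", {
  means <- flat_means(n_analytes = 3, mean = 10, sd = 2)  # SD/mean = 0.2
  sim <- simulate_replicates(simulation_config(means, n_replicates = 1000,
                                               seed = 5))
  for (g in unique(sim$sample_group)) for (a in unique(sim$analyte_id)) {
    v <- sim$value[sim$sample_group == g & sim$analyte_id == a]
    expect_lt(abs(mean(v) - 10) / 10, 0.05)
    expect_lt(abs(stats::sd(v) - 2) / 2, 0.10)
  }
})

test_that("relative-content replicates renormalize to 100% per replicate", {
  means <- as.data.frame(flat_means(n_analytes = 5, mean = 20, sd = 2))
  tab <- analyte_table(means, "relative_percent")
  sim <- simulate_replicates(simulation_config(tab, n_replicates = 3, seed = 2))
  sums <- tapply(sim$value, paste(sim$sample_group, sim$replicate), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("e-nose simulation reproduces the elevated-sensor pattern", {
  cfg <- simulation_config(flat_means(2), seed = 3,
                           enose_profile = default_enose_profile())
  en <- simulate_enose(cfg)
  expect_identical(en, simulate_enose(cfg))
  gm <- stats::aggregate(value ~ analyte_id + sample_group, data = en, FUN = mean)
  hi <- c("S2", "S3", "S6")
  for (g in unique(gm$sample_group)) {
    d <- gm[gm$sample_group == g, ]
    expect_gt(min(d$value[d$analyte_id %in% hi]),
              max(d$value[!d$analyte_id %in% hi]))
  }
  expect_error(simulate_enose(simulation_config(flat_means(2), seed = 3)),
               "enose_profile")
})

test_that("zero-noise sensor tables have rank = distinct profiles - 1", {
  # three groups with general-position sensor profiles, no noise
  pr <- expand.grid(sensor = paste0("S", 1:6), group = c("A", "B", "C"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(4)
  pr$mean <- runif(nrow(pr), 1, 5)
  pr$sd <- 0
  cfg <- simulation_config(flat_means(2), seed = 9, enose_profile = pr)
  en <- simulate_enose(cfg)
  pc <- pca(analyte_matrix(en), scaling = "center")
  expect_equal(sum(pc$explained_variance_fraction > 1e-10), 2)
})

test_that("discrimination injection is targeted, monotone and identity at 0", {
  means <- flat_means(n_analytes = 6, mean = 5, sd = 0.5)
  expect_identical(inject_discrimination(means, "v1", 0), means)
  inj <- inject_discrimination(means, c("v1", "v2"), 5)
  d <- as.data.frame(inj)
  for (id in c("v1", "v2")) {
    prof <- d$value[d$analyte_id == id][order(d$sample_group[d$analyte_id == id])]
    expect_true(all(diff(prof) > 0))                 # monotone A -> E
    expect_equal(range(prof), c(5 - 2.5, 5 + 2.5))   # +/- shift * SD
  }
  expect_equal(d$value[!d$analyte_id %in% c("v1", "v2")],
               rep(5, 4 * 5))                        # others untouched
  expect_error(inject_discrimination(means, "nope", 2), "unknown analyte")
})
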