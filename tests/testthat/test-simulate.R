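test_that("default parameters carry the calibrated sample sizes, means and derived SDs", {
  p <- default_species_params()
  expect_length(p, 6)
  vw <- p[["vagans.worker"]]
  expect_equal(vw$n, 35L)
  expect_equal(unname(vw$mean["mr1"]), 1.46)
  # SD back-derived from a central 99% normal interval: (hi - lo) / (2 q_0.995)
  expect_equal(unname(vw$sd["mr1"]), (1.62 - 1.30) / (2 * qnorm(0.995)),
               tolerance = 1e-12)
  expect_equal(unname(vw$sd["mr1"]), 0.0621, tolerance = 1e-3)
  sw <- p[["sandersoni.worker"]]
  expect_equal(unname(sw$sd["mrl"]), 0.0388, tolerance = 1e-3)
  expect_equal(sum(vapply(p, `[[`, integer(1), "n")), 115L)
  for (cell in p) {
    expect_true(isSymmetric(cell$corr))
    expect_equal(unname(diag(cell$corr)), rep(1, 3))
    expect_gte(min(eigen(cell$corr, symmetric = TRUE)$values), 0)
  }
})

test_that("derived SDs recover the stated 99% intervals under simulation", {
  # independent oracle: draw 1e6 normals with the derived SD and check that
  # the empirical (0.5%, 99.5%) quantiles recover the interval bounds
  p <- default_species_params()
  vw <- p[["vagans.worker"]]
  set.seed(101)
  draws <- rnorm(1e6, vw$mean["mr1"], vw$sd["mr1"])
  q <- quantile(draws, c(0.005, 0.995), names = FALSE)
  expect_equal(q, c(1.30, 1.62), tolerance = 0.005)
})

test_that("simulate_specimens is seed-deterministic and reproduces the design", {
  p <- default_species_params()
  a <- simulate_specimens(p, seed = 11)
  b <- simulate_specimens(p, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 115L)
  expect_equal(as.integer(table(a$species_dna)[c("perplexus", "sandersoni", "vagans")]),
               c(22L, 49L, 44L))
  expect_equal(sum(a$caste == "queen"), 34L)
  # raw measurements are consistent with the drawn ratios
  re <- compute_ratios(a[, setdiff(names(a), c("mr1", "mr3", "mrl"))])
  expect_equal(re$mr1, a$mr1)
  expect_equal(re$mr3, a$mr3)
  expect_equal(re$mrl, a$mrl)
  expect_true(all(a$mrl < 1))
  # hair traits respect the cell vocabularies
  expect_true(all(a$mesipisternum[a$species_dna == "vagans"] == "light"))
  expect_true(all(a$scutum_black[a$species_dna == "perplexus"] %in% c("none", "few")))
})

test_that("degenerate noise collapses every bee onto the cell mean", {
  p <- default_species_params()["vagans.worker"]
  p[[1]]$sd[] <- 1e-12
  class(p) <- "species_caste_params"
  df <- simulate_specimens(p, seed = 2)
  expect_equal(df$mr1, rep(1.46, 35), tolerance = 1e-9)
  expect_equal(df$mrl, rep(0.92, 35), tolerance = 1e-9)
})

test_that("simulated cell means recover the calibration targets (law of large numbers)", {
  p <- default_species_params()
  set.seed(3)
  means <- replicate(200, {
    x <- simulate_specimens(p, seed = sample.int(1e6, 1))
    mean(x$mr1[x$species_dna == "vagans" & x$caste == "worker"])
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1.46), 3 * se + 1e-6)
})

test_that("observer replicate simulation matches its noise model", {
  df <- simulate_specimens(seed = 42)
  # zero noise: all replicates identical, within-observer correlation 1
  reps0 <- simulate_observer_replicates(df, observer_noise(0, 0), seed = 1)
  r1 <- reps0[reps0$observer == "Obs1" & reps0$rep == 1, ]
  r2 <- reps0[reps0$observer == "Obs1" & reps0$rep == 2, ]
  expect_equal(r1$mr1, r2$mr1)
  expect_equal(cor(r1$mrl, r2$mrl), 1.0)

  # noise inverted from a target repeatability is recovered: R = var/(var+sd^2)
  target <- c(mr1 = 0.95, mr3 = 0.94, mrl = 0.92)
  wsd <- vapply(names(target), function(m) within_sd_for_r(df[[m]], target[m]),
                numeric(1))
  reps <- simulate_observer_replicates(df, observer_noise(wsd, 0.01), seed = 8)
  rr <- repeatability_report(reps)
  for (m in names(target)) {
    got <- rr$r[rr$comparison == "Within Obs1" & rr$measurement == m]
    expect_equal(got, unname(target[m]), tolerance = 0.03)
  }
  # replicate SDs stay small, as for careful reticle measurements
  s <- tapply(reps$mrl, reps$id, sd)
  expect_lt(max(s), 0.11)
})

test_that("synthetic barcode sets hit their divergence targets exactly", {
  bc <- simulate_barcode_set(seed = 5)
  expect_equal(nrow(bc), 115L)
  expect_identical(bc, simulate_barcode_set(seed = 5))
  h <- collapse_haplotypes(bc)
  expect_length(h, 4)  # sandersoni, vagans, two perplexus haplotypes
  s1 <- bc$sequence[bc$species == "sandersoni"][1]
  v1 <- bc$sequence[bc$species == "vagans"][1]
  expect_equal(percent_identity(s1, v1), 1 - 6 / 140)
  # the two perplexus haplotypes differ at exactly one site
  hp <- Filter(function(x) "perplexus" %in% names(x$species), h)
  expect_length(hp, 2)
  d <- sum(strsplit(hp[[1]]$sequence, "")[[1]] != strsplit(hp[[2]]$sequence, "")[[1]])
  expect_equal(d, 1L)
  # infeasible divergence triangles are refused
  bad <- barcode_sim_spec(divergence = c(sandersoni.vagans = 20L,
                                         perplexus.sandersoni = 2L,
                                         perplexus.vagans = 2L))
  expect_error(simulate_barcode_set(bad, seed = 1), "triangle")
  # odd-parity triangles are feasible too
  odd <- barcode_sim_spec(divergence = c(sandersoni.vagans = 5L,
                                         perplexus.sandersoni = 8L,
                                         perplexus.vagans = 8L),
                          haplotype_split = NULL)
  bco <- simulate_barcode_set(odd, counts = c(sandersoni = 2L, vagans = 2L,
                                              perplexus = 2L), seed = 3)
  expect_equal(percent_identity(bco$sequence[1], bco$sequence[3]), 1 - 5 / 140)
})
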