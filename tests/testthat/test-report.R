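# independent textbook computation of the pooled two-sample t test
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

test_that("pooled t test matches the explicit formula on random cases", {
  withr::with_seed(31, {
    for (i in 1:50) {
      a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      got <- unpaired_ttest(a, b)
      want <- pooled_t_oracle(a, b)
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  })
})

test_that("degenerate and separated samples behave sensibly", {
  same <- c(1, 2, 3, 4)
  r <- unpaired_ttest(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  shifted <- unpaired_ttest(same, same + 10)
  expect_lt(shifted$p, 0.001)
  # zero variance in both groups
  flat <- unpaired_ttest(rep(2, 3), rep(2, 4))
  expect_equal(flat$p, 1)
  expect_true(flat$degenerate)
  apart <- unpaired_ttest(rep(2, 3), rep(5, 4))
  expect_equal(apart$p, 0)
  expect_true(apart$degenerate)
  expect_error(unpaired_ttest(1, c(1, 2)), "n >= 2")
})

test_that("type-I error of the test is nominal under the null", {
  n_rep <- 10000L
  rejections <- withr::with_seed(77, {
    sum(vapply(seq_len(n_rep), function(i) {
      unpaired_ttest(rnorm(4), rnorm(4))$p < 0.05
    }, logical(1)))
  })
  rate <- rejections / n_rep
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("group summaries reproduce means/SDs and suppress n = 1 statistics", {
  vals <- tibble::tibble(
    tracer = rep(c("A", "B"), each = 4),
    region = "tumor", parameter = "vt",
    value = c(2.1, 2.3, 2.2, 2.4, 3.1, 3.0, 3.2, 3.3))
  tab <- summarize_groups(vals)
  a <- tab[tab$tracer == "A", ]
  expect_equal(a$mean, mean(vals$value[1:4]))
  expect_equal(a$sd, stats::sd(vals$value[1:4]))
  expect_true(is.na(a$p_vs_ref))   # reference group has no p
  b <- tab[tab$tracer == "B", ]
  expect_equal(b$p_vs_ref,
               unpaired_ttest(vals$value[1:4], vals$value[5:8])$p)

  # identical groups give p = 1
  same <- vals; same$value[5:8] <- same$value[1:4]
  expect_equal(summarize_groups(same)$p_vs_ref[2], 1)

  single <- tibble::tibble(tracer = c("A", "B"), region = "tumor",
                           parameter = "vt", value = c(2, 3))
  stab <- summarize_groups(single)
  expect_true(all(is.na(stab$sd)))
  expect_true(all(is.na(stab$p_vs_ref)))
  expect_match(stab$label[1], "n=1")
})

test_that("pipeline runs end to end, is deterministic, and honors config", {
  cfg <- default_pipeline_config(noise_scale = 1, n_per_group = 2L,
                                 phantom_dim = 24L, seed = 4L)
  res1 <- run_pipeline(cfg)
  expect_equal(nrow(res1$subjects), 6L)
  expect_true(all(is.finite(res1$summary$mean)))
  expect_true(all(c("vt", "bp", "vs") %in% res1$summary$parameter))
  expect_true(file.exists(file.path(cfg$out_dir, "summary.csv")))
  expect_true(file.exists(file.path(cfg$out_dir,
                                    "tracer_A_s01_tumor_tac.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "run.log")))

  cfg2 <- cfg
  cfg2$out_dir <- tempfile("dynpet-rep-")
  res2 <- run_pipeline(cfg2)
  expect_identical(res1$subjects$vt, res2$subjects$vt)
  expect_identical(res1$subjects$bp, res2$subjects$bp)
  expect_identical(readLines(file.path(cfg$out_dir, "summary.csv")),
                   readLines(file.path(cfg2$out_dir, "summary.csv")))
  unlink(c(cfg$out_dir, cfg2$out_dir), recursive = TRUE)
})

test_that("noise-free pipeline recovers ground-truth Bp; no-reference config drops Bp", {
  cfg <- default_pipeline_config(noise_scale = 0, n_per_group = 1L,
                                 phantom_dim = 24L, seed = 2L)
  res <- run_pipeline(cfg)
  bp_a <- res$subjects$bp[res$subjects$tracer == "tracer_A"]
  # residual bias combines Logan finite-time bias with blood-volume
  # contamination of the tumor and muscle VOIs (vB = 0.05 / 0.02)
  expect_lt(abs(bp_a - 3.75) / 3.75, 0.12)
  vt_a <- res$subjects$vt[res$subjects$tracer == "tracer_A"]
  truth_vt <- 0.25 / 0.45 * (1 + 0.15 / 0.04)
  expect_lt(abs(vt_a - truth_vt) / truth_vt, 0.10)

  cfg2 <- default_pipeline_config(noise_scale = 0, n_per_group = 1L,
                                  phantom_dim = 24L, seed = 2L,
                                  with_reference = FALSE)
  res2 <- run_pipeline(cfg2)
  expect_false("bp" %in% names(res2$subjects))
  expect_true("vt" %in% names(res2$subjects))
  unlink(c(cfg$out_dir, cfg2$out_dir), recursive = TRUE)
})
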