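toy_table <- function(values) {
  # values: list of per-participant c(level1, level2, ...) vectors
  k <- length(values[[1]])
  dplyr::bind_rows(lapply(seq_along(values), function(i) {
    tibble::tibble(participant = sprintf("P%02d", i),
                   condition = letters[seq_len(k)],
                   y = values[[i]])
  }))
}

test_that("one-way rm-ANOVA reproduces the hand-computed toy example", {
  # participants (1,2), (2,4), (3,5): diffs -1,-2,-2 -> t = -5, F = 25
  tab <- toy_table(list(c(1, 2), c(2, 4), c(3, 5)))
  fit <- rm_anova(tab, "y", "condition")
  an <- tidy(fit)
  expect_equal(an$statistic, 25, tolerance = 1e-9)
  expect_equal(an$df_num, 1)
  expect_equal(an$df_den, 2)
  tt <- paired_t(tab$y[tab$condition == "a"], tab$y[tab$condition == "b"])
  expect_equal(tt$statistic, -5, tolerance = 1e-12)
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$n_effects, 1)
})

test_that("F equals t-squared for any 2-level within design", {
  set.seed(8)
  for (rep in 1:10) {
    vals <- lapply(1:9, function(i) stats::rnorm(2))
    tab <- toy_table(vals)
    f <- tidy(rm_anova(tab, "y", "condition"))$statistic
    t2 <- paired_t(tab$y[tab$condition == "a"],
                   tab$y[tab$condition == "b"])$statistic^2
    expect_equal(f, t2, tolerance = 1e-9)
  }
})

test_that("rm-ANOVA handles constants, label permutations and imbalance", {
  const <- toy_table(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  an <- tidy(rm_anova(const, "y", "condition"))
  expect_equal(an$statistic, 0)
  expect_equal(an$p.value, 1)

  set.seed(3)
  tab <- toy_table(lapply(1:8, function(i) stats::rnorm(4)))
  f0 <- tidy(rm_anova(tab, "y", "condition"))$statistic
  perm <- tab
  relabel <- sample(unique(tab$participant))
  perm$participant <- relabel[match(tab$participant,
                                    unique(tab$participant))]
  expect_equal(tidy(rm_anova(perm, "y", "condition"))$statistic, f0,
               tolerance = 1e-9)
  expect_error(rm_anova(tab[-1, ], "y", "condition"), "balanced")
})

test_that("two-factor rm-ANOVA returns all three effects with correct df", {
  set.seed(5)
  tab <- tidyr::expand_grid(participant = sprintf("P%02d", 1:17),
                            zone = c("initial_fixation", "pre_cue"),
                            condition = letters[1:4])
  tab$rate <- stats::rnorm(nrow(tab), 1) +
    2 * (tab$zone == "initial_fixation")
  fit <- rm_anova(tab, "rate", c("zone", "condition"))
  an <- tidy(fit)
  expect_setequal(an$effect, c("zone", "condition", "zone:condition"))
  expect_equal(an$df_num[an$effect == "zone"], 1)
  expect_equal(an$df_den[an$effect == "zone"], 16)
  expect_equal(an$df_num[an$effect == "condition"], 3)
  expect_equal(an$df_den[an$effect == "condition"], 48)
  expect_equal(an$df_num[an$effect == "zone:condition"], 3)
  expect_equal(an$df_den[an$effect == "zone:condition"], 48)
  expect_lt(an$p.value[an$effect == "zone"], 0.001)
  # Greenhouse-Geisser: epsilon = 1 for 2-level effects, <= 1 otherwise
  gg <- tidy(rm_anova(tab, "rate", c("zone", "condition"),
                      sphericity = "greenhouse_geisser"))
  expect_equal(gg$epsilon[gg$effect == "zone"], 1, tolerance = 1e-9)
  eps_c <- gg$epsilon[gg$effect == "condition"]
  expect_true(eps_c <= 1 + 1e-9 && eps_c >= 1 / 3)
  # with epsilon = 1 the correction is a no-op; for large F it is
  # conservative (never smaller p)
  expect_equal(gg$p.adj[gg$effect == "zone"],
               gg$p.value[gg$effect == "zone"], tolerance = 1e-9)
  big <- gg$statistic >= 1
  expect_true(all(gg$p.adj[big] >= gg$p.value[big] - 1e-12))
})

test_that("paired t matches hand arithmetic and is antisymmetric", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)
  tt <- paired_t(x, y)
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  rev_tt <- paired_t(y, x)
  expect_equal(rev_tt$statistic, -tt$statistic)
  expect_equal(rev_tt$p.value, tt$p.value)
  expect_error(paired_t(x, x), "variance")
  expect_error(paired_t(x, y[1:2]), "equal length")
})

test_that("post hoc letters group indistinguishable levels", {
  set.seed(12)
  base <- lapply(1:10, function(i) stats::rnorm(4, sd = 0.1))
  same <- toy_table(lapply(base, function(v) rep(mean(v), 4)))
  ph_same <- posthoc_pairwise(same, "y", "condition")
  expect_equal(unique(ph_same$letters$letters), "a")
  expect_true(all(ph_same$comparisons$p.value == 1))

  shifted <- toy_table(lapply(base, function(v) v + c(0, 0, 0, 50)))
  ph <- posthoc_pairwise(shifted, "y", "condition")
  lt <- ph$letters
  expect_equal(length(unique(lt$letters[lt$level != "d"])), 1)
  expect_false(lt$letters[lt$level == "d"] %in%
                 lt$letters[lt$level != "d"])
  # Holm never decreases a p-value
  expect_true(all(ph$comparisons$p.adj >= ph$comparisons$p.value))
  raw <- posthoc_pairwise(shifted, "y", "condition", correction = "none")
  expect_equal(raw$comparisons$p.adj, raw$comparisons$p.value)
})

test_that("condition_stats assembles the full statistical design", {
  set.seed(17)
  zones <- c("initial_fixation", "pre_cue_250", "post_inhibition",
             "movement", "pre_cue_inhibition", "post_cue_inhibition")
  zone_tab <- tidyr::expand_grid(participant = sprintf("P%02d", 1:8),
                                 condition = task_conditions(),
                                 zone = zones)
  zone_tab$mean_rate <- stats::rnorm(nrow(zone_tab), 0.5, 0.1) +
    (zone_tab$zone == "initial_fixation")
  rt_tab <- tidyr::expand_grid(participant = sprintf("P%02d", 1:8),
                               condition = c("reach_visible",
                                             "reach_invisible"))
  rt_tab$reaction_time <- stats::rnorm(nrow(rt_tab), 0.4, 0.03) +
    0.07 * (rt_tab$condition == "reach_invisible")
  st <- condition_stats(zone_tab, rt_tab = rt_tab)
  expect_s3_class(st$zone_by_condition, "rm_anova")
  expect_setequal(tidy(st$zone_by_condition)$effect,
                  c("zone", "condition", "zone:condition"))
  expect_lt(tidy(st$zone_by_condition)$p.value[1], 0.01)
  expect_named(st$one_way, c("initial_fixation", "pre_cue_250",
                             "post_inhibition", "movement"))
  # the movement-zone contrast drops cue monitoring: df follow 3 conditions
  mv <- tidy(st$one_way$movement)
  expect_equal(mv$df_num, 2)
  expect_s3_class(st$cue_inhibition, "rm_anova")
  expect_gt(st$rt_test$statistic, 0)
})
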