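test_that("Fisher z matches its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(19), tolerance = 1e-9)
  expect_equal(fisher_z(0.9), 1.4722, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -0.5493, tolerance = 1e-4)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))        # strictly increasing
  expect_equal(fisher_z(-r), -fisher_z(r))       # odd
  expect_error(fisher_z(1.2), "outside")
  expect_warning(zc <- fisher_z(1), "clipped")
  expect_true(is.finite(zc))
})

test_that("per-participant correlations cover all 21 pairs", {
  d <- full_design_rows(2)
  set.seed(2)
  x <- rnorm(nrow(d))
  d$ord_mean <- 1 + 4 * plogis(x); d$kss <- round(5 + 2 * x)
  d$sdlp_cm <- 25 + 5 * x + rnorm(nrow(d)); d$perclos_pct <- 4 + x
  d$sem_pct <- 6 + x; d$eeg_alpha_power <- exp(x); d$eeg_theta_power <- exp(x / 2)
  d$kss <- pmin(pmax(d$kss, 1), 9)
  tab <- assemble_measure_table(d)
  cors <- participant_correlations(tab)
  expect_equal(nrow(cors), 2 * choose(7, 2))
  expect_equal(sort(unique(paste(cors$measure_a, cors$measure_b))),
               sort(apply(utils::combn(drowsival:::MEASURE_COLS, 2), 2, paste,
                          collapse = " ")))

  # exact linear dependence gives r = 1; noisy permutation case gives 0.6
  small <- data.frame(participant_id = "p", session = 1, trial = 1:4,
                      kss = pmin(9, c(1, 2, 3, 4)), sdlp_cm = 2 * c(1, 2, 3, 4),
                      perclos_pct = c(2, 1, 4, 3))
  tab2 <- assemble_measure_table(small)
  c2 <- participant_correlations(tab2, c("kss", "sdlp_cm", "perclos_pct"))
  expect_equal(c2$r[c2$measure_a == "kss" & c2$measure_b == "sdlp_cm"], 1)
  expect_equal(c2$r[c2$measure_a == "kss" & c2$measure_b == "perclos_pct"], 0.6)
})

test_that("constant measures yield undefined correlations, excluded with note", {
  d <- data.frame(participant_id = "p", session = 1, trial = 1:5,
                  kss = c(2, 3, 4, 5, 6), sdlp_cm = rep(20, 5))
  tab <- assemble_measure_table(d)
  cors <- participant_correlations(tab, c("kss", "sdlp_cm"))
  expect_true(is.na(cors$r))
  expect_message(expect_error(group_z_test(cors$r), ">= 2"), "excluded")
})

test_that("group z-test reproduces hand-computed statistics", {
  g <- group_z_test(c(1, 2, 3))
  expect_equal(g$mean_z, 2)
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(g$t, 3.4641, tolerance = 1e-4)
  expect_equal(g$df, 2)
  # agrees with the base t-test as an independent oracle
  tt <- t.test(c(1, 2, 3))
  expect_equal(g$p, tt$p.value)
  expect_equal(c(g$ci_low, g$ci_high), as.numeric(tt$conf.int))
  expect_error(group_z_test(rep(0.5, 4)), "variance")
  expect_error(group_z_test(1), ">= 2")
})

test_that("the 95% interval covers the true mean at nominal rate", {
  set.seed(8)
  cover <- replicate(100, {
    z <- rnorm(17, 1.0, 0.2)
    g <- group_z_test(z)
    g$ci_low <= 1.0 && 1.0 <= g$ci_high
  })
  expect_gte(mean(cover), 0.90)
})

test_that("repeated-measures ANOVA has the design degrees of freedom", {
  d <- full_design_rows(17)
  set.seed(4)
  d$kss <- pmin(9, pmax(1, round(4 + 0.1 * d$session + rnorm(nrow(d)))))
  tab <- assemble_measure_table(d)
  a <- rm_anova(tab, "kss")
  expect_equal(a$df_trial, 23)
  expect_equal(a$df_error, 368)
  expect_equal(a$n, 17)
})

test_that("ANOVA F matches the aov oracle on random complete designs", {
  set.seed(14)
  for (case in 1:8) {
    n <- sample(4:10, 1); T <- sample(3:8, 1)
    m <- matrix(rnorm(n * T), n, T) + rnorm(n)  # subject effects
    d <- data.frame(participant_id = rep(sprintf("p%d", 1:n), T),
                    session = rep(1, n * T), trial = rep(1:T, each = n),
                    kss = 5)
    tab <- assemble_measure_table(d)
    tab$trial_order <- tab$trial
    tab$kss <- as.vector(m[cbind(match(tab$participant_id, sprintf("p%d", 1:n)),
                                 tab$trial)])
    got <- rm_anova(tab, "kss")
    want <- oracle_rm_anova_f(m)
    expect_equal(got$f, want$f, tolerance = 1e-9)
    expect_equal(got$df_trial, want$df_trial)
    expect_equal(got$df_error, want$df_error)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("under a pure subject-effect null the F statistic centres on 1", {
  set.seed(15)
  f <- replicate(50, {
    n <- 6; T <- 8
    m <- matrix(rnorm(n * T), n, T) + 2 * rnorm(n)
    d <- data.frame(participant_id = rep(sprintf("p%d", 1:n), each = T),
                    session = rep(1:T, n), trial = 1,
                    sdlp_cm = abs(as.vector(t(m))) + 10)
    tab <- assemble_measure_table(d)
    rm_anova(tab, "sdlp_cm")$f
  })
  expect_equal(mean(f), 1, tolerance = 0.2)
})

test_that("time-course summaries report per-trial means and standard errors", {
  d <- full_design_rows(2)
  d$sem_pct <- 5
  tab <- assemble_measure_table(d)
  tc <- time_course_summary(tab, "sem_pct")
  expect_equal(nrow(tc), 24L)
  expect_true(all(tc$se == 0))

  d2 <- data.frame(participant_id = c("a", "b"), session = 1, trial = 1,
                   sem_pct = c(1, 3))
  tc2 <- time_course_summary(assemble_measure_table(d2), "sem_pct")
  expect_equal(tc2$mean, 2)
  expect_equal(tc2$se, 1)
})
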