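test_that("empirical tables are maximum-likelihood cell frequencies", {
  co <- data.frame(X = rep(c(0, 1), c(130, 39)))
  t1 <- empirical_tables(co, "X")
  expect_equal(pt_prob(t1, c(X = "0")), 130 / 169)

  co4 <- data.frame(Z = rep(c("60", "70", "80", "90"), each = 100))
  t4 <- empirical_tables(co4, "Z")
  expect_equal(t4$p, rep(0.25, 4))

  expect_warning(t0 <- empirical_tables(data.frame(X = c(1, 1)), "X"),
                 "single observed level")
  expect_equal(pt_prob(t0, c(X = "1")), 1)

  expect_error(empirical_tables(data.frame(X = numeric(0)), "X"), "empty")
})

test_that("conditional slices of a table sum to one on every supported stratum", {
  spec <- scm_preset("nlr_like")
  t <- exact_joint(spec)
  for (x in pt_levels(t, "X")) {
    for (z in pt_levels(t, "Z")) {
      if (pt_prob(t, c(X = x, Z = z)) == 0) next
      s <- sum(vapply(pt_levels(t, "Y"), function(y) {
        pt_cond(t, c(Y = y), c(X = x, Z = z))
      }, 1))
      expect_equal(s, 1, tolerance = 1e-9)
    }
  }
})

test_that("back-door adjustment reduces correctly and matches ground truth", {
  spec <- scm_preset("confounder")
  t <- exact_joint(spec)
  # degenerate adjustment: the plain conditional
  expect_equal(backdoor_estimate(t, "X", "Y", "1", "1"),
               pt_cond(t, c(Y = "1"), c(X = "1")))
  gt <- ground_truth_ace(spec, "X", "Y")
  for (x in c("0", "1")) {
    est <- backdoor_estimate(t, "X", "Y", x, "1", adjust = "U")
    truth <- if (x == "0") gt$p_do_control else gt$p_do_treated
    expect_equal(est, truth, tolerance = 1e-9)
  }
  # collapsibility: when S is independent of everything, adjusting is a no-op
  b <- c("0", "1")
  g2 <- causal_graph(list(c("X", "Y")), nodes = "S")
  m2 <- list(
    S = scm_mechanism(b, probs = matrix(c(0.5, 0.5), 1)),
    X = scm_mechanism(b, probs = matrix(c(0.7, 0.3), 1)),
    Y = scm_mechanism(b, "X", list(X = b),
                      function(cfg) if (cfg$X == "1") c(0.1, 0.9) else c(0.8, 0.2)))
  t2 <- exact_joint(scm_spec(g2, m2))
  expect_equal(backdoor_estimate(t2, "X", "Y", "1", "1", adjust = "S"),
               backdoor_estimate(t2, "X", "Y", "1", "1"), tolerance = 1e-12)
})

test_that("front-door adjustment matches exact interventional truth", {
  spec <- scm_preset("frontdoor")
  t <- exact_joint(spec)
  gt <- ground_truth_ace(spec, "X", "Y")
  expect_equal(frontdoor_estimate(t, "X", "Y", "0", "1", "Z"),
               gt$p_do_control, tolerance = 1e-9)
  expect_equal(frontdoor_estimate(t, "X", "Y", "1", "1", "Z"),
               gt$p_do_treated, tolerance = 1e-9)

  # a mediator that is an exactly deterministic copy of X leaves empty
  # (x', m) strata: that is a genuine positivity violation and must error;
  # a near-deterministic copy in an unconfounded chain collapses to the
  # plain conditional as the copy noise vanishes
  b <- c("0", "1")
  g <- causal_graph(list(c("X", "M"), c("M", "Y")))
  copy_spec <- function(eps) {
    scm_spec(g, list(
      X = scm_mechanism(b, probs = matrix(c(0.6, 0.4), 1)),
      M = scm_mechanism(b, "X", list(X = b), function(cfg) {
        p <- if (cfg$X == "1") 1 - eps else eps
        c(1 - p, p)
      }),
      Y = scm_mechanism(b, "M", list(M = b),
                        function(cfg) if (cfg$M == "1") c(0.2, 0.8) else c(0.9, 0.1))))
  }
  expect_error(frontdoor_estimate(exact_joint(copy_spec(0)),
                                  "X", "Y", "1", "1", "M"),
               "positivity")
  tc <- exact_joint(copy_spec(1e-6))
  expect_equal(frontdoor_estimate(tc, "X", "Y", "1", "1", "M"),
               pt_cond(tc, c(Y = "1"), c(X = "1")), tolerance = 1e-4)

  # outcome independent of exposure and mediator: every inner term is P(y)
  g0 <- causal_graph(list(c("X", "M")), nodes = "Y")
  m0 <- list(
    X = scm_mechanism(b, probs = matrix(c(0.6, 0.4), 1)),
    M = scm_mechanism(b, "X", list(X = b),
                      function(cfg) if (cfg$X == "1") c(0.3, 0.7) else c(0.8, 0.2)),
    Y = scm_mechanism(b, probs = matrix(c(0.35, 0.65), 1)))
  t0 <- exact_joint(scm_spec(g0, m0))
  expect_equal(frontdoor_estimate(t0, "X", "Y", "1", "1", "M"), 0.65,
               tolerance = 1e-12)
})

test_that("back-door and front-door agree where both criteria hold", {
  # observed confounder plus a clean mediator: both routes identify the effect
  b <- c("0", "1")
  g <- causal_graph(list(c("U", "X"), c("U", "Y"), c("X", "Z"), c("Z", "Y")))
  mech <- list(
    U = scm_mechanism(b, probs = matrix(c(0.55, 0.45), 1)),
    X = scm_mechanism(b, "U", list(U = b),
                      function(cfg) if (cfg$U == "1") c(0.35, 0.65) else c(0.8, 0.2)),
    Z = scm_mechanism(b, "X", list(X = b),
                      function(cfg) if (cfg$X == "1") c(0.25, 0.75) else c(0.7, 0.3)),
    Y = scm_mechanism(b, c("U", "Z"), list(U = b, Z = b), function(cfg) {
      p <- 0.15 + 0.45 * (cfg$Z == "1") + 0.25 * (cfg$U == "1")
      c(1 - p, p)
    }))
  spec <- scm_spec(g, mech)
  t <- exact_joint(spec)
  gt <- ground_truth_ace(spec, "X", "Y")
  for (x in c("0", "1")) {
    truth <- if (x == "0") gt$p_do_control else gt$p_do_treated
    bd <- backdoor_estimate(t, "X", "Y", x, "1", adjust = "U")
    fd <- frontdoor_estimate(t, "X", "Y", x, "1", "Z")
    expect_equal(bd, truth, tolerance = 1e-9)
    expect_equal(fd, truth, tolerance = 1e-9)
    expect_equal(bd, fd, tolerance = 1e-9)
  }
})

test_that("the estimand tree-walk agrees with the named estimators", {
  spec <- scm_preset("frontdoor")
  t <- exact_joint(spec)
  id <- identify_effect(spec$graph, "X", "Y")
  expect_equal(interventional_probability(id, t, "0", "1"),
               frontdoor_estimate(t, "X", "Y", "0", "1", "Z"),
               tolerance = 1e-12)

  conf <- scm_preset("confounder")
  tc <- exact_joint(conf)
  idc <- identify_effect(conf$graph, "X", "Y")
  expect_equal(idc$pattern, "backdoor")
  expect_equal(interventional_probability(idc, tc, "1", "1"),
               backdoor_estimate(tc, "X", "Y", "1", "1", adjust = "U"),
               tolerance = 1e-12)
})

test_that("identified interventional distributions are normalized", {
  for (pattern in c("confounder", "frontdoor", "nlr_like")) {
    spec <- scm_preset(pattern, latent_confounder = pattern != "confounder")
    t <- exact_joint(spec)
    id <- identify_effect(spec$graph, "X", "Y")
    for (x in c("0", "1")) {
      total <- sum(vapply(pt_levels(t, "Y"), function(y) {
        interventional_probability(id, t, x, y)
      }, 1))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("the joint-weight front-door variant multiplies and sums as printed", {
  inner <- c(0.173077, 0.453963, 0.699023, 0.864253)
  w_ctl <- c(0.047337, 0.195266, 0.426036, 0.100592)
  w_trt <- c(0.017751, 0.071006, 0.12426, 0.017751)
  # tolerances reflect the 6 d.p. rounding of the published factors
  expect_lt(abs(frontdoor_joint_weight_estimate(inner, w_ctl) - 0.481582),
            1.5e-6)
  expect_lt(abs(frontdoor_joint_weight_estimate(inner, w_trt) - 0.137509),
            1.5e-6)
  expect_equal(frontdoor_joint_weight_estimate(0.7, 1), 0.7)
  expect_error(frontdoor_joint_weight_estimate(c(0.2, -0.1), c(1, 1)),
               "nonnegative")
  # renormalized weights give a proper mixture of the inner sums
  wn <- w_ctl / sum(w_ctl)
  mix <- frontdoor_joint_weight_estimate(inner, wn)
  expect_gte(mix, min(inner))
  expect_lte(mix, max(inner))
})

test_that("positivity violations are strict errors naming the stratum", {
  co <- data.frame(X = c(0, 0, 1, 1), S = c(0, 0, 1, 1),
                   Y = c(0, 1, 0, 1))
  t <- suppressWarnings(empirical_tables(co, c("X", "S", "Y")))
  expect_error(backdoor_estimate(t, "X", "Y", "1", "1", adjust = "S"),
               "positivity")
  # smoothing is the opt-in escape
  ts <- empirical_tables(co, c("X", "S", "Y"), smooth = 0.5)
  expect_no_error(backdoor_estimate(ts, "X", "Y", "1", "1", adjust = "S"))
})

test_that("additive smoothing converges monotonically to the raw estimate", {
  spec <- scm_preset("frontdoor", seed = 3)
  sim <- simulate_cohort(spec, 4000)
  co <- as.data.frame(sim)[c("X", "Z", "Y")]
  raw <- frontdoor_estimate(empirical_tables(co, names(co)),
                            "X", "Y", "0", "1", "Z")
  ests <- vapply(c(1, 0.1, 0.01), function(l) {
    frontdoor_estimate(empirical_tables(co, names(co), smooth = l),
                       "X", "Y", "0", "1", "Z")
  }, 1)
  devs <- abs(ests - raw)
  expect_true(all(diff(devs) <= 1e-12))
  expect_lt(devs[3], devs[1])
})

test_that("the Wald ratio recovers the trivial instrument cases", {
  n <- 400
  i <- rep(c(0, 1), each = n / 2)
  df <- data.frame(I = i, X = i, Y = i)
  t <- empirical_tables(df, c("I", "X", "Y"))
  expect_equal(iv_wald_estimate(t, "I", "X", "Y"), 1)
  withr::with_seed(4, {
    df2 <- data.frame(I = i, X = i, Y = rep(c(0.3, 0.3), n / 2))
  })
  expect_equal(iv_wald_estimate(df2, "I", "X", "Y"), 0)
  df3 <- data.frame(I = i, X = 1, Y = i)
  expect_error(iv_wald_estimate(df3, "I", "X", "Y"), "instrument")
})

test_that("the ACE is a validated signed difference with both scales", {
  a <- ace(0.481582, 0.137509)
  expect_equal(a$ace, 0.344073, tolerance = 1e-9)
  expect_equal(a$percent, 34.4073, tolerance = 1e-6)
  expect_equal(ace(0.5, 0.5)$ace, 0)
  expect_equal(ace(1, 0)$ace, 1)
  expect_error(ace(1.2, 0.5), "\\[0, 1\\]")
})
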