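b01 <- c("0", "1")

test_that("simulation is mechanism-faithful and bit-reproducible", {
  g <- causal_graph(list(c("X", "Y")))
  point <- scm_spec(g, list(
    X = scm_mechanism(b01, probs = matrix(c(0, 1), 1)),
    Y = scm_mechanism(b01, "X", list(X = b01),
                      function(cfg) if (cfg$X == "1") c(0, 1) else c(1, 0))))
  sim <- simulate_cohort(point, 50, seed = 1)
  expect_true(all(sim$X == "1"))
  expect_true(all(sim$Y == "1"))

  coin <- scm_spec(causal_graph(nodes = "X"),
                   list(X = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1))))
  s <- simulate_cohort(coin, 1e5, seed = 9)
  expect_lt(abs(mean(s$X == "1") - 0.5), 0.01)

  spec <- scm_preset("nlr_like", seed = 11)
  expect_identical(simulate_cohort(spec, 500), simulate_cohort(spec, 500))
  expect_false(identical(simulate_cohort(spec, 500, seed = 12),
                         simulate_cohort(spec, 500, seed = 13)))
})

test_that("per-node substreams are stable when the model grows", {
  g1 <- causal_graph(nodes = c("A", "B"))
  m1 <- list(A = scm_mechanism(b01, probs = matrix(c(0.4, 0.6), 1)),
             B = scm_mechanism(b01, probs = matrix(c(0.7, 0.3), 1)))
  g2 <- causal_graph(nodes = c("A", "B", "C"))
  m2 <- c(m1, list(C = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1))))
  s1 <- simulate_cohort(scm_spec(g1, m1), 200, seed = 21)
  s2 <- simulate_cohort(scm_spec(g2, m2), 200, seed = 21)
  expect_identical(s1$A, s2$A)
  expect_identical(s1$B, s2$B)
})

test_that("exact joints enumerate the mechanism products", {
  coin <- scm_spec(causal_graph(nodes = "X"),
                   list(X = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1))))
  expect_equal(exact_joint(coin)$p, c(0.5, 0.5))

  chain <- scm_spec(causal_graph(list(c("X", "Y"))), list(
    X = scm_mechanism(b01, probs = matrix(c(0.7, 0.3), 1)),
    Y = scm_mechanism(b01, "X", list(X = b01),
                      function(cfg) if (cfg$X == "1") c(0.1, 0.9) else c(0.8, 0.2))))
  expect_equal(pt_prob(exact_joint(chain), c(Y = "1")),
               0.7 * 0.2 + 0.3 * 0.9) # = 0.41
  # marginalizing out the latent confounder still normalizes
  t <- exact_joint(scm_preset("confounder", latent_confounder = TRUE))
  expect_setequal(t$vars, c("X", "Y"))
  expect_equal(sum(t$p), 1, tolerance = 1e-12)
})

test_that("empirical frequencies converge to the exact joint", {
  spec <- scm_preset("nlr_like", seed = 31)
  t_exact <- exact_joint(spec)
  sim <- simulate_cohort(spec, 1e5)
  t_emp <- empirical_tables(as.data.frame(sim)[c("X", "Y", "Z")],
                            c("X", "Y", "Z"))
  for (i in seq_len(nrow(t_exact$grid))) {
    cell <- as.list(t_exact$grid[i, , drop = FALSE])
    expect_lt(abs(pt_prob(t_emp, cell) - t_exact$p[i]), 0.01)
  }
})

test_that("interventions replace the mechanism and cut incoming arrows", {
  spec <- scm_preset("frontdoor")
  done <- intervene(spec, "X", "0")
  expect_equal(pt_prob(exact_joint(done), c(X = "0")), 1)
  # the manipulated graph equals the overline mutilation
  expect_identical(done$graph$edges, mutilate(spec$graph, overline = "X")$edges)
  expect_error(intervene(spec, "X", "7"), "not a level")

  # intervening on a childless node leaves every other marginal unchanged
  spec2 <- scm_preset("confounder")
  before <- exact_joint(spec2, observed_only = FALSE)
  after <- exact_joint(intervene(spec2, "Y", "1"), observed_only = FALSE)
  for (v in c("U", "X")) {
    expect_equal(pt_prob(after, stats::setNames("1", v)),
                 pt_prob(before, stats::setNames("1", v)), tolerance = 1e-12)
  }
})

test_that("interventions commute with marginalization over non-descendants", {
  spec <- scm_preset("nlr_like")
  done <- intervene(spec, "Z", "80")
  before <- exact_joint(spec, observed_only = FALSE)
  after <- exact_joint(done, observed_only = FALSE)
  # U and X are non-descendants of Z: their joint must be untouched
  for (u in b01) for (x in b01) {
    expect_equal(pt_prob(after, c(U = u, X = x)),
                 pt_prob(before, c(U = u, X = x)), tolerance = 1e-12)
  }
})

test_that("exact ground truth reproduces hand-computed interventions", {
  # no directed path: intervening moves nothing
  iso <- scm_spec(causal_graph(nodes = c("X", "Y")), list(
    X = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1)),
    Y = scm_mechanism(b01, probs = matrix(c(0.3, 0.7), 1))))
  expect_equal(ground_truth_ace(iso, "X", "Y")$ace, 0)

  chain <- scm_spec(causal_graph(list(c("X", "Y"))), list(
    X = scm_mechanism(b01, probs = matrix(c(0.7, 0.3), 1)),
    Y = scm_mechanism(b01, "X", list(X = b01),
                      function(cfg) if (cfg$X == "1") c(0.1, 0.9) else c(0.8, 0.2))))
  gt <- ground_truth_ace(chain, "X", "Y")
  expect_equal(gt$p_do_treated, 0.9, tolerance = 1e-12)
  expect_equal(gt$p_do_control, 0.2, tolerance = 1e-12)
  expect_equal(gt$ace, -0.7, tolerance = 1e-12)

  # confounding makes the naive conditional contrast wrong
  conf <- scm_preset("confounder")
  t <- exact_joint(conf)
  naive <- pt_cond(t, c(Y = "1"), c(X = "0")) - pt_cond(t, c(Y = "1"), c(X = "1"))
  expect_gt(abs(naive - ground_truth_ace(conf, "X", "Y")$ace), 0.01)
})

test_that("no confounding makes interventional and observational agree", {
  chain <- scm_spec(causal_graph(list(c("X", "Z"), c("Z", "Y"))), list(
    X = scm_mechanism(b01, probs = matrix(c(0.6, 0.4), 1)),
    Z = scm_mechanism(b01, "X", list(X = b01),
                      function(cfg) if (cfg$X == "1") c(0.2, 0.8) else c(0.75, 0.25)),
    Y = scm_mechanism(b01, "Z", list(Z = b01),
                      function(cfg) if (cfg$Z == "1") c(0.15, 0.85) else c(0.7, 0.3))))
  t <- exact_joint(chain)
  gt <- ground_truth_ace(chain, "X", "Y")
  expect_equal(gt$p_do_treated, pt_cond(t, c(Y = "1"), c(X = "1")),
               tolerance = 1e-12)
  expect_equal(gt$p_do_control, pt_cond(t, c(Y = "1"), c(X = "0")),
               tolerance = 1e-12)
})

test_that("presets expose the advertised identification patterns", {
  fd <- scm_preset("frontdoor")
  expect_equal(find_frontdoor_set(fd$graph, "X", "Y"), "Z")
  conf_lat <- scm_preset("confounder", latent_confounder = TRUE)
  id <- identify_effect(conf_lat$graph, "X", "Y")
  expect_true(id$pattern %in% c("frontdoor", "unidentified"))
  expect_false("U" %in% id$auxiliary)
  iv <- scm_preset("instrument")
  expect_equal(identify_effect(iv$graph, "X", "Y")$pattern, "instrument")
})

test_that("the study-shaped preset has the right exposure prevalence", {
  treated <- vapply(1:100, function(s) {
    sim <- simulate_cohort(scm_preset("nlr_like"), 169, seed = 1000 + s)
    sum(sim$X == "1")
  }, 1)
  expect_lt(abs(mean(treated) - 39), 3)
  # and exactly the study's marginal in the exact joint
  t <- exact_joint(scm_preset("nlr_like"))
  expect_equal(pt_prob(t, c(X = "1")), 39 / 169, tolerance = 1e-12)
})

test_that("committed preset fixtures match the code and their ground truth", {
  dir <- system.file("extdata", "presets", package = "doqed")
  for (pattern in c("confounder", "frontdoor", "instrument", "nlr_like")) {
    stem <- gsub("_", "-", pattern)
    spec <- scm_from_json(file.path(dir, paste0("synthetic-", stem, "-scm.json")))
    fresh <- scm_preset(pattern)
    expect_equal(spec$mechanisms, fresh$mechanisms, tolerance = 1e-15)
    gt_file <- jsonlite::fromJSON(
      file.path(dir, paste0("synthetic-", stem, "-ground-truth.json")))
    gt <- ground_truth_ace(spec, "X", "Y")
    expect_equal(gt$ace, gt_file$ace, tolerance = 1e-12)
    expect_equal(gt$p_do_control, gt_file$p_do_control, tolerance = 1e-12)
  }
})

test_that("malformed mechanisms are rejected", {
  g <- causal_graph(list(c("X", "Y")))
  expect_error(scm_spec(g, list(X = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1)))),
               "missing mechanism")
  expect_error(
    scm_spec(g, list(
      X = scm_mechanism(b01, probs = matrix(c(0.5, 0.5), 1)),
      Y = scm_mechanism(b01, "X", list(X = b01), probs = rbind(c(0.5, 0.6), c(0.5, 0.5))))),
    "sum to 1")
  expect_error(scm_mechanism(b01, probs = matrix(c(-0.1, 1.1), 1)), "malformed")
})
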