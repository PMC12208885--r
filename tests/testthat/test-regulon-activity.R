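test_that("balanced sampling returns exact per-type counts deterministically", {
  ct <- rep(c("A", "B", "C", "D", "E"), times = c(700, 600, 500, 500, 300))
  idx <- suppressWarnings(sample_balanced(ct, 500, seed = 2))
  expect_length(idx, 2500)
  expect_true(all(table(ct[idx]) == 500))
  expect_warning(sample_balanced(ct, 500, seed = 2), "replacement")
  expect_identical(suppressWarnings(sample_balanced(ct, 500, seed = 2)),
                   suppressWarnings(sample_balanced(ct, 500, seed = 2)))
  expect_error(sample_balanced(factor(c("A", "A"), levels = c("A", "B")), 2),
               "no cells")
  expect_error(sample_balanced(character(0), 10), "no cells")
})

test_that("correlation discovery recovers planted targets and drops null TFs", {
  spec <- list(list(tf_id = "TFA", n_targets = 50L, r = 0.8),
               list(tf_id = "TFnull", n_targets = 0L, r = 0))
  sim <- simulate_expression(expression_sim_config(
    n_cell_types = 5, n_cells_per_type = 400, n_genes = 300,
    tf_specs = spec, seed = 11))
  regs <- discover_regulons(sim$lognorm, c("TFA", "TFnull"), seed = 11)
  expect_true("TFA" %in% names(regs))
  expect_gte(length(intersect(regs$TFA$targets, sim$regulons$TFA$targets)), 45)
  expect_lte(length(setdiff(regs$TFA$targets, sim$regulons$TFA$targets)), 2)
  # independent TF yields no regulon
  expect_false("TFnull" %in% names(regs))
  # constant gene: jitter gives a defined (near-zero) correlation, no target
  Xc <- sim$lognorm
  Xc[, 5] <- 1
  regs2 <- discover_regulons(Xc, "TFA", seed = 11)
  expect_false(colnames(Xc)[5] %in% regs2$TFA$targets)
  expect_warning(discover_regulons(sim$lognorm, "absent", seed = 1),
                 "absent")
})

test_that("recovery score hits its closed-form extremes and uniform expectation", {
  G <- 200
  genes <- sprintf("g%03d", 1:G)
  # targets at the very top of every cell -> score 1
  X <- matrix(rnorm(50 * G), 50, G,
              dimnames = list(sprintf("c%02d", 1:50), genes))
  tg <- genes[1:8]
  X[, tg] <- X[, tg] + 100
  reg <- list(regulon("tf", tg))
  expect_equal(unname(score_regulons(X, reg)[, 1]), rep(1, 50))
  # regulon covering all genes -> saturation at 1
  reg_all <- list(regulon("tfx", genes))
  expect_equal(unname(score_regulons(X, reg_all)[, 1]), rep(1, 50))

  # uniformly scattered targets: E[raw] = m T(T+1) / (2G), normalized
  set.seed(3)
  n <- 1000
  Xr <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
  m <- 10; Tn <- floor(0.05 * G)
  reg_u <- list(regulon("tfu", sample(genes, m)))
  expected <- (m * Tn * (Tn + 1) / (2 * G)) /
    (m * (m + 1) / 2 + m * (Tn - m))
  expect_lt(abs(mean(score_regulons(Xr, reg_u)[, 1]) - expected), 0.02)

  # rank-based: any strictly monotone per-cell transform leaves scores fixed
  s1 <- score_regulons(Xr, reg_u)
  s2 <- score_regulons(exp(2 * Xr) + 5, reg_u)
  expect_equal(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_error(score_regulons(Xr, list()), "no regulons")
})

test_that("stability filter keeps structured regulons and discards noise", {
  sim <- make_planted_sim(17, n_planted = 2, n_decoys = 1, n_types = 5,
                          n_cells_per_type = 200, n_genes = 300,
                          n_targets = 20, r = 0.8)
  st <- stability_filter(sim$lognorm, sim$cell_type,
                         c(sim$planted, sim$decoys), seed = 17)
  expect_true(all(sim$planted %in% st$retained))
  expect_false(any(sim$decoys %in% st$retained))
  expect_true(all(st$report$p[st$report$tf %in% sim$planted] < 0.001))

  # a pure-noise regulon forced through a fixed backend is discarded
  noise_backend <- function(X, tfs, seed) {
    list(regulon("noise_tf", colnames(X)[10:29]))
  }
  set.seed(99)
  Xn <- matrix(rnorm(240 * 60), 240, 60,
               dimnames = list(NULL, sprintf("g%02d", 1:60)))
  ctn <- rep(paste0("t", 1:4), each = 60)
  discarded <- vapply(1:50, function(b) {
    st0 <- stability_filter(Xn, ctn, "noise_tf", n_splits = 10,
                            seed = 1000 + b, backend = noise_backend)
    !"noise_tf" %in% st0$retained
  }, logical(1))
  expect_gte(mean(discarded), 0.95)

  expect_error(stability_filter(sim$lognorm, rep("A", nrow(sim$lognorm)),
                                "TF01"), ">= 3 cell types")
  expect_error(stability_filter(sim$lognorm, sim$cell_type, "TF01",
                                n_splits = 0), "n_splits")
})

test_that("one-way R2 matches hand ANOVA, lm, and null expectation", {
  # A: {0, 2}, B: {1, 3} -> SST 5, SSE 4, R2 = 0.2 exactly
  expect_equal(unname(r2_one_way(c(0, 2, 1, 3), c("A", "A", "B", "B"))), 0.2)
  # perfect separation -> exactly 1
  expect_equal(unname(r2_one_way(c(1, 1, 2, 2), c("A", "A", "B", "B"))), 1)
  # cross-check against lm on arbitrary data
  set.seed(8)
  y <- rnorm(120); g <- sample(letters[1:4], 120, TRUE)
  expect_equal(unname(r2_one_way(y, g)),
               summary(lm(y ~ g))$r.squared, tolerance = 1e-12)
  # affine invariance
  expect_equal(r2_one_way(3 * y + 7, g), r2_one_way(y, g))
  # iid null: E[R2] ~ (k-1)/(n-1) << 0.5
  set.seed(9)
  sc <- matrix(runif(2500 * 4), 2500, 4,
               dimnames = list(NULL, paste0("r", 1:4)))
  ct <- rep(paste0("t", 1:5), each = 500)
  dn <- discriminability_filter(sc, ct, n_reps = 20, n_per_type = 500,
                                seed = 5)
  expect_lt(max(dn$mean_r2), 0.05)
  expect_length(dn$retained, 0)
  expect_error(discriminability_filter(sc, rep("t1", 2500)), ">= 2 cell")
})

test_that("projection onto new populations is consistent and overlap-guarded", {
  sim <- make_planted_sim(23, n_planted = 2, n_decoys = 0, n_types = 4,
                          n_cells_per_type = 150, n_genes = 300,
                          n_targets = 15, r = 0.8)
  regs <- discover_regulons(sim$lognorm, sim$planted, seed = 23)
  ref_scores <- score_regulons(sim$lognorm, regs)
  # identical cells -> identical scores
  pr <- project_scores(sim$lognorm, regs, cell_type = sim$cell_type)
  expect_equal(pr$scores, ref_scores)
  expect_equal(dim(pr$type_means), c(4L, length(regs)))

  # dropping most targets of a regulon from the universe is an error
  drop <- regs[[1]]$targets[-1]
  X2 <- sim$lognorm[, setdiff(colnames(sim$lognorm), drop)]
  expect_error(project_scores(X2, regs), "overlap")
  expect_warning(project_scores(X2, regs, on_low_overlap = "warn"),
                 "overlap")

  # a planted activated module in a new population scores above reference types
  act <- sim$lognorm
  tf <- names(regs)[1]
  act[, c(tf, regs[[tf]]$targets)] <- act[, c(tf, regs[[tf]]$targets)] + 5
  pr2 <- project_scores(act, regs, cell_type = rep("preL", nrow(act)))
  expect_gt(pr2$type_means["preL", tf], max(pr$type_means[, tf]))
})
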