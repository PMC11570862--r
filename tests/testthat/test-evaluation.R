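test_that("chain-centric split reproduces the benchmark subset sizes", {
  keys <- sprintf("pdb%03d_%s", 1:376, rep(c("A", "B"), 188))
  sp <- chain_centric_split(keys, c(0.503, 0.255, 0.242), seed = 11)
  expect_equal(unname(sp$sizes), c(189, 96, 91))
  expect_equal(unname(round(100 * sp$fractions_achieved, 1)),
               c(50.3, 25.5, 24.2))
})

test_that("splits are complete, disjoint and deterministic", {
  keys <- sprintf("k%02d", 1:40)
  expect_true(all(chain_centric_split(keys, c(1, 0, 0))$assignment == "train"))
  s1 <- chain_centric_split(keys, seed = 5)
  s2 <- chain_centric_split(keys, seed = 5)
  expect_identical(s1$assignment, s2$assignment)
  expect_error(chain_centric_split(c("a", "a", "b")), "duplicate")
  expect_error(chain_centric_split(keys, c(0.5, 0.4, 0.2)), "sum to 1")
  for (seed in 1:20) {
    sp <- chain_centric_split(keys, c(0.6, 0.2, 0.2), seed)
    expect_setequal(names(sp$assignment), keys)
    expect_equal(sum(sp$sizes), 40)
  }
})

test_that("dcc matches toy geometry and independent arithmetic", {
  s <- mk_structure(mk_atoms(c(0, 0, 0,  3, 4, 0,  1, 1, 1), res_seq = 1:3))
  ids <- names(polymer_residues(s))
  expect_equal(dcc(ids[1], ids[1], s), 0)
  expect_equal(dcc(ids[1], ids[2], s), 5)
  expect_equal(dcc(ids[2], ids[1], s), dcc(ids[1], ids[2], s))
  expect_true(is.na(dcc(character(0), ids[1], s)))
  expect_error(dcc("nope", ids[1], s), "missing from structure")
  # random sets vs direct centroid arithmetic
  fx <- make_labelled_fixture(seed = 17, id = "dc")
  res <- polymer_residues(fx)
  set.seed(4)
  for (rep in 1:5) {
    A <- sample(names(res), 4); B <- sample(names(res), 3)
    ca <- colMeans(do.call(rbind, lapply(res[A], function(r)
      cbind(r$x, r$y, r$z))))
    cb <- colMeans(do.call(rbind, lapply(res[B], function(r)
      cbind(r$x, r$y, r$z))))
    expect_equal(dcc(A, B, fx), sqrt(sum((ca - cb)^2)), tolerance = 1e-9)
  }
})

test_that("success_rate honours cutoff and the undefined policy", {
  expect_equal(success_rate(c(0.5, 3.9, 4.1)), 200 / 3)
  expect_equal(success_rate(c(NA, NA), undefined_policy = "count_as_failure"), 0)
  expect_error(success_rate(numeric(0)), "empty")
  set.seed(9)
  v <- c(runif(180, 0, 10), rep(NA, 20))
  expect_equal(success_rate(v, 4, "exclude"),
               100 * sum(v <= 4, na.rm = TRUE) / 180)
  expect_equal(success_rate(v, 4, "count_as_failure"),
               100 * sum(v <= 4, na.rm = TRUE) / 200)
})

test_that("classification metrics reproduce printed and derived values", {
  # printed benchmark rows: F1 from precision/recall
  expect_equal(round(f1_score(1.0000, 0.6800), 4), 0.8095)
  expect_equal(round(f1_score(0.8276, 0.6667), 4), 0.7385)
  expect_equal(round(f1_score(0.8704, 0.6104), 4), 0.7176)
  # perfect prediction
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(m$f1, 1); expect_equal(m$mcc, 1); expect_equal(m$roc_auc, 1)
  # direct formula evaluation from counts
  m2 <- metrics_from_counts(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(m2$f1, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_equal(m2$mcc, 10 / sqrt(600))
  expect_equal(m2$accuracy, 0.7)
  expect_error(classification_metrics(c(1, 0), 0.5), "length mismatch")
})

test_that("roc_auc equals the Mann-Whitney statistic", {
  set.seed(12)
  y <- rbinom(200, 1, 0.3)
  s <- rnorm(200) + y
  w <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE)
  expect_equal(roc_auc(y, s),
               unname(w$statistic) / (sum(y == 1) * sum(y == 0)))
})

test_that("pocket coverage reproduces the published arithmetic", {
  expect_equal(round(percent_outside(6087, 1364), 2), 18.31)
  expect_equal(round(percent_outside(3286, 4165), 2), 55.90)
  afr <- list(c1 = c("r1", "r2"), c2 = "r3")
  pk <- list(c1 = list(p1 = c("r1", "r2")), c2 = list(p1 = "r3"))
  pc <- pocket_coverage(afr, pk)
  expect_equal(pc$percent_out, 0)
  expect_warning(pc2 <- pocket_coverage(afr, pk["c1"]), "no pockets")
  expect_equal(pc2$n_out, 1)
})

test_that("pocket set TSV importer round-trips", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tpocket_id\tidentity",
               "c1\t1\tr1", "c1\t1\tr2", "c1\t2\tr9", "c2\t1\tr3"), p)
  ps <- read_pocket_sets(p)
  expect_equal(names(ps), c("c1", "c2"))
  expect_length(ps$c1, 2)
  expect_equal(ps$c1[["1"]], c("r1", "r2"))
})
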