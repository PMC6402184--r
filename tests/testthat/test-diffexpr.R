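test_that("rpkm follows its definition", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  # independent recomputation of the formula on an arbitrary tuple
  expect_equal(rpkm(7, 1234, 3.1e7), 7 * 1e9 / (1234 * 3.1e7))
  expect_equal(rpkm(c(1, 2), 100, 1e6), c(10, 20))
  expect_error(rpkm(1, 0, 1e6), "positive")
  expect_error(rpkm(1, 100, 0), "positive")
})

test_that("ac_pvalue matches its closed-form cases", {
  for (x in c(0, 1, 7, 50, 1234))
    expect_equal(ac_pvalue(x, x, 5e5, 5e5), 1)
  # x=0, y=10, equal libraries: conditional is Geometric(1/2);
  # P(Y >= 10) = 2^-10, doubled
  expect_equal(ac_pvalue(0, 10, 1, 1), 2^-9)
  expect_equal(ac_pvalue(0, 10, 3e6, 3e6), 2^-9)
})

test_that("ac_pvalue equals the negative-binomial tail oracle", {
  set.seed(101)
  for (i in 1:200) {
    x <- sample(0:30, 1)
    y <- sample(0:30, 1)
    N1 <- 1e5
    N2 <- N1 * sample(c(0.5, 1, 2), 1)
    expect_equal(ac_pvalue(x, y, N1, N2), ac_oracle(x, y, N1, N2),
                 tolerance = 1e-12)
  }
})

test_that("ac_pvalue swap symmetry holds up to the discrete point mass", {
  # The doubled-min-tail two-sided p cannot be exactly invariant under
  # (x, N1) <-> (y, N2) because both tails include the observed count:
  # the two conditioning directions differ by exactly that point mass.
  set.seed(202)
  for (i in 1:100) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    N1 <- sample(1:5, 1) * 1e5; N2 <- sample(1:5, 1) * 1e5
    p1 <- ac_pvalue(x, y, N1, N2)
    p2 <- ac_pvalue(y, x, N2, N1)
    bound <- 2 * max(stats::dnbinom(y, size = x + 1, prob = N1 / (N1 + N2)),
                     stats::dnbinom(x, size = y + 1, prob = N2 / (N1 + N2)))
    expect_lte(abs(p1 - p2), bound + 1e-12)
  }
})

test_that("ac_pvalue is vectorised and validates input", {
  expect_equal(ac_pvalue(c(0, 5), c(10, 5), 1, 1),
               c(ac_pvalue(0, 10, 1, 1), 1))
  expect_error(ac_pvalue(-1, 2), "non-negative")
  expect_error(ac_pvalue(2.5, 2), "non-negative")
  expect_error(ac_pvalue(1, 2, 0, 1), "positive")
})

test_that("bh_adjust is the BH step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(303)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone-consistent with sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("classify_de applies the class screening standards", {
  expect_equal(classify_de(0.5, 1e-9, "lncRNA"), "ns")   # effect-size gate
  expect_equal(classify_de(2, 0.01, "lncRNA"), "ns")     # q gate 0.001
  expect_equal(classify_de(2, 0.01, "miRNA"), "up")      # q gate 0.05
  expect_equal(classify_de(-2, 1e-5, "mRNA"), "down")
  expect_equal(classify_de(c(2, -2), c(1e-5, 1e-5), c("mRNA", "mRNA")),
               c("up", "down"))
  expect_error(classify_de(1, 0.5, "protein"), "configuration error")
})

make_cm <- function(counts, group) {
  count_matrix(counts, group = group,
               feature_class = rep("mRNA", nrow(counts)),
               feature_length = rep(1000, nrow(counts)),
               library_size = rep(1e6, ncol(counts)))
}

test_that("run_de handles all-zero features and antisymmetry", {
  set.seed(404)
  counts <- matrix(rpois(40, 50), 4, 10,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  counts[1, ] <- 0
  counts[2, 6:10] <- counts[2, 6:10] + 500
  grp <- rep(c("control", "case"), each = 5)
  de <- run_de(make_cm(counts, grp))
  z <- de[de$feature_id == "g1", ]
  expect_equal(z$p, 1)
  expect_equal(z$direction, "ns")
  expect_equal(z$log2fc, 0)
  # swapping group labels flips every direction
  de2 <- run_de(make_cm(counts, rev(grp)))
  flip <- c(up = "down", down = "up", ns = "ns")
  m <- match(de$feature_id, de2$feature_id)
  expect_equal(unname(flip[de$direction]), de2$direction[m])
  # p-values agree only up to the observed point mass (both two-sided
  # tails include the observed count, so the two conditioning directions
  # differ by exactly that pmf)
  xs <- rowSums(counts[de$feature_id, 1:5])
  ys <- rowSums(counts[de$feature_id, 6:10])
  bound <- 2 * pmax(stats::dnbinom(ys, size = xs + 1, prob = 0.5),
                    stats::dnbinom(xs, size = ys + 1, prob = 0.5))
  expect_true(all(abs(de$p - de2$p[m]) <= bound + 1e-12))
})

test_that("run_de is invariant to pre-pooling the samples", {
  set.seed(505)
  counts <- matrix(rpois(100, 80), 10, 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  grp <- rep(c("control", "case"), each = 5)
  cm <- make_cm(counts, grp)
  pooled <- pool_samples(cm, grp)
  expect_equal(ncol(pooled$counts), 2)
  de1 <- run_de(cm)
  de2 <- run_de(pooled)
  expect_equal(de1$p, de2$p)
  expect_equal(de1$log2fc, de2$log2fc)
})

test_that("run_de skips features without a valid length", {
  counts <- matrix(10, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm <- count_matrix(counts, group = rep(c("case", "control"), each = 2),
                     feature_class = c("mRNA", "mRNA"),
                     feature_length = c(1000, NA))
  expect_warning(de <- run_de(cm), "skipped")
  expect_equal(de$feature_id, "a")
})

test_that("planted simulation recovery is reported against the manifest", {
  cfg <- sim_config(seed = 5, n_lncrna = 60, n_mirna = 20, n_mrna = 120,
                    n_samples_per_group = 5, de_fraction = 0.1,
                    planted_log2fc = 2, nb_dispersion = 0,
                    baseline_mean = 100)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$counts)
  rec <- de_recovery(de, sim$truth)
  expect_equal(rec$n_true, nrow(sim$truth$de))
  expect_gte(rec$sensitivity, 0)
  expect_lte(rec$sensitivity, 1)
  expect_gte(rec$fdr, 0)
  expect_lte(rec$fdr, 1)
  # q-values within each class must match the oracle on the reported p
  for (cl in unique(de$class)) {
    sel <- de$class == cl
    expect_equal(de$q[sel], bh_oracle(de$p[sel]), tolerance = 1e-12)
  }
})
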